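# ---- Copy-number heterogeneity: gains/losses, GII, WGD, Jaccard ITH ---------

GAIN_LOG2 <- log2(2.5 / 2)
LOSS_LOG2 <- log2(1.5 / 2)

#' Call gain/loss relative to ploidy
#'
#' log_ratio = log2(total_cn / ploidy); gain iff log_ratio >= log2(2.5/2),
#' loss iff log_ratio < log2(1.5/2), otherwise neutral.
#'
#' @param total_cn total copy number (vectorized).
#' @param ploidy region ploidy (> 0).
#' @return character vector in {"gain","neutral","loss"}.
#' @export
call_gain_loss <- function(total_cn, ploidy) {
  if (any(ploidy <= 0)) stop("ploidy must be > 0")
  if (any(total_cn < 0)) stop("total_cn must be >= 0")
  lr <- suppressWarnings(log2(total_cn / ploidy))
  lr[total_cn == 0] <- -Inf
  ifelse(lr >= GAIN_LOG2, "gain", ifelse(lr < LOSS_LOG2, "loss", "neutral"))
}

seg_lengths <- function(segs) as.double(segs$end) - as.double(segs$start) + 1

check_seg_bounds <- function(segs) {
  lens <- hg19_contigs()
  if (any(segs$end > lens[segs$chrom])) {
    stop("segment extends past contig end")
  }
}

#' Genome instability index for one region
#'
#' Total length of gained plus lost segments divided by the autosomal
#' genome size. The patient-level GII is the mean over regions
#' ([gii_patient()]).
#'
#' @param segs [segments_cn()] for one region.
#' @param ploidy region ploidy.
#' @param genome_size_bp denominator (default the hg19 autosomal genome).
#' @param include_sex include X/Y segments (default FALSE).
#' @return fraction in [0,1].
#' @export
gii_region <- function(segs, ploidy, genome_size_bp = autosome_size(),
                       include_sex = FALSE) {
  if (genome_size_bp <= 0) stop("genome_size_bp must be > 0")
  segs <- as.data.frame(segs)
  if (!include_sex) segs <- segs[!segs$chrom %in% c("X", "Y"), , drop = FALSE]
  if (!nrow(segs)) return(0)
  check_seg_bounds(segs)
  call <- call_gain_loss(segs$total_cn, ploidy)
  sum(seg_lengths(segs)[call != "neutral"]) / genome_size_bp
}

#' Patient-level genome instability index (mean over regions)
#'
#' @param segs [segments_cn()] for one patient.
#' @param profiles [region_profiles()] for the same patient.
#' @param ... passed to [gii_region()].
#' @return mean regional GII.
#' @export
gii_patient <- function(segs, profiles, ...) {
  vals <- vapply(profiles$region_id, function(r) {
    gii_region(segs[segs$region_id == r, , drop = FALSE],
               profiles$ploidy[profiles$region_id == r], ...)
  }, numeric(1))
  mean(vals)
}

#' Whole-genome doubling detection by permutation
#'
#' Observed statistic: length-weighted fraction of the autosomal genome
#' with major allele copy number >= 2. Null distribution: `n_sim` genomes
#' built by randomly re-pairing the segments' (major, minor) states with
#' the segment lengths (a length-preserving permutation), with
#' p = (1 + #\{sim >= observed\}) / (n_sim + 1). The ploidy class comes
#' from the length-weighted mean total copy number, rounded; the class
#' thresholds are p <= 0.001 up to triploid, p <= 0.05 for tetraploid,
#' p <= 0.5 for pentaploid and p <= 1 at hexaploid or above. A fully
#' doubled genome (statistic 1.0) with rounded ploidy >= 4 is reported as
#' WGD directly, since every permutation then reproduces the observed
#' statistic and the permutation p is uninformative.
#'
#' @param segs [segments_cn()] for one region.
#' @param n_sim number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list of class `wgd_result`: is_wgd, p_value, ploidy_class,
#'   observed_statistic, mean_ploidy, n_sim, seed.
#' @export
detect_wgd <- function(segs, n_sim = 10000, seed = 1) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  segs <- as.data.frame(segs)
  segs <- segs[!segs$chrom %in% c("X", "Y"), , drop = FALSE]
  if (!nrow(segs)) {
    warning("no autosomal segments; WGD undefined")
    return(structure(list(is_wgd = NA, p_value = NA_real_,
                          ploidy_class = NA_character_,
                          observed_statistic = NA_real_,
                          mean_ploidy = NA_real_, n_sim = n_sim, seed = seed),
                     class = "wgd_result"))
  }
  len <- seg_lengths(segs)
  w <- len / sum(len)
  state <- as.integer(segs$major_cn >= 2)
  observed <- sum(w * state)
  mean_ploidy <- sum(w * segs$total_cn)
  pl <- round(mean_ploidy)
  ploidy_class <- if (pl <= 3) "<=triploid" else if (pl == 4) "tetraploid"
    else if (pl == 5) "pentaploid" else ">=hexaploid"
  threshold <- switch(ploidy_class, "<=triploid" = 0.001,
                      "tetraploid" = 0.05, "pentaploid" = 0.5,
                      ">=hexaploid" = 1)
  p <- with_seed(seed, function() {
    sims <- vapply(seq_len(n_sim), function(i) sum(w * sample(state)),
                   numeric(1))
    (1 + sum(sims >= observed - 1e-12)) / (n_sim + 1)
  })
  is_wgd <- p <= threshold
  if (observed >= 1 - 1e-12 && pl >= 4) is_wgd <- TRUE
  structure(list(is_wgd = is_wgd, p_value = p, ploidy_class = ploidy_class,
                 observed_statistic = observed, mean_ploidy = mean_ploidy,
                 n_sim = n_sim, seed = seed),
            class = "wgd_result")
}

#' Project segments onto fixed genomic bins
#'
#' Cross-region CNV comparison needs a common universe; regions are
#' segmented independently, so segments are projected onto fixed bins
#' (default 10 Mb) per autosome. A bin takes the direction (gain/loss)
#' that covers the majority of its segment-covered length; LOH is flagged
#' when LOH segments (minor_cn = 0, total > 0) cover the majority.
#'
#' @param segs [segments_cn()] for one region.
#' @param ploidy region ploidy (for gain/loss calls).
#' @param bin_size bin width in bp (default 1e7).
#' @return data.frame: bin (chrom:start), chrom, start, end, direction
#'   ("gain"/"loss"/"neutral"), loh; only bins with segment coverage.
#' @export
bin_cnv_events <- function(segs, ploidy, bin_size = 1e7) {
  segs <- as.data.frame(segs)
  segs <- segs[!segs$chrom %in% c("X", "Y"), , drop = FALSE]
  if (!nrow(segs)) {
    return(data.frame(bin = character(), chrom = character(),
                      start = integer(), end = integer(),
                      direction = character(), loh = logical(),
                      stringsAsFactors = FALSE))
  }
  call <- call_gain_loss(segs$total_cn, ploidy)
  loh <- segs$minor_cn == 0 & segs$total_cn > 0
  out <- list()
  for (ch in unique(segs$chrom)) {
    s <- which(segs$chrom == ch)
    clen <- hg19_contigs()[[ch]]
    starts <- seq(1, clen, by = bin_size)
    for (bs in starts) {
      be <- min(bs + bin_size - 1, clen)
      ov <- pmin(segs$end[s], be) - pmax(segs$start[s], bs) + 1
      hit <- ov > 0
      if (!any(hit)) next
      ovl <- ov[hit]; cl <- call[s][hit]; lo <- loh[s][hit]
      covered <- sum(ovl)
      dir_len <- c(gain = sum(ovl[cl == "gain"]),
                   loss = sum(ovl[cl == "loss"]),
                   neutral = sum(ovl[cl == "neutral"]))
      direction <- names(dir_len)[which.max(dir_len)]
      if (dir_len[[direction]] <= covered / 2 && direction != "neutral") {
        direction <- "neutral"
      }
      out[[length(out) + 1L]] <- data.frame(
        bin = sprintf("%s:%d", ch, bs), chrom = ch,
        start = as.integer(bs), end = as.integer(be),
        direction = direction, loh = sum(ovl[lo]) > covered / 2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Classify CNV events as clonal or subclonal across regions
#'
#' On a common binning: a (bin, gain) event is clonal iff every region
#' shows gain at that bin, subclonal if gain appears in at least one but
#' not all regions. A (bin, loss) event is clonal iff every region shows
#' loss or LOH at the bin; otherwise subclonal.
#'
#' @param events named list (one entry per region) of data.frames from
#'   [bin_cnv_events()].
#' @return data.frame: bin, direction, n_regions_with_event, clonality.
#' @export
classify_cnv_clonality <- function(events) {
  if (length(events) < 2) stop("need >= 2 regions")
  if (is.null(names(events)) || any(!nzchar(names(events)))) {
    stop("events list must be named by region")
  }
  n_regions <- length(events)
  gain_bins <- lapply(events, function(e) e$bin[e$direction == "gain"])
  loss_bins <- lapply(events, function(e) e$bin[e$direction == "loss"])
  loh_bins <- lapply(events, function(e) e$bin[e$loh])
  rows <- list()
  for (b in unique(unlist(gain_bins))) {
    n <- sum(vapply(gain_bins, function(g) b %in% g, logical(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      bin = b, direction = "gain", n_regions_with_event = n,
      clonality = if (n == n_regions) "clonal" else "subclonal",
      stringsAsFactors = FALSE)
  }
  for (b in unique(unlist(loss_bins))) {
    n <- sum(vapply(loss_bins, function(g) b %in% g, logical(1)))
    covered <- vapply(seq_len(n_regions), function(i) {
      b %in% loss_bins[[i]] || b %in% loh_bins[[i]]
    }, logical(1))
    rows[[length(rows) + 1L]] <- data.frame(
      bin = b, direction = "loss", n_regions_with_event = n,
      clonality = if (all(covered)) "clonal" else "subclonal",
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(bin = character(), direction = character(),
                      n_regions_with_event = integer(),
                      clonality = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' CNV intratumor heterogeneity (mean pairwise Jaccard distance)
#'
#' Events are keyed by (bin, direction); for each pair of regions the
#' Jaccard distance 1 - |A n B| / |A u B| is computed and the mean over
#' all pairs returned. A pair whose union is empty contributes 0.
#'
#' @param event_sets named list (one per region, >= 2) of character
#'   vectors of event keys, e.g. "1:10000001:gain".
#' @return fraction in [0,1]; NA with a warning for a single region.
#' @export
cnv_ith <- function(event_sets) {
  if (length(event_sets) < 2) {
    warning("cnv_ith undefined for a single region")
    return(NA_real_)
  }
  sets <- lapply(event_sets, unique)
  pairs <- utils::combn(length(sets), 2)
  d <- apply(pairs, 2, function(ij) {
    a <- sets[[ij[1]]]; b <- sets[[ij[2]]]
    u <- union(a, b)
    if (!length(u)) return(0)
    1 - length(intersect(a, b)) / length(u)
  })
  mean(d)
}

#' Event keys for [cnv_ith()] from binned events
#' @param events data.frame from [bin_cnv_events()].
#' @return character vector of "bin:direction" keys (gain/loss only).
#' @export
cnv_event_keys <- function(events) {
  e <- events[events$direction %in% c("gain", "loss"), , drop = FALSE]
  paste(e$bin, e$direction, sep = ":")
}
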