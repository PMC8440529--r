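# ---- Post-calling somatic filters and cross-region rescue -------------------

#' Somatic filter parameters
#'
#' Defaults follow the usual post-calling criteria for FFPE exome cohorts:
#' at least 5 mutant reads, normal depth >= 10, tumor depth > 30 is relaxed
#' here to >= 30 via `min_tumor_depth`, VAF >= 3%, population allele
#' frequency <= 1%. Rescue across regions requires VAF > 1% and fewer than
#' 5 mutant reads in the matched normal.
#'
#' @param min_alt_reads minimum tumor mutant reads (default 5).
#' @param min_normal_depth minimum matched-normal depth (default 10).
#' @param min_tumor_depth minimum tumor depth (default 30).
#' @param min_vaf minimum tumor VAF (default 0.03).
#' @param max_population_af maximum population allele frequency (default 0.01).
#' @param rescue_min_vaf rescue VAF threshold, exclusive (default 0.01).
#' @param rescue_max_normal_alt rescue normal mutant-read bound, exclusive
#'   (default 5).
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_alt_reads = 5, min_normal_depth = 10,
                          min_tumor_depth = 30, min_vaf = 0.03,
                          max_population_af = 0.01, rescue_min_vaf = 0.01,
                          rescue_max_normal_alt = 5) {
  p <- list(min_alt_reads = min_alt_reads, min_normal_depth = min_normal_depth,
            min_tumor_depth = min_tumor_depth, min_vaf = min_vaf,
            max_population_af = max_population_af,
            rescue_min_vaf = rescue_min_vaf,
            rescue_max_normal_alt = rescue_max_normal_alt)
  if (any(unlist(p) < 0)) stop("filter thresholds must be >= 0")
  if (min_vaf <= rescue_min_vaf) stop("min_vaf must exceed rescue_min_vaf")
  class(p) <- "filter_params"
  p
}

#' Apply post-calling somatic filters
#'
#' Retains exactly the calls with alt_reads >= min_alt_reads, normal_depth
#' >= min_normal_depth, tumor depth >= min_tumor_depth, VAF >= min_vaf and
#' population_af <= max_population_af. Order is preserved. Per-rule
#' rejection counts are attached as attribute "rejections" (a call failing
#' several rules counts once per rule).
#'
#' @param calls a [mutation_calls()] data.frame.
#' @param params a [filter_params()] list.
#' @return filtered [mutation_calls()] data.frame.
#' @export
apply_somatic_filters <- function(calls, params = filter_params()) {
  calls <- mutation_calls(calls)
  depth <- calls$alt_reads + calls$ref_reads
  vaf <- ifelse(depth > 0, calls$alt_reads / depth, 0)
  fail <- cbind(
    alt_reads = calls$alt_reads < params$min_alt_reads,
    normal_depth = calls$normal_depth < params$min_normal_depth,
    tumor_depth = depth < params$min_tumor_depth,
    vaf = vaf < params$min_vaf,
    population_af = calls$population_af > params$max_population_af
  )
  keep <- !apply(fail, 1, any)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejections") <- colSums(fail, na.rm = TRUE)
  mrith_log("filters", "%d in, %d retained", nrow(calls), nrow(out))
  out
}

#' Rescue mutations across regions of one patient
#'
#' A variant that passed filters in at least one region of a patient but
#' not in all of them is looked up in the raw pileups of the remaining
#' regions and added there iff its local VAF exceeds `rescue_min_vaf`
#' (strict) and its normal mutant-read count is below
#' `rescue_max_normal_alt` (strict). Rescued records carry rescued = TRUE.
#' Rescue never removes a call and never introduces a variant absent from
#' every region.
#'
#' @param calls filtered [mutation_calls()] for one patient (>= 1 region).
#' @param pileups data.frame of raw counts at candidate loci with columns
#'   region_id, chrom, pos, ref, alt, alt_reads, ref_reads,
#'   normal_alt_reads, normal_depth. Loci missing from the pileups are
#'   treated as absent (with a warning).
#' @param params a [filter_params()] list.
#' @param regions optional character vector of all region ids for the
#'   patient; default the union of regions seen in `calls` and `pileups`.
#' @return augmented [mutation_calls()] data.frame.
#' @export
rescue_cross_region <- function(calls, pileups, params = filter_params(),
                                regions = NULL) {
  calls <- mutation_calls(calls)
  if (is.null(regions)) {
    regions <- sort(unique(c(calls$region_id, pileups$region_id)))
  }
  if (length(unique(calls$patient_id)) > 1) {
    stop("rescue_cross_region expects calls from a single patient")
  }
  vkey <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  key <- vkey(calls)
  pkey <- paste(vkey(pileups), pileups$region_id, sep = "@")
  added <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    have <- unique(calls$region_id[rows])
    need <- setdiff(regions, have)
    if (!length(need)) next
    proto <- calls[rows[1], , drop = FALSE]
    for (r in need) {
      i <- match(paste(k, r, sep = "@"), pkey)
      if (is.na(i)) {
        warning(sprintf("no pileup for %s in region %s; treated as absent", k, r))
        next
      }
      d <- pileups$alt_reads[i] + pileups$ref_reads[i]
      v <- if (d > 0) pileups$alt_reads[i] / d else 0
      if (v > params$rescue_min_vaf &&
          pileups$normal_alt_reads[i] < params$rescue_max_normal_alt) {
        rec <- proto
        rec$region_id <- r
        rec$alt_reads <- pileups$alt_reads[i]
        rec$ref_reads <- pileups$ref_reads[i]
        rec$normal_alt_reads <- pileups$normal_alt_reads[i]
        rec$normal_depth <- pileups$normal_depth[i]
        rec$rescued <- TRUE
        added[[length(added) + 1L]] <- rec
      }
    }
  }
  if (length(added)) {
    out <- mutation_calls(rbind(as.data.frame(calls),
                                do.call(rbind, added)))
  } else {
    out <- calls
  }
  mrith_log("rescue", "%d rescued records", length(added))
  out
}
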