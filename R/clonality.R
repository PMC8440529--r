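# ---- CCF estimation, mutation clustering, SNV ITH and TMB ------------------

#' Mutation copy number from VAF, purity and local copy number
#'
#' mut_cn = vaf * (purity * tumor_cn + (1 - purity) * normal_cn) / purity.
#' Linear in VAF; equals 2 * vaf for a pure diploid tumor.
#'
#' @param vaf variant allele frequency in [0,1].
#' @param purity tumor purity in (0,1].
#' @param tumor_cn local total copy number in the tumor.
#' @param normal_cn local copy number in the normal (default 2).
#' @return numeric mutation copy number.
#' @export
mutation_copy_number <- function(vaf, purity, tumor_cn, normal_cn = 2) {
  if (any(purity <= 0 | purity > 1)) stop("purity must lie in (0,1]")
  if (any(tumor_cn < 0)) stop("tumor_cn must be >= 0")
  vaf * (purity * tumor_cn + (1 - purity) * normal_cn) / purity
}

#' Multiplicity and cancer cell fraction from mutation copy number
#'
#' multiplicity = round(mut_cn) clamped to [1, max(major_cn, 1)];
#' ccf = mut_cn / multiplicity, capped at `cap` (sequencing noise,
#' especially in FFPE material, can push raw CCF above 1). The `capped`
#' flag records where the cap engaged.
#'
#' @param mut_cn mutation copy number.
#' @param major_cn major allele copy number at the site (upper bound for
#'   multiplicity).
#' @param cap CCF cap (default 1.5).
#' @return data.frame with multiplicity, ccf, capped.
#' @export
estimate_ccf <- function(mut_cn, major_cn, cap = 1.5) {
  mult <- pmin(pmax(round(mut_cn), 1), pmax(major_cn, 1))
  ccf <- mut_cn / mult
  capped <- ccf > cap
  ccf[capped] <- cap
  data.frame(multiplicity = as.integer(mult), ccf = ccf, capped = capped)
}

# locate covering segment per (region, chrom, pos); NA when uncovered
match_segment <- function(calls, segs) {
  idx <- rep(NA_integer_, nrow(calls))
  if (!nrow(segs)) return(idx)
  skey <- paste(segs$region_id, segs$chrom)
  ckey <- paste(calls$region_id, calls$chrom)
  for (k in unique(ckey)) {
    rows <- which(ckey == k)
    srows <- which(skey == k)
    if (!length(srows)) next
    for (i in rows) {
      j <- srows[segs$start[srows] <= calls$pos[i] &
                   segs$end[srows] >= calls$pos[i]]
      if (length(j)) idx[i] <- j[1]
    }
  }
  idx
}

#' Per-mutation, per-region CCF table for one patient
#'
#' Joins calls with the covering copy-number segment and the region's
#' purity, then computes mutation copy number, multiplicity and CCF.
#' Sites not covered by any segment are assumed diploid heterozygous
#' (total 2, major 1). Mutations at sites with tumor copy number 0 are
#' excluded with a warning.
#'
#' @param calls [mutation_calls()] for one patient (filtered + rescued).
#' @param segs [segments_cn()] for the same patient.
#' @param profiles [region_profiles()] for the same patient.
#' @param cap CCF cap passed to [estimate_ccf()].
#' @return data.frame: mutation_key, region_id, gene, effect, vaf, depth,
#'   purity, tumor_cn, major_cn, minor_cn, mut_cn, multiplicity, ccf, capped.
#' @export
ccf_table <- function(calls, segs, profiles, cap = 1.5) {
  calls <- mutation_calls(calls)
  if (!nrow(calls)) stop("no mutations")
  pidx <- match(calls$region_id, profiles$region_id)
  if (anyNA(pidx)) stop("region(s) without purity/ploidy profile")
  sidx <- match_segment(calls, segs)
  tumor_cn <- ifelse(is.na(sidx), 2, segs$total_cn[sidx])
  major_cn <- ifelse(is.na(sidx), 1L, segs$major_cn[sidx])
  minor_cn <- ifelse(is.na(sidx), 1L, segs$minor_cn[sidx])
  zero_cn <- tumor_cn == 0
  if (any(zero_cn)) {
    warning(sprintf("%d mutation record(s) at copy-number-0 sites excluded",
                    sum(zero_cn)))
  }
  keep <- !zero_cn
  calls <- calls[keep, , drop = FALSE]
  tumor_cn <- tumor_cn[keep]; major_cn <- major_cn[keep]
  minor_cn <- minor_cn[keep]; pidx <- pidx[keep]
  purity <- profiles$purity[pidx]
  mut_cn <- mutation_copy_number(calls$vaf, purity, tumor_cn)
  est <- estimate_ccf(mut_cn, major_cn, cap = cap)
  vaf_coef <- purity * est$multiplicity /
    (purity * tumor_cn + (1 - purity) * 2)
  data.frame(
    mutation_key = paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":"),
    region_id = calls$region_id,
    gene = calls$gene, effect = calls$effect,
    vaf = calls$vaf, depth = calls$alt_reads + calls$ref_reads,
    purity = purity, tumor_cn = tumor_cn,
    major_cn = major_cn, minor_cn = minor_cn,
    mut_cn = mut_cn,
    multiplicity = est$multiplicity, ccf = est$ccf, capped = est$capped,
    vaf_coef = vaf_coef,
    stringsAsFactors = FALSE
  )
}

#' CCF matrix (mutations x regions) from a CCF table
#'
#' Regions where a mutation was not observed get CCF 0 (absence is an
#' observation of prevalence 0 in that region, in keeping with the
#' clustering model).
#'
#' The depth matrix holds *effective* depths: the CCF is a linear
#' transform of the VAF (ccf = vaf / vaf_coef with vaf_coef =
#' purity * multiplicity / (purity * tumor_cn + (1 - purity) * 2)), so
#' binomial read noise is inflated by 1 / vaf_coef^2 on the CCF scale.
#' The effective depth n_eff = 4 * (ccf/2)(1 - ccf/2) * depth *
#' vaf_coef^2 / (vaf (1 - vaf)) makes the clustering model's
#' Binomial(n_eff, prevalence/2) variance match the actual sampling
#' variance of the CCF estimate.
#'
#' @param tab output of [ccf_table()].
#' @param nonsilent_only restrict to nonsilent mutations (default TRUE,
#'   matching the convention that silent mutations pass through
#'   unclustered).
#' @return list with ccf (matrix) and depth (matrix of effective depths;
#'   the region's median effective depth where unobserved).
#' @export
ccf_matrix <- function(tab, nonsilent_only = TRUE) {
  if (nonsilent_only) tab <- tab[tab$effect == "nonsilent", , drop = FALSE]
  muts <- unique(tab$mutation_key)
  regions <- sort(unique(tab$region_id))
  ccf <- matrix(0, length(muts), length(regions),
                dimnames = list(muts, regions))
  pi_c <- pmin(pmax(tab$ccf, 0.05), 1.4)
  v <- pmin(pmax(tab$vaf, 0.01), 0.99)
  n_eff <- 4 * (pi_c / 2) * (1 - pi_c / 2) * tab$depth * tab$vaf_coef^2 /
    (v * (1 - v))
  n_eff <- pmax(n_eff, 4)
  med_by_region <- tapply(n_eff, tab$region_id, stats::median)
  dep <- matrix(rep(med_by_region[regions], each = length(muts)),
                length(muts), length(regions),
                dimnames = list(muts, regions))
  i <- match(tab$mutation_key, muts)
  j <- match(tab$region_id, regions)
  ccf[cbind(i, j)] <- tab$ccf
  dep[cbind(i, j)] <- n_eff
  list(ccf = ccf, depth = dep)
}

# with_seed: run fn under a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

#' Cluster mutations by CCF across regions (binomial mixture EM)
#'
#' A deterministic stand-in for sampling-based subclonal deconvolution:
#' mutations are assigned to clusters with per-region prevalences by a
#' binomial-likelihood mixture fitted with EM. For each k in 1..k_max the
#' model is fitted from a k-means++-style seeded initialization (best of
#' `n_restarts`), and k is selected by BIC.
#'
#' The observation model treats each entry as y ~ Binomial(n, pi/2) where
#' y approximates the mutant read count implied by the CCF at the entry's
#' depth and pi is the cluster prevalence in that region; the factor 2 maps
#' prevalence to an effective allele fraction on the CCF scale.
#'
#' @param ccf mutations x regions CCF matrix (0 where absent; NA treated
#'   as 0).
#' @param depth matching matrix of read depths (scalar recycled; default 100).
#' @param k_max largest cluster count tried (default 6).
#' @param seed RNG seed for initialization (default 1).
#' @param n_restarts EM restarts per k (default 4).
#' @param cap upper bound accepted for input CCF values (default 1.5);
#'   fitted cluster prevalences are themselves constrained to [0, 1],
#'   since a cellular prevalence is a fraction of tumor cells.
#' @return list of class `cluster_solution`: n_clusters, prevalence
#'   (k x regions), assignment (per mutation), mixing, log_lik, bic,
#'   bic_by_k.
#' @export
cluster_ccf <- function(ccf, depth = 100, k_max = 6, seed = 1,
                        n_restarts = 4, cap = 1.5) {
  if (k_max < 1) stop("k_max must be >= 1")
  ccf <- as.matrix(ccf)
  ccf[is.na(ccf)] <- 0
  M <- nrow(ccf); R <- ncol(ccf)
  if (M < 1) stop("need at least one mutation")
  if (length(depth) == 1) depth <- matrix(depth, M, R)
  depth <- as.matrix(depth)
  # implied successes at allele-fraction scale ccf/2 (fractional counts
  # are fine: the likelihood uses no factorial terms)
  p_obs <- pmin(ccf / 2, 1)
  y <- p_obs * depth

  loglik_by_cluster <- function(prev) {
    # returns M x k matrix of per-mutation log-likelihoods
    k <- nrow(prev)
    out <- matrix(0, M, k)
    for (j in seq_len(k)) {
      p <- pmin(pmax(prev[j, ] / 2, 1e-6), 1 - 1e-6)
      ll <- y * log(matrix(p, M, R, byrow = TRUE)) +
        (depth - y) * log(matrix(1 - p, M, R, byrow = TRUE))
      out[, j] <- rowSums(ll)
    }
    out
  }

  fit_k <- function(k, init_rows) {
    prev <- matrix(ccf[init_rows, , drop = FALSE], k, R)
    prev <- pmin(pmax(prev, 0.01), 1)
    mix <- rep(1 / k, k)
    ll_old <- -Inf
    for (iter in seq_len(200)) {
      lmat <- loglik_by_cluster(prev)
      lmat <- sweep(lmat, 2, log(mix), "+")
      mx <- apply(lmat, 1, max)
      pr <- exp(lmat - mx)
      rs <- rowSums(pr)
      gamma <- pr / rs
      ll <- sum(mx + log(rs))
      if (is.finite(ll_old) && abs(ll - ll_old) < 1e-8 * (abs(ll) + 1)) break
      ll_old <- ll
      mix <- pmax(colMeans(gamma), 1e-10)
      mix <- mix / sum(mix)
      for (j in seq_len(k)) {
        num <- colSums(gamma[, j] * y)
        den <- colSums(gamma[, j] * depth)
        prev[j, ] <- pmin(pmax(2 * num / pmax(den, 1e-10), 0), 1)
      }
    }
    list(prev = prev, mix = mix, gamma = gamma, log_lik = ll)
  }

  kmeanspp_rows <- function(k) {
    rows <- integer(k)
    rows[1] <- sample.int(M, 1)
    if (k > 1) {
      for (j in 2:k) {
        d2 <- apply(ccf, 1, function(r) {
          min(colSums((t(ccf[rows[seq_len(j - 1)], , drop = FALSE]) - r)^2))
        })
        if (sum(d2) <= 0) rows[j] <- sample.int(M, 1)
        else rows[j] <- sample.int(M, 1, prob = d2)
      }
    }
    rows
  }

  with_seed(seed, function() {
    best_overall <- NULL
    bic_by_k <- rep(NA_real_, k_max)
    for (k in seq_len(min(k_max, M))) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- fit_k(k, kmeanspp_rows(k))
        if (is.null(best) || fit$log_lik > best$log_lik) best <- fit
      }
      n_par <- k * R + (k - 1)
      bic <- -2 * best$log_lik + n_par * log(M)
      bic_by_k[k] <- bic
      if (is.null(best_overall) || bic < best_overall$bic) {
        best_overall <- c(best, list(bic = bic, k = k))
      }
    }
    assignment <- apply(best_overall$gamma, 1, which.max)
    sol <- list(
      n_clusters = best_overall$k,
      prevalence = best_overall$prev,
      assignment = assignment,
      mixing = best_overall$mix,
      log_lik = best_overall$log_lik,
      bic = best_overall$bic,
      bic_by_k = bic_by_k,
      regions = colnames(ccf),
      mutation_keys = rownames(ccf)
    )
    class(sol) <- "cluster_solution"
    sol
  })
}

#' Clonal/subclonal assignment from a cluster solution
#'
#' The cluster whose mean prevalence across regions is maximal is the
#' clonal cluster; every other cluster is subclonal. Ties go to the larger
#' cluster, then to the lower cluster id.
#'
#' @param solution a `cluster_solution` from [cluster_ccf()].
#' @return logical vector per mutation, TRUE = clonal.
#' @export
assign_clonality <- function(solution) {
  mean_prev <- rowMeans(solution$prevalence)
  size <- tabulate(solution$assignment, nbins = solution$n_clusters)
  ord <- order(-mean_prev, -size, seq_along(mean_prev))
  clonal_cluster <- ord[1]
  solution$assignment == clonal_cluster
}

#' SNV intratumor heterogeneity
#'
#' Fraction of mutations that are subclonal: (# subclonal) / (# total),
#' over the patient-level union of mutations.
#'
#' @param clonal logical vector (TRUE = clonal) over a patient's mutations.
#' @return fraction in [0,1]; NA for zero mutations.
#' @export
snv_ith <- function(clonal) {
  if (!length(clonal)) return(NA_real_)
  sum(!clonal) / length(clonal)
}

#' Tumor mutational burden
#'
#' Multi-region TMB = size of the cross-region union of nonsilent
#' mutations divided by the callable coding footprint in Mb. Per-region
#' TMBs use each region's own nonsilent count.
#'
#' @param calls [mutation_calls()] for one patient.
#' @param coding_mb callable coding megabases (default 38).
#' @return list with tmb (union-based), per_region (named vector),
#'   n_union.
#' @export
tmb <- function(calls, coding_mb = 38) {
  if (coding_mb <= 0) stop("coding_mb must be > 0")
  calls <- as.data.frame(calls)
  ns <- calls[calls$effect == "nonsilent", , drop = FALSE]
  key <- paste(ns$chrom, ns$pos, ns$ref, ns$alt, sep = ":")
  n_union <- length(unique(key))
  per_region <- vapply(split(key, ns$region_id),
                       function(k) length(unique(k)) / coding_mb, numeric(1))
  list(tmb = n_union / coding_mb, per_region = per_region, n_union = n_union)
}

#' Average TMB per mutation cluster
#' @param tmb_value multi-region TMB (mutations/Mb).
#' @param n_clusters number of mutation clusters (>= 1).
#' @return tmb_value / n_clusters.
#' @export
tmb_per_cluster <- function(tmb_value, n_clusters) {
  if (any(n_clusters < 1)) stop("n_clusters must be >= 1")
  tmb_value / n_clusters
}
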