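# ---- 96-context mutational spectra and signature refitting ------------------

SBS_SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

#' The 96 trinucleotide substitution classes
#'
#' Pyrimidine-convention single-base substitutions (C>A, C>G, C>T, T>A,
#' T>C, T>G) crossed with the 16 flanking-base combinations, in the
#' conventional order: substitution class major, then 5' flank A,C,G,T,
#' then 3' flank A,C,G,T.
#'
#' @return data.frame with columns sub, flank5, flank3, label
#'   (e.g. "A[C>A]A").
#' @export
sbs96_bins <- function() {
  grid <- expand.grid(flank3 = BASES, flank5 = BASES, sub = SBS_SUBS,
                      stringsAsFactors = FALSE)[, c("sub", "flank5", "flank3")]
  grid <- grid[order(match(grid$sub, SBS_SUBS), match(grid$flank5, BASES),
                     match(grid$flank3, BASES)), ]
  rownames(grid) <- NULL
  grid$label <- sprintf("%s[%s]%s", grid$flank5, grid$sub, grid$flank3)
  grid
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, NULL), function(b)
    paste(rev(b), collapse = ""), character(1)))
}

#' Map SNVs to 96-bin labels in the pyrimidine convention
#'
#' Purine-reference SNVs are reverse-complemented so that the reference
#' base is always C or T.
#'
#' @param ref,alt single reference/alternate bases.
#' @param context 3-mer centred on the mutated base (reference strand).
#' @return character vector of bin labels; NA for non-SNV records.
#' @export
sbs96_label <- function(ref, alt, context) {
  n <- length(ref)
  lab <- rep(NA_character_, n)
  is_snv <- nchar(ref) == 1 & nchar(alt) == 1 & ref %in% BASES &
    alt %in% BASES & !is.na(context) & nchar(context) == 3
  if (!any(is_snv)) return(lab)
  r <- ref[is_snv]; a <- alt[is_snv]; ctx <- toupper(context[is_snv])
  if (any(substr(ctx, 2, 2) != r)) {
    bad <- which(substr(ctx, 2, 2) != r)[1]
    stop(sprintf("context '%s' does not match ref '%s' at its centre",
                 ctx[bad], r[bad]))
  }
  pur <- r %in% c("A", "G")
  r[pur] <- chartr("ACGT", "TGCA", r[pur])
  a[pur] <- chartr("ACGT", "TGCA", a[pur])
  ctx[pur] <- revcomp(ctx[pur])
  lab[is_snv] <- sprintf("%s[%s>%s]%s", substr(ctx, 1, 1), r, a,
                         substr(ctx, 3, 3))
  lab
}

#' Compute a 96-context mutation spectrum
#'
#' @param calls a [mutation_calls()] data.frame (or any data.frame with
#'   ref, alt, context columns); rows without a valid SNV+context are
#'   skipped and counted in the "n_skipped" attribute.
#' @return named integer vector of length 96 (bin order of
#'   [sbs96_bins()]); attributes n_snv, n_skipped.
#' @export
trinucleotide_spectrum <- function(calls) {
  bins <- sbs96_bins()
  lab <- sbs96_label(calls$ref, calls$alt, calls$context)
  counts <- table(factor(lab, levels = bins$label))
  spec <- as.integer(counts)
  names(spec) <- bins$label
  attr(spec, "n_snv") <- sum(!is.na(lab))
  attr(spec, "n_skipped") <- sum(is.na(lab))
  spec
}

#' Refit signature exposures by non-negative least squares
#'
#' Solves min || catalog %*% w - spectrum/sum(spectrum) ||_2 with w >= 0,
#' renormalizes the weights to sum 1, zeroes exposures below
#' `prune` (the deconstructSigs-style pruning convention) and renormalizes
#' again.
#'
#' @param spectrum 96-vector of counts (sum > 0).
#' @param catalog 96 x S matrix of signature profiles, columns summing
#'   to 1 (see [read_signature_catalog()]).
#' @param prune exposures below this fraction are zeroed (default 0.06).
#' @return list with weights (named, sum 1), residual_norm (L2 residual of
#'   the reconstruction using the final weights), n_mutations.
#' @export
fit_signatures <- function(spectrum, catalog, prune = 0.06) {
  catalog <- as.matrix(catalog)
  if (length(spectrum) != nrow(catalog)) {
    stop("spectrum length does not match catalog rows")
  }
  total <- sum(spectrum)
  if (total <= 0) stop("empty spectrum")
  target <- spectrum / total
  if (ncol(catalog) == 1L) {
    w <- 1
  } else {
    sol <- pracma::lsqnonneg(catalog, as.numeric(target))
    w <- sol$x
    if (sum(w) <= 0) stop("degenerate NNLS solution (all-zero weights)")
    w <- w / sum(w)
    w[w < prune] <- 0
    w <- w / sum(w)
  }
  w <- as.numeric(w)
  names(w) <- colnames(catalog)
  resid <- sqrt(sum((as.numeric(catalog %*% w) - target)^2))
  list(weights = w, residual_norm = resid, n_mutations = total)
}

#' Read a signature catalog TSV
#'
#' Expected layout: first column `label` with the 96 bin labels in
#' [sbs96_bins()] order, remaining columns one per signature, each summing
#' to 1. The package ships a deterministic synthetic 30-signature catalog
#' (see [synthetic_signature_catalog()]).
#'
#' @param path TSV path; default the packaged synthetic catalog.
#' @return 96 x S numeric matrix with bin labels as rownames.
#' @export
read_signature_catalog <- function(path = system.file(
  "extdata", "signature_catalog_synthetic.tsv", package = "mrith")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  bins <- sbs96_bins()
  if (!identical(df$label, bins$label)) {
    df <- df[match(bins$label, df$label), ]
    if (anyNA(df$label)) stop("catalog does not cover the 96 bins")
  }
  m <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  rownames(m) <- bins$label
  m <- sweep(m, 2, colSums(m), "/")
  m
}

#' Generate the synthetic signature catalog
#'
#' A deterministic stand-in for a 30-signature single-base-substitution
#' reference catalog, for use where the real reference catalog cannot be
#' redistributed. Column 1 mimics an ageing-like profile (C>T at NpCpG),
#' column 4 a tobacco-like profile (broad C>A); the remaining columns are
#' sparse Dirichlet draws from a fixed seed. Profiles are synthetic: they
#' reproduce the format and mathematical behaviour of a reference catalog,
#' not the biology of any published signature.
#'
#' @param n_signatures number of columns (default 30).
#' @return 96 x n_signatures matrix, columns sum to 1.
#' @export
synthetic_signature_catalog <- function(n_signatures = 30) {
  bins <- sbs96_bins()
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(96301L)
  m <- matrix(stats::rgamma(96 * n_signatures, shape = 0.15), nrow = 96)
  # ageing-like: C>T with 3' G
  m[, 1] <- 0.01
  m[bins$sub == "C>T" & bins$flank3 == "G", 1] <- 1
  # tobacco-like: broad C>A
  if (n_signatures >= 4) {
    m[, 4] <- 0.02
    m[bins$sub == "C>A", 4] <- 0.5 + stats::runif(16)
  }
  m <- sweep(m, 2, colSums(m), "/")
  rownames(m) <- bins$label
  colnames(m) <- sprintf("Signature.%d", seq_len(n_signatures))
  m
}

#' Sample trinucleotide contexts from a signature mixture
#'
#' Draws 96-bin classes i.i.d. from `catalog %*% weights` and returns
#' reference-strand ref/alt/context triplets (pyrimidine strand, so ref is
#' always C or T).
#'
#' @param n number of SNVs.
#' @param weights named non-negative weights over catalog columns (sum 1).
#' @param catalog 96 x S matrix.
#' @return data.frame with ref, alt, context.
#' @export
sample_contexts <- function(n, weights, catalog) {
  p <- as.numeric(catalog %*% weights)
  p <- p / sum(p)
  bins <- sbs96_bins()
  idx <- sample.int(96, n, replace = TRUE, prob = p)
  data.frame(
    ref = substr(bins$sub[idx], 1, 1),
    alt = substr(bins$sub[idx], 3, 3),
    context = paste0(bins$flank5[idx], substr(bins$sub[idx], 1, 1),
                     bins$flank3[idx]),
    stringsAsFactors = FALSE
  )
}
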