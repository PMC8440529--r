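# ---- Driver gene occurrence and dominant scores ----------------------------

#' Packaged driver gene list
#'
#' A compact, synthetic subset of a cancer gene census: the recurrent SCLC
#' genes plus well-known lung-cancer drivers, one symbol per line. It
#' stands in for the full census gene list, which cannot be redistributed
#' here; any character vector of symbols can be supplied instead wherever
#' a driver list is accepted.
#'
#' @param path file path; default the packaged list.
#' @return character vector of gene symbols.
#' @export
driver_genes <- function(path = system.file(
  "extdata", "driver_genes_synthetic.txt", package = "mrith")) {
  readLines(path)
}

#' Driver gene occurrence
#'
#' Occurrence = Frequency / n, where Frequency is the number of patients
#' carrying the gene and n the cohort size.
#'
#' @param frequency patients carrying the gene (0 <= frequency <= n).
#' @param n cohort size (> 0).
#' @return fraction in [0,1].
#' @export
occurrence <- function(frequency, n) {
  if (any(n <= 0)) stop("n must be > 0")
  if (any(frequency < 0 | frequency > n)) stop("frequency must lie in [0, n]")
  frequency / n
}

#' Driver dominant score
#'
#' Measures how much a driver gene co-occurs with other (rarer) drivers:
#' score(g) = [ sum over tumors t containing g of
#'              sum over co-occurring drivers d != g in t of 1/freq(d) ]
#'            * 1/freq(g),
#' where freq(x) is the number of tumors carrying driver x. A gene that
#' always appears alone scores 0; co-occurrence with rare drivers raises
#' the score more than co-occurrence with ubiquitous ones. `mode =
#' "per_tumor"` averages the inner sum over the tumors containing g
#' instead of summing it.
#'
#' @param gene gene symbol.
#' @param tumor_sets named list, one character vector of mutated driver
#'   genes per tumor.
#' @param mode "pooled" (default; sums over tumors) or "per_tumor".
#' @return non-negative number.
#' @export
dominant_score <- function(gene, tumor_sets, mode = c("pooled", "per_tumor")) {
  mode <- match.arg(mode)
  tumor_sets <- lapply(tumor_sets, unique)
  all_genes <- unique(unlist(tumor_sets))
  freq <- vapply(all_genes, function(g) {
    sum(vapply(tumor_sets, function(s) g %in% s, logical(1)))
  }, numeric(1))
  names(freq) <- all_genes
  if (!gene %in% all_genes) stop("gene absent from all tumors: ", gene)
  with_g <- Filter(function(s) gene %in% s, tumor_sets)
  inner <- vapply(with_g, function(s) {
    co <- setdiff(s, gene)
    if (!length(co)) 0 else sum(1 / freq[co])
  }, numeric(1))
  total <- if (mode == "pooled") sum(inner) else mean(inner)
  total / freq[[gene]]
}

#' Cohort driver score table
#'
#' Computes frequency, occurrence and dominant score for every driver
#' gene observed in the cohort.
#'
#' @param tumor_sets named list of per-tumor mutated gene vectors.
#' @param drivers driver gene list (default [driver_genes()]); genes
#'   outside the list are ignored.
#' @param mode passed to [dominant_score()].
#' @return data.frame: gene, frequency, occurrence, dominant_score,
#'   sorted by decreasing frequency.
#' @export
driver_score_table <- function(tumor_sets, drivers = driver_genes(),
                               mode = "pooled") {
  n <- length(tumor_sets)
  sets <- lapply(tumor_sets, function(s) intersect(unique(s), drivers))
  genes <- unique(unlist(sets))
  if (!length(genes)) {
    return(data.frame(gene = character(), frequency = integer(),
                      occurrence = numeric(), dominant_score = numeric()))
  }
  freq <- vapply(genes, function(g) {
    sum(vapply(sets, function(s) g %in% s, logical(1)))
  }, numeric(1))
  score <- vapply(genes, function(g) dominant_score(g, sets, mode = mode),
                  numeric(1))
  out <- data.frame(gene = genes, frequency = as.integer(freq),
                    occurrence = occurrence(freq, n),
                    dominant_score = score, stringsAsFactors = FALSE)
  out <- out[order(-out$frequency, out$gene), ]
  rownames(out) <- NULL
  out
}
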