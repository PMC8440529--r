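# Shared builders for small in-code fixtures.

make_calls <- function(n = 3, patient_id = "P001", region_id = "R1",
                       alt_reads = 30L, ref_reads = 70L,
                       normal_alt_reads = 0L, normal_depth = 60L,
                       effect = "nonsilent", population_af = 0,
                       chrom = "1", pos = NULL, gene = NULL) {
  if (n == 0) {
    return(mutation_calls(data.frame(
      patient_id = character(), region_id = character(), chrom = character(),
      pos = integer(), ref = character(), alt = character(),
      gene = character(), effect = character(), alt_reads = integer(),
      ref_reads = integer(), normal_alt_reads = integer(),
      normal_depth = integer(), population_af = numeric(),
      context = character(), rescued = logical(),
      stringsAsFactors = FALSE)))
  }
  if (is.null(pos)) pos <- seq(100L, by = 1000L, length.out = n)
  mutation_calls(data.frame(
    patient_id = patient_id, region_id = region_id,
    chrom = chrom, pos = pos,
    ref = "C", alt = "T",
    gene = if (is.null(gene)) sprintf("G%03d", seq_len(n)) else gene,
    effect = effect,
    alt_reads = alt_reads, ref_reads = ref_reads,
    normal_alt_reads = normal_alt_reads, normal_depth = normal_depth,
    population_af = population_af,
    context = "ACA", rescued = FALSE,
    stringsAsFactors = FALSE))
}

make_segs <- function(patient_id = "P001", region_id = "R1",
                      chrom = "1", start = 1L, end = 249250621L,
                      total_cn = 2, major_cn = 1L, minor_cn = 1L) {
  segments_cn(data.frame(
    patient_id = patient_id, region_id = region_id, chrom = chrom,
    start = start, end = end, total_cn = total_cn,
    major_cn = major_cn, minor_cn = minor_cn, stringsAsFactors = FALSE))
}

make_profiles <- function(patient_id = "P001", regions = c("R1", "R2", "R3"),
                          purity = 0.6, ploidy = 2) {
  region_profiles(data.frame(
    patient_id = patient_id, region_id = regions,
    purity = purity, ploidy = ploidy, stringsAsFactors = FALSE))
}

# presence matrix with a given number of shared and private mutations
make_presence <- function(shared, private, regions = c("R1", "R2", "R3")) {
  rows <- list()
  for (i in seq_len(shared)) rows[[length(rows) + 1L]] <- rep(TRUE, length(regions))
  for (r in seq_along(private)) {
    for (i in seq_len(private[r])) {
      v <- rep(FALSE, length(regions)); v[r] <- TRUE
      rows[[length(rows) + 1L]] <- v
    }
  }
  m <- do.call(rbind, rows)
  dimnames(m) <- list(sprintf("m%03d", seq_len(nrow(m))), regions)
  m
}
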