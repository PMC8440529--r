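# ---- Readers / writers ------------------------------------------------------
# Every external format the pipeline touches is plain TSV except VCF, which
# goes through vcfR. Coordinates are 1-based inclusive everywhere internally;
# VCF positions are already 1-based so no conversion happens at that boundary.

mrith_log <- function(stage, ...) {
  if (isTRUE(getOption("mrith.verbose", FALSE))) {
    message(sprintf("[mrith:%s] %s", stage, sprintf(...)))
  }
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s '%s' is missing column(s): %s",
                 what, path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read a table of somatic mutation calls
#'
#' @param path file path.
#' @param dialect "maf_tsv" (TSV with the package's documented header) or
#'   "vcf" (VCF >= 4.2; tumor read counts from the AD/DP FORMAT fields of
#'   `tumor_sample`, normal counts from `normal_sample`; multiallelic ALT
#'   records are split into one record per alternate allele). For the VCF
#'   dialect `patient_id` and `region_id` identify the sample since VCF
#'   carries neither; optional INFO keys GENE, EFFECT, PAF and CONTEXT
#'   populate the corresponding columns.
#' @param patient_id,region_id identifiers for the VCF dialect.
#' @param tumor_sample,normal_sample sample column names for the VCF
#'   dialect; default first and second sample.
#' @return A [mutation_calls()] data.frame.
#' @export
read_mutation_table <- function(path, dialect = c("maf_tsv", "vcf"),
                                patient_id = NULL, region_id = NULL,
                                tumor_sample = NULL, normal_sample = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "maf_tsv") {
    df <- read_tsv_checked(path, setdiff(MUTATION_COLS, c("context", "rescued")),
                           "mutation table")
    out <- mutation_calls(df)
  } else {
    out <- read_vcf_calls(path, patient_id, region_id, tumor_sample, normal_sample)
  }
  mrith_log("read_mutation_table", "%s: %d records", path, nrow(out))
  out
}

read_vcf_calls <- function(path, patient_id, region_id,
                           tumor_sample, normal_sample) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(patient_id) || is.null(region_id)) {
    stop("patient_id and region_id are required for the vcf dialect")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!nrow(fix)) return(mutation_calls(data.frame()))
  samples <- colnames(v@gt)[-1]
  if (is.null(tumor_sample)) tumor_sample <- samples[1]
  if (is.null(normal_sample)) normal_sample <- if (length(samples) > 1) samples[2] else NA
  ad <- vcfR::extract.gt(v, element = "AD")
  ad_t <- ad[, tumor_sample]
  ad_n <- if (!is.na(normal_sample)) ad[, normal_sample] else
    rep(NA_character_, nrow(fix))
  info_key <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene <- info_key("GENE"); effect <- info_key("EFFECT")
  paf <- suppressWarnings(as.numeric(info_key("PAF")))
  context <- info_key("CONTEXT")

  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    adt <- suppressWarnings(as.integer(strsplit(ad_t[i], ",", fixed = TRUE)[[1]]))
    adn <- if (!is.na(ad_n[i])) {
      suppressWarnings(as.integer(strsplit(ad_n[i], ",", fixed = TRUE)[[1]]))
    } else integer()
    if (length(adt) < length(alts) + 1) {
      stop(sprintf("VCF record at line for %s:%s has malformed AD field",
                   fix$CHROM[i], fix$POS[i]))
    }
    rows[[i]] <- data.frame(
      patient_id = patient_id, region_id = region_id,
      chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
      ref = fix$REF[i], alt = alts,
      gene = if (is.na(gene[i])) "." else gene[i],
      effect = if (is.na(effect[i])) "nonsilent" else effect[i],
      alt_reads = adt[seq_along(alts) + 1L],
      ref_reads = adt[1L],
      normal_alt_reads = if (length(adn)) sum(adn[-1L]) else 0L,
      normal_depth = if (length(adn)) sum(adn) else 0L,
      population_af = if (is.na(paf[i])) 0 else paf[i],
      context = context[i],
      rescued = FALSE,
      stringsAsFactors = FALSE
    )
  }
  mutation_calls(do.call(rbind, rows))
}

#' Write a mutation table to TSV
#' @param calls a [mutation_calls()] data.frame.
#' @param path output path.
#' @export
write_mutation_table <- function(calls, path) {
  df <- as.data.frame(calls)[, MUTATION_COLS]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read allele-specific copy-number segments (SEG-like TSV)
#' @param path file path.
#' @return A [segments_cn()] data.frame, sorted by (region, chrom, start).
#' @export
read_segments <- function(path) {
  df <- read_tsv_checked(path, SEGMENT_COLS, "segment table")
  out <- segments_cn(df)
  mrith_log("read_segments", "%s: %d segments", path, nrow(out))
  out
}

#' Write segments to TSV
#' @param segs a [segments_cn()] data.frame.
#' @param path output path.
#' @export
write_segments <- function(segs, path) {
  utils::write.table(as.data.frame(segs)[, SEGMENT_COLS], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-region purity/ploidy profiles
#' @param path file path.
#' @return A [region_profiles()] data.frame.
#' @export
read_region_profiles <- function(path) {
  region_profiles(read_tsv_checked(
    path, c("patient_id", "region_id", "purity", "ploidy"), "profile table"))
}

#' Read a cohort clinical table
#' @param path file path.
#' @return A [clinical_records()] data.frame.
#' @export
read_clinical <- function(path) {
  clinical_records(read_tsv_checked(path, CLINICAL_COLS, "clinical table"))
}

PATIENT_REPORT_COLS <- c(
  "patient_id", "n_regions", "n_mutations", "n_nonsilent", "snv_ith",
  "cnv_ith", "tmb", "tmb_per_cluster", "n_clusters", "wgd", "gii"
)

#' Write per-patient heterogeneity reports
#'
#' One row per patient with the pipeline's headline metrics, in a fixed
#' column order: patient_id, n_regions, n_mutations, n_nonsilent, snv_ith,
#' cnv_ith, tmb, tmb_per_cluster, n_clusters, wgd, gii. Re-reading with
#' [read_patient_report()] reproduces the table exactly.
#'
#' @param report data.frame with the columns above.
#' @param path output path.
#' @export
write_patient_report <- function(report, path) {
  missing <- setdiff(PATIENT_REPORT_COLS, names(report))
  if (length(missing)) {
    stop("patient report is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(report)[, PATIENT_REPORT_COLS]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-patient heterogeneity reports
#' @param path file path.
#' @return data.frame in the [write_patient_report()] column order.
#' @export
read_patient_report <- function(path) {
  df <- read_tsv_checked(path, PATIENT_REPORT_COLS, "patient report")
  df$wgd <- as.logical(df$wgd)
  df
}
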