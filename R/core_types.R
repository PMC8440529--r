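#' @keywords internal
"_PACKAGE"

# ---- Domain types -----------------------------------------------------------
# All domain objects are plain data.frames with a class tag and a validator,
# in the style of survival/ape: cheap to construct, transparent to inspect,
# and round-trippable through TSV.

MUTATION_COLS <- c(
  "patient_id", "region_id", "chrom", "pos", "ref", "alt", "gene", "effect",
  "alt_reads", "ref_reads", "normal_alt_reads", "normal_depth",
  "population_af", "context", "rescued"
)

SEGMENT_COLS <- c(
  "patient_id", "region_id", "chrom", "start", "end",
  "total_cn", "major_cn", "minor_cn"
)

#' Construct and validate a table of somatic mutation calls
#'
#' One row per (variant, region). `vaf` is always recomputed from the read
#' counts; positions are 1-based. `effect` is taken from the input
#' (annotation is upstream of this package), and must be one of
#' "nonsilent"/"silent".
#'
#' @param df data.frame with the columns listed in the package README
#'   (patient_id, region_id, chrom, pos, ref, alt, gene, effect, alt_reads,
#'   ref_reads, normal_alt_reads, normal_depth, population_af, context,
#'   rescued). `context` and `rescued` are optional and default to NA/FALSE.
#' @return A `mutation_calls` data.frame with a derived `vaf` column.
#' @export
mutation_calls <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"context" %in% names(df)) df$context <- NA_character_
  if (!"rescued" %in% names(df)) df$rescued <- FALSE
  missing <- setdiff(MUTATION_COLS, names(df))
  if (length(missing)) {
    stop("mutation table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, MUTATION_COLS]
  for (col in c("pos", "alt_reads", "ref_reads", "normal_alt_reads", "normal_depth")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df$population_af <- as.numeric(df$population_af)
  df$rescued <- as.logical(df$rescued)
  if (nrow(df)) {
    df$chrom <- normalize_chrom(df$chrom)
    counts <- c("alt_reads", "ref_reads", "normal_alt_reads", "normal_depth")
    for (col in counts) {
      if (anyNA(df[[col]]) || any(df[[col]] < 0)) {
        stop("negative or missing read counts in column ", col)
      }
    }
    if (any(df$ref == df$alt)) stop("ref equal to alt in mutation table")
    if (any(!df$effect %in% c("nonsilent", "silent"))) {
      stop("effect must be 'nonsilent' or 'silent'")
    }
    if (any(df$population_af < 0 | df$population_af > 1, na.rm = TRUE)) {
      stop("population_af outside [0,1]")
    }
  }
  depth <- df$alt_reads + df$ref_reads
  df$vaf <- ifelse(depth > 0, df$alt_reads / depth, NA_real_)
  class(df) <- c("mutation_calls", "data.frame")
  df
}

#' Construct and validate allele-specific copy-number segments
#'
#' Segments are 1-based inclusive, sorted by (region, chrom, start);
#' overlapping segments within one region are rejected.
#'
#' @param df data.frame with patient_id, region_id, chrom, start, end,
#'   total_cn, major_cn, minor_cn.
#' @return A `segments_cn` data.frame.
#' @export
segments_cn <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(SEGMENT_COLS, names(df))
  if (length(missing)) {
    stop("segment table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- df[, SEGMENT_COLS]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$total_cn <- as.numeric(df$total_cn)
  df$major_cn <- as.integer(df$major_cn)
  df$minor_cn <- as.integer(df$minor_cn)
  if (nrow(df)) {
    df$chrom <- normalize_chrom(df$chrom)
    if (any(df$start > df$end)) stop("segment with start > end")
    if (any(df$total_cn < 0)) stop("negative total_cn")
    if (any(df$minor_cn < 0)) stop("negative minor_cn")
    if (any(df$major_cn < df$minor_cn)) {
      stop("segment with major_cn < minor_cn")
    }
    ok <- is.na(df$major_cn) | is.na(df$minor_cn) |
      (df$major_cn + df$minor_cn == round(df$total_cn))
    if (any(!ok)) stop("major_cn + minor_cn != round(total_cn)")
    chrom_rank <- match(df$chrom, names(hg19_contigs()))
    ord <- order(df$patient_id, df$region_id, chrom_rank, df$start)
    df <- df[ord, , drop = FALSE]
    rownames(df) <- NULL
    key <- interaction(df$patient_id, df$region_id, df$chrom, drop = TRUE)
    for (grp in split(seq_len(nrow(df)), key)) {
      if (length(grp) < 2) next
      s <- df$start[grp]; e <- df$end[grp]
      bad <- which(s[-1] <= e[-length(e)])
      if (length(bad)) {
        stop(sprintf(
          "overlapping segments in %s/%s chr%s at rows %d and %d",
          df$patient_id[grp[1]], df$region_id[grp[1]], df$chrom[grp[1]],
          grp[bad[1]], grp[bad[1] + 1L]
        ))
      }
    }
  }
  class(df) <- c("segments_cn", "data.frame")
  df
}

#' Construct and validate per-region purity/ploidy profiles
#'
#' @param df data.frame with patient_id, region_id, purity in (0,1],
#'   ploidy > 0.
#' @return A `region_profiles` data.frame.
#' @export
region_profiles <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(c("patient_id", "region_id", "purity", "ploidy"), names(df))
  if (length(missing)) {
    stop("profile table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$purity <- as.numeric(df$purity)
  df$ploidy <- as.numeric(df$ploidy)
  if (nrow(df)) {
    if (any(df$purity <= 0 | df$purity > 1)) stop("purity outside (0,1]")
    if (any(df$ploidy <= 0)) stop("ploidy must be positive")
  }
  class(df) <- c("region_profiles", "data.frame")
  df
}

CLINICAL_COLS <- c(
  "patient_id", "age", "sex", "smoking", "stage", "tumor_size", "histology",
  "treatment_after_surgery", "dfs_time", "dfs_event", "os_time", "os_event"
)

#' Construct and validate a cohort clinical table
#'
#' Mirrors the usual surgical-cohort descriptive table: demographics,
#' stage, histology (pure vs combined SCLC), adjuvant treatment and
#' DFS/OS endpoints. `tnb` (tumor neoantigen burden) and `egfr_classic`
#' are optional.
#'
#' @param df data.frame of per-patient records.
#' @return A `clinical_records` data.frame.
#' @export
clinical_records <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(CLINICAL_COLS, names(df))
  if (length(missing)) {
    stop("clinical table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df$dfs_event <- as.logical(df$dfs_event)
  df$os_event <- as.logical(df$os_event)
  df$treatment_after_surgery <- as.logical(df$treatment_after_surgery)
  if (nrow(df)) {
    if (any(df$dfs_time < 0 | df$os_time < 0, na.rm = TRUE)) {
      stop("negative survival time")
    }
    if (any(!df$stage %in% c("I", "II", "III", "IV"), na.rm = TRUE)) {
      stop("stage must be I-IV")
    }
  }
  class(df) <- c("clinical_records", "data.frame")
  df
}
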