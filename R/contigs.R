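#' hg19 contig dictionary
#'
#' Lengths (bp) of the hg19 primary assembly chromosomes 1-22, X and Y.
#' Coordinates throughout the package are 1-based inclusive against these
#' contigs. Sex chromosomes are excluded from genome-wide denominators
#' (GII, WGD statistic) by default because tumor copy number on X/Y is
#' confounded by sex.
#'
#' @param include_sex logical; include X and Y.
#' @return Named integer vector of contig lengths.
#' @export
hg19_contigs <- function(include_sex = TRUE) {
  len <- c(
    `1` = 249250621L,  `2` = 243199373L,  `3` = 198022430L,
    `4` = 191154276L,  `5` = 180915260L,  `6` = 171115067L,
    `7` = 159138663L,  `8` = 146364022L,  `9` = 141213431L,
    `10` = 135534747L, `11` = 135006516L, `12` = 133851895L,
    `13` = 115169878L, `14` = 107349540L, `15` = 102531392L,
    `16` = 90354753L,  `17` = 81195210L,  `18` = 78077248L,
    `19` = 59128983L,  `20` = 63025520L,  `21` = 48129895L,
    `22` = 51304566L,  X = 155270560L,    Y = 59373566L
  )
  if (!include_sex) len <- len[!names(len) %in% c("X", "Y")]
  len
}

#' Total autosomal genome size in bp (hg19)
#' @return double scalar.
#' @export
autosome_size <- function() sum(as.double(hg19_contigs(include_sex = FALSE)))

# Normalize "chr1"-style names to the internal bare dictionary.
normalize_chrom <- function(chrom) {
  ch <- sub("^chr", "", as.character(chrom))
  bad <- !ch %in% names(hg19_contigs())
  if (any(bad)) {
    stop("unknown contig(s): ", paste(unique(ch[bad]), collapse = ", "))
  }
  ch
}
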