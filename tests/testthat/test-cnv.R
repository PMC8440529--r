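test_that("gain/loss calls follow the log2 thresholds against ploidy", {
  expect_equal(call_gain_loss(3, 2), "gain")     # log2(1.5) >= log2(1.25)
  expect_equal(call_gain_loss(2, 2), "neutral")
  expect_equal(call_gain_loss(1, 2), "loss")     # -1 < log2(0.75)
  expect_equal(call_gain_loss(2.5, 2), "gain")   # boundary is inclusive
  expect_equal(call_gain_loss(1.5, 2), "neutral")# loss boundary is exclusive
  expect_equal(call_gain_loss(0, 2), "loss")
  expect_error(call_gain_loss(2, 0), "ploidy")
})

test_that("GII is the altered-length fraction of the genome", {
  neutral <- make_segs(total_cn = 2)
  expect_equal(gii_region(neutral, 2), 0)

  chroms <- names(hg19_contigs(include_sex = FALSE))
  lens <- hg19_contigs(include_sex = FALSE)
  all_gain <- segments_cn(data.frame(
    patient_id = "P1", region_id = "R1", chrom = chroms, start = 1L,
    end = as.integer(lens), total_cn = 4, major_cn = 3L, minor_cn = 1L,
    stringsAsFactors = FALSE))
  expect_equal(gii_region(all_gain, 2), 1.0)

  mixed <- segments_cn(data.frame(
    patient_id = "P1", region_id = "R1", chrom = c("1", "2", "3"),
    start = 1L, end = c(150e6, 150e6, 100e6),
    total_cn = c(4, 1, 2), major_cn = c(3L, 1L, 1L),
    minor_cn = c(1L, 0L, 1L), stringsAsFactors = FALSE))
  expect_equal(gii_region(mixed, 2, genome_size_bp = 3e9), 0.1)
})

test_that("fully doubled and fully diploid genomes give definitive WGD calls", {
  chroms <- names(hg19_contigs(include_sex = FALSE))
  lens <- hg19_contigs(include_sex = FALSE)
  doubled <- segments_cn(data.frame(
    patient_id = "P1", region_id = "R1", chrom = chroms, start = 1L,
    end = as.integer(lens), total_cn = 4, major_cn = 2L, minor_cn = 2L,
    stringsAsFactors = FALSE))
  w <- detect_wgd(doubled, n_sim = 200, seed = 1)
  expect_equal(w$observed_statistic, 1.0)
  expect_equal(w$ploidy_class, "tetraploid")
  expect_true(w$is_wgd)

  diploid <- segments_cn(data.frame(
    patient_id = "P1", region_id = "R1", chrom = chroms, start = 1L,
    end = as.integer(lens), total_cn = 2, major_cn = 1L, minor_cn = 1L,
    stringsAsFactors = FALSE))
  w2 <- detect_wgd(diploid, n_sim = 200, seed = 1)
  expect_equal(w2$observed_statistic, 0.0)
  expect_false(w2$is_wgd)
})

test_that("the permutation p-value matches an independent oracle", {
  chroms <- names(hg19_contigs(include_sex = FALSE))
  lens <- hg19_contigs(include_sex = FALSE)
  set.seed(21)
  major <- ifelse(runif(22) < 0.6, 2L, 1L)
  segs <- segments_cn(data.frame(
    patient_id = "P1", region_id = "R1", chrom = chroms, start = 1L,
    end = as.integer(lens), total_cn = as.numeric(major + 1L),
    major_cn = major, minor_cn = 1L, stringsAsFactors = FALSE))
  w <- detect_wgd(segs, n_sim = 2000, seed = 99)

  # independent brute-force permutation with its own RNG stream
  len <- as.double(segs$end) - as.double(segs$start) + 1
  wts <- len / sum(len)
  state <- as.integer(segs$major_cn >= 2)
  obs <- sum(wts * state)
  set.seed(12345)
  sims <- replicate(2000, sum(wts * state[sample.int(22)]))
  p_oracle <- (1 + sum(sims >= obs - 1e-12)) / 2001
  mc_se <- sqrt(p_oracle * (1 - p_oracle) / 2000)
  expect_lt(abs(w$p_value - p_oracle), 4 * mc_se + 1e-3)
})

test_that("CNV clonality follows the all-regions rule, with LOH backing losses", {
  ev <- function(bins_gain = character(), bins_loss = character(),
                 bins_loh = character()) {
    bins <- c(bins_gain, bins_loss, bins_loh)
    data.frame(bin = bins,
               chrom = rep("1", length(bins)),
               start = rep(1L, length(bins)), end = rep(2L, length(bins)),
               direction = rep(c("gain", "loss", "neutral"),
                               c(length(bins_gain), length(bins_loss),
                                 length(bins_loh))),
               loh = rep(c(FALSE, FALSE, TRUE),
                         c(length(bins_gain), length(bins_loss),
                           length(bins_loh))),
               stringsAsFactors = FALSE)
  }
  events <- list(R1 = ev(bins_gain = "b1", bins_loss = "b2"),
                 R2 = ev(bins_gain = "b1", bins_loss = "b2"),
                 R3 = ev(bins_gain = "b1", bins_loh = "b2"))
  got <- classify_cnv_clonality(events)
  expect_equal(got$clonality[got$bin == "b1" & got$direction == "gain"],
               "clonal")
  # loss in 2 regions + LOH in the third counts as clonal loss
  expect_equal(got$clonality[got$bin == "b2" & got$direction == "loss"],
               "clonal")

  events2 <- list(R1 = ev(bins_gain = "b1"), R2 = ev(), R3 = ev())
  got2 <- classify_cnv_clonality(events2)
  expect_equal(got2$clonality, "subclonal")
  expect_error(classify_cnv_clonality(events[1]), ">= 2 regions")
})

test_that("cnv_ith is the mean pairwise Jaccard distance", {
  same <- list(R1 = c("a", "b"), R2 = c("a", "b"), R3 = c("a", "b"))
  expect_equal(cnv_ith(same), 0)
  disjoint <- list(R1 = "a", R2 = "b", R3 = "c")
  expect_equal(cnv_ith(disjoint), 1)
  mixed <- list(R1 = c("a", "b"), R2 = c("b", "c"), R3 = c("a", "b"))
  expect_equal(cnv_ith(mixed), mean(c(2 / 3, 0, 2 / 3)))
  # empty-union pairs contribute 0
  expect_equal(cnv_ith(list(R1 = character(), R2 = character())), 0)
  expect_warning(v <- cnv_ith(list(R1 = "a")), "single region")
  expect_true(is.na(v))
  # invariant under region relabeling
  expect_equal(cnv_ith(mixed), cnv_ith(rev(mixed)))
})

test_that("segments project onto fixed bins by majority covered length", {
  segs <- segments_cn(data.frame(
    patient_id = "P1", region_id = "R1", chrom = "1",
    start = c(1L, 15000001L), end = c(15000000L, 40000000L),
    total_cn = c(4, 2), major_cn = c(3L, 1L), minor_cn = c(1L, 1L),
    stringsAsFactors = FALSE))
  ev <- bin_cnv_events(segs, ploidy = 2, bin_size = 1e7)
  expect_equal(ev$direction[ev$bin == "1:1"], "gain")
  # second bin: 5 Mb gain vs 5 Mb neutral -> no majority, neutral
  expect_equal(ev$direction[ev$bin == "1:10000001"], "neutral")
  expect_equal(ev$direction[ev$bin == "1:30000001"], "neutral")
})
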