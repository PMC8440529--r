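test_that("filter boundaries follow the stated thresholds", {
  base <- make_calls(1, alt_reads = 30L, ref_reads = 170L,
                     normal_depth = 60L)
  expect_equal(nrow(apply_somatic_filters(base)), 1)

  low_alt <- make_calls(1, alt_reads = 4L, ref_reads = 96L)
  expect_equal(nrow(apply_somatic_filters(low_alt)), 0)

  # vaf exactly at 3% is retained, just below is rejected
  at <- make_calls(1, alt_reads = 6L, ref_reads = 194L)
  below <- make_calls(1, alt_reads = 29L, ref_reads = 971L)
  expect_equal(at$vaf, 0.03)
  expect_equal(below$vaf, 0.029)
  expect_equal(nrow(apply_somatic_filters(at)), 1)
  expect_equal(nrow(apply_somatic_filters(below)), 0)

  shallow_normal <- make_calls(1, normal_depth = 9L)
  expect_equal(nrow(apply_somatic_filters(shallow_normal)), 0)

  common <- make_calls(1, population_af = 0.02)
  expect_equal(nrow(apply_somatic_filters(common)), 0)
})

test_that("filters equal an independent per-record predicate oracle", {
  set.seed(7)
  n <- 1000
  depth <- rpois(n, 120)
  alt <- rbinom(n, depth, runif(n, 0, 0.4))
  calls <- mutation_calls(data.frame(
    patient_id = "P1", region_id = sample(c("R1", "R2"), n, TRUE),
    chrom = sample(c("1", "2", "X"), n, TRUE),
    pos = sample.int(4e7, n), ref = "C", alt = "A",
    gene = "G1", effect = sample(c("nonsilent", "silent"), n, TRUE),
    alt_reads = alt, ref_reads = depth - alt,
    normal_alt_reads = rbinom(n, 30, 0.02),
    normal_depth = rpois(n, 15),
    population_af = ifelse(runif(n) < 0.1, runif(n, 0, 0.05), 0),
    stringsAsFactors = FALSE))
  got <- apply_somatic_filters(calls)

  d <- as.data.frame(calls)
  v <- ifelse(d$alt_reads + d$ref_reads > 0,
              d$alt_reads / (d$alt_reads + d$ref_reads), 0)
  keep <- d$alt_reads >= 5 & d$normal_depth >= 10 &
    (d$alt_reads + d$ref_reads) >= 30 & v >= 0.03 & d$population_af <= 0.01
  oracle <- d[keep, , drop = FALSE]
  rownames(oracle) <- NULL
  expect_equal(as.data.frame(got), oracle, ignore_attr = TRUE)
  # ordering is preserved exactly
  expect_identical(got$pos, oracle$pos)
})

test_that("filtering is idempotent", {
  set.seed(11)
  n <- 200
  depth <- rpois(n, 100)
  alt <- rbinom(n, depth, 0.2)
  calls <- mutation_calls(data.frame(
    patient_id = "P1", region_id = "R1", chrom = "1",
    pos = seq_len(n), ref = "C", alt = "G", gene = "G", effect = "nonsilent",
    alt_reads = alt, ref_reads = depth - alt, normal_alt_reads = 0L,
    normal_depth = rpois(n, 40), population_af = 0,
    stringsAsFactors = FALSE))
  once <- apply_somatic_filters(calls)
  twice <- apply_somatic_filters(once)
  expect_equal(as.data.frame(twice), as.data.frame(once))
})

rescue_fixture <- function(r3_alt, r3_ref, r3_nalt = 0L) {
  calls <- rbind(
    as.data.frame(make_calls(1, region_id = "R1", pos = 100L)),
    as.data.frame(make_calls(1, region_id = "R2", pos = 100L)))
  pile <- data.frame(
    region_id = "R3", chrom = "1", pos = 100L, ref = "C", alt = "T",
    alt_reads = r3_alt, ref_reads = r3_ref, normal_alt_reads = r3_nalt,
    normal_depth = 60L, stringsAsFactors = FALSE)
  list(calls = mutation_calls(calls), pile = pile)
}

test_that("rescue adds the variant where VAF > 1% and normal support is low", {
  fx <- rescue_fixture(3L, 197L)  # vaf 1.5%
  got <- rescue_cross_region(fx$calls, fx$pile,
                             regions = c("R1", "R2", "R3"))
  expect_equal(nrow(got), 3)
  r3 <- got[got$region_id == "R3", ]
  expect_true(r3$rescued)
  expect_false(any(got$rescued[got$region_id != "R3"]))
})

test_that("rescue declines low-VAF or normal-supported loci", {
  fx <- rescue_fixture(1L, 199L)  # vaf 0.5%
  got <- rescue_cross_region(fx$calls, fx$pile, regions = c("R1", "R2", "R3"))
  expect_equal(nrow(got), 2)

  fx2 <- rescue_fixture(4L, 196L, r3_nalt = 5L)  # normal alt at the bound
  got2 <- rescue_cross_region(fx2$calls, fx2$pile,
                              regions = c("R1", "R2", "R3"))
  expect_equal(nrow(got2), 2)
})

test_that("rescue is a no-op when the variant is already ubiquitous", {
  calls <- mutation_calls(do.call(rbind, lapply(c("R1", "R2", "R3"),
    function(r) as.data.frame(make_calls(1, region_id = r, pos = 100L)))))
  pile <- data.frame(region_id = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     alt_reads = integer(), ref_reads = integer(),
                     normal_alt_reads = integer(), normal_depth = integer())
  got <- rescue_cross_region(calls, pile, regions = c("R1", "R2", "R3"))
  expect_equal(as.data.frame(got), as.data.frame(calls))
})

test_that("a locus missing from the pileups warns and is treated as absent", {
  fx <- rescue_fixture(3L, 197L)
  pile_empty <- fx$pile[0, ]
  expect_warning(
    got <- rescue_cross_region(fx$calls, pile_empty,
                               regions = c("R1", "R2", "R3")),
    "no pileup")
  expect_equal(nrow(got), 2)
})
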