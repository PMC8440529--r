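test_that("mutation copy number follows the purity/CN correction", {
  expect_equal(mutation_copy_number(0.5, 1, 2, 2), 1.0)
  expect_equal(mutation_copy_number(0, 0.7, 3, 2), 0)
  expect_equal(mutation_copy_number(0.25, 0.5, 4, 2), 1.5)
  expect_error(mutation_copy_number(0.5, 0, 2, 2), "purity")
  # linear in vaf
  v <- seq(0, 0.5, by = 0.1)
  out <- mutation_copy_number(v, 0.6, 3, 2)
  expect_equal(out, v * out[2] / 0.1)
})

test_that("multiplicity and CCF derive from mutation copy number", {
  expect_equal(estimate_ccf(1.0, 1), data.frame(
    multiplicity = 1L, ccf = 1.0, capped = FALSE))
  e <- estimate_ccf(2.1, 2)
  expect_equal(e$multiplicity, 2L)
  expect_equal(e$ccf, 1.05)
  expect_false(e$capped)
  expect_equal(estimate_ccf(0.4, 2)$ccf, 0.4)
  # cap engages with a flag
  e2 <- estimate_ccf(1.8, 1)
  expect_equal(e2$ccf, 1.5)
  expect_true(e2$capped)
})

test_that("a homogeneous CCF matrix yields a single cluster", {
  set.seed(3)
  ccf <- matrix(pmin(rnorm(300, 1, 0.05), 1.5), 100, 3)
  sol <- cluster_ccf(ccf, depth = 250, k_max = 5, seed = 1)
  expect_equal(sol$n_clusters, 1)
  expect_true(all(assign_clonality(sol)))
  expect_equal(snv_ith(assign_clonality(sol)), 0)
})

test_that("two well-separated clusters are recovered with correct labels", {
  set.seed(5)
  n1 <- 120; n2 <- 80; depth <- 250
  sim_ccf <- function(n, prev) {
    t(replicate(n, vapply(prev, function(p)
      2 * rbinom(1, depth, p / 2) / depth, numeric(1))))
  }
  ccf <- rbind(sim_ccf(n1, c(1, 1, 1)), sim_ccf(n2, c(0.6, 0, 0)))
  truth <- rep(1:2, c(n1, n2))
  sol <- cluster_ccf(ccf, depth = depth, k_max = 5, seed = 2)
  expect_equal(sol$n_clusters, 2)
  # align estimated cluster ids to truth by majority
  map <- tapply(sol$assignment, truth, function(x)
    as.integer(names(which.max(table(x)))))
  acc <- mean(sol$assignment == map[truth])
  expect_gte(acc, 0.95)
  clonal <- assign_clonality(sol)
  expect_equal(snv_ith(clonal), n2 / (n1 + n2), tolerance = 0.05)
})

test_that("clustering is deterministic for a fixed seed", {
  set.seed(9)
  ccf <- matrix(runif(90, 0, 1), 30, 3)
  a <- cluster_ccf(ccf, depth = 100, k_max = 4, seed = 42)
  b <- cluster_ccf(ccf, depth = 100, k_max = 4, seed = 42)
  expect_identical(a, b)
  expect_error(cluster_ccf(ccf, k_max = 0), "k_max")
})

test_that("clonality goes to the max-prevalence cluster with size tie-break", {
  sol <- structure(list(
    n_clusters = 2L,
    prevalence = matrix(c(0.95, 0.40, 0.95, 0.40, 0.95, 0.40), 2, 3),
    assignment = rep(c(1L, 2L), c(25, 15))), class = "cluster_solution")
  expect_true(all(assign_clonality(sol)[1:25]))
  expect_false(any(assign_clonality(sol)[26:40]))

  tie <- structure(list(
    n_clusters = 2L,
    prevalence = matrix(0.5, 2, 3),
    assignment = rep(c(1L, 2L), c(10, 30))), class = "cluster_solution")
  cl <- assign_clonality(tie)
  expect_true(all(cl[11:40]))   # larger cluster wins the tie
  expect_false(any(cl[1:10]))
})

test_that("snv_ith counts subclonal fraction", {
  expect_equal(snv_ith(rep(TRUE, 10)), 0)
  expect_equal(snv_ith(rep(FALSE, 10)), 1)
  expect_equal(snv_ith(rep(c(FALSE, TRUE), c(3, 7))), 0.3)
  expect_true(is.na(snv_ith(logical(0))))
})

test_that("TMB uses the cross-region union of nonsilent mutations", {
  calls <- mutation_calls(rbind(
    as.data.frame(make_calls(380, region_id = "R1",
                             pos = seq(1000L, by = 1000L, length.out = 380))),
    as.data.frame(make_calls(380, region_id = "R2",
                             pos = seq(1000L, by = 1000L, length.out = 380)))))
  tb <- tmb(calls, coding_mb = 38)
  expect_equal(tb$tmb, 10.0)
  expect_equal(unname(tb$per_region["R1"]), 10.0)  # identical sets: union = single region
  expect_equal(tmb(make_calls(0), 38)$tmb, 0)
  expect_error(tmb(make_calls(2), 0), "coding_mb")
})

test_that("TMB per cluster divides by the cluster count", {
  expect_equal(tmb_per_cluster(10, 5), 2)
  expect_equal(tmb_per_cluster(7.3, 1), 7.3)
  expect_equal(tmb_per_cluster(10.2, 3), 3.4)
  expect_error(tmb_per_cluster(10, 0), "n_clusters")
})

test_that("BIC does not materially over-split noiseless input", {
  set.seed(13)
  for (k_true in 1:3) {
    prev <- matrix(runif(k_true * 3, 0.2, 1), k_true, 3)
    prev[1, ] <- 1
    ccf <- prev[rep(seq_len(k_true), each = 40), , drop = FALSE]
    sol <- cluster_ccf(ccf, depth = 500, k_max = 6, seed = 5)
    expect_lte(sol$n_clusters, k_true + 1)
  }
})
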