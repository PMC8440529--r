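test_that("log-rank matches survival::survdiff on random instances", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(20:60, 1)
    time <- round(rexp(n, 0.05), 3)
    event <- runif(n) < 0.7
    group <- sample(c("a", "b"), n, replace = TRUE)
    if (length(unique(group)) < 2) group[1:2] <- c("a", "b")
    got <- logrank_test(group, time, event)
    ref <- survival::survdiff(survival::Surv(time, event) ~ group)
    expect_equal(got$chi_square, unname(ref$chisq), tolerance = 1e-8)
  }
})

test_that("log-rank is symmetric and degenerates sensibly", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- rep(TRUE, 6)
  g <- rep(c("x", "y"), 3)
  a <- logrank_test(g, time, event)
  b <- logrank_test(rev(g), time, event)
  expect_equal(a$chi_square, b$chi_square)

  # identical survival in both groups
  same <- logrank_test(rep(c("x", "y"), each = 5),
                       rep(c(1, 2, 3, 4, 5), 2), rep(TRUE, 10))
  expect_lt(same$chi_square, 0.01)
  expect_gt(same$p, 0.9)
  expect_error(logrank_test(rep("x", 5), 1:5, rep(TRUE, 5)), "2 non-empty")
})

test_that("best cutoff separates two survival regimes and matches brute force", {
  values <- c(1:10, 91:100)
  time <- c(50 + 1:10, 1:10)  # low covariate -> long survival
  event <- rep(TRUE, 20)
  got <- best_cutoff_dichotomize(values, time, event)
  expect_gte(got$cutoff, 10)
  expect_lt(got$cutoff, 91)
  expect_equal(unname(got$group), factor(rep(c("low", "high"), each = 10),
                                         levels = c("low", "high")))

  # brute force over every admissible observed cutoff
  qs <- quantile(values, c(0.2, 0.8), type = 7)
  cand <- sort(unique(values))
  cand <- cand[cand >= qs[1] & cand < qs[2]]
  chis <- vapply(cand, function(cut)
    logrank_test(values > cut, time, event)$chi_square, numeric(1))
  expect_equal(got$cutoff, cand[which.max(chis)])
  expect_equal(got$chi_square, max(chis))
})

test_that("cutoff scan handles ties and degenerate configurations", {
  # no survival signal at all: every cutoff ties at 0, smallest returned
  values <- rep(c(1, 2, 3, 4, 5), 4)
  time <- rep(5, 20); event <- rep(TRUE, 20)
  got <- best_cutoff_dichotomize(values, time, event)
  expect_equal(got$chi_square, 0)
  expect_equal(got$cutoff, min(values[values >= quantile(values, 0.2)]))

  expect_error(best_cutoff_dichotomize(rep(1, 20), time, event), "constant")
  expect_error(best_cutoff_dichotomize(values, time, event,
                                       min_group_frac = 0.5), "cutoff")
})

test_that("upper-quantile dichotomization follows the type-7 convention", {
  g <- upper_quantile_dichotomize(1:40, q = 0.75)
  expect_equal(sum(g == "high"), sum(1:40 >= quantile(1:40, 0.75, type = 7)))
  expect_equal(sum(g == "high"), 10)
  expect_true(all(upper_quantile_dichotomize(rep(3, 10)) == "high"))
  expect_true(all(upper_quantile_dichotomize(1:10, q = 0) == "high"))
  expect_error(upper_quantile_dichotomize(numeric(0)), "empty")
})

test_that("Cox recovers a known hazard ratio of 2", {
  set.seed(47)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  t_true <- rexp(n, 0.02 * exp(log(2) * x))
  cens <- runif(n, 10, 120)
  d <- data.frame(x = x, time = pmin(t_true, cens), event = t_true <= cens)
  fit <- cox_fit(d, "x", "time", "event")
  expect_true(attr(fit, "converged"))
  expect_gt(fit$hr[fit$term == "x"], 1.7)
  expect_lt(fit$hr[fit$term == "x"], 2.3)
})

test_that("Cox CI covers 1 for a null covariate most of the time", {
  set.seed(53)
  cover <- vapply(1:60, function(i) {
    n <- 150
    x <- rnorm(n)
    t_true <- rexp(n, 0.03)
    cens <- runif(n, 5, 80)
    d <- data.frame(x = x, time = pmin(t_true, cens), event = t_true <= cens)
    fit <- cox_fit(d, "x", "time", "event")
    fit$ci_lower[1] <= 1 && fit$ci_upper[1] >= 1
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("Cox flags non-estimable inputs instead of raising", {
  d <- data.frame(x = rnorm(20), time = rexp(20), event = FALSE)
  fit <- cox_fit(d, "x", "time", "event")
  expect_false(attr(fit, "converged"))
  expect_true(all(is.na(fit$hr)))
})

test_that("cohort summary reproduces category counts and percentages", {
  cl <- read_clinical(system.file("extdata", "clinical_table1_synthetic.tsv",
                                  package = "mrith"))
  s <- cohort_summary(cl)
  male <- s[s$variable == "sex" & s$level == "Male" & s$stratum == "Total", ]
  expect_equal(male$n, 35)
  expect_equal(male$pct, 87.5)
  # percentages within a category sum to 100 up to rounding
  sex_tot <- s[s$variable == "sex" & s$stratum == "Total", ]
  expect_equal(sum(sex_tot$pct), 100, tolerance = 0.2)
  # age median by stratum
  age_p <- s[s$variable == "age" & s$stratum == "P-SCLC", ]
  expect_equal(age_p$median, 64)
})

test_that("spearman utility delegates to the standard implementation", {
  set.seed(59)
  x <- rnorm(30); y <- x + rnorm(30)
  got <- spearman_cor(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rho, unname(ref$estimate))
  expect_equal(got$p, ref$p.value)
})
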