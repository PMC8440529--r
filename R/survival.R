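# ---- Survival associations and cohort descriptives --------------------------

#' Two-group log-rank test
#'
#' Standard (unweighted) two-group log-rank statistic: at each distinct
#' event time the observed events in group 1 are compared with the
#' hypergeometric expectation given the risk sets; the squared
#' standardized sum is chi-square with 1 df. Implemented directly so that
#' the best-cutoff scan below has a self-contained statistic; agreement
#' with survival::survdiff is enforced in the test suite.
#'
#' @param group two-level grouping (factor/character/logical).
#' @param time follow-up times.
#' @param event event indicators (TRUE/1 = event).
#' @return list with chi_square and p (chi-square with 1 df).
#' @export
logrank_test <- function(group, time, event) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop("need exactly 2 non-empty groups")
  group <- droplevels(group)
  event <- as.logical(event)
  in1 <- group == levels(group)[1]
  times <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & in1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & in1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi <- if (V > 0) (O - E)^2 / V else 0
  list(chi_square = chi, p = stats::pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Best-cutoff dichotomization (maximally selected log-rank statistic)
#'
#' Scans the observed values lying strictly between the `min_group_frac`
#' and 1 - `min_group_frac` quantiles and returns the cutoff maximizing
#' the log-rank chi-square for the split value > cutoff vs <= cutoff.
#' Ties break to the smaller cutoff. The selected p-value is optimistic
#' (no selection-bias correction is applied).
#'
#' @param values numeric covariate.
#' @param time,event survival endpoint.
#' @param min_group_frac minimum fraction per group (default 0.2).
#' @return list: cutoff, group (factor "low"/"high"), chi_square, p.
#' @export
best_cutoff_dichotomize <- function(values, time, event, min_group_frac = 0.2) {
  ok <- !is.na(values) & !is.na(time) & !is.na(event)
  if (sum(ok) < 10) stop("need >= 10 analyzable records")
  v <- values[ok]
  if (length(unique(v)) < 2) stop("no valid cutoff: values are constant")
  qs <- stats::quantile(v, c(min_group_frac, 1 - min_group_frac), type = 7)
  cand <- sort(unique(v))
  cand <- cand[cand >= qs[1] & cand < qs[2]]
  if (!length(cand)) stop("no valid cutoff: no candidates between quantiles")
  best <- NULL
  for (cut in cand) {
    g <- v > cut
    if (!any(g) || all(g)) next
    lr <- logrank_test(g, time[ok], event[ok])
    if (is.null(best) || lr$chi_square > best$chi_square + 1e-12) {
      best <- c(lr, list(cutoff = cut))
    }
  }
  if (is.null(best)) stop("no valid cutoff")
  group <- factor(ifelse(values > best$cutoff, "high", "low"),
                  levels = c("low", "high"))
  list(cutoff = best$cutoff, group = group,
       chi_square = best$chi_square, p = best$p)
}

#' Upper-quantile dichotomization
#'
#' high iff value >= quantile_q(values) (type-7 linear interpolation);
#' the TMB convention, with q = 0.75 by default.
#'
#' @param values numeric vector (non-empty).
#' @param q quantile in [0,1] (default 0.75).
#' @return factor "low"/"high".
#' @export
upper_quantile_dichotomize <- function(values, q = 0.75) {
  if (!length(values)) stop("empty input")
  cut <- stats::quantile(values, q, type = 7, na.rm = TRUE)
  factor(ifelse(values >= cut, "high", "low"), levels = c("low", "high"))
}

#' Cox proportional-hazards fit with standard adjusters
#'
#' Thin wrapper around survival::coxph returning hazard ratios with 95%
#' confidence intervals. Separation or non-convergence is flagged in the
#' result rather than raised.
#'
#' @param data data.frame containing the covariates and endpoint columns.
#' @param covariate name of the covariate of interest.
#' @param time_col,event_col endpoint column names.
#' @param adjusters character vector of adjustment covariates (default
#'   none; the cohort convention is age, smoking, tumor_size, stage).
#' @return data.frame (one row per model term): term, hr, ci_lower,
#'   ci_upper, p, plus attributes "converged" and "n".
#' @export
cox_fit <- function(data, covariate, time_col, event_col,
                    adjusters = character()) {
  vars <- c(covariate, adjusters)
  cols <- c(vars, time_col, event_col)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  n_events <- sum(as.logical(d[[event_col]]))
  flagged <- function(msg) {
    out <- data.frame(term = vars, hr = NA_real_, ci_lower = NA_real_,
                      ci_upper = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
    attr(out, "converged") <- FALSE
    attr(out, "note") <- msg
    attr(out, "n") <- nrow(d)
    out
  }
  if (n_events == 0) return(flagged("zero events: non-estimable"))
  if (n_events < length(vars)) return(flagged("fewer events than covariates"))
  fml <- stats::as.formula(sprintf(
    "survival::Surv(%s, %s) ~ %s", time_col, event_col,
    paste(vars, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    tryCatch(survival::coxph(fml, data = d), error = function(e) NULL),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (is.null(fit)) return(flagged("coxph failed"))
  s <- summary(fit)
  out <- data.frame(
    term = rownames(s$coefficients),
    hr = s$coefficients[, "exp(coef)"],
    ci_lower = s$conf.int[, "lower .95"],
    ci_upper = s$conf.int[, "upper .95"],
    p = s$coefficients[, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "converged") <- !warned
  attr(out, "n") <- nrow(d)
  out
}

#' Cohort descriptive summary stratified by histology
#'
#' Per-category counts and percentages plus medians with ranges, overall
#' and split by pure vs combined histology, in the layout of a clinical
#' descriptive table.
#'
#' @param clinical a [clinical_records()] data.frame; optional columns
#'   (sex, smoking, drinking, egfr_classic, status via os_event) are
#'   summarized when present.
#' @return data.frame: variable, level, stratum ("Total" plus one per
#'   histology), n, pct (percent within stratum, 1 decimal), median,
#'   range_low, range_high (for continuous variables).
#' @export
cohort_summary <- function(clinical) {
  cl <- as.data.frame(clinical)
  strata <- c(list(Total = cl), split(cl, cl$histology))
  rows <- list()
  cat_row <- function(variable, values, stratum_name, d) {
    lv <- sort(unique(values[!is.na(values)]))
    vals <- d[[variable]]
    for (l in c(lv, if (anyNA(values)) "NA")) {
      n <- if (identical(l, "NA")) sum(is.na(vals)) else sum(vals == l, na.rm = TRUE)
      rows[[length(rows) + 1L]] <<- data.frame(
        variable = variable, level = as.character(l), stratum = stratum_name,
        n = n, pct = if (nrow(d)) round(100 * n / nrow(d), 1) else 0,
        median = NA_real_, range_low = NA_real_, range_high = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  num_row <- function(variable, stratum_name, d) {
    v <- d[[variable]]
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, level = "", stratum = stratum_name,
      n = sum(!is.na(v)), pct = NA_real_,
      median = stats::median(v, na.rm = TRUE),
      range_low = suppressWarnings(min(v, na.rm = TRUE)),
      range_high = suppressWarnings(max(v, na.rm = TRUE)),
      stringsAsFactors = FALSE)
  }
  cl$status <- ifelse(cl$os_event, "Dead", "Alive")
  cat_vars <- intersect(c("sex", "smoking", "drinking", "stage",
                          "treatment_after_surgery", "status",
                          "egfr_classic"), names(cl))
  num_vars <- intersect(c("age", "tumor_size"), names(cl))
  for (sn in names(strata)) {
    d <- strata[[sn]]
    d$status <- ifelse(d$os_event, "Dead", "Alive")
    for (v in num_vars) num_row(v, sn, d)
    for (v in cat_vars) cat_row(v, cl[[v]], sn, d)
  }
  do.call(rbind, rows)
}

#' Spearman rank correlation (thin utility)
#'
#' Delegates to stats::cor.test(method = "spearman"); used for the
#' TMB-vs-TNB association.
#'
#' @param x,y numeric vectors.
#' @return list with rho and p.
#' @export
spearman_cor <- function(x, y) {
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value)
}
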