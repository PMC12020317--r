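# The study's statistical machinery as reusable operations: linear trends
# tested against constant models with F-tests, logistic trends tested with
# likelihood-ratio chi-squared tests, nonparametric group comparisons, and
# AM-ULA summary-score aggregation.

#' Linear trend versus a constant model
#'
#' Ordinary least squares of `y` on `x` (time in weeks), with an F-test of
#' the linear model against the intercept-only model, as used for threshold
#' charge, tissue resistance, and crosstalk stability. For simple regression
#' this F-test is algebraically identical to the two-sided t-test on the
#' slope.
#'
#' @param x numeric time covariate (weeks); must not be constant.
#' @param y numeric response.
#' @return A `trend_result` list: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `f_statistic`, `df`, `model = "linear_vs_constant"`.
#' @export
#' @examples
#' linear_trend_test(1:10, 2 + 3 * (1:10))$slope  # 3
linear_trend_test <- function(x, y) {
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("x is degenerate (all time points equal)")
  fit <- stats::lm(y ~ x)
  sse <- sum(stats::residuals(fit)^2)
  ssr <- sum((stats::fitted(fit) - mean(y))^2)
  df2 <- length(y) - 2
  sst <- ssr + sse
  # degenerate against the scale of y, not of the (possibly all-noise) sums
  if (sst <= 100 * .Machine$double.eps * max(sum(y^2), 1)) sst <- 0
  if (sst == 0 || ssr <= 1e-12 * sst) {
    # constant response (up to floating-point noise): no trend to test
    f <- 0; p <- 1; r2 <- 0
  } else if (sse <= 1e-12 * sst) {
    f <- Inf; p <- 0; r2 <- 1
  } else {
    f <- ssr / (sse / df2)
    p <- stats::pf(f, 1, df2, lower.tail = FALSE)
    r2 <- ssr / (ssr + sse)
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, p_value = p, f_statistic = f,
                 df = c(1, df2), model = "linear_vs_constant"),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend_result: %s> slope = %.4g, R^2 = %.3f, p = %.3g\n",
              x$model, x$slope, x$r_squared, x$p_value))
  invisible(x)
}

#' Logistic trend versus a constant model
#'
#' Binomial logistic regression of a proportion on time, compared to the
#' intercept-only model with a likelihood-ratio chi-squared test, as used for
#' the percent of contacts evoking hand percepts and per-descriptor reporting
#' rates. Complete or quasi-complete separation is detected (via glm
#' convergence warnings or divergent coefficients) and handled by a
#' Haldane-Anscombe 0.5 continuity-corrected refit, flagged in the result.
#'
#' @param x numeric time covariate (weeks).
#' @param successes integer vector of successes per session.
#' @param totals integer vector (or scalar) of trials per session.
#' @return A `trend_result` list: `slope` (log-odds per week), `intercept`,
#'   `p_value`, `chisq`, `separation` flag, `model = "logistic_vs_constant"`.
#' @export
logistic_trend_test <- function(x, successes, totals) {
  if (length(totals) == 1) totals <- rep(totals, length(successes))
  if (any(totals <= 0)) stop("totals must be positive")
  fit_once <- function(s, t) {
    full <- stats::glm(cbind(s, t - s) ~ x, family = stats::binomial())
    null <- stats::glm(cbind(s, t - s) ~ 1, family = stats::binomial())
    list(full = full, null = null)
  }
  fits <- withCallingHandlers(
    fit_once(successes, totals),
    warning = function(w) invokeRestart("muffleWarning"))
  separated <- !fits$full$converged ||
    abs(stats::coef(fits$full)[2]) > 50
  if (separated) {
    # continuity-corrected refit keeps the likelihood finite
    fits <- withCallingHandlers(
      fit_once(successes + 0.5, totals + 1),
      warning = function(w) invokeRestart("muffleWarning"))
  }
  dev_drop <- fits$null$deviance - fits$full$deviance
  p <- stats::pchisq(max(dev_drop, 0), df = 1, lower.tail = FALSE)
  structure(list(slope = unname(stats::coef(fits$full)[2]),
                 intercept = unname(stats::coef(fits$full)[1]),
                 r_squared = NA_real_, p_value = p,
                 chisq = max(dev_drop, 0), separation = separated,
                 model = "logistic_vs_constant"),
            class = "trend_result")
}

#' Nonparametric group comparison
#'
#' Dispatches on the shape of the data the way the study did: a paired
#' Wilcoxon signed-rank test for two paired samples, a Wilcoxon rank-sum test
#' for two independent samples, and a one-way Kruskal-Wallis test with a
#' Tukey-style (studentized-range on mean ranks, i.e. Nemenyi) family-wise
#' adjusted post-hoc for three or more groups.
#'
#' @param groups a list of numeric vectors (>= 2 groups).
#' @param paired logical; only valid for two equal-length groups.
#' @param alternative test direction, passed to the two-group tests
#'   (`"greater"` reproduces the study's right-tailed survey comparisons).
#' @return A list with `method`, `statistic`, `p_value`, and for >= 3 groups
#'   `pairwise_p` (symmetric matrix of family-wise adjusted p-values).
#' @export
group_compare <- function(groups, paired = FALSE,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (any(lengths(groups) == 0)) stop("empty group")
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  if (paired) {
    if (k != 2 || length(groups[[1]]) != length(groups[[2]]))
      stop("paired comparison needs exactly 2 equal-length groups")
    if (all(groups[[1]] == groups[[2]])) {
      # all differences zero: no evidence against the null
      return(list(method = "wilcoxon_signed_rank", statistic = 0,
                  p_value = 1))
    }
    ht <- suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]], paired = TRUE,
                         alternative = alternative, exact = NULL))
    return(list(method = "wilcoxon_signed_rank",
                statistic = unname(ht$statistic), p_value = ht$p.value))
  }
  if (k == 2) {
    ht <- suppressWarnings(
      stats::wilcox.test(groups[[1]], groups[[2]],
                         alternative = alternative, exact = NULL))
    return(list(method = "wilcoxon_rank_sum",
                statistic = unname(ht$statistic), p_value = ht$p.value))
  }
  ht <- stats::kruskal.test(groups)
  # Tukey-style post-hoc on mean ranks (Nemenyi): q = diff of mean ranks over
  # SE, referred to the studentized range with k groups and df = Inf
  pooled <- unlist(groups)
  ranks <- rank(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  mean_ranks <- tapply(ranks, idx, mean)
  n <- length(pooled)
  pw <- matrix(NA_real_, k, k)
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      se <- sqrt(n * (n + 1) / 12 *
                   (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
      q <- abs(mean_ranks[i] - mean_ranks[j]) / se * sqrt(2)
      pw[i, j] <- pw[j, i] <- stats::ptukey(q, k, Inf, lower.tail = FALSE)
    }
  }
  diag(pw) <- 1
  list(method = "kruskal_wallis_tukey",
       statistic = unname(ht$statistic), p_value = ht$p.value,
       pairwise_p = pw)
}

#' AM-ULA summary score
#'
#' Aggregates a tasks x repetitions grid of 0-4 item scores following the
#' validated protocol: mean score per task across surviving repetitions, mean
#' of those task means, times 10. Repetitions in which the prosthesis
#' malfunctioned should be entered as `NA`; tasks with no surviving
#' repetition are dropped with a warning.
#'
#' @param task_scores numeric matrix, tasks x repetitions, scores in `[0, 4]`
#'   (`NA` = removed trial).
#' @return The summary score (0-40 scale).
#' @export
#' @examples
#' amula_summary(matrix(2, 18, 3))  # 20
amula_summary <- function(task_scores) {
  task_scores <- as.matrix(task_scores)
  if (any(task_scores < 0 | task_scores > 4, na.rm = TRUE))
    stop("scores must lie in [0, 4]")
  task_means <- rowMeans(task_scores, na.rm = TRUE)
  dead <- is.nan(task_means)
  if (all(dead)) stop("no task has a surviving repetition")
  if (any(dead)) {
    warning(sum(dead), " task(s) with no surviving repetitions dropped")
    task_means <- task_means[!dead]
  }
  10 * mean(task_means)
}

#' Compare two AM-ULA condition scores against the minimum detectable change
#'
#' @param score_a,score_b summary scores from [amula_summary()].
#' @param mdc minimum detectable change (4.4 at 95% confidence for the
#'   AM-ULA).
#' @return A list with `difference`, `mdc`, and `meaningful` (`TRUE` iff
#'   `|difference| > mdc`).
#' @export
#' @examples
#' amula_compare(14.4, 13.9)$meaningful  # FALSE
amula_compare <- function(score_a, score_b, mdc = 4.4) {
  d <- score_a - score_b
  list(difference = d, mdc = mdc, meaningful = abs(d) > mdc)
}
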