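#' Bivariate association statistics
#'
#' Cross-sectional 2x2 tables are laid out as (a, b, c, d) = (exposed with
#' outcome, exposed without, referent with outcome, referent without). The
#' prevalence odds ratio is the cross-product ad/bc with a Woolf (log-odds)
#' confidence interval. Fisher's exact test follows the probability-mass
#' convention for the two-sided p-value.
#'
#' @name stats-module
NULL

#' Construct a 2x2 contingency table
#'
#' @param a,b exposed counts with / without the outcome.
#' @param c,d referent counts with / without the outcome.
#' @return list of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop_("2x2 cells must be nonnegative integers")
  }
  if (sum(cells) == 0) stop_("2x2 table is all zero")
  structure(as.list(cells), class = "contingency_2x2")
}

#' Prevalence odds ratio with Woolf confidence interval
#'
#' POR = (a/b)/(c/d) = ad/bc; the CI is exp(log POR +/- z * SE) with
#' SE = sqrt(1/a + 1/b + 1/c + 1/d). If any cell is zero, the Haldane-Anscombe
#' continuity correction (0.5 added to every cell) is applied and the result is
#' tagged `continuity_corrected`; a table with an all-zero row or column margin
#' is undefined and errors.
#'
#' @param t a `contingency_2x2`.
#' @param z normal quantile for the interval (default 1.959964, a 95% CI).
#' @return list of class `association_result`: `por`, `ci_low`, `ci_high`,
#'   `method`, `continuity_corrected`.
#' @examples
#' prevalence_odds_ratio(contingency_2x2(236, 143, 71, 22))
#' @export
prevalence_odds_ratio <- function(t, z = 1.959964) {
  stopifnot(inherits(t, "contingency_2x2"))
  cells <- c(t$a, t$b, t$c, t$d)
  margins_ok <- all(c(t$a + t$b, t$c + t$d, t$a + t$c, t$b + t$d) > 0)
  if (!margins_ok) stop_("POR undefined: a row or column margin is zero")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  por <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  structure(list(
    por = por,
    ci_low = exp(log(por) - z * se),
    ci_high = exp(log(por) + z * se),
    method = "POR (Woolf CI)",
    continuity_corrected = corrected
  ), class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s: %.2f (%.2f-%.2f)%s\n", x$method, x$por, x$ci_low,
              x$ci_high,
              if (isTRUE(x$continuity_corrected)) " [continuity-corrected]"
              else ""))
  invisible(x)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass method: with the margins fixed,
#' the hypergeometric probabilities of all tables no more probable than the
#' observed one are summed (a relative tolerance of 1e-7 guards against
#' floating-point ties).
#'
#' @param t a `contingency_2x2`.
#' @return two-sided p-value in (0, 1].
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "contingency_2x2"))
  m <- t$a + t$b        # exposed margin
  n <- t$c + t$d        # referent margin
  k <- t$a + t$c        # outcome margin
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(t$a, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Pearson chi-square test of independence
#'
#' @param table an r x c matrix of counts.
#' @return list with `statistic` (sum (O-E)^2/E), `df` = (r-1)(c-1) and
#'   `p_value` (upper tail).
#' @export
chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop_("chi-square undefined: zero row or column margin")
  }
  res <- stats::chisq.test(table, correct = FALSE)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value))
}

#' Two-sample t-test on medication counts
#'
#' Welch's unequal-variance test by default, with a pooled-variance option.
#' Two identical zero-variance samples are reported as p = 1 (no evidence of a
#' difference) with a message rather than an error.
#'
#' @param x,y numeric samples of size >= 2.
#' @param var_equal pool the variances (classical two-sample t-test).
#' @return list with `statistic`, `df`, `p_value`, `mean_x`, `mean_y`.
#' @export
t_test <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop_("both samples need n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      message("both samples constant and equal; p = 1 by convention")
      return(list(statistic = 0, df = NA_real_, p_value = 1,
                  mean_x = mean(x), mean_y = mean(y)))
    }
    stop_("zero variance in both samples with unequal means")
  }
  res <- stats::t.test(x, y, var.equal = var_equal)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, mean_x = mean(x), mean_y = mean(y))
}

#' Odds ratio per additional medication (univariate logistic regression)
#'
#' Fits logit P(y = 1) = alpha + beta x by iteratively reweighted least
#' squares, iterating until the relative change in log-likelihood falls below
#' `tol` (default 1e-10) or `max_iter` iterations. The reported odds ratio is
#' exp(beta) — the multiplicative change in the odds of the outcome per
#' additional medication — with a Wald confidence interval. Complete
#' separation is reported as an error rather than a silently diverging
#' estimate.
#'
#' @param x numeric covariate (per-patient medication counts).
#' @param y binary outcome (0/1 or logical).
#' @param conf_level confidence level for the Wald interval.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @return list of class `logistic_or`: `or`, `ci_low`, `ci_high`, `slope`,
#'   `intercept`, `se_slope`, `p_value` (Wald), `converged`, `n_iter`.
#' @export
logistic_or_per_unit <- function(x, y, conf_level = 0.95, tol = 1e-10,
                                 max_iter = 100) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop_("y must be binary (0/1)")
  if (length(unique(x)) < 2) stop_("x is constant; slope is not identifiable")
  if (length(unique(y)) < 2) stop_("both outcome classes must be present")
  X <- cbind(1, x)
  beta <- c(stats::qlogis(mean(y)), 0)
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - log1p(exp(eta)))
  }
  ll_old <- loglik(beta)
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    if (any(w < 1e-12)) w <- pmax(w, 1e-12)
    z <- eta + (y - mu) / w
    fit <- stats::lm.wfit(X, z, w)
    beta <- fit$coefficients
    ll_new <- loglik(beta)
    if (abs(ll_new - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll_new
  }
  # separation diagnostic: diverging slope or fitted probabilities pinned at
  # 0/1 for every observation
  mu <- stats::plogis(drop(X %*% beta))
  if (!converged || abs(beta[2]) > 30 ||
      all(mu < 1e-8 | mu > 1 - 1e-8)) {
    stop_("logistic fit did not converge (possible complete separation)")
  }
  W <- diag(mu * (1 - mu))
  info <- t(X) %*% W %*% X
  se <- sqrt(diag(solve(info)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  slope <- unname(beta[2])
  structure(list(
    or = exp(slope),
    ci_low = exp(slope - zq * se[2]),
    ci_high = exp(slope + zq * se[2]),
    slope = slope,
    intercept = unname(beta[1]),
    se_slope = unname(se[2]),
    p_value = 2 * stats::pnorm(-abs(slope / se[2])),
    converged = converged,
    n_iter = iter
  ), class = "logistic_or")
}

#' @export
print.logistic_or <- function(x, ...) {
  cat(sprintf(
    "OR per additional unit: %.3f (%.3f-%.3f), Wald p = %.3g\n",
    x$or, x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Association table for a categorical variable against a binary outcome
#'
#' Recreates the published table layout: every non-reference category of the
#' variable is compared to the reference category in a 2x2 table of outcome
#' counts, giving a POR and Woolf CI per category. Patients with a missing
#' value are dropped from that variable's rows (complete-case).
#'
#' @param variable character/factor vector, one value per patient.
#' @param outcome logical vector, one value per patient.
#' @param reference reference category; defaults to the first level observed.
#' @return data.frame: `category`, `n`, `n_outcome`, `n_no_outcome`, `por`,
#'   `ci_low`, `ci_high` (reference row has NA statistics), with POR/CI
#'   rounded to two decimals.
#' @export
association_table <- function(variable, outcome, reference = NULL) {
  keep <- !is.na(variable) & !is.na(outcome)
  variable <- as.character(variable[keep])
  outcome <- as.logical(outcome[keep])
  cats <- unique(variable)
  reference <- reference %||% cats[1]
  if (!reference %in% cats) stop_("reference category not observed")
  c_ref <- sum(variable == reference & outcome)
  d_ref <- sum(variable == reference & !outcome)
  rows <- lapply(c(reference, setdiff(cats, reference)), function(cat) {
    a <- sum(variable == cat & outcome)
    b <- sum(variable == cat & !outcome)
    if (cat == reference) {
      data.frame(category = cat, n = a + b, n_outcome = a, n_no_outcome = b,
                 por = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      res <- prevalence_odds_ratio(contingency_2x2(a, b, c_ref, d_ref))
      data.frame(category = cat, n = a + b, n_outcome = a, n_no_outcome = b,
                 por = round_half_up(res$por, 2),
                 ci_low = round_half_up(res$ci_low, 2),
                 ci_high = round_half_up(res$ci_high, 2),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
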