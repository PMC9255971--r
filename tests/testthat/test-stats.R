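test_that("POR and Woolf CI reproduce published two-decimal values", {
  r1 <- prevalence_odds_ratio(contingency_2x2(236, 143, 71, 22))
  expect_equal(round_half_up(r1$por, 2), 0.51)
  expect_equal(round_half_up(r1$ci_low, 2), 0.30)
  expect_equal(round_half_up(r1$ci_high, 2), 0.86)

  r2 <- prevalence_odds_ratio(contingency_2x2(301, 172, 176, 62))
  expect_equal(round_half_up(r2$por, 2), 0.62)
  expect_equal(round_half_up(r2$ci_low, 2), 0.44)
  expect_equal(round_half_up(r2$ci_high, 2), 0.87)

  sym <- prevalence_odds_ratio(contingency_2x2(5, 5, 5, 5))
  expect_equal(sym$por, 1.0)
})

test_that("POR transposition inverts the estimate and swaps the CI", {
  set.seed(17)
  for (rep in 1:10) {
    cells <- sample(1:200, 4)
    r <- prevalence_odds_ratio(do.call(contingency_2x2, as.list(cells)))
    r_t <- prevalence_odds_ratio(contingency_2x2(cells[3], cells[4],
                                                 cells[1], cells[2]))
    expect_equal(r_t$por, 1 / r$por)
    expect_equal(r_t$ci_low, 1 / r$ci_high)
    expect_equal(r_t$ci_high, 1 / r$ci_low)
    expect_true(r$ci_low <= r$por && r$por <= r$ci_high)
  }
})

test_that("zero cells trigger the continuity correction; zero margins error", {
  r <- prevalence_odds_ratio(contingency_2x2(10, 0, 5, 5))
  expect_true(r$continuity_corrected)
  expect_equal(r$por, (10.5 * 5.5) / (0.5 * 5.5))
  expect_error(prevalence_odds_ratio(contingency_2x2(0, 0, 5, 5)), "margin")
  expect_error(contingency_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("Fisher exact matches direct hypergeometric enumeration", {
  # (10,0,0,10): only the observed table and its mirror are as extreme;
  # p = 2 / choose(20, 10) = 2/184756
  expect_equal(fisher_exact(contingency_2x2(10, 0, 0, 10)), 2 / 184756)
  expect_equal(fisher_exact(contingency_2x2(5, 5, 5, 5)), 1.0)
})

test_that("Fisher exact agrees with full enumeration and stats::fisher.test", {
  set.seed(29)
  for (rep in 1:40) {
    total <- sample(8:40, 1)
    cells <- as.vector(stats::rmultinom(1, total, prob = runif(4, 0.1, 1)))
    t <- contingency_2x2(cells[1], cells[2], cells[3], cells[4])
    p <- fisher_exact(t)
    expect_equal(p, oracle_fisher(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-12)
    m <- matrix(cells, 2, byrow = TRUE)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
      expect_equal(p, stats::fisher.test(m)$p.value, tolerance = 1e-7)
    }
    expect_gt(p, 0)
    expect_lte(p, 1)
  }
})

test_that("chi-square follows the Pearson formula", {
  prop <- matrix(c(10, 20, 30, 60), 2) # perfectly proportional
  r <- chi_square(prop)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  r2 <- chi_square(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))
  expect_equal(r2$statistic, 20 / 3, tolerance = 1e-12) # hand: 4 * 25/15
  expect_equal(r2$df, 1)

  # 3x2 fixture vs textbook formula recomputation
  tab <- matrix(c(12, 8, 15, 25, 9, 11), nrow = 3, byrow = TRUE)
  r3 <- chi_square(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r3$statistic, sum((tab - expected)^2 / expected))
  expect_equal(r3$df, 2)
  expect_equal(r3$p_value, pchisq(r3$statistic, 2, lower.tail = FALSE))

  expect_error(chi_square(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "margin")
})

test_that("t-test handles identical, separated and degenerate samples", {
  x <- rnorm(30)
  expect_equal(t_test(x, x)$p_value, 1.0)
  set.seed(37)
  a <- rnorm(50)
  expect_lt(t_test(a, a + 100)$p_value, 1e-6)
  expect_message(r <- t_test(rep(2, 5), rep(2, 7)), "convention")
  expect_equal(r$p_value, 1)
  expect_error(t_test(1, c(1, 2)), "n >= 2")
})

test_that("t-test null rejection rate is calibrated at the 5% level", {
  set.seed(41)
  reject <- 0
  for (r in 1:1000) {
    p <- t_test(rnorm(25), rnorm(25))$p_value
    reject <- reject + (p < 0.05)
  }
  expect_gte(reject / 1000, 0.03)
  expect_lte(reject / 1000, 0.07)
})

test_that("logistic fit matches glm and behaves under the null", {
  set.seed(43)
  x <- rpois(400, 5)
  y <- runif(400) < 0.3 # independent of x
  fit <- logistic_or_per_unit(x, y)
  g <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(fit$slope, unname(coef(g)[2]), tolerance = 1e-8)
  expect_equal(fit$intercept, unname(coef(g)[1]), tolerance = 1e-8)
  expect_equal(fit$se_slope,
               unname(sqrt(diag(stats::vcov(g)))[2]), tolerance = 1e-6)
  expect_true(fit$ci_low <= 1 && 1 <= fit$ci_high)
})

test_that("logistic fit rejects degenerate inputs and separation", {
  expect_error(logistic_or_per_unit(rep(3, 10), rbinom(10, 1, 0.5)),
               "constant")
  expect_error(logistic_or_per_unit(1:10, rep(1, 10)), "classes")
  x <- c(1:10, 11:20)
  y <- c(rep(0, 10), rep(1, 10)) # complete separation
  expect_error(logistic_or_per_unit(x, y), "separation|converge")
})

test_that("logistic slope recovers a planted effect as n grows", {
  set.seed(53)
  b <- log(1.39)
  est <- function(n) {
    x <- pmin(rnbinom(n, size = 25, mu = 5.4), 24)
    y <- runif(n) < plogis(-2.9 + b * x)
    logistic_or_per_unit(x, y)$slope
  }
  bias_small <- abs(mean(replicate(30, est(200))) - b)
  bias_large <- abs(mean(replicate(30, est(5000))) - b)
  expect_lt(bias_large, bias_small + 0.01)
  expect_lt(bias_large, 0.02)
})

test_that("association tables mirror the published layout", {
  variable <- c(rep("ref", 40), rep("cat", 60))
  outcome <- c(rep(TRUE, 10), rep(FALSE, 30), rep(TRUE, 30), rep(FALSE, 30))
  tab <- association_table(variable, outcome, reference = "ref")
  expect_equal(tab$category, c("ref", "cat"))
  expect_true(is.na(tab$por[1]))
  manual <- prevalence_odds_ratio(contingency_2x2(30, 30, 10, 30))
  expect_equal(tab$por[2], round_half_up(manual$por, 2))
  # missing values are dropped complete-case
  variable[1:5] <- NA
  tab2 <- association_table(variable, outcome, reference = "ref")
  expect_equal(tab2$n[tab2$category == "ref"], 35)
})
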