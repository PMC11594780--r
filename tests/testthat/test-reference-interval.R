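test_that("D/R one-third rule removes extremes strictly above the threshold", {
  f <- dr_outlier_filter(c(1, 2, 3, 100))
  expect_identical(f$kept, c(1, 2, 3))
  expect_identical(f$removed, 100)

  # D/R exactly one third is retained
  f2 <- dr_outlier_filter(c(1, 2, 3, 4))
  expect_identical(f2$kept, c(1, 2, 3, 4))
  expect_identical(f2$removed, numeric(0))

  # low tail is screened symmetrically
  f3 <- dr_outlier_filter(c(-50, 1, 2, 3))
  expect_identical(f3$kept, c(1, 2, 3))
  expect_identical(f3$removed, -50)

  expect_error(dr_outlier_filter(c(1, 2)), "at least 3")
})

test_that("optional iteration re-applies the rule to a fixed point", {
  x <- c(7, 5, 1000, 8, 6, 100, 9)
  # one pass removes only the largest extreme; 100 is masked by 1000
  f1 <- dr_outlier_filter(x)
  expect_identical(f1$removed, 1000)
  # iterating re-detects 100 once 1000 is gone, then stops (D/R = 1/4)
  f2 <- dr_outlier_filter(x, iterate = TRUE)
  expect_identical(f2$removed, c(1000, 100))
  expect_identical(f2$kept, c(7, 5, 8, 6, 9))
})

test_that("D/R filter matches a brute-force oracle on exhaustive small arrays", {
  alphabet <- c(0, 1, 3, 9)
  for (len in 3:6) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    for (i in seq_len(nrow(grid))) {
      x <- as.numeric(grid[i, ])
      for (iterate in c(FALSE, TRUE)) {
        got <- dr_outlier_filter(x, iterate = iterate)
        want <- dr_oracle(x, iterate = iterate)
        expect_identical(sort(got$kept), sort(want$kept))
        expect_identical(sort(got$removed), sort(want$removed))
      }
    }
  }
})

test_that("nonparametric limits follow the rank p(n+1) convention", {
  expect_equal(nonparametric_limits(1:1000),
               c(lower = 25.025, upper = 975.975), tolerance = 1e-12)
  # boundary ranks clamp to the extreme order statistics
  expect_equal(nonparametric_limits(1:39), c(lower = 1, upper = 39))
  expect_equal(nonparametric_limits(rep(7.5, 50)), c(lower = 7.5, upper = 7.5))
  expect_error(nonparametric_limits(numeric(0)), "empty")
})

test_that("nonparametric limits agree with an independent interpolation oracle", {
  set.seed(101)
  for (i in 1:500) {
    n <- sample(5:2000, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rlnorm(n), runif(n, -10, 10))
    got <- nonparametric_limits(x)
    want <- unname(quantile(x, c(0.025, 0.975), type = 6))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("limit CI rank search reproduces the exact binomial solution", {
  x <- sort(rnorm(120))
  lo <- limit_confidence_interval(x, 0.025, 0.90)
  expect_identical(lo$ranks, c(1L, 7L))
  expect_equal(lo$coverage, 0.9204666, tolerance = 1e-6)
  expect_identical(lo$values, c(x[1], x[7]))

  hi <- limit_confidence_interval(x, 0.975, 0.90)
  expect_identical(hi$ranks, c(114L, 120L))
  expect_equal(hi$coverage, 0.9204666, tolerance = 1e-6)

  # n = 20 cannot attain 90% coverage for the 2.5th percentile
  expect_error(limit_confidence_interval(rnorm(20), 0.025, 0.90), "insufficient n")
})

test_that("limit CI rank search matches an O(n^2) exhaustive oracle", {
  ci_oracle <- function(n, p, conf) {
    best <- NULL
    for (l in 1:(n - 1)) for (u in (l + 1):n) {
      cov <- pbinom(u - 1, n, p) - pbinom(l - 1, n, p)
      if (cov >= conf) {
        cand <- list(l = l, u = u, w = u - l, off = abs((l + u) / 2 - p * (n + 1)))
        if (is.null(best) || cand$w < best$w ||
            (cand$w == best$w && cand$off < best$off)) best <- cand
      }
    }
    best
  }
  set.seed(55)
  cases <- expand.grid(n = c(60, 120, 147, 250), p = c(0.025, 0.1, 0.5, 0.9, 0.975))
  for (i in seq_len(nrow(cases))) {
    n <- cases$n[i]; p <- cases$p[i]
    want <- ci_oracle(n, p, 0.90)
    if (is.null(want)) {
      # no rank pair attains the confidence level at this n
      expect_error(limit_confidence_interval(rnorm(n), p, 0.90), "insufficient n")
    } else {
      got <- limit_confidence_interval(rnorm(n), p, 0.90)
      expect_identical(got$ranks, as.integer(c(want$l, want$u)),
                       label = sprintf("ranks for n=%d p=%.3f", n, p))
    }
  }
})

test_that("the rank-(1,7) CI covers the true 2.5th percentile at its exact rate", {
  set.seed(202)
  n_sim <- 5000
  true_q <- qnorm(0.025)
  hits <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    x <- sort(rnorm(120))
    hits[i] <- x[1] <= true_q && true_q <= x[7]
  }
  # exact coverage is 0.9204666; Monte Carlo tolerance ~3.5 SE
  expect_gt(mean(hits), 0.90)
  expect_equal(mean(hits), 0.9204666, tolerance = 0.015)
})

test_that("establish_ri recovers standard-normal limits at n = 1000", {
  set.seed(31)
  ri <- establish_ri(rnorm(1000), index = "test", zone = "gamma")
  expect_lt(abs(ri$lower - qnorm(0.025)), 0.35)
  expect_lt(abs(ri$upper - qnorm(0.975)), 0.35)
  expect_identical(ri$n, 1000L)
  # CI endpoints are order statistics bracketing each limit
  expect_true(ri$lower_ci[1] <= ri$lower && ri$lower <= ri$lower_ci[2])
  expect_true(ri$upper_ci[1] <= ri$upper && ri$upper <= ri$upper_ci[2])
  td <- tidy(ri)
  expect_identical(td$index, "test")
  expect_identical(td$n, 1000L)
  gl <- glance(ri)
  expect_gte(gl$lower_ci_coverage, 0.90)
})

test_that("gross outliers are removed and the sample replenished to target n", {
  set.seed(32)
  vals <- c(rnorm(999), 1e6)
  reserve <- rnorm(50)
  ri <- establish_ri(vals, replenish = reserve, target_n = 1000)
  expect_identical(ri$n, 1000L)
  expect_gte(ri$n_outliers_removed, 1L)
  expect_true(1e6 %in% ri$removed)
  expect_lt(ri$upper, 10)

  # an exhausted reserve is an explicit error
  expect_error(establish_ri(c(rnorm(99), 1e6), replenish = numeric(0), target_n = 100),
               "exhausted")
})

test_that("constant input gives a degenerate interval with degenerate CIs", {
  ri <- establish_ri(rep(3.25, 200))
  expect_identical(ri$lower, 3.25)
  expect_identical(ri$upper, 3.25)
  expect_identical(ri$lower_ci, c(3.25, 3.25))
  expect_identical(ri$upper_ci, c(3.25, 3.25))
  expect_identical(ri$n_outliers_removed, 0L)
})

test_that("binomial validation applies the 10%/20% thresholds to strict exceedances", {
  ri <- list(lower = -1, upper = 1)
  mk <- function(k_out, n = 20) c(rep(0, n - k_out), rep(2, k_out))
  expect_identical(validate_ri(ri, mk(2))$status, "valid")
  expect_identical(validate_ri(ri, mk(3))$status, "indeterminate")
  expect_identical(validate_ri(ri, mk(5))$status, "invalid")
  # boundary values are inside (strict comparison)
  v <- validate_ri(ri, c(-1, 1, 0))
  expect_identical(v$n_outside, 0L)
  expect_identical(v$status, "valid")
  expect_error(validate_ri(ri, numeric(0)), "at least one")
})

test_that("widening an interval never increases the number outside", {
  set.seed(77)
  vals <- rnorm(200)
  widths <- seq(0.5, 3, by = 0.25)
  outside <- vapply(widths, function(w) {
    validate_ri(list(lower = -w, upper = w), vals)$n_outside
  }, integer(1))
  expect_true(all(diff(outside) <= 0))
})

test_that("establish_ri_table fits all ten index/zone combinations with complementation", {
  cohort <- simulate_cohort(200, c(normal = 1), sim_config(), seed = 41)
  panel <- compute_panels(cohort)
  reserve <- simulate_cohort(60, c(normal = 1), sim_config(), seed = 42)
  reserve_panel <- compute_panels(reserve)
  used <- 0L
  replenish <- function(k) {
    ids <- unique(reserve_panel$case_id)[(used + 1L):(used + k)]
    used <<- used + k
    reserve_panel[reserve_panel$case_id %in% ids, ]
  }
  rit <- establish_ri_table(panel, replenish = replenish, target_n = 200)
  expect_identical(nrow(rit), 10L)
  expect_setequal(rit$index, c("sharpness", "light_chain", "igg", "iga", "igm"))
  expect_true(all(rit$lower <= rit$upper))
  expect_true(all(rit$n == 200L))
  expect_true(all(rit$lower_ci_lo <= rit$lower & rit$lower <= rit$lower_ci_hi))
  expect_true(all(rit$upper_ci_lo <= rit$upper & rit$upper <= rit$upper_ci_hi))

  vre <- validate_ri_table(rit, compute_panels(
    simulate_cohort(20, c(normal = 1), sim_config(), seed = 43)))
  expect_identical(nrow(vre), 10L)
  expect_true(all(vre$n_total == 20L))
  expect_true(all(vre$status %in% c("valid", "indeterminate", "invalid")))
})

test_that("display rounding reports integers except the light chain index", {
  rit <- tibble::tibble(index = c("sharpness", "light_chain"), zone = "gamma",
                        lower = c(1.4, 1.056), upper = c(6.6, 2.714),
                        lower_ci_lo = c(1.1, 1.01), lower_ci_hi = c(1.9, 1.11),
                        upper_ci_lo = c(6.2, 2.61), upper_ci_hi = c(7.1, 2.81),
                        n = 100L, n_outliers_removed = 0L)
  rr <- report_ri(rit)
  expect_identical(rr$lower, c(1, 1.06))
  expect_identical(rr$upper, c(7, 2.71))
})
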