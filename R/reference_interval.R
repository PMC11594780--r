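#' D/R one-third rule for outlier exclusion
#'
#' For the largest (and, symmetrically, the smallest) observation, `D` is
#' the absolute gap to its adjacent observation and `R` is the sample
#' range; an extreme is excluded when `D/R` strictly exceeds one third
#' (equality retains the point). By default the rule is applied in a
#' single pass over both extremes, the form in which it screens a
#' reference sample before limit estimation; re-screening after sample
#' complementation happens in [establish_ri()]. With `iterate = TRUE` the
#' pass is instead repeated on the remaining values until none is removed.
#' Within one pass, when both extremes qualify, the one with the larger
#' `D/R` is recorded first.
#'
#' @param values Numeric vector, `n >= 3`.
#' @param iterate Re-apply the rule to a fixed point (default `FALSE`:
#'   one pass). Note that small regular samples can erode completely
#'   under iteration (in `c(1, 2, 3)` the extremes have `D/R = 1/2`).
#' @return List with `kept` (surviving values, original order) and
#'   `removed` (excluded values in removal order).
#' @examples
#' dr_outlier_filter(c(1, 2, 3, 100))
#' @export
dr_outlier_filter <- function(values, iterate = FALSE) {
  if (length(values) < 3L) abort("D/R outlier screening needs at least 3 values.")
  if (anyNA(values)) abort("values must not contain NA.")
  x <- sort(values)
  removed <- numeric()
  repeat {
    n <- length(x)
    if (n < 3L) break
    r <- x[n] - x[1L]
    if (r <= 0) break
    d_hi <- x[n] - x[n - 1L]
    d_lo <- x[2L] - x[1L]
    hit_hi <- d_hi / r > 1 / 3
    hit_lo <- d_lo / r > 1 / 3
    if (!hit_hi && !hit_lo) break
    if (hit_hi && hit_lo) {
      pass <- if (d_hi >= d_lo) c(x[n], x[1L]) else c(x[1L], x[n])
      x <- x[-c(1L, n)]
    } else if (hit_hi) {
      pass <- x[n]; x <- x[-n]
    } else {
      pass <- x[1L]; x <- x[-1L]
    }
    removed <- c(removed, pass)
    if (!iterate) break
  }
  kept <- values
  for (v in removed) kept <- kept[-match(v, kept)]
  list(kept = kept, removed = removed)
}

## rank-based percentile: rank r = p(n+1), linear interpolation between
## adjacent order statistics, clamped to [1, n]
np_quantile <- function(sorted, p) {
  n <- length(sorted)
  r <- pmin(pmax(p * (n + 1), 1), n)
  lo <- floor(r)
  hi <- pmin(lo + 1, n)
  unname(sorted[lo] + (r - lo) * (sorted[hi] - sorted[lo]))
}

#' Nonparametric reference limits
#'
#' The lower and upper limits of a central `coverage` interval, estimated
#' by the rank-based nonparametric method: the limit at percentile `p` is
#' the order statistic of rank `p (n + 1)`, linearly interpolated between
#' adjacent order statistics for fractional ranks and clamped to
#' `[1, n]`.
#'
#' @param values Numeric vector, `n >= 2` (a single value yields a
#'   degenerate interval).
#' @param coverage Central coverage (default 0.95, i.e. the 2.5th and
#'   97.5th percentiles).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' nonparametric_limits(1:1000)  # 25.025, 975.975
#' @export
nonparametric_limits <- function(values, coverage = 0.95) {
  if (!length(values)) abort("cannot compute limits of an empty sample.")
  if (anyNA(values)) abort("values must not contain NA.")
  s <- sort(values)
  a <- (1 - coverage) / 2
  c(lower = np_quantile(s, a), upper = np_quantile(s, 1 - a))
}

#' Order-statistic confidence interval for a percentile
#'
#' Chooses order-statistic ranks `1 <= l < u <= n` bracketing the `p`-th
#' percentile so that the exact binomial coverage
#' `P(l <= B <= u - 1)`, `B ~ Binomial(n, p)`, is at least `conf`,
#' minimizing the width `u - l`; ties between equally narrow pairs are
#' broken toward the pair most central around the expected rank
#' `p (n + 1)`. No normal approximation is used.
#'
#' @param values Numeric vector (sorted internally).
#' @param p Percentile in (0, 1), e.g. 0.025 or 0.975.
#' @param conf Two-tailed confidence level (default 0.90).
#' @return List with `ranks` `c(l, u)`, `values` (the data values at those
#'   ranks), and `coverage` (achieved exact coverage).
#' @examples
#' x <- rnorm(120)
#' limit_confidence_interval(x, 0.025)$ranks  # 1 7
#' @export
limit_confidence_interval <- function(values, p, conf = 0.90) {
  n <- length(values)
  if (anyNA(values)) abort("values must not contain NA.")
  best <- NULL
  center <- p * (n + 1)
  for (l in seq_len(n - 1L)) {
    lo_mass <- pbinom(l - 1L, n, p)
    target <- lo_mass + conf
    if (target > pbinom(n - 1L, n, p)) break  # no feasible u for this or larger l
    u <- qbinom(target, n, p) + 1L
    if (u <= l || u > n) next
    cov <- pbinom(u - 1L, n, p) - lo_mass
    if (cov < conf) next
    cand <- list(l = l, u = u, cov = cov, width = u - l,
                 off = abs((l + u) / 2 - center))
    if (is.null(best) || cand$width < best$width ||
        (cand$width == best$width && cand$off < best$off)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    abort(sprintf("insufficient n (%d) for a %.0f%% confidence interval of the %.3g percentile.",
                  n, 100 * conf, 100 * p))
  }
  s <- sort(values)
  list(ranks = as.integer(c(best$l, best$u)),
       values = c(s[best$l], s[best$u]), coverage = best$cov)
}

#' Establish a nonparametric reference interval
#'
#' Full establishment procedure: iterated D/R outlier screening, optional
#' complementation of removed samples back to `target_n` from a replenish
#' source (with re-screening of the complemented sample), rank-based
#' 2.5th/97.5th percentile limits, and exact-binomial 90% confidence
#' intervals of both limits.
#'
#' @param values Numeric vector of index values from reference
#'   individuals.
#' @param replenish Optional source of replacement values: a numeric
#'   reserve consumed in order, or a function `f(k)` returning `k` fresh
#'   values. When provided, the sample is complemented back to `target_n`
#'   after each screening pass.
#' @param target_n Sample size to complement back to (default: the input
#'   size).
#' @param coverage Central coverage of the interval (default 0.95).
#' @param conf Confidence level for the limit CIs (default 0.90).
#' @param index,zone Optional labels stored in the result.
#' @return An object of class `czeis_ri`: list with `index`, `zone`,
#'   `lower`, `upper`, `lower_ci`, `upper_ci` (each `c(lo, hi)`),
#'   `lower_ci_ranks`, `upper_ci_ranks`, `ci_coverage`, `n`,
#'   `n_outliers_removed`, `removed`, `coverage`, `conf`. Has [tidy()] and
#'   [glance()] methods.
#' @export
establish_ri <- function(values, replenish = NULL, target_n = length(values),
                         coverage = 0.95, conf = 0.90,
                         index = NA_character_, zone = NA_character_) {
  draw <- NULL
  if (!is.null(replenish)) {
    if (is.function(replenish)) {
      draw <- replenish
    } else {
      reserve <- as.numeric(replenish)
      pos <- 0L
      draw <- function(k) {
        if (pos + k > length(reserve)) abort("replenish source exhausted.")
        out <- reserve[(pos + 1L):(pos + k)]
        pos <<- pos + k
        out
      }
    }
    if (length(values) < target_n) {
      values <- c(values, draw(target_n - length(values)))
    }
  }
  removed_all <- numeric()
  repeat {
    flt <- dr_outlier_filter(values)
    removed_all <- c(removed_all, flt$removed)
    values <- flt$kept
    if (!length(flt$removed) || is.null(draw)) break
    values <- c(values, draw(target_n - length(values)))
  }
  lim <- nonparametric_limits(values, coverage)
  a <- (1 - coverage) / 2
  ci_lo <- limit_confidence_interval(values, a, conf)
  ci_hi <- limit_confidence_interval(values, 1 - a, conf)
  structure(
    list(index = index, zone = zone,
         lower = lim[["lower"]], upper = lim[["upper"]],
         lower_ci = ci_lo$values, upper_ci = ci_hi$values,
         lower_ci_ranks = ci_lo$ranks, upper_ci_ranks = ci_hi$ranks,
         ci_coverage = c(lower = ci_lo$coverage, upper = ci_hi$coverage),
         n = length(values), n_outliers_removed = length(removed_all),
         removed = removed_all, coverage = coverage, conf = conf),
    class = "czeis_ri"
  )
}

#' @export
print.czeis_ri <- function(x, ...) {
  lab <- if (is.na(x$index)) "" else sprintf(" %s/%s", x$index, x$zone)
  cat(sprintf("<czeis_ri>%s [%.4g, %.4g] (n=%d, %d outliers removed)\n",
              lab, x$lower, x$upper, x$n, x$n_outliers_removed))
  cat(sprintf("  %.0f%% CI lower limit: [%.4g, %.4g]; upper limit: [%.4g, %.4g]\n",
              100 * x$conf, x$lower_ci[1], x$lower_ci[2],
              x$upper_ci[1], x$upper_ci[2]))
  invisible(x)
}

#' Validate a reference interval against new reference individuals
#'
#' Binomial transference validation: count the values strictly outside
#' the interval. The interval is *valid* when no more than 10% of the
#' individuals fall outside (`n_outside <= floor(0.10 n)`), *invalid* when
#' more than 20% fall outside, and *indeterminate* (further testing)
#' in between. Comparisons use full precision.
#'
#' @param ri A `czeis_ri`, or anything with `lower`/`upper` elements, or a
#'   numeric `c(lower, upper)`.
#' @param values Index values of the validation individuals (`n >= 1`).
#' @return Object of class `czeis_validation`: list with `n_total`,
#'   `n_outside`, `status` (`"valid"`, `"indeterminate"`, `"invalid"`),
#'   and `outside` (per-case logical flags).
#' @examples
#' ri <- establish_ri(rnorm(1000))
#' validate_ri(ri, rnorm(20))
#' @export
validate_ri <- function(ri, values) {
  if (is.numeric(ri) && length(ri) == 2L) ri <- list(lower = ri[1], upper = ri[2])
  if (!length(values)) abort("validation needs at least one value.")
  outside <- values < ri$lower | values > ri$upper
  n <- length(values)
  k <- sum(outside)
  status <- if (k <= floor(0.10 * n + 1e-9)) "valid"
            else if (k > 0.20 * n + 1e-9) "invalid"
            else "indeterminate"
  structure(list(n_total = n, n_outside = k, status = status, outside = outside),
            class = "czeis_validation")
}

#' @export
print.czeis_validation <- function(x, ...) {
  cat(sprintf("<czeis_validation> %s (%d/%d outside)\n",
              x$status, x$n_outside, x$n_total))
  invisible(x)
}

panel_index_values <- function(panel, index, zone) {
  v <- panel[[index]][panel$zone == zone]
  v[!is.na(v)]
}

#' Establish reference intervals for all ten index/zone combinations
#'
#' Runs [establish_ri()] for each of the five indexes in each of the gamma
#' and beta-2 zones of an index panel. Undefined light-chain values are
#' excluded from their sample.
#'
#' @param panel Index panel tibble from [compute_panels()].
#' @param replenish Optional function `f(k)` returning a panel tibble for
#'   `k` fresh reference cases; used to complement each index's sample
#'   back to `target_n` after outlier removal.
#' @param target_n Complementation target (default: cases in `panel`).
#' @inheritParams establish_ri
#' @return Tibble of class `czeis_ri_tbl` with one row per index/zone:
#'   `index`, `zone`, `lower`, `upper`, `lower_ci_lo`, `lower_ci_hi`,
#'   `upper_ci_lo`, `upper_ci_hi`, `n`, `n_outliers_removed`.
#' @export
establish_ri_table <- function(panel, replenish = NULL,
                               target_n = length(unique(panel$case_id)),
                               coverage = 0.95, conf = 0.90) {
  grid <- tidyr::expand_grid(index = INDEX_NAMES, zone = c("gamma", "beta2"))
  ris <- purrr::pmap(grid, function(index, zone) {
    vals <- panel_index_values(panel, index, zone)
    rep_fun <- if (is.null(replenish)) NULL else function(k) {
      out <- numeric(0)
      while (length(out) < k) {
        fresh <- replenish(k - length(out))
        out <- c(out, panel_index_values(fresh, index, zone))
      }
      out[seq_len(k)]
    }
    establish_ri(vals, replenish = rep_fun, target_n = target_n,
                 coverage = coverage, conf = conf, index = index, zone = zone)
  })
  out <- purrr::map_dfr(ris, tidy)
  structure(out, ris = ris, class = c("czeis_ri_tbl", class(out)))
}

#' Validate a reference-interval table against an index panel
#'
#' @param ri_tbl Tibble from [establish_ri_table()] (or any tibble with
#'   `index`, `zone`, `lower`, `upper`).
#' @param panel Index panel of the validation individuals.
#' @return Tibble with one row per index/zone: `index`, `zone`, `n_total`,
#'   `n_outside`, `status`.
#' @export
validate_ri_table <- function(ri_tbl, panel) {
  purrr::pmap_dfr(
    ri_tbl[, c("index", "zone", "lower", "upper")],
    function(index, zone, lower, upper) {
      vals <- panel_index_values(panel, index, zone)
      vr <- validate_ri(list(lower = lower, upper = upper), vals)
      tibble(index = index, zone = zone, n_total = vr$n_total,
             n_outside = vr$n_outside, status = vr$status)
    }
  )
}

#' Apply display rounding to a reference-interval table
#'
#' Limits and CI bounds for the light-chain index are reported to 2
#' decimals, all other indexes to the nearest integer. Formatting only;
#' validation and flagging always use full precision.
#'
#' @param ri_tbl Tibble from [establish_ri_table()].
#' @return The table with rounded limit columns.
#' @export
report_ri <- function(ri_tbl) {
  cols <- c("lower", "upper", "lower_ci_lo", "lower_ci_hi",
            "upper_ci_lo", "upper_ci_hi")
  dplyr::mutate(
    ri_tbl,
    dplyr::across(dplyr::any_of(cols),
                  ~ ifelse(.data$index == "light_chain", round(.x, 2), round(.x)))
  )
}
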