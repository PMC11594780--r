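#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a reference interval
#'
#' @param x A `czeis_ri` from [establish_ri()].
#' @param ... Unused.
#' @return One-row tibble: `index`, `zone`, `lower`, `upper`,
#'   `lower_ci_lo`, `lower_ci_hi`, `upper_ci_lo`, `upper_ci_hi`, `n`,
#'   `n_outliers_removed`.
#' @method tidy czeis_ri
#' @export
tidy.czeis_ri <- function(x, ...) {
  tibble(
    index = x$index, zone = x$zone, lower = x$lower, upper = x$upper,
    lower_ci_lo = x$lower_ci[1], lower_ci_hi = x$lower_ci[2],
    upper_ci_lo = x$upper_ci[1], upper_ci_hi = x$upper_ci[2],
    n = x$n, n_outliers_removed = x$n_outliers_removed
  )
}

#' Summarize a reference interval fit
#'
#' @inheritParams tidy.czeis_ri
#' @return One-row tibble: sample size, outliers removed, nominal
#'   coverage, CI confidence level, and the achieved exact binomial
#'   coverages of both limit CIs.
#' @method glance czeis_ri
#' @export
glance.czeis_ri <- function(x, ...) {
  tibble(
    n = x$n, n_outliers_removed = x$n_outliers_removed,
    coverage = x$coverage, conf = x$conf,
    lower_ci_coverage = x$ci_coverage[["lower"]],
    upper_ci_coverage = x$ci_coverage[["upper"]]
  )
}

#' Tidy a validation result
#'
#' @param x A `czeis_validation` from [validate_ri()].
#' @param ... Unused.
#' @return One-row tibble: `n_total`, `n_outside`, `status`.
#' @method tidy czeis_validation
#' @export
tidy.czeis_validation <- function(x, ...) {
  tibble(n_total = x$n_total, n_outside = x$n_outside, status = x$status)
}
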