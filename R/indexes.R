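## optional centered moving average (odd window); off by default everywhere
smooth_channel <- function(v, window) {
  if (is.null(window) || window <= 1L) return(v)
  if (window %% 2L == 0L) abort("smoothing window must be odd.")
  k <- rep(1 / window, window)
  out <- stats::filter(v, k, sides = 2)
  out[is.na(out)] <- v[is.na(out)]
  as.numeric(out)
}

ref_curve <- function(ts, smooth_window = NULL) {
  smooth_channel(ts$channels["REF", ], smooth_window)
}

#' Locate the evaluation peak of a zone
#'
#' The evaluation point for all indexes is the apex of the reference
#' (no-antiserum) curve within the zone: the argmax of `REF` over the
#' half-open interval, ties broken to the smallest index. Prominence is
#' the apex absorbance minus the larger of the two zone-edge `REF` values;
#' it may be zero or negative for flat or edge-peaked zones and is
#' reported so callers can gate on it.
#'
#' @param ts A [trace_set()].
#' @param zones A [zone_map()].
#' @param zone Zone name (must be at least 3 points wide).
#' @param smooth_window Optional odd moving-average window applied to `REF`
#'   before locating the apex (default none).
#' @return List with `zone`, `apex` (0-based index), `apex_absorbance`,
#'   `prominence`.
#' @export
locate_peak <- function(ts, zones, zone, smooth_window = NULL) {
  zi <- zone_interval(zones, zone)
  if (zi["end"] - zi["start"] < 3L) {
    abort(sprintf("zone '%s' is narrower than 3 points.", zone))
  }
  p <- ref_curve(ts, smooth_window)
  seg <- p[(zi["start"] + 1L):zi["end"]]  # 0-based [start, end) -> 1-based
  rel <- which.max(seg)                   # first maximum: smallest index
  apex <- zi[["start"]] + rel - 1L
  list(zone = zone, apex = apex, apex_absorbance = seg[rel],
       prominence = seg[rel] - max(seg[1L], seg[length(seg)]))
}

second_diff_sharpness <- function(p, x) {
  # x is 0-based; negated central second difference, positive at peaks
  -(p[x + 2L] + p[x] - 2 * p[x + 1L])
}

#' Finite-difference sharpness index
#'
#' The sharpness index at a point `x` is the negated central second
#' difference of the reference curve,
#' `-(P(x+1) + P(x-1) - 2 P(x))`, so that sharp peaks score positive and
#' a sharper peak scores higher. By default it is evaluated at the zone
#' apex; `mode = "max"` instead returns the maximum of the expression over
#' the interior points of the zone.
#'
#' @inheritParams locate_peak
#' @param mode `"apex"` (default) or `"max"`.
#' @return Sharpness index (a.u.).
#' @examples
#' ch <- setNames(rep(list(c(0, 0, 1, 0, 0)), 6), c("REF","IgG","IgA","IgM","K","L"))
#' ts <- trace_set("spike", ch)
#' zm <- zone_map(5, fractions = list(beta2 = c(0, 0.2), gamma = c(0.2, 1)))
#' sharpness_index(ts, zm, "gamma")  # 2
#' @export
sharpness_index <- function(ts, zones, zone, mode = c("apex", "max"),
                            smooth_window = NULL) {
  mode <- match.arg(mode)
  p <- ref_curve(ts, smooth_window)
  n <- length(p)
  if (mode == "apex") {
    pk <- locate_peak(ts, zones, zone, smooth_window)
    x <- pk$apex
    if (x < 1L || x > n - 2L) {
      abort(sprintf("apex of zone '%s' lies at the axis boundary; sharpness needs both neighbors.", zone))
    }
    second_diff_sharpness(p, x)
  } else {
    zi <- zone_interval(zones, zone)
    # interior zone points: both neighbors inside the zone and the axis
    xs <- max(zi[["start"]] + 1L, 1L):min(zi[["end"]] - 2L, n - 2L)
    max(second_diff_sharpness(p, xs))
  }
}

#' Light chain index
#'
#' `Q = (P - K) / (P - L)` at the zone apex, where `P`, `K`, `L` are the
#' reference, anti-kappa and anti-lambda curves. Reflects the kappa/lambda
#' balance of the immunoglobulins under the peak; values far from the
#' reference interval in either direction suggest light-chain restriction.
#' When the denominator magnitude falls below `delta` the index is
#' undefined and `NA` is returned with a `reason` attribute.
#'
#' @inheritParams locate_peak
#' @param delta Denominator floor (a.u.); default `1e-9`.
#' @return The index, or `NA` (attribute `reason`) when undefined.
#' @export
light_chain_index <- function(ts, zones, zone, delta = 1e-9,
                              smooth_window = NULL) {
  pk <- locate_peak(ts, zones, zone, smooth_window)
  i <- pk$apex + 1L
  p <- unname(ts$channels["REF", i])
  num <- p - unname(ts$channels["K", i])
  den <- p - unname(ts$channels["L", i])
  if (abs(den) < delta) {
    return(structure(NA_real_,
                     reason = sprintf("light chain index undefined in zone '%s': |P - L| = %.3g below floor %.3g",
                                      zone, abs(den), delta)))
  }
  num / den
}

#' Immunoglobulin (IgG/IgA/IgM) index
#'
#' The immunosubtraction difference `P - G` (respectively `P - A`,
#' `P - M`) at the zone apex: the absorbance removed by the anti-isotype
#' antiserum, a proxy for the concentration of that isotype under the
#' peak. Negative values are meaningful (noise or over-subtraction) and
#' are never clamped.
#'
#' @inheritParams locate_peak
#' @param isotype `"IgG"`, `"IgA"` or `"IgM"`.
#' @return The index (a.u.).
#' @export
immunoglobulin_index <- function(ts, zones, zone, isotype = c("IgG", "IgA", "IgM"),
                                 smooth_window = NULL) {
  isotype <- match.arg(isotype)
  pk <- locate_peak(ts, zones, zone, smooth_window)
  i <- pk$apex + 1L
  unname(ts$channels["REF", i] - ts$channels[isotype, i])
}

panel_one_zone <- function(ts, zones, zone, delta = 1e-9, smooth_window = NULL) {
  pk <- locate_peak(ts, zones, zone, smooth_window)
  x <- pk$apex
  p <- ref_curve(ts, smooth_window)
  n <- length(p)
  sharp <- if (x >= 1L && x <= n - 2L) second_diff_sharpness(p, x) else NA_real_
  i <- x + 1L
  ref <- unname(ts$channels["REF", i])
  num <- ref - unname(ts$channels["K", i])
  den <- ref - unname(ts$channels["L", i])
  lc_undef <- abs(den) < delta
  tibble(
    case_id = ts$case_id, zone = zone,
    sharpness = sharp,
    light_chain = if (lc_undef) NA_real_ else num / den,
    igg = ref - unname(ts$channels["IgG", i]),
    iga = ref - unname(ts$channels["IgA", i]),
    igm = ref - unname(ts$channels["IgM", i]),
    apex_index = x, apex_absorbance = pk$apex_absorbance,
    prominence = pk$prominence, lc_undefined = lc_undef
  )
}

#' Compute the full index panel for one case
#'
#' Evaluates all five indexes (sharpness, light chain, IgG, IgA, IgM) at
#' the reference-curve apex of the gamma and beta-2 zones. Values are kept
#' at full precision; use [report_panel()] for display rounding.
#'
#' @inheritParams light_chain_index
#' @return Tibble with one row per zone (`gamma`, `beta2`) and columns
#'   `case_id`, `zone`, the five indexes, `apex_index`, `apex_absorbance`,
#'   `prominence`, `lc_undefined`.
#' @export
compute_panel <- function(ts, zones = zone_map(ts$n_points), delta = 1e-9,
                          smooth_window = NULL) {
  dplyr::bind_rows(
    panel_one_zone(ts, zones, "gamma", delta, smooth_window),
    panel_one_zone(ts, zones, "beta2", delta, smooth_window)
  )
}

#' Compute index panels for a collection of cases
#'
#' @param cases List of [trace_set()] objects or `czeis_sim_case` objects
#'   (their `traceset` element is used).
#' @inheritParams compute_panel
#' @return Tibble with two rows (gamma, beta2) per case.
#' @export
compute_panels <- function(cases, zones = NULL, delta = 1e-9,
                           smooth_window = NULL) {
  if (inherits(cases, "czeis_trace") || inherits(cases, "czeis_sim_case")) {
    cases <- list(cases)
  }
  cases <- lapply(cases, function(x) if (inherits(x, "czeis_sim_case")) x$traceset else x)
  if (is.null(zones)) zones <- zone_map(cases[[1]]$n_points)
  zone_names <- c("gamma", "beta2")
  zi <- lapply(zone_names, zone_interval, zones = zones)
  m <- 2L * length(cases)
  out <- list(case_id = character(m), zone = rep(zone_names, length(cases)),
              sharpness = numeric(m), light_chain = numeric(m),
              igg = numeric(m), iga = numeric(m), igm = numeric(m),
              apex_index = integer(m), apex_absorbance = numeric(m),
              prominence = numeric(m), lc_undefined = logical(m))
  k <- 0L
  for (ts in cases) {
    ch <- ts$channels
    p <- if (is.null(smooth_window)) ch["REF", ] else smooth_channel(ch["REF", ], smooth_window)
    n <- length(p)
    for (z in 1:2) {
      k <- k + 1L
      s <- zi[[z]][["start"]]; e <- zi[[z]][["end"]]
      seg <- p[(s + 1L):e]
      rel <- which.max(seg)
      x <- s + rel - 1L
      i <- x + 1L
      ref <- ch["REF", i]
      den <- ref - ch["L", i]
      lc_undef <- abs(den) < delta
      out$case_id[k] <- ts$case_id
      out$sharpness[k] <- if (x >= 1L && x <= n - 2L)
        -(p[i + 1L] + p[i - 1L] - 2 * p[i]) else NA_real_
      out$light_chain[k] <- if (lc_undef) NA_real_ else (ref - ch["K", i]) / den
      out$igg[k] <- ref - ch["IgG", i]
      out$iga[k] <- ref - ch["IgA", i]
      out$igm[k] <- ref - ch["IgM", i]
      out$apex_index[k] <- x
      out$apex_absorbance[k] <- seg[rel]
      out$prominence[k] <- seg[rel] - max(seg[1L], seg[length(seg)])
      out$lc_undefined[k] <- lc_undef
    }
  }
  tibble::new_tibble(out, nrow = m)
}

#' Apply display rounding to an index panel
#'
#' Reported values follow the printed precision conventional for these
#' indexes: light chain to 2 decimals, all other indexes to the nearest
#' integer. Stored full-precision values should be used for any
#' computation; this is formatting only.
#'
#' @param panel Tibble from [compute_panel()]/[compute_panels()].
#' @return The panel with rounded index columns.
#' @export
report_panel <- function(panel) {
  dplyr::mutate(
    panel,
    dplyr::across(dplyr::any_of(c("sharpness", "igg", "iga", "igm")), round),
    dplyr::across(dplyr::any_of("light_chain"), ~ round(.x, 2))
  )
}
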