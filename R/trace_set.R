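#' Construct a CZE-IS trace set
#'
#' A trace set holds one case's six aligned absorbance curves: the reference
#' electrophoresis run without antiserum (`REF`) and the five
#' immunosubtraction runs (`IgG`, `IgA`, `IgM`, `K`, `L`). Values are
#' instrument arbitrary units (UV absorbance); the time axis is implicit,
#' 0-based, with `axis_unit` seconds per point.
#'
#' @param case_id Single string identifying the case.
#' @param channels Named list or matrix of six numeric vectors of equal
#'   length. Names must be exactly `REF`, `IgG`, `IgA`, `IgM`, `K`, `L`
#'   (any order; stored in canonical order). A matrix is taken as channels
#'   in rows, with rownames giving the channel names.
#' @param axis_unit Seconds per point (informational only). Default 1.
#' @param clipped Logical; `TRUE` declares that absorbances have been
#'   clipped at zero, in which case negative values are a violation.
#'   Default `FALSE` (negative values permitted, e.g. raw subtraction
#'   output).
#'
#' @return An object of class `czeis_trace`: a list with elements
#'   `case_id`, `n_points`, `channels` (6 x n_points numeric matrix with
#'   rownames `REF`, `IgG`, `IgA`, `IgM`, `K`, `L`), `axis_unit`, `clipped`.
#'
#' @examples
#' ch <- setNames(rep(list(rep(1, 300)), 6), c("REF","IgG","IgA","IgM","K","L"))
#' ts <- trace_set("case1", ch)
#' validate_traceset(ts)
#' @export
trace_set <- function(case_id, channels, axis_unit = 1, clipped = FALSE) {
  if (!is.character(case_id) || length(case_id) != 1L || is.na(case_id)) {
    abort("`case_id` must be a single non-missing string.")
  }
  if (is.matrix(channels)) {
    mat <- channels
  } else if (is.list(channels)) {
    lens <- lengths(channels)
    if (length(unique(lens)) > 1L) {
      # keep the ragged input representable: pad with NA so validation reports it
      n <- max(lens)
      mat <- matrix(NA_real_, nrow = length(channels), ncol = n,
                    dimnames = list(names(channels), NULL))
      for (i in seq_along(channels)) mat[i, seq_len(lens[i])] <- channels[[i]]
      attr(mat, "ragged_lengths") <- lens
    } else {
      mat <- do.call(rbind, lapply(channels, as.numeric))
      rownames(mat) <- names(channels)
    }
  } else {
    abort("`channels` must be a named list or matrix.")
  }
  nm <- rownames(mat)
  if (!is.null(nm) && setequal(nm, CHANNELS) && !anyDuplicated(nm)) {
    rg <- attr(mat, "ragged_lengths")
    mat <- mat[CHANNELS, , drop = FALSE]
    attr(mat, "ragged_lengths") <- rg
  }
  structure(
    list(case_id = case_id, n_points = ncol(mat), channels = mat,
         axis_unit = axis_unit, clipped = isTRUE(clipped)),
    class = "czeis_trace"
  )
}

#' @export
print.czeis_trace <- function(x, ...) {
  cat(sprintf("<czeis_trace> case '%s': %d channels x %d points\n",
              x$case_id, nrow(x$channels), x$n_points))
  invisible(x)
}

#' Validate a trace set against its structural invariants
#'
#' Checks that exactly the six canonical channels are present without
#' duplicates, that all channels have equal length, that all values are
#' finite, and (when the trace declares itself clipped) that no value is
#' negative. Violations are described, never raised, so the function is
#' total over well-typed input.
#'
#' @param ts A [trace_set()] object.
#' @return Character vector of violation descriptions; empty if the trace
#'   set satisfies all invariants.
#' @export
validate_traceset <- function(ts) {
  out <- character()
  if (!inherits(ts, "czeis_trace")) return("not a czeis_trace object")
  mat <- ts$channels
  nm <- rownames(mat)
  if (is.null(nm)) {
    out <- c(out, "channels are unnamed")
    nm <- character()
  }
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    out <- c(out, sprintf("duplicate channel '%s'", dup))
  }
  missing <- setdiff(CHANNELS, nm)
  if (length(missing)) {
    out <- c(out, sprintf("missing channel '%s'", missing))
  }
  extra <- setdiff(nm, CHANNELS)
  if (length(extra)) {
    out <- c(out, sprintf("unknown channel '%s'", extra))
  }
  ragged <- attr(mat, "ragged_lengths")
  if (!is.null(ragged)) {
    out <- c(out, sprintf("ragged length: channel '%s' has %d points, expected %d",
                          names(ragged)[ragged != ts$n_points],
                          ragged[ragged != ts$n_points], ts$n_points))
  } else if (!is.numeric(mat)) {
    out <- c(out, "non-numeric channel values")
  }
  if (is.numeric(mat) && is.null(ragged)) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)
    if (nrow(bad)) {
      out <- c(out, sprintf("non-finite value in channel '%s' at t=%d",
                            rownames(mat)[bad[, 1]], bad[, 2] - 1L))
    }
    if (ts$clipped && any(mat < 0, na.rm = TRUE)) {
      out <- c(out, "negative absorbance in a trace declared clipped")
    }
  }
  out
}

#' Define electrophoretic zones on the point axis
#'
#' Maps the six serum protein electrophoresis zones (albumin, alpha-1,
#' alpha-2, beta-1, beta-2, gamma) to half-open, 0-based index intervals
#' `[start, end)` on an `n_points` axis. Boundaries are given as fractions
#' of the axis and are fully configurable; the defaults follow a typical
#' SPEP fraction layout. With `orientation = "gamma_first"` the zones are
#' mirrored, for instruments whose export runs gamma at low indices.
#'
#' @param n_points Axis length (default 300).
#' @param fractions Named list mapping each zone to `c(start, end)`
#'   fractions in `[0, 1]`, in albumin-to-gamma order.
#' @param orientation `"albumin_first"` (default) or `"gamma_first"`.
#' @return A tibble of class `czeis_zones` with columns `zone`, `start`,
#'   `end` (0-based, half-open) and attributes `n_points`, `orientation`.
#' @examples
#' zone_map()
#' zone_map(300, orientation = "gamma_first")
#' @export
zone_map <- function(n_points = 300,
                     fractions = list(
                       albumin = c(0.05, 0.25), alpha1 = c(0.25, 0.35),
                       alpha2  = c(0.35, 0.48), beta1  = c(0.48, 0.58),
                       beta2   = c(0.58, 0.70), gamma  = c(0.70, 0.98)
                     ),
                     orientation = c("albumin_first", "gamma_first")) {
  orientation <- match.arg(orientation)
  if (!all(c("beta2", "gamma") %in% names(fractions))) {
    abort("zone map must define at least the beta2 and gamma zones.")
  }
  fr <- do.call(rbind, fractions)
  if (any(fr < 0) || any(fr > 1) || any(fr[, 1] >= fr[, 2])) {
    abort("zone fractions must satisfy 0 <= start < end <= 1.")
  }
  if (any(fr[-1, 1] < fr[-nrow(fr), 2])) {
    abort("zone intervals must be disjoint and ordered.")
  }
  start <- as.integer(round(fr[, 1] * n_points))
  end <- as.integer(round(fr[, 2] * n_points))
  zones <- tibble(zone = names(fractions), start = start, end = end)
  if (orientation == "gamma_first") {
    zones <- tibble(zone = rev(zones$zone),
                    start = rev(as.integer(n_points) - zones$end),
                    end = rev(as.integer(n_points) - zones$start))
  }
  structure(zones, n_points = n_points, orientation = orientation,
            class = c("czeis_zones", class(zones)))
}

#' Read a zone map from a YAML or JSON configuration file
#'
#' The file must contain a `zones` mapping from zone name to
#' `[start_fraction, end_fraction]` and may contain `orientation` and
#' `n_points` keys.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param n_points Axis length, used when the file does not set it.
#' @return A [zone_map()] tibble.
#' @export
read_zone_map <- function(path, n_points = 300) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg$zones)) abort("zone config must have a 'zones' mapping.")
  fractions <- lapply(cfg$zones, function(z) as.numeric(z)[1:2])
  zone_map(n_points = cfg$n_points %||% n_points,
           fractions = fractions,
           orientation = cfg$orientation %||% "albumin_first")
}

zone_interval <- function(zones, zone) {
  i <- match(zone, zones$zone)
  if (is.na(i)) abort(sprintf("zone '%s' is not defined in the zone map.", zone))
  c(start = zones$start[i], end = zones$end[i])
}
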