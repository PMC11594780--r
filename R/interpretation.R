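#' Default interpretation rule table
#'
#' The pattern call is a pure function of the ten index flags. The rule
#' table is shipped as data (also at
#' `system.file("extdata", "rules_default.csv", package = "czeis")`) so a
#' laboratory can reorder precedence. Predicates, in the package's
#' default precedence:
#'
#' * `suspect_monoclonal` — in some zone, the sharpness flag is high or
#'   the light-chain flag is outside its interval (low or high).
#' * `polyclonal` — some immunoglobulin flag is high while sharpness and
#'   light chain are normal in both zones.
#' * `hypogammaglobulinemia` — some immunoglobulin flag is low, no
#'   immunoglobulin flag is high, and sharpness and light chain are normal
#'   in both zones.
#' * `normal` — all ten flags normal.
#' * `mixed/other` — fallback when no rule fires.
#'
#' @param path Optional CSV with columns `pattern`, `precedence` to
#'   override the default ordering.
#' @return Tibble with columns `pattern`, `precedence`, sorted by
#'   precedence.
#' @export
default_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rules_default.csv", package = "czeis")
  }
  rules <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("pattern", "precedence") %in% names(rules))) {
    abort("rule table must have columns 'pattern' and 'precedence'.")
  }
  dplyr::arrange(as_tibble(rules), .data$precedence)
}

#' Flag an index panel against reference intervals
#'
#' Each defined index value is flagged `low` when strictly below the lower
#' limit, `high` when strictly above the upper limit, and `normal`
#' otherwise (boundary values are normal); undefined light-chain values
#' are flagged `undefined`. Comparisons use full precision.
#'
#' @param panel Index panel tibble from [compute_panels()].
#' @param ri_tbl Reference-interval table with `index`, `zone`, `lower`,
#'   `upper` (e.g. from [establish_ri_table()]).
#' @return Tibble with one row per case/zone/index: `case_id`, `zone`,
#'   `index`, `value`, `lower`, `upper`, `flag`.
#' @export
flag_panel <- function(panel, ri_tbl) {
  long <- tidyr::pivot_longer(
    panel[, c("case_id", "zone", INDEX_NAMES)],
    cols = dplyr::all_of(INDEX_NAMES),
    names_to = "index", values_to = "value"
  )
  joined <- dplyr::left_join(long, ri_tbl[, c("index", "zone", "lower", "upper")],
                             by = c("index", "zone"))
  bad <- dplyr::filter(joined, !is.na(.data$value) & is.na(.data$lower))
  if (nrow(bad)) {
    abort(sprintf("no reference interval for defined index %s in zone %s.",
                  bad$index[1], bad$zone[1]))
  }
  dplyr::mutate(
    joined,
    flag = dplyr::case_when(
      is.na(.data$value) ~ "undefined",
      .data$value < .data$lower ~ "low",
      .data$value > .data$upper ~ "high",
      TRUE ~ "normal"
    )
  )
}

## pattern for one case's ten flags; pure function of the flag table
pattern_from_flags <- function(flags, rules) {
  get_flag <- function(ix, zn) flags$flag[flags$index == ix & flags$zone == zn]
  zones_here <- unique(flags$zone)
  mono_zone <- vapply(zones_here, function(z) {
    get_flag("sharpness", z) == "high" ||
      get_flag("light_chain", z) %in% c("low", "high")
  }, logical(1))
  clonality <- flags$flag[flags$index %in% c("sharpness", "light_chain")]
  ig <- flags$flag[flags$index %in% c("igg", "iga", "igm")]
  fired <- c(
    suspect_monoclonal = any(mono_zone),
    polyclonal = any(ig == "high") && all(clonality == "normal"),
    hypogammaglobulinemia = any(ig == "low") && !any(ig == "high") &&
      all(clonality == "normal"),
    normal = all(flags$flag == "normal")
  )
  for (p in rules$pattern) {
    if (isTRUE(fired[[p]])) return(p)
  }
  "mixed/other"
}

rationale_from_flags <- function(flags, pattern) {
  ab <- flags[flags$flag != "normal", ]
  if (!nrow(ab)) return(sprintf("pattern %s: all ten indexes within their reference intervals", pattern))
  msgs <- purrr::pmap_chr(ab, function(case_id, zone, index, value, lower, upper, flag) {
    if (flag == "undefined") {
      sprintf("%s %s undefined", zone, index)
    } else {
      sprintf("%s %s %.4g %s reference interval [%.4g, %.4g]",
              zone, index, value, if (flag == "high") "above" else "below",
              lower, upper)
    }
  })
  sprintf("pattern %s: %s", pattern, paste(msgs, collapse = "; "))
}

#' Interpret index panels against reference intervals
#'
#' Flags every index with [flag_panel()] and reduces each case's ten flags
#' to a pattern call via the precedence-ordered rule table (see
#' [default_rules()]): monoclonal suspicion from sharpness/light-chain
#' abnormality in either zone, polyclonal from elevated immunoglobulin
#' indexes with clean clonality flags, hypogammaglobulinemia from low
#' immunoglobulin indexes, otherwise normal or mixed/other.
#'
#' @inheritParams flag_panel
#' @param rules Rule table (default [default_rules()]).
#' @return Tibble of class `czeis_interpretation` with one row per case:
#'   `case_id`, `pattern`, `rationale`; the full flag table is attached as
#'   attribute `flags`.
#' @export
interpret_cases <- function(panel, ri_tbl, rules = default_rules()) {
  flags <- flag_panel(panel, ri_tbl)
  out <- flags |>
    dplyr::group_by(.data$case_id) |>
    dplyr::group_modify(function(d, key) {
      pattern <- pattern_from_flags(d, rules)
      tibble(pattern = pattern, rationale = rationale_from_flags(d, pattern))
    }) |>
    dplyr::ungroup()
  out <- out[match(unique(panel$case_id), out$case_id), ]
  structure(out, flags = flags,
            class = c("czeis_interpretation", class(out)))
}

#' Per-index flags of an interpretation
#'
#' @param x A `czeis_interpretation` from [interpret_cases()].
#' @return The flag tibble (one row per case/zone/index).
#' @export
interpretation_flags <- function(x) attr(x, "flags")
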