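#' Convert trace sets to a long tibble
#'
#' @param cases A `czeis_trace` or list of them.
#' @return Tibble with columns `case_id`, `channel`, `t` (0-based),
#'   `absorbance`; channels in canonical order within each case.
#' @export
as_traces_tbl <- function(cases) {
  if (inherits(cases, "czeis_trace")) cases <- list(cases)
  purrr::map_dfr(cases, function(ts) {
    mat <- ts$channels
    tibble(
      case_id = ts$case_id,
      channel = rep(rownames(mat), each = ncol(mat)),
      t = rep(0:(ncol(mat) - 1L), times = nrow(mat)),
      absorbance = as.vector(t(mat))
    )
  })
}

#' Read CZE-IS trace sets from CSV
#'
#' Two dialects are supported. *Long*: columns `case_id`, `channel`, `t`
#' (0-based point index), `absorbance`. *Wide*: columns `case_id`,
#' `channel`, `v0` ... `v{n-1}`, one row per channel. Each case must carry
#' exactly the six channels `REF`, `IgG`, `IgA`, `IgM`, `K`, `L` with equal
#' lengths and finite values; any violation is raised as a parse error
#' naming the case and problem.
#'
#' @param source Path to a CSV file (or connection readable by
#'   [readr::read_csv()]).
#' @param dialect `"long"` or `"wide"`.
#' @return Named list of [trace_set()] objects, one per `case_id`, in
#'   order of first appearance.
#' @export
read_traces <- function(source, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  # values are parsed from character with base R's correctly-rounded reader,
  # so a %.17g-formatted file reproduces the original doubles bit for bit
  df <- readr::read_csv(source, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  parse_num <- function(x, case_id) {
    v <- suppressWarnings(as.numeric(x))
    bad <- is.na(v) & !tolower(x) %in% c("na", "nan")
    if (any(bad)) {
      abort(sprintf("non-numeric absorbance '%s' for case '%s'.",
                    x[which(bad)[1]], case_id[which(bad)[1]]))
    }
    v
  }
  if (dialect == "long") {
    need <- c("case_id", "channel", "t", "absorbance")
    if (!all(need %in% names(df))) {
      abort(sprintf("long dialect requires columns %s.",
                    paste(need, collapse = ", ")))
    }
    df$t <- as.integer(df$t)
    df$absorbance <- parse_num(df$absorbance, df$case_id)
    split_cases <- split(df, factor(df$case_id, levels = unique(df$case_id)))
    cases <- lapply(split_cases, function(d) {
      chans <- lapply(split(d, d$channel), function(dc) {
        dc$absorbance[order(dc$t)]
      })
      trace_set(d$case_id[[1]], chans)
    })
  } else {
    vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
    if (!all(c("case_id", "channel") %in% names(df)) || !length(vcols)) {
      abort("wide dialect requires columns case_id, channel, v0..v{n-1}.")
    }
    vcols <- vcols[order(as.integer(sub("^v", "", vcols)))]
    split_cases <- split(df, factor(df$case_id, levels = unique(df$case_id)))
    cases <- lapply(split_cases, function(d) {
      mat <- matrix(parse_num(unlist(d[, vcols], use.names = FALSE),
                              rep(d$case_id, times = length(vcols))),
                    nrow = nrow(d),
                    dimnames = list(d$channel, NULL))
      trace_set(d$case_id[[1]], mat)
    })
  }
  for (ts in cases) {
    v <- validate_traceset(ts)
    if (length(v)) {
      abort(sprintf("invalid trace set for case '%s': %s",
                    ts$case_id, paste(v, collapse = "; ")))
    }
  }
  cases
}

#' Write CZE-IS trace sets to CSV
#'
#' Inverse of [read_traces()]: `read_traces(write_traces(x, f, d), d)`
#' reproduces `x` exactly (values round-trip through full-precision
#' decimal representation).
#'
#' @param cases A `czeis_trace` or list of them (may be empty: a
#'   header-only file is written).
#' @param sink Output path.
#' @inheritParams read_traces
#' @return `sink`, invisibly.
#' @export
write_traces <- function(cases, sink, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (inherits(cases, "czeis_trace")) cases <- list(cases)
  for (ts in cases) {
    v <- validate_traceset(ts)
    if (length(v)) {
      abort(sprintf("refusing to write invalid case '%s': %s",
                    ts$case_id, paste(v, collapse = "; ")))
    }
  }
  # decimal representation at full precision: %.17g round-trips IEEE doubles
  fmt <- function(x) sprintf("%.17g", x)
  if (dialect == "long") {
    df <- if (length(cases)) {
      dplyr::mutate(as_traces_tbl(cases), absorbance = fmt(.data$absorbance))
    } else {
      tibble(case_id = character(), channel = character(),
             t = integer(), absorbance = double())
    }
  } else {
    if (length(cases)) {
      df <- purrr::map_dfr(cases, function(ts) {
        wide <- as_tibble(matrix(fmt(ts$channels), nrow = nrow(ts$channels)),
                          .name_repair = ~ paste0("v", seq_along(.x) - 1L))
        dplyr::bind_cols(case_id = ts$case_id, channel = rownames(ts$channels), wide)
      })
    } else {
      df <- tibble(case_id = character(), channel = character())
    }
  }
  readr::write_csv(df, sink, progress = FALSE)
  invisible(sink)
}
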