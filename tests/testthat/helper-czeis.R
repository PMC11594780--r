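# small fixtures built in code

# trace set where every channel is the same vector v
flat_ts <- function(v, case_id = "t1", clipped = FALSE) {
  trace_set(case_id, setNames(rep(list(v), 6), c("REF", "IgG", "IgA", "IgM", "K", "L")),
            clipped = clipped)
}

# trace set from a named list of channel vectors, filling the rest with zeros
make_ts <- function(..., n = NULL, case_id = "t1") {
  given <- list(...)
  if (is.null(n)) n <- length(given[[1]])
  ch <- setNames(rep(list(rep(0, n)), 6), c("REF", "IgG", "IgA", "IgM", "K", "L"))
  for (nm in names(given)) ch[[nm]] <- given[[nm]]
  trace_set(case_id, ch)
}

# a zone map whose gamma zone spans most of a short axis (for tiny fixtures)
tiny_zones <- function(n) {
  zone_map(n, fractions = list(beta2 = c(0, 0.2), gamma = c(0.2, 1)))
}

# noise-free simulator config for exact-algebra tests
quiet_config <- function(...) sim_config(noise_sd = 0, ...)

# independent brute-force oracle for the D/R rule: re-sorts each call,
# recursion only in iterate mode
dr_oracle <- function(x, iterate = FALSE) {
  if (length(x) < 3L) return(list(kept = x, removed = numeric()))
  s <- sort(x)
  n <- length(s)
  r <- s[n] - s[1]
  if (r <= 0) return(list(kept = x, removed = numeric()))
  out <- numeric()
  if ((s[n] - s[n - 1]) / r > 1 / 3) out <- c(out, s[n])
  if ((s[2] - s[1]) / r > 1 / 3) out <- c(out, s[1])
  if (!length(out)) return(list(kept = x, removed = numeric()))
  keep <- x
  for (v in out) keep <- keep[-match(v, keep)]
  if (!iterate) return(list(kept = keep, removed = out))
  rest <- dr_oracle(keep, iterate = TRUE)
  list(kept = rest$kept, removed = c(out, rest$removed))
}
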