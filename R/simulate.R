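#' Simulator configuration for synthetic CZE-IS cases
#'
#' Describes the generative model for a six-channel electropherogram:
#' fixed Gaussian background peaks for the non-immunoglobulin fractions
#' (albumin, alpha-1, alpha-2, beta-1), broad Gaussian immunoglobulin
#' components per isotype with per-case log-normal amplitudes, a per-case
#' Beta-distributed kappa fraction splitting immunoglobulin mass between
#' light chains, antisera subtraction with efficiency `epsilon`, and
#' additive i.i.d. Gaussian noise per channel. A monoclonal case adds a
#' narrow spike attributed to one isotype and one light chain; a
#' polyclonal case scales all isotype amplitudes by `polyclonal_scale`.
#'
#' Default amplitudes are calibrated so that a normal case's index panel
#' has the same order of magnitude as published reference intervals for
#' these indexes (gamma IgG index in the tens-to-hundreds, gamma light
#' chain index between roughly 1 and 3).
#'
#' @param n_points Points per curve (default 300).
#' @param background Named list of `list(amplitude, center, width)` for the
#'   non-immunoglobulin fractions; centers are axis fractions, widths in
#'   points.
#' @param immunoglobulins Named list (`IgG`, `IgA`, `IgM`) of
#'   `list(meanlog, sdlog, center, width)`; per-case amplitudes are drawn
#'   log-normal.
#' @param kappa_mean,kappa_conc Mean and concentration of the Beta
#'   distribution of the per-case kappa fraction (shape1 = mean * conc).
#' @param subtraction_efficiency Fraction `epsilon` in (0, 1] of targeted
#'   immunoglobulin mass removed by an antiserum.
#' @param noise_sd Standard deviation of the additive channel noise (a.u.).
#' @param clip_negative If `TRUE`, clip simulated absorbances at zero (the
#'   resulting trace sets are marked `clipped`).
#' @param case_type `"normal"`, `"monoclonal"` or `"polyclonal"`.
#' @param spike For monoclonal cases, optional fixed spike
#'   `list(zone, isotype, light_chain, amplitude, width, center_fraction)`;
#'   if `NULL`, spike parameters are drawn per case from `spike_defaults`.
#'   Must be `NULL` for non-monoclonal case types.
#' @param spike_defaults Sampling distributions for drawn spikes: zone,
#'   isotype and light-chain probabilities, log-normal amplitude, uniform
#'   width range (points), and the central fraction of the zone within
#'   which the spike center is placed.
#' @param polyclonal_scale Multiplier (> 1) applied to all isotype
#'   amplitudes in polyclonal cases.
#' @param axis_unit Seconds per point (informational).
#'
#' @return A list of class `czeis_sim_config`.
#' @export
sim_config <- function(n_points = 300,
                       background = list(
                         albumin = list(amplitude = 1000, center = 0.15, width = 8),
                         alpha1  = list(amplitude = 120,  center = 0.30, width = 7),
                         alpha2  = list(amplitude = 180,  center = 0.41, width = 9),
                         beta1   = list(amplitude = 160,  center = 0.52, width = 7)
                       ),
                       immunoglobulins = list(
                         IgG = list(meanlog = log(170), sdlog = 0.25, center = 0.82, width = 30),
                         IgA = list(meanlog = log(90),  sdlog = 0.30, center = 0.64, width = 12),
                         IgM = list(meanlog = log(60),  sdlog = 0.30, center = 0.60, width = 14)
                       ),
                       kappa_mean = 0.62, kappa_conc = 60,
                       subtraction_efficiency = 0.95,
                       noise_sd = 0.8,
                       clip_negative = FALSE,
                       case_type = c("normal", "monoclonal", "polyclonal"),
                       spike = NULL,
                       spike_defaults = list(
                         zone_probs = c(gamma = 0.8, beta2 = 0.2),
                         isotype_probs = c(IgG = 0.6, IgA = 0.25, IgM = 0.15),
                         light_chain_probs = c(kappa = 0.6, lambda = 0.4),
                         amplitude_meanlog = log(800), amplitude_sdlog = 0.4,
                         width_range = c(1.5, 3), center_margin = 0.2
                       ),
                       polyclonal_scale = 2.5,
                       axis_unit = 1) {
  case_type <- match.arg(case_type)
  cfg <- structure(
    list(n_points = n_points, background = background,
         immunoglobulins = immunoglobulins,
         kappa_mean = kappa_mean, kappa_conc = kappa_conc,
         subtraction_efficiency = subtraction_efficiency,
         noise_sd = noise_sd, clip_negative = isTRUE(clip_negative),
         case_type = case_type, spike = spike,
         spike_defaults = spike_defaults,
         polyclonal_scale = polyclonal_scale, axis_unit = axis_unit),
    class = "czeis_sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_points >= 10)
  for (b in cfg$background) {
    if (b$amplitude < 0 || b$width <= 0) abort("background amplitudes must be >= 0 and widths > 0.")
  }
  if (!setequal(names(cfg$immunoglobulins), c("IgG", "IgA", "IgM"))) {
    abort("immunoglobulins must be named IgG, IgA, IgM.")
  }
  for (g in cfg$immunoglobulins) {
    if (g$sdlog < 0 || g$width <= 0) abort("immunoglobulin sdlog must be >= 0 and width > 0.")
  }
  if (cfg$kappa_mean <= 0 || cfg$kappa_mean >= 1 || cfg$kappa_conc <= 0) {
    abort("kappa_mean must lie in (0, 1) and kappa_conc must be positive.")
  }
  eps <- cfg$subtraction_efficiency
  # 0 is permitted and means no subtraction (all six channels coincide up to noise)
  if (eps < 0 || eps > 1) abort("subtraction_efficiency must lie in [0, 1].")
  if (cfg$noise_sd < 0) abort("noise_sd must be >= 0.")
  if (!is.null(cfg[["spike"]]) && cfg$case_type != "monoclonal") {
    abort("a spike may only be configured for case_type = 'monoclonal'.")
  }
  if (!is.null(cfg[["spike"]])) {
    sp <- cfg[["spike"]]
    if (!sp$zone %in% c("gamma", "beta2")) abort("spike zone must be gamma or beta2.")
    if (!sp$isotype %in% c("IgG", "IgA", "IgM")) abort("spike isotype must be IgG, IgA or IgM.")
    if (!sp$light_chain %in% c("kappa", "lambda")) abort("spike light_chain must be kappa or lambda.")
    if (sp$amplitude < 0 || sp$width <= 0) abort("spike amplitude must be >= 0 and width > 0.")
  }
  if (cfg$polyclonal_scale <= 1) abort("polyclonal_scale must exceed 1.")
  invisible(cfg)
}

## precompute the deterministic parts shared by all cases of one config
compile_sim_config <- function(cfg, zones = zone_map(cfg$n_points)) {
  x <- seq_len(cfg$n_points) - 1
  gauss <- function(center_frac, width) {
    exp(-(x - center_frac * (cfg$n_points - 1))^2 / (2 * width^2))
  }
  bg <- Reduce(`+`, lapply(cfg$background, function(b) b$amplitude * gauss(b$center, b$width)))
  ig_unit <- vapply(cfg$immunoglobulins, function(g) gauss(g$center, g$width),
                    numeric(cfg$n_points))
  list(x = x, background = bg, ig_unit = ig_unit, zones = zones)
}

draw_spike <- function(cfg, comp) {
  if (!is.null(cfg[["spike"]])) {
    sp <- cfg[["spike"]]
  } else {
    sd <- cfg$spike_defaults
    sp <- list(
      zone = sample(names(sd$zone_probs), 1L, prob = sd$zone_probs),
      isotype = sample(names(sd$isotype_probs), 1L, prob = sd$isotype_probs),
      light_chain = sample(names(sd$light_chain_probs), 1L, prob = sd$light_chain_probs),
      amplitude = rlnorm(1L, sd$amplitude_meanlog, sd$amplitude_sdlog),
      width = runif(1L, sd$width_range[1], sd$width_range[2])
    )
    zi <- zone_interval(comp$zones, sp$zone)
    w <- zi["end"] - zi["start"]
    m <- cfg$spike_defaults$center_margin
    sp$center_fraction <- runif(1L, (zi["start"] + m * w) / cfg$n_points,
                                (zi["end"] - m * w) / cfg$n_points)
  }
  sp
}

simulate_trace_impl <- function(cfg, comp, case_id, case_type) {
  n <- cfg$n_points
  igs <- cfg$immunoglobulins
  amps <- vapply(igs, function(g) rlnorm(1L, g$meanlog, g$sdlog), numeric(1))
  if (case_type == "polyclonal") amps <- amps * cfg$polyclonal_scale
  kappa <- rbeta(1L, cfg$kappa_mean * cfg$kappa_conc,
                 (1 - cfg$kappa_mean) * cfg$kappa_conc)
  spike <- if (case_type == "monoclonal") draw_spike(cfg, comp) else NULL

  mass <- comp$ig_unit %*% diag(amps)  # columns IgG, IgA, IgM
  colnames(mass) <- names(igs)
  poly_total <- rowSums(mass)
  kappa_mass <- kappa * poly_total
  lambda_mass <- (1 - kappa) * poly_total
  if (!is.null(spike)) {
    sc <- spike$amplitude *
      exp(-(comp$x - spike$center_fraction * (n - 1))^2 / (2 * spike$width^2))
    mass[, spike$isotype] <- mass[, spike$isotype] + sc
    if (spike$light_chain == "kappa") kappa_mass <- kappa_mass + sc
    else lambda_mass <- lambda_mass + sc
  }
  ref_clean <- comp$background + rowSums(mass)
  eps <- cfg$subtraction_efficiency
  noise <- function() if (cfg$noise_sd > 0) rnorm(n, 0, cfg$noise_sd) else 0
  ch <- rbind(
    REF = ref_clean + noise(),
    IgG = ref_clean - eps * mass[, "IgG"] + noise(),
    IgA = ref_clean - eps * mass[, "IgA"] + noise(),
    IgM = ref_clean - eps * mass[, "IgM"] + noise(),
    K   = ref_clean - eps * kappa_mass + noise(),
    L   = ref_clean - eps * lambda_mass + noise()
  )
  if (cfg$clip_negative) ch[ch < 0] <- 0
  structure(
    list(
      traceset = trace_set(case_id, ch, axis_unit = cfg$axis_unit,
                           clipped = cfg$clip_negative),
      label = list(case_type = case_type, kappa_fraction = kappa,
                   amplitudes = amps, spike = spike)
    ),
    class = "czeis_sim_case"
  )
}

#' @export
print.czeis_sim_case <- function(x, ...) {
  cat(sprintf("<czeis_sim_case> '%s' (%s)\n", x$traceset$case_id, x$label$case_type))
  invisible(x)
}

with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate one CZE-IS case
#'
#' Draws the per-case randomness (isotype amplitudes, kappa fraction,
#' spike parameters for monoclonal cases, channel noise) and assembles the
#' six channels: `REF` is the sum of background, immunoglobulin mass and
#' any spike; each antiserum channel subtracts `epsilon` times the mass it
#' targets; all channels carry independent additive noise. Identical
#' `(config, seed)` gives bitwise-identical output.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param case_id Case identifier (default derived from the seed).
#' @return A `czeis_sim_case`: list with `traceset` (a [trace_set()]) and
#'   `label` (case type, kappa fraction, drawn amplitudes, spike
#'   parameters if any).
#' @examples
#' sc <- simulate_trace(sim_config(), seed = 1)
#' validate_traceset(sc$traceset)
#' @export
simulate_trace <- function(config, seed, case_id = paste0("sim", seed)) {
  validate_sim_config(config)
  comp <- compile_sim_config(config)
  with_seed(seed, simulate_trace_impl(config, comp, case_id, config$case_type))
}

#' Simulate a labelled cohort of CZE-IS cases
#'
#' Case types are drawn from `mixture`; per-case randomness is drawn
#' independently from the config distributions. Reproducible under `seed`.
#'
#' @param n Number of cases (0 allowed).
#' @param mixture Named proportions over
#'   `c("normal", "monoclonal", "polyclonal")`; must sum to 1.
#' @param config A [sim_config()]; its `case_type`/`spike` fields are
#'   overridden per case by the mixture draw.
#' @param seed Integer seed.
#' @return List of `czeis_sim_case` objects, named by case id.
#' @examples
#' cohort <- simulate_cohort(5, c(normal = 1), sim_config(), seed = 1)
#' sim_labels(cohort)
#' @export
simulate_cohort <- function(n, mixture = c(normal = 1), config = sim_config(),
                            seed = 1L) {
  validate_sim_config(config)
  if (is.null(names(mixture)) ||
      !all(names(mixture) %in% c("normal", "monoclonal", "polyclonal")) ||
      any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8) {
    abort("`mixture` must be named proportions over normal/monoclonal/polyclonal summing to 1.")
  }
  if (n == 0) return(list())
  comp <- compile_sim_config(config)
  cfg <- config
  cfg["spike"] <- list(if (config$case_type == "monoclonal") config[["spike"]] else NULL)
  with_seed(seed, {
    types <- if (length(mixture) == 1L) rep(names(mixture), n)
             else sample(names(mixture), n, replace = TRUE, prob = mixture)
    ids <- sprintf("sim%0*d", max(4L, nchar(n)), seq_len(n))
    cases <- vector("list", n)
    for (i in seq_len(n)) {
      cases[[i]] <- simulate_trace_impl(cfg, comp, ids[i], types[i])
    }
    names(cases) <- ids
    cases
  })
}

#' Ground-truth labels of a simulated cohort as a tibble
#'
#' @param cases List of `czeis_sim_case` (from [simulate_cohort()]).
#' @return Tibble with one row per case: `case_id`, `case_type`,
#'   `kappa_fraction`, the drawn isotype amplitudes, and spike parameters
#'   (`NA` for non-monoclonal cases).
#' @export
sim_labels <- function(cases) {
  purrr::map_dfr(cases, function(sc) {
    lb <- sc$label
    sp <- lb$spike
    tibble(
      case_id = sc$traceset$case_id,
      case_type = lb$case_type,
      kappa_fraction = lb$kappa_fraction,
      igg_amplitude = lb$amplitudes[["IgG"]],
      iga_amplitude = lb$amplitudes[["IgA"]],
      igm_amplitude = lb$amplitudes[["IgM"]],
      spike_zone = if (is.null(sp)) NA_character_ else sp$zone,
      spike_isotype = if (is.null(sp)) NA_character_ else sp$isotype,
      spike_light_chain = if (is.null(sp)) NA_character_ else sp$light_chain,
      spike_amplitude = if (is.null(sp)) NA_real_ else sp$amplitude,
      spike_width = if (is.null(sp)) NA_real_ else sp$width,
      spike_center_fraction = if (is.null(sp)) NA_real_ else sp$center_fraction
    )
  })
}
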