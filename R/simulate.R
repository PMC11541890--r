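#' Simulation parameters for synthetic DPV traces
#'
#' The generator composes each trace as a smooth instrumental background plus
#' Gaussian peaks drawn from the analyte peak library, plus replicate noise:
#'
#' `I(E) = baseline(E) + sum over peaks of
#'   sign * amplitude_scale * conc * rel_amplitude * gauss(E; Ep + jitter, w)
#'   + white noise`
#'
#' The background is a cubic polynomial with exponential rises at both ends
#' of the potential window, mimicking solvent-discharge currents at the
#' anodic and cathodic limits. Gaussian widths are interpreted as full width
#' at half maximum (FWHM), the conventional DPV half-width.
#'
#' @param step_potential Grid spacing in V; default 0.010 V (the instrument
#'   step potential).
#' @param potential_limits Sweep limits in V; default `c(-2, 2)`.
#' @param amplitude_scale Peak current per concentration unit, in uA per
#'   umol/L for a peak of relative amplitude 1.
#' @param baseline_coef Coefficients (intercept first) of the cubic
#'   polynomial background, in uA.
#' @param edge_scale,edge_decay Amplitude (uA) and e-folding width (V) of the
#'   exponential edge currents at the potential-window limits.
#' @param noise_sd_fraction Additive white-noise sd as a fraction of the
#'   largest peak component height in the trace.
#' @param noise_floor Minimum white-noise sd in uA (instrument background
#'   noise present even for blank traces).
#' @param potential_jitter_sd Per-peak potential jitter sd in V, modelling
#'   run-to-run drift of peak positions.
#' @param pH Solution pH; peak potentials are stated at pH 8.0 (the method's
#'   working pH in 0.1 mol/L Britton-Robinson buffer).
#' @param pH_shift_slope Linear shift of every peak potential per pH unit,
#'   in V; default -0.059 V/pH (peaks move to more negative potentials as pH
#'   increases), applied relative to pH 8.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(step_potential = 0.010,
                       potential_limits = c(-2, 2),
                       amplitude_scale = 0.05,
                       baseline_coef = c(2.0, 0.8, 0.3, -0.2),
                       edge_scale = 1.5,
                       edge_decay = 0.10,
                       noise_sd_fraction = 0.02,
                       noise_floor = 0.05,
                       potential_jitter_sd = 0.005,
                       pH = 8.0,
                       pH_shift_slope = -0.059) {
  stopifnot(step_potential > 0, noise_sd_fraction >= 0, noise_floor >= 0,
            potential_jitter_sd >= 0, edge_decay > 0,
            length(potential_limits) == 2L,
            potential_limits[1] < potential_limits[2])
  structure(list(step_potential = step_potential,
                 potential_limits = potential_limits,
                 amplitude_scale = amplitude_scale,
                 baseline_coef = baseline_coef,
                 edge_scale = edge_scale,
                 edge_decay = edge_decay,
                 noise_sd_fraction = noise_sd_fraction,
                 noise_floor = noise_floor,
                 potential_jitter_sd = potential_jitter_sd,
                 pH = pH,
                 pH_shift_slope = pH_shift_slope),
            class = "sim_params")
}

# Gaussian peak parameterized by FWHM.
gauss_fwhm <- function(E, center, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  exp(-((E - center)^2) / (2 * sigma^2))
}

potential_grid <- function(params, scan) {
  g <- seq(params$potential_limits[1], params$potential_limits[2],
           by = params$step_potential)
  if (scan == "cathodic") rev(g) else g
}

#' Evaluate the configured instrumental background
#'
#' @param params A [sim_params()] object.
#' @param E Potentials in V.
#' @return Background currents in uA.
#' @export
eval_baseline <- function(params, E) {
  b <- params$baseline_coef
  poly <- outer(E, seq_along(b) - 1, `^`) %*% b
  lim <- params$potential_limits
  edge <- params$edge_scale *
    (exp((E - lim[2]) / params$edge_decay) -
       exp((lim[1] - E) / params$edge_decay))
  as.numeric(poly) + edge
}

normalize_composition <- function(composition) {
  if (is.numeric(composition) && !is.null(names(composition))) {
    composition <- data.frame(analyte_id = names(composition),
                              conc_um = as.numeric(composition))
  }
  if (is.null(composition) || (is.data.frame(composition) &&
                               nrow(composition) == 0L)) {
    return(data.frame(analyte_id = character(), conc_um = numeric()))
  }
  stopifnot(is.data.frame(composition),
            all(c("analyte_id", "conc_um") %in% names(composition)))
  if (any(composition$conc_um <= 0)) {
    stop("concentrations must be positive", call. = FALSE)
  }
  composition
}

#' Simulate one DPV trace for a mixture of analytes
#'
#' The signal model is additive over the composition: each analyte
#' contributes its library peaks for the requested scan direction, scaled by
#' concentration and relative amplitude. Given the same seed the trace is
#' fully reproducible.
#'
#' @param composition Either a named numeric vector of concentrations in
#'   umol/L (names are analyte ids) or a data frame with columns
#'   `analyte_id`, `conc_um`. An empty composition yields the bare baseline
#'   (plus noise).
#' @param scan `"anodic"` or `"cathodic"`.
#' @param params A [sim_params()] object.
#' @param seed Integer seed for noise and jitter.
#' @param lib Peak library; defaults to the bundled one.
#' @param r2_scale Multiplier applied to the amplitude of peaks labelled
#'   `R2`, used to emulate samples where the lower-sensitivity R2 process
#'   falls below the detection limit. Default 1.
#' @return A [voltammogram()] whose `meta` records the composition, pH,
#'   scan, and seed.
#' @export
simulate_voltammogram <- function(composition, scan = c("anodic", "cathodic"),
                                  params = sim_params(), seed = 1L,
                                  lib = default_peak_library(),
                                  r2_scale = 1) {
  scan <- match.arg(scan)
  composition <- normalize_composition(composition)
  E <- potential_grid(params, scan)
  base <- eval_baseline(params, E)

  peaks <- do.call(rbind, lapply(seq_len(nrow(composition)), function(i) {
    prof <- get_profile(composition$analyte_id[i], lib)
    pk <- prof[[scan]]
    if (nrow(pk) == 0L) return(NULL)
    pk$conc_um <- composition$conc_um[i]
    pk$analyte_id <- composition$analyte_id[i]
    pk
  }))

  current <- base
  max_height <- 0
  with_seed(seed, {
    if (!is.null(peaks) && nrow(peaks)) {
      amp <- params$amplitude_scale * peaks$conc_um * peaks$rel_amplitude
      amp[peaks$label == "R2"] <- amp[peaks$label == "R2"] * r2_scale
      sgn <- ifelse(peaks$sign == "oxidation", 1, -1)
      center <- peaks$potential_V +
        params$pH_shift_slope * (params$pH - 8.0)
      jitter <- stats::rnorm(nrow(peaks), 0, params$potential_jitter_sd)
      for (k in seq_len(nrow(peaks))) {
        if (amp[k] == 0) next
        current <- current + sgn[k] * amp[k] *
          gauss_fwhm(E, center[k] + jitter[k], peaks$width_V[k])
      }
      max_height <- max(amp)
    }
    noise_sd <- max(params$noise_sd_fraction * max_height, params$noise_floor)
    if (noise_sd > 0) {
      current <- current + stats::rnorm(length(E), 0, noise_sd)
    }
  })

  voltammogram(E, current, scan,
               meta = list(composition = composition, pH = params$pH,
                           seed = seed, scan = scan))
}

#' Simulate the 46-sample seized-panel fixture
#'
#' Builds a labelled panel of 46 synthetic seized samples (anodic and
#' cathodic trace per sample) mirroring the composition counts of the seized
#' panel the method was applied to: 42 SC-containing samples spanning groups
#' G1-G6 (two of them SC mixtures, samples 8 and 28), four SC-free samples,
#' caffeine co-formulated in 14 samples, MDMA in two (samples 7 and 46), and
#' six samples (7, 26, 27, 30, 32, 40) whose R2 process is suppressed below
#' the detection limit. SC identities of individual samples are filled by
#' round-robin over the 15 library SCs; the four negatives contain,
#' respectively, cocaine (silent), paracetamol, ketamine, and MDMA only.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer top-level seed; per-sample seeds are derived from it.
#' @return An object of class `sc_panel`: a list with `samples` (each a list
#'   `id`, `anodic`, `cathodic`, `truth`) and a `manifest` data frame with
#'   the truth labels.
#' @export
make_fixture_46 <- function(params = sim_params(), seed = 1L) {
  negatives <- c(10L, 22L, 44L, 46L)
  mixtures <- c(8L, 28L)
  r2_suppressed <- c(7L, 26L, 27L, 30L, 32L, 40L)
  caffeine_in <- c(3L, 19L, 20L, 23L, 25L, 29L, 30L, 33L, 34L, 35L, 36L,
                   38L, 39L, 41L)
  mdma_in <- c(7L, 46L)

  lib <- default_peak_library()
  scs <- library_analytes(lib, "SC")
  positives <- setdiff(1:46, negatives)
  singles <- setdiff(positives, mixtures)
  sc_of <- stats::setNames(rep(scs, length.out = length(singles)), singles)
  mix_of <- list("8" = c("methylone", "dibutylone"),
                 "28" = c("mephedrone", "MDPV"))
  neg_of <- list("10" = "cocaine", "22" = "paracetamol", "44" = "ketamine",
                 "46" = "MDMA")
  group_of <- function(ids) {
    gs <- vapply(ids, function(a) get_profile(a, lib)$group, character(1))
    if (length(gs) > 1L) resolve_mixture(gs) else gs
  }

  samples <- lapply(1:46, function(i) {
    s <- derive_seed(seed, i)
    sc_ids <- if (i %in% mixtures) mix_of[[as.character(i)]]
      else if (i %in% negatives) character(0)
      else unname(sc_of[as.character(i)])
    analytes <- sc_ids
    if (i %in% negatives) analytes <- neg_of[[as.character(i)]]
    if (i %in% caffeine_in) analytes <- c(analytes, "caffeine")
    if (i %in% mdma_in && !"MDMA" %in% analytes) {
      analytes <- c(analytes, "MDMA")
    }
    conc <- with_seed(derive_seed(s, 999L),
                      stats::runif(length(analytes), 50, 150))
    comp <- data.frame(analyte_id = analytes, conc_um = conc)
    r2s <- if (i %in% r2_suppressed) 0 else 1
    truth_group <- if (length(sc_ids)) group_of(sc_ids) else NA_character_
    list(id = i,
         anodic = simulate_voltammogram(comp, "anodic", params,
                                        seed = derive_seed(s, 1L),
                                        lib = lib, r2_scale = r2s),
         cathodic = simulate_voltammogram(comp, "cathodic", params,
                                          seed = derive_seed(s, 2L),
                                          lib = lib, r2_scale = r2s),
         truth = list(positive = length(sc_ids) > 0L,
                      group = truth_group,
                      analytes = analytes,
                      caffeine = i %in% caffeine_in,
                      mdma = "MDMA" %in% analytes,
                      r2_suppressed = i %in% r2_suppressed))
  })

  manifest <- data.frame(
    sample = 1:46,
    truth_positive = vapply(samples, function(s) s$truth$positive,
                            logical(1)),
    truth_group = vapply(samples, function(s) s$truth$group, character(1)),
    analytes = vapply(samples, function(s)
      paste(s$truth$analytes, collapse = "+"), character(1)),
    caffeine = vapply(samples, function(s) s$truth$caffeine, logical(1)),
    mdma = vapply(samples, function(s) s$truth$mdma, logical(1)),
    r2_suppressed = vapply(samples, function(s) s$truth$r2_suppressed,
                           logical(1))
  )
  structure(list(samples = samples, manifest = manifest, seed = seed),
            class = "sc_panel")
}

#' @export
print.sc_panel <- function(x, ...) {
  cat(sprintf("Synthetic seized panel: %d samples (%d SC-positive), seed %d\n",
              nrow(x$manifest), sum(x$manifest$truth_positive), x$seed))
  invisible(x)
}

#' Simulate a calibration series
#'
#' Generates replicate traces of a single analyte at increasing
#' concentrations, as used to establish the calibration curve of the R1 peak
#' current for the model analyte MPHP.
#'
#' @param analyte_id Analyte to calibrate (default `"MPHP"`, the least
#'   electroactive SC and the method's model molecule).
#' @param concentrations Concentration levels in umol/L. Default: 8
#'   log-spaced levels between 1 and 100 umol/L.
#' @param replicates Traces per level; default 3.
#' @param scan Scan direction; the R1 reduction is read from the cathodic
#'   scan by default.
#' @param params A [sim_params()] object.
#' @param seed Integer top-level seed.
#' @return List of [voltammogram()]s (levels x replicates, level-major),
#'   each with `conc_um` and `replicate` in its `meta`.
#' @export
simulate_calibration <- function(analyte_id = "MPHP",
                                 concentrations = exp(seq(log(1), log(100),
                                                          length.out = 8)),
                                 replicates = 3L,
                                 scan = c("cathodic", "anodic"),
                                 params = sim_params(), seed = 1L) {
  scan <- match.arg(scan)
  if (length(concentrations) == 0L) {
    stop("`concentrations` must be nonempty", call. = FALSE)
  }
  out <- list()
  k <- 0L
  for (ci in seq_along(concentrations)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      comp <- stats::setNames(concentrations[ci], analyte_id)
      vg <- simulate_voltammogram(comp, scan, params,
                                  seed = derive_seed(seed, k))
      vg$meta$conc_um <- concentrations[ci]
      vg$meta$replicate <- r
      out[[k]] <- vg
    }
  }
  out
}
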