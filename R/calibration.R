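#' Fit a calibration line and compute LOD/LOQ
#'
#' Ordinary least squares of the response (R1 peak current, uA) on
#' concentration (umol/L). The detection and quantification limits follow
#' LOD = 3.3 * sigma / S and LOQ = 10 * sigma / S, where S is the slope and
#' sigma the standard deviation of the response, taken here as the residual
#' standard deviation of the regression (n - 2 denominator).
#'
#' @param concentrations Concentrations in umol/L (one per observation).
#' @param responses Peak currents in uA, same length.
#' @return Object of class `calibration_result`: `slope`, `intercept`,
#'   `sigma`, `r_squared`, `lod`, `loq` (umol/L), `range` (the
#'   concentration span fitted), `n`.
#' @export
fit_calibration <- function(concentrations, responses) {
  stopifnot(length(concentrations) == length(responses))
  if (length(unique(concentrations)) < 3L) {
    stop("calibration needs at least 3 distinct concentration levels",
         call. = FALSE)
  }
  fit <- stats::lm(responses ~ concentrations)
  s <- unname(stats::coef(fit)[2])
  n <- length(responses)
  sigma <- sqrt(sum(stats::residuals(fit)^2) / (n - 2))
  if (abs(s) < .Machine$double.eps * max(abs(responses), 1)) {
    stop("calibration slope is zero; LOD/LOQ undefined", call. = FALSE)
  }
  sstot <- sum((responses - mean(responses))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sstot
  structure(list(slope = s,
                 intercept = unname(stats::coef(fit)[1]),
                 sigma = sigma,
                 r_squared = r2,
                 lod = 3.3 * sigma / abs(s),
                 loq = 10 * sigma / abs(s),
                 range = range(concentrations),
                 n = n),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration over %.3g-%.3g umol/L (n = %d):\n", x$range[1],
              x$range[2], x$n))
  cat(sprintf("  slope %.4g uA/(umol/L), sigma %.4g uA, r2 = %.4f\n",
              x$slope, x$sigma, x$r_squared))
  cat(sprintf("  LOD %.3g umol/L, LOQ %.3g umol/L\n", x$lod, x$loq))
  invisible(x)
}

#' Find the widest linear concentration range
#'
#' Scans all contiguous spans of at least three concentration levels and
#' returns the widest one whose ordinary least-squares fit reaches
#' `r2_min`, preferring spans that include the top level (calibrations are
#' anchored at the high end; low levels drop out as they approach the
#' detection limit).
#'
#' @param levels Concentrations in umol/L, one per observation (replicates
#'   share a level value).
#' @param responses Responses in uA, same length.
#' @param r2_min Minimum coefficient of determination; default 0.99.
#' @return Object of class `linear_range`: `qualifies` (logical), `lo`,
#'   `hi` (umol/L, NA when nothing qualifies), `r_squared`, `n_levels`, and
#'   `diagnostics` (per-span r2 table).
#' @export
find_linear_range <- function(levels, responses, r2_min = 0.99) {
  stopifnot(length(levels) == length(responses))
  u <- sort(unique(levels))
  K <- length(u)
  if (K < 4L) stop("need at least 4 distinct levels", call. = FALSE)
  # closed-form OLS r2 per span; a flat (zero-variance) span has no
  # explanatory power and scores 0
  span_r2 <- function(x, y) {
    sstot <- sum((y - mean(y))^2)
    if (sstot == 0) return(0)
    sxx <- sum((x - mean(x))^2)
    b <- sum((x - mean(x)) * (y - mean(y))) / sxx
    a <- mean(y) - b * mean(x)
    1 - sum((y - a - b * x)^2) / sstot
  }
  spans <- list()
  for (i in seq_len(K - 2L)) {
    for (j in seq(i + 2L, K)) {
      inx <- levels >= u[i] & levels <= u[j]
      spans[[length(spans) + 1L]] <- data.frame(
        lo = u[i], hi = u[j], n_levels = j - i + 1L,
        includes_top = j == K,
        r_squared = span_r2(levels[inx], responses[inx]))
    }
  }
  diag <- do.call(rbind, spans)
  ok <- diag[diag$r_squared >= r2_min, , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(structure(list(qualifies = FALSE, lo = NA_real_, hi = NA_real_,
                          r_squared = NA_real_, n_levels = 0L,
                          diagnostics = diag),
                     class = "linear_range"))
  }
  ok <- ok[order(-ok$n_levels, -ok$includes_top, -ok$hi, ok$lo), ,
           drop = FALSE]
  structure(list(qualifies = TRUE, lo = ok$lo[1], hi = ok$hi[1],
                 r_squared = ok$r_squared[1], n_levels = ok$n_levels[1],
                 diagnostics = diag),
            class = "linear_range")
}

#' @export
print.linear_range <- function(x, ...) {
  if (x$qualifies) {
    cat(sprintf("Linear range: %.4g-%.4g umol/L (%d levels, r2 = %.4f)\n",
                x$lo, x$hi, x$n_levels, x$r_squared))
  } else {
    cat("No contiguous level span reaches the requested r2\n")
  }
  invisible(x)
}

#' Replicate repeatability of peak current and potential
#'
#' Computes the relative standard deviation (RSD%, 100 * sd / |mean|) of
#' the peak current I_p and peak potential E_p across replicates, per
#' process (and per analyte when given), and flags entries exceeding the
#' repeatability bounds.
#'
#' @param peaks Data frame with columns `process`, `potential`, `height`
#'   and optionally `analyte`; one row per replicate measurement.
#' @param ip_bound,ep_bound RSD bounds in percent; defaults 13.0 for I_p
#'   and 1.0 for E_p.
#' @return Data frame with one row per (analyte,) process: replicate count,
#'   means, RSDs and pass flags. An RSD is `NA` (flagged `undefined`) when
#'   the corresponding mean is zero.
#' @export
repeatability <- function(peaks, ip_bound = 13.0, ep_bound = 1.0) {
  stopifnot(all(c("process", "potential", "height") %in% names(peaks)))
  key <- if ("analyte" %in% names(peaks)) {
    interaction(peaks$analyte, peaks$process, drop = TRUE)
  } else factor(peaks$process)
  rows <- lapply(levels(key), function(k) {
    g <- peaks[key == k, , drop = FALSE]
    if (nrow(g) < 2L) {
      stop("repeatability needs >= 2 replicates per process (", k, ")",
           call. = FALSE)
    }
    rsd <- function(v) {
      m <- mean(abs(v))
      if (m == 0) NA_real_ else 100 * stats::sd(abs(v)) / m
    }
    ip <- rsd(g$height)
    ep <- rsd(g$potential)
    data.frame(analyte = if ("analyte" %in% names(g)) g$analyte[1]
                 else NA_character_,
               process = g$process[1], n = nrow(g),
               ip_mean = mean(abs(g$height)), ip_rsd = ip,
               ep_mean = mean(g$potential), ep_rsd = ep,
               ip_pass = !is.na(ip) && ip <= ip_bound,
               ep_pass = !is.na(ep) && ep <= ep_bound,
               undefined = is.na(ip) || is.na(ep))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the R1 peak current from a preprocessed cathodic trace
#'
#' @param cathodic_vg A cropped, baseline-corrected cathodic
#'   [voltammogram()].
#' @param config A [screen_config()].
#' @return The absolute R1 peak current in uA, or 0 when no R1-window
#'   reduction at least `min_height` tall is detected (no measurable
#'   signal, as for levels below the detection limit).
#' @export
extract_r1_current <- function(cathodic_vg, config = screen_config()) {
  pk <- detect_peaks(cathodic_vg, config$min_prominence_fraction,
                     config$min_width)
  pk <- pk[abs(pk$height) >= config$min_height, , drop = FALSE]
  w <- data.frame(label = "R1", lo = config$r1_window[1],
                  hi = config$r1_window[2], sign = "reduction")
  m <- match_peaks(pk, w)
  if (m$matched[1]) abs(m$height[1]) else 0
}

#' Run a full synthetic calibration of an analyte
#'
#' Simulates replicate traces over the given concentration levels,
#' preprocesses each cathodic trace (crop + baseline subtraction, no
#' normalization so currents stay in uA), extracts the R1 peak current, and
#' fits the calibration line.
#'
#' @inheritParams simulate_calibration
#' @param config A [screen_config()].
#' @return List with `fit` (a `calibration_result`), `data` (data frame of
#'   concentration/response pairs), and `linear_range` (a `linear_range`,
#'   computed when there are at least 4 levels).
#' @export
calibrate_analyte <- function(analyte_id = "MPHP",
                              concentrations = exp(seq(log(1), log(100),
                                                       length.out = 8)),
                              replicates = 3L, params = sim_params(),
                              seed = 1L, config = screen_config()) {
  traces <- simulate_calibration(analyte_id, concentrations, replicates,
                                 scan = "cathodic", params = params,
                                 seed = seed)
  data <- do.call(rbind, lapply(traces, function(vg) {
    pp <- preprocess(vg)
    data.frame(conc_um = vg$meta$conc_um, replicate = vg$meta$replicate,
               response_uA = extract_r1_current(pp, config))
  }))
  fit <- fit_calibration(data$conc_um, data$response_uA)
  lr <- if (length(unique(data$conc_um)) >= 4L) {
    find_linear_range(data$conc_um, data$response_uA)
  }
  list(fit = fit, data = data, linear_range = lr)
}
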