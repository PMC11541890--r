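#' Default crop windows per scan direction
#'
#' The screening method analyses the anodic sweep between -1.60 and +1.60 V
#' and the cathodic sweep between +1.80 and -1.80 V; currents outside these
#' windows are dominated by solvent-discharge edge currents.
#'
#' @param scan `"anodic"` or `"cathodic"`.
#' @return Numeric `c(lo, hi)` in V.
#' @export
default_crop_window <- function(scan = c("anodic", "cathodic")) {
  scan <- match.arg(scan)
  if (scan == "anodic") c(-1.60, 1.60) else c(-1.80, 1.80)
}

#' Crop a voltammogram to a potential window
#'
#' Keeps exactly the grid points with `lo <= E <= hi` (both ends inclusive);
#' the scan direction and point order are preserved.
#'
#' @param vg A [voltammogram()].
#' @param lo,hi Window bounds in V. Defaults to [default_crop_window()] for
#'   the trace's scan direction.
#' @return The cropped [voltammogram()].
#' @export
crop <- function(vg, lo = NULL, hi = NULL) {
  stopifnot(is_voltammogram(vg))
  if (is.null(lo) || is.null(hi)) {
    w <- default_crop_window(vg$scan)
    if (is.null(lo)) lo <- w[1]
    if (is.null(hi)) hi <- w[2]
  }
  # tolerate grid-accumulation floating-point error at the window edges
  eps <- 1e-9 * max(1, abs(lo), abs(hi))
  keep <- vg$potential >= lo - eps & vg$potential <= hi + eps
  if (!any(keep)) {
    stop(sprintf("crop window [%g, %g] V does not intersect the trace", lo,
                 hi), call. = FALSE)
  }
  voltammogram(vg$potential[keep], vg$current[keep], vg$scan, vg$meta)
}

#' Baseline-fit configuration
#'
#' Controls the iterative polynomial background fit: a polynomial of the
#' given order is fitted to the currents, points deviating from the fit by
#' more than `clip_k` times the median absolute deviation (MAD) of the
#' residuals are excluded, and the fit is repeated until the baseline stops
#' changing (relative change below `tol`) or `max_iter` is reached. The
#' clipping removes peak regions so they do not drag the background fit.
#'
#' @param order Polynomial order (>= 1); default 3.
#' @param max_iter Maximum iterations; default 50.
#' @param clip_k MAD multiplier for the clip rule; default 2.5.
#' @param tol Relative convergence tolerance on the fitted baseline;
#'   default 1e-4.
#' @return A list of class `baseline_config`.
#' @export
baseline_config <- function(order = 3L, max_iter = 50L, clip_k = 2.5,
                            tol = 1e-4) {
  stopifnot(order >= 1, max_iter >= 1, tol > 0, clip_k > 0)
  structure(list(order = as.integer(order), max_iter = as.integer(max_iter),
                 clip_k = clip_k, tol = tol),
            class = "baseline_config")
}

#' Subtract an iteratively fitted polynomial baseline
#'
#' Automated stand-in for interactive background subtraction: fits a
#' polynomial to the trace with iterative exclusion of peak regions (points
#' far above or below the current fit, on the MAD scale, are clipped each
#' round). The corrected trace plus the baseline reconstructs the input
#' exactly.
#'
#' @param vg A [voltammogram()].
#' @param cfg A [baseline_config()].
#' @return A list with elements `corrected` and `baseline` (both
#'   [voltammogram()]s) and `converged` (logical). A warning is raised if
#'   the fit did not converge within `max_iter`; the best fit is returned.
#' @export
correct_baseline <- function(vg, cfg = baseline_config()) {
  stopifnot(is_voltammogram(vg), inherits(cfg, "baseline_config"))
  n <- length(vg$potential)
  if (n <= 2 * (cfg$order + 1)) {
    stop("trace too short for a baseline fit of order ", cfg$order,
         call. = FALSE)
  }
  x <- vg$potential
  y <- vg$current
  keep <- rep(TRUE, n)
  keep_prev <- NULL
  converged <- FALSE
  # Orthogonal polynomial basis computed once on the full grid; subset fits
  # reuse it so the fitted baseline is always evaluated on every point.
  basis <- cbind(1, stats::poly(x, cfg$order))
  baseline <- rep(0, n)
  for (it in seq_len(cfg$max_iter)) {
    coefs <- stats::lm.fit(basis[keep, , drop = FALSE], y[keep])$coefficients
    coefs[is.na(coefs)] <- 0
    new_baseline <- as.numeric(basis %*% coefs)
    delta <- max(abs(new_baseline - baseline))
    # shift-invariant scale, so adding a constant current leaves the
    # convergence path (and hence the corrected trace) unchanged
    scale <- max(diff(range(y)), 1e-12)
    baseline <- new_baseline
    if (it > 1 && delta <= cfg$tol * scale) {
      converged <- TRUE
      break
    }
    r <- y - baseline
    s <- stats::mad(r[keep])
    if (s <= 0) s <- max(abs(r[keep]), 1e-12)
    keep_new <- abs(r) <= cfg$clip_k * s
    # never clip away so much that the fit becomes underdetermined
    if (sum(keep_new) < 2 * (cfg$order + 1)) break
    if (identical(keep_new, keep) || identical(keep_new, keep_prev)) {
      # clip set stabilized (or entered a 2-cycle between two nearly
      # identical fits): the baseline has stopped moving materially
      converged <- TRUE
      break
    }
    keep_prev <- keep
    keep <- keep_new
  }
  if (!converged) {
    warning("baseline fit did not converge within ", cfg$max_iter,
            " iterations; returning best fit", call. = FALSE)
  }
  corrected <- voltammogram(x, y - baseline, vg$scan, vg$meta)
  base_vg <- voltammogram(x, baseline, vg$scan, vg$meta)
  list(corrected = corrected, baseline = base_vg, converged = converged)
}

#' Normalize currents to unit maximum magnitude
#'
#' Divides the currents by the maximum absolute current so that
#' `max(abs(current)) == 1`. Both oxidation and reduction peaks keep their
#' sign, which is why max-absolute scaling is used rather than min-max.
#'
#' @param vg A [voltammogram()].
#' @return The normalized [voltammogram()].
#' @export
normalize_current <- function(vg) {
  stopifnot(is_voltammogram(vg))
  m <- max(abs(vg$current))
  if (m == 0) stop("cannot normalize an all-zero trace", call. = FALSE)
  voltammogram(vg$potential, vg$current / m, vg$scan, vg$meta)
}

#' Standard preprocessing chain
#'
#' Crops to the default (or given) window, subtracts the iteratively fitted
#' polynomial baseline, and optionally normalizes. This is the chain applied
#' before peak detection (unnormalized) and before chemometrics
#' (normalized).
#'
#' @param vg A [voltammogram()].
#' @param window Crop window `c(lo, hi)` in V, or `NULL` for the per-scan
#'   default.
#' @param cfg A [baseline_config()].
#' @param normalize Normalize after baseline subtraction? Default `FALSE`.
#' @return The preprocessed [voltammogram()].
#' @export
preprocess <- function(vg, window = NULL, cfg = baseline_config(),
                       normalize = FALSE) {
  cropped <- if (is.null(window)) crop(vg) else crop(vg, window[1], window[2])
  out <- correct_baseline(cropped, cfg)$corrected
  if (normalize) out <- normalize_current(out)
  out
}
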