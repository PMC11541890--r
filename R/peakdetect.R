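#' Detect oxidation and reduction peaks in a preprocessed trace
#'
#' Oxidation processes appear as local maxima of the signed current and
#' reduction processes as local minima. Each candidate extremum is kept if
#' its topographic prominence reaches `min_prominence_fraction` of the
#' largest absolute current in the trace and its width at half prominence
#' reaches `min_width`. The width criterion suppresses single-point noise
#' spikes; real DPV processes are ~0.07 V wide at half height.
#'
#' @param vg A baseline-corrected [voltammogram()].
#' @param min_prominence_fraction Prominence threshold as a fraction of
#'   `max(abs(current))`; default 0.05.
#' @param min_width Minimum width at half prominence in V; default 0.02.
#' @return A data frame of class `detected_peaks`, sorted by potential, with
#'   columns `potential` (V), `height` (signed current at the extremum, uA),
#'   `prominence` (uA), `width` (V), `sign` (`"oxidation"`/`"reduction"`),
#'   and `scan`. Zero rows when nothing qualifies.
#' @export
detect_peaks <- function(vg, min_prominence_fraction = 0.05,
                         min_width = 0.02) {
  stopifnot(is_voltammogram(vg))
  # work on an increasing-potential view so widths are in +V units
  ord <- order(vg$potential)
  E <- vg$potential[ord]
  y <- vg$current[ord]
  step <- stats::median(diff(E))
  ymax <- max(abs(y))
  empty <- data.frame(potential = numeric(), height = numeric(),
                      prominence = numeric(), width = numeric(),
                      sign = character(), scan = character())
  if (ymax == 0) {
    return(structure(empty, class = c("detected_peaks", "data.frame")))
  }
  thr <- min_prominence_fraction * ymax

  one_side <- function(sig, label) {
    idx <- which(diff(sign(diff(sig))) < 0) + 1L
    if (!length(idx)) return(NULL)
    out <- lapply(idx, function(i) {
      # both the prominence and the signed peak current must clear the
      # threshold: a saddle between two deep valleys is prominent but is
      # not an observed process of the opposite sign
      if (sig[i] < thr) return(NULL)
      pr <- peak_prominence(sig, i)
      if (pr < thr) return(NULL)
      w <- peak_width(sig, i, pr, step)
      if (w < min_width) return(NULL)
      data.frame(potential = E[i], height = y[i], prominence = pr,
                 width = w, sign = label, scan = vg$scan)
    })
    do.call(rbind, out)
  }

  res <- rbind(one_side(y, "oxidation"), one_side(-y, "reduction"))
  if (is.null(res) || nrow(res) == 0L) {
    return(structure(empty, class = c("detected_peaks", "data.frame")))
  }
  res <- res[order(res$potential), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, class = c("detected_peaks", "data.frame"))
}

# Topographic prominence of the local maximum of `sig` at index i: drop from
# the peak to the higher of the two key saddles (lowest point between the
# peak and the nearest higher terrain on each side, or the window edge).
peak_prominence <- function(sig, i) {
  n <- length(sig)
  left_min <- sig[i]
  j <- i - 1L
  while (j >= 1L && sig[j] <= sig[i]) {
    if (sig[j] < left_min) left_min <- sig[j]
    j <- j - 1L
  }
  right_min <- sig[i]
  j <- i + 1L
  while (j <= n && sig[j] <= sig[i]) {
    if (sig[j] < right_min) right_min <- sig[j]
    j <- j + 1L
  }
  sig[i] - max(left_min, right_min)
}

# Width at half prominence, linearly interpolated, in potential units.
peak_width <- function(sig, i, prom, step) {
  ref <- sig[i] - prom / 2
  n <- length(sig)
  jl <- i
  while (jl > 1L && sig[jl - 1L] >= ref) jl <- jl - 1L
  left <- if (jl > 1L) {
    # crossing lies between jl-1 and jl
    (jl - 1L) + (ref - sig[jl - 1L]) / (sig[jl] - sig[jl - 1L])
  } else jl
  jr <- i
  while (jr < n && sig[jr + 1L] >= ref) jr <- jr + 1L
  right <- if (jr < n) {
    jr + (sig[jr] - ref) / (sig[jr] - sig[jr + 1L])
  } else jr
  (right - left) * step
}

#' Match detected peaks to labelled potential windows
#'
#' Each window receives the largest-magnitude in-window peak (of the
#' requested sign, when given) or is reported absent. Windows are half-open
#' `(lo, hi]` and must not overlap after tolerance expansion, so each peak
#' can match at most one window. When two in-window peaks tie in magnitude,
#' the one nearer the window centre wins.
#'
#' @param peaks A `detected_peaks` data frame from [detect_peaks()].
#' @param windows Data frame with columns `label`, `lo`, `hi` (V) and
#'   optionally `sign` (`NA` = either sign).
#' @param tolerance Symmetric window expansion in V; default 0.
#' @return Data frame of class `match_result` with one row per window:
#'   `label`, `lo`, `hi`, `matched` (logical), and the matched peak's
#'   `potential`, `height`, `prominence`, `width` (NA when absent).
#' @export
match_peaks <- function(peaks, windows, tolerance = 0) {
  stopifnot(is.data.frame(windows),
            all(c("label", "lo", "hi") %in% names(windows)))
  if (anyDuplicated(windows$label)) {
    stop("window labels must be unique", call. = FALSE)
  }
  lo <- windows$lo - tolerance
  hi <- windows$hi + tolerance
  ord <- order(lo)
  if (any(lo[ord][-1] < hi[ord][-length(ord)])) {
    stop("windows overlap after tolerance expansion", call. = FALSE)
  }
  want_sign <- if ("sign" %in% names(windows)) windows$sign
    else rep(NA_character_, nrow(windows))

  out <- data.frame(label = windows$label, lo = windows$lo, hi = windows$hi,
                    matched = FALSE, potential = NA_real_, height = NA_real_,
                    prominence = NA_real_, width = NA_real_)
  if (!is.null(peaks) && nrow(peaks)) {
    for (w in seq_len(nrow(windows))) {
      inw <- peaks$potential > lo[w] & peaks$potential <= hi[w]
      if (!is.na(want_sign[w])) inw <- inw & peaks$sign == want_sign[w]
      if (!any(inw)) next
      cand <- peaks[inw, , drop = FALSE]
      centre <- (lo[w] + hi[w]) / 2
      cand <- cand[order(-abs(cand$height), abs(cand$potential - centre)), ,
                   drop = FALSE]
      out$matched[w] <- TRUE
      out$potential[w] <- cand$potential[1]
      out$height[w] <- cand$height[1]
      out$prominence[w] <- cand$prominence[1]
      out$width[w] <- cand$width[1]
    }
  }
  structure(out, class = c("match_result", "data.frame"))
}

#' Write a detected-peak table as delimited text
#'
#' @param peaks A `detected_peaks` data frame.
#' @param path Output path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.table(as.data.frame(peaks), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
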