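#' Screening-rule configuration
#'
#' All decision windows and thresholds of the rule-based classifier, with the
#' method's published potentials as defaults. The R1 window covers both the
#' -1.40/-1.30 V family and the thiophene analogue's R1 at -1.22 V; R2
#' likewise covers -1.60 and -1.47 V. Windows are half-open `(lo, hi]`, with
#' the shared -1.45 V boundary belonging to R2.
#'
#' @param r1_window,r2_window Cathodic-scan reduction windows in V.
#' @param anodic_window Potential range in which anodic-scan oxidation
#'   processes are counted for group assignment; excludes the thiophene
#'   oxidations below 0 V by construction.
#' @param g6_window Window of the thiophene marker oxidations.
#' @param g5_band Band that both peaks of a two-process (pyrrolidine, G5)
#'   profile must occupy.
#' @param o1_window Window of the methylenedioxy ~+0.60 V oxidation.
#' @param min_height Minimum absolute baseline-corrected peak current in uA
#'   for a process to count as observed. Keeps blank-level noise out of the
#'   decision rules.
#' @param caffeine_window Window of the caffeine oxidation (~+1.30 V).
#' @param caffeine_factor A +1.30 V peak whose height exceeds the
#'   next-largest anodic peak by this factor is attributed to caffeine even
#'   when a methylenedioxy SC could claim the window.
#' @param mdma_red_windows Two cathodic windows (~-0.70 and ~-0.50 V) that
#'   must both hold reductions for the MDMA/MDEA flag.
#' @param par_red_window,par_ox_window Paracetamol marker windows
#'   (reduction ~-0.24 V, oxidation ~+0.21 V).
#' @param min_prominence_fraction,min_width Passed to [detect_peaks()].
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(r1_window = c(-1.45, -1.15),
                          r2_window = c(-1.70, -1.45),
                          anodic_window = c(0.45, 1.40),
                          g6_window = c(-0.40, -0.10),
                          g5_band = c(0.80, 1.10),
                          o1_window = c(0.50, 0.70),
                          min_height = 0.3,
                          caffeine_window = c(1.20, 1.40),
                          caffeine_factor = 1.5,
                          mdma_red_windows = list(c(-0.80, -0.60),
                                                  c(-0.60, -0.40)),
                          par_red_window = c(-0.34, -0.14),
                          par_ox_window = c(0.11, 0.31),
                          min_prominence_fraction = 0.05,
                          min_width = 0.02) {
  structure(list(r1_window = r1_window, r2_window = r2_window,
                 anodic_window = anodic_window, g6_window = g6_window,
                 g5_band = g5_band, o1_window = o1_window,
                 min_height = min_height,
                 caffeine_window = caffeine_window,
                 caffeine_factor = caffeine_factor,
                 mdma_red_windows = mdma_red_windows,
                 par_red_window = par_red_window,
                 par_ox_window = par_ox_window,
                 min_prominence_fraction = min_prominence_fraction,
                 min_width = min_width),
            class = "screen_config")
}

in_win <- function(E, w) E > w[1] & E <= w[2]

# Observed peaks: detected peaks tall enough to count as real processes.
observed <- function(peaks, config) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(peaks)
  peaks[abs(peaks$height) >= config$min_height, , drop = FALSE]
}

#' Assign an SC structural group from the anodic-scan oxidation pattern
#'
#' Decision table, evaluated top-down:
#' 1. any oxidation peak in the thiophene window (-0.40, -0.10] V -> G6;
#' 2. otherwise count the oxidation peaks n inside the anodic window
#'    (+0.45, +1.40] V: n = 5 -> G4; 4 -> G3; 3 -> G2; n = 2 with both
#'    peaks in the +0.90/+1.0 V band and no ~+0.60 V process -> G5;
#'    n <= 1 -> G1. Any other pattern returns `NA` (no group).
#'
#' @param anodic_peaks A `detected_peaks` data frame from the anodic scan
#'   (only rows with `sign == "oxidation"` are used).
#' @param cathodic_peaks Optional cathodic-scan peaks, recorded as
#'   corroborating evidence only; they do not enter the decision table.
#' @param config A [screen_config()].
#' @return One of `"G1"`..`"G6"`, or `NA_character_` when no pattern fits.
#' @export
assign_group <- function(anodic_peaks, cathodic_peaks = NULL,
                         config = screen_config()) {
  ox <- anodic_peaks[anodic_peaks$sign == "oxidation", , drop = FALSE]
  if (nrow(ox) && any(in_win(ox$potential, config$g6_window))) return("G6")
  inw <- ox[in_win(ox$potential, config$anodic_window), , drop = FALSE]
  n <- nrow(inw)
  if (n >= 6L) return(NA_character_)
  if (n == 5L) return("G4")
  if (n == 4L) return("G3")
  if (n == 3L) return("G2")
  if (n == 2L) {
    both_band <- all(in_win(inw$potential, config$g5_band))
    has_o1 <- any(in_win(ox$potential, config$o1_window))
    if (both_band && !has_o1) return("G5")
    return(NA_character_)
  }
  "G1"
}

#' Resolve an SC mixture to a single reported group
#'
#' Mixtures of SCs are assigned to the candidate group with the higher
#' number of expected anodic processes; ties go to the lower group index.
#'
#' @param candidate_groups Character vector of group ids (`"G1"`..`"G6"`).
#' @return One group id.
#' @export
resolve_mixture <- function(candidate_groups) {
  if (length(candidate_groups) == 0L) {
    stop("no candidate groups to resolve", call. = FALSE)
  }
  n_anodic <- vapply(candidate_groups,
                     function(g) group_signature(g)$n_anodic_expected,
                     integer(1))
  idx <- as.integer(sub("^G", "", candidate_groups))
  candidate_groups[order(-n_anodic, idx)][1]
}

#' Flag common interferents from the peak evidence
#'
#' * caffeine: an anodic oxidation at ~+1.30 V, either without the
#'   methylenedioxy ~+0.60 V companion or towering over the next-largest
#'   anodic peak by `caffeine_factor`;
#' * MDMA/MDEA: cathodic reductions at both ~-0.70 and ~-0.50 V (these do
#'   not overlap the R1/R2 windows, so MDMA-containing SC samples remain
#'   detectable);
#' * paracetamol: the ~-0.24 V reduction together with the ~+0.21 V
#'   oxidation;
#' * other: anodic activity in an R1-negative sample that none of the above
#'   patterns explains.
#'
#' @param anodic_peaks,cathodic_peaks `detected_peaks` data frames (either
#'   may be `NULL`).
#' @param config A [screen_config()].
#' @return Character vector of flags (possibly empty), with attribute
#'   `caffeine_route` (`"no_o1"` or `"dominant"`) when caffeine is flagged.
#' @export
flag_interferents <- function(anodic_peaks, cathodic_peaks,
                              config = screen_config()) {
  flags <- character(0)
  route <- NULL
  aox <- if (!is.null(anodic_peaks)) {
    p <- observed(anodic_peaks, config)
    p[p$sign == "oxidation", , drop = FALSE]
  } else NULL
  cred <- if (!is.null(cathodic_peaks)) {
    p <- observed(cathodic_peaks, config)
    p[p$sign == "reduction", , drop = FALSE]
  } else NULL

  if (!is.null(aox) && nrow(aox)) {
    caf <- in_win(aox$potential, config$caffeine_window)
    if (any(caf)) {
      has_o1 <- any(in_win(aox$potential, config$o1_window))
      caf_h <- max(abs(aox$height[caf]))
      rest <- abs(aox$height[!caf])
      dominant <- length(rest) == 0L ||
        caf_h > config$caffeine_factor * max(rest)
      if (!has_o1) {
        flags <- c(flags, "caffeine"); route <- "no_o1"
      } else if (dominant) {
        flags <- c(flags, "caffeine"); route <- "dominant"
      }
    }
  }
  if (!is.null(cred) && nrow(cred)) {
    hit <- vapply(config$mdma_red_windows,
                  function(w) any(in_win(cred$potential, w)), logical(1))
    if (all(hit)) flags <- c(flags, "MDMA/MDEA")
    par_red <- any(in_win(cred$potential, config$par_red_window))
    par_ox <- !is.null(aox) && nrow(aox) &&
      any(in_win(aox$potential, config$par_ox_window))
    if (par_red && par_ox) flags <- c(flags, "paracetamol")
  }
  r1_found <- !is.null(cred) && nrow(cred) &&
    any(in_win(cred$potential, config$r1_window))
  if (!r1_found && length(flags) == 0L) {
    active <- (!is.null(aox) && nrow(aox) > 0L) ||
      (!is.null(cred) && nrow(cred) > 0L)
    if (active) flags <- "other"
  }
  if (!is.null(route)) attr(flags, "caffeine_route") <- route
  flags
}

#' Screen one sample from its anodic and cathodic DPV traces
#'
#' Implements the decision rules of the screening method: a sample is
#' SC-positive if and only if its cathodic scan shows a reduction in the R1
#' window (R2 is recorded as supporting evidence but, having lower
#' sensitivity, is never required). Positive samples are assigned a
#' structural group from the anodic-scan oxidation pattern via
#' [assign_group()], and interferents are flagged via [flag_interferents()].
#' When caffeine is flagged through the "no +0.60 V companion" route, the
#' +1.30 V peak is attributed to caffeine and excluded from the anodic
#' count; when flagged through peak dominance the window may also hold a
#' methylenedioxy SC process, so the count keeps it.
#'
#' @param anodic_vg Anodic-scan [voltammogram()], or `NULL` (screening then
#'   degrades to cathodic-only evidence and no group is assigned).
#' @param cathodic_vg Cathodic-scan [voltammogram()]; required, since the
#'   class fingerprint lives in the cathodic R1/R2 processes.
#' @param config A [screen_config()].
#' @param preprocessed Set `TRUE` when the traces are already cropped and
#'   baseline-corrected.
#' @return An object of class `screening_result`: `positive`, `r1_found`,
#'   `r2_found`, `assigned_group` (`NA` when none), `anodic_count`,
#'   `interferent_flags`, and `evidence` (the cathodic window matches and
#'   the observed peak tables).
#' @export
screen_sample <- function(anodic_vg = NULL, cathodic_vg,
                          config = screen_config(), preprocessed = FALSE) {
  if (missing(cathodic_vg) || is.null(cathodic_vg)) {
    stop("a cathodic-scan trace is required: the SC fingerprint lives in ",
         "the cathodic R1/R2 processes", call. = FALSE)
  }
  if (cathodic_vg$scan != "cathodic") {
    stop("`cathodic_vg` is not a cathodic-scan trace", call. = FALSE)
  }
  if (!preprocessed) {
    cathodic_vg <- preprocess(cathodic_vg)
    if (!is.null(anodic_vg)) anodic_vg <- preprocess(anodic_vg)
  }
  det <- function(vg) detect_peaks(vg, config$min_prominence_fraction,
                                   config$min_width)
  cpeaks <- observed(det(cathodic_vg), config)
  apeaks <- if (!is.null(anodic_vg)) observed(det(anodic_vg), config)

  rwin <- data.frame(label = c("R1", "R2"),
                     lo = c(config$r1_window[1], config$r2_window[1]),
                     hi = c(config$r1_window[2], config$r2_window[2]),
                     sign = "reduction")
  # R2 owns the shared -1.45 V boundary: windows are (lo, hi] and R2 is
  # listed with hi = -1.45 < R1's lo... (R2 window precedes R1 on the axis)
  rmatch <- match_peaks(cpeaks, rwin)
  r1_found <- rmatch$matched[rmatch$label == "R1"]
  r2_found <- rmatch$matched[rmatch$label == "R2"]
  positive <- isTRUE(r1_found)

  flags <- flag_interferents(apeaks, cpeaks, config)

  group <- NA_character_
  anodic_count <- NA_integer_
  if (!is.null(apeaks)) {
    count_peaks <- apeaks
    if ("caffeine" %in% flags &&
        identical(attr(flags, "caffeine_route"), "no_o1") &&
        nrow(count_peaks)) {
      drop <- count_peaks$sign == "oxidation" &
        in_win(count_peaks$potential, config$caffeine_window)
      count_peaks <- count_peaks[!drop, , drop = FALSE]
    }
    ox <- count_peaks[count_peaks$sign == "oxidation", , drop = FALSE]
    anodic_count <- sum(in_win(ox$potential, config$anodic_window))
    if (positive) group <- assign_group(count_peaks, cpeaks, config)
  }

  structure(list(positive = positive,
                 r1_found = isTRUE(r1_found),
                 r2_found = isTRUE(r2_found),
                 assigned_group = group,
                 anodic_count = anodic_count,
                 interferent_flags = as.character(flags),
                 evidence = list(cathodic_matches = rmatch,
                                 anodic_peaks = apeaks,
                                 cathodic_peaks = cpeaks)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("SC screening: %s%s%s\n",
              if (x$positive) "POSITIVE" else "negative",
              if (x$positive && !is.na(x$assigned_group))
                paste0(" (", x$assigned_group, ")") else "",
              if (length(x$interferent_flags))
                paste0(" [flags: ",
                       paste(x$interferent_flags, collapse = ", "), "]")
              else ""))
  cat(sprintf("  R1 %s, R2 %s; anodic processes: %s\n",
              if (x$r1_found) "found" else "absent",
              if (x$r2_found) "found" else "absent",
              if (is.na(x$anodic_count)) "n/a" else x$anodic_count))
  invisible(x)
}
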