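#' The analyte peak library
#'
#' The screening rules rest on a curated library of expected redox processes:
#' for each analyte, the peak potentials (V vs Ag/AgCl), the peak sign
#' (oxidation or reduction), and a relative amplitude, recorded separately for
#' the anodic and cathodic sweep directions. Synthetic cathinones (SCs) carry
#' the class fingerprint: two cathodic reductions, R1 near -1.4 to -1.2 V and
#' R2 near -1.6 to -1.45 V. Common adulterants and co-seized drugs
#' (caffeine, paracetamol, anesthetics, MDMA/MDEA, piperazines) are profiled
#' as interferents; amphetamine, methamphetamine and cocaine are
#' electrochemically silent on the boron-doped diamond electrode.
#'
#' The library ships as two plain CSV files under `inst/extdata` so that new
#' analytes (e.g. bupropion, benzylone, dipentylone) can be appended without
#' touching code:
#'
#' * `analytes.csv`: `analyte_id`, `category` (`SC` / `interferent` /
#'   `silent`), `group` (`G1`..`G6`, empty for non-SCs);
#' * `peaks.csv`: `analyte_id`, `scan` (`anodic` / `cathodic`), `label`
#'   (`R1`, `R2`, `O1`..`O5`, ...), `potential_V`, `sign`, `rel_amplitude`
#'   in (0, 1], `width_V` (full width at half maximum; empty = default).
#'
#' @param analytes_file,peaks_file Optional paths overriding the bundled
#'   library files.
#' @param default_width Peak full width at half maximum in V used when
#'   `width_V` is empty. Default 0.07 V, a typical DPV half-width.
#' @return An object of class `peak_library` with elements `analytes` and
#'   `peaks` (data frames).
#' @seealso [get_profile()], [group_signature()], [write_peak_library()]
#' @export
read_peak_library <- function(analytes_file = NULL, peaks_file = NULL,
                              default_width = 0.07) {
  if (is.null(analytes_file)) {
    analytes_file <- system.file("extdata", "analytes.csv",
                                 package = "voltscreen", mustWork = TRUE)
  }
  if (is.null(peaks_file)) {
    peaks_file <- system.file("extdata", "peaks.csv",
                              package = "voltscreen", mustWork = TRUE)
  }
  analytes <- utils::read.csv(analytes_file, stringsAsFactors = FALSE,
                              na.strings = c("NA", ""))
  peaks <- utils::read.csv(peaks_file, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need_a <- c("analyte_id", "category", "group")
  need_p <- c("analyte_id", "scan", "label", "potential_V", "sign",
              "rel_amplitude", "width_V")
  if (!all(need_a %in% names(analytes))) {
    stop("analyte table must have columns: ", paste(need_a, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_p %in% names(peaks))) {
    stop("peak table must have columns: ", paste(need_p, collapse = ", "),
         call. = FALSE)
  }
  peaks$width_V[is.na(peaks$width_V)] <- default_width
  bad <- !peaks$analyte_id %in% analytes$analyte_id
  if (any(bad)) {
    stop("peak table references unknown analyte(s): ",
         paste(unique(peaks$analyte_id[bad]), collapse = ", "), call. = FALSE)
  }
  stopifnot(all(peaks$sign %in% c("oxidation", "reduction")),
            all(peaks$scan %in% c("anodic", "cathodic")),
            all(peaks$rel_amplitude > 0 & peaks$rel_amplitude <= 1),
            all(peaks$width_V > 0))
  structure(list(analytes = analytes, peaks = peaks,
                 default_width = default_width),
            class = "peak_library")
}

#' Write a peak library back to CSV files
#'
#' @param lib A `peak_library` object.
#' @param analytes_file,peaks_file Output paths.
#' @return The two paths, invisibly.
#' @export
write_peak_library <- function(lib, analytes_file, peaks_file) {
  stopifnot(inherits(lib, "peak_library"))
  utils::write.csv(lib$analytes, analytes_file, row.names = FALSE, na = "")
  utils::write.csv(lib$peaks, peaks_file, row.names = FALSE, na = "")
  invisible(c(analytes_file, peaks_file))
}

# Package-local cache for the bundled library.
.vs_cache <- new.env(parent = emptyenv())

#' Bundled peak library (cached)
#'
#' @return The `peak_library` parsed from the files shipped with the package.
#' @export
default_peak_library <- function() {
  if (is.null(.vs_cache$lib)) .vs_cache$lib <- read_peak_library()
  .vs_cache$lib
}

#' @export
print.peak_library <- function(x, ...) {
  tab <- table(x$analytes$category)
  cat(sprintf("Peak library: %d analytes (%s), %d peak records\n",
              nrow(x$analytes),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              nrow(x$peaks)))
  invisible(x)
}

#' List the analyte ids in a library
#'
#' @param lib A `peak_library`; defaults to the bundled one.
#' @param category Optional filter: `"SC"`, `"interferent"` or `"silent"`.
#' @return Character vector of analyte ids.
#' @export
library_analytes <- function(lib = default_peak_library(), category = NULL) {
  a <- lib$analytes
  if (!is.null(category)) a <- a[a$category %in% category, , drop = FALSE]
  a$analyte_id
}

#' Look up an analyte's expected electrochemical profile
#'
#' @param analyte_id One analyte id, e.g. `"mephedrone"` or `"caffeine"`.
#' @param lib A `peak_library`; defaults to the bundled one.
#' @return An `analyte_profile`: a list with `analyte_id`, `category`,
#'   `group` (`NA` for non-SCs), and the per-scan peak tables `anodic` and
#'   `cathodic` (columns `label`, `potential_V`, `sign`, `rel_amplitude`,
#'   `width_V`). Silent analytes have empty peak tables.
#' @export
get_profile <- function(analyte_id, lib = default_peak_library()) {
  stopifnot(length(analyte_id) == 1L)
  i <- match(analyte_id, lib$analytes$analyte_id)
  if (is.na(i)) {
    stop("analyte '", analyte_id, "' is not in the peak library",
         call. = FALSE)
  }
  pk <- lib$peaks[lib$peaks$analyte_id == analyte_id, , drop = FALSE]
  take <- function(scan) {
    out <- pk[pk$scan == scan,
              c("label", "potential_V", "sign", "rel_amplitude", "width_V"),
              drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(
    list(analyte_id = analyte_id,
         category = lib$analytes$category[i],
         group = lib$analytes$group[i],
         anodic = take("anodic"),
         cathodic = take("cathodic")),
    class = "analyte_profile"
  )
}

#' @export
print.analyte_profile <- function(x, ...) {
  grp <- if (is.na(x$group)) "" else paste0(" [", x$group, "]")
  cat(sprintf("%s (%s)%s: %d anodic-scan, %d cathodic-scan peaks\n",
              x$analyte_id, x$category, grp, nrow(x$anodic),
              nrow(x$cathodic)))
  invisible(x)
}

#' Electrochemical signature of an SC structural group
#'
#' The six groups are distinguished by the number of anodic-scan oxidation
#' processes (and, for the thiophene-bearing group G6, oxidations at negative
#' potentials): G1 shows at most one anodic process (~+1.1 to +1.2 V), G5 two
#' (~+0.90 and +1.0 V), G2 three (~+0.60, +1.0, +1.25 V), G3 four, G4 five,
#' and G6 four of which two sit below 0 V. Groups G2-G4 carry the
#' 3,4-methylenedioxy ring, whose hallmark is the ~+0.60 V oxidation.
#'
#' @param group_id One of `"G1"`..`"G6"`.
#' @return A `group_signature` list: `group_id`, `n_anodic_expected`,
#'   `anodic_windows` (matrix of lo/hi bounds in V), and `special_markers`
#'   (logical flags `methylenedioxy`, `thiophene`).
#' @export
group_signature <- function(group_id) {
  sig <- .group_signatures[[group_id]]
  if (is.null(sig)) {
    stop("unknown SC group '", group_id, "' (expected G1..G6)", call. = FALSE)
  }
  sig
}

win <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  colnames(m) <- c("lo", "hi")
  m
}

.group_signatures <- list(
  G1 = structure(list(group_id = "G1", n_anodic_expected = 1L,
                      anodic_windows = win(1.00, 1.30),
                      special_markers = c(methylenedioxy = FALSE,
                                          thiophene = FALSE)),
                 class = "group_signature"),
  G2 = structure(list(group_id = "G2", n_anodic_expected = 3L,
                      anodic_windows = win(0.50, 0.70, 0.90, 1.10,
                                           1.15, 1.35),
                      special_markers = c(methylenedioxy = TRUE,
                                          thiophene = FALSE)),
                 class = "group_signature"),
  G3 = structure(list(group_id = "G3", n_anodic_expected = 4L,
                      anodic_windows = win(0.50, 0.70, 0.73, 0.93,
                                           0.93, 1.13, 1.13, 1.33),
                      special_markers = c(methylenedioxy = TRUE,
                                          thiophene = FALSE)),
                 class = "group_signature"),
  G4 = structure(list(group_id = "G4", n_anodic_expected = 5L,
                      anodic_windows = win(0.50, 0.70, 0.70, 0.85,
                                           0.85, 0.95, 0.95, 1.10,
                                           1.10, 1.30),
                      special_markers = c(methylenedioxy = TRUE,
                                          thiophene = FALSE)),
                 class = "group_signature"),
  G5 = structure(list(group_id = "G5", n_anodic_expected = 2L,
                      anodic_windows = win(0.80, 1.00, 0.90, 1.10),
                      special_markers = c(methylenedioxy = FALSE,
                                          thiophene = FALSE)),
                 class = "group_signature"),
  G6 = structure(list(group_id = "G6", n_anodic_expected = 4L,
                      anodic_windows = win(-0.40, -0.10, -0.27, -0.07,
                                           0.72, 0.92, 0.85, 1.05),
                      special_markers = c(methylenedioxy = FALSE,
                                          thiophene = TRUE)),
                 class = "group_signature")
)

#' @export
print.group_signature <- function(x, ...) {
  marks <- names(x$special_markers)[x$special_markers]
  cat(sprintf("%s: %d anodic process(es)%s\n", x$group_id,
              x$n_anodic_expected,
              if (length(marks)) paste0(" + ", paste(marks, collapse = ", "))
              else ""))
  invisible(x)
}
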