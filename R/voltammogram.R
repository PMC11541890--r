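#' Construct a DPV voltammogram
#'
#' A voltammogram holds one differential pulse voltammetry (DPV) trace: a
#' potential grid (V vs Ag/AgCl), the measured currents (uA), the sweep
#' direction, and free-form metadata (composition, pH, replicate index, ...).
#'
#' Anodic sweeps run toward positive potentials, so the grid must be strictly
#' increasing; cathodic sweeps are strictly decreasing.
#'
#' @param potential Numeric potential grid in V vs Ag/AgCl.
#' @param current Numeric currents in uA, same length as `potential`.
#' @param scan Either `"anodic"` or `"cathodic"`.
#' @param meta Named list of metadata carried along with the trace.
#' @return An object of class `voltammogram`.
#' @export
voltammogram <- function(potential, current, scan = c("anodic", "cathodic"),
                         meta = list()) {
  scan <- match.arg(scan)
  potential <- as.numeric(potential)
  current <- as.numeric(current)
  if (length(potential) != length(current)) {
    stop("`potential` and `current` must have equal length", call. = FALSE)
  }
  if (length(potential) < 2L) {
    stop("a voltammogram needs at least two grid points", call. = FALSE)
  }
  d <- diff(potential)
  if (scan == "anodic" && any(d <= 0)) {
    stop("anodic scans require a strictly increasing potential grid",
         call. = FALSE)
  }
  if (scan == "cathodic" && any(d >= 0)) {
    stop("cathodic scans require a strictly decreasing potential grid",
         call. = FALSE)
  }
  structure(
    list(potential = potential, current = current, scan = scan,
         meta = as.list(meta)),
    class = "voltammogram"
  )
}

#' @export
print.voltammogram <- function(x, ...) {
  cat(sprintf("DPV voltammogram (%s scan): %d points, %.2f to %.2f V\n",
              x$scan, length(x$potential), x$potential[1],
              x$potential[length(x$potential)]))
  cat(sprintf("  current range: %.3f to %.3f uA\n",
              min(x$current), max(x$current)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.voltammogram <- function(x, ...) {
  data.frame(potential_V = x$potential, current_uA = x$current)
}

#' @export
length.voltammogram <- function(x) length(x$potential)

is_voltammogram <- function(x) inherits(x, "voltammogram")

#' Read a voltammogram from a CSV trace file
#'
#' Expects at least the columns `potential_V` and `current_uA`; extra columns
#' are ignored. The scan direction is inferred from the monotonicity of the
#' potential grid unless a metadata sidecar (`<path>.meta.json`) states it.
#'
#' @param path Path to a CSV file.
#' @return A [voltammogram()].
#' @export
read_voltammogram <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = TRUE)
  need <- c("potential_V", "current_uA")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trace file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  pot <- as.numeric(df$potential_V)
  d <- diff(pot)
  if (all(d > 0)) {
    scan <- "anodic"
  } else if (all(d < 0)) {
    scan <- "cathodic"
  } else {
    stop("trace file ", path, " has a non-monotonic potential grid",
         call. = FALSE)
  }
  meta <- list()
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$scan)) scan <- match.arg(meta$scan, c("anodic", "cathodic"))
  }
  voltammogram(pot, as.numeric(df$current_uA), scan, meta)
}

#' Write a voltammogram as a CSV trace file
#'
#' Writes the two-column trace (`potential_V`, `current_uA`) and, when the
#' trace carries metadata, a JSON sidecar at `<path>.meta.json` recording the
#' scan direction and metadata. Values round-trip through [read_voltammogram()]
#' to better than 1e-9.
#'
#' @param vg A [voltammogram()].
#' @param path Output CSV path.
#' @param sidecar Write the metadata sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_voltammogram <- function(vg, path, sidecar = TRUE) {
  stopifnot(is_voltammogram(vg))
  df <- as.data.frame(vg)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- c(list(scan = vg$scan), vg$meta)
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}

# Restore-on-exit seeded evaluation so simulation calls do not disturb the
# caller's RNG stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-trace seed derivation from one top-level seed.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 1009 + 7919 * as.double(index)) %% 2147483647)
}
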