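#' Assemble a feature matrix from preprocessed trace pairs
#'
#' Rows are samples (analyte x replicate), columns are the current values on
#' the common cropped potential grid, anodic scan first then cathodic scan.
#' All traces must share the same grids.
#'
#' @param pairs List of samples, each a list with elements `anodic` and
#'   `cathodic` ([voltammogram()]s, already preprocessed and normalized) and
#'   optionally `label`, `analyte`, `replicate`, `group`.
#' @return An object of class `feature_matrix`: list with `x` (numeric
#'   matrix) and `info` (data frame of row metadata).
#' @export
build_matrix <- function(pairs) {
  stopifnot(length(pairs) >= 1L)
  ref_a <- pairs[[1]]$anodic$potential
  ref_c <- pairs[[1]]$cathodic$potential
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (length(p$anodic$potential) != length(ref_a) ||
        max(abs(p$anodic$potential - ref_a)) > 1e-9 ||
        length(p$cathodic$potential) != length(ref_c) ||
        max(abs(p$cathodic$potential - ref_c)) > 1e-9) {
      stop("trace ", i, " is not on the common potential grid ",
           "(different crop windows?)", call. = FALSE)
    }
    c(p$anodic$current, p$cathodic$current)
  })
  x <- do.call(rbind, rows)
  colnames(x) <- c(sprintf("a_%+.3f", ref_a), sprintf("c_%+.3f", ref_c))
  grab <- function(f, default) {
    vapply(seq_along(pairs), function(i) {
      v <- pairs[[i]][[f]]
      if (is.null(v)) default else as.character(v)
    }, character(1))
  }
  info <- data.frame(label = grab("label", NA_character_),
                     analyte = grab("analyte", NA_character_),
                     replicate = grab("replicate", NA_character_),
                     group = grab("group", NA_character_))
  rn <- ifelse(is.na(info$label),
               paste0(info$analyte, "_", info$replicate), info$label)
  rownames(x) <- make.unique(rn)
  structure(list(x = x, info = info), class = "feature_matrix")
}

#' Principal component analysis of a voltammogram matrix
#'
#' Column-mean-centred, unscaled PCA (the traces are already normalized to
#' unit maximum current). Component signs are fixed so that each loading's
#' largest-magnitude entry is positive, making score plots reproducible.
#'
#' @param m A `feature_matrix` (or bare numeric matrix).
#' @param n_components Number of components to keep; default
#'   `min(nrow - 1, ncol)`.
#' @param scale. Autoscale columns as well? Default `FALSE`.
#' @return Object of class `pca_result`: `scores`, `loadings`, `explained`
#'   (variance fractions, non-increasing), `center`, `scale`.
#' @export
run_pca <- function(m, n_components = NULL, scale. = FALSE) {
  x <- if (inherits(m, "feature_matrix")) m$x else as.matrix(m)
  if (nrow(x) < 2L) stop("PCA needs at least 2 rows", call. = FALSE)
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp) {
    stop("n_components exceeds min(rows - 1, cols) = ", max_comp,
         call. = FALSE)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  keep <- seq_len(n_components)
  load <- pc$rotation[, keep, drop = FALSE]
  scores <- pc$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadings = load,
                 explained = explained[keep],
                 center = pc$center,
                 scale = if (isTRUE(scale.)) pc$scale else NULL),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d components; PC1 %.2f%%, PC2 %s%% of variance\n",
              ncol(x$scores), 100 * x$explained[1],
              if (length(x$explained) > 1)
                sprintf("%.2f", 100 * x$explained[2]) else "-"))
  invisible(x)
}

#' Agglomerative hierarchical clustering of a voltammogram matrix
#'
#' @param m A `feature_matrix` (or bare numeric matrix).
#' @param linkage One of `"ward.D2"` (default), `"average"`, `"complete"`,
#'   `"single"`.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"maximum"`.
#' @return Object of class `hca_result`: the `stats::hclust` tree plus
#'   `heights`, `similarity` (100 * (1 - h / max(h)), the similarity scale
#'   used to read dendrograms), `linkage`, `metric`, and the row `info`.
#' @export
run_hca <- function(m, linkage = c("ward.D2", "average", "complete",
                                   "single"),
                    metric = c("euclidean", "manhattan", "maximum")) {
  linkage <- match.arg(linkage)
  metric <- match.arg(metric)
  x <- if (inherits(m, "feature_matrix")) m$x else as.matrix(m)
  if (nrow(x) < 2L) stop("clustering needs at least 2 rows", call. = FALSE)
  d <- stats::dist(x, method = metric)
  hc <- stats::hclust(d, method = linkage)
  structure(list(hclust = hc, merge = hc$merge, heights = hc$height,
                 similarity = 100 * (1 - hc$height / max(hc$height)),
                 linkage = linkage, metric = metric,
                 labels = hc$labels,
                 info = if (inherits(m, "feature_matrix")) m$info),
            class = "hca_result")
}

#' @export
print.hca_result <- function(x, ...) {
  cat(sprintf("HCA (%s linkage, %s distance): %d merges\n", x$linkage,
              x$metric, length(x$heights)))
  invisible(x)
}

#' Cut a dendrogram at the largest merge-height gap
#'
#' Finds the largest gap between successive (sorted) merge heights and cuts
#' the tree there, so the number of clusters is chosen by the data rather
#' than fixed in advance.
#'
#' @param h An `hca_result`.
#' @return List with `k` (number of clusters), `partition` (integer labels
#'   per row), and `gap` (the height gap exploited).
#' @export
cut_by_gap <- function(h) {
  stopifnot(inherits(h, "hca_result"))
  hts <- sort(h$heights)
  m <- length(hts)
  if (m == 1L) {
    return(list(k = 2L, partition = stats::cutree(h$hclust, 2L),
                gap = hts[1]))
  }
  gaps <- diff(hts)
  i <- which.max(gaps)
  k <- (m + 1L) - i
  list(k = k, partition = stats::cutree(h$hclust, k), gap = gaps[i])
}

#' Cut a dendrogram into k clusters
#'
#' @param h An `hca_result`.
#' @param k Number of clusters.
#' @return Integer cluster labels per row.
#' @export
cut_k <- function(h, k) {
  stopifnot(inherits(h, "hca_result"))
  stats::cutree(h$hclust, k)
}

#' Build the standards matrix used for group discovery
#'
#' Simulates the 15 SC standards at a common concentration with the given
#' number of replicates, runs the standard preprocessing chain (crop,
#' baseline subtraction, normalization) on both scan directions, and stacks
#' the traces into a `feature_matrix` ready for [run_pca()] / [run_hca()].
#'
#' @param replicates Replicates per standard; default 3.
#' @param conc_um Standard concentration in umol/L; default 100.
#' @param params A [sim_params()] object.
#' @param seed Integer seed.
#' @return A `feature_matrix` whose `info` carries analyte, replicate and
#'   the designed group of each row.
#' @export
standards_matrix <- function(replicates = 3L, conc_um = 100,
                             params = sim_params(), seed = 1L) {
  lib <- default_peak_library()
  scs <- library_analytes(lib, "SC")
  pairs <- list()
  k <- 0L
  for (a in scs) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      comp <- stats::setNames(conc_um, a)
      an <- simulate_voltammogram(comp, "anodic", params,
                                  seed = derive_seed(seed, 2L * k - 1L),
                                  lib = lib)
      ca <- simulate_voltammogram(comp, "cathodic", params,
                                  seed = derive_seed(seed, 2L * k),
                                  lib = lib)
      pairs[[k]] <- list(anodic = preprocess(an, normalize = TRUE),
                         cathodic = preprocess(ca, normalize = TRUE),
                         analyte = a, replicate = r,
                         group = get_profile(a, lib)$group)
    }
  }
  build_matrix(pairs)
}
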