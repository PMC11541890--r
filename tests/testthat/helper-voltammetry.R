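# Shared helpers: noise-free parameter sets, analytic traces, and
# brute-force oracles used to cross-check PCA/HCA.

# Generator settings with every stochastic term switched off.
quiet_params <- function(...) {
  sim_params(noise_sd_fraction = 0, noise_floor = 0,
             potential_jitter_sd = 0, ...)
}

# A bare trace from explicit currents on a uniform grid.
flat_trace <- function(currents, lo = -1.6, scan = "anodic", step = 0.01) {
  E <- lo + step * (seq_along(currents) - 1)
  if (scan == "cathodic") {
    voltammogram(rev(E), rev(currents), "cathodic")
  } else {
    voltammogram(E, currents, "anodic")
  }
}

# Sum of Gaussian peaks (FWHM parameterization, as the generator uses).
gauss_sum <- function(E, centers, heights, fwhm = 0.07) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  y <- numeric(length(E))
  for (i in seq_along(centers)) {
    y <- y + heights[i] * exp(-(E - centers[i])^2 / (2 * sigma^2))
  }
  y
}

# Noise-free anodic/cathodic pair for one analyte, screened or raw.
quiet_pair <- function(analyte, conc = 100, seed = 11) {
  p <- quiet_params()
  list(
    anodic = simulate_voltammogram(stats::setNames(conc, analyte), "anodic",
                                   p, seed = seed),
    cathodic = simulate_voltammogram(stats::setNames(conc, analyte),
                                     "cathodic", p, seed = seed + 1)
  )
}

# Brute-force covariance eigendecomposition PCA oracle.
pca_oracle <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  list(explained = ev$values / sum(ev$values), loadings = ev$vectors)
}

# Naive O(n^3) average-linkage agglomeration; returns the cophenetic
# distance matrix, which pins down both merge order and heights.
naive_average_coph <- function(x) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, n)
  cd <- d # cluster-to-cluster mean distances, indexed like d
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA)
    best_h <- Inf
    idx <- which(active)
    for (a in idx) {
      for (b in idx) {
        if (a < b && cd[a, b] < best_h) {
          best_h <- cd[a, b]
          best <- c(a, b)
        }
      }
    }
    a <- best[1]; b <- best[2]
    for (i in clusters[[a]]) for (j in clusters[[b]]) {
      coph[i, j] <- best_h
      coph[j, i] <- best_h
    }
    merged <- c(clusters[[a]], clusters[[b]])
    # unweighted average linkage: mean over all cross pairs
    for (c0 in idx) {
      if (c0 == a || c0 == b) next
      cd[a, c0] <- mean(d[merged, clusters[[c0]], drop = FALSE])
      cd[c0, a] <- cd[a, c0]
    }
    clusters[[a]] <- merged
    active[b] <- FALSE
  }
  coph
}

# Permutation-invariant check that two partitions are identical.
same_partition <- function(p1, p2) {
  tab <- table(p1, p2)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}
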