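test_that("a noise-free dibutylone anodic trace yields its four oxidations
           and the R1 reduction", {
  vg <- quiet_pair("dibutylone")$anodic
  pk <- detect_peaks(preprocess(vg))
  ox <- pk[pk$sign == "oxidation", ]
  red <- pk[pk$sign == "reduction", ]
  expect_identical(nrow(ox), 4L)
  expect_lt(max(abs(sort(ox$potential) - c(0.60, 0.83, 1.03, 1.19))), 0.021)
  expect_identical(nrow(red), 1L)
  expect_lt(abs(red$potential - (-1.40)), 0.021)
})

test_that("flat and empty inputs give empty peak lists", {
  expect_identical(nrow(detect_peaks(flat_trace(rep(0, 50)))), 0L)
})

test_that("two Gaussians 0.05 V apart merge into a single peak", {
  E <- seq(0.5, 1.5, by = 0.01)
  y <- gauss_sum(E, c(0.975, 1.025), c(1, 1))
  pk <- detect_peaks(voltammogram(E, y, "anodic"))
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$potential, 1.00, tolerance = 0.011)
})

test_that("detection recovers the full library peak set of every profiled
           analyte on noise-free traces", {
  lib <- default_peak_library()
  p <- quiet_params()
  scale <- p$amplitude_scale * 100
  for (a in library_analytes(lib)) {
    prof <- get_profile(a, lib)
    for (scan in c("anodic", "cathodic")) {
      truth <- prof[[scan]]
      vg <- simulate_voltammogram(stats::setNames(100, a), scan, p,
                                  seed = 21)
      pk <- detect_peaks(preprocess(vg))
      expect_identical(nrow(pk), nrow(truth),
                       label = sprintf("%s %s peak count", a, scan))
      if (nrow(truth) == 0L) next
      truth <- truth[order(truth$potential_V), ]
      expect_lt(max(abs(pk$potential - truth$potential_V)), 0.0101)
      expect_lt(max(abs(abs(pk$height) /
                          (scale * truth$rel_amplitude) - 1)), 0.02)
      expect_identical(pk$sign, truth$sign)
    }
  }
})

test_that("raising the prominence threshold never adds peaks", {
  vg <- preprocess(simulate_voltammogram(c(MDPV = 100), "anodic",
                                         sim_params(), seed = 5))
  counts <- vapply(c(0.01, 0.05, 0.1, 0.2, 0.5, 0.9),
                   function(f) nrow(detect_peaks(vg, f)), integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("window matching follows the largest-peak rule", {
  rwin <- data.frame(label = c("R2", "R1"),
                     lo = c(-1.70, -1.45), hi = c(-1.45, -1.15),
                     sign = "reduction")
  pk <- data.frame(potential = -1.38, height = -4, prominence = 4,
                   width = 0.07, sign = "reduction", scan = "cathodic")
  m <- match_peaks(pk, rwin)
  expect_true(m$matched[m$label == "R1"])
  expect_false(m$matched[m$label == "R2"])
  expect_equal(m$potential[m$label == "R1"], -1.38)

  # paracetamol's -0.24 V reduction falls in neither window
  par <- data.frame(potential = -0.24, height = -3, prominence = 3,
                    width = 0.07, sign = "reduction", scan = "cathodic")
  expect_false(any(match_peaks(par, rwin)$matched))

  # empty peak list: every window absent
  empty <- detect_peaks(flat_trace(rep(0, 50)))
  expect_false(any(match_peaks(empty, rwin)$matched))

  # a shared boundary belongs to the lower (R2) window: half-open (lo, hi]
  edge <- data.frame(potential = -1.45, height = -4, prominence = 4,
                     width = 0.07, sign = "reduction", scan = "cathodic")
  m2 <- match_peaks(edge, rwin)
  expect_true(m2$matched[m2$label == "R2"])
  expect_false(m2$matched[m2$label == "R1"])
})

test_that("matching breaks height ties by distance to the window centre and
           rejects overlapping windows", {
  w <- data.frame(label = "W", lo = -1.45, hi = -1.15)
  pk <- data.frame(potential = c(-1.35, -1.21), height = c(4, 4),
                   prominence = c(4, 4), width = 0.07, sign = "oxidation",
                   scan = "anodic")
  m <- match_peaks(pk, w)
  expect_equal(m$potential, -1.35) # centre is -1.30

  bad <- data.frame(label = c("A", "B"), lo = c(0, 0.5), hi = c(0.6, 1))
  expect_error(match_peaks(pk, bad), "overlap")
  expect_error(match_peaks(pk, w, tolerance = 0.2), NA)
})
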