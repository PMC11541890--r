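test_that("an empty composition at zero noise is exactly the baseline", {
  p <- quiet_params()
  vg <- simulate_voltammogram(data.frame(analyte_id = character(),
                                         conc_um = numeric()),
                              "anodic", p, seed = 1)
  expect_equal(vg$current, eval_baseline(p, vg$potential), tolerance = 1e-12)
  expect_identical(vg$scan, "anodic")
  expect_equal(diff(vg$potential), rep(p$step_potential, length(vg) - 1),
               tolerance = 1e-9)
})

test_that("bad compositions are rejected", {
  expect_error(simulate_voltammogram(c(`no-such-drug` = 10), "anodic",
                                     quiet_params()), "no-such-drug")
  expect_error(simulate_voltammogram(data.frame(analyte_id = "MPHP",
                                                conc_um = -1),
                                     "anodic", quiet_params()), "positive")
})

test_that("the signal model is linear in concentration and additive over
           mixtures", {
  p <- quiet_params()
  v50 <- simulate_voltammogram(c(MPHP = 50), "anodic", p, seed = 4)
  v100 <- simulate_voltammogram(c(MPHP = 100), "anodic", p, seed = 4)
  bl <- eval_baseline(p, v50$potential)
  expect_equal(v100$current - bl, 2 * (v50$current - bl), tolerance = 1e-9)

  va <- simulate_voltammogram(c(methylone = 100), "anodic", p, seed = 5)
  vb <- simulate_voltammogram(c(caffeine = 80), "anodic", p, seed = 5)
  vab <- simulate_voltammogram(c(methylone = 100, caffeine = 80), "anodic",
                               p, seed = 5)
  expect_equal(vab$current - bl, (va$current - bl) + (vb$current - bl),
               tolerance = 1e-9)
})

test_that("traces are deterministic given the seed", {
  p <- sim_params() # full noise model
  a1 <- simulate_voltammogram(c(ephylone = 80), "cathodic", p, seed = 42)
  a2 <- simulate_voltammogram(c(ephylone = 80), "cathodic", p, seed = 42)
  a3 <- simulate_voltammogram(c(ephylone = 80), "cathodic", p, seed = 43)
  expect_identical(a1$current, a2$current)
  expect_false(identical(a1$current, a3$current))
})

test_that("raising the pH shifts every peak to more negative potentials", {
  p8 <- quiet_params()
  p10 <- quiet_params(pH = 10)
  v8 <- simulate_voltammogram(c(MPHP = 100), "cathodic", p8, seed = 1)
  v10 <- simulate_voltammogram(c(MPHP = 100), "cathodic", p10, seed = 1)
  # R1 minimum and O2 maximum both move by -0.059 * 2 = -0.118 V
  shift <- -0.059 * 2
  r1_8 <- v8$potential[which.min(v8$current)]
  r1_10 <- v10$potential[which.min(v10$current)]
  expect_lt(abs((r1_10 - r1_8) - shift), 0.011)
  bl <- eval_baseline(p8, v8$potential)
  o2_8 <- v8$potential[which.max(v8$current - bl)]
  o2_10 <- v10$potential[which.max(v10$current - bl)]
  expect_lt(abs((o2_10 - o2_8) - shift), 0.011)
})

test_that("an MPHP standard shows its two anodic processes at +0.90/+1.0 V", {
  vg <- simulate_voltammogram(c(MPHP = 100), "anodic", sim_params(),
                              seed = 1)
  pk <- detect_peaks(preprocess(vg))
  ox <- pk[pk$sign == "oxidation", ]
  ox <- ox[order(-ox$height), ][1:2, ]
  expect_lt(max(abs(sort(ox$potential) - c(0.90, 1.00))), 0.021)
})

test_that("replicate repeatability stays inside the published RSD bounds", {
  # 5 replicates at default noise for a representative of each group
  reps <- lapply(c("mephedrone", "ephylone", "dibutylone", "MDPV", "MPHP",
                   "alpha-PVT"), function(a) {
    do.call(rbind, lapply(1:5, function(r) {
      vg <- simulate_voltammogram(stats::setNames(100, a), "cathodic",
                                  sim_params(), seed = 400 + 31 * r)
      pp <- preprocess(vg)
      w <- data.frame(label = "R1", lo = -1.45, hi = -1.15,
                      sign = "reduction")
      m <- match_peaks(detect_peaks(pp), w)
      data.frame(analyte = a, process = "R1", potential = m$potential[1],
                 height = m$height[1])
    }))
  })
  tab <- repeatability(do.call(rbind, reps))
  expect_true(all(tab$ip_pass))
  expect_true(all(tab$ep_pass))
  expect_true(all(tab$ip_rsd < 13.0))
  expect_true(all(tab$ep_rsd < 1.0))
})

test_that("the 46-sample fixture mirrors the seized-panel composition", {
  panel <- make_fixture_46(seed = 7)
  man <- panel$manifest
  expect_identical(nrow(man), 46L)
  expect_identical(sum(man$truth_positive), 42L)
  expect_identical(sum(!man$truth_positive), 4L)
  expect_identical(sum(man$caffeine), 14L)
  expect_identical(which(man$mdma), c(7L, 46L))
  expect_identical(which(man$r2_suppressed), c(7L, 26L, 27L, 30L, 32L, 40L))
  # the two mixture samples resolve to the group with more anodic processes
  expect_identical(man$analytes[8], "methylone+dibutylone")
  expect_identical(man$truth_group[8], "G3")
  expect_identical(man$truth_group[28], "G4")
  # mixtures and R2-suppressed samples are all truth-positive
  expect_true(all(man$truth_positive[c(7, 8, 26, 27, 28, 30, 32, 40)]))
  # every designed group appears somewhere in the panel
  expect_setequal(unique(stats::na.omit(man$truth_group)), paste0("G", 1:6))

  panel2 <- make_fixture_46(seed = 7)
  expect_identical(panel2$samples[[13]]$anodic$current,
                   panel$samples[[13]]$anodic$current)
  panel3 <- make_fixture_46(seed = 8)
  expect_false(identical(panel3$samples[[13]]$anodic$current,
                         panel$samples[[13]]$anodic$current))
})

test_that("calibration series have the requested layout and scale with
           concentration", {
  p <- quiet_params()
  tr <- simulate_calibration("MPHP", seq(15, 100, length.out = 7),
                             replicates = 3, params = p, seed = 2)
  expect_length(tr, 21L)
  # zero noise: R1 component height is exactly proportional to concentration
  heights <- vapply(tr, function(vg) {
    bl <- eval_baseline(p, vg$potential)
    max(abs(vg$current - bl))
  }, numeric(1))
  concs <- vapply(tr, function(vg) vg$meta$conc_um, numeric(1))
  expect_equal(heights / concs, rep(heights[1] / concs[1], 21),
               tolerance = 1e-9)

  # 2% noise: regression slope recovers the generator constant within 5%
  cal <- calibrate_analyte("MPHP", seq(15, 100, length.out = 7),
                           replicates = 3, params = sim_params(), seed = 2)
  expect_equal(cal$fit$slope, sim_params()$amplitude_scale,
               tolerance = 0.05)
  expect_error(simulate_calibration("MPHP", numeric(0)), "nonempty")
})
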