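test_that("all 15 SC standards screen positive with their designed group", {
  lib <- default_peak_library()
  for (a in library_analytes(lib, "SC")) {
    pr <- quiet_pair(a)
    res <- screen_sample(pr$anodic, pr$cathodic)
    expect_true(res$positive, label = paste(a, "positive"))
    expect_true(res$r1_found, label = paste(a, "R1"))
    expect_true(res$r2_found, label = paste(a, "R2"))
    expect_identical(res$assigned_group, get_profile(a, lib)$group,
                     label = paste(a, "group"))
    expect_length(res$interferent_flags, 0)
  }
})

test_that("all 13 interferent-only samples screen negative", {
  lib <- default_peak_library()
  for (a in library_analytes(lib, c("interferent", "silent"))) {
    pr <- quiet_pair(a)
    res <- screen_sample(pr$anodic, pr$cathodic)
    expect_false(res$positive, label = paste(a, "negative"))
    expect_true(is.na(res$assigned_group))
  }
})

test_that("R1 alone suffices for a positive call (R2 below detection)", {
  p <- quiet_params()
  comp <- c(ephylone = 100)
  an <- simulate_voltammogram(comp, "anodic", p, seed = 2, r2_scale = 0)
  ca <- simulate_voltammogram(comp, "cathodic", p, seed = 3, r2_scale = 0)
  res <- screen_sample(an, ca)
  expect_true(res$positive)
  expect_true(res$r1_found)
  expect_false(res$r2_found)
  expect_identical(res$assigned_group, "G2")
})

test_that("caffeine-only samples are negative but flagged; silent drugs
           leave no trace", {
  caf <- quiet_pair("caffeine")
  res <- screen_sample(caf$anodic, caf$cathodic)
  expect_false(res$positive)
  expect_identical(res$interferent_flags, "caffeine")

  coc <- quiet_pair("cocaine")
  res2 <- screen_sample(coc$anodic, coc$cathodic)
  expect_false(res2$positive)
  expect_length(res2$interferent_flags, 0)
})

test_that("the group decision table follows the anodic-process count", {
  mk <- function(pots) {
    n <- length(pots)
    data.frame(potential = pots, height = rep(4, n),
               prominence = rep(4, n), width = rep(0.07, n),
               sign = rep("oxidation", n), scan = rep("anodic", n))
  }
  expect_identical(assign_group(mk(c(0.60, 1.00, 1.25))), "G2")
  expect_identical(assign_group(mk(c(0.60, 0.83, 1.03, 1.19))), "G3")
  expect_identical(assign_group(mk(c(0.60, 0.78, 0.90, 1.01, 1.19))), "G4")
  expect_identical(assign_group(mk(c(0.90, 1.00))), "G5")
  expect_identical(assign_group(mk(1.19)), "G1")
  expect_identical(assign_group(mk(numeric(0))), "G1") # R1-only profile
  expect_identical(assign_group(mk(c(-0.31, -0.17, 0.82, 0.95))), "G6")
  # two processes including the +0.60 V marker match no library pattern
  expect_identical(assign_group(mk(c(0.60, 1.00))), NA_character_)
  expect_identical(assign_group(mk(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0))),
                   NA_character_)
})

test_that("mixtures resolve to the group with more anodic processes", {
  expect_identical(resolve_mixture(c("G2", "G3")), "G3")
  expect_identical(resolve_mixture("G5"), "G5")
  expect_identical(resolve_mixture(c("G1", "G4")), "G4")
  expect_identical(resolve_mixture(c("G3", "G6")), "G3") # tie: lower index
  expect_error(resolve_mixture(character(0)), "no candidate")
})

test_that("interferent flags fire on their marker patterns", {
  mkc <- function(pots, scan = "cathodic", sign = "reduction", h = -4) {
    n <- length(pots)
    data.frame(potential = pots, height = rep(h, n),
               prominence = rep(abs(h), n), width = rep(0.07, n),
               sign = rep(sign, n), scan = rep(scan, n))
  }
  fl <- flag_interferents(NULL, mkc(c(-0.70, -0.50)))
  expect_true("MDMA/MDEA" %in% fl)
  expect_false("MDMA/MDEA" %in% flag_interferents(NULL, mkc(-0.70)))
  expect_length(flag_interferents(NULL, mkc(numeric(0))), 0)
  fl2 <- flag_interferents(mkc(0.21, "anodic", "oxidation", 4), mkc(-0.24))
  expect_true("paracetamol" %in% fl2)
})

test_that("a caffeinated SC sample keeps its group and gains the caffeine
           flag", {
  p <- quiet_params()
  # adulterant in excess, as is typical of seized tablets
  comp <- c(ephylone = 100, caffeine = 200)
  an <- simulate_voltammogram(comp, "anodic", p, seed = 6)
  ca <- simulate_voltammogram(comp, "cathodic", p, seed = 7)
  res <- screen_sample(an, ca)
  expect_true(res$positive)
  expect_identical(res$assigned_group, "G2")
  expect_true("caffeine" %in% res$interferent_flags)
})

test_that("positivity is robust to any co-formulated interferent", {
  p <- quiet_params()
  lib <- default_peak_library()
  for (intf in library_analytes(lib, c("interferent", "silent"))) {
    comp <- stats::setNames(c(100, 100), c("MPHP", intf))
    an <- simulate_voltammogram(comp, "anodic", p, seed = 8)
    ca <- simulate_voltammogram(comp, "cathodic", p, seed = 9)
    res <- screen_sample(an, ca)
    expect_true(res$positive, label = paste("MPHP +", intf))
  }
})

test_that("screening requires a cathodic trace and checks its direction", {
  pr <- quiet_pair("MPHP")
  expect_error(screen_sample(pr$anodic, NULL), "cathodic")
  expect_error(screen_sample(NULL, pr$anodic), "not a cathodic")
  # cathodic-only evidence still yields the positivity call
  res <- screen_sample(NULL, pr$cathodic)
  expect_true(res$positive)
  expect_true(is.na(res$assigned_group))
  expect_true(is.na(res$anodic_count))
})
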