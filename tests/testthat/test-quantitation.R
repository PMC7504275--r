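test_that("relative response factors normalize response per concentration to the IS", {
  expect_equal(compute_rrf(100, 2, 100, 2), 1.0)
  expect_equal(compute_rrf(345, 0.3, 345, 0.3), 1.0) # NNN against itself
  expect_equal(compute_rrf(200, 1, 100, 1), 2.0)
  expect_error(compute_rrf(0, 1, 100, 1), "positive")
  expect_error(compute_rrf(100, 1, 100, -1), "positive")
})

test_that("calibration fitting reports slope, r-squared and nonlinearity flag", {
  pts <- data.frame(conc = 1:7, area = 50 * (1:7))
  cal <- fit_calibration(pts, "OOO")
  expect_equal(cal$slope, 50)
  expect_equal(cal$r_squared, 1.0)
  expect_false(cal$flagged)

  set.seed(3)
  conc <- rep(c(0.05, 0.1, 0.5, 1, 2.5, 5, 10), each = 3)
  noisy <- data.frame(conc = conc, area = 50 * conc * exp(rnorm(21, 0, 0.01)))
  cal2 <- fit_calibration(noisy)
  expect_equal(cal2$slope, 50, tolerance = 0.05)
  expect_gt(cal2$r_squared, 0.99)

  flat <- fit_calibration(data.frame(conc = 1:5, area = rep(100, 5)))
  expect_equal(flat$slope, 0)
  expect_true(flat$flagged)

  expect_error(fit_calibration(data.frame(conc = c(1, 1, 2), area = 1:3)),
    "underdetermined")
})

test_that("internal-standard quantitation follows the RRF formula", {
  # one analyte with the same area as the IS, rrf 1: 3 mg IS / 30 mg oil -> 100 mg/g
  pt <- peak_table(tibble::tibble(
    rt_min = c(2, 2 + 0.93 * 25, 27),
    area = c(1e6, 1e5, 1e5),
    role = c("solvent", "analyte", "is")
  ))
  ident <- identify_peaks(pt, ret_model, "OOO")
  prof <- quantify(ident, data.frame(tg = "OOO", rrf = 1),
    is_mass_mg = 3, sample_mass_mg = 30)
  expect_equal(prof$mg_per_g[prof$tg == "OOO"], 100)

  # doubling the response factor halves the reported content
  prof2 <- quantify(ident, data.frame(tg = "OOO", rrf = 2),
    is_mass_mg = 3, sample_mass_mg = 30)
  expect_equal(prof2$mg_per_g, 50)
})

test_that("quantitation marks below-LOD analytes Nd and requires an IS", {
  pt <- peak_table(tibble::tibble(
    rt_min = c(2, 2 + 0.93 * 25, 27),
    area = c(1e6, 1, 1e5),
    role = c("solvent", "analyte", "is")
  ))
  ident <- identify_peaks(pt, ret_model, "OOO")
  prof <- quantify(ident, data.frame(tg = "OOO", rrf = 1),
    lod = data.frame(tg = "OOO", lod_ug_ml = 0.053))
  expect_true(is.na(prof$mg_per_g[prof$tg == "OOO"]))

  attr(ident, "is_area") <- NULL
  expect_error(quantify(ident, data.frame(tg = "OOO", rrf = 1)),
    "internal-standard")
})

test_that("pipeline round-trips a zero-noise chromatogram to the input profile", {
  cfg <- quiet_cfg()
  for (prof in list(rro, oo)) {
    pt <- generate_peak_table(prof, cfg, seed = 5)
    got <- analyze_peak_table(pt, cfg)
    truth <- prof[!is.na(prof$mg_per_g), ]
    m <- match(truth$tg, got$tg)
    expect_false(anyNA(m))
    expect_equal(got$mg_per_g[m], truth$mg_per_g, tolerance = 1e-10)
  }
})

test_that("round-trip identity holds for random profiles and response factors", {
  cand <- union(rro$tg, oo$tg)
  for (seed in 1:5) {
    set.seed(seed)
    tgs <- sample(cand, 6)
    prof <- oil_profile(tgs, runif(6, 5, 300))
    rrf <- data.frame(tg = tgs, rrf = runif(6, 0.4, 2.3))
    cfg <- quiet_cfg(rrf = rrf)
    got <- analyze_peak_table(generate_peak_table(prof, cfg, seed = seed), cfg)
    m <- match(prof$tg, got$tg)
    expect_equal(got$mg_per_g[m], prof$mg_per_g, tolerance = 1e-10)
  }
})

test_that("composition percentages use quantified-TG total and sum to 100", {
  pc <- composition_percent(rro)
  expect_equal(sum(pc$percent), 100, tolerance = 1e-9)
  expect_equal(round_half_up(pc$percent[pc$tg == "OOO"]), 46)
  pc_oo <- composition_percent(oo)
  expect_equal(sum(pc_oo$percent), 100, tolerance = 1e-9)
  expect_equal(round_half_up(pc_oo$percent[pc_oo$tg == "OOO"]), 52)

  single <- composition_percent(oil_profile("OOO", 12))
  expect_equal(single$percent, 100)
  expect_error(composition_percent(oil_profile(c("PPO", "OOLn"), c(NA, NA))),
    "empty profile")
})

test_that("ECN grouping partitions the composition", {
  g_rro <- ecn_group_composition(rro)
  expect_equal(sum(g_rro$percent), 100, tolerance = 1e-9)
  expect_equal(round_half_up(g_rro$percent[g_rro$ecn == 48]), 52)
  expect_equal(round_half_up(g_rro$percent[g_rro$ecn == 44]), 20)
  g_oo <- ecn_group_composition(oo)
  expect_equal(round_half_up(g_oo$percent[g_oo$ecn == 48]), 79)
  expect_equal(round_half_up(g_oo$percent[g_oo$ecn == 46]), 16)

  expect_equal(ecn_group_composition(oil_profile("PPP", 50)),
    tibble::tibble(ecn = 48L, percent = 100))
})

test_that("blend composition reproduces the printed indicator percentages", {
  b25 <- oil_profile_fixture("OO_in_RRO_2.5")
  pc <- composition_percent(b25)
  expect_equal(round_half_up(pc$percent[pc$tg == "OOP"], 2), 9.24)
  expect_equal(round_half_up(pc$percent[pc$tg == "PPO"], 2), 0.44)
})

test_that("detection counts from the packaged profiles match the study", {
  expect_equal(sum(!is.na(rro$mg_per_g)), 8)
  expect_equal(sum(!is.na(oo$mg_per_g)), 10)
})

test_that("half-up rounding rounds away from zero at the printed precision", {
  expect_equal(round_half_up(c(46.5, 45.4999, -1.5)), c(47, 45, -2))
  expect_equal(round_half_up(0.125, 2), 0.13) # base round() would give 0.12
})
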