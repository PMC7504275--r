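test_that("relative retention time follows the solvent/IS normalization", {
  expect_equal(relative_retention_time(27, 2, 27), 1.0)
  expect_equal(relative_retention_time(2, 2, 27), 0.0)
  expect_equal(relative_retention_time(22, 2, 27), 0.80)
  expect_error(relative_retention_time(5, 10, 10), "degenerate")
  expect_error(relative_retention_time(1, 2, 27), "precedes")
})

test_that("rrt is invariant under affine rescaling of the time axis", {
  set.seed(7)
  for (i in 1:20) {
    solvent <- runif(1, 1, 3)
    is_t <- solvent + runif(1, 10, 30)
    rts <- sort(runif(5, solvent, is_t))
    a <- runif(1, 0.5, 3)
    b <- runif(1, -0.5, 5)
    expect_equal(
      relative_retention_time(a * rts + b, a * solvent + b, a * is_t + b),
      relative_retention_time(rts, solvent, is_t)
    )
  }
})

test_that("printed standard rrts bin as 3 / 3 / 11 across the elution window", {
  r <- std_tab$rrt
  expect_equal(sum(r >= 0.70 & r < 0.80), 3)
  expect_equal(sum(r >= 0.80 & r < 0.90), 3)
  expect_equal(sum(r > 0.90), 11)
})

test_that("chart fitting builds anchors, a virtual Ln anchor, and errors when underdetermined", {
  an <- ret_model$anchors
  expect_setequal(an$acyl, c("P", "S", "O", "L", "N", "Ln"))
  expect_equal(an$log_rrt[an$acyl == "O"], log(0.93))
  expect_equal(an$log_rrt[an$acyl == "L"], log(0.97))
  # saturated anchors sit on the DB = 0 axis
  expect_true(all(an$db[an$acyl %in% c("P", "S", "N")] == 0))
  # Ln has no monoacid standard: virtual anchor via OOLn on the O/Ln line
  expect_true(an$virtual[an$acyl == "Ln"])
  expect_equal(exp(an$log_rrt[an$acyl == "Ln"]),
    interp_oracle(0.93, 3, 0.96, 5, 9))

  expect_error(
    fit_identification_plot(data.frame(tg = "OOO", rrt = 0.93)),
    "underdetermined"
  )
})

test_that("two-acyl prediction interpolates DB on the log(rrt) scale", {
  # oracle recomputed here from the anchor definition, independent of the model
  expect_equal(predict_rrt(ret_model, "OOL"), interp_oracle(0.93, 3, 0.97, 6, 4))
  expect_equal(predict_rrt(ret_model, "LLO"), interp_oracle(0.93, 3, 0.97, 6, 5))
  expect_equal(predict_rrt(ret_model, "OOS"), interp_oracle(0.91, 0, 0.93, 3, 2))
  expect_equal(round(predict_rrt(ret_model, "OOL"), 3), 0.943)
  expect_equal(round(predict_rrt(ret_model, "LLO"), 3), 0.956)
  # monoacid anchors pass through
  expect_equal(predict_rrt(ret_model, "OOO"), 0.93)
  # saturated mixed TGs interpolate in CN on the DB=0 axis
  expect_equal(predict_rrt(ret_model, "PPS"),
    exp(log(0.70) + (50 - 48) / (54 - 48) * (log(0.91) - log(0.70))))
  expect_error(predict_rrt(ret_model, "PLnP"), NA) # between P/Ln lines, predictable
})

test_that("three-acyl prediction averages the covering pairwise lines", {
  # POL (DB=3): P/O at 3, P/L at 3, O/L at 3
  pol <- exp(mean(log(c(
    interp_oracle(0.70, 0, 0.93, 3, 3),
    interp_oracle(0.70, 0, 0.97, 6, 3),
    interp_oracle(0.93, 3, 0.97, 6, 3)
  ))))
  expect_equal(predict_rrt(ret_model, "POL"), pol)
  # POLn (DB=4): the P/O line (span 0-3) cannot cover DB=4 and is excluded
  a_ln <- interp_oracle(0.93, 3, 0.96, 5, 9)
  poln <- exp(mean(log(c(
    interp_oracle(0.70, 0, a_ln, 9, 4),
    interp_oracle(0.93, 3, a_ln, 9, 4)
  ))))
  expect_equal(predict_rrt(ret_model, "POLn"), poln)
  expect_error(predict_rrt(ret_model, "OOX"), "unknown residue")
})

test_that("mixed-acid standards are predicted within 0.02 of their printed rrt", {
  for (tg in c("OOL", "OOP", "OPO", "LLO", "LLS", "OOS", "PPL", "PPS", "OOLn")) {
    printed <- std_tab$rrt[std_tab$tg == tg]
    expect_lt(abs(predict_rrt(ret_model, tg) - printed), 0.02)
  }
})

test_that("standard references keep printed rrts at printed precision, de-rounding collisions", {
  refs <- ret_model$refs
  expect_equal(round(refs$rrt_ref, 2), refs$rrt_printed)
  # distinct-multiset standards sharing a printed rrt get distinct references
  expect_false(any(duplicated(refs$rrt_ref)))
  # non-colliding standards keep the printed value exactly
  expect_equal(refs$rrt_ref[refs$tg == "PPP"], 0.70)
  expect_equal(refs$rrt_ref[refs$tg == "NNN"], 1.00)
})

test_that("peaks are matched, ranked, and ambiguity is reported not resolved silently", {
  mk <- function(rrts) peak_table(tibble::tibble(
    rt_min = c(2, 2 + rrts * 25, 27),
    area = c(1e6, rep(1e4, length(rrts)), 1e5),
    role = c("solvent", rep("analyte", length(rrts)), "is")
  ))
  cand <- std_tab$tg

  one <- identify_peaks(mk(0.70), ret_model, cand)
  expect_equal(one$label, "PPP")
  expect_equal(one$n_matches, 1L)

  amb <- identify_peaks(mk(0.85), ret_model, cand)
  expect_setequal(amb$matches[[1]]$tg, c("OOP", "PSO"))

  none <- identify_peaks(mk(numeric(0)), ret_model, cand)
  expect_equal(nrow(none), 0)

  far <- identify_peaks(mk(0.50), ret_model, cand)
  expect_true(is.na(far$label))
  expect_equal(far$n_matches, 0L)
})

test_that("zero-noise chromatograms are identified 100% up to positional isomers", {
  cfg <- quiet_cfg()
  cand <- union(rro$tg, oo$tg)
  for (prof in list(rro, oo)) {
    pt <- generate_peak_table(prof, cfg, seed = 11)
    ident <- assign_identities(identify_peaks(pt, cfg$model, cand))
    truth <- sort(prof$tg[!is.na(prof$mg_per_g)])
    expect_equal(sort(ident$label), truth)
  }
})

test_that("area floor drops artifact peaks before identification", {
  pt <- peak_table(tibble::tibble(
    rt_min = c(2, 2.6, 2 + 0.93 * 25, 27),
    area = c(1e6, 5, 1e4, 1e5),
    role = c("solvent", "analyte", "analyte", "is")
  ))
  ident <- identify_peaks(pt, ret_model, "OOO", area_floor = 10)
  expect_equal(nrow(ident), 1)
  expect_equal(ident$label, "OOO")
})

test_that("model dump is a readable key-value text file", {
  p <- withr::local_tempfile(fileext = ".txt")
  write_retention_model(ret_model, p)
  lines <- readLines(p)
  expect_match(lines[1], "^tolerance:")
  expect_length(grep("^anchor ", lines), nrow(ret_model$anchors))
  expect_length(grep("^ref ", lines), nrow(ret_model$refs))
})
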