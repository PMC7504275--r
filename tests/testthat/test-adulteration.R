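bm <- blend_model(oo, rro)
std_rsd <- std_tab[, c("tg", "rsd_pct")]
std_lod <- std_tab[, c("tg", "lod_ug_ml")]

test_that("blend model checks that indicators are absent from the opposite oil", {
  expect_equal(bm$indicators_a, c("PPO", "PPL", "PSO"))
  expect_error(blend_model(oo, rro, indicators_a = "OOO"), "not Nd")
  expect_error(blend_model(oo, rro, indicators_b = "LLL"), "not quantified")
})

test_that("mixing is mass-linear with Nd treated as zero but preserved", {
  expect_equal(mix_profiles(0, oo, rro)$mg_per_g[match(rro$tg, mix_profiles(0, oo, rro)$tg)],
    rro$mg_per_g)
  m1 <- mix_profiles(1, oo, rro)
  expect_equal(m1$mg_per_g[match(oo$tg, m1$tg)], oo$mg_per_g)
  m10 <- mix_profiles(0.10, rro, oo) # 10% rapeseed in olive
  expect_equal(m10$mg_per_g[m10$tg == "OOLn"], 0.10 * 117.8)
  expect_error(mix_profiles(1.2, oo, rro), "\\[0, 1\\]")
})

test_that("nested mixes compose consistently at the endpoints", {
  for (f in c(0, 1)) {
    for (g in c(0, 1)) {
      inner <- mix_profiles(g, oo, rro)
      outer <- mix_profiles(f, oo, inner)
      direct <- mix_profiles(f + g - f * g, oo, rro)
      m <- match(direct$tg, outer$tg)
      expect_equal(outer$mg_per_g[m], direct$mg_per_g)
    }
  }
})

test_that("indicator detection flags each direction from its marker TGs", {
  floors <- indicator_floors(std_lod, union(bm$indicators_a, bm$indicators_b))

  pure <- detect_indicators(rro, bm, floors)
  expect_false(pure$a_in_b$flagged)

  b1 <- detect_indicators(oil_profile_fixture("OO_in_RRO_1"), bm, floors)
  expect_true(b1$a_in_b$flagged)
  got <- b1$a_in_b$indicators
  expect_equal(got$mg_per_g[match(c("PPO", "PPL", "PSO"), got$tg)],
    c(0.8, 0.9, 0.2))

  only_ooln <- detect_indicators(oil_profile("OOLn", 5), bm, floors)
  expect_true(only_ooln$b_in_a$flagged)
  expect_false(only_ooln$a_in_b$flagged)
})

test_that("missing-LOD indicators fall back to the largest tabulated LOD", {
  fl <- indicator_floors(std_lod, c("PPO", "OOLn"))
  expect_equal(unname(fl["PPO"]), 0.330 * 10 / 30) # PPO has no tabulated LOD
  expect_equal(unname(fl["OOLn"]), 0.330 * 10 / 30)
})

test_that("fraction estimation inverts noise-free mixing exactly", {
  q <- mix_profiles(0.025, oo, rro)
  est <- estimate_blend_fraction(q, bm, "a_in_b", rsd = std_rsd)
  expect_equal(est$f_hat, 0.025, tolerance = 1e-9)
  expect_equal(est$status, "detected")

  est1 <- estimate_blend_fraction(oo, bm, "a_in_b")
  expect_equal(est1$f_hat, 1)

  est0 <- estimate_blend_fraction(rro, bm, "a_in_b")
  expect_equal(est0$f_hat, 0)
  expect_equal(est0$status, "not_detected")
})

test_that("per-indicator estimates ratio the query against the source oil", {
  q10 <- oil_profile_fixture("RRO_in_OO_10")
  est <- estimate_blend_fraction(q10, bm, "b_in_a", rsd = std_rsd)
  per <- est$per_indicator
  expect_equal(per$f_hat[per$tg == "OOLn"], 12.2 / 117.8)
  expect_equal(round(per$f_hat[per$tg == "OOLn"], 3), 0.104)
})

test_that("theoretical-vs-experimental tables difference the mixing model", {
  q <- mix_profiles(0.05, oo, rro)
  tab <- theoretical_vs_experimental(q, 0.05, bm, "a_in_b")
  expect_true(all(tab$diff == 0))
  expect_true(all(tab$pct_of_total == 0))

  q25 <- oil_profile_fixture("OO_in_RRO_2.5")
  tab25 <- theoretical_vs_experimental(q25, 0.025, bm, "a_in_b")
  expect_equal(tab25$theoretical[tab25$tg == "OOLn"], 0.975 * 117.8)
  expect_equal(tab25$experimental[tab25$tg == "OOLn"], 97.3)

  expect_error(theoretical_vs_experimental(q, 1.5, bm), "\\[0, 1\\]")
})
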