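#!/usr/bin/env Rscript
# Adulteration screening of every packaged blend profile: indicator-TG
# detection in both directions, per-indicator and combined blend-fraction
# estimates, and theoretical-vs-experimental comparison under the linear
# mixing model.

suppressPackageStartupMessages(library(tgquant))
dir.create("results", showWarnings = FALSE)

std <- tg_standards()
bm <- blend_model(oil_profile_fixture("OO"), oil_profile_fixture("RRO"))
floors <- indicator_floors(
  std[, c("tg", "lod_ug_ml")],
  union(bm$indicators_a, bm$indicators_b)
)

blends <- expand.grid(
  direction = c("OO_in_RRO", "RRO_in_OO"),
  pct = c("1", "2.5", "5", "10"),
  stringsAsFactors = FALSE
)
screen <- do.call(rbind, lapply(seq_len(nrow(blends)), function(i) {
  s <- paste0(blends$direction[i], "_", blends$pct[i])
  q <- oil_profile_fixture(s)
  dir <- if (blends$direction[i] == "OO_in_RRO") "a_in_b" else "b_in_a"
  est <- estimate_blend_fraction(q, bm, dir,
    rsd = std[, c("tg", "rsd_pct")], floors = floors)
  det <- detect_indicators(q, bm, floors)[[dir]]
  data.frame(
    sample = s, declared_f = as.numeric(blends$pct[i]) / 100,
    flagged = det$flagged,
    f_hat_combined = round(est$f_hat, 4),
    f_hat_indicators = round(mean(est$per_indicator$f_hat), 4)
  )
}))
write.csv(screen, "results/adulteration_screen.csv", row.names = FALSE)
message("Declared vs estimated blend fractions (measured blend profiles):")
print(screen, row.names = FALSE)
message("All declared blends flagged: ", all(screen$flagged))
message(
  "Note: estimates from the measured blend profiles exceed the declared ",
  "fractions, especially for olive-in-rapeseed: the measured indicator ",
  "contents are systematically above the linear mixing model (e.g. PPO at ",
  "1% measured at 0.8 mg/g vs 0.21 theoretical). Detection is robust; ",
  "fraction estimation is accurate where mixing is linear (see 04_simulation.R)."
)

tve <- theoretical_vs_experimental(
  oil_profile_fixture("RRO_in_OO_10"), 0.10, bm, "b_in_a"
)
write.csv(tve, "results/theoretical_vs_experimental_10pct.csv", row.names = FALSE)
message(sprintf(
  "10%% rapeseed-in-olive: OOLn expected %.1f mg/g from mixing, measured %.1f mg/g.",
  tve$theoretical[tve$tg == "OOLn"], tve$experimental[tve$tg == "OOLn"]
))
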