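# Shared fixtures: packaged standards/profiles and a fitted model.
std_tab <- tg_standards()
ret_model <- fit_identification_plot(std_tab[, c("tg", "rrt")])
rro <- oil_profile_fixture("RRO")
oo <- oil_profile_fixture("OO")

quiet_cfg <- function(...) sim_config(area_sigma = 0, ...)

# independent closed-form oracle for two-anchor log-linear interpolation
interp_oracle <- function(rrt0, db0, rrt1, db1, db) {
  exp(log(rrt0) + (db - db0) / (db1 - db0) * (log(rrt1) - log(rrt0)))
}
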