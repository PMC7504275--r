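# Evaluate code under a temporary RNG state so generators are pure
# functions of their seed and never disturb the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulation configuration
#'
#' Bundles everything the chromatogram generator needs. Defaults emulate
#' the study conditions: pure-oil profiles from the packaged composition
#' table, standard rrt/RRF/LOD tables from the packaged standards table,
#' 30 mg oil + 3 mg NNN in 10 mL solvent, blend fractions 1/2.5/5/10%,
#' triplicate preparation, 5% multiplicative (lognormal) area noise, and no
#' retention-time jitter (jitter is opt-in; the instrument's intraday rt
#' spread is below 0.5%). The absolute time axis (solvent 2.0 min, IS 27.0
#' min) is a free constant; only rrt is physically meaningful.
#'
#' @param profiles Named list of two pure [oil_profile()]s (`OO`, `RRO`).
#' @param standards Data frame `tg`, `rrt` of retention standards.
#' @param rrf Data frame `tg`, `rrf`.
#' @param lod Data frame `tg`, `lod_ug_ml`.
#' @param rsd Data frame `tg`, `rsd_pct` (used for estimator weighting).
#' @param fractions Blend fractions simulated by [generate_blend_series()].
#' @param replicates Preparations per blend.
#' @param solvent_rt,is_rt Solvent-front and internal-standard retention
#'   times, minutes.
#' @param is_area Reference internal-standard area, counts.
#' @param area_sigma Multiplicative (lognormal) area noise sigma.
#' @param rt_jitter_sigma Relative retention-time jitter sigma (Gaussian,
#'   truncated at 3 sigma).
#' @param sample_mass_mg,is_mass_mg,dilution_ml Sample-prep constants.
#' @param seed Integer seed fixing the full output stream.
#' @param registry Fatty-acid registry.
#' @param tolerance Identification tolerance passed to the fitted model.
#' @return List of class `sim_config`, including the fitted
#'   `retention_model` under `$model`.
#' @export
sim_config <- function(profiles = list(
                         OO = oil_profile_fixture("OO"),
                         RRO = oil_profile_fixture("RRO")
                       ),
                       standards = tg_standards()[, c("tg", "rrt")],
                       rrf = tg_standards()[, c("tg", "rrf")],
                       lod = tg_standards()[, c("tg", "lod_ug_ml")],
                       rsd = tg_standards()[, c("tg", "rsd_pct")],
                       fractions = c(0.01, 0.025, 0.05, 0.10),
                       replicates = 3,
                       solvent_rt = 2.0, is_rt = 27.0, is_area = 1e5,
                       area_sigma = 0.05, rt_jitter_sigma = 0,
                       sample_mass_mg = 30, is_mass_mg = 3, dilution_ml = 10,
                       seed = 1,
                       registry = default_fa_registry(),
                       tolerance = 0.0105) {
  stopifnot(area_sigma >= 0, rt_jitter_sigma >= 0, all(fractions >= 0 & fractions <= 1))
  cfg <- list(
    profiles = profiles, standards = tibble::as_tibble(standards),
    rrf = tibble::as_tibble(rrf), lod = tibble::as_tibble(lod),
    rsd = tibble::as_tibble(rsd),
    fractions = fractions, replicates = replicates,
    solvent_rt = solvent_rt, is_rt = is_rt, is_area = is_area,
    area_sigma = area_sigma, rt_jitter_sigma = rt_jitter_sigma,
    sample_mass_mg = sample_mass_mg, is_mass_mg = is_mass_mg,
    dilution_ml = dilution_ml, seed = seed, registry = registry
  )
  cfg$model <- fit_identification_plot(cfg$standards, registry, tolerance)
  class(cfg) <- "sim_config"
  cfg
}

#' Perturb an oil profile with multiplicative noise
#'
#' Each non-Nd content is multiplied by lognormal noise (keeps contents
#' positive); Nd stays Nd. With sigma = 0.05 the per-TG RSD is about 5%.
#'
#' @param base An [oil_profile()].
#' @param noise_sigma Lognormal sigma.
#' @param seed Optional seed.
#' @return Perturbed `oil_profile`.
#' @export
generate_profile <- function(base, noise_sigma, seed = NULL) {
  with_seed(seed, {
    v <- base$mg_per_g
    keep <- !is.na(v)
    v[keep] <- v[keep] * exp(stats::rnorm(sum(keep), 0, noise_sigma))
    oil_profile(base$tg, v)
  })
}

#' Generate a synthetic peak table from an oil profile
#'
#' Emits a solvent-front peak, the NNN internal-standard peak, and one peak
#' per TG at rt = solvent_rt + rrt * (is_rt - solvent_rt), where rrt comes
#' from the configured retention model's reference table (standard rrt where
#' available, chart prediction otherwise). Areas follow the
#' internal-standard model area = rrf * (TG mass / IS mass) * IS area, with
#' multiplicative noise on every peak including the IS. Positional isomers
#' in the profile merge into a single peak (co-elution). TGs whose implied
#' in-vial concentration falls below their LOD are omitted, so they come
#' back Nd from quantitation.
#'
#' @param profile An [oil_profile()].
#' @param cfg A [sim_config()].
#' @param seed Optional seed (defaults to an unseeded draw so that callers
#'   can manage one stream across many tables).
#' @return A [peak_table()].
#' @export
generate_peak_table <- function(profile, cfg, seed = NULL) {
  with_seed(seed, {
    desc <- tg_describe(profile$tg, cfg$registry)
    keep <- !is.na(profile$mg_per_g)
    kdesc <- desc[keep, ]
    # merge positional isomers: one peak per acyl multiset
    content <- tapply(profile$mg_per_g[keep], kdesc$multiset, sum)
    fst <- !duplicated(kdesc$multiset)
    name_of <- stats::setNames(kdesc$tg[fst], kdesc$multiset[fst])
    tgs <- unname(name_of[names(content)])
    content <- as.numeric(content)

    conc_ug_ml <- content * cfg$sample_mass_mg / cfg$dilution_ml
    l <- cfg$lod$lod_ug_ml[match(tgs, cfg$lod$tg)]
    l[is.na(l)] <- max(cfg$lod$lod_ug_ml)
    det <- conc_ug_ml >= l
    tgs <- tgs[det]; content <- content[det]

    a_is <- cfg$is_area * exp(stats::rnorm(1, 0, cfg$area_sigma))
    rows <- tibble::tibble(
      rt_min = c(cfg$solvent_rt, cfg$is_rt),
      area = c(10 * cfg$is_area, a_is),
      role = c("solvent", "is")
    )
    if (length(tgs)) {
      refs <- reference_rrt(cfg$model, tgs)
      rrt <- refs$rrt_ref[match(
        tg_describe(tgs, cfg$registry)$multiset, refs$multiset
      )]
      r <- cfg$rrf$rrf[match(tgs, cfg$rrf$tg)]
      r[is.na(r)] <- 1
      mass_mg <- content * cfg$sample_mass_mg / 1000
      area <- r * (mass_mg / cfg$is_mass_mg) * a_is *
        exp(stats::rnorm(length(tgs), 0, cfg$area_sigma))
      rt <- cfg$solvent_rt + rrt * (cfg$is_rt - cfg$solvent_rt)
      if (cfg$rt_jitter_sigma > 0) {
        e <- stats::rnorm(length(rt), 0, cfg$rt_jitter_sigma)
        e <- pmin(pmax(e, -3 * cfg$rt_jitter_sigma), 3 * cfg$rt_jitter_sigma)
        rt <- rt * (1 + e)
      }
      rows <- rbind(rows, tibble::tibble(rt_min = rt, area = area, role = "analyte"))
    }
    peak_table(rows)
  })
}

#' Generate the full blend-series experiment
#'
#' Mixes the two pure profiles at every configured fraction in both
#' directions and generates replicate peak tables, reproducing the blending
#' design (4 fractions x 2 directions x triplicates by default). The whole
#' series is a pure function of the config seed.
#'
#' @param cfg A [sim_config()].
#' @return Tibble `direction` (`"OO_in_RRO"`/`"RRO_in_OO"`), `fraction`,
#'   `replicate`, `table` (list column of [peak_table()]s).
#' @export
generate_blend_series <- function(cfg) {
  with_seed(cfg$seed, {
    grid <- expand.grid(
      replicate = seq_len(cfg$replicates),
      fraction = cfg$fractions,
      direction = c("OO_in_RRO", "RRO_in_OO"),
      stringsAsFactors = FALSE
    )[, c("direction", "fraction", "replicate")]
    grid <- grid[order(grid$direction, grid$fraction, grid$replicate), ]
    tabs <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      if (grid$direction[i] == "OO_in_RRO") {
        mixed <- mix_profiles(grid$fraction[i], cfg$profiles$OO, cfg$profiles$RRO)
      } else {
        mixed <- mix_profiles(grid$fraction[i], cfg$profiles$RRO, cfg$profiles$OO)
      }
      tabs[[i]] <- generate_peak_table(mixed, cfg)
    }
    out <- tibble::as_tibble(grid)
    out$table <- tabs
    out
  })
}
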