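# content lookup with Nd/absent treated as 0 (Nd propagates as 0 in sums but
# is never *reported* as 0)
content0 <- function(profile, tg) {
  v <- profile$mg_per_g[match(tg, profile$tg)]
  ifelse(is.na(v), 0, v)
}

#' Build a two-oil blend model
#'
#' Holds the two pure-oil profiles and, per direction, the indicator TGs:
#' TGs quantified in one pure oil but Nd in the other, whose appearance in a
#' sample flags blending. Defaults are the olive-oil indicators PPO, PPL,
#' PSO (absent from rapeseed oil) and the rapeseed indicator OOLn (absent
#' from olive oil).
#'
#' @param pure_a,pure_b [oil_profile()]s of the two pure oils (a = OO,
#'   b = RRO in the default use).
#' @param indicators_a TGs present in `pure_a`, Nd in `pure_b`.
#' @param indicators_b TGs present in `pure_b`, Nd in `pure_a`.
#' @param name_a,name_b Display names.
#' @return List of class `blend_model`.
#' @export
blend_model <- function(pure_a, pure_b,
                        indicators_a = c("PPO", "PPL", "PSO"),
                        indicators_b = c("OOLn"),
                        name_a = "OO", name_b = "RRO") {
  chk <- function(ind, src, opp, src_nm, opp_nm) {
    bad <- ind[content0(src, ind) <= 0]
    if (length(bad)) stop(sprintf(
      "indicator(s) %s not quantified in %s", paste(bad, collapse = ", "), src_nm))
    bad <- ind[content0(opp, ind) > 0]
    if (length(bad)) stop(sprintf(
      "indicator(s) %s not Nd in %s", paste(bad, collapse = ", "), opp_nm))
  }
  chk(indicators_a, pure_a, pure_b, name_a, name_b)
  chk(indicators_b, pure_b, pure_a, name_b, name_a)
  structure(
    list(
      pure_a = pure_a, pure_b = pure_b,
      indicators_a = indicators_a, indicators_b = indicators_b,
      name_a = name_a, name_b = name_b
    ),
    class = "blend_model"
  )
}

#' Linearly mix two oil profiles
#'
#' content_i = f * a_i + (1 - f) * b_i over the union TG namespace, with Nd
#' treated as 0 in the arithmetic. A resulting zero that traces back to an
#' Nd entry stays Nd.
#'
#' @param f Mass fraction of oil `a`, in `[0, 1]`.
#' @param a,b [oil_profile()]s.
#' @return Mixed `oil_profile`.
#' @export
mix_profiles <- function(f, a, b) {
  if (f < 0 || f > 1) stop("mixing fraction must lie in [0, 1]")
  tgs <- union(a$tg, b$tg)
  va <- content0(a, tgs)
  vb <- content0(b, tgs)
  v <- f * va + (1 - f) * vb
  nd_a <- is.na(a$mg_per_g[match(tgs, a$tg)]) | !(tgs %in% a$tg)
  nd_b <- is.na(b$mg_per_g[match(tgs, b$tg)]) | !(tgs %in% b$tg)
  v[v == 0 & (nd_a | nd_b)] <- NA_real_
  oil_profile(tgs, v)
}

#' Default indicator detection floors from an LOD table
#'
#' Converts per-TG LODs (ug/mL in the injected solution) to the equivalent
#' oil content through the sample prep (default 30 mg oil in 10 mL solvent:
#' 1 mg/g of oil = 3 ug/mL in the vial). TGs without a tabulated LOD fall
#' back to the largest LOD in the table.
#'
#' @param lod Data frame `tg`, `lod_ug_ml`.
#' @param tgs TG names to produce floors for.
#' @param sample_mass_mg,dilution_ml Sample prep constants.
#' @return Named numeric vector of floors, mg/g.
#' @export
indicator_floors <- function(lod, tgs, sample_mass_mg = 30, dilution_ml = 10) {
  l <- lod$lod_ug_ml[match(tgs, lod$tg)]
  l[is.na(l)] <- max(lod$lod_ug_ml)
  stats::setNames(l * dilution_ml / sample_mass_mg, tgs)
}

#' Flag adulteration from indicator TGs
#'
#' A direction is flagged when any of its indicator TGs is quantified at or
#' above its detection floor.
#'
#' @param query Quantified [oil_profile()] of the sample.
#' @param model A [blend_model()].
#' @param floors Named numeric vector of per-TG floors (mg/g), e.g. from
#'   [indicator_floors()]. Defaults to 0 (any quantified amount flags).
#' @return List with per-direction elements `a_in_b` and `b_in_a`, each
#'   containing `flagged` and a tibble of indicator contents and percents.
#' @export
detect_indicators <- function(query, model, floors = NULL) {
  tot <- total_mg_g(query)
  one <- function(ind) {
    fl <- if (is.null(floors)) stats::setNames(rep(0, length(ind)), ind) else floors[ind]
    fl[is.na(fl)] <- 0
    q <- content0(query, ind)
    tab <- tibble::tibble(
      tg = ind, mg_per_g = q, floor = unname(fl),
      percent = if (tot > 0) 100 * q / tot else NA_real_,
      detected = q >= unname(fl) & q > 0
    )
    list(flagged = any(tab$detected), indicators = tab)
  }
  list(
    a_in_b = one(model$indicators_a),
    b_in_a = one(model$indicators_b)
  )
}

#' Estimate the blend fraction
#'
#' Inverts the linear mixing model. Per indicator, f_i = query_i / pure_i
#' (content in the adulterant oil). The combined estimate is a weighted
#' least-squares fit of query = f * adulterant + (1 - f) * base over every
#' TG quantified in either pure oil, constrained to `[0, 1]`. Weights are
#' inverse squared absolute uncertainties, with each TG's reported RSD
#' setting the relative scale (median RSD for TGs without one).
#'
#' @param query Quantified [oil_profile()].
#' @param model A [blend_model()].
#' @param direction `"a_in_b"` (default: oil a is the adulterant) or
#'   `"b_in_a"`.
#' @param rsd Optional data frame `tg`, `rsd_pct` for weighting.
#' @param floors Detection floors as in [detect_indicators()].
#' @return List `f_hat`, `status` (`"detected"`/`"not_detected"`),
#'   `per_indicator` tibble, `direction`.
#' @export
estimate_blend_fraction <- function(query, model,
                                    direction = c("a_in_b", "b_in_a"),
                                    rsd = NULL, floors = NULL) {
  direction <- match.arg(direction)
  adding <- if (direction == "a_in_b") model$pure_a else model$pure_b
  base <- if (direction == "a_in_b") model$pure_b else model$pure_a
  ind <- if (direction == "a_in_b") model$indicators_a else model$indicators_b

  det <- detect_indicators(query, model, floors)[[direction]]
  per_ind <- tibble::tibble(
    tg = ind,
    f_hat = content0(query, ind) / content0(adding, ind)
  )
  if (!det$flagged) {
    return(list(
      f_hat = 0, status = "not_detected",
      per_indicator = per_ind, direction = direction
    ))
  }

  tgs <- union(adding$tg[!is.na(adding$mg_per_g)], base$tg[!is.na(base$mg_per_g)])
  va <- content0(adding, tgs)
  vb <- content0(base, tgs)
  q <- content0(query, tgs)
  d <- va - vb
  rel <- if (is.null(rsd)) rep(1, length(tgs)) else {
    r <- rsd$rsd_pct[match(tgs, rsd$tg)] / 100
    r[is.na(r)] <- stats::median(rsd$rsd_pct) / 100
    r
  }
  w <- 1 / (rel * pmax(q, 1))^2
  keep <- d != 0
  f_hat <- sum(w[keep] * d[keep] * (q[keep] - vb[keep])) / sum(w[keep] * d[keep]^2)
  list(
    f_hat = min(max(f_hat, 0), 1), status = "detected",
    per_indicator = per_ind, direction = direction
  )
}

#' Theoretical versus experimental blend composition
#'
#' For a declared blend fraction, compares the composition expected from
#' linear mixing of the pure profiles with the measured one.
#'
#' @param query Measured [oil_profile()] of the blend.
#' @param f Declared adulterant fraction in `[0, 1]`.
#' @param model A [blend_model()].
#' @param direction As in [estimate_blend_fraction()].
#' @return Tibble per TG: `theoretical`, `experimental`, `diff`
#'   (experimental - theoretical), `pct_of_total` (diff as percent of total
#'   theoretical TG), `rel_pct` (percent of the theoretical content, NA when
#'   theoretical is Nd).
#' @export
theoretical_vs_experimental <- function(query, f, model,
                                        direction = c("a_in_b", "b_in_a")) {
  direction <- match.arg(direction)
  if (f < 0 || f > 1) stop("declared fraction must lie in [0, 1]")
  adding <- if (direction == "a_in_b") model$pure_a else model$pure_b
  base <- if (direction == "a_in_b") model$pure_b else model$pure_a
  th <- mix_profiles(f, adding, base)
  tgs <- union(th$tg, query$tg)
  v_th <- content0(th, tgs)
  v_ex <- content0(query, tgs)
  tibble::tibble(
    tg = tgs,
    theoretical = v_th,
    experimental = v_ex,
    diff = v_ex - v_th,
    pct_of_total = 100 * (v_ex - v_th) / sum(v_th),
    rel_pct = ifelse(v_th > 0, 100 * abs(v_ex - v_th) / v_th, NA_real_)
  )
}
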