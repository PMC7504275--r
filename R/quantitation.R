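#' Construct an oil TG profile
#'
#' An oil profile maps TG names to contents in mg per g oil. `NA` encodes
#' "Nd" (not detected: below the method's detection capability), which is a
#' distinct state from zero and is preserved through I/O and reporting.
#'
#' @param tg Character vector of TG names.
#' @param mg_per_g Numeric contents, `NA` = Nd.
#' @return Tibble of class `oil_profile` with columns `tg`, `mg_per_g`.
#' @export
oil_profile <- function(tg, mg_per_g) {
  if (anyDuplicated(tg)) stop("duplicate TG names in profile")
  if (any(mg_per_g < 0, na.rm = TRUE)) stop("contents must be non-negative")
  out <- tibble::tibble(tg = as.character(tg), mg_per_g = as.numeric(mg_per_g))
  class(out) <- c("oil_profile", class(out))
  out
}

#' Total quantified TG content of a profile
#'
#' Sum of non-Nd contents, mg/g. This is the denominator used for
#' composition percentages (percent of total quantified TG, not of oil
#' mass).
#'
#' @param profile An `oil_profile`.
#' @return Numeric total, mg/g.
#' @export
total_mg_g <- function(profile) sum(profile$mg_per_g, na.rm = TRUE)

#' Round half away from zero
#'
#' Reporting rounding at printed precision (46.5 -> 47), as opposed to
#' base R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Relative response factor against the internal standard
#'
#' rrf = (area_std / conc_std) / (area_is / conc_is): the detector response
#' per unit concentration of a TG relative to NNN. A compound responding
#' more strongly than NNN has rrf > 1, and its raw area is divided by rrf
#' during quantitation.
#'
#' @param area_std,conc_std Standard peak area (counts) and concentration
#'   (mg/mL).
#' @param area_is,conc_is Internal-standard area and concentration.
#' @return Dimensionless rrf.
#' @export
compute_rrf <- function(area_std, conc_std, area_is, conc_is) {
  vals <- c(area_std, conc_std, area_is, conc_is)
  if (any(vals <= 0)) stop("all areas and concentrations must be positive")
  (area_std / conc_std) / (area_is / conc_is)
}

#' Fit a calibration curve
#'
#' Ordinary least-squares line of area versus concentration, with r^2 and a
#' nonlinearity flag.
#'
#' @param points Data frame with columns `conc` (mg/mL) and `area`.
#' @param tg_name Optional TG name recorded in the result.
#' @param r2_floor Flag the curve when r^2 falls below this (default 0.99).
#' @return List of class `calibration_curve`: `tg`, `slope`, `intercept`,
#'   `r_squared`, `range`, `flagged`.
#' @export
fit_calibration <- function(points, tg_name = NA_character_, r2_floor = 0.99) {
  points <- as.data.frame(points)
  stopifnot(all(c("conc", "area") %in% names(points)))
  if (length(unique(points$conc)) < 3) {
    stop("calibration underdetermined: need at least 3 distinct concentrations")
  }
  fit <- stats::lm(area ~ conc, data = points)
  sst <- sum((points$area - mean(points$area))^2)
  # zero-variance response carries no linear signal: define r2 = 0
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(
    list(
      tg = tg_name,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r_squared = r2,
      range = range(points$conc),
      flagged = r2 < r2_floor
    ),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration %s: area = %.3g + %.3g * conc, r2 = %.4f%s>\n",
    ifelse(is.na(x$tg), "curve", x$tg), x$intercept, x$slope, x$r_squared,
    if (x$flagged) " [FLAGGED nonlinear]" else ""
  ))
  invisible(x)
}

#' Internal-standard quantitation of identified peaks
#'
#' content_i (mg/g) = area_i / (rrf_i * area_IS) * is_mass / sample_mass *
#' 1000. Peaks whose implied in-vial concentration falls below the TG's LOD
#' are reported Nd rather than as a number.
#'
#' @param ident Identified (and assigned) peak table from
#'   [identify_peaks()]/[assign_identities()].
#' @param rrf Data frame with columns `tg`, `rrf`.
#' @param is_mass_mg Internal-standard mass added, mg (method default 3).
#' @param sample_mass_mg Oil mass, mg (method default 30).
#' @param lod Optional data frame `tg`, `lod_ug_ml` for Nd marking.
#' @param dilution_ml Sample dilution volume, mL (method default 10).
#' @param rrf_default Response factor for TGs missing from `rrf`.
#' @return An [oil_profile()] over the identified TGs.
#' @export
quantify <- function(ident, rrf, is_mass_mg = 3, sample_mass_mg = 30,
                     lod = NULL, dilution_ml = 10, rrf_default = 1) {
  stopifnot(inherits(ident, "tg_ident"))
  a_is <- attr(ident, "is_area")
  if (is.null(a_is) || length(a_is) != 1 || a_is <= 0) {
    stop("no internal-standard peak: cannot quantify")
  }
  hit <- ident[!is.na(ident$label), ]
  if (anyDuplicated(hit$label)) stop("duplicate identity after assignment; resolve first")
  r <- rrf$rrf[match(hit$label, rrf$tg)]
  if (anyNA(r) && is.null(rrf_default)) {
    stop("missing RRF for: ", paste(hit$label[is.na(r)], collapse = ", "))
  }
  r[is.na(r)] <- rrf_default
  content <- hit$area / (r * a_is) * is_mass_mg / sample_mass_mg * 1000
  if (!is.null(lod)) {
    conc_ug_ml <- content * sample_mass_mg / dilution_ml / 1000 * 1000
    l <- lod$lod_ug_ml[match(hit$label, lod$tg)]
    content[!is.na(l) & conc_ug_ml < l] <- NA_real_
  }
  oil_profile(hit$label, content)
}

#' TG composition as percent of total quantified TG
#'
#' @param profile An `oil_profile` with at least one non-Nd entry.
#' @return Tibble `tg`, `percent` (exact, summing to 100); apply
#'   [round_half_up()] for report precision.
#' @export
composition_percent <- function(profile) {
  tot <- total_mg_g(profile)
  if (tot <= 0) stop("empty profile: no quantified TG to take percentages of")
  keep <- !is.na(profile$mg_per_g)
  tibble::tibble(
    tg = profile$tg[keep],
    percent = 100 * profile$mg_per_g[keep] / tot
  )
}

#' Composition grouped by equivalent carbon number
#'
#' @param profile An `oil_profile`; TG names must be parseable.
#' @param registry Fatty-acid registry.
#' @return Tibble `ecn`, `percent`, descending percent.
#' @export
ecn_group_composition <- function(profile, registry = default_fa_registry()) {
  pc <- composition_percent(profile)
  e <- vapply(pc$tg, function(nm) ecn(nm, registry), integer(1))
  agg <- stats::aggregate(pc$percent, list(ecn = e), sum)
  names(agg)[2] <- "percent"
  tibble::as_tibble(agg[order(-agg$percent), ])
}
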