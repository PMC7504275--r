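#' Spike recovery
#'
#' recovery (%) = detected / spiked * 100. Values outside 70-130% are
#' flagged (attribute `flagged`), not rejected: FID response to TGs varies
#' widely and measured recoveries span 21-148%.
#'
#' @param detected,spiked Amounts in the same unit; `spiked > 0`.
#' @return Percent recovery with logical attribute `flagged`.
#' @export
recovery <- function(detected, spiked) {
  if (any(spiked <= 0)) stop("spiked amount must be positive")
  r <- 100 * detected / spiked
  attr(r, "flagged") <- r < 70 | r > 130
  r
}

#' Relative standard deviation
#'
#' RSD (%) = sd / mean * 100, with the sample (n-1) standard deviation.
#'
#' @param values At least two measurements with non-zero mean.
#' @return Percent RSD.
#' @export
rsd <- function(values) {
  if (length(values) < 2) stop("RSD needs at least 2 values")
  m <- mean(values)
  if (m == 0) stop("RSD undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Intraday / interday precision
#'
#' Intraday precision is the mean of within-day RSDs; interday precision is
#' the RSD of the day means. Computed per TG on either retention time or
#' area.
#'
#' @param reps Data frame with columns `tg`, `day`, and the measured
#'   quantity columns (`rt`, `area`, ...).
#' @param grouping `"intraday"` or `"interday"`.
#' @param quantity Name of the measured column, `"rt"` or `"area"`.
#' @return Tibble `tg`, `precision_pct`.
#' @export
precision <- function(reps, grouping = c("intraday", "interday"),
                      quantity = c("rt", "area")) {
  grouping <- match.arg(grouping)
  quantity <- match.arg(quantity)
  reps <- as.data.frame(reps)
  stopifnot(all(c("tg", "day", quantity) %in% names(reps)))
  one_tg <- function(d) {
    if (grouping == "intraday") {
      mean(tapply(d[[quantity]], d$day, rsd))
    } else {
      day_means <- tapply(d[[quantity]], d$day, mean)
      rsd(as.numeric(day_means))
    }
  }
  out <- vapply(split(reps, reps$tg), one_tg, numeric(1))
  tibble::tibble(tg = names(out), precision_pct = unname(out))
}

#' Limits of detection and quantitation
#'
#' LOD is estimated as the blank-to-signal ratio at the lowest calibration
#' concentration: lod = low_conc * blank_signal / low_conc_signal. LOQ is
#' defined as 3 x LOD.
#'
#' @param blank_signal Blank signal, counts (> 0).
#' @param low_conc_signal Signal at the lowest concentration (> blank).
#' @param low_conc Lowest concentration, ug/mL.
#' @return List `lod`, `loq` in ug/mL.
#' @export
lod_loq <- function(blank_signal, low_conc_signal, low_conc) {
  if (blank_signal <= 0) stop("blank signal must be positive")
  if (low_conc_signal <= blank_signal) {
    stop("not detectable: low-concentration signal does not exceed blank")
  }
  lod <- low_conc * blank_signal / low_conc_signal
  list(lod = lod, loq = 3 * lod)
}

#' Assemble a per-TG validation report
#'
#' Merges recovery, precision, repeatability and LOD/LOQ columns into one
#' table mirroring the usual method-validation layout.
#'
#' @param tg Character vector of TG names.
#' @param ... Named numeric vectors (same length as `tg`) to include, e.g.
#'   `recovery_pct`, `lod_ug_ml`, `loq_ug_ml`, `precision_pct`, `rsd_pct`.
#' @return Tibble with `tg` plus the supplied columns.
#' @export
validation_report <- function(tg, ...) {
  cols <- list(...)
  stopifnot(all(vapply(cols, length, integer(1)) == length(tg)))
  tibble::as_tibble(c(list(tg = tg), cols))
}

#' Write a validation report as delimited text
#'
#' @param report Tibble from [validation_report()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
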