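#' Read a peak table from delimited text
#'
#' Expects a comma-separated file with a header row and columns `rt_min`,
#' `area`, `role` (`solvent|is|analyte`). Malformed rows are reported with
#' their line numbers.
#'
#' @param path CSV file.
#' @return A [peak_table()].
#' @export
read_peak_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("rt_min", "area", "role")
  if (!all(need %in% names(raw))) {
    stop(sprintf(
      "%s: missing required column(s): %s",
      path, paste(setdiff(need, names(raw)), collapse = ", ")
    ))
  }
  rt <- suppressWarnings(as.numeric(raw$rt_min))
  area <- suppressWarnings(as.numeric(raw$area))
  bad <- which(is.na(rt) | is.na(area) | !raw$role %in% c("solvent", "is", "analyte"))
  if (length(bad)) {
    stop(sprintf(
      "%s: malformed row(s) at line(s) %s",
      path, paste(bad + 1L, collapse = ", ") # +1 for the header line
    ))
  }
  peak_table(tibble::tibble(rt_min = rt, area = area, role = raw$role))
}

#' Write a peak table as delimited text
#'
#' @param table A [peak_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(table, path) {
  utils::write.csv(
    as.data.frame(table)[, c("rt_min", "area", "role")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Read an oil profile from delimited text
#'
#' Columns `tg`, `mg_per_g`; the token `"Nd"` (any case) marks
#' not-detected and is read as the Nd state, never as 0.
#'
#' @param path CSV file.
#' @return An [oil_profile()].
#' @export
read_profile <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("tg", "mg_per_g") %in% names(raw))) {
    stop(path, ": profile file needs columns tg, mg_per_g")
  }
  if (anyDuplicated(raw$tg)) {
    stop(path, ": duplicate TG names: ",
      paste(unique(raw$tg[duplicated(raw$tg)]), collapse = ", "))
  }
  is_nd <- tolower(trimws(raw$mg_per_g)) == "nd"
  v <- suppressWarnings(as.numeric(raw$mg_per_g))
  bad <- which(is.na(v) & !is_nd)
  if (length(bad)) {
    stop(sprintf("%s: malformed content at line(s) %s", path,
      paste(bad + 1L, collapse = ", ")))
  }
  v[is_nd] <- NA_real_
  oil_profile(raw$tg, v)
}

#' Write an oil profile as delimited text
#'
#' Nd entries are written as the token `"Nd"`.
#'
#' @param profile An [oil_profile()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  out <- data.frame(
    tg = profile$tg,
    mg_per_g = ifelse(is.na(profile$mg_per_g), "Nd",
      format(profile$mg_per_g, trim = TRUE, scientific = FALSE)
    )
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a relative-response-factor table
#'
#' @param path CSV file with columns `tg`, `rrf`.
#' @return Tibble `tg`, `rrf`.
#' @export
read_rrf_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("tg", "rrf") %in% names(raw))) {
    stop(path, ": RRF file needs columns tg, rrf")
  }
  if (any(raw$rrf <= 0)) stop(path, ": RRF values must be positive")
  tibble::as_tibble(raw)
}

#' Packaged TG-standard table
#'
#' The 17 TG retention/validation standards shipped with the package:
#' descriptors (CN, DB, ECN), relative retention time, relative response
#' factor, recovery, LOD/LOQ and precision columns.
#'
#' @return Tibble, one row per standard.
#' @export
tg_standards <- function() {
  tibble::as_tibble(utils::read.csv(
    system.file("extdata", "tg_standards.csv", package = "tgquant"),
    stringsAsFactors = FALSE
  ))
}

#' Packaged oil composition table
#'
#' TG contents (mg/g, with Nd) of refined rapeseed oil (`RRO`), olive oil
#' (`OO`) and their blends at 1, 2.5, 5 and 10% in both directions
#' (`OO_in_RRO_*`, `RRO_in_OO_*`).
#'
#' @return Long tibble `tg`, `sample`, `mg_per_g` (NA = Nd), `sd`.
#' @export
oil_profiles_table <- function() {
  raw <- utils::read.csv(
    system.file("extdata", "oil_profiles.csv", package = "tgquant"),
    stringsAsFactors = FALSE, colClasses = c(mg_per_g = "character")
  )
  is_nd <- tolower(trimws(raw$mg_per_g)) == "nd"
  raw$mg_per_g <- suppressWarnings(as.numeric(raw$mg_per_g))
  raw$mg_per_g[is_nd] <- NA_real_
  tibble::as_tibble(raw)
}

#' One packaged oil profile
#'
#' @param sample Sample name in [oil_profiles_table()], e.g. `"RRO"`,
#'   `"OO"`, `"OO_in_RRO_2.5"`.
#' @return An [oil_profile()].
#' @export
oil_profile_fixture <- function(sample) {
  tab <- oil_profiles_table()
  tab <- tab[tab$sample == sample, ]
  if (nrow(tab) == 0) {
    stop("unknown sample '", sample, "'; see oil_profiles_table()$sample")
  }
  oil_profile(tab$tg, tab$mg_per_g)
}

#' Identify, assign and quantify a peak table in one call
#'
#' Convenience wrapper chaining [identify_peaks()], [assign_identities()]
#' and [quantify()].
#'
#' @param table A [peak_table()].
#' @param cfg A [sim_config()] supplying model, RRF, LOD and prep constants
#'   (the same config whether the table is synthetic or read from disk).
#' @param candidates Candidate TG names (default: the union of the config's
#'   pure-profile namespaces).
#' @return An [oil_profile()].
#' @export
analyze_peak_table <- function(table, cfg,
                               candidates = union(
                                 cfg$profiles[[1]]$tg, cfg$profiles[[2]]$tg
                               )) {
  ident <- identify_peaks(table, cfg$model, candidates)
  ident <- assign_identities(ident)
  quantify(
    ident, cfg$rrf,
    is_mass_mg = cfg$is_mass_mg, sample_mass_mg = cfg$sample_mass_mg,
    lod = cfg$lod, dilution_ml = cfg$dilution_ml
  )
}
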