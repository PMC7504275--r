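#' Relative retention time
#'
#' rrt = (rt_analyte - rt_solvent) / (rt_IS - rt_solvent). Dimensionless and
#' invariant under affine rescaling of the time axis, which is why peak
#' matching is done on rrt rather than absolute retention time.
#'
#' @param rt_analyte Analyte retention time(s), minutes. Vectorized.
#' @param rt_solvent Solvent-front retention time, minutes.
#' @param rt_is Internal-standard (NNN) retention time, minutes.
#' @return Numeric rrt value(s).
#' @export
relative_retention_time <- function(rt_analyte, rt_solvent, rt_is) {
  if (rt_is <= rt_solvent) {
    stop("degenerate reference: rt_is must exceed rt_solvent")
  }
  if (any(rt_analyte < rt_solvent)) {
    stop("analyte retention time precedes the solvent front")
  }
  (rt_analyte - rt_solvent) / (rt_is - rt_solvent)
}

#' Construct a peak table
#'
#' A peak table is the integrated output of one GC-FID run: retention time
#' and area per peak, with exactly one row flagged `solvent` (front) and one
#' flagged `is` (internal standard NNN); all other rows are analytes.
#'
#' @param df Data frame with columns `rt_min`, `area`, `role`
#'   (`"solvent"|"is"|"analyte"`).
#' @return Tibble of class `peak_table`, sorted by retention time.
#' @export
peak_table <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("rt_min", "area", "role")
  if (!all(need %in% names(df))) {
    stop("peak table must have columns: ", paste(need, collapse = ", "))
  }
  if (sum(df$role == "solvent") != 1) stop("peak table needs exactly one solvent row")
  if (sum(df$role == "is") != 1) stop("peak table needs exactly one internal-standard (is) row")
  if (any(df$rt_min <= 0)) stop("retention times must be positive")
  if (any(df$area < 0)) stop("areas must be non-negative")
  if (df$rt_min[df$role == "solvent"] >= df$rt_min[df$role == "is"]) {
    stop("solvent front must elute before the internal standard")
  }
  df <- df[order(df$rt_min), ]
  class(df) <- c("peak_table", class(df))
  df
}

solvent_rt <- function(pt) pt$rt_min[pt$role == "solvent"]
is_rt <- function(pt) pt$rt_min[pt$role == "is"]
is_area <- function(pt) pt$area[pt$role == "is"]

log_interp <- function(x0, y0, x1, y1, x) y0 + (x - x0) / (x1 - x0) * (y1 - y0)

#' Fit the log(rrt)-versus-DB identification chart
#'
#' Builds the interpolation chart used to identify TGs from relative
#' retention times. Saturated and monoacid standards define anchor points
#' (DB of the monoacid TG, log rrt); anchors of different acyls are joined
#' by straight lines in (DB, log rrt) space; mixed-acid TGs then sit on (two
#' acyls) or between (three acyls) those lines. An acyl with no monoacid
#' standard (here Ln, since trilinolenin is not among the standards) gets a
#' virtual anchor inferred by inverting the two-acyl interpolation through a
#' mixed standard that contains it (OOLn on the O/Ln line).
#'
#' @param standards Data frame with columns `tg` (name) and `rrt` (observed).
#'   Positional isomers are collapsed onto the first-listed name.
#' @param registry Fatty-acid registry.
#' @param tolerance Matching half-width on the log(rrt) scale. The default,
#'   0.0105, corresponds to about 0.01 rrt units in the TG elution region —
#'   the rounding grid of a 2-decimal rrt report.
#' @return Object of class `retention_model` with anchors, the de-rounded
#'   standard reference table, and the tolerance.
#' @export
fit_identification_plot <- function(standards,
                                    registry = default_fa_registry(),
                                    tolerance = 0.0105) {
  standards <- tibble::as_tibble(standards)
  stopifnot(all(c("tg", "rrt") %in% names(standards)), all(standards$rrt > 0))
  desc <- tg_describe(standards$tg, registry)
  desc$rrt <- standards$rrt

  # collapse positional isomers: same acyl multiset, one chart point
  desc <- desc[!duplicated(desc$multiset), ]

  mono <- desc[desc$n_acyls_distinct == 1, ]
  anchors <- tibble::tibble(
    acyl = substr(mono$multiset, 1, nchar(mono$multiset)), # placeholder, fixed below
    db = mono$db, cn = mono$cn, log_rrt = log(mono$rrt), virtual = FALSE
  )
  anchors$acyl <- vapply(mono$tg, function(nm) {
    unique(parse_tg_name(nm, registry)$acyls)
  }, character(1))

  # virtual anchors from two-acyl standards whose partner acyl is anchored
  for (a in setdiff(registry$code, anchors$acyl)) {
    cand <- desc[desc$n_acyls_distinct == 2, ]
    ests <- numeric(0)
    for (i in seq_len(nrow(cand))) {
      p <- parse_tg_name(cand$tg[i], registry)
      if (!a %in% p$acyls) next
      b <- setdiff(unique(p$acyls), a)
      j <- match(b, anchors$acyl)
      if (is.na(j)) next
      db_a3 <- 3 * registry$double_bonds[match(a, registry$code)]
      db_b3 <- anchors$db[j]
      if (p$db == db_b3 || db_a3 == db_b3) next
      ests <- c(ests, anchors$log_rrt[j] +
        (log(cand$rrt[i]) - anchors$log_rrt[j]) * (db_a3 - db_b3) / (p$db - db_b3))
    }
    if (length(ests) > 0) {
      anchors <- rbind(anchors, tibble::tibble(
        acyl = a,
        db = 3 * registry$double_bonds[match(a, registry$code)],
        cn = 3 * registry$acyl_carbons[match(a, registry$code)],
        log_rrt = mean(ests), virtual = TRUE
      ))
    }
  }
  if (nrow(anchors) < 2) stop("model underdetermined: fewer than two usable anchors")

  model <- structure(
    list(anchors = anchors, registry = registry, tolerance = tolerance),
    class = "retention_model"
  )
  model$refs <- deround_standard_refs(model, desc)
  model
}

#' @export
print.retention_model <- function(x, ...) {
  cat(sprintf(
    "<retention_model: %d anchors (%d virtual), %d standard references, tol=%.4f log-rrt>\n",
    nrow(x$anchors), sum(x$anchors$virtual), nrow(x$refs), x$tolerance
  ))
  invisible(x)
}

# Reference rrt per standard, de-rounding printed collisions: standards with
# distinct acyl multisets but identical printed rrt (a 2-decimal rounding
# artifact -- the column does resolve them, or they could not be quantified
# separately) are spread deterministically within the rounding band, ordered
# by model-predicted rrt, 0.004 apart around the printed value.
deround_standard_refs <- function(model, desc) {
  pred <- vapply(desc$tg, function(nm) {
    tryCatch(predict_rrt(model, nm), error = function(e) NA_real_)
  }, numeric(1))
  refs <- tibble::tibble(
    tg = desc$tg, multiset = desc$multiset,
    n_acyls_distinct = desc$n_acyls_distinct,
    rrt_printed = desc$rrt, predicted = pred, rrt_ref = desc$rrt
  )
  for (v in unique(refs$rrt_printed)) {
    idx <- which(refs$rrt_printed == v)
    if (length(idx) < 2) next
    ord <- idx[order(refs$predicted[idx], refs$tg[idx])]
    k <- length(ord)
    refs$rrt_ref[ord] <- v + (seq_len(k) - (k + 1) / 2) * 0.004
  }
  refs
}

#' Predict the rrt of a TG from the identification chart
#'
#' Monoacid TGs return their own anchor. Two-acyl TGs are linearly
#' interpolated in DB on the log(rrt) scale along the line joining their two
#' monoacid anchors. Three-acyl TGs take the mean (log scale) of the
#' pairwise-line interpolations whose DB span covers the TG's DB. Saturated
#' mixed TGs (all anchors at DB = 0, e.g. PPS) are interpolated in carbon
#' number along the DB = 0 axis instead.
#'
#' @param model A `retention_model`.
#' @param tg TG name or `tg` object.
#' @return Predicted rrt.
#' @export
predict_rrt <- function(model, tg) {
  if (is.character(tg)) tg <- parse_tg_name(tg, model$registry)
  u <- unique(tg$acyls)
  j <- match(u, model$anchors$acyl)
  if (anyNA(j)) {
    stop(sprintf(
      "cannot predict rrt of %s: no anchor for acyl %s",
      tg$name, paste(u[is.na(j)], collapse = ", ")
    ))
  }
  an <- model$anchors[j, ]
  if (length(u) == 1) {
    return(exp(an$log_rrt))
  }
  pairs <- utils::combn(seq_len(nrow(an)), 2)
  vals <- numeric(0)
  for (k in seq_len(ncol(pairs))) {
    i1 <- pairs[1, k]; i2 <- pairs[2, k]
    if (an$db[i1] == an$db[i2]) next
    lo <- min(an$db[i1], an$db[i2]); hi <- max(an$db[i1], an$db[i2])
    if (tg$db < lo || tg$db > hi) next
    vals <- c(vals, log_interp(an$db[i1], an$log_rrt[i1], an$db[i2], an$log_rrt[i2], tg$db))
  }
  if (length(vals) == 0 && tg$db == 0 && all(an$db == 0)) {
    for (k in seq_len(ncol(pairs))) {
      i1 <- pairs[1, k]; i2 <- pairs[2, k]
      if (an$cn[i1] == an$cn[i2]) next
      lo <- min(an$cn[i1], an$cn[i2]); hi <- max(an$cn[i1], an$cn[i2])
      if (tg$cn < lo || tg$cn > hi) next
      vals <- c(vals, log_interp(an$cn[i1], an$log_rrt[i1], an$cn[i2], an$log_rrt[i2], tg$cn))
    }
  }
  if (length(vals) == 0) {
    stop(sprintf("cannot predict rrt of %s: no usable line covers DB=%d", tg$name, tg$db))
  }
  exp(mean(vals))
}

#' Reference rrt values for candidate TGs
#'
#' For a candidate whose acyl multiset matches a fitted standard, the
#' (de-rounded) observed standard rrt is used; otherwise the chart
#' prediction. Candidates that are positional isomers of each other collapse
#' onto the first-listed name.
#'
#' @param model A `retention_model`.
#' @param candidates Character vector of TG names.
#' @return Tibble with `tg`, `multiset`, `rrt_ref`, `source`
#'   (`"standard"|"predicted"`), `n_acyls_distinct`.
#' @export
reference_rrt <- function(model, candidates) {
  desc <- tg_describe(candidates, model$registry)
  desc <- desc[!duplicated(desc$multiset), ]
  m <- match(desc$multiset, model$refs$multiset)
  rrt_ref <- ifelse(!is.na(m), model$refs$rrt_ref[m], NA_real_)
  src <- ifelse(!is.na(m), "standard", "predicted")
  for (i in which(is.na(rrt_ref))) {
    rrt_ref[i] <- predict_rrt(model, desc$tg[i])
  }
  tibble::tibble(
    tg = desc$tg, multiset = desc$multiset, rrt_ref = rrt_ref,
    source = src, n_acyls_distinct = desc$n_acyls_distinct
  )
}

#' Identify peaks against candidate TGs
#'
#' Each analyte peak is matched against every candidate whose reference
#' log(rrt) lies within the model tolerance (widened 1.5x for three-acyl
#' candidates predicted without a standard reference, which sit less
#' precisely "between the lines"). Matches are ranked by |log rrt
#' difference|; the top match is proposed as `label`, `NA` meaning unknown.
#' Ambiguous peaks keep their full ranked candidate set.
#'
#' @param table A `peak_table`.
#' @param model A `retention_model`.
#' @param candidates Character vector of candidate TG names.
#' @param area_floor Peaks with area below this are dropped before
#'   identification (solvent-tail artifacts).
#' @return Tibble of class `tg_ident` with one row per analyte peak:
#'   `rt_min`, `area`, `rrt`, `label`, `n_matches`, `matches` (list column of
#'   ranked tibbles). Attributes `is_area`, `solvent_rt`, `is_rt` carry the
#'   run references for downstream quantitation.
#' @export
identify_peaks <- function(table, model, candidates, area_floor = 0) {
  stopifnot(inherits(table, "peak_table"))
  refs <- reference_rrt(model, candidates)
  an <- table[table$role == "analyte" & table$area >= area_floor, ]
  rrt <- if (nrow(an)) {
    relative_retention_time(an$rt_min, solvent_rt(table), is_rt(table))
  } else numeric(0)
  tol <- model$tolerance *
    ifelse(refs$n_acyls_distinct == 3 & refs$source == "predicted", 1.5, 1)

  matches <- vector("list", nrow(an))
  label <- rep(NA_character_, nrow(an))
  for (i in seq_len(nrow(an))) {
    d <- abs(log(rrt[i]) - log(refs$rrt_ref))
    hit <- which(d <= tol)
    m <- refs[hit, c("tg", "rrt_ref")]
    m$dist <- d[hit]
    m <- m[order(m$dist, m$tg), ]
    matches[[i]] <- m
    if (nrow(m)) label[i] <- m$tg[1]
  }
  out <- tibble::tibble(
    rt_min = an$rt_min, area = an$area, rrt = rrt,
    label = label,
    n_matches = vapply(matches, nrow, integer(1)),
    matches = matches
  )
  attr(out, "is_area") <- is_area(table)
  attr(out, "solvent_rt") <- solvent_rt(table)
  attr(out, "is_rt") <- is_rt(table)
  class(out) <- c("tg_ident", class(out))
  out
}

#' Resolve ranked identifications to unique labels
#'
#' Greedy one-to-one assignment between peaks and candidates in order of
#' increasing |log rrt| distance: once a candidate is taken by a closer peak
#' it is unavailable to others. Resolves, e.g., adjacent OOP/PSO peaks that
#' each list both candidates.
#'
#' @param ident Output of [identify_peaks()].
#' @return The same table with `label` replaced by the assigned identity
#'   (`NA` = unknown).
#' @export
assign_identities <- function(ident) {
  rows <- do.call(rbind, lapply(seq_len(nrow(ident)), function(i) {
    m <- ident$matches[[i]]
    if (nrow(m) == 0) return(NULL)
    data.frame(peak = i, tg = m$tg, dist = m$dist, stringsAsFactors = FALSE)
  }))
  label <- rep(NA_character_, nrow(ident))
  if (!is.null(rows)) {
    rows <- rows[order(rows$dist, rows$tg), ]
    for (r in seq_len(nrow(rows))) {
      i <- rows$peak[r]
      if (!is.na(label[i]) || rows$tg[r] %in% label) next
      label[i] <- rows$tg[r]
    }
  }
  ident$label <- label
  ident
}

#' Dump a retention model to a plain-text key-value file
#'
#' @param model A `retention_model`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_retention_model <- function(model, path) {
  lines <- c(
    sprintf("tolerance: %.6f", model$tolerance),
    sprintf(
      "anchor %s: db=%d cn=%d log_rrt=%.6f virtual=%s",
      model$anchors$acyl, model$anchors$db, model$anchors$cn,
      model$anchors$log_rrt, model$anchors$virtual
    ),
    sprintf(
      "ref %s: rrt_printed=%.4f rrt_ref=%.4f",
      model$refs$tg, model$refs$rrt_printed, model$refs$rrt_ref
    )
  )
  writeLines(lines, path)
  invisible(path)
}
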