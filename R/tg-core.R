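#' Built-in fatty-acid registry
#'
#' The six acyl codes used throughout: P = palmitoyl (16:0), S = stearoyl
#' (18:0), O = oleoyl (18:1), L = linoleoyl (18:2), Ln = linolenoyl (18:3)
#' and N = nonadecanoyl (19:0, the internal-standard acyl). The registry is
#' extensible: bind extra rows (e.g. G = gadoleic 20:1) with [fa_registry()].
#'
#' @return A tibble with columns `code`, `acyl_carbons`, `double_bonds`.
#' @export
default_fa_registry <- function() {
  fa_registry(tibble::tibble(
    code = c("P", "S", "O", "L", "Ln", "N"),
    acyl_carbons = c(16L, 18L, 18L, 18L, 18L, 19L),
    double_bonds = c(0L, 0L, 1L, 2L, 3L, 0L)
  ))
}

#' Validate a fatty-acid registry
#'
#' @param df Data frame with columns `code`, `acyl_carbons`, `double_bonds`.
#' @return The validated registry tibble.
#' @export
fa_registry <- function(df) {
  df <- tibble::as_tibble(df)
  need <- c("code", "acyl_carbons", "double_bonds")
  if (!all(need %in% names(df))) {
    stop("registry must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$code)) stop("duplicate acyl codes in registry")
  if (any(df$acyl_carbons < 2)) stop("acyl_carbons must be >= 2")
  if (any(df$double_bonds < 0)) stop("double_bonds must be >= 0")
  df
}

#' Read a fatty-acid registry from delimited text
#'
#' @param path CSV file with columns `code`, `acyl_carbons`, `double_bonds`.
#' @return Registry tibble.
#' @export
read_fa_registry <- function(path) {
  fa_registry(utils::read.csv(path, stringsAsFactors = FALSE))
}

# Greedy-longest-match tokenizer: at each position try the longest registry
# code first, so "Ln" is one acyl, never "L" + dangling "n".
tokenize_tg_name <- function(name, registry) {
  codes <- registry$code[order(nchar(registry$code), decreasing = TRUE)]
  rest <- name
  out <- character(0)
  while (nzchar(rest)) {
    hit <- codes[startsWith(rest, codes)]
    if (length(hit) == 0) {
      stop(sprintf("cannot parse TG name '%s': unknown residue '%s'", name, rest))
    }
    out <- c(out, hit[[1]])
    rest <- substr(rest, nchar(hit[[1]]) + 1L, nchar(rest))
  }
  out
}

#' Parse a triacylglycerol name
#'
#' Splits a concatenated acyl-code name (e.g. `"OOLn"`) into exactly three
#' acyls and derives the molecular descriptors: carbon number CN (sum of
#' acyl-chain carbons), double-bond number DB, and equivalent carbon number
#' ECN = CN - 2*DB.
#'
#' @param name TG name, a concatenation of three registry codes.
#' @param registry Fatty-acid registry (default [default_fa_registry()]).
#' @return A list of class `tg` with `name`, `acyls` (character, length 3),
#'   `cn`, `db`, `ecn`.
#' @examples
#' parse_tg_name("OOP")  # cn 52, db 2, ecn 48
#' @export
parse_tg_name <- function(name, registry = default_fa_registry()) {
  stopifnot(is.character(name), length(name) == 1)
  acyls <- tokenize_tg_name(name, registry)
  if (length(acyls) != 3) {
    stop(sprintf("TG name '%s' parses to %d acyls, expected 3", name, length(acyls)))
  }
  idx <- match(acyls, registry$code)
  cn <- sum(registry$acyl_carbons[idx])
  db <- sum(registry$double_bonds[idx])
  structure(
    list(name = name, acyls = acyls, cn = cn, db = db, ecn = cn - 2L * db),
    class = "tg"
  )
}

#' @export
print.tg <- function(x, ...) {
  cat(sprintf("<TG %s: CN=%d DB=%d ECN=%d>\n", x$name, x$cn, x$db, x$ecn))
  invisible(x)
}

#' Equivalent carbon number
#'
#' ECN = CN - 2*DB. TGs of equal ECN elute similarly on the column, which is
#' why literature compositions are often grouped by ECN.
#'
#' @param tg A `tg` object from [parse_tg_name()], or a TG name.
#' @param registry Registry used if `tg` is a name.
#' @return Integer ECN.
#' @export
ecn <- function(tg, registry = default_fa_registry()) {
  if (is.character(tg)) tg <- parse_tg_name(tg, registry)
  tg$cn - 2L * tg$db
}

#' Elution-order sort key
#'
#' TGs elute in order of increasing carbon number and, within a carbon
#' number, increasing unsaturation. Positional isomers (same acyl multiset)
#' tie.
#'
#' @param tg A `tg` object or TG name.
#' @param registry Registry used if `tg` is a name.
#' @return Numeric key; sort ascending for elution order.
#' @export
elution_order_key <- function(tg, registry = default_fa_registry()) {
  if (is.character(tg)) tg <- parse_tg_name(tg, registry)
  tg$cn + tg$db / 100
}

# Canonical key for an acyl multiset: sorted acyl codes joined. Positional
# isomers (OOP vs OPO) share a key; the column cannot separate them.
acyl_multiset_key <- function(acyls) paste(sort(acyls), collapse = "|")

#' Describe a vector of TG names
#'
#' Vectorized descriptor table for a set of TG names.
#'
#' @param names Character vector of TG names.
#' @param registry Fatty-acid registry.
#' @return Tibble with columns `tg`, `cn`, `db`, `ecn`, `n_acyls_distinct`,
#'   `multiset` (canonical acyl-multiset key).
#' @export
tg_describe <- function(names, registry = default_fa_registry()) {
  parsed <- lapply(names, parse_tg_name, registry = registry)
  tibble::tibble(
    tg = names,
    cn = vapply(parsed, `[[`, integer(1), "cn"),
    db = vapply(parsed, `[[`, integer(1), "db"),
    ecn = vapply(parsed, `[[`, integer(1), "ecn"),
    n_acyls_distinct = vapply(parsed, function(p) length(unique(p$acyls)), integer(1)),
    multiset = vapply(parsed, function(p) acyl_multiset_key(p$acyls), character(1))
  )
}
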