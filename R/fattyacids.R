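#' Parse shorthand fatty-acid nomenclature
#'
#' Splits names of the form `"C:D n-x [qualifier]"` -- chain length,
#' number of double bonds, optional omega (n-x) designation, optional
#' trailing qualifier kept verbatim (e.g. `"17:0 Phytanic"`).
#'
#' @param name fatty-acid name, e.g. `"16:1 n-7"`, `"22:6 n-3"`, `"16:0"`.
#' @return list: `raw_name`, `chain_length`, `n_double_bonds`, `omega`
#'   (integer or `NA`), `qualifier` (character or `NA`).
#' @examples
#' parse_fa_name("20:5 n-3")
#' @export
parse_fa_name <- function(name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(trimws(name)))
    stop_("fatty-acid name must be a nonempty string")
  txt <- trimws(name)
  m <- regmatches(txt, regexec(
    "^([0-9]+):([0-9]+)(?:[[:space:]]*n-([0-9]+))?(?:[[:space:]]+(\\S.*))?$", txt))[[1L]]
  if (length(m) == 0L)
    stop_("malformed fatty-acid name '%s' (expected 'C:D [n-x] [qualifier]')", name)
  chain <- as.integer(m[2L])
  dbl <- as.integer(m[3L])
  omega <- if (nzchar(m[4L])) as.integer(m[4L]) else NA_integer_
  qual <- if (length(m) >= 5L && nzchar(m[5L])) m[5L] else NA_character_
  if (chain < 4L)
    stop_("implausible chain length %d in '%s' (must be >= 4)", chain, name)
  if (!is.na(omega) && dbl == 0L)
    stop_("omega designation on a saturated acid in '%s'", name)
  if (is.na(omega) && dbl >= 1L)
    stop_("unsaturated acid '%s' lacks its n-x omega designation", name)
  list(raw_name = txt, chain_length = chain, n_double_bonds = dbl,
       omega = omega, qualifier = qual)
}

#' Saturation class of a fatty acid
#'
#' 0 double bonds -> SAFA (branched/phytanic acids included), 1 -> MUFA,
#' `>= 2` -> PUFA.
#'
#' @param fa parsed record from [parse_fa_name()] or a name string.
#' @return `"SAFA"`, `"MUFA"` or `"PUFA"`.
#' @export
classify_fatty_acid <- function(fa) {
  if (is.character(fa)) fa <- parse_fa_name(fa)
  if (fa$n_double_bonds == 0L) "SAFA"
  else if (fa$n_double_bonds == 1L) "MUFA"
  else "PUFA"
}

#' Class sums over a fatty-acid composition profile
#'
#' Sums of percent-of-total-FA by saturation class (SAFA/MUFA/PUFA, a
#' partition) and omega series (n-3/n-6/n-9, drawn only from records with
#' that designation), plus EPA+DHA (20:5 n-3 + 22:6 n-3) and the "big
#' four" dominant diatom acids (14:0 + 16:0 + 16:1 n-7 + 20:5 n-3).
#' Sums are exact; round for display at the conventional 1 decimal.
#'
#' @param fa_names character vector of fatty-acid names (no duplicates).
#' @param percents percent of total FA for each name, `>= 0`.
#' @return named list: `safa`, `mufa`, `pufa`, `omega3`, `omega6`,
#'   `omega9`, `epa_plus_dha`, `big_four`.
#' @export
fa_class_sums <- function(fa_names, percents) {
  stopifnot(length(fa_names) == length(percents), length(fa_names) >= 1L)
  if (anyDuplicated(fa_names))
    stop_("duplicate fatty-acid names: %s",
          paste(unique(fa_names[duplicated(fa_names)]), collapse = ", "))
  if (any(percents < 0, na.rm = TRUE)) stop_("percents must be >= 0")
  percents <- ifelse(is.na(percents), 0, as.numeric(percents))
  parsed <- lapply(fa_names, parse_fa_name)
  cls <- vapply(parsed, classify_fatty_acid, character(1))
  omg <- vapply(parsed, function(p) p$omega, integer(1))
  pick <- function(keep) sum(percents[keep])
  out <- list(
    safa = pick(cls == "SAFA"),
    mufa = pick(cls == "MUFA"),
    pufa = pick(cls == "PUFA"),
    omega3 = pick(!is.na(omg) & omg == 3L),
    omega6 = pick(!is.na(omg) & omg == 6L),
    omega9 = pick(!is.na(omg) & omg == 9L),
    epa_plus_dha = pick(fa_names %in% c("20:5 n-3", "22:6 n-3")),
    big_four = pick(fa_names %in% c("14:0", "16:0", "16:1 n-7", "20:5 n-3")))
  if (out$safa + out$mufa + out$pufa > 100 + 0.5)
    warn_("class sums exceed 100%% beyond rounding slack (%.1f)",
          out$safa + out$mufa + out$pufa)
  out
}

#' Packaged community fatty-acid composition table
#'
#' Per-site percent-of-total-FA values for the displayed acids of the
#' end-of-season community lipid analysis (acids under 0.1% at both
#' sites are not displayed, so displayed-row sums can fall slightly
#' short of independently printed totals; see
#' [fa_printed_sums()] for the printed SUM rows).
#'
#' @param path CSV fixture path.
#' @return data frame: `fa_name`, `outer_pct`, `inner_pct`.
#' @export
fatty_acid_table <- function(path = extdata_path("fatty_acids.csv")) {
  utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
}

#' Printed fatty-acid class totals
#'
#' The class totals as printed in the source table (percent of total FA
#' per site). Where a printed total disagrees with the sum of displayed
#' rows by more than rounding slack, [fa_reconciliation()] reports the
#' difference; the printed value is never silently "corrected".
#'
#' @param path CSV fixture path.
#' @return data frame: `quantity`, `outer_pct`, `inner_pct`.
#' @export
fa_printed_sums <- function(path = extdata_path("fatty_acid_printed_sums.csv")) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Reconcile computed class sums with printed totals
#'
#' @param site `"outer"` or `"inner"`.
#' @param slack difference regarded as rounding (default 0.5).
#' @return data frame: quantity, computed, printed, difference,
#'   `within_rounding`.
#' @export
fa_reconciliation <- function(site = c("outer", "inner"), slack = 0.5) {
  site <- match.arg(site)
  tab <- fatty_acid_table()
  col <- paste0(site, "_pct")
  sums <- fa_class_sums(tab$fa_name, tab[[col]])
  printed <- fa_printed_sums()
  keys <- c("safa", "mufa", "pufa", "omega3", "omega6", "omega9", "epa_plus_dha")
  out <- data.frame(
    quantity = keys,
    computed = vapply(keys, function(k) sums[[k]], numeric(1)),
    printed = printed[[col]][match(keys, printed$quantity)])
  out$difference <- out$computed - out$printed
  out$within_rounding <- abs(out$difference) <= slack
  rownames(out) <- NULL
  out
}
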