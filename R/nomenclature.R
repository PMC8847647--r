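# Shorthand lipid nomenclature: "CLASS(C:D)" sum compositions, optionally
# followed by an adduct annotation, e.g. "TG(52:3)", "SM(39:1)",
# "PC(36:3) [M+Cl]-".

.lipid_classes <- c("TG", "DG", "MG", "PC", "PE", "PS", "PI", "PG", "PA",
                    "SM", "CE", "LPC", "LPE", "FA")

#' Parse shorthand lipid names
#'
#' Parses sum-composition shorthand of the form `CLASS(C:D)`, where `C` is the
#' total acyl-chain carbon count and `D` the total number of double bonds.
#' Class tokens are matched case-insensitively against the common glyceride,
#' phospholipid, sphingolipid and fatty-acid classes (`TG`, `DG`, `MG`, `PC`,
#' `PE`, `PS`, `PI`, `PG`, `PA`, `SM`, `CE`, `LPC`, `LPE`, `FA`); anything
#' else is kept with `lipid_class = "other"`. Text after the closing
#' parenthesis (typically an adduct annotation such as `[M+Cl]-`) is stored
#' verbatim in `adduct` and ignored for classification. Leading and trailing
#' whitespace is tolerated.
#'
#' Odd-chain status is defined at the sum-composition level: a species is
#' odd-chain when its total carbon count is odd. Per-chain parity cannot be
#' resolved from shorthand names.
#'
#' @param names character vector of shorthand names.
#' @return A data frame of class `lipid_species` with one row per input name
#'   and columns `raw_name`, `lipid_class`, `total_carbons`, `double_bonds`,
#'   `adduct` (`NA` when absent) and `odd_chain`.
#' @examples
#' parse_lipid_name(c("TG(52:3)", "SM(39:1)", "FA(15:0)"))
#' @seealso [format_lipid_name()], [flag_tg_derived()]
#' @export
parse_lipid_name <- function(names) {
  if (length(names) == 0L || !is.character(names) || anyNA(names) ||
      any(!nzchar(trimws(names)))) {
    stop("'names' must be a non-empty character vector of non-empty strings",
         call. = FALSE)
  }
  core <- "^\\s*([A-Za-z]+)\\s*\\(\\s*([0-9]+)\\s*:\\s*([0-9]+)\\s*\\)(.*?)\\s*$"
  ok <- grepl(core, names)
  if (any(!ok)) {
    stop("cannot parse lipid name(s) (no 'CLASS(C:D)' core): ",
         paste(sQuote(names[!ok]), collapse = ", "), call. = FALSE)
  }
  cls_raw <- toupper(sub(core, "\\1", names))
  carbons <- as.integer(sub(core, "\\2", names))
  dbonds <- as.integer(sub(core, "\\3", names))
  adduct <- trimws(sub(core, "\\4", names))
  adduct[!nzchar(adduct)] <- NA_character_
  cls <- ifelse(cls_raw %in% .lipid_classes, cls_raw, "other")
  out <- data.frame(
    raw_name = names,
    lipid_class = cls,
    total_carbons = carbons,
    double_bonds = dbonds,
    adduct = adduct,
    odd_chain = carbons %% 2L == 1L,
    stringsAsFactors = FALSE
  )
  class(out) <- c("lipid_species", "data.frame")
  out
}

#' Serialise parsed lipid species back to canonical shorthand
#'
#' The canonical form is `CLASS(C:D)` with no whitespace; an adduct, when
#' present, is appended after a single space. Parsing a canonical name and
#' re-serialising it is the identity.
#'
#' @param species a `lipid_species` data frame from [parse_lipid_name()].
#' @return character vector of canonical names.
#' @export
format_lipid_name <- function(species) {
  stopifnot(inherits(species, "lipid_species") || is.data.frame(species))
  base <- sprintf("%s(%d:%d)", species$lipid_class, species$total_carbons,
                  species$double_bonds)
  has_adduct <- !is.na(species$adduct)
  base[has_adduct] <- paste(base[has_adduct], species$adduct[has_adduct])
  base
}

#' Flag diglycerides/monoglycerides compatible with a triglyceride inventory
#'
#' A DG (or MG) is considered TG-derived when some TG in the inventory could
#' yield it by loss of one (DG) or two (MG) acyl chains of plausible size.
#' The plausible single-chain window is 10-26 carbons and 0-6 double bonds,
#' spanning medium-chain through long-chain polyunsaturated fatty acids; for
#' MG species the window is doubled since two chains are lost. The flag is
#' monotone in the inventory: adding TG species can only turn it on.
#'
#' @param glycerides `lipid_species` rows of class DG or MG.
#' @param tg_inventory `lipid_species` rows, all of class TG.
#' @param chain_carbons length-2 integer, carbon range of one lost acyl chain.
#' @param chain_double_bonds length-2 integer, double-bond range of one lost
#'   acyl chain.
#' @return logical vector, one entry per row of `glycerides`.
#' @examples
#' dg <- parse_lipid_name("DG(34:2)")
#' tg <- parse_lipid_name("TG(52:3)")
#' flag_tg_derived(dg, tg)   # TRUE: 52 - 34 = 18 carbons, 3 - 2 = 1 double bond
#' @export
flag_tg_derived <- function(glycerides, tg_inventory,
                            chain_carbons = c(10L, 26L),
                            chain_double_bonds = c(0L, 6L)) {
  stopifnot(is.data.frame(glycerides), is.data.frame(tg_inventory))
  if (!all(glycerides$lipid_class %in% c("DG", "MG"))) {
    stop("flag_tg_derived() expects DG or MG species only", call. = FALSE)
  }
  if (nrow(tg_inventory) > 0L && !all(tg_inventory$lipid_class == "TG")) {
    stop("'tg_inventory' must contain TG species only", call. = FALSE)
  }
  vapply(seq_len(nrow(glycerides)), function(i) {
    n_lost <- if (glycerides$lipid_class[i] == "DG") 1L else 2L
    dc <- tg_inventory$total_carbons - glycerides$total_carbons[i]
    dd <- tg_inventory$double_bonds - glycerides$double_bonds[i]
    any(dc >= n_lost * chain_carbons[1] & dc <= n_lost * chain_carbons[2] &
        dd >= n_lost * chain_double_bonds[1] &
        dd <= n_lost * chain_double_bonds[2])
  }, logical(1))
}

# Canonical sort order used everywhere aligned lists are built: lipid class,
# then total carbons, then double bonds, then the raw name as tie break.
lipid_order <- function(species) {
  order(species$lipid_class, species$total_carbons, species$double_bonds,
        species$raw_name, method = "radix")
}
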