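# cached copy of the packaged chemistry table, filled on first use
.chem_env <- new.env(parent = emptyenv())

#' Residue chemistry table
#'
#' Returns the per-residue side-chain chemistry table the substitution
#' classifier runs on: non-hydrogen side-chain atom counts, a four-way
#' polarity/charge class (histidine counted as positive), and flags for the
#' two residues with special backbone/bond chemistry (cysteine, proline).
#'
#' @param path Optional path to an alternate chemistry TSV with columns
#'   `code`, `heavy_atoms`, `polarity_class`, `is_cysteine`, `is_proline`.
#'   Defaults to the table shipped with the package.
#' @return A data frame with one row per canonical residue (20 rows).
#' @export
residue_profiles <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.chem_env$profiles)) return(.chem_env$profiles)
    path <- system.file("extdata", "residue_chemistry.tsv", package = "opsinsites")
    cache <- TRUE
  } else cache <- FALSE
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(tab) == 20L, !anyDuplicated(tab$code),
            all(tab$polarity_class %in% c("nonpolar", "polar", "positive", "negative")))
  tab$is_cysteine <- as.logical(tab$is_cysteine)
  tab$is_proline <- as.logical(tab$is_proline)
  rownames(tab) <- tab$code
  if (cache) .chem_env$profiles <- tab
  tab
}

#' Look up the chemistry profile of one residue
#'
#' @param code One-letter amino-acid symbol (case-insensitive).
#' @return A one-row data frame with fields `code`, `heavy_atoms`,
#'   `polarity_class`, `is_cysteine`, `is_proline`.
#' @examples
#' residue_profile("G")$heavy_atoms  # 0: glycine has no side chain
#' residue_profile("H")$polarity_class  # "positive"
#' @export
residue_profile <- function(code) {
  prof <- residue_profiles()
  code <- toupper(code)
  if (length(code) != 1L || is.na(code) || !code %in% prof$code)
    stop("invalid residue symbol: ", deparse(code),
         " (expected one of the 20 canonical one-letter codes)", call. = FALSE)
  prof[code, , drop = FALSE]
}

# canonical label vocabulary, in report order
.label_kinds <- c(
  "increase_in_size", "decrease_in_size",
  "gain_of_polarity", "loss_of_polarity",
  "gain_of_positive_charge", "loss_of_positive_charge",
  "gain_of_negative_charge", "loss_of_negative_charge",
  "gain_disulfide_potential", "loss_disulfide_potential",
  "gain_backbone_rigidity", "gain_backbone_flexibility",
  "most_likely_insignificant")

.label_row <- function(kind, from_class = NA_character_, to_class = NA_character_,
                       magnitude = NA_integer_) {
  data.frame(kind = kind, from_class = from_class, to_class = to_class,
             magnitude = magnitude, stringsAsFactors = FALSE)
}

#' Classify an amino-acid substitution by structural/chemical significance
#'
#' Applies the categorical significance rules used throughout the candidate
#' screen, in fixed order: (1) side-chain size, called when the non-hydrogen
#' side-chain atom counts differ by two or more; (2) charge gain/loss, when
#' the polarity class changes and either side is charged (charge labels
#' suppress plain polarity labels at the same site); (3) polarity gain/loss,
#' when exactly one side is polar; (4) disulfide potential, when exactly one
#' side is cysteine; (5) backbone rigidity/flexibility, when exactly one side
#' is proline; (6) if nothing fired and the residues differ, the substitution
#' is called most likely insignificant. Identical residues return an empty
#' label set.
#'
#' Transitions between the positive and negative classes emit both a loss and
#' a gain charge label. The direction convention is fixed: `a` is the first
#' paralog's residue and `b` the second's.
#'
#' @param a,b One-letter residue symbols (ordered: a -> b).
#' @return A data frame of labels with columns `kind`, `from_class`,
#'   `to_class`, `magnitude` (size labels only); zero rows for `a == b`.
#' @examples
#' classify_substitution("A", "Q")$kind  # gain of polarity + increase in size
#' classify_substitution("T", "H")$kind  # gain of positive charge (from polar) + size
#' classify_substitution("I", "L")$kind  # most likely insignificant
#' @export
classify_substitution <- function(a, b) {
  pa <- residue_profile(a); pb <- residue_profile(b)
  out <- data.frame(kind = character(0), from_class = character(0),
                    to_class = character(0), magnitude = integer(0),
                    stringsAsFactors = FALSE)
  if (pa$code == pb$code) return(out)

  d <- pb$heavy_atoms - pa$heavy_atoms
  if (abs(d) >= 2L)
    out <- rbind(out, .label_row(if (d > 0) "increase_in_size" else "decrease_in_size",
                                 magnitude = abs(d)))

  ca <- pa$polarity_class; cb <- pb$polarity_class
  charged <- c("positive", "negative")
  charge_fired <- FALSE
  if (ca != cb && (ca %in% charged || cb %in% charged)) {
    charge_fired <- TRUE
    if (ca %in% charged)
      out <- rbind(out, .label_row(paste0("loss_of_", ca, "_charge"),
                                   from_class = ca, to_class = .neutralize(cb)))
    if (cb %in% charged)
      out <- rbind(out, .label_row(paste0("gain_of_", cb, "_charge"),
                                   from_class = .neutralize(ca), to_class = cb))
  }
  if (!charge_fired && xor(ca == "polar", cb == "polar"))
    out <- rbind(out, .label_row(
      if (cb == "polar") "gain_of_polarity" else "loss_of_polarity"))

  if (xor(pa$is_cysteine, pb$is_cysteine))
    out <- rbind(out, .label_row(
      if (pb$is_cysteine) "gain_disulfide_potential" else "loss_disulfide_potential"))

  if (xor(pa$is_proline, pb$is_proline))
    out <- rbind(out, .label_row(
      if (pb$is_proline) "gain_backbone_rigidity" else "gain_backbone_flexibility"))

  if (nrow(out) == 0L) out <- .label_row("most_likely_insignificant")
  out[order(match(out$kind, .label_kinds)), , drop = FALSE]
}

# charge-label annotation for an uncharged class: the tables print "neutral"
# for nonpolar partners and the class name otherwise
.neutralize <- function(class) if (class == "nonpolar") "neutral" else class

#' Classify a set of ordered residue pairs and take the label-kind union
#'
#' Expands multi-residue paralog states (e.g. "T/S" vs "Q") into ordered
#' pairs and returns the union of label kinds over all pairs; identical
#' pairs contribute nothing. A record is structurally significant when any
#' expanded pair yields a label other than most-likely-insignificant.
#'
#' @param pairs Character vector of ordered pairs in `"A>B"` form.
#' @return Character vector of label kinds in canonical order.
#' @export
classify_pairs <- function(pairs) {
  kinds <- character(0)
  for (p in pairs) {
    ab <- strsplit(p, ">", fixed = TRUE)[[1]]
    if (length(ab) != 2L || nchar(ab[1]) != 1L || nchar(ab[2]) != 1L)
      stop("malformed residue pair: ", deparse(p), call. = FALSE)
    kinds <- union(kinds, classify_substitution(ab[1], ab[2])$kind)
  }
  kinds[order(match(kinds, .label_kinds))]
}

#' Is a label-kind set structurally significant?
#'
#' @param kinds Character vector of label kinds.
#' @return TRUE when any kind other than `most_likely_insignificant` present.
#' @export
is_significant <- function(kinds) {
  any(kinds != "most_likely_insignificant")
}
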