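#' The BLOSUM62 substitution matrix restricted to the 20 canonical residues
#'
#' @return A symmetric 20 x 20 integer matrix of log-odds scores.
#' @export
blosum62 <- function() {
  if (!is.null(.chem_env$blosum62)) return(.chem_env$blosum62)
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aa <- residue_profiles()$code
  m <- e$BLOSUM62[aa, aa]
  .chem_env$blosum62 <- m
  m
}

#' Construct/validate a pairwise alignment object
#'
#' An alignment is two equal-length gapped rows plus a score. Degapping the
#' rows recovers the aligned sequences; no column may be gap/gap.
#'
#' @param row_a,row_b Equal-length strings over residues and `-`.
#' @param score Alignment score in matrix units (optional).
#' @return An object of class `pairwise_alignment`.
#' @export
pairwise_alignment <- function(row_a, row_b, score = NA_real_) {
  if (nchar(row_a) != nchar(row_b))
    stop("alignment rows differ in length", call. = FALSE)
  va <- strsplit(row_a, "")[[1]]; vb <- strsplit(row_b, "")[[1]]
  if (any(va == "-" & vb == "-"))
    stop("alignment contains a gap/gap column", call. = FALSE)
  structure(list(row_a = row_a, row_b = row_b, score = score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Pairwise alignment (", nchar(x$row_a), " columns, score ",
      format(x$score), ")\n", sep = "")
  cat(" a: ", x$row_a, "\n b: ", x$row_b, "\n", sep = "")
  invisible(x)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed via
#' the Biostrings aligner. A gap of length L costs `gap_open + L * gap_extend`
#' (both given as non-positive score contributions).
#'
#' @param a,b Sequences: plain strings of one-letter residues.
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param gap_open,gap_extend Gap penalties in score units, `gap_open <=
#'   gap_extend <= 0`.
#' @return A [pairwise_alignment()] with the optimal score.
#' @export
global_align <- function(a, b, matrix = blosum62(), gap_open = -10, gap_extend = -1) {
  for (s in list(a, b)) {
    if (!nzchar(s)) stop("empty sequence", call. = FALSE)
    bad <- setdiff(strsplit(s, "")[[1]], rownames(matrix))
    if (length(bad))
      stop("residue(s) absent from substitution matrix: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!(gap_open <= gap_extend && gap_extend <= 0))
    stop("gap penalties must satisfy gap_open <= gap_extend <= 0", call. = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = matrix, gapOpening = -gap_open,
    gapExtension = -gap_extend, type = "global")
  pairwise_alignment(as.character(Biostrings::alignedPattern(pa)),
                     as.character(Biostrings::alignedSubject(pa)),
                     score = Biostrings::score(pa))
}

#' Percent similarity between two aligned paralogs
#'
#' Counts columns whose residue pair is identical or chemically conserved --
#' substitution-matrix score at or above `conserved_threshold` (every BLOSUM62
#' diagonal entry is >= 4, so identities always qualify) -- and divides by the
#' denominator selected by `denominator_mode`:
#' `both_residue_columns` (default) counts only columns where both rows carry
#' a residue; `mean_sequence_length` uses the mean of the two degapped
#' sequence lengths.
#'
#' @param aln A [pairwise_alignment()].
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param conserved_threshold Minimum score counted as conserved (default 1).
#' @param denominator_mode One of `"both_residue_columns"`,
#'   `"mean_sequence_length"`.
#' @return Percentage in \[0, 100\] (unrounded).
#' @examples
#' aln <- pairwise_alignment("ACDE", "ACDQ")
#' percent_similarity(aln)  # 100: E-Q scores 2 under BLOSUM62
#' @export
percent_similarity <- function(aln, matrix = blosum62(), conserved_threshold = 1,
                               denominator_mode = c("both_residue_columns",
                                                    "mean_sequence_length")) {
  denominator_mode <- match.arg(denominator_mode)
  stopifnot(inherits(aln, "pairwise_alignment"))
  va <- strsplit(aln$row_a, "")[[1]]; vb <- strsplit(aln$row_b, "")[[1]]
  both <- va != "-" & vb != "-"
  denom <- switch(denominator_mode,
    both_residue_columns = sum(both),
    mean_sequence_length = mean(c(sum(va != "-"), sum(vb != "-"))))
  if (denom == 0) stop("no qualifying denominator columns", call. = FALSE)
  scores <- matrix[cbind(va[both], vb[both])]
  100 * sum(scores >= conserved_threshold) / denom
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write protein sequences (optionally gapped rows) to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    writeLines(substring(s, seq(1, nchar(s), 60), pmin(seq(1, nchar(s), 60) + 59, nchar(s))), con)
  }
  invisible(path)
}
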