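#' Run the end-to-end candidate-site screen
#'
#' Composes the pipeline stages: (optionally) align a paralog pair and
#' compute percent similarity, map the query onto reference numbering,
#' (optionally) derive binding-pocket membership from a structure, then
#' screen the evidence table and write the candidate report, headline counts
#' and a run manifest. The main path is fully deterministic; two runs on
#' identical inputs produce byte-identical outputs.
#'
#' @param evidence Path to an evidence TSV (default: the packaged table).
#' @param out_dir Output directory (created if needed).
#' @param sequences Optional FASTA with >= 2 sequences: the first two are
#'   globally aligned and their percent similarity reported.
#' @param structure Optional PDB path; pocket membership is computed with the
#'   distance rule and written alongside the report.
#' @param ligand Ligand residue name for the structure stage (default RET).
#' @param cutoff Pocket cutoff in Angstrom (default 4).
#' @param paralog_wide_branches Branch labels treated as paralog-wide in the
#'   headline summary.
#' @param criteria Logical 3-vector toggling the candidacy clauses.
#' @return Invisibly, a list with `candidates`, `headline`, `similarity`
#'   (or NULL), `pocket` (or NULL) and `manifest`.
#' @export
run_pipeline <- function(evidence = NULL, out_dir,
                         sequences = NULL, structure = NULL, ligand = "RET",
                         cutoff = 4.0,
                         paralog_wide_branches = c("UV-C", "UV-D", "LW-C", "LW-E"),
                         criteria = c(TRUE, TRUE, TRUE)) {
  if (is.null(evidence))
    evidence <- system.file("extdata", "tables23_evidence.tsv", package = "opsinsites")
  for (p in c(evidence, sequences, structure))
    if (!is.null(p) && !file.exists(p))
      stop("input file does not exist: ", p, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  manifest <- list(
    tool = "opsinsites",
    version = as.character(utils::packageVersion("opsinsites")),
    inputs = Filter(Negate(is.null), list(
      evidence = list(path = evidence, md5 = tools::md5sum(evidence)[[1]]),
      sequences = if (!is.null(sequences)) list(path = sequences, md5 = tools::md5sum(sequences)[[1]]),
      structure = if (!is.null(structure)) list(path = structure, md5 = tools::md5sum(structure)[[1]]))),
    config = list(ligand = ligand, cutoff = cutoff,
                  paralog_wide_branches = paralog_wide_branches,
                  criteria = criteria),
    status = "failed")
  write_manifest <- function()
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  on.exit(write_manifest())

  similarity <- NULL
  if (!is.null(sequences)) {
    seqs <- read_fasta(sequences)
    if (length(seqs) < 2) stop("stage align: need at least two sequences", call. = FALSE)
    aln <- global_align(seqs[[1]], seqs[[2]])
    similarity <- percent_similarity(aln)
    numbering <- tryCatch(
      map_to_reference(global_align(reference_sequence(), seqs[[1]])),
      error = function(e) stop("stage number: ", conditionMessage(e), call. = FALSE))
    reg <- annotate_regions(numbering$site_label)
    numtab <- cbind(numbering, region = reg$region, region_class = reg$region_class)
    utils::write.table(numtab, file.path(out_dir, "numbering.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  pocket <- NULL
  if (!is.null(structure)) {
    model <- tryCatch(read_structure(structure, ligand = ligand),
                      error = function(e) stop("stage pocket: ", conditionMessage(e), call. = FALSE))
    pocket <- binding_pocket(model, cutoff = cutoff)
    write_pocket_tsv(pocket, file.path(out_dir, "pocket.tsv"))
  }

  ev <- tryCatch(load_evidence_table(evidence),
                 error = function(e) stop("stage screen: ", conditionMessage(e), call. = FALSE))
  candidates <- screen_candidates(ev, criteria = criteria)
  headline <- summarize_headline(candidates, paralog_wide_branches = paralog_wide_branches)
  render_report(candidates, file.path(out_dir, "candidates.tsv"))
  jsonlite::write_json(
    c(headline, if (!is.null(similarity)) list(percent_similarity = similarity)),
    file.path(out_dir, "counts.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)

  manifest$status <- "ok"
  manifest$n_candidates <- nrow(candidates)
  write_manifest(); on.exit()
  invisible(list(candidates = candidates, headline = headline,
                 similarity = similarity, pocket = pocket, manifest = manifest))
}
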