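# Seed-deterministic generators giving every analysis stage a download-free,
# statistically controlled test surface. All randomness goes through a local
# RNG stream so generation never disturbs the caller's RNG state.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Ordered residue pairs guaranteed non-conservative under BLOSUM62
#'
#' All ordered pairs of distinct canonical residues whose matrix score falls
#' below the threshold, verified against the matrix at call time. Used to
#' plant substitutions whose similarity contribution is exactly zero.
#'
#' @param matrix Substitution matrix (default [blosum62()]).
#' @param threshold Conserved-score threshold (default 1).
#' @return Two-column character matrix of (from, to) pairs.
#' @export
nonconservative_pairs <- function(matrix = blosum62(), threshold = 1) {
  aa <- rownames(matrix)
  idx <- which(matrix < threshold, arr.ind = TRUE)
  cbind(from = aa[idx[, 1]], to = aa[idx[, 2]])
}

#' Generate a paralog pair with a planted conserved fraction
#'
#' Sequence B differs from A at exactly
#' `round((1 - conserved_fraction) * length)` positions, each substitution
#' drawn from a pool of pairs scoring below the conservation threshold, so
#' [percent_similarity()] on the (gap-free) pair equals
#' `conserved_fraction * 100` exactly.
#'
#' @param length Residue count (>= 10).
#' @param conserved_fraction Target fraction in \[0, 1\].
#' @param seed RNG seed.
#' @return List with `a`, `b` (sequences), `positions` (substituted sites),
#'   `expected_similarity` (percent), and `alignment` (the gap-free
#'   [pairwise_alignment()]).
#' @export
generate_paralog_pair <- function(length, conserved_fraction, seed = 1) {
  stopifnot(length >= 10, conserved_fraction >= 0, conserved_fraction <= 1)
  n_sub <- round((1 - conserved_fraction) * length)
  pool <- nonconservative_pairs()
  .with_seed(seed, {
    a <- sample(residue_profiles()$code, length, replace = TRUE)
    b <- a
    positions <- sort(sample.int(length, n_sub))
    for (p in positions) {
      choices <- pool[pool[, "from"] == a[p], "to"]
      b[p] <- sample(choices, 1)
    }
    sa <- paste(a, collapse = ""); sb <- paste(b, collapse = "")
    list(a = sa, b = sb, positions = positions,
         expected_similarity = 100 * (length - n_sub) / length,
         alignment = pairwise_alignment(sa, sb))
  })
}

#' Apply indels to a sequence and derive the truth numbering
#'
#' Edits a query relative to a reference-length sequence and returns both the
#' edited sequence and the alignment/numbering the edits imply, for testing
#' the insertion-code ("242^a") bookkeeping.
#'
#' @param seq Reference-coordinate sequence (string).
#' @param inserts List of `list(after_pos, residues)` insertions (positions
#'   on `seq`, 0 allowed for an N-terminal insertion).
#' @param deletes Integer vector of positions of `seq` to delete.
#' @return List with `variant` (edited sequence), `alignment` (implied
#'   [pairwise_alignment()] with row_a = `seq` gapped at insertions), and
#'   `truth` (data frame query_pos, query_residue, site_label).
#' @export
generate_indel_variant <- function(seq, inserts = list(), deletes = integer(0)) {
  n <- nchar(seq)
  v <- strsplit(seq, "")[[1]]
  ins_at <- vapply(inserts, function(i) as.integer(i[[1]]), 1L)
  if (any(ins_at < 0 | ins_at > n)) stop("insert position out of range", call. = FALSE)
  if (anyDuplicated(ins_at)) stop("overlapping insertions", call. = FALSE)
  if (any(deletes < 1 | deletes > n) || anyDuplicated(deletes))
    stop("invalid or overlapping deletions", call. = FALSE)
  if (length(intersect(ins_at, deletes)))
    stop("overlapping edits: insertion anchored at a deleted position", call. = FALSE)

  row_a <- character(0); row_b <- character(0)
  ins_map <- if (length(inserts))
    stats::setNames(lapply(inserts, function(i) strsplit(i[[2]], "")[[1]]), ins_at)
  else list()
  emit_ins <- function(pos) {
    res <- ins_map[[as.character(pos)]]
    if (!is.null(res)) {
      row_a <<- c(row_a, rep("-", length(res)))
      row_b <<- c(row_b, res)
    }
  }
  emit_ins(0L)
  for (p in seq_len(n)) {
    row_a <- c(row_a, v[p])
    row_b <- c(row_b, if (p %in% deletes) "-" else v[p])
    emit_ins(p)
  }
  aln <- pairwise_alignment(paste(row_a, collapse = ""), paste(row_b, collapse = ""))

  # truth numbering by direct bookkeeping over the edits
  labels <- character(0); residues <- character(0)
  add_ins <- function(pos) {
    res <- ins_map[[as.character(pos)]]
    if (!is.null(res)) {
      labels <<- c(labels, paste0(pos, "^", vapply(seq_along(res), .ins_code, "")))
      residues <<- c(residues, res)
    }
  }
  add_ins(0L)
  for (p in seq_len(n)) {
    if (!(p %in% deletes)) { labels <- c(labels, as.character(p)); residues <- c(residues, v[p]) }
    add_ins(p)
  }
  truth <- data.frame(query_pos = seq_along(labels), query_residue = residues,
                      site_label = labels, stringsAsFactors = FALSE)
  list(variant = paste(row_b[row_b != "-"], collapse = ""),
       alignment = aln, truth = truth)
}

# one PDB ATOM/HETATM line in fixed columns
.pdb_line <- function(record, serial, name, resname, chain, resseq, xyz, element) {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, " ", resname, chain, resseq, " ",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

#' Generate a toy structure with a planted binding pocket
#'
#' Places a small retinal-like ligand (`RET` HETATM cluster) near the origin
#' and `n_residues` single-chain polymer residues around it: residues listed
#' in `planted_pocket` get a minimum ligand distance drawn uniformly from
#' `(1, cutoff]`; all others are placed at least `cutoff + 1` away. The
#' resulting PDB text therefore has a known truth pocket.
#'
#' @param n_residues Number of polymer residues (>= 1).
#' @param planted_pocket Integer indices (1..n_residues) planted inside the
#'   cutoff.
#' @param cutoff Pocket cutoff in Angstrom (default 4.0).
#' @param seed RNG seed.
#' @param n_ligand_atoms Ligand atom count (default 10).
#' @return List with `pdb` (character lines), `truth` (integer indices of
#'   pocket residues), and `distances` (planted minimum distances).
#' @export
generate_toy_structure <- function(n_residues, planted_pocket = integer(0),
                                   cutoff = 4.0, seed = 1, n_ligand_atoms = 10) {
  stopifnot(n_residues >= 1, all(planted_pocket %in% seq_len(n_residues)))
  .with_seed(seed, {
    lig <- matrix(stats::runif(n_ligand_atoms * 3, -1.5, 1.5), ncol = 3)
    rand_dir <- function() {
      repeat {
        u <- stats::rnorm(3); l <- sqrt(sum(u^2))
        if (l > 1e-6) return(u / l)
      }
    }
    centroid <- colMeans(lig)
    min_dist <- function(p) sqrt(min(colSums((t(lig) - p)^2)))
    # place a two-atom residue (CA at the target minimum distance, CB behind
    # it) so that the residue's minimum ligand distance is exactly (planted)
    # or at least (non-pocket) the target
    place_residue <- function(target) {
      for (try in 1:500) {
        anchor <- lig[sample.int(nrow(lig), 1L), ]
        ca <- anchor + rand_dir() * target
        d_ca <- min_dist(ca)
        if (!isTRUE(all.equal(d_ca, target))) next  # another ligand atom is nearer
        u <- ca - centroid; u <- u / sqrt(sum(u^2))
        cb <- ca + u * 1.5
        if (min_dist(cb) >= d_ca) return(list(ca = ca, cb = cb, d = d_ca))
      }
      stop("geometric placement failed", call. = FALSE)
    }
    lines <- character(0); serial <- 0L
    for (i in seq_len(nrow(lig))) {
      serial <- serial + 1L
      lines <- c(lines, .pdb_line("HETATM", serial, "C1", "RET", "A", 900L, lig[i, ], "C"))
    }
    truth <- sort(unique(as.integer(planted_pocket)))
    dists <- numeric(n_residues)
    for (r in seq_len(n_residues)) {
      target <- if (r %in% truth) stats::runif(1, 1 + 1e-6, cutoff)
                else cutoff + 1 + stats::runif(1, 0, 50)
      res <- place_residue(target)
      dists[r] <- res$d
      serial <- serial + 1L
      lines <- c(lines, .pdb_line("ATOM", serial, "CA", "ALA", "A", r, res$ca, "C"))
      serial <- serial + 1L
      lines <- c(lines, .pdb_line("ATOM", serial, "CB", "ALA", "A", r, res$cb, "C"))
    }
    list(pdb = c(lines, "END"), truth = truth, distances = dists)
  })
}

#' Generate an evidence table with a planted candidate count
#'
#' Builds an evidence TSV in the documented schema where exactly
#' `n_candidates` of `n_sites` sites satisfy the screen, with the planted
#' per-clause mix: each candidate is assigned one clause from `clause_mix`
#' (sampled with replacement) and given only the evidence that clause needs;
#' non-candidates get an insignificant substitution, no branches, no
#' literature, and stay outside the pocket.
#'
#' @param n_sites Total sites.
#' @param n_candidates Planted candidates (<= n_sites).
#' @param clause_mix Clauses to sample from (subset of 1:3).
#' @param seed RNG seed.
#' @param path Optional path to also write the TSV.
#' @return List with `table` (data frame in the evidence schema), `truth`
#'   (candidate site labels) and `clauses` (planted clause per candidate).
#' @export
generate_evidence_fixture <- function(n_sites, n_candidates, clause_mix = 1:3,
                                      seed = 1, path = NULL) {
  stopifnot(n_candidates <= n_sites, all(clause_mix %in% 1:3))
  .with_seed(seed, {
    sites <- as.character(seq(10, by = 3, length.out = n_sites))
    cand_idx <- sort(sample.int(n_sites, n_candidates))
    clauses <- if (n_candidates)
      clause_mix[sample.int(length(clause_mix), n_candidates, replace = TRUE)]
    else integer(0)
    rows <- lapply(seq_len(n_sites), function(i) {
      is_cand <- i %in% cand_idx
      clause <- if (is_cand) clauses[match(i, cand_idx)] else 0L
      data.frame(
        gene_class = "UVS", site = sites[i], region = "TM3",
        in_cbp = if (clause == 3L) "1" else "0",
        ps_lineage = if (clause == 1L) "synthetic lineage" else ".",
        branch = if (clause == 1L) "UV-C" else ".",
        pairs = if (clause == 3L) "A>Q" else "I>L",
        printed_significance = ".", expected_labels = ".",
        exception = "0", agrees_with_print = "1",
        lit_ps = if (clause == 2L) "synthetic_lit[K1]" else ".",
        lit_shift = ".", notes = ".", stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (!is.null(path)) {
      con <- file(path, "w")
      utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
      close(con)
    }
    list(table = tab, truth = sites[cand_idx], clauses = clauses)
  })
}
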