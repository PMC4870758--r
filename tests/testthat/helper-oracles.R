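# Independent brute-force oracles used to check the analysis implementations.

# Enumerate ALL global alignments of two short sequences and return the
# optimal affine-gap score. A gap run of length L costs open + L * extend.
brute_force_align_score <- function(a, b, matrix, gap_open = -10, gap_extend = -1) {
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  best <- -Inf
  # state: (i, j, last_move) with moves: M substitution, X gap in b, Y gap in a
  rec <- function(i, j, last, score) {
    if (i > length(va) && j > length(vb)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(va) && j <= length(vb))
      rec(i + 1, j + 1, "M", score + matrix[va[i], vb[j]])
    if (i <= length(va))
      rec(i + 1, j, "X", score + gap_extend + if (last != "X") gap_open else 0)
    if (j <= length(vb))
      rec(i, j + 1, "Y", score + gap_extend + if (last != "Y") gap_open else 0)
  }
  rec(1, 1, "-", 0)
  best
}

# All-pairs minimum residue-ligand distance oracle over a structure_model.
brute_force_pocket <- function(model, cutoff = 4.0, exclude_h = TRUE) {
  atoms <- model$atoms
  if (exclude_h) atoms <- atoms[toupper(atoms$element) != "H", ]
  lig <- atoms[atoms$is_ligand, ]
  poly <- atoms[!atoms$is_ligand, ]
  keys <- unique(paste(poly$chain, poly$residue_seq, sep = ":"))
  mind <- vapply(keys, function(k) {
    r <- poly[paste(poly$chain, poly$residue_seq, sep = ":") == k, ]
    m <- Inf
    for (i in seq_len(nrow(r))) for (j in seq_len(nrow(lig)))
      m <- min(m, sqrt(sum((c(r$x[i], r$y[i], r$z[i]) - c(lig$x[j], lig$y[j], lig$z[j]))^2)))
    m
  }, 1.0)
  keys[mind <= cutoff]
}

# Tiny PDB text builder for parser tests.
make_pdb_lines <- function(records) {
  # records: data.frame(record, serial, name, resname, chain, resseq, x, y, z, element)
  vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    sprintf("%-6s%5d %-4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            r$record, r$serial, r$name, " ", r$resname, r$chain, r$resseq, " ",
            r$x, r$y, r$z, 1.00, 0.00, r$element)
  }, "")
}

packaged_evidence_path <- function()
  system.file("extdata", "tables23_evidence.tsv", package = "opsinsites")
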