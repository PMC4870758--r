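# bijective base-26 rendering of insertion indices: 1 -> a, 26 -> z, 27 -> aa
.ins_code <- function(k) {
  stopifnot(k >= 1)
  out <- ""
  while (k > 0) {
    r <- (k - 1) %% 26
    out <- paste0(letters[r + 1], out)
    k <- (k - 1) %/% 26
  }
  out
}

.parse_site_label <- function(label) {
  # returns list(anchor, ins) where ins = 0 for plain integer labels
  m <- regmatches(label, regexec("^([0-9]+)(\\^([a-z]+))?$", label))[[1]]
  if (length(m) == 0)
    stop("malformed site label: ", deparse(label), call. = FALSE)
  anchor <- as.integer(m[2])
  ins <- if (nzchar(m[4])) {
    v <- utf8ToInt(m[4]) - utf8ToInt("a") + 1L
    as.integer(sum(v * 26^(rev(seq_along(v)) - 1L)))
  } else 0L
  list(anchor = anchor, ins = ins)
}

#' Order site labels numerically with insertions after their anchor
#'
#' @param labels Character vector of labels like `"137"` or `"242^a"`.
#' @return Integer ordering permutation (as from [order()]).
#' @export
order_site_labels <- function(labels) {
  parsed <- lapply(labels, .parse_site_label)
  order(vapply(parsed, `[[`, 1L, "anchor"), vapply(parsed, `[[`, 1L, "ins"))
}

#' The packaged reference sequence used for site numbering
#'
#' A synthetic 348-residue rhodopsin-like protein (constructed in-package,
#' with the canonical rhodopsin landmark residues at their usual positions;
#' it is not the deposited bovine sequence). Any reference can be substituted
#' by passing your own FASTA path.
#'
#' @param path Optional FASTA path of an alternate reference.
#' @return A single (unnamed) residue string.
#' @export
reference_sequence <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rhodopsin_reference_synthetic.fasta",
                        package = "opsinsites")
  unname(read_fasta(path)[1])
}

#' Map aligned query positions onto reference site numbering
#'
#' Given a global alignment whose first row degaps to the reference, each
#' non-gap query position is labeled with the reference position of its
#' column. Query residues falling in columns where the reference is gapped
#' receive insertion codes anchored to the last preceding reference position
#' (`"242^a"` for the first residue inserted between reference 242 and 243;
#' codes run a, b, ..., z, aa, ...). Insertions before the first reference
#' residue anchor to 0.
#'
#' @param aln A [pairwise_alignment()] with `row_a` the (gapped) reference
#'   and `row_b` the query.
#' @param reference Degapped reference sequence `row_a` must match
#'   (default the packaged reference).
#' @return A data frame with columns `query_pos`, `query_residue`,
#'   `site_label`.
#' @export
map_to_reference <- function(aln, reference = reference_sequence()) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  va <- strsplit(aln$row_a, "")[[1]]; vb <- strsplit(aln$row_b, "")[[1]]
  if (paste(va[va != "-"], collapse = "") != reference)
    stop("row_a does not degap to the reference sequence", call. = FALSE)
  ref_pos <- 0L; ins <- 0L; qpos <- 0L
  rows <- vector("list", sum(vb != "-"))
  k <- 0L
  for (i in seq_along(va)) {
    if (va[i] != "-") { ref_pos <- ref_pos + 1L; ins <- 0L }
    if (vb[i] == "-") next
    qpos <- qpos + 1L
    label <- if (va[i] != "-") as.character(ref_pos) else {
      ins <- ins + 1L
      paste0(ref_pos, "^", .ins_code(ins))
    }
    k <- k + 1L
    rows[[k]] <- data.frame(query_pos = qpos, query_residue = vb[i],
                            site_label = label, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' The packaged transmembrane/loop region map
#'
#' @param path Optional alternate region TSV with columns `name`, `label`,
#'   `start`, `end` (1-based closed intervals over the reference).
#' @return Data frame of non-overlapping intervals sorted by `start`.
#' @export
region_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "rhodopsin_regions.tsv", package = "opsinsites")
  reg <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  reg <- reg[order(reg$start), ]
  stopifnot(all(reg$end >= reg$start),
            all(reg$start[-1] == reg$end[-nrow(reg)] + 1L))
  reg
}

#' Annotate site labels with their structural region
#'
#' Integer labels get the containing interval's region; insertion codes
#' inherit the region of their anchor position.
#'
#' @param site_labels Character vector of site labels (`"137"`, `"242^a"`).
#' @param regions Region map from [region_map()].
#' @return Data frame with columns `site_label`, `region` (interval name,
#'   e.g. `"TM5"`) and `region_class` (broad label: TM/CL/EL).
#' @export
annotate_regions <- function(site_labels, regions = region_map()) {
  anchors <- vapply(site_labels, function(l) .parse_site_label(l)$anchor, 1L)
  idx <- vapply(anchors, function(a) {
    j <- which(regions$start <= a & a <= regions$end)
    if (length(j) != 1L)
      stop("site ", a, " outside region map coverage", call. = FALSE)
    j
  }, 1L)
  data.frame(site_label = site_labels, region = regions$name[idx],
             region_class = regions$label[idx], stringsAsFactors = FALSE)
}
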