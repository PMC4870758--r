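#' Likelihood-ratio test p-value for a branch-site selection test
#'
#' Compares the alternative model's log-likelihood against the null with
#' omega fixed at 1: the statistic 2(lnL_alt - lnL_null) is referred to an
#' upper-tail chi-square distribution with `df` degrees of freedom. A
#' slightly negative statistic (within `tolerance`) is clamped to 0 with a
#' warning, as optimisers can return lnL_alt marginally below lnL_null.
#'
#' @param lnL_null,lnL_alt Log-likelihoods of the null and alternative fits.
#' @param df Degrees of freedom (>= 1).
#' @param tolerance Allowed negative slack in the statistic (default 1e-6).
#' @return p-value in \[0, 1\].
#' @examples
#' lrt_pvalue(-1000, -1000 + 3.841459 / 2, df = 1)  # ~0.05
#' @export
lrt_pvalue <- function(lnL_null, lnL_alt, df = 1, tolerance = 1e-6) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < 0) {
    if (stat < -tolerance)
      stop("lnL_alt is below lnL_null by more than the tolerance", call. = FALSE)
    warning("negative LRT statistic clamped to 0")
    stat <- 0
  }
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

# split a semicolon-separated field, treating "." and "" as empty
.split_field <- function(x) {
  if (is.na(x) || x %in% c(".", "")) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

#' Load a combined-evidence table
#'
#' Reads the documented evidence TSV (one row per substitution record) and
#' groups rows by (gene_class, site) into one per-site evidence record,
#' merging branch labels, residue pairs and literature entries by union.
#' Multi-residue paralog states are carried as explicit ordered pairs and
#' classified with [classify_pairs()].
#'
#' @param path Evidence TSV path; defaults to the packaged transcription of
#'   the published UVS/LWS candidate tables.
#' @param gene_class Optional filter, `"UVS"` or `"LWS"`.
#' @return A data frame of class `site_evidence` with one row per site:
#'   gene_class, site, region, in_cbp, branches (list), pairs (list),
#'   labels (list of classifier label kinds), lit_ps (list), lit_shift
#'   (list), n_records.
#' @export
load_evidence_table <- function(path = NULL, gene_class = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tables23_evidence.tsv", package = "opsinsites")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  needed <- c("gene_class", "site", "region", "in_cbp", "branch", "pairs",
              "lit_ps", "lit_shift")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("evidence table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!is.null(gene_class)) tab <- tab[tab$gene_class %in% gene_class, , drop = FALSE]
  if (nrow(tab) == 0L)
    return(structure(data.frame(), class = c("site_evidence", "data.frame")))

  for (i in seq_len(nrow(tab))) {
    pr <- .split_field(tab$pairs[i])
    res <- unlist(strsplit(pr, ">", fixed = TRUE))
    bad <- setdiff(res, residue_profiles()$code)
    if (length(bad))
      stop("row ", i, ": invalid residue(s) ", paste(bad, collapse = ", "),
           call. = FALSE)
    .parse_site_label(tab$site[i])  # validates label syntax
    if (!grepl("^(TM[1-7]?|CL[1-3]?|EL[1-3]?|N-term|C-term)$", tab$region[i]))
      stop("row ", i, ": unknown region code ", deparse(tab$region[i]), call. = FALSE)
  }

  key <- paste(tab$gene_class, tab$site)
  groups <- split(seq_len(nrow(tab)), factor(key, levels = unique(key)))
  rows <- lapply(groups, function(idx) {
    g <- tab[idx, , drop = FALSE]
    if (length(unique(g$region)) != 1L || length(unique(g$in_cbp)) != 1L)
      stop("conflicting region/CBP flags for site ", g$site[1], call. = FALSE)
    pairs <- unique(unlist(lapply(g$pairs, .split_field)))
    data.frame(
      gene_class = g$gene_class[1], site = g$site[1], region = g$region[1],
      in_cbp = g$in_cbp[1] == "1",
      branches = I(list(unique(unlist(lapply(g$branch, .split_field))))),
      pairs = I(list(pairs)),
      labels = I(list(classify_pairs(pairs))),
      lit_ps = I(list(unique(unlist(lapply(g$lit_ps, .split_field))))),
      lit_shift = I(list(unique(unlist(lapply(g$lit_shift, .split_field))))),
      n_records = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # order by gene class (UVS first), then numeric site with insertions after anchor
  ord <- unlist(lapply(split(seq_len(nrow(out)),
                             factor(out$gene_class, levels = intersect(c("UVS", "LWS"), out$gene_class))),
                       function(ix) ix[order_site_labels(out$site[ix])]),
                use.names = FALSE)
  out <- out[ord, ]
  rownames(out) <- NULL
  class(out) <- c("site_evidence", "data.frame")
  out
}

#' Screen sites against the three candidacy criteria
#'
#' A site is a candidate spectral-tuning site when any enabled clause fires:
#' (1) it is under branch-site positive selection in an opsin paralog
#' (`branches` nonempty); (2) a homologous site in another organism carries
#' positive selection or a documented wavelength shift (`lit_ps` or
#' `lit_shift` nonempty); (3) it lies in the chromophore binding pocket and
#' at least one paralog substitution is structurally significant (a label
#' other than most-likely-insignificant).
#'
#' @param evidence A `site_evidence` table from [load_evidence_table()].
#' @param criteria Logical vector of length 3 toggling the clauses.
#' @param pocket Optional pocket table from [binding_pocket()] joined through
#'   reference numbering: a data frame with columns `site_label`,
#'   `in_pocket`; when given, it overrides the evidence `in_cbp` flags.
#' @return An object of class `tuning_screen`: the candidate subset with
#'   logical columns `crit_ps`, `crit_literature`, `crit_pocket`.
#' @export
screen_candidates <- function(evidence, criteria = c(TRUE, TRUE, TRUE),
                              pocket = NULL) {
  stopifnot(length(criteria) == 3L, is.logical(criteria))
  if (nrow(evidence) == 0L) {
    out <- cbind(evidence, data.frame(crit_ps = logical(0),
                                      crit_literature = logical(0),
                                      crit_pocket = logical(0)))
    class(out) <- c("tuning_screen", "data.frame")
    return(out)
  }
  if (!is.null(pocket)) {
    hit <- match(evidence$site, pocket$site_label)
    evidence$in_cbp <- ifelse(is.na(hit), FALSE, pocket$in_pocket[hit])
  }
  crit_ps <- vapply(evidence$branches, function(b) length(b) > 0, TRUE)
  crit_lit <- mapply(function(p, s) length(p) + length(s) > 0,
                     evidence$lit_ps, evidence$lit_shift)
  crit_pocket <- evidence$in_cbp &
    vapply(evidence$labels, is_significant, TRUE)
  crit_ps <- crit_ps & criteria[1]
  crit_lit <- crit_lit & criteria[2]
  crit_pocket <- crit_pocket & criteria[3]
  keep <- crit_ps | crit_lit | crit_pocket
  out <- evidence[keep, , drop = FALSE]
  out$crit_ps <- crit_ps[keep]
  out$crit_literature <- crit_lit[keep]
  out$crit_pocket <- crit_pocket[keep]
  rownames(out) <- NULL
  class(out) <- c("tuning_screen", "site_evidence", "data.frame")
  out
}

#' Headline partition of the candidate set
#'
#' Splits each gene class's candidates into binding-pocket sites and
#' non-pocket sites whose positive-selection branches include a
#' paralog-wide branch (a branch spanning a whole buprestid paralog clade,
#' default UV-C/UV-D for UVS and LW-C/LW-E for LWS).
#'
#' @param candidates A `tuning_screen` from [screen_candidates()].
#' @param paralog_wide_branches Branch labels counted as paralog-wide.
#' @return A list per gene class with elements `cbp_sites`,
#'   `non_cbp_paralog_wide_sites` (site-label vectors) and the counts
#'   `n_cbp`, `n_non_cbp_paralog_wide`, `n_candidates`.
#' @export
summarize_headline <- function(candidates,
                               paralog_wide_branches = c("UV-C", "UV-D", "LW-C", "LW-E")) {
  stopifnot(length(paralog_wide_branches) > 0)
  out <- list()
  for (gc in unique(candidates$gene_class)) {
    g <- candidates[candidates$gene_class == gc, , drop = FALSE]
    cbp <- g$site[g$in_cbp]
    wide <- vapply(g$branches, function(b) length(intersect(b, paralog_wide_branches)) > 0, TRUE)
    non_cbp_wide <- g$site[!g$in_cbp & wide]
    out[[gc]] <- list(cbp_sites = cbp,
                      non_cbp_paralog_wide_sites = non_cbp_wide,
                      n_cbp = length(cbp),
                      n_non_cbp_paralog_wide = length(non_cbp_wide),
                      n_candidates = nrow(g))
  }
  out
}

#' @export
print.tuning_screen <- function(x, ...) {
  cat("Candidate spectral-tuning sites:", nrow(x), "\n")
  for (gc in unique(x$gene_class)) {
    g <- x[x$gene_class == gc, ]
    cat(sprintf("  %s (%d): %s\n", gc, nrow(g), paste(g$site, collapse = ", ")))
  }
  invisible(x)
}

#' @method summary tuning_screen
#' @export
summary.tuning_screen <- function(object, ...) {
  hl <- summarize_headline(object, ...)
  for (gc in names(hl)) {
    h <- hl[[gc]]
    cat(sprintf("%s: %d candidates; %d in binding pocket {%s}; %d non-pocket paralog-wide {%s}\n",
                gc, h$n_candidates, h$n_cbp, paste(h$cbp_sites, collapse = ","),
                h$n_non_cbp_paralog_wide,
                paste(h$non_cbp_paralog_wide_sites, collapse = ",")))
  }
  invisible(hl)
}

#' Render the candidate report
#'
#' One row per candidate site with gene class, site, region, pocket flag,
#' residue pairs, structural labels, positive-selection branches, literature
#' keys and the criteria that fired; rows ordered by gene class then numeric
#' site (insertions after their anchor).
#'
#' @param candidates A `tuning_screen`.
#' @param path Optional TSV output path.
#' @return The report data frame (invisibly when written to `path`).
#' @export
render_report <- function(candidates, path = NULL) {
  fmt <- function(l) vapply(l, function(v) if (length(v)) paste(v, collapse = ";") else ".", "")
  rep <- data.frame(
    gene_class = candidates$gene_class,
    site = candidates$site,
    region = candidates$region,
    in_cbp = as.integer(candidates$in_cbp),
    pairs = fmt(candidates$pairs),
    structural_labels = fmt(candidates$labels),
    ps_branches = fmt(candidates$branches),
    lit_ps = fmt(candidates$lit_ps),
    lit_shift = fmt(candidates$lit_shift),
    criteria = apply(cbind(candidates$crit_ps, candidates$crit_literature,
                           candidates$crit_pocket), 1,
                     function(v) paste(which(v), collapse = ",")),
    stringsAsFactors = FALSE)
  if (nrow(rep)) {
    ord <- unlist(lapply(split(seq_len(nrow(rep)),
                               factor(rep$gene_class, levels = c("UVS", "LWS"))),
                         function(ix) ix[order_site_labels(rep$site[ix])]),
                  use.names = FALSE)
    rep <- rep[ord, ]
    rownames(rep) <- NULL
  }
  if (!is.null(path)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("# candidate spectral-tuning sites; criteria: 1=PS 2=literature 3=pocket+structure", con)
    utils::write.table(rep, con, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep))
  }
  rep
}

#' Branch label to foreground lineage map
#'
#' @param path Optional alternate TSV.
#' @return Data frame with columns branch, gene_class, paralog_wide, lineage.
#' @export
branch_lineages <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "branch_lineages.tsv", package = "opsinsites")
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
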