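#' Hypergeometric gene-set overlap test
#'
#' Annotates a response gene list against a reference gene set: overlap
#' count, percent of the list (rounded to integer, as printed in
#' functional-annotation tables), and the hypergeometric upper-tail
#' enrichment p-value given the gene universe size.
#'
#' @param gene_list character vector (the response list).
#' @param set a [gene_set()] or character vector (the annotation set,
#'   assumed to lie within the universe).
#' @param universe integer, number of genes in the testable universe.
#' @return list with `k` (overlap), `n_list`, `n_set`, `fraction`
#'   (integer percent of the list) and `hypergeom_p`.
#' @examples
#' overlap_fraction(144, 313)  # 46
#' @export
overlap_test <- function(gene_list, set, universe) {
  members <- if (inherits(set, "gene_set")) set$members else unique(set)
  gene_list <- unique(gene_list)
  if (universe < length(gene_list) || universe < length(members)) {
    stop_ldsig("universe smaller than the list or the set")
  }
  k <- length(intersect(gene_list, members))
  p <- stats::phyper(k - 1L, length(members), universe - length(members),
                     length(gene_list), lower.tail = FALSE)
  list(k = k, n_list = length(gene_list), n_set = length(members),
       fraction = overlap_fraction(k, length(gene_list)),
       hypergeom_p = p)
}

#' @rdname overlap_test
#' @param k overlap count.
#' @param n_list list size.
#' @export
overlap_fraction <- function(k, n_list) as.integer(round(100 * k / n_list))

#' Cross-species direction concordance
#'
#' A gene's response is concordant when it is up-regulated in the
#' sensitive strain, down-regulated or unchanged in the resistant strain,
#' and up in the human comparator set -- or the full mirror image (down,
#' up-or-unchanged, down).  "Unchanged" (`ns`) means the gene failed the
#' low-dose list criteria, not a tested equivalence.  Genes the human set
#' marks as changing in both directions are never concordant and are
#' counted separately.
#'
#' @param sensitive,resistant direction maps for the two mouse strains:
#'   named vectors with values `"up"`/`"down"`; genes absent from a map
#'   are treated as `ns`.  Typically built from [gene_list()] output via
#'   [direction_map()].
#' @param human a directed [gene_set()] (+1 up, -1 down); members listed
#'   with both signs in the source may be supplied via `human_both`.
#' @param human_both optional character vector of genes with evidence for
#'   both up- and down-regulation in the human comparator.
#' @param categories optional named character vector mapping gene ->
#'   functional category for the count split.
#' @return A `concordance_result`: data.frame with one row per human-set
#'   gene (`gene`, `dir_sensitive`, `dir_resistant`, `dir_human`,
#'   `concordant`), plus attributes `n_concordant` and `by_category`.
#' @export
concordance <- function(sensitive, resistant, human, human_both = character(0),
                        categories = NULL) {
  stopifnot(inherits(human, "gene_set"))
  if (is.null(human$directions)) {
    stop_ldsig("human comparator set must be directed")
  }
  genes <- human$members
  dir_of <- function(map, g) {
    if (g %in% names(map)) unname(map[g]) else "ns"
  }
  dir_s <- vapply(genes, dir_of, character(1), map = sensitive)
  dir_r <- vapply(genes, dir_of, character(1), map = resistant)
  dir_h <- ifelse(genes %in% human_both, "both",
                  ifelse(human$directions[genes] > 0, "up", "down"))
  conc <- (dir_s == "up" & dir_r %in% c("down", "ns") & dir_h == "up") |
    (dir_s == "down" & dir_r %in% c("up", "ns") & dir_h == "down")
  out <- data.frame(gene = genes, dir_sensitive = dir_s,
                    dir_resistant = dir_r, dir_human = dir_h,
                    concordant = conc, row.names = NULL,
                    stringsAsFactors = FALSE)
  by_cat <- NULL
  if (!is.null(categories)) {
    cat_of <- ifelse(genes %in% names(categories),
                     categories[genes], "uncategorized")
    by_cat <- tapply(conc, cat_of, sum)
  }
  structure(out, class = c("concordance_result", "data.frame"),
            n_concordant = sum(conc), by_category = by_cat,
            n_both = sum(dir_h == "both"))
}

#' Direction map from an up/down gene list
#'
#' @param lists output of [gene_list()] (list with `up` and `down`).
#' @return named character vector gene -> "up"/"down" for use in
#'   [concordance()].
#' @export
direction_map <- function(lists) {
  stats::setNames(c(rep("up", length(lists$up)),
                    rep("down", length(lists$down))),
                  c(lists$up, lists$down))
}
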