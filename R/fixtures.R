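#' Packaged fixtures of the published COA and dose-response tables
#'
#' The package ships plain-text transcriptions of four printed tables from
#' the motivating study: the 55-gene cancer-outcome-associated (COA) set of
#' the systemic baseline signature, the 36-gene COA set of the sensitive
#' strain's 1-month low-dose signature, the 28-row low-dose "thresholded"
#' gene table, and the functional-overlap counts of the early low-dose
#' response list.  Duplicate category rows (RPS6, SUPT16H appear under two
#' categories) are preserved so row counts match the published layout.
#'
#' @param which one of `"baseline"` (55-gene COA table) or `"ld_1month"`
#'   (36-gene COA table).
#' @return [load_coa_fixture()] returns a `coa_fixture` data.frame with
#'   columns `gene`, `probe_id`, `p_value`, `category`,
#'   `lower_in_above_median`.
#' @export
load_coa_fixture <- function(which = c("baseline", "ld_1month")) {
  which <- match.arg(which)
  file <- switch(which,
                 baseline  = "table2_coa_baseline.tsv",
                 ld_1month = "table3_coa_1month.tsv")
  path <- system.file("extdata", file, package = "ldsig", mustWork = TRUE)
  tab <- utils::read.delim(path, colClasses = c(
    gene = "character", probe_id = "character", p_value = "numeric",
    category = "character", lower_in_above_median = "logical"))
  validate_coa_fixture(tab)
  class(tab) <- c("coa_fixture", "data.frame")
  tab
}

validate_coa_fixture <- function(tab) {
  required <- c("gene", "probe_id", "p_value", "category",
                "lower_in_above_median")
  if (!all(required %in% names(tab))) {
    stop_ldsig("COA fixture lacks column(s): %s",
               paste(setdiff(required, names(tab)), collapse = ", "))
  }
  if (any(tab$p_value <= 0 | tab$p_value >= 1)) {
    stop_ldsig("COA fixture p-values must lie in (0, 1)")
  }
  ok_cat <- c("rna_processing", "stress_response", "mitosis", "other")
  if (!all(tab$category %in% ok_cat)) {
    stop_ldsig("unknown COA category: %s",
               paste(setdiff(tab$category, ok_cat), collapse = ", "))
  }
  # the inverse flag is a property of the gene, not of the category row
  flag_by_gene <- tapply(tab$lower_in_above_median, tab$gene,
                         function(v) length(unique(v)))
  if (any(flag_by_gene > 1L)) {
    stop_ldsig("inconsistent lower_in_above_median flag for gene(s): %s",
               paste(names(flag_by_gene)[flag_by_gene > 1L], collapse = ", "))
  }
  invisible(tab)
}

#' Summarize a COA fixture table
#'
#' Counts match the published presentation: unique genes deduplicate by
#' symbol across categories, inverse genes are those flagged as expressed
#' at lower levels in the above-median patient group, and per-category
#' counts are row counts (not deduplicated).
#'
#' @param table a `coa_fixture` data.frame (see [load_coa_fixture()]).
#' @return list with `n_rows`, `n_unique_genes`, `n_inverse_genes`,
#'   `per_category_row_counts` (named integer vector), `min_p`, `max_p`.
#' @examples
#' summarize_coa_fixture(load_coa_fixture("baseline"))$n_unique_genes  # 55
#' @export
summarize_coa_fixture <- function(table) {
  if (!nrow(table)) stop_ldsig("empty COA table")
  validate_coa_fixture(table)
  inverse <- unique(table$gene[table$lower_in_above_median])
  list(n_rows = nrow(table),
       n_unique_genes = length(unique(table$gene)),
       n_inverse_genes = length(inverse),
       per_category_row_counts = c(table(table$category)),
       min_p = min(table$p_value),
       max_p = max(table$p_value))
}

#' @rdname load_coa_fixture
#' @return [load_thresholded_fixture()] returns a data.frame of per-gene
#'   log2 fold changes versus sham for sensitive/resistant strain at low
#'   and high dose; `NA` marks a non-significant (unreported) response.
#' @export
load_thresholded_fixture <- function() {
  path <- system.file("extdata", "table4_thresholded.tsv",
                      package = "ldsig", mustWork = TRUE)
  tab <- utils::read.delim(path, colClasses = "character")
  for (col in c("sensitive_ld", "sensitive_hd", "resistant_ld",
                "resistant_hd")) {
    v <- tab[[col]]
    v[tolower(v) == "ns"] <- NA
    tab[[col]] <- as.numeric(v)
  }
  tab
}

#' @rdname load_coa_fixture
#' @return [load_overlap_fixture()] returns a data.frame with columns
#'   `gene_function`, `overlap`, `list_size` (printed annotation-overlap
#'   counts for the early low-dose response list).
#' @export
load_overlap_fixture <- function() {
  path <- system.file("extdata", "table1_overlap.tsv",
                      package = "ldsig", mustWork = TRUE)
  utils::read.delim(path, colClasses = c(gene_function = "character",
                                         overlap = "integer",
                                         list_size = "integer"))
}
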