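#' Derive the cross-tissue systemic baseline signature
#'
#' A gene belongs to the systemic signature when the strain difference
#' (sensitive minus resistant, log2) is significant and at least
#' 1.5-fold in BOTH blood and mammary gland, with the same sign in the
#' two tissues.  Genes differential in only one tissue are excluded:
#' single-tissue strain differences did not carry the downstream survival
#' association, so the cross-tissue ("systemic") requirement is the core
#' of the definition.  The squared Pearson correlation of the qualifying
#' genes' blood versus mammary log-ratios is reported descriptively.
#'
#' @param blood,mg `gene_contrast` data.frames (strain contrasts in blood
#'   and mammary gland) over the same gene universe.
#' @param p_cut per-tissue p cutoff.
#' @param fc_cut per-tissue fold-change floor (log2).
#' @return A `systemic_signature`: list with `genes` (data.frame of
#'   `symbol`, `blood_log2_ratio`, `mg_log2_ratio`, `direction`) and
#'   `r_squared` (NA with a warning when fewer than 3 genes qualify).
#' @export
derive_systemic_signature <- function(blood, mg, p_cut = 0.05,
                                      fc_cut = log2(1.5)) {
  if (!identical(sort(blood$gene), sort(mg$gene))) {
    stop_ldsig("blood and mammary contrasts must cover the same genes")
  }
  mg <- mg[match(blood$gene, mg$gene), ]
  pass <- blood$p_value <= p_cut & mg$p_value <= p_cut &
    abs(blood$log2_fc) >= fc_cut & abs(mg$log2_fc) >= fc_cut &
    sign(blood$log2_fc) == sign(mg$log2_fc)
  genes <- data.frame(symbol = blood$gene[pass],
                      blood_log2_ratio = blood$log2_fc[pass],
                      mg_log2_ratio = mg$log2_fc[pass],
                      direction = sign(blood$log2_fc[pass]),
                      row.names = NULL, stringsAsFactors = FALSE)
  genes <- genes[order(genes$symbol), ]
  rownames(genes) <- NULL
  if (nrow(genes) >= 3L) {
    r2 <- stats::cor(genes$blood_log2_ratio, genes$mg_log2_ratio)^2
  } else {
    warning("fewer than 3 qualifying genes; r_squared undefined",
            call. = FALSE)
    r2 <- NA_real_
  }
  structure(list(genes = genes, r_squared = r2,
                 p_cut = p_cut, fc_cut = fc_cut),
            class = "systemic_signature")
}

#' @export
print.systemic_signature <- function(x, ...) {
  cat(sprintf("systemic_signature: %d genes (p <= %g, |log2 fc| >= %.3f), r^2 = %s\n",
              nrow(x$genes), x$p_cut, x$fc_cut,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.3f", x$r_squared))))
  invisible(x)
}

#' Negative-control signature of least-differential genes
#'
#' Selects the k genes with the least strain-differential expression in
#' both tissues: those minimizing max(|blood log2 fc|, |mammary log2 fc|).
#' Ties break by the larger of the two p-values (least significant first),
#' then lexicographic symbol.  Used as a size-matched null signature whose
#' downstream survival association should be indistinguishable from chance.
#'
#' @param blood,mg `gene_contrast` data.frames over the same gene universe.
#' @param k number of control genes.
#' @return character vector of k gene symbols.
#' @export
negative_control_signature <- function(blood, mg, k) {
  if (k > nrow(blood)) stop_ldsig("k exceeds the gene universe")
  mg <- mg[match(blood$gene, mg$gene), ]
  worst_fc <- pmax(abs(blood$log2_fc), abs(mg$log2_fc))
  worst_p <- pmax(blood$p_value, mg$p_value)
  ord <- order(worst_fc, -worst_p, blood$gene)
  blood$gene[ord][seq_len(k)]
}

#' Export a systemic signature as a directed gene set
#'
#' @param signature a `systemic_signature`.
#' @return a [gene_set()] with +1/-1 member directions (sign of the
#'   sensitive-minus-resistant ratio).
#' @export
signature_gene_set <- function(signature) {
  stopifnot(inherits(signature, "systemic_signature"))
  gene_set("systemic_baseline", signature$genes$symbol,
           directions = stats::setNames(signature$genes$direction,
                                        signature$genes$symbol),
           description = "cross-tissue strain-baseline signature")
}
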