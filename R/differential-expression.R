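#' Welch's unequal-variance t-test
#'
#' Two-sided t-test with Welch-Satterthwaite degrees of freedom, the one
#' two-group test used throughout the package (baseline strain contrasts,
#' dose contrasts, COA refinement, micronucleus baseline comparison).
#' Degenerate input where both groups have zero variance and equal means
#' returns p = 1 by convention.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with `t_stat`, `df`, `p_value`.
#' @examples
#' welch_t(c(1, 2, 3, 4), c(3, 4, 5, 6))
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop_ldsig("welch_t needs at least 2 observations per group")
  }
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t_stat = 0, df = length(x) + length(y) - 2, p_value = 1))
    }
    stop_ldsig("zero variance in both groups with unequal means")
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

# Row-wise Welch t for a genes x samples matrix split into two column sets.
# Returns a data.frame; vectorized so whole-study contrasts stay fast.
row_welch <- function(values, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(values[, idx_a, drop = FALSE])
  mb <- rowMeans(values[, idx_b, drop = FALSE])
  va <- rowSums((values[, idx_a, drop = FALSE] - ma)^2) / (na - 1L)
  vb <- rowSums((values[, idx_b, drop = FALSE] - mb)^2) / (nb - 1L)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  # both-groups-constant convention: equal means -> t = 0, p = 1
  degen <- va == 0 & vb == 0
  tt[degen & ma == mb] <- 0
  p[degen & ma == mb] <- 1
  df[degen] <- na + nb - 2L
  data.frame(gene = rownames(values), log2_fc = ma - mb,
             t_stat = tt, df = df, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene two-group contrast
#'
#' Computes, for every gene, the log2 fold change (mean of group A minus
#' mean of group B on the stored log2 scale), the Welch t statistic and its
#' two-sided p-value, plus Benjamini-Hochberg q-values reported alongside
#' for information (gene listing itself uses raw graded p cutoffs).
#'
#' @param study an [expression_study()].
#' @param group_a,group_b named filter lists selecting disjoint non-empty
#'   sample groups, e.g. `list(strain = "sensitive", dose = "sham")`.
#' @return A `gene_contrast` data.frame with columns `gene`, `log2_fc`,
#'   `t_stat`, `df`, `p_value`, `q_value`, `direction`; one row per gene.
#' @export
contrast <- function(study, group_a, group_b) {
  stopifnot(inherits(study, "expression_study"))
  sel_a <- sample_filter(study, group_a)
  sel_b <- sample_filter(study, group_b)
  if (!any(sel_a) || !any(sel_b)) stop_ldsig("empty sample selection")
  if (any(sel_a & sel_b)) stop_ldsig("group filters overlap")
  out <- row_welch(study$values, which(sel_a), which(sel_b))
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- sign(out$log2_fc)
  class(out) <- c("gene_contrast", "data.frame")
  out
}

#' Graded-threshold gene lists
#'
#' Response gene lists are built on a fold-change floor of 1.5-fold
#' (|log2 fc| >= log2 1.5) with a dose-graded p cutoff: 0.01 at high dose,
#' 0.1 at low dose, and 0.05 for baseline strain contrasts.  The laxer
#' low-dose cutoff reflects the smaller effect sizes expected below 10 cGy.
#'
#' @param contrasts a `gene_contrast` data.frame from [contrast()].
#' @param dose one of `"LD"`, `"HD"`, `"baseline"`; sets the p cutoff.
#' @param fc_cut fold-change floor on the log2 scale.
#' @param p_cut override the dose-implied p cutoff.
#' @return list with `up`, `down` (character vectors of gene symbols) and
#'   the `p_cut`/`fc_cut` actually applied.
#' @export
gene_list <- function(contrasts, dose = c("LD", "HD", "baseline"),
                      fc_cut = log2(1.5), p_cut = NULL) {
  dose <- match.arg(dose)
  if (is.null(p_cut)) {
    p_cut <- switch(dose, HD = 0.01, LD = 0.1, baseline = 0.05)
  }
  pass <- abs(contrasts$log2_fc) >= fc_cut & contrasts$p_value <= p_cut
  list(up = contrasts$gene[pass & contrasts$log2_fc > 0],
       down = contrasts$gene[pass & contrasts$log2_fc < 0],
       p_cut = p_cut, fc_cut = fc_cut)
}

#' Dose-response nonlinearity classification
#'
#' Classifies genes by the shape of their low- versus high-dose responses
#' across the sensitive and resistant strains at one time point:
#' \describe{
#'   \item{thresholded}{significant high-dose response in the same
#'     direction in both strains, low-dose significant in the sensitive
#'     strain only — evidence of a genotype-dependent low-dose induction
#'     threshold.}
#'   \item{plateau}{low and high dose significant in the sensitive strain,
#'     same direction, with |log2 fc| ratio within `plateau_band` —
#'     a response that saturates below the high dose.}
#'   \item{opposite}{low and high dose significant in the sensitive strain
#'     with opposing signs.}
#'   \item{other}{everything else.}
#' }
#' Significance uses the dose-graded criteria of [gene_list()].
#'
#' @param sensitive_ld,sensitive_hd,resistant_ld,resistant_hd
#'   `gene_contrast` data.frames over the same gene universe (dose vs sham
#'   within strain).
#' @param fc_cut fold-change floor (log2).
#' @param plateau_band two-element numeric, the allowed LD/HD magnitude
#'   ratio for a plateau call; symmetric on the log scale by default.
#' @return data.frame with per-gene condition log2 fold changes,
#'   significance flags and `class`.
#' @export
classify_dose_response <- function(sensitive_ld, sensitive_hd,
                                   resistant_ld, resistant_hd,
                                   fc_cut = log2(1.5),
                                   plateau_band = c(2 / 3, 3 / 2)) {
  genes <- sensitive_ld$gene
  for (d in list(sensitive_hd, resistant_ld, resistant_hd)) {
    if (!identical(d$gene, genes)) {
      stop_ldsig("contrasts must cover the same gene universe in order")
    }
  }
  sig <- function(con, p_cut) {
    abs(con$log2_fc) >= fc_cut & con$p_value <= p_cut
  }
  s_ld <- sig(sensitive_ld, 0.1);  s_hd <- sig(sensitive_hd, 0.01)
  r_ld <- sig(resistant_ld, 0.1);  r_hd <- sig(resistant_hd, 0.01)
  f_s_ld <- sensitive_ld$log2_fc; f_s_hd <- sensitive_hd$log2_fc
  f_r_ld <- resistant_ld$log2_fc; f_r_hd <- resistant_hd$log2_fc

  thresholded <- s_hd & r_hd & sign(f_s_hd) == sign(f_r_hd) & s_ld &
    sign(f_s_ld) == sign(f_s_hd) & !r_ld
  ratio <- abs(f_s_ld) / abs(f_s_hd)
  plateau <- s_ld & s_hd & sign(f_s_ld) == sign(f_s_hd) &
    ratio >= plateau_band[1L] & ratio <= plateau_band[2L]
  opposite <- s_ld & s_hd & sign(f_s_ld) != sign(f_s_hd) &
    sign(f_s_ld) != 0 & sign(f_s_hd) != 0

  cls <- rep("other", length(genes))
  cls[plateau] <- "plateau"
  cls[opposite] <- "opposite"
  cls[thresholded] <- "thresholded"  # thresholded takes precedence
  data.frame(gene = genes, class = cls,
             sensitive_ld = f_s_ld, sensitive_hd = f_s_hd,
             resistant_ld = f_r_ld, resistant_hd = f_r_hd,
             sig_sensitive_ld = s_ld, sig_sensitive_hd = s_hd,
             sig_resistant_ld = r_ld, sig_resistant_hd = r_hd,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify dose-response rows given precomputed fold changes
#'
#' Variant of [classify_dose_response()] for tables where significance is
#' already encoded: an `NA` fold change means not significantly modulated
#' (the "ns" entries of published fold-change tables).
#'
#' @param tab data.frame with numeric columns `sensitive_ld`,
#'   `sensitive_hd`, `resistant_ld`, `resistant_hd`; `NA` = ns.
#' @param plateau_band allowed LD/HD magnitude ratio for a plateau call.
#' @return character vector of classes, one per row.
#' @export
classify_fc_rows <- function(tab, plateau_band = c(2 / 3, 3 / 2)) {
  apply_row <- function(s_ld, s_hd, r_ld, r_hd) {
    sig <- function(v) !is.na(v)
    if (sig(s_hd) && sig(r_hd) && sign(s_hd) == sign(r_hd) &&
        sig(s_ld) && sign(s_ld) == sign(s_hd) && !sig(r_ld)) {
      return("thresholded")
    }
    if (sig(s_ld) && sig(s_hd) && sign(s_ld) != sign(s_hd)) {
      return("opposite")
    }
    if (sig(s_ld) && sig(s_hd)) {
      r <- abs(s_ld) / abs(s_hd)
      if (r >= plateau_band[1L] && r <= plateau_band[2L]) return("plateau")
    }
    "other"
  }
  vapply(seq_len(nrow(tab)), function(i) {
    apply_row(tab$sensitive_ld[i], tab$sensitive_hd[i],
              tab$resistant_ld[i], tab$resistant_hd[i])
  }, character(1))
}

#' Paired comparison of response magnitudes
#'
#' Tests whether two sets of |log2 fold change| magnitudes differ, e.g.
#' the resistant strain's high-dose responses against the sensitive
#' strain's high-dose (or low-dose) responses over a shared gene set.
#' Paired mode is a two-sided paired t-test on the absolute values.
#'
#' @param values_a,values_b numeric vectors of log2 fold changes.
#' @param paired compare gene-by-gene (vectors aligned over the same gene
#'   set) or as independent samples.
#' @return list with `t_stat`, `df`, `p_value`, `mean_abs_a`, `mean_abs_b`.
#' @export
magnitude_comparison <- function(values_a, values_b, paired = TRUE) {
  if (paired && length(values_a) != length(values_b)) {
    stop_ldsig("paired comparison needs equal-length vectors")
  }
  a <- abs(values_a); b <- abs(values_b)
  if (paired && stats::var(a - b) == 0) {
    return(list(t_stat = 0, df = length(a) - 1, p_value = 1,
                mean_abs_a = mean(a), mean_abs_b = mean(b)))
  }
  ht <- stats::t.test(a, b, paired = paired)
  list(t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_abs_a = mean(a), mean_abs_b = mean(b))
}
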