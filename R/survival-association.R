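#' Survival cohort container
#'
#' Patient-by-gene expression (stored genes x patients) with right-censored
#' follow-up: `time` is follow-up in arbitrary units, `event` is 1 for a
#' disease event/death and 0 for censoring.
#'
#' @param expression numeric matrix, genes x patients, with gene rownames
#'   and patient-id colnames.
#' @param time non-negative numeric follow-up per patient.
#' @param event logical/0-1 event indicator per patient.
#' @return A `survival_cohort` object.
#' @export
survival_cohort <- function(expression, time, event) {
  if (!is.matrix(expression) || is.null(rownames(expression)) ||
      is.null(colnames(expression))) {
    stop_ldsig("expression must be a matrix with gene and patient names")
  }
  n <- ncol(expression)
  if (length(time) != n || length(event) != n) {
    stop_ldsig("time/event length must equal the number of patients")
  }
  if (any(time < 0)) stop_ldsig("negative follow-up time")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop_ldsig("event must be 0/1")
  structure(list(expression = expression, time = as.numeric(time),
                 event = event, patient_ids = colnames(expression)),
            class = "survival_cohort")
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d genes x %d patients, %d events (%.0f%% censored)\n",
              nrow(x$expression), ncol(x$expression), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' Read / write a survival cohort as TSV
#'
#' The expression file mirrors the expression-study layout (gene column +
#' one column per patient); the clinical file has columns `patient_id`,
#' `time`, `event`.
#'
#' @param expr_path,clinical_path file paths.
#' @export
read_survival_cohort <- function(expr_path, clinical_path) {
  raw <- utils::read.delim(expr_path, check.names = FALSE)
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  rownames(mat) <- raw[[1L]]
  clin <- utils::read.delim(clinical_path)
  clin <- clin[match(colnames(mat), as.character(clin$patient_id)), ]
  if (any(is.na(clin$time))) stop_ldsig("clinical data missing for a patient")
  survival_cohort(mat, clin$time, clin$event)
}

#' @rdname read_survival_cohort
#' @param cohort a `survival_cohort`.
#' @export
write_survival_cohort <- function(cohort, expr_path, clinical_path) {
  stopifnot(inherits(cohort, "survival_cohort"))
  tab <- data.frame(gene = rownames(cohort$expression), cohort$expression,
                    check.names = FALSE)
  utils::write.table(tab, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  clin <- data.frame(patient_id = cohort$patient_ids, time = cohort$time,
                     event = cohort$event)
  utils::write.table(clin, clinical_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expr_path, clinical_path))
}

#' Per-patient signature sum-score
#'
#' For each patient, sums the (optionally standardized) expression of the
#' signature genes.  `zscore` mode standardizes each gene across patients
#' before summing, making the sum scale-free across genes; `raw` sums the
#' stored intensities.  Optional +1/-1 directions multiply each gene's
#' contribution, so a "risky-when-low" subset can be scored with -1 signs.
#' Genes absent from the cohort are skipped with a warning; a gene with
#' zero variance contributes 0 in zscore mode (with a warning).
#'
#' @param cohort a [survival_cohort()].
#' @param genes character vector of (human) gene symbols.
#' @param directions optional named +1/-1 vector keyed by gene.
#' @param normalization `"zscore"` or `"raw"`.
#' @return numeric score vector, one per patient, named by patient id.
#' @export
signature_score <- function(cohort, genes, directions = NULL,
                            normalization = c("zscore", "raw")) {
  stopifnot(inherits(cohort, "survival_cohort"))
  normalization <- match.arg(normalization)
  present <- genes[genes %in% rownames(cohort$expression)]
  missing <- setdiff(genes, present)
  if (!length(present)) stop_ldsig("none of the signature genes are in the cohort")
  if (length(missing)) {
    warning(sprintf("%d signature gene(s) absent from cohort: %s",
                    length(missing),
                    paste(utils::head(missing, 5), collapse = ", ")),
            call. = FALSE)
  }
  expr <- cohort$expression[present, , drop = FALSE]
  if (normalization == "zscore") {
    mu <- rowMeans(expr)
    sdv <- apply(expr, 1L, stats::sd)
    zero <- sdv == 0
    if (any(zero)) {
      warning(sprintf("constant gene(s) contribute 0 to the score: %s",
                      paste(present[zero], collapse = ", ")), call. = FALSE)
      sdv[zero] <- Inf  # (x - mu)/Inf = 0
    }
    expr <- (expr - mu) / sdv
  }
  w <- rep(1, length(present))
  if (!is.null(directions)) {
    hit <- present %in% names(directions)
    w[hit] <- directions[present[hit]]
  }
  stats::setNames(colSums(expr * w), cohort$patient_ids)
}

#' Median split of a score vector
#'
#' Dichotomizes patients at the sample median of the score.  Scores
#' strictly above the median go to the `above` group; ties with the median
#' (and the median itself at odd n) go `below` — a deterministic rule that
#' matters on discrete scores.
#'
#' @param scores numeric vector, length >= 2.
#' @return A `score_split`: list with `score`, `group` (factor
#'   above/below) and `cut` (the median).
#' @export
median_split <- function(scores) {
  if (length(scores) < 2L) stop_ldsig("median split needs >= 2 scores")
  if (length(unique(scores)) == 1L) {
    stop_ldsig("all scores identical; median split undefined")
  }
  cut <- stats::median(scores)
  group <- factor(ifelse(scores > cut, "above", "below"),
                  levels = c("below", "above"))
  structure(list(score = scores, group = group, cut = cut),
            class = "score_split")
}

#' Kaplan-Meier product-limit estimate
#'
#' Standard product-limit estimator over distinct event times; subjects
#' censored at an event time are counted as at risk at that time (censored
#' after events, the usual convention).
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @return A `km_curve` data.frame with columns `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`, one row per distinct event time.
#' @examples
#' km_estimate(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3, 1/3, 0
#' @export
km_estimate <- function(time, event) {
  if (length(time) != length(event)) stop_ldsig("time/event length mismatch")
  if (any(time < 0)) stop_ldsig("negative follow-up time")
  event <- as.integer(event)
  times <- sort(unique(time[event == 1L]))
  n_risk <- n_event <- n_censor <- integer(length(times))
  surv <- numeric(length(times))
  s <- 1
  for (i in seq_along(times)) {
    tt <- times[i]
    n_risk[i] <- sum(time >= tt)
    n_event[i] <- sum(time == tt & event == 1L)
    n_censor[i] <- sum(time == tt & event == 0L)
    s <- s * (1 - n_event[i] / n_risk[i])
    surv[i] <- s
  }
  out <- data.frame(time = times, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events summed over distinct event times with
#' the hypergeometric variance, which handles tied event times; the
#' statistic is referred to chi-square on 1 df.  With zero events overall
#' the test is undefined and returns p = 1 with a warning.
#'
#' @param time1,event1 follow-up and event indicator for group 1.
#' @param time2,event2 follow-up and event indicator for group 2.
#' @return A `logrank_result`: list with `chi_sq`, `df` (= 1), `p_value`,
#'   `observed` and `expected` event counts per group.
#' @export
logrank_test <- function(time1, event1, time2, event2) {
  if (!length(time1) || !length(time2)) stop_ldsig("both groups must be non-empty")
  event1 <- as.integer(event1); event2 <- as.integer(event2)
  if (sum(event1) + sum(event2) == 0L) {
    warning("no events in either group; log-rank undefined, p = 1",
            call. = FALSE)
    return(structure(list(chi_sq = 0, df = 1L, p_value = 1,
                          observed = c(0, 0), expected = c(0, 0)),
                     class = "logrank_result"))
  }
  time <- c(time1, time2)
  event <- c(event1, event2)
  grp1 <- c(rep(TRUE, length(time1)), rep(FALSE, length(time2)))
  times <- sort(unique(time[event == 1L]))
  o1 <- e1 <- v <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & grp1)
    d <- sum(time == tt & event == 1L)
    d1 <- sum(time == tt & event == 1L & grp1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1L) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1L)
    }
  }
  chi <- if (v > 0) (o1 - e1)^2 / v else 0
  total <- sum(event)
  structure(list(chi_sq = chi, df = 1L,
                 p_value = stats::pchisq(chi, 1L, lower.tail = FALSE),
                 observed = c(o1, total - o1),
                 expected = c(e1, total - e1)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-sq = %.3f (df 1), p = %.3g\n",
              x$chi_sq, x$p_value))
  invisible(x)
}

#' Cancer-outcome-associated (COA) gene refinement
#'
#' Given a median split of the cohort on a signature sum-score, tests each
#' signature gene individually with a Welch t-test between the above- and
#' below-median patient groups.  Genes with p below `alpha` (default 0.01)
#' form the COA set; `direction` records whether the gene is expressed at
#' higher or lower levels in the above-median group, and the
#' `lower_in_above` subset is the analogue of the published 9-gene inverse
#' signature (risk-associated when down-regulated).
#'
#' @param cohort a [survival_cohort()].
#' @param split a [median_split()] of a score derived from the same cohort.
#' @param genes signature genes to test (those present in the cohort).
#' @param alpha per-gene significance cutoff.
#' @return A `coa_table` data.frame with columns `gene`, `t_stat`, `df`,
#'   `p_value`, `direction` for the genes passing `alpha`, ordered by
#'   p-value; attribute `tested` holds all per-gene results.
#' @export
coa_refine <- function(cohort, split, genes, alpha = 0.01) {
  stopifnot(inherits(cohort, "survival_cohort"),
            inherits(split, "score_split"))
  if (length(split$group) != ncol(cohort$expression)) {
    stop_ldsig("split does not match the cohort")
  }
  above <- split$group == "above"
  if (sum(above) < 2L || sum(!above) < 2L) {
    stop_ldsig("each patient group needs >= 2 members")
  }
  present <- genes[genes %in% rownames(cohort$expression)]
  if (!length(present)) stop_ldsig("no signature genes in the cohort")
  res <- row_welch(cohort$expression[present, , drop = FALSE],
                   which(above), which(!above))
  res$direction <- ifelse(res$log2_fc > 0, "higher_in_above",
                          "lower_in_above")
  keep <- res[res$p_value < alpha, c("gene", "t_stat", "df", "p_value",
                                     "direction")]
  keep <- keep[order(keep$p_value), ]
  rownames(keep) <- NULL
  structure(keep, class = c("coa_table", "data.frame"),
            tested = res, alpha = alpha)
}

#' End-to-end survival association of a mouse signature
#'
#' Composes the full chain: map the mouse signature to human orthologs,
#' sum-score each patient, split at the median score, estimate
#' Kaplan-Meier curves per group, compare them with the log-rank test,
#' refine to COA genes, and re-test the inverse (lower-in-above) COA
#' subset as a directed signature scored with -1 signs.
#'
#' @param cohort a [survival_cohort()].
#' @param mouse_signature character vector of mouse symbols, or a
#'   `systemic_signature` (its gene table is used).
#' @param table an [ortholog_table()].
#' @param normalization passed to [signature_score()].
#' @param coa_alpha passed to [coa_refine()].
#' @return A `survival_report`: list with `human_genes`, `dropped`,
#'   `score`, `split`, `km_above`, `km_below`, `logrank`, `coa`,
#'   `inverse_genes`, `inverse_logrank` (NULL when no inverse genes).
#' @export
survival_pipeline <- function(cohort, mouse_signature, table,
                              normalization = "zscore", coa_alpha = 0.01) {
  if (inherits(mouse_signature, "systemic_signature")) {
    mouse_signature <- mouse_signature$genes$symbol
  }
  mapped <- map_signature(mouse_signature, table)
  score <- signature_score(cohort, mapped$human_genes,
                           normalization = normalization)
  split <- median_split(score)
  above <- split$group == "above"
  km_above <- km_estimate(cohort$time[above], cohort$event[above])
  km_below <- km_estimate(cohort$time[!above], cohort$event[!above])
  lr <- logrank_test(cohort$time[above], cohort$event[above],
                     cohort$time[!above], cohort$event[!above])
  coa <- coa_refine(cohort, split, mapped$human_genes, alpha = coa_alpha)
  inverse <- coa$gene[coa$direction == "lower_in_above"]
  inverse_lr <- NULL
  if (length(inverse)) {
    inv_score <- signature_score(
      cohort, inverse,
      directions = stats::setNames(rep(-1, length(inverse)), inverse),
      normalization = normalization)
    inv_split <- median_split(inv_score)
    inv_above <- inv_split$group == "above"
    inverse_lr <- logrank_test(cohort$time[inv_above],
                               cohort$event[inv_above],
                               cohort$time[!inv_above],
                               cohort$event[!inv_above])
  }
  structure(list(human_genes = mapped$human_genes, dropped = mapped$dropped,
                 score = score, split = split, km_above = km_above,
                 km_below = km_below, logrank = lr, coa = coa,
                 inverse_genes = inverse, inverse_logrank = inverse_lr,
                 normalization = normalization),
            class = "survival_report")
}

#' @export
print.survival_report <- function(x, ...) {
  cat(sprintf("survival_report: %d human orthologs (%d mouse genes unmapped)\n",
              length(x$human_genes), length(x$dropped)))
  cat(sprintf("  normalization: %s; median cut %.3f (%d above / %d below)\n",
              x$normalization, x$split$cut, sum(x$split$group == "above"),
              sum(x$split$group == "below")))
  cat(sprintf("  log-rank chi-sq %.2f, p = %.3g; COA genes: %d (%d inverse)\n",
              x$logrank$chi_sq, x$logrank$p_value, nrow(x$coa),
              length(x$inverse_genes)))
  invisible(x)
}
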