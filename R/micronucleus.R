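#' Micronucleus count records and per-animal frequencies
#'
#' Micronucleated reticulocyte (RET) and normochromatic erythrocyte (NCE)
#' counts per animal, as produced by flow cytometry: `cells_scored` cells
#' examined, `mn_cells` of them micronucleated.  Frequencies are reported
#' per 10^4 cells scored.
#'
#' @param records data.frame with columns `animal_id`, `strain`, `dose`,
#'   `time_point`, `cell_class` (`RET`/`NCE`), `cells_scored`, `mn_cells`.
#' @return [mn_frequencies()] returns the records with an `freq` column
#'   (MN cells per 10^4 scored), order preserved.
#' @examples
#' rec <- data.frame(animal_id = "a1", strain = "sensitive", dose = "sham",
#'                   time_point = "t1", cell_class = "RET",
#'                   cells_scored = 20000, mn_cells = 30)
#' mn_frequencies(rec)$freq  # 15
#' @export
mn_frequencies <- function(records) {
  required <- c("animal_id", "strain", "dose", "time_point", "cell_class",
                "cells_scored", "mn_cells")
  miss <- setdiff(required, names(records))
  if (length(miss)) {
    stop_ldsig("MN records lack column(s): %s", paste(miss, collapse = ", "))
  }
  if (any(records$cells_scored <= 0)) stop_ldsig("cells_scored must be positive")
  if (any(records$mn_cells > records$cells_scored)) {
    stop_ldsig("mn_cells exceeds cells_scored")
  }
  records$freq <- 1e4 * records$mn_cells / records$cells_scored
  records
}

#' @rdname mn_frequencies
#' @param path TSV path.
#' @export
read_mn_records <- function(path) {
  utils::read.delim(path, colClasses = c(
    animal_id = "character", strain = "character", dose = "character",
    time_point = "character", cell_class = "character",
    cells_scored = "integer", mn_cells = "integer"))
}

#' @rdname mn_frequencies
#' @export
write_mn_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Baseline micronucleus frequency comparison between strains
#'
#' Percent difference of group A's mean frequency relative to group B,
#' with a two-tailed unequal-variance (Welch) t-test.
#'
#' @param freqs_a,freqs_b per-animal frequencies, >= 2 animals each.
#' @return list with `percent_diff` (100 * (mean_a - mean_b) / mean_b),
#'   `t_stat`, `df`, `p_value`.
#' @export
baseline_compare <- function(freqs_a, freqs_b) {
  if (length(freqs_a) < 2L || length(freqs_b) < 2L) {
    stop_ldsig("each group needs >= 2 animals")
  }
  if (mean(freqs_b) == 0) stop_ldsig("reference group mean is zero")
  tt <- welch_t(freqs_a, freqs_b)
  list(percent_diff = 100 * (mean(freqs_a) - mean(freqs_b)) / mean(freqs_b),
       t_stat = tt$t_stat, df = tt$df, p_value = tt$p_value)
}

#' Dunnett many-to-one comparisons by Monte Carlo
#'
#' Compares each treatment group against a shared control inside a
#' pooled-variance one-way ANOVA, adjusting the per-comparison two-sided
#' p-values for the family of k comparisons.  The reference distribution
#' of max_j |T_j| -- the joint null of k correlated t statistics sharing
#' the control mean and the pooled error variance -- is evaluated by
#' seeded Monte Carlo rather than from tabulated critical points: group
#' means are drawn as independent normals with variance 1/n_j, the pooled
#' variance as chi-square on the ANOVA error df, and the comparison
#' statistics assembled exactly as for the data.
#'
#' @param groups list of numeric vectors (treatment groups), each n >= 2.
#' @param control numeric vector, the control group.
#' @param n_mc number of Monte Carlo draws.
#' @param seed integer seed for the draw (global RNG state untouched).
#' @return data.frame with one row per treatment group: `group`, `n`,
#'   `mean_diff`, `t_stat`, `p_unadjusted`, `p_adjusted`.
#' @export
dunnett_vs_control <- function(groups, control, n_mc = 1e5, seed = 1L) {
  if (!length(groups)) stop_ldsig("need at least one treatment group")
  if (is.numeric(groups)) groups <- list(groups)
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L) || length(control) < 2L) {
    stop_ldsig("every group needs >= 2 observations")
  }
  k <- length(groups)
  n0 <- length(control)
  n_total <- sum(sizes) + n0
  df_err <- n_total - (k + 1L)
  mse <- (sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) +
            sum((control - mean(control))^2)) / df_err
  if (mse == 0) stop_ldsig("zero pooled variance")
  mean_diff <- vapply(groups, mean, numeric(1)) - mean(control)
  tt <- mean_diff / sqrt(mse * (1 / sizes + 1 / n0))
  p_unadj <- 2 * stats::pt(abs(tt), df_err, lower.tail = FALSE)

  max_t <- with_seed(seed, {
    z0 <- stats::rnorm(n_mc, sd = sqrt(1 / n0))
    s2 <- stats::rchisq(n_mc, df_err) / df_err
    m <- matrix(stats::rnorm(n_mc * k), n_mc, k)
    m <- sweep(m, 2L, sqrt(1 / sizes), `*`)
    tmat <- (m - z0) / sqrt(s2 %o% (1 / sizes + 1 / n0))
    apply(abs(tmat), 1L, max)
  })
  p_adj <- vapply(tt, function(t_i) mean(max_t >= abs(t_i)), numeric(1))
  p_adj <- pmax(p_adj, p_unadj)  # adjustment can only increase p
  data.frame(group = names(groups) %||% paste0("group", seq_len(k)),
             n = sizes, mean_diff = mean_diff, t_stat = tt,
             p_unadjusted = p_unadj, p_adjusted = p_adj,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Micronucleus dose-response analysis
#'
#' Fits one Dunnett family per cell class and time point, comparing each
#' dose group's per-animal frequencies against the sham control of the
#' same strain, plus the baseline strain comparison on sham animals.
#'
#' @param records MN count records (see [mn_frequencies()]).
#' @param n_mc,seed passed to [dunnett_vs_control()].
#' @return list with `dunnett` (data.frame over strain x cell class x
#'   time point x dose) and `baseline` (per cell class strain comparison
#'   at the earliest time point's sham animals).
#' @export
mn_analyze <- function(records, n_mc = 1e5, seed = 1L) {
  freqs <- mn_frequencies(records)
  out <- list()
  combos <- unique(freqs[, c("strain", "cell_class", "time_point")])
  for (i in seq_len(nrow(combos))) {
    sub <- freqs[freqs$strain == combos$strain[i] &
                   freqs$cell_class == combos$cell_class[i] &
                   freqs$time_point == combos$time_point[i], ]
    ctrl <- sub$freq[sub$dose == "sham"]
    doses <- setdiff(unique(sub$dose), "sham")
    if (!length(doses) || length(ctrl) < 2L) next
    groups <- lapply(doses, function(d) sub$freq[sub$dose == d])
    names(groups) <- doses
    dn <- dunnett_vs_control(groups, ctrl, n_mc = n_mc,
                             seed = child_seed(seed, i))
    dn$strain <- combos$strain[i]
    dn$cell_class <- combos$cell_class[i]
    dn$time_point <- combos$time_point[i]
    out[[length(out) + 1L]] <- dn
  }
  baseline <- lapply(split(freqs[freqs$dose == "sham", ],
                           freqs$cell_class[freqs$dose == "sham"]),
                     function(sub) {
    a <- sub$freq[sub$strain == "sensitive"]
    b <- sub$freq[sub$strain == "resistant"]
    if (length(a) >= 2L && length(b) >= 2L) baseline_compare(a, b) else NULL
  })
  list(dunnett = do.call(rbind, out), baseline = baseline)
}
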