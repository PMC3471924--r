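# Independent oracles used across the suite.  These deliberately use
# different algorithms (enumeration, permutation, closed forms, or an
# external package) from the implementation they check.

# Exact permutation p for the Welch t statistic over all label splits.
perm_welch_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  idx <- utils::combn(n, length(x))
  obs <- abs(welch_t(x, y)$t_stat)
  stats <- apply(idx, 2L, function(i) {
    abs(welch_t(pooled[i], pooled[-i])$t_stat)
  })
  mean(stats >= obs - 1e-12)
}

# Exact permutation p for the log-rank chi-square over all group splits.
perm_logrank_p <- function(time1, event1, time2, event2) {
  time <- c(time1, time2); event <- c(event1, event2)
  n <- length(time)
  idx <- utils::combn(n, length(time1))
  obs <- logrank_test(time1, event1, time2, event2)$chi_sq
  stats <- apply(idx, 2L, function(i) {
    logrank_test(time[i], event[i], time[-i], event[-i])$chi_sq
  })
  mean(stats >= obs - 1e-12)
}

# Hypergeometric upper tail by exhaustive enumeration of all subsets of
# size n_draw from a universe with n_white successes.
enum_hyper_p <- function(k, n_white, n_total, n_draw) {
  counts <- vapply(0:n_draw, function(j) {
    choose(n_white, j) * choose(n_total - n_white, n_draw - j)
  }, numeric(1))
  sum(counts[(k + 1):(n_draw + 1)]) / choose(n_total, n_draw)
}

# Hand product-limit computation for a small worked example.
hand_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  vapply(ts, function(tt) {
    d <- sum(time == tt & event == 1)
    r <- sum(time >= tt)
    s <<- s * (1 - d / r)
    s
  }, numeric(1))
}

# Brute-force triple-loop concordance count.
brute_concordance <- function(dir_s, dir_r, dir_h) {
  n <- 0L
  for (i in seq_along(dir_h)) {
    s <- dir_s[i]; r <- dir_r[i]; h <- dir_h[i]
    if (s == "up" && (r == "down" || r == "ns") && h == "up") n <- n + 1L
    else if (s == "down" && (r == "up" || r == "ns") && h == "down") n <- n + 1L
  }
  n
}

# Small deterministic expression study: 4 genes x 2 groups of 3 samples.
tiny_study <- function(values = NULL) {
  genes <- c("Parp3", "Msh5", "Smc6", "Rad23a")
  ids <- c(paste0("s", 1:3), paste0("r", 1:3))
  if (is.null(values)) {
    values <- matrix(seq_len(24), 4, 6, dimnames = list(genes, ids))
    storage.mode(values) <- "double"
  } else {
    dimnames(values) <- list(genes, ids)
  }
  meta <- data.frame(sample_id = ids,
                     strain = rep(c("sensitive", "resistant"), each = 3),
                     tissue = "mammary", dose = "sham", time = "baseline",
                     replicate = rep(1:3, 2))
  expression_study(values, meta)
}
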