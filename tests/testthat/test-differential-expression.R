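test_that("welch_t matches the textbook formula and its conventions", {
  # degenerate convention: identical constant-variance-free comparison
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t_stat, 0)
  expect_equal(welch_t(c(5, 5), c(5, 5))$p_value, 1)
  expect_error(welch_t(1, c(1, 2)), "2 observations")
  expect_error(welch_t(c(5, 5), c(7, 7)), "zero variance")

  x <- c(1, 2, 3, 4); y <- c(3, 4, 5, 6)
  got <- welch_t(x, y)
  # independent hand computation of the Welch statistic and df
  se2 <- var(x) / 4 + var(y) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(se2)
  df_hand <- se2^2 / ((var(x) / 4)^2 / 3 + (var(y) / 4)^2 / 3)
  p_hand <- 2 * pt(abs(t_hand), df_hand, lower.tail = FALSE)
  expect_equal(got$t_stat, t_hand, tolerance = 1e-10)
  expect_equal(got$df, df_hand, tolerance = 1e-10)
  expect_equal(got$p_value, p_hand, tolerance = 1e-10)
})

test_that("welch_t p agrees with the exact permutation p at n = 4 + 4", {
  set.seed(42)
  x <- rnorm(4, 0, 1); y <- rnorm(4, 0.8, 1)
  p_perm <- perm_welch_p(x, y)
  p_t <- welch_t(x, y)$p_value
  # 70 splits give granularity 1/70; the asymptotic p should land within
  # a couple of grid steps of the exact permutation p
  expect_lt(abs(p_t - p_perm), 0.1)
})

test_that("contrast is antisymmetric, complete, and zero on copies", {
  study <- tiny_study(matrix(rnorm(24), 4, 6))
  a <- list(strain = "sensitive"); b <- list(strain = "resistant")
  ab <- contrast(study, a, b)
  ba <- contrast(study, b, a)
  expect_equal(ab$log2_fc, -ba$log2_fc)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(nrow(ab), nrow(study$values))
  expect_equal(ab$direction, sign(ab$log2_fc))

  # duplicated columns: group means equal gene by gene
  vals <- matrix(rnorm(12), 4, 3)
  study2 <- tiny_study(cbind(vals, vals))
  same <- contrast(study2, a, b)
  expect_equal(same$log2_fc, rep(0, 4))

  expect_error(contrast(study, a, a), "overlap")
  expect_error(contrast(study, list(strain = "none"), b), "empty")
})

test_that("contrast agrees with per-gene stats::t.test", {
  study <- tiny_study(matrix(rnorm(24, sd = 2), 4, 6))
  res <- contrast(study, list(strain = "sensitive"),
                  list(strain = "resistant"))
  for (i in 1:4) {
    ht <- t.test(study$values[i, 1:3], study$values[i, 4:6])
    expect_equal(res$p_value[i], ht$p.value, tolerance = 1e-12)
    expect_equal(res$t_stat[i], unname(ht$statistic), tolerance = 1e-12)
  }
})

test_that("gene_list applies graded dose cutoffs and is monotone", {
  con <- data.frame(gene = c("A", "B", "C"),
                    log2_fc = c(0.60, 0.60, 0.50),
                    p_value = c(0.05, 0.05, 0.001))
  # 0.60 >= log2(1.5) ~ 0.585, p 0.05 <= 0.1 -> in at LD
  expect_true("A" %in% gene_list(con, "LD")$up)
  # same gene excluded at HD (p > 0.01)
  expect_false("A" %in% unlist(gene_list(con, "HD")[c("up", "down")]))
  # below fold floor is out regardless of p
  expect_false("C" %in% unlist(gene_list(con, "LD")[c("up", "down")]))

  # monotonicity: relaxing either threshold never removes a gene
  set.seed(1)
  rnd <- data.frame(gene = sprintf("g%03d", 1:200),
                    log2_fc = rnorm(200), p_value = runif(200))
  strict <- gene_list(rnd, "LD", fc_cut = 0.8, p_cut = 0.02)
  laxer_p <- gene_list(rnd, "LD", fc_cut = 0.8, p_cut = 0.2)
  laxer_fc <- gene_list(rnd, "LD", fc_cut = 0.4, p_cut = 0.02)
  expect_true(all(strict$up %in% laxer_p$up))
  expect_true(all(strict$down %in% laxer_fc$down))
})

test_that("dose-response classes follow their definitions", {
  mk <- function(fc, p) data.frame(gene = c("g1", "g2", "g3", "g4"),
                                   log2_fc = fc, p_value = p)
  # g1: thresholded (published exemplar pattern: sensitive LD -1.23 /
  #     HD -1.84, resistant LD ns / HD -1.25)
  # g2: opposite within sensitive (+0.9 LD, -1.1 HD)
  # g3: plateau (0.70 vs 0.72)
  # g4: nothing
  s_ld <- mk(c(-1.23, 0.9, 0.70, 0.1), c(0.001, 0.001, 0.001, 0.9))
  s_hd <- mk(c(-1.84, -1.1, 0.72, 0.1), c(0.001, 0.001, 0.001, 0.9))
  r_ld <- mk(c(-0.05, 0.0, 0.0, 0.0), c(0.9, 0.9, 0.9, 0.9))
  r_hd <- mk(c(-1.25, 0.0, 0.0, 0.0), c(0.001, 0.9, 0.9, 0.9))
  cls <- classify_dose_response(s_ld, s_hd, r_ld, r_hd)
  expect_equal(cls$class, c("thresholded", "opposite", "plateau", "other"))

  # re-derivable from the stored flags and fold changes (idempotence)
  rebuilt <- classify_fc_rows(data.frame(
    sensitive_ld = ifelse(cls$sig_sensitive_ld, cls$sensitive_ld, NA),
    sensitive_hd = ifelse(cls$sig_sensitive_hd, cls$sensitive_hd, NA),
    resistant_ld = ifelse(cls$sig_resistant_ld, cls$resistant_ld, NA),
    resistant_hd = ifelse(cls$sig_resistant_hd, cls$resistant_hd, NA)))
  expect_equal(rebuilt, cls$class)
})

test_that("magnitude comparison detects shifts and is null on identity", {
  v <- rnorm(28)
  expect_equal(magnitude_comparison(v, v)$p_value, 1)
  set.seed(7)
  b <- abs(rnorm(28, 1, 0.1))
  a <- b + 0.5 + rnorm(28, 0, 0.1)
  expect_lt(magnitude_comparison(a, b)$p_value, 1e-6)
  expect_error(magnitude_comparison(1:3, 1:4), "equal-length")
})

test_that("paired magnitude p agrees with a sign-flip permutation oracle", {
  set.seed(11)
  a <- abs(rnorm(8, 1.2, 0.4)); b <- abs(rnorm(8, 1.0, 0.4))
  p_t <- magnitude_comparison(a, b)$p_value
  d <- a - b
  obs <- abs(mean(d) / (sd(d) / sqrt(8)))
  signs <- expand.grid(rep(list(c(-1, 1)), 8))
  p_perm <- mean(apply(signs, 1L, function(s) {
    ds <- d * s
    abs(mean(ds) / (sd(ds) / sqrt(8))) >= obs - 1e-12
  }))
  expect_lt(abs(p_t - p_perm), 0.1)
})
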