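mk_cohort <- function(expr, time, event) {
  dimnames(expr) <- list(sprintf("G%02d", seq_len(nrow(expr))),
                         sprintf("p%02d", seq_len(ncol(expr))))
  survival_cohort(expr, time, event)
}

test_that("signature scores are standardized sums with direction signs", {
  set.seed(3)
  expr <- matrix(rnorm(5 * 20, mean = 10, sd = 3), 5, 20)
  cohort <- mk_cohort(expr, rexp(20), rbinom(20, 1, 0.7))

  s1 <- signature_score(cohort, "G01")
  expect_equal(mean(s1), 0, tolerance = 1e-12)
  expect_equal(sd(s1), 1, tolerance = 1e-12)

  genes <- c("G01", "G02", "G03")
  undirected <- signature_score(cohort, genes)
  flipped <- signature_score(cohort, genes,
                             directions = setNames(rep(-1, 3), genes))
  expect_equal(flipped, -undirected)

  # invariant under per-gene affine transforms in zscore mode
  expr2 <- expr * c(2, 0.5, 3, 1, 10) + c(100, -4, 0, 7, 1)
  cohort2 <- mk_cohort(expr2, cohort$time, cohort$event)
  expect_equal(signature_score(cohort2, genes), undirected,
               tolerance = 1e-12)

  # constant gene contributes zero, with a warning
  expr3 <- expr; expr3[2, ] <- 5
  cohort3 <- mk_cohort(expr3, cohort$time, cohort$event)
  expect_warning(s3 <- signature_score(cohort3, genes), "constant")
  expect_equal(s3, signature_score(cohort, c("G01", "G03")))

  expect_warning(signature_score(cohort, c("G01", "NOPE")), "absent")
  expect_error(signature_score(cohort, "NOPE"), "none")
})

test_that("median split puts strict exceedance above, ties below", {
  s <- median_split(c(a = 1, b = 2, c = 3, d = 4))
  expect_equal(s$cut, 2.5)
  expect_equal(names(s$score)[s$group == "above"], c("c", "d"))

  s <- median_split(c(1, 2, 2, 3))
  expect_equal(s$cut, 2)
  expect_equal(sum(s$group == "above"), 1L)

  s <- median_split(c(1, 2, 3))
  expect_equal(s$cut, 2)
  expect_equal(sum(s$group == "above"), 1L)

  expect_error(median_split(rep(1, 5)), "identical")
  expect_error(median_split(3), ">= 2")
})

test_that("Kaplan-Meier estimate matches closed forms and survfit", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))

  # all censored: no event rows, survivor function constant 1
  expect_equal(nrow(km_estimate(c(1, 2, 3), c(0, 0, 0))), 0L)

  # worked example with censoring and ties against a hand computation
  time <- c(1, 2, 2, 3, 4, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1, 0, 1)
  km <- km_estimate(time, event)
  expect_equal(km$survival, hand_km(time, event), tolerance = 1e-12)

  # independent implementation: survival::survfit
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  expect_equal(km$survival, summary(fit)$surv, tolerance = 1e-12)
  expect_equal(km$n_risk, summary(fit)$n.risk)

  # no censoring: equals the empirical survivor function exactly
  set.seed(8)
  t2 <- rexp(40)
  km2 <- km_estimate(t2, rep(1, 40))
  emp <- vapply(km2$time, function(tt) mean(t2 > tt), numeric(1))
  expect_equal(km2$survival, emp, tolerance = 1e-12)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank matches survdiff, handles ties, and is symmetric", {
  set.seed(21)
  t1 <- round(rexp(30, 0.2), 1); e1 <- rbinom(30, 1, 0.8)
  t2 <- round(rexp(30, 0.4), 1); e2 <- rbinom(30, 1, 0.8)
  lr <- logrank_test(t1, e1, t2, e2)
  sd_fit <- survival::survdiff(
    survival::Surv(c(t1, t2), c(e1, e2)) ~ rep(1:2, each = 30))
  expect_equal(lr$chi_sq, sd_fit$chisq, tolerance = 1e-10)
  expect_equal(lr$observed, unname(sd_fit$obs), tolerance = 1e-10)
  expect_equal(lr$expected, unname(sd_fit$exp), tolerance = 1e-10)

  # relabeling invariance and non-negativity
  lr_swap <- logrank_test(t2, e2, t1, e1)
  expect_equal(lr_swap$chi_sq, lr$chi_sq, tolerance = 1e-12)
  expect_gte(lr$chi_sq, 0)

  # identical groups
  same <- logrank_test(t1, e1, t1, e1)
  expect_equal(same$chi_sq, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)

  # zero events -> p = 1 with a warning
  expect_warning(zero <- logrank_test(c(1, 2), c(0, 0), c(3), c(0)),
                 "no events")
  expect_equal(zero$p_value, 1)
})

test_that("log-rank p agrees with exact permutation at small n", {
  set.seed(13)
  t1 <- rexp(8, 0.2); e1 <- rbinom(8, 1, 0.9)
  t2 <- rexp(8, 0.35); e2 <- rbinom(8, 1, 0.9)
  p_perm <- perm_logrank_p(t1, e1, t2, e2)
  p_chi <- logrank_test(t1, e1, t2, e2)$p_value
  expect_lt(abs(p_chi - p_perm), 0.05)
})

test_that("COA refinement flags score-driven genes with directions", {
  set.seed(17)
  n <- 80
  score_gene <- rnorm(n)
  noise <- matrix(rnorm(3 * n), 3, n)
  expr <- rbind(score_gene, noise, -score_gene + rnorm(n, sd = 0.3))
  cohort <- mk_cohort(expr, rexp(n), rbinom(n, 1, 0.8))
  split <- median_split(signature_score(cohort, "G01"))
  coa <- coa_refine(cohort, split, rownames(cohort$expression))
  expect_lte(nrow(coa), 5L)
  expect_true("G01" %in% coa$gene)
  expect_equal(coa$direction[coa$gene == "G01"], "higher_in_above")
  expect_equal(coa$direction[coa$gene == "G05"], "lower_in_above")

  # direction labels flip exactly when the score is negated
  split_neg <- median_split(-split$score)
  coa_neg <- coa_refine(cohort, split_neg, rownames(cohort$expression))
  both <- intersect(coa$gene, coa_neg$gene)
  expect_gt(length(both), 0L)
  for (g in both) {
    expect_false(coa$direction[coa$gene == g] ==
                   coa_neg$direction[coa_neg$gene == g])
  }
  expect_error(coa_refine(cohort, split, "NOPE"), "no signature genes")
})

test_that("survival pipeline composes the stages coherently", {
  cfg <- synth_config(seed = 6, n_patients = 120)
  sig <- sprintf("Sig%02d", 1:40)
  tab <- gen_ortholog_table(sig, 0.1, seed = 2)
  cohort <- gen_cohort(cfg, unlist(tab))$cohort
  rep <- survival_pipeline(cohort, sig, tab)
  expect_true(all(rep$human_genes %in% rownames(cohort$expression)))
  expect_equal(length(rep$score), 120L)
  # planted risk: above-median group survives worse at a shared time point
  surv_at <- function(km, tt) {
    i <- findInterval(tt, km$time)
    if (i == 0) 1 else km$survival[i]
  }
  t_star <- median(cohort$time)
  expect_lt(surv_at(rep$km_above, t_star), surv_at(rep$km_below, t_star))
  expect_lt(rep$logrank$p_value, 0.01)
  # directed re-score identity: -1 signs equal the negated undirected score
  inv <- rep$inverse_genes
  if (length(inv)) {
    undirected <- signature_score(cohort, inv)
    directed <- signature_score(cohort, inv,
                                directions = setNames(rep(-1, length(inv)),
                                                      inv))
    expect_equal(directed, -undirected)
  }
})
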