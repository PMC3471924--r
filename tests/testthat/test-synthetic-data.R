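test_that("config validation rejects impossible designs", {
  expect_error(synth_config(n_genes = 100, n_baseline_signature = 131),
               "exceed")
  expect_error(synth_config(censor_fraction = 1), "censor_fraction")
  expect_error(synth_config(residual_sd = 0), "residual_sd")
})

test_that("all generators are deterministic under a fixed seed", {
  cfg <- synth_config(seed = 5, n_genes = 500)
  a <- gen_mouse_study(cfg); b <- gen_mouse_study(cfg)
  expect_identical(a$study$values, b$study$values)
  expect_identical(a$truth, b$truth)

  ca <- gen_cohort(cfg, sprintf("S%02d", 1:20))
  cb <- gen_cohort(cfg, sprintf("S%02d", 1:20))
  expect_identical(ca$cohort$expression, cb$cohort$expression)
  expect_identical(ca$cohort$time, cb$cohort$time)

  expect_identical(gen_mn_counts(cfg)$mn_cells, gen_mn_counts(cfg)$mn_cells)

  # generators leave the caller's RNG state untouched
  set.seed(99); before <- .Random.seed
  invisible(gen_mouse_study(cfg))
  expect_identical(.Random.seed, before)
})

test_that("null study is calibrated: no planted effects, ~5% strain DE", {
  hits <- 0L; total <- 0L
  for (s in 1:20) {
    cfg <- synth_config(seed = s, n_genes = 1000, baseline_effect = 0,
                        ld_effect = 0, hd_effect = 0)
    sim <- gen_mouse_study(cfg)
    con <- contrast(sim$study,
                    list(strain = "sensitive", tissue = "blood",
                         dose = "sham"),
                    list(strain = "resistant", tissue = "blood",
                         dose = "sham"))
    hits <- hits + sum(con$p_value <= 0.05)
    total <- total + nrow(con)
  }
  band <- qbinom(c(0.005, 0.995), total, 0.05) / total
  # sham blood groups pool both time points: n = 8 vs 8 Welch t
  expect_gte(hits / total, band[1])
  expect_lte(hits / total, band[2])
})

test_that("planted baseline effects are recovered within Monte-Carlo error", {
  cfg <- synth_config(seed = 7)
  sim <- gen_mouse_study(cfg)
  con <- contrast(sim$study,
                  list(strain = "sensitive", tissue = "mammary",
                       dose = "sham"),
                  list(strain = "resistant", tissue = "mammary",
                       dose = "sham"))
  dirs <- sim$truth$baseline_signature
  planted <- con[match(names(dirs), con$gene), ]
  oriented <- planted$log2_fc * dirs
  n_per_side <- sum(sim$study$samples$strain == "sensitive" &
                      sim$study$samples$tissue == "mammary" &
                      sim$study$samples$dose == "sham")
  se <- cfg$residual_sd * sqrt(2 / n_per_side) / sqrt(length(dirs))
  expect_lt(abs(mean(oriented) - cfg$baseline_effect), 3 * se)
})

test_that("cohort censoring behaves as configured", {
  cfg0 <- synth_config(seed = 2, censor_fraction = 0, n_patients = 100)
  ch0 <- gen_cohort(cfg0, sprintf("S%02d", 1:10))$cohort
  expect_true(all(ch0$event == 1L))

  fracs <- vapply(1:20, function(s) {
    cfg <- synth_config(seed = s, censor_fraction = 0.3, n_patients = 159)
    mean(gen_cohort(cfg, sprintf("S%02d", 1:10))$cohort$event == 0L)
  }, numeric(1))
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - 0.3), 3 * se + 0.02)
})

test_that("null cohort has exchangeable scores and hazards", {
  # score_log_hr = 0: any split gives equal hazards; planted loading signs
  # still shape expression but not survival
  ps <- vapply(1:60, function(s) {
    cfg <- synth_config(seed = s, score_log_hr = 0, n_patients = 100,
                        n_cohort_background = 0)
    ch <- gen_cohort(cfg, sprintf("S%02d", 1:20))$cohort
    split <- median_split(signature_score(ch, sprintf("S%02d", 1:20)))
    ab <- split$group == "above"
    logrank_test(ch$time[ab], ch$event[ab],
                 ch$time[!ab], ch$event[!ab])$p_value
  }, numeric(1))
  expect_gt(mean(ps < 0.05), 0)   # sanity: not degenerate at 0 ...
  expect_lt(mean(ps < 0.05), 0.15)  # ... and near alpha, not powered
})

test_that("MN counts respect equal-rate and scaled-rate configurations", {
  cfg_eq <- synth_config(seed = 1, mn_baseline = list(
    RET = c(sensitive = 20, resistant = 20),
    NCE = c(sensitive = 10, resistant = 10)))
  pct <- vapply(1:25, function(s) {
    cfg <- synth_config(seed = s, mn_baseline = cfg_eq$mn_baseline)
    f <- mn_frequencies(gen_mn_counts(cfg))
    sham <- f[f$dose == "sham" & f$cell_class == "RET" &
                f$time_point == "week3", ]
    baseline_compare(sham$freq[sham$strain == "sensitive"],
                     sham$freq[sham$strain == "resistant"])$percent_diff
  }, numeric(1))
  expect_lt(abs(mean(pct)), 3 * sd(pct) / sqrt(length(pct)))

  bad <- synth_config(seed = 1)
  bad$mn_dose_effects$RET[["HD"]] <- 1e9
  expect_error(gen_mn_counts(bad), "rate")
})
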