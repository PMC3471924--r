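#' Synthetic study configuration
#'
#' Collects every knob of the synthetic-data generators with defaults that
#' mirror the emulated study design: two strains (radiation-sensitive and
#' -resistant) x two tissues x {sham, LD, HD} x {4 h, 1 month}, four
#' arrays per group, six animals per micronucleus group, a 131-gene
#' cross-tissue baseline signature, and a 159-patient survival cohort
#' whose hazard follows a planted signature score.
#'
#' @param seed master seed; every generator derives its stream from it.
#' @param n_genes number of mouse genes.
#' @param n_reps_per_group arrays per strain x tissue x dose x time cell.
#' @param residual_sd residual log2 SD around each gene's baseline.
#' @param n_baseline_signature planted cross-tissue strain-baseline genes.
#' @param baseline_effect strain offset (log2) of planted baseline genes,
#'   applied concordantly in both tissues with a random +/- direction.
#' @param n_ld_response named integer vector: generic low-dose response
#'   genes planted per strain at the late (1-month) time point.
#' @param n_thresholded,n_plateau,n_opposite early-response subsets:
#'   `thresholded` respond to HD in both strains but to LD only in the
#'   sensitive strain; `plateau` respond equally at LD and HD in the
#'   sensitive strain; `opposite` flip sign between LD and HD.
#' @param ld_effect,hd_effect response magnitudes (log2).
#' @param n_patients survival-cohort size.
#' @param n_cohort_background cohort genes unrelated to the signature.
#' @param latent_loading loading of each signature gene on the cohort's
#'   shared latent risk factor (per-gene variance share = loading^2).
#' @param frac_risk_up fraction of signature genes with positive loading
#'   (risk-associated when high); the remainder load negatively and are
#'   the analogue of the published inverse COA subset.
#' @param score_log_hr log hazard ratio per SD of the latent score.
#' @param censor_fraction target fraction of censored patients.
#' @param n_animals_per_group animals per MN dose group.
#' @param mn_cells_scored cells scored per animal and cell class.
#' @param mn_baseline per-10^4 sham MN rates, list by cell class with
#'   `sensitive`/`resistant` entries (defaults give the sensitive strain
#'   36% higher MN-RET and 57% higher MN-NCE baselines).
#' @param mn_dose_effects multiplicative dose effects on the sham rate,
#'   list by cell class.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         n_genes = 10000L,
                         n_reps_per_group = 4L,
                         residual_sd = 0.25,
                         n_baseline_signature = 131L,
                         baseline_effect = 1.0,
                         n_ld_response = c(sensitive = 105L, resistant = 100L),
                         n_thresholded = 28L,
                         n_plateau = 76L,
                         n_opposite = 35L,
                         ld_effect = 1.0,
                         hd_effect = 1.5,
                         n_patients = 159L,
                         n_cohort_background = 200L,
                         latent_loading = 0.55,
                         frac_risk_up = 0.85,
                         score_log_hr = log(2.5),
                         censor_fraction = 0.3,
                         n_animals_per_group = 6L,
                         mn_cells_scored = 20000L,
                         mn_baseline = list(
                           RET = c(sensitive = 27.2, resistant = 20),
                           NCE = c(sensitive = 15.7, resistant = 10)),
                         mn_dose_effects = list(
                           RET = c(sham = 1, LD = 1, HD = 5, `LD+HD` = 5),
                           NCE = c(sham = 1, LD = 1.2, HD = 3, `LD+HD` = 3))) {
  cfg <- list(seed = seed, n_genes = as.integer(n_genes),
              n_reps_per_group = as.integer(n_reps_per_group),
              residual_sd = residual_sd,
              n_baseline_signature = as.integer(n_baseline_signature),
              baseline_effect = baseline_effect,
              n_ld_response = n_ld_response,
              n_thresholded = as.integer(n_thresholded),
              n_plateau = as.integer(n_plateau),
              n_opposite = as.integer(n_opposite),
              ld_effect = ld_effect, hd_effect = hd_effect,
              n_patients = as.integer(n_patients),
              n_cohort_background = as.integer(n_cohort_background),
              latent_loading = latent_loading,
              frac_risk_up = frac_risk_up,
              score_log_hr = score_log_hr,
              censor_fraction = censor_fraction,
              n_animals_per_group = as.integer(n_animals_per_group),
              mn_cells_scored = as.integer(mn_cells_scored),
              mn_baseline = mn_baseline,
              mn_dose_effects = mn_dose_effects)
  counts <- c(cfg$n_genes, cfg$n_reps_per_group, cfg$n_baseline_signature,
              cfg$n_patients, cfg$n_animals_per_group, cfg$mn_cells_scored)
  if (any(counts <= 0L)) stop_ldsig("all counts must be positive")
  if (cfg$residual_sd <= 0) stop_ldsig("residual_sd must be positive")
  if (cfg$censor_fraction < 0 || cfg$censor_fraction >= 1) {
    stop_ldsig("censor_fraction must lie in [0, 1)")
  }
  planted <- cfg$n_baseline_signature + sum(cfg$n_ld_response) +
    cfg$n_thresholded + cfg$n_plateau + cfg$n_opposite
  if (planted > cfg$n_genes) {
    stop_ldsig("planted gene sets (%d) exceed n_genes (%d)",
               planted, cfg$n_genes)
  }
  if (abs(cfg$latent_loading) >= 1) stop_ldsig("latent_loading must be < 1")
  if (cfg$frac_risk_up < 0 || cfg$frac_risk_up > 1) {
    stop_ldsig("frac_risk_up must lie in [0, 1]")
  }
  structure(cfg, class = "synth_config")
}

# Mouse-style (title case) synthetic symbols.
synth_gene_ids <- function(n) sprintf("Gene%05d", seq_len(n))

#' Generate a synthetic two-strain mouse expression study
#'
#' Simulates log2 intensities for `n_genes` genes over the full design
#' (strain x tissue x dose x time x replicate) as independent Gaussian
#' residuals around per-gene baselines, then plants:
#' \itemize{
#'   \item baseline-signature genes: a +/- `baseline_effect` offset in the
#'     sensitive strain, concordant across both tissues, at every dose and
#'     time (a constitutive strain difference);
#'   \item thresholded genes: mammary response to HD in both strains but
#'     to LD only in the sensitive strain (early time point);
#'   \item plateau genes: equal-magnitude LD and HD mammary responses in
#'     the sensitive strain (early);
#'   \item opposite genes: sign-flipped LD versus HD mammary responses in
#'     the sensitive strain (early);
#'   \item generic per-strain LD response genes at the late time point
#'     (the 1-month signature; directions half up, half down).
#' }
#'
#' @param config a [synth_config()].
#' @return list with `study` (an [expression_study()]) and `truth`
#'   (planted gene sets with directions).
#' @export
gen_mouse_study <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(child_seed(config$seed, 11L), {
    genes <- synth_gene_ids(config$n_genes)
    design <- expand.grid(replicate = seq_len(config$n_reps_per_group),
                          time = c("early", "late"),
                          dose = c("sham", "LD", "HD"),
                          tissue = c("mammary", "blood"),
                          strain = c("sensitive", "resistant"),
                          stringsAsFactors = FALSE)
    design$sample_id <- sprintf("%s_%s_%s_%s_r%d",
                                substr(design$strain, 1, 4),
                                substr(design$tissue, 1, 3), design$dose,
                                design$time, design$replicate)
    n_samp <- nrow(design)

    base <- stats::rnorm(config$n_genes, mean = 8, sd = 1.5)
    values <- matrix(stats::rnorm(config$n_genes * n_samp,
                                  sd = config$residual_sd),
                     config$n_genes, n_samp) + base
    dimnames(values) <- list(genes, design$sample_id)

    # carve disjoint planted sets off the front of the gene vector
    take <- local({
      pos <- 0L
      function(n) {
        out <- genes[pos + seq_len(n)]
        pos <<- pos + n
        out
      }
    })
    baseline_genes <- take(config$n_baseline_signature)
    thresh_genes <- take(config$n_thresholded)
    plateau_genes <- take(config$n_plateau)
    opposite_genes <- take(config$n_opposite)
    ld_genes <- lapply(config$n_ld_response, take)

    rdir <- function(g) stats::setNames(sample(c(-1, 1), length(g),
                                               replace = TRUE), g)
    base_dir <- rdir(baseline_genes)
    thresh_dir <- rdir(thresh_genes)
    plateau_dir <- rdir(plateau_genes)
    opposite_dir <- rdir(opposite_genes)
    ld_dir <- lapply(ld_genes, function(g) {
      # deterministic half-up/half-down so the "up at 1 month" list has
      # a known size
      stats::setNames(rep(c(1, -1), length.out = length(g)), g)
    })

    add <- function(gset, dirs, sel, effect) {
      if (!length(gset) || !any(sel)) return()
      values[gset, sel] <<- values[gset, sel] + dirs[gset] * effect
    }
    sens <- design$strain == "sensitive"
    mam <- design$tissue == "mammary"
    early <- design$time == "early"
    ld <- design$dose == "LD"
    hd <- design$dose == "HD"

    # constitutive strain baseline difference, both tissues, everywhere
    add(baseline_genes, base_dir, sens, config$baseline_effect)
    # thresholded: HD both strains, LD sensitive only (mammary, early)
    add(thresh_genes, thresh_dir, mam & early & hd, config$hd_effect)
    add(thresh_genes, thresh_dir, mam & early & ld & sens, config$ld_effect)
    # plateau: equal LD and HD response, sensitive mammary early
    add(plateau_genes, plateau_dir, mam & early & ld & sens, config$ld_effect)
    add(plateau_genes, plateau_dir, mam & early & hd & sens, config$ld_effect)
    # opposite: sign flip between LD and HD, sensitive mammary early
    add(opposite_genes, opposite_dir, mam & early & ld & sens,
        config$ld_effect)
    add(opposite_genes, opposite_dir, mam & early & hd & sens,
        -config$hd_effect)
    # generic 1-month LD responses per strain (mammary, late)
    for (st in names(ld_genes)) {
      add(ld_genes[[st]], ld_dir[[st]],
          mam & !early & ld & (design$strain == st), config$ld_effect)
    }

    meta <- design[, c("sample_id", "strain", "tissue", "dose", "time",
                       "replicate")]
    truth <- list(baseline_signature = base_dir,
                  thresholded = thresh_dir,
                  plateau = plateau_dir,
                  opposite = opposite_dir,
                  ld_late = ld_dir)
    list(study = expression_study(values, meta), truth = truth)
  })
}

#' Generate a synthetic right-censored survival cohort
#'
#' Patient expression is standard normal per gene; each signature gene
#' additionally loads on one shared latent factor F ~ N(0, 1) with
#' loading +/- `latent_loading` (residual variance rescaled so every gene
#' has unit variance); a `frac_risk_up` share of genes load positively,
#' the rest negatively.  Event times are exponential with per-patient log
#' hazard `score_log_hr * F`, so the planted risk direction follows the
#' latent factor that the signature sum-score estimates.  Censoring times
#' are uniform on (0, tau) with tau solved so the expected censored
#' fraction matches `censor_fraction`.  Background genes carry no signal.
#'
#' @param config a [synth_config()].
#' @param signature character vector of (human) gene symbols to plant.
#' @param directions optional named +1/-1 vector fixing each gene's
#'   loading sign; unnamed genes are sampled with `frac_risk_up`.
#' @return list with `cohort` (a [survival_cohort()]) and `truth`
#'   (per-gene loading signs and latent factor = per-patient linear
#'   predictor scale).
#' @export
gen_cohort <- function(config, signature, directions = NULL) {
  stopifnot(inherits(config, "synth_config"))
  signature <- unique(as.character(signature))
  if (!length(signature)) stop_ldsig("signature must be non-empty")
  with_seed(child_seed(config$seed, 23L), {
    n <- config$n_patients
    a <- config$latent_loading
    f <- stats::rnorm(n)
    dir <- stats::setNames(
      ifelse(stats::runif(length(signature)) < config$frac_risk_up, 1, -1),
      signature)
    if (!is.null(directions)) {
      hit <- intersect(signature, names(directions))
      dir[hit] <- directions[hit]
    }
    sig_expr <- (a * dir) %o% f +
      sqrt(1 - a^2) * matrix(stats::rnorm(length(signature) * n),
                             length(signature), n)
    bg_ids <- sprintf("BG%04d", seq_len(config$n_cohort_background))
    bg_expr <- matrix(stats::rnorm(config$n_cohort_background * n),
                      config$n_cohort_background, n)
    expr <- rbind(sig_expr, bg_expr)
    dimnames(expr) <- list(c(signature, bg_ids), sprintf("pt%03d", seq_len(n)))

    rate <- 0.1 * exp(config$score_log_hr * f)
    t_event <- stats::rexp(n, rate)
    if (config$censor_fraction == 0) {
      time <- t_event
      event <- rep(1L, n)
    } else {
      # C ~ U(0, tau): P(censor | T = t) = min(t / tau, 1)
      target <- function(tau) mean(pmin(t_event / tau, 1)) -
        config$censor_fraction
      tau <- stats::uniroot(target, c(1e-6, 1e6), tol = 1e-9)$root
      cens <- stats::runif(n, 0, tau)
      event <- as.integer(t_event <= cens)
      time <- pmin(t_event, cens)
    }
    list(cohort = survival_cohort(expr, time, event),
         truth = list(latent = f, loading_sign = dir,
                      linear_predictor = config$score_log_hr * f))
  })
}

#' Generate synthetic micronucleus counts
#'
#' Per-animal micronucleated-cell counts are binomial draws with
#' strain- and dose-specific rates: the sham rate per cell class comes
#' from `mn_baseline`, dose groups multiply it by `mn_dose_effects` at the
#' two early sampling times; at 1 month all groups revert to baseline
#' except the sensitive strain after HD (or LD+HD), which stays elevated
#' (persistent genomic instability in the sensitive genotype only).
#'
#' @param config a [synth_config()].
#' @return data.frame of MN records (see [mn_frequencies()]).
#' @export
gen_mn_counts <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(child_seed(config$seed, 37L), {
    doses <- c("sham", "LD", "HD", "LD+HD")
    times <- c("week3", "week4", "month1")
    rows <- expand.grid(animal = seq_len(config$n_animals_per_group),
                        dose = doses, time_point = times,
                        cell_class = c("RET", "NCE"),
                        strain = c("sensitive", "resistant"),
                        stringsAsFactors = FALSE)
    rate <- numeric(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      base <- config$mn_baseline[[rows$cell_class[i]]][[rows$strain[i]]] / 1e4
      mult <- config$mn_dose_effects[[rows$cell_class[i]]][[rows$dose[i]]]
      if (rows$time_point[i] == "month1") {
        persistent <- rows$strain[i] == "sensitive" &&
          rows$dose[i] %in% c("HD", "LD+HD")
        mult <- if (persistent) mult else 1
      }
      rate[i] <- base * mult
    }
    if (any(rate < 0 | rate > 1)) stop_ldsig("MN rate outside [0, 1]")
    data.frame(animal_id = sprintf("%s_%s_%s_a%d",
                                   substr(rows$strain, 1, 4), rows$dose,
                                   rows$time_point, rows$animal),
               strain = rows$strain, dose = rows$dose,
               time_point = rows$time_point, cell_class = rows$cell_class,
               cells_scored = config$mn_cells_scored,
               mn_cells = stats::rbinom(nrow(rows), config$mn_cells_scored,
                                        rate),
               stringsAsFactors = FALSE)
  })
}

#' Generate a lossy mouse-to-human ortholog table
#'
#' Maps each retained mouse symbol to its upper-cased human counterpart;
#' a seeded random `drop_fraction` of the input genes get no mapping,
#' emulating the loss when associating mouse signature genes with human
#' orthologs.
#'
#' @param genes character vector of mouse symbols.
#' @param drop_fraction fraction of genes left unmapped, in [0, 1).
#' @param seed integer seed.
#' @return an [ortholog_table()] (possibly empty).
#' @export
gen_ortholog_table <- function(genes, drop_fraction = 0, seed = 1L) {
  if (drop_fraction < 0 || drop_fraction >= 1) {
    stop_ldsig("drop_fraction must lie in [0, 1)")
  }
  genes <- unique(as.character(genes))
  if (!length(genes)) {
    return(structure(stats::setNames(list(), character(0)),
                     class = "ortholog_table"))
  }
  keep <- with_seed(seed, stats::runif(length(genes)) >= drop_fraction)
  ortholog_table(data.frame(mouse_symbol = genes[keep],
                            human_symbol = toupper(genes[keep])))
}
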