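#' Simulation configuration for synthetic cohorts
#'
#' Bundles every tunable of the synthetic-data generator with validation.
#' Defaults follow the genotyping design the package targets: a 56-SNP
#' candidate panel of which 8 variants carry an engineered call-rate failure
#' and 4 an engineered Hardy-Weinberg violation (so a default QC run retains
#' 44), per-allele effect sizes on the scale of GWAS adult-BMI betas, and a
#' polygenic component explaining ~5% of BMI Z-score variance.
#'
#' @param n_snps Number of variants in the simulated panel.
#' @param maf_range Length-2 numeric in (0, 0.5]: minor-allele-frequency
#'   sampling bounds (risk-allele frequencies are drawn uniformly here).
#' @param beta_scale Centre of the per-allele effect distribution in BMI
#'   Z-score units per risk allele; betas are drawn uniformly in
#'   `beta_scale * c(1/3, 5/3)`.
#' @param n_individuals Cohort size.
#' @param missing_rate Per-call missingness probability for variants without
#'   an engineered call-rate failure.
#' @param n_qc_fail_callrate Number of variants given >5% missingness
#'   (deterministically `callrate_fail_missing` of calls set missing).
#' @param n_qc_fail_hwe Number of variants whose genotype frequencies are
#'   distorted away from Hardy-Weinberg proportions.
#' @param h2_target Fraction of BMI Z-score variance attributable to the
#'   polygenic score; must lie in `[0, 1)`.
#' @param gxe_effects Named (or unnamed) numeric vector of true
#'   score-by-environment interaction coefficients; length must not exceed
#'   `n_env_factors`.
#' @param n_env_factors Number of lifestyle/environment columns generated.
#' @param env_type `"ordinal"` (small-integer questionnaire codes 0-4) or
#'   `"continuous"` (standard normal).
#' @param callrate_fail_missing Missingness fraction forced onto engineered
#'   call-rate failures (must exceed 0.05).
#' @param hwe_reject_prob Target probability that the exact test rejects an
#'   engineered HWE failure at `hwe_alpha`; the inbreeding-coefficient
#'   magnitude is solved from this. Near-1 default makes the engineered
#'   failure count deterministic.
#' @param hwe_alpha Significance level the engineered failures are solved
#'   against.
#' @param cov_var Phenotype variance fraction assigned to sex/Tanner/origin
#'   covariate effects.
#' @param zcut_ow,zcut_ob BMI Z-score cut-offs labelling overweight and
#'   obesity in simulated cohorts.
#' @param traj_group_sizes Integer vector of five pubertal trajectory group
#'   sizes (normal-weight stable; overweight/obese never IR; IR resolved;
#'   incident IR; persistent IR).
#' @param traj_enrich_or Odds multiplier for top-tertile score membership in
#'   the groups named by `traj_enrich_groups` (1 = no enrichment).
#' @param traj_enrich_groups Trajectory groups receiving score enrichment.
#' @param rct_n_placebo,rct_n_treated Arm sizes for the simulated trial.
#' @param rct_treat_effect True mean additional BMI Z reduction (T0 - T1) in
#'   the treated arm.
#' @param rct_interaction True score-by-treatment interaction coefficient on
#'   the T0 - T1 response.
#' @param seed Master seed; every sub-simulation derives its own stream from
#'   it by a fixed offset.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_snps = 10, n_individuals = 50, seed = 1)
#' sim <- simulate_panel(cfg)
#' sim$panel
sim_config <- function(n_snps = 56,
                       maf_range = c(0.1, 0.5),
                       beta_scale = 0.045,
                       n_individuals = 600,
                       missing_rate = 0.01,
                       n_qc_fail_callrate = 8,
                       n_qc_fail_hwe = 4,
                       h2_target = 0.05,
                       gxe_effects = numeric(0),
                       n_env_factors = 47,
                       env_type = c("ordinal", "continuous"),
                       callrate_fail_missing = 0.10,
                       hwe_reject_prob = 1 - 1e-6,
                       hwe_alpha = 1e-4,
                       cov_var = 0.10,
                       zcut_ow = 1.04,
                       zcut_ob = 1.64,
                       traj_group_sizes = c(20, 20, 20, 20, 16),
                       traj_enrich_or = 1,
                       traj_enrich_groups = "OWOB_persistent_IR",
                       rct_n_placebo = 59,
                       rct_n_treated = 65,
                       rct_treat_effect = 0.3,
                       rct_interaction = 0,
                       seed = 1L) {
  env_type <- match.arg(env_type)
  cfg <- list(
    n_snps = n_snps, maf_range = maf_range, beta_scale = beta_scale,
    n_individuals = n_individuals, missing_rate = missing_rate,
    n_qc_fail_callrate = n_qc_fail_callrate, n_qc_fail_hwe = n_qc_fail_hwe,
    h2_target = h2_target, gxe_effects = gxe_effects,
    n_env_factors = n_env_factors, env_type = env_type,
    callrate_fail_missing = callrate_fail_missing,
    hwe_reject_prob = hwe_reject_prob, hwe_alpha = hwe_alpha,
    cov_var = cov_var, zcut_ow = zcut_ow, zcut_ob = zcut_ob,
    traj_group_sizes = traj_group_sizes, traj_enrich_or = traj_enrich_or,
    traj_enrich_groups = traj_enrich_groups,
    rct_n_placebo = rct_n_placebo, rct_n_treated = rct_n_treated,
    rct_treat_effect = rct_treat_effect, rct_interaction = rct_interaction,
    seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_snps < 0) abort("`n_snps` must be non-negative.")
  if (length(cfg$maf_range) != 2L || any(cfg$maf_range <= 0) ||
      any(cfg$maf_range > 0.5) || cfg$maf_range[1] > cfg$maf_range[2]) {
    abort("`maf_range` must be an increasing pair within (0, 0.5].")
  }
  if (cfg$h2_target < 0 || cfg$h2_target >= 1) {
    abort("`h2_target` must lie in [0, 1).")
  }
  if (cfg$n_qc_fail_callrate < 0 || cfg$n_qc_fail_hwe < 0) {
    abort("Engineered-failure counts must be non-negative.")
  }
  if (cfg$n_qc_fail_callrate + cfg$n_qc_fail_hwe > cfg$n_snps) {
    abort("Engineered failures cannot exceed `n_snps`.")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  if (cfg$callrate_fail_missing <= 0.05) {
    abort("`callrate_fail_missing` must exceed 0.05 to guarantee a call-rate failure.")
  }
  if (length(cfg$gxe_effects) > cfg$n_env_factors) {
    abort("More interaction coefficients than environment factors.")
  }
  if (cfg$cov_var < 0 || cfg$cov_var + cfg$h2_target >= 1) {
    abort("`cov_var` + `h2_target` must stay below 1.")
  }
  if (length(cfg$traj_group_sizes) != 5L || any(cfg$traj_group_sizes < 0)) {
    abort("`traj_group_sizes` must be five non-negative counts.")
  }
  invisible(cfg)
}

#' Simulate a weighted variant panel
#'
#' Draws `n_snps` biallelic variants with risk-allele frequencies uniform in
#' `maf_range` and positive per-allele BMI Z-score weights around
#' `beta_scale`, mimicking a GWAS-derived scoring file. The returned `truth`
#' tibble records the generating frequency of every variant.
#'
#' @param config A [sim_config()].
#' @return A list with `panel` (tibble: `snp_id`, `chrom`, `pos`,
#'   `risk_allele`, `other_allele`, `beta`) and `truth` (tibble adding
#'   `freq`, the generating risk-allele frequency).
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  if (n == 0L) {
    empty <- tibble::tibble(snp_id = character(), chrom = character(),
                            pos = integer(), risk_allele = character(),
                            other_allele = character(), beta = double())
    return(list(panel = empty,
                truth = dplyr::mutate(empty, freq = double())))
  }
  with_seed(derive_seed(config$seed, 1L), {
    freq <- runif(n, config$maf_range[1], config$maf_range[2])
    beta <- runif(n, config$beta_scale / 3, config$beta_scale * 5 / 3)
    pairs <- t(vapply(seq_len(n),
                      function(i) sample(c("A", "C", "G", "T"), 2L),
                      character(2L)))
    panel <- tibble::tibble(
      snp_id = sprintf("snp%03d", seq_len(n)),
      chrom = as.character(1L + (seq_len(n) - 1L) %% 22L),
      pos = 10000L + 1000L * seq_len(n),
      risk_allele = pairs[, 1],
      other_allele = pairs[, 2],
      beta = beta
    )
    list(panel = panel, truth = dplyr::mutate(panel, freq = freq))
  })
}

# Minimal inbreeding coefficient whose HWE-distorted genotype frequencies are
# rejected by a 1-df test at `alpha` with probability >= `power`, from the
# noncentral chi-square relation ncp = n * F^2.
solve_hwe_distortion <- function(n, alpha, power) {
  lambda <- (sqrt(qchisq(1 - alpha, df = 1)) + qnorm(power))^2
  f <- sqrt(lambda / n)
  if (f > 1) {
    abort(sprintf(
      "n = %d is too small to engineer a Hardy-Weinberg failure rejected with probability %.3g at alpha = %.3g; minimum n is %d.",
      n, power, alpha, ceiling(lambda)))
  }
  f
}

#' Simulate genotype calls with engineered QC failures
#'
#' Genotypes are multinomial draws from exact Hardy-Weinberg proportions
#' (p^2, 2pq, q^2) of each variant's generating frequency. The first
#' `n_qc_fail_hwe` designated variants are instead drawn with an
#' excess-homozygosity distortion (inbreeding coefficient `F > 0`) whose
#' magnitude is solved so the exact test rejects at `hwe_alpha` with
#' probability at least `hwe_reject_prob`; the `n_qc_fail_callrate`
#' designated variants have a fixed `callrate_fail_missing` fraction of calls
#' set to missing; all other variants receive Bernoulli(`missing_rate`)
#' missingness.
#'
#' @param panel Panel tibble from [simulate_panel()] (the `truth` variant
#'   with a `freq` column, or a bare panel in which case frequencies are
#'   redrawn).
#' @param config A [sim_config()].
#' @return List with `genotypes` (tibble: `id` plus one character column per
#'   SNP holding unordered allele pairs such as `"AG"`, `NA` = missing) and
#'   `truth` (tibble: `snp_id`, `freq`, `qc_class`, `f_distortion`).
#' @export
simulate_genotypes <- function(panel, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(panel) == 0L) abort("Cannot simulate genotypes for an empty panel.")
  n_ind <- config$n_individuals
  if (n_ind < 1L) abort("Need at least one individual.")
  if (!"freq" %in% names(panel)) {
    panel <- dplyr::mutate(panel,
      freq = with_seed(derive_seed(config$seed, 1L),
                       runif(dplyr::n(), config$maf_range[1], config$maf_range[2])))
  }
  with_seed(derive_seed(config$seed, 2L), {
    n_snp <- nrow(panel)
    idx <- sample.int(n_snp)
    hwe_fail <- idx[seq_len(config$n_qc_fail_hwe)]
    cr_fail <- idx[config$n_qc_fail_hwe + seq_len(config$n_qc_fail_callrate)]
    f_dist <- if (config$n_qc_fail_hwe > 0) {
      solve_hwe_distortion(n_ind, config$hwe_alpha, config$hwe_reject_prob)
    } else 0
    geno <- matrix(NA_character_, nrow = n_ind, ncol = n_snp)
    qc_class <- rep("clean", n_snp)
    qc_class[hwe_fail] <- "fail_hwe"
    qc_class[cr_fail] <- "fail_callrate"
    f_used <- ifelse(qc_class == "fail_hwe", f_dist, 0)
    for (j in seq_len(n_snp)) {
      p <- panel$freq[j]
      q <- 1 - p
      f <- f_used[j]
      probs <- c(p^2 + f * p * q, 2 * p * q * (1 - f), q^2 + f * p * q)
      counts <- drop(rmultinom(1L, n_ind, probs))
      if (qc_class[j] == "clean") {
        # a clean variant is one that passes QC by construction: on the rare
        # chance rejection of a null draw, redraw so the engineered failure
        # count is exactly the QC drop count
        tries <- 0L
        while (hwe_exact_test(counts[1], counts[2], counts[3]) < config$hwe_alpha) {
          counts <- drop(rmultinom(1L, n_ind, probs))
          tries <- tries + 1L
          if (tries > 1000L) abort("Could not draw a QC-clean variant; lower `hwe_alpha`.")
        }
      }
      dos <- rep(c(2L, 1L, 0L), counts)
      dos <- dos[sample.int(length(dos))]
      a1 <- panel$risk_allele[j]
      a2 <- panel$other_allele[j]
      cell <- c(paste0(a2, a2),
                paste(sort(c(a1, a2)), collapse = ""),
                paste0(a1, a1))
      geno[, j] <- cell[dos + 1L]
      if (qc_class[j] == "fail_callrate") {
        n_miss <- ceiling(config$callrate_fail_missing * n_ind)
        geno[sample.int(n_ind, n_miss), j] <- NA_character_
      } else if (config$missing_rate > 0) {
        miss <- runif(n_ind) < config$missing_rate
        geno[miss, j] <- NA_character_
      }
    }
    colnames(geno) <- panel$snp_id
    genotypes <- dplyr::bind_cols(
      tibble::tibble(id = sprintf("ind%04d", seq_len(n_ind))),
      tibble::as_tibble(geno)
    )
    truth <- tibble::tibble(snp_id = panel$snp_id, freq = panel$freq,
                            qc_class = qc_class, f_distortion = f_used)
    list(genotypes = genotypes, truth = truth)
  })
}

#' Simulate an additive polygenic BMI Z-score phenotype
#'
#' The polygenic signal is the weighted risk-allele count (the same quantity
#' [compute_pgrs()] later reconstructs), standardised and rescaled so its
#' share of total phenotype variance equals `h2_target` in expectation.
#' Sex, Tanner stage and recruitment-site effects contribute a further
#' `cov_var` fraction; the remainder is Gaussian noise. Weight status is
#' labelled from the configured BMI Z cut-offs.
#'
#' @param dosage Complete dosage tibble (`id` + numeric SNP columns).
#' @param panel Panel tibble with matching `snp_id` and `beta`.
#' @param config A [sim_config()].
#' @return List with `cohort` (tibble: `id`, `sex`, `age`, `tanner`,
#'   `origin`, `pgrs`, `bmi_z`, `weight_status`) and `truth` (list with the
#'   realised variance fraction and the scaling used).
#' @export
simulate_phenotypes <- function(dosage, panel, config) {
  stopifnot(inherits(config, "sim_config"))
  snps <- snp_cols(dosage)
  if (anyNA(dosage[snps])) abort("Dosage matrix must be complete (impute first).")
  g <- as.numeric(as.matrix(dosage[snps]) %*% panel$beta[match(snps, panel$snp_id)])
  n <- nrow(dosage)
  h2 <- config$h2_target
  with_seed(derive_seed(config$seed, 3L), {
    sex <- sample(c("male", "female"), n, replace = TRUE)
    age <- runif(n, 6, 14)
    pubertal <- runif(n) < stats::plogis(age - 10.5)
    tanner <- ifelse(pubertal, sample(2:5, n, replace = TRUE), 1L)
    tanner <- factor(c("I", "II", "III", "IV", "V")[tanner],
                     levels = c("I", "II", "III", "IV", "V"))
    origin <- factor(sample(c("cordoba", "santiago", "zaragoza"), n, replace = TRUE))
    signal <- if (h2 > 0 && sd(g) > 0) sqrt(h2) * as.numeric(scale(g)) else rep(0, n)
    covlin <- 0.4 * (sex == "male") + 0.25 * (as.integer(tanner) - 1) +
      0.3 * (as.integer(origin) - 2)
    covpart <- if (config$cov_var > 0 && sd(covlin) > 0) {
      sqrt(config$cov_var) * as.numeric(scale(covlin))
    } else rep(0, n)
    noise <- rnorm(n, 0, sqrt(max(1 - h2 - config$cov_var, 1e-12)))
    bmi_z <- signal + covpart + noise
    cohort <- tibble::tibble(
      id = dosage$id, sex = sex, age = age, tanner = tanner, origin = origin,
      pgrs = g, bmi_z = bmi_z,
      weight_status = cut(bmi_z, c(-Inf, config$zcut_ow, config$zcut_ob, Inf),
                          labels = c("NW", "OW", "OB"), right = FALSE)
    )
    truth <- list(h2_target = h2,
                  realized_h2 = if (var(bmi_z) > 0) var(signal) / var(bmi_z) else 0,
                  beta_score = if (h2 > 0 && sd(g) > 0) sqrt(h2) / sd(g) else 0,
                  score = g)
    list(cohort = cohort, truth = truth)
  })
}

#' Add simulated environment/lifestyle factors
#'
#' Appends `n_env_factors` questionnaire-style columns (`env_01`, ...).
#' Factors paired with a nonzero configured interaction coefficient modify
#' BMI Z by `coefficient x score x factor` (the literal moderated-regression
#' product term); all other factors are independent noise.
#'
#' @param cohort Cohort tibble with `bmi_z` and `pgrs` columns.
#' @param config A [sim_config()]; `config$gxe_effects` holds the true
#'   interaction coefficients, matched to the first factors unless named
#'   (names must be factor column names such as `"env_01"`).
#' @return The cohort with environment columns appended and `bmi_z` updated;
#'   the applied coefficients are recorded in the `"gxe_truth"` attribute.
#' @export
simulate_environment <- function(cohort, config) {
  stopifnot(inherits(config, "sim_config"))
  assert_cols(cohort, c("bmi_z", "pgrs"), "cohort")
  k <- config$n_env_factors
  eff <- config$gxe_effects
  if (length(eff) > k) abort("More nonzero interaction effects than environment factors.")
  n <- nrow(cohort)
  nm <- sprintf("env_%02d", seq_len(k))
  with_seed(derive_seed(config$seed, 4L), {
    env <- if (config$env_type == "ordinal") {
      matrix(sample(0:4, n * k, replace = TRUE), n, k)
    } else {
      matrix(rnorm(n * k), n, k)
    }
    colnames(env) <- nm
    truth <- setNames(numeric(k), nm)
    if (length(eff) > 0) {
      tgt <- if (!is.null(names(eff)) && all(names(eff) != "")) names(eff) else nm[seq_along(eff)]
      bad <- setdiff(tgt, nm)
      if (length(bad) > 0) abort(sprintf("Unknown environment factor(s): %s", paste(bad, collapse = ", ")))
      truth[tgt] <- eff
      cohort$bmi_z <- cohort$bmi_z +
        rowSums(sweep(env[, tgt, drop = FALSE], 2, as.numeric(eff), `*`)) * cohort$pgrs
    }
    out <- dplyr::bind_cols(cohort, tibble::as_tibble(env))
    attr(out, "gxe_truth") <- truth
    out
  })
}

#' Simulate a two-timepoint pubertal trajectory cohort
#'
#' Generates one child per slot of `traj_group_sizes`, with a prepubertal
#' baseline (Tanner I) and a pubertal follow-up (Tanner II-V) whose BMI
#' Z-score and HOMA-IR values fall on the group-consistent side of the
#' weight and insulin-resistance cut-offs (2.5 prepubertal; 3.38 boys / 3.90
#' girls pubertal, both inclusive). Scores are N(1.18, 0.13) draws; groups
#' listed in `traj_enrich_groups` have their top-tertile odds multiplied by
#' `traj_enrich_or`.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (long tibble, one row per id x timepoint) and
#'   `truth` (group labels and enrichment parameters).
#' @export
simulate_longitudinal <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- config$traj_group_sizes
  groups <- c("NW_nonIR_stable", "OWOB_nonIR_stable", "OWOB_IR_resolved",
              "OWOB_incident_IR", "OWOB_persistent_IR")
  n <- sum(sizes)
  cuts <- ir_cutoffs()
  with_seed(derive_seed(config$seed, 5L), {
    group <- rep(groups, sizes)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    origin <- factor(sample(c("cordoba", "santiago", "zaragoza"), n, replace = TRUE))
    # score: base normal, with optional top-tertile enrichment
    mu <- 1.18; s <- 0.13
    q2 <- qnorm(2 / 3, mu, s)
    base_top <- runif(n) < 1 / 3
    enrich <- group %in% config$traj_enrich_groups & config$traj_enrich_or != 1
    odds <- (1 / 3) / (2 / 3) * config$traj_enrich_or
    p_top <- odds / (1 + odds)
    top <- ifelse(enrich, runif(n) < p_top, base_top)
    u <- runif(n)
    pgrs <- ifelse(top,
                   qnorm(2 / 3 + u / 3, mu, s),
                   qnorm(u * 2 / 3, mu, s))
    ir0 <- group %in% c("OWOB_IR_resolved", "OWOB_persistent_IR")
    ir1 <- group %in% c("OWOB_incident_IR", "OWOB_persistent_IR")
    nw <- group == "NW_nonIR_stable"
    draw_homa <- function(is_ir, cutoff) {
      ifelse(is_ir, cutoff * runif(n, 1.05, 1.8), cutoff * runif(n, 0.3, 0.95))
    }
    cut1 <- ifelse(sex == "male", cuts$pubertal_boys, cuts$pubertal_girls)
    homa0 <- draw_homa(ir0, cuts$prepubertal)
    homa1 <- draw_homa(ir1, cut1)
    draw_bmiz <- function(is_nw) {
      ow <- runif(n) < 0.3  # overweight rather than obese among the OW/OB groups
      ifelse(is_nw, runif(n, -1.5, config$zcut_ow - 0.01),
             ifelse(ow, runif(n, config$zcut_ow, config$zcut_ob - 0.01),
                    runif(n, config$zcut_ob, config$zcut_ob + 2)))
    }
    bmi0 <- draw_bmiz(nw)
    bmi1 <- draw_bmiz(nw)
    age0 <- runif(n, 6, 9)
    age1 <- age0 + runif(n, 3, 5)
    tanner1 <- factor(c("II", "III", "IV", "V")[sample.int(4L, n, replace = TRUE)],
                      levels = c("I", "II", "III", "IV", "V"))
    ids <- sprintf("long%04d", seq_len(n))
    cohort <- dplyr::bind_rows(
      tibble::tibble(id = ids, group = group, timepoint = "T0", sex = sex,
                     age = age0, tanner = factor("I", levels = levels(tanner1)),
                     origin = origin, bmi_z = bmi0, homa_ir = homa0, pgrs = pgrs),
      tibble::tibble(id = ids, group = group, timepoint = "T1", sex = sex,
                     age = age1, tanner = tanner1, origin = origin,
                     bmi_z = bmi1, homa_ir = homa1, pgrs = pgrs)
    ) |> dplyr::arrange(.data$id, .data$timepoint)
    list(cohort = cohort,
         truth = list(groups = setNames(group, ids),
                      enrich_or = config$traj_enrich_or,
                      enriched = config$traj_enrich_groups))
  })
}

#' Simulate a two-arm weight-reduction trial
#'
#' Placebo/treated children with obesity measured at baseline (T0) and after
#' the intervention (T1). The treated arm's BMI Z reduction (T0 - T1) is
#' shifted by `rct_treat_effect` plus `rct_interaction x score`; a
#' per-patient random intercept induces within-child correlation so both the
#' delta-regression and the mixed-model analyses apply.
#'
#' @param config A [sim_config()].
#' @return List with `cohort` (long tibble: `id`, `arm`, `timepoint`, `sex`,
#'   `tanner`, `pgrs`, `bmi_z`) and `truth` (the generating effects).
#' @export
simulate_rct <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$rct_n_placebo + config$rct_n_treated
  arm <- rep(c("placebo", "metformin"), c(config$rct_n_placebo, config$rct_n_treated))
  with_seed(derive_seed(config$seed, 6L), {
    sex <- sample(c("male", "female"), n, replace = TRUE)
    tanner <- factor(sample(c("I", "II", "III", "IV", "V"), n, replace = TRUE),
                     levels = c("I", "II", "III", "IV", "V"))
    pgrs <- rnorm(n, 1.18, 0.13)
    b <- rnorm(n, 0, 0.5)                      # patient random intercept
    treated <- as.integer(arm == "metformin")
    bmi0 <- 2.5 + b + rnorm(n, 0, 0.3)
    delta <- 0.1 + config$rct_treat_effect * treated +
      config$rct_interaction * pgrs * treated + rnorm(n, 0, 0.3)
    bmi1 <- bmi0 - delta
    ids <- sprintf("rct%04d", seq_len(n))
    cohort <- dplyr::bind_rows(
      tibble::tibble(id = ids, arm = arm, timepoint = "T0", sex = sex,
                     tanner = tanner, pgrs = pgrs, bmi_z = bmi0),
      tibble::tibble(id = ids, arm = arm, timepoint = "T1", sex = sex,
                     tanner = tanner, pgrs = pgrs, bmi_z = bmi1)
    ) |> dplyr::arrange(.data$id, .data$timepoint)
    list(cohort = cohort,
         truth = list(treat_effect = config$rct_treat_effect,
                      interaction = config$rct_interaction,
                      ranef_sd = 0.5))
  })
}
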