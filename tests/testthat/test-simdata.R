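test_that("panel simulation is deterministic, bounded and handles the empty case", {
  cfg <- sim_config(n_snps = 44, seed = 7)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1$panel), 44)
  expect_true(all(p1$panel$beta > 0))

  empty <- simulate_panel(sim_config(n_snps = 0, n_qc_fail_callrate = 0,
                                     n_qc_fail_hwe = 0))
  expect_equal(nrow(empty$panel), 0)

  big <- simulate_panel(sim_config(n_snps = 1000, maf_range = c(0.1, 0.5),
                                   n_qc_fail_callrate = 0, n_qc_fail_hwe = 0,
                                   seed = 3))
  expect_true(all(big$truth$freq >= 0.1 & big$truth$freq <= 0.5))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(maf_range = c(0.2, 0.6)), "maf_range")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), "maf_range")
  expect_error(sim_config(h2_target = 1), "h2_target")
  expect_error(sim_config(n_snps = 5, n_qc_fail_callrate = 4, n_qc_fail_hwe = 2),
               "exceed")
  expect_error(sim_config(n_individuals = 10)$seed, NA)
  expect_error(
    simulate_genotypes(simulate_panel(sim_config(n_snps = 5, seed = 1,
                                                 n_qc_fail_callrate = 0,
                                                 n_qc_fail_hwe = 0))$truth,
                       sim_config(n_snps = 5, n_individuals = 10,
                                  n_qc_fail_callrate = 0, n_qc_fail_hwe = 1)),
    "minimum n")
})

test_that("genotypes follow Hardy-Weinberg proportions and the missingness contract", {
  cfg <- sim_config(n_snps = 1, maf_range = c(0.3, 0.3), n_individuals = 10000,
                    n_qc_fail_callrate = 0, n_qc_fail_hwe = 0,
                    missing_rate = 0, seed = 11)
  sim <- simulate_genotypes(simulate_panel(cfg)$truth, cfg)
  g <- sim$genotypes[[2]]
  expect_false(anyNA(g))
  pan <- simulate_panel(cfg)$panel
  dos <- to_dosage(sim$genotypes, pan)[[2]]
  # expected (p^2, 2pq, q^2) at p = 0.3 for the risk allele
  exp_freq <- c(`2` = 0.09, `1` = 0.42, `0` = 0.49)
  for (d in c(0, 1, 2)) {
    fhat <- mean(dos == d)
    f0 <- exp_freq[as.character(d)]
    se <- sqrt(f0 * (1 - f0) / 10000)
    expect_lt(abs(fhat - f0), 3 * se)
  }
})

test_that("engineered failures land where designated and clean SNPs stay callable", {
  cfg <- sim_config(n_snps = 20, n_individuals = 600, n_qc_fail_callrate = 3,
                    n_qc_fail_hwe = 2, missing_rate = 0, seed = 5)
  sim <- simulate_genotypes(simulate_panel(cfg)$truth, cfg)
  cr <- call_rate(sim$genotypes)
  truth <- sim$truth
  expect_equal(sum(truth$qc_class == "fail_callrate"), 3)
  expect_true(all(cr$call_rate[match(truth$snp_id[truth$qc_class == "fail_callrate"],
                                     cr$snp_id)] < 0.95))
  expect_true(all(cr$call_rate[match(truth$snp_id[truth$qc_class == "clean"],
                                     cr$snp_id)] == 1))
  expect_true(all(truth$f_distortion[truth$qc_class == "fail_hwe"] > 0))
})

test_that("phenotype variance decomposition hits its target and the null is flat", {
  cfg <- sim_config(n_snps = 20, n_individuals = 5000, n_qc_fail_callrate = 0,
                    n_qc_fail_hwe = 0, missing_rate = 0, h2_target = 0.05,
                    seed = 21)
  sp <- simulate_panel(cfg)
  dos <- to_dosage(simulate_genotypes(sp$truth, cfg)$genotypes, sp$panel)
  ph <- simulate_phenotypes(dos, sp$panel, cfg)
  expect_gt(ph$truth$realized_h2, 0.03)
  expect_lt(ph$truth$realized_h2, 0.07)
  expect_setequal(levels(ph$cohort$weight_status), c("NW", "OW", "OB"))

  cfg0 <- sim_config(n_snps = 20, n_individuals = 2000, n_qc_fail_callrate = 0,
                     n_qc_fail_hwe = 0, missing_rate = 0, h2_target = 0,
                     seed = 22)
  ph0 <- simulate_phenotypes(dos[1:2000, ], sp$panel, cfg0)
  d0 <- dplyr::inner_join(ph0$cohort, compute_pgrs(dos[1:2000, ], sp$panel) |>
                            dplyr::rename(score = "pgrs"), by = "id")
  r0 <- fit_linear(d0, "bmi_z", "score")$result
  expect_lt(abs(r0$statistic), 3)
})

test_that("environment factors carry the configured interaction and nothing else", {
  cfg <- sim_config(n_snps = 10, n_individuals = 400, n_qc_fail_callrate = 0,
                    n_qc_fail_hwe = 0, missing_rate = 0, n_env_factors = 5,
                    gxe_effects = c(env_02 = 0.5), seed = 13)
  sp <- simulate_panel(cfg)
  dos <- to_dosage(simulate_genotypes(sp$truth, cfg)$genotypes, sp$panel)
  coh <- simulate_environment(simulate_phenotypes(dos, sp$panel, cfg)$cohort, cfg)
  expect_length(grep("^env_", names(coh)), 5)
  expect_equal(unname(attr(coh, "gxe_truth")["env_02"]), 0.5)
  expect_error(
    simulate_environment(coh,
                         sim_config(n_env_factors = 1,
                                    gxe_effects = c(0.1, 0.2))),
    "factors")
})

test_that("longitudinal cohort bookkeeping and status sides are correct", {
  cfg <- sim_config(seed = 2)
  sim <- simulate_longitudinal(cfg)
  expect_equal(nrow(sim$cohort), 96 * 2)
  expect_equal(length(unique(sim$cohort$id)), 96)
  nw0 <- dplyr::filter(sim$cohort, .data$group == "NW_nonIR_stable",
                       .data$timepoint == "T0")
  expect_true(all(nw0$homa_ir < 2.5))
  nw1 <- dplyr::filter(sim$cohort, .data$group == "NW_nonIR_stable",
                       .data$timepoint == "T1")
  cuts <- ir_cutoffs()
  lim <- ifelse(nw1$sex == "male", cuts$pubertal_boys, cuts$pubertal_girls)
  expect_true(all(nw1$homa_ir < lim))
  per <- dplyr::filter(sim$cohort, .data$group == "OWOB_persistent_IR")
  expect_true(all(per$bmi_z >= cfg$zcut_ow))
})

test_that("simulated trial has the configured arm sizes and both timepoints", {
  sim <- simulate_rct(sim_config(seed = 4))
  expect_equal(sum(sim$cohort$arm == "placebo"), 59 * 2)
  expect_equal(sum(sim$cohort$arm == "metformin"), 65 * 2)
  expect_setequal(unique(sim$cohort$timepoint), c("T0", "T1"))
  expect_identical(sim$cohort, simulate_rct(sim_config(seed = 4))$cohort)
})
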