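# Independent oracles and small fixture builders used across test files.

# Direct-factorial evaluation of the exact Hardy-Weinberg null: enumerate
# every heterozygote count compatible with the observed allele totals and sum
# the probabilities of configurations no more probable than the observed one.
# Independent of the recurrence-based implementation in the package.
enum_hwe_p <- function(n_rr, n_rh, n_hh) {
  n <- n_rr + n_rh + n_hh
  n_a <- 2 * n_rr + n_rh
  n_b <- 2 * n_hh + n_rh
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(hets, function(h) {
    r <- (n_a - h) / 2
    o <- (n_b - h) / 2
    lfactorial(n) - lfactorial(r) - lfactorial(h) - lfactorial(o) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }, double(1))
  p <- exp(logp)
  p_obs <- p[hets == n_rh]
  sum(p[p <= p_obs * (1 + 1e-12)])
}

# Exhaustive case-control pair counting AUC (ties get half credit).
pair_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  mean(outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b)))
}

# 2x2 contingency odds ratio and Woolf log-OR standard error.
table_or <- function(exposure, outcome) {
  a <- sum(exposure == 1 & outcome == 1)
  b <- sum(exposure == 1 & outcome == 0)
  c <- sum(exposure == 0 & outcome == 1)
  d <- sum(exposure == 0 & outcome == 0)
  list(or = (a * d) / (b * c), se = sqrt(1 / a + 1 / b + 1 / c + 1 / d))
}

# A tiny hand-constructed panel + genotype pair for unit tests.
tiny_panel <- function() {
  tibble::tibble(
    snp_id = c("s1", "s2", "s3"),
    chrom = c("1", "2", "3"), pos = c(100L, 200L, 300L),
    risk_allele = c("A", "G", "C"),
    other_allele = c("G", "T", "T"),
    beta = c(0.05, 0.02, 0.08)
  )
}

tiny_genotypes <- function() {
  tibble::tibble(
    id = c("i1", "i2", "i3", "i4"),
    s1 = c("AA", "AG", "GG", NA),
    s2 = c("GT", "TT", "GG", "GT"),
    s3 = c("CC", "CT", NA, "TT")
  )
}

# Synthetic half-year weight cut-off grid (not the published reference table).
toy_cutoff_table <- function() {
  grid <- expand.grid(sex = c("male", "female"), age = seq(6, 14, by = 0.5),
                      stringsAsFactors = FALSE)
  grid$ow_cutoff <- 17 + 0.45 * (grid$age - 6) + ifelse(grid$sex == "female", 0.2, 0)
  grid$ob_cutoff <- grid$ow_cutoff + 2.5
  weight_cutoff_table(grid)
}

# Long-format two-arm trial table built directly (independent of simulate_rct).
toy_rct <- function(n_per_arm = 40, interaction = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_arm
    arm <- rep(c("placebo", "metformin"), each = n_per_arm)
    treated <- as.integer(arm == "metformin")
    pgrs <- rnorm(n, 1.2, 0.15)
    b <- rnorm(n, 0, 0.4)
    bmi0 <- 2.5 + b + rnorm(n, 0, 0.25)
    delta <- 0.1 + 0.3 * treated + interaction * pgrs * treated + rnorm(n, 0, 0.25)
    ids <- sprintf("p%03d", seq_len(n))
    tanner <- factor(sample(c("I", "II", "III"), n, replace = TRUE))
    dplyr::bind_rows(
      tibble::tibble(id = ids, arm = arm, timepoint = "T0", sex = "female",
                     tanner = tanner, pgrs = pgrs, bmi_z = bmi0),
      tibble::tibble(id = ids, arm = arm, timepoint = "T1", sex = "female",
                     tanner = tanner, pgrs = pgrs, bmi_z = bmi0 - delta)
    )
  })
}
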