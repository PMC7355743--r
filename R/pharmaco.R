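#' Score-by-treatment interaction on the delta response
#'
#' Reshapes the long trial table to one row per child, computes the BMI
#' Z-score response as `T0 - T1` (positive = reduction), and fits
#' `delta ~ score + arm + score:arm + covariates` by OLS. The reported row
#' is the score-by-treatment interaction.
#'
#' @param rct Long-format trial tibble: `id`, `arm` (two levels, the first
#'   alphabetically is taken as reference unless `arm` is a factor),
#'   `timepoint` (`"T0"`/`"T1"`), `bmi_z`, a score column and covariates
#'   (constant within child).
#' @param score_col Score column name (default `"pgrs"`).
#' @param covariates Covariate column names (default none).
#' @return An object of class `grs_fit` whose `$result` is the interaction
#'   row; the delta direction is recorded in `$direction`.
#' @export
drug_response_interaction <- function(rct, score_col = "pgrs", covariates = NULL) {
  wide <- rct_to_wide(rct, score_col, covariates)
  if (length(unique(wide$arm)) < 2) abort("Both trial arms must be present.")
  wide$treated <- as.integer(wide$arm == treatment_level(wide$arm))
  wide$delta <- wide$bmi_z_t0 - wide$bmi_z_t1
  rhs <- paste(c(sprintf("`%s` * treated", score_col),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fml <- as.formula(paste("delta ~", rhs), env = globalenv())
  fit <- lm(fml, data = wide)
  check_full_rank(fit)
  sm <- coef(summary(fit))
  row <- grep(":", rownames(sm), fixed = TRUE, value = TRUE)[1]
  ci <- wald_ci(sm[row, 1], sm[row, 2], df = fit$df.residual)
  result <- tibble::tibble(
    term = sprintf("%s:treated", score_col),
    estimate = sm[row, 1], se = sm[row, 2], statistic = sm[row, 3],
    p_value = sm[row, 4], ci_lo = ci[1], ci_hi = ci[2], n_used = nrow(wide)
  )
  structure(list(fit = fit, fit_reduced = NULL, result = result,
                 variance = tibble::tibble(full_r2 = summary(fit)$r.squared),
                 type = "linear", direction = "T0_minus_T1"),
            class = "grs_fit")
}

#' Mixed-model three-way score x time x treatment test
#'
#' Linear mixed-effects model on the long trial table with a random
#' intercept per child, fixed effects for score, time and arm with all
#' two-way products and the three-way product, plus covariates. Inference is
#' the Wald t-test on the three-way term (Satterthwaite degrees of freedom).
#' With balanced, complete two-timepoint data the three-way fixed effect
#' equals the delta-regression interaction of
#' [drug_response_interaction()] up to the sign implied by the opposite
#' delta direction (there T0 - T1; here time runs forward).
#'
#' @inheritParams drug_response_interaction
#' @param covariates Covariate column names (default `"tanner"`).
#' @return List with `result` (the three-way row as a tibble), `ranef_sd`
#'   (random-intercept SD) and `fit` (the `lmerMod`).
#' @export
lme_three_way <- function(rct, score_col = "pgrs", covariates = "tanner") {
  assert_cols(rct, c("id", "arm", "timepoint", "bmi_z", score_col, covariates))
  reps <- table(rct$id)
  if (mean(reps >= 2) < 0.5) {
    abort("Most children need repeated measures; with one timepoint each use drug_response_interaction().")
  }
  dat <- rct
  dat$time <- as.integer(dat$timepoint == "T1")
  dat$treated <- as.integer(dat$arm == treatment_level(dat$arm))
  rhs <- paste(c(sprintf("`%s` * time * treated", score_col),
                 sprintf("`%s`", covariates), "(1 | id)"), collapse = " + ")
  fml <- as.formula(paste("bmi_z ~", rhs), env = globalenv())
  fit <- lmerTest::lmer(fml, data = dat, REML = TRUE)
  sm <- coef(summary(fit))
  row <- rownames(sm)[vapply(strsplit(rownames(sm), ":"), length, integer(1)) == 3L]
  if (length(row) != 1) abort("Three-way term not found in the fit.")
  ci <- wald_ci(sm[row, "Estimate"], sm[row, "Std. Error"], df = sm[row, "df"])
  result <- tibble::tibble(
    term = sprintf("%s:time:treated", score_col),
    estimate = sm[row, "Estimate"], se = sm[row, "Std. Error"],
    statistic = sm[row, "t value"], p_value = sm[row, "Pr(>|t|)"],
    ci_lo = ci[1], ci_hi = ci[2], n_used = length(unique(dat$id))
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  list(result = result,
       ranef_sd = vc$sdcor[vc$grp == "id"][1],
       fit = fit)
}

# Treatment arm = the non-reference level; "placebo" is the reference when
# present, otherwise the first sorted level.
treatment_level <- function(arm) {
  lv <- if (is.factor(arm)) levels(arm) else sort(unique(as.character(arm)))
  if ("placebo" %in% lv) setdiff(lv, "placebo")[1] else lv[length(lv)]
}

rct_to_wide <- function(rct, score_col, covariates) {
  assert_cols(rct, c("id", "arm", "timepoint", "bmi_z", score_col, covariates))
  if (!all(c("T0", "T1") %in% rct$timepoint)) {
    abort("Both timepoints T0 and T1 are required.")
  }
  keep <- unique(c("id", "arm", score_col, covariates))
  base <- dplyr::distinct(rct[keep])
  if (anyDuplicated(base$id)) abort("Arm, score or covariates vary within a child.")
  wide <- tidyr::pivot_wider(rct[c("id", "timepoint", "bmi_z")],
                             names_from = "timepoint", values_from = "bmi_z")
  names(wide) <- c("id", "bmi_z_t0", "bmi_z_t1")[match(names(wide), c("id", "T0", "T1"))]
  out <- dplyr::inner_join(base, wide, by = "id")
  out[complete.cases(out[c("bmi_z_t0", "bmi_z_t1")]), , drop = FALSE]
}
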