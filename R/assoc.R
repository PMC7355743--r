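#' Linear association between an outcome and the score
#'
#' Ordinary least squares of `outcome` on `exposure` plus covariates.
#' Reports the exposure row (estimate in outcome units per score unit, SE,
#' t, p, 95% t-based CI) and the variance explained: full-model R-squared
#' and the exposure's partial R-squared, the drop in R-squared when the
#' exposure is removed.
#'
#' @param data A data frame; rows with missing values in any used column are
#'   dropped (complete-case analysis).
#' @param outcome,exposure Column names.
#' @param covariates Character vector of covariate column names (categorical
#'   columns should be factors; they enter as indicator terms).
#' @return An object of class `grs_fit`; see [tidy.grs_fit()],
#'   [glance.grs_fit()]. The exposure row is in `$result`, variance measures
#'   in `$variance`.
#' @export
fit_linear <- function(data, outcome, exposure, covariates = NULL) {
  assert_cols(data, c(outcome, exposure, covariates))
  dat <- data[complete.cases(data[c(outcome, exposure, covariates)]),
              c(outcome, exposure, covariates), drop = FALSE]
  n <- nrow(dat)
  if (n <= length(covariates) + 2) abort("Too few complete cases for the model.")
  if (length(unique(dat[[exposure]])) < 2) abort(sprintf("Exposure `%s` is constant.", exposure))
  fit <- lm(build_formula(outcome, c(exposure, covariates)), data = dat)
  check_full_rank(fit)
  fit_red <- lm(build_formula(outcome, covariates), data = dat)
  sm <- summary(fit)
  row <- coef(sm)[exposure_term(fit, exposure), , drop = FALSE]
  ci <- wald_ci(row[1, 1], row[1, 2], df = fit$df.residual)
  result <- tibble::tibble(
    term = exposure, estimate = row[1, 1], se = row[1, 2],
    statistic = row[1, 3], p_value = row[1, 4],
    ci_lo = ci[1], ci_hi = ci[2], n_used = n
  )
  variance <- tibble::tibble(
    full_r2 = sm$r.squared,
    full_adj_r2 = sm$adj.r.squared,
    reduced_r2 = summary(fit_red)$r.squared,
    partial_r2 = sm$r.squared - summary(fit_red)$r.squared
  )
  structure(list(fit = fit, fit_reduced = fit_red, result = result,
                 variance = variance, type = "linear"),
            class = "grs_fit")
}

#' Logistic association between a binary outcome and the score
#'
#' Maximum-likelihood logistic regression. Reports the exposure log-odds
#' row with `or = exp(estimate)` and the per-0.1-unit odds ratio
#' `exp(0.1 * estimate)` (an 0.1 change in a score is the natural increment
#' when scores span roughly one unit). Deviance-based D-squared
#' (`1 - deviance/null deviance`) and Nagelkerke pseudo-R-squared are both
#' reported: published work sometimes labels such a quantity "h2" without
#' defining it, so the two candidates are emitted side by side.
#'
#' @inheritParams fit_linear
#' @param outcome Binary (0/1, logical, or two-level factor) column name.
#' @return An object of class `grs_fit`.
#' @export
fit_logistic <- function(data, outcome, exposure, covariates = NULL) {
  assert_cols(data, c(outcome, exposure, covariates))
  dat <- data[complete.cases(data[c(outcome, exposure, covariates)]),
              c(outcome, exposure, covariates), drop = FALSE]
  y <- dat[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) abort("Outcome must be binary.")
  if (length(unique(y)) < 2) abort("Both outcome classes must be present.")
  dat[[outcome]] <- y
  fit <- fit_glm_guarded(build_formula(outcome, c(exposure, covariates)), dat)
  check_full_rank(fit)
  fit_red <- fit_glm_guarded(build_formula(outcome, covariates), dat)
  sm <- summary(fit)
  row <- coef(sm)[exposure_term(fit, exposure), , drop = FALSE]
  ci <- wald_ci(row[1, 1], row[1, 2])
  result <- tibble::tibble(
    term = exposure, estimate = row[1, 1], se = row[1, 2],
    statistic = row[1, 3], p_value = row[1, 4],
    ci_lo = ci[1], ci_hi = ci[2],
    or = exp(row[1, 1]), or_ci_lo = exp(ci[1]), or_ci_hi = exp(ci[2]),
    or_per_0.1 = exp(0.1 * row[1, 1]),
    n_used = nrow(dat)
  )
  variance <- tibble::tibble(
    d2 = 1 - fit$deviance / fit$null.deviance,
    nagelkerke = nagelkerke_r2(fit),
    nagelkerke_reduced = nagelkerke_r2(fit_red)
  )
  structure(list(fit = fit, fit_reduced = fit_red, result = result,
                 variance = variance, type = "logistic"),
            class = "grs_fit")
}

fit_glm_guarded <- function(formula, data) {
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) {
    abort(paste("Logistic fit shows (quasi-)complete separation:",
                "fitted probabilities reached 0/1 or a coefficient diverged.",
                "Check for a predictor that perfectly splits the outcome."))
  }
  fit
}

nagelkerke_r2 <- function(fit) {
  n <- length(fit$y)
  cox_snell <- 1 - exp((fit$deviance - fit$null.deviance) / n)
  cox_snell / (1 - exp(-fit$null.deviance / n))
}

check_full_rank <- function(fit) {
  if (any(is.na(coef(fit)))) {
    abort(sprintf("Model is rank deficient; collinear term(s): %s.",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")))
  }
  invisible(fit)
}

# First coefficient name generated by `exposure` (handles backquoting).
exposure_term <- function(fit, exposure) {
  nm <- names(coef(fit))
  hit <- nm[nm %in% c(exposure, sprintf("`%s`", exposure))]
  if (length(hit) == 0) abort(sprintf("Term `%s` not found in the fit.", exposure))
  hit[1]
}

#' Odds ratios of an outcome across score strata
#'
#' One logistic model with indicator terms for every non-reference stratum,
#' giving each stratum's odds ratio against the reference (e.g. Q4 vs Q1).
#'
#' @param data Data frame containing the outcome, a `stratum` factor and any
#'   covariates.
#' @param outcome Binary outcome column name.
#' @param reference Reference stratum label (default `"Q1"`).
#' @param covariates Covariate column names.
#' @return Tibble with one row per non-reference stratum: log-OR `estimate`,
#'   `se`, `statistic`, `p_value`, `or`, CI bounds and `n_used`.
#' @export
quantile_contrast <- function(data, outcome, reference = "Q1", covariates = NULL) {
  assert_cols(data, c(outcome, "stratum", covariates))
  dat <- data[complete.cases(data[c(outcome, "stratum", covariates)]), , drop = FALSE]
  dat$stratum <- droplevels(as.factor(dat$stratum))
  if (!reference %in% levels(dat$stratum)) {
    abort(sprintf("Reference stratum '%s' is empty or absent.", reference))
  }
  if (any(table(dat$stratum) == 0)) abort("Every stratum must be non-empty.")
  dat$stratum <- stats::relevel(dat$stratum, ref = reference)
  y <- dat[[outcome]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  dat[[outcome]] <- as.integer(y)
  fit <- fit_glm_guarded(build_formula(outcome, c("stratum", covariates)), dat)
  sm <- coef(summary(fit))
  rows <- grep("^stratum", rownames(sm), value = TRUE)
  purrr::map_dfr(rows, function(r) {
    ci <- wald_ci(sm[r, 1], sm[r, 2])
    tibble::tibble(
      stratum = sub("^stratum", "", r), reference = reference,
      estimate = sm[r, 1], se = sm[r, 2], statistic = sm[r, 3],
      p_value = sm[r, 4], or = exp(sm[r, 1]),
      or_ci_lo = exp(ci[1]), or_ci_hi = exp(ci[2]), n_used = nrow(dat)
    )
  })
}

#' Per-SNP association scan
#'
#' One linear model per variant (dosage as exposure, shared covariates) with
#' a Benjamini-Hochberg adjusted p-value column across the scan. Per-SNP
#' fitting errors are recorded in the row, not fatal.
#'
#' @param dosage Dosage tibble (`id` + numeric SNP columns).
#' @param cohort Phenotype tibble with `id`, the outcome and covariates.
#' @param outcome Outcome column name (default `"bmi_z"`).
#' @param covariates Covariate column names.
#' @return Tibble of class `grs_scan`: `snp_id`, estimate columns, `fdr`,
#'   and an `error` column (`NA` when the fit succeeded).
#' @export
per_snp_scan <- function(dosage, cohort, outcome = "bmi_z", covariates = NULL) {
  snps <- snp_cols(dosage)
  dat <- dplyr::inner_join(dosage, cohort, by = "id")
  rows <- purrr::map(snps, function(s) {
    tryCatch(
      dplyr::mutate(dplyr::rename(fit_linear(dat, outcome, s, covariates)$result,
                                  snp_id = "term"),
                    error = NA_character_),
      error = function(e) {
        tibble::tibble(snp_id = s, estimate = NA_real_, se = NA_real_,
                       statistic = NA_real_, p_value = NA_real_,
                       ci_lo = NA_real_, ci_hi = NA_real_, n_used = NA_integer_,
                       error = conditionMessage(e))
      }
    )
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$fdr[ok] <- bh_fdr(out$p_value[ok])
  class(out) <- c("grs_scan", class(out))
  out
}

#' Stepwise AIC selection of independently contributing SNPs
#'
#' Greedy bidirectional search minimising the Akaike information criterion,
#' starting from the covariate-only model; covariates are always retained.
#' Ties and the visiting order are deterministic given the input order of
#' candidates.
#'
#' @param data Data frame with outcome, candidate dosage columns and
#'   covariates (complete cases are used).
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate SNP columns.
#' @param covariates Covariate column names, never dropped.
#' @return List with `selected` (character), `aic`, and `fit` (the final
#'   `lm`).
#' @export
stepwise_aic <- function(data, outcome, candidates, covariates = NULL) {
  if (length(candidates) < 1) abort("Need at least one candidate.")
  assert_cols(data, c(outcome, candidates, covariates))
  dat <- data[complete.cases(data[c(outcome, candidates, covariates)]),
              c(outcome, candidates, covariates), drop = FALSE]
  # step() re-evaluates candidate models in the formula environment, so the
  # data must be reachable from there
  fml_base <- build_formula(outcome, covariates)
  upper <- build_formula(outcome, c(covariates, candidates))
  environment(fml_base) <- environment()
  environment(upper) <- environment()
  base <- lm(fml_base, data = dat)
  final <- step(base,
                scope = list(lower = formula(base), upper = upper),
                direction = "both", trace = 0)
  kept <- attr(terms(final), "term.labels")
  kept <- gsub("`", "", kept)
  list(selected = intersect(candidates, kept), aic = AIC(final), fit = final)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: with p-values sorted ascending,
#' the i-th adjusted value is `min_{j >= i} (p_j * m / j)` capped at 1, and
#' results are returned in the input order.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
#' @examples
#' bh_fdr(c(0.001, 0.01, 0.04, 0.5))
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  out <- numeric(m)
  # guard the adjusted >= raw invariant against one-ulp rounding in p*m/m
  out[o] <- pmin(pmax(q, p[o]), 1)
  out
}

#' Variance explained by a model component
#'
#' For nested linear models: the R-squared difference. For nested logistic
#' models: deviance-based D-squared of each fit plus the Nagelkerke
#' pseudo-R-squared difference.
#'
#' @param fit_full,fit_reduced Nested `lm` or `glm` fits on identical rows
#'   (or `grs_fit` objects, whose stored full/reduced pair is used when only
#'   `fit_full` is given).
#' @return One-row tibble of variance measures.
#' @export
variance_explained <- function(fit_full, fit_reduced = NULL) {
  if (inherits(fit_full, "grs_fit") && is.null(fit_reduced)) {
    fit_reduced <- fit_full$fit_reduced
    fit_full <- fit_full$fit
  }
  n_f <- length(stats::residuals(fit_full))
  n_r <- length(stats::residuals(fit_reduced))
  if (n_f != n_r) abort("Models were fitted on different numbers of rows.")
  t_full <- attr(terms(fit_full), "term.labels")
  t_red <- attr(terms(fit_reduced), "term.labels")
  if (!all(t_red %in% t_full)) abort("`fit_reduced` is not nested in `fit_full`.")
  if (inherits(fit_full, "glm")) {
    tibble::tibble(
      d2_full = 1 - fit_full$deviance / fit_full$null.deviance,
      d2_reduced = 1 - fit_reduced$deviance / fit_reduced$null.deviance,
      nagelkerke_delta = nagelkerke_r2(fit_full) - nagelkerke_r2(fit_reduced)
    )
  } else {
    r2f <- summary(fit_full)$r.squared
    r2r <- summary(fit_reduced)$r.squared
    tibble::tibble(full_r2 = r2f, reduced_r2 = r2r, component_r2 = r2f - r2r)
  }
}

#' @export
#' @method tidy grs_fit
#' @rdname fit_linear
#' @param x A `grs_fit` object.
#' @param ... Unused.
tidy.grs_fit <- function(x, ...) {
  sm <- coef(summary(x$fit))
  df <- if (x$type == "linear") x$fit$df.residual else Inf
  tibble::tibble(
    term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
    statistic = sm[, 3], p_value = sm[, 4],
    ci_lo = sm[, 1] - (if (is.finite(df)) qt(0.975, df) else qnorm(0.975)) * sm[, 2],
    ci_hi = sm[, 1] + (if (is.finite(df)) qt(0.975, df) else qnorm(0.975)) * sm[, 2]
  )
}

#' @export
#' @method glance grs_fit
#' @rdname fit_linear
glance.grs_fit <- function(x, ...) {
  dplyr::bind_cols(
    x$variance,
    tibble::tibble(n = x$result$n_used, aic = AIC(x$fit), model_type = x$type)
  )
}

#' @export
print.grs_fit <- function(x, ...) {
  cat(sprintf("<grs_fit: %s> n = %d\n", x$type, x$result$n_used))
  print(x$result)
  invisible(x)
}

#' Forest-style plot of a scan result
#'
#' @param object A `grs_scan` tibble (from [per_snp_scan()],
#'   [interaction_scan()] or [delta_association()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot grs_scan
autoplot.grs_scan <- function(object, ...) {
  lab <- names(object)[1]
  dat <- dplyr::filter(object, !is.na(.data$estimate))
  dat$label <- stats::reorder(dat[[lab]], dat$estimate)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_lo, xmax = .data$ci_hi),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$fdr < 0.05)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
                                 name = "FDR < 0.05") +
    ggplot2::labs(x = "estimate (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
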