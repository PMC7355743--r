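#' Single gene-by-environment interaction fit
#'
#' Moderated regression of BMI Z-score on the score, one environment factor,
#' their product, and covariates:
#' `bmi_z = b0 + b1*score + b2*E + b3*(score x E) + covariates + e`.
#' Inference is the two-sided marginal t-test on the product coefficient
#' `b3` (with one degree of freedom this is asymptotically equivalent to the
#' likelihood-ratio test). Variables are entered uncentred by default, the
#' literal model form; `center = TRUE` centres score and factor first, which
#' changes the main effects but leaves `b3` identical.
#'
#' @param cohort Data frame with the outcome, score, factor and covariates.
#' @param factor_col Environment factor column (quantitative or ordinal,
#'   entered as numeric codes).
#' @param score_col Score column name (default `"pgrs"`).
#' @param outcome Outcome column name (default `"bmi_z"`).
#' @param covariates Covariate column names (default origin and Tanner).
#' @param center Centre score and factor before fitting (default FALSE).
#' @return One-row tibble: `factor_id`, `beta3`, `se`, `statistic`,
#'   `p_value`, `ci_lo`, `ci_hi`, `n_used`.
#' @export
interaction_fit <- function(cohort, factor_col, score_col = "pgrs",
                            outcome = "bmi_z",
                            covariates = c("origin", "tanner"),
                            center = FALSE) {
  assert_cols(cohort, c(outcome, score_col, factor_col, covariates))
  used <- c(outcome, score_col, factor_col, covariates)
  dat <- cohort[complete.cases(cohort[used]), used, drop = FALSE]
  if (nrow(dat) <= length(covariates) + 4) abort("Too few complete cases.")
  if (!is.numeric(dat[[factor_col]])) {
    abort(sprintf("Factor `%s` must be quantitative or ordinal (numeric codes).", factor_col))
  }
  if (length(unique(dat[[factor_col]])) < 2) {
    abort(sprintf("Factor `%s` is constant.", factor_col))
  }
  if (center) {
    dat[[score_col]] <- dat[[score_col]] - mean(dat[[score_col]])
    dat[[factor_col]] <- dat[[factor_col]] - mean(dat[[factor_col]])
  }
  rhs <- paste(c(sprintf("`%s` * `%s`", score_col, factor_col),
                 sprintf("`%s`", covariates)), collapse = " + ")
  fml <- as.formula(sprintf("`%s` ~ %s", outcome, rhs), env = globalenv())
  fit <- lm(fml, data = dat)
  check_full_rank(fit)
  sm <- coef(summary(fit))
  prod_row <- grep(":", rownames(sm), fixed = TRUE, value = TRUE)
  prod_row <- prod_row[grepl(gsub("`", "", factor_col),
                             gsub("`", "", prod_row), fixed = TRUE)][1]
  ci <- wald_ci(sm[prod_row, 1], sm[prod_row, 2], df = fit$df.residual)
  tibble::tibble(
    factor_id = factor_col, beta3 = sm[prod_row, 1], se = sm[prod_row, 2],
    statistic = sm[prod_row, 3], p_value = sm[prod_row, 4],
    ci_lo = ci[1], ci_hi = ci[2], n_used = nrow(dat)
  )
}

#' Gene-by-environment interaction scan
#'
#' One [interaction_fit()] per listed factor, complete cases per factor,
#' Benjamini-Hochberg FDR across the whole scan (one family, never split
#' into subfamilies), sorted by p-value. Per-factor errors are recorded in
#' the row and do not stop the scan.
#'
#' @inheritParams interaction_fit
#' @param factors Character vector of factor column names; defaults to every
#'   column starting with `"env_"`.
#' @return Tibble of class `grs_scan`, one row per factor, with an `fdr`
#'   column and an `error` column.
#' @export
interaction_scan <- function(cohort, factors = NULL, score_col = "pgrs",
                             outcome = "bmi_z",
                             covariates = c("origin", "tanner"),
                             center = FALSE) {
  if (is.null(factors)) factors <- grep("^env_", names(cohort), value = TRUE)
  if (length(factors) == 0) abort("No environment factors to scan.")
  rows <- purrr::map(factors, function(f) {
    tryCatch(
      dplyr::mutate(
        interaction_fit(cohort, f, score_col, outcome, covariates, center),
        error = NA_character_),
      error = function(e) {
        tibble::tibble(factor_id = f, beta3 = NA_real_, se = NA_real_,
                       statistic = NA_real_, p_value = NA_real_,
                       ci_lo = NA_real_, ci_hi = NA_real_,
                       n_used = NA_integer_, error = conditionMessage(e))
      })
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$fdr[ok] <- bh_fdr(out$p_value[ok])
  out <- dplyr::arrange(out, dplyr::desc(!is.na(.data$p_value)), .data$p_value)
  out <- dplyr::rename(out, estimate = "beta3")
  class(out) <- c("grs_scan", class(out))
  out
}

#' Score-band summaries for interaction plots
#'
#' Splits individuals into three score bands at mean - SD and mean + SD and
#' fits the outcome-on-factor slope within each band, the display used for
#' interaction (crossover) plots.
#'
#' @inheritParams interaction_fit
#' @return Tibble with one row per band (`low`, `mid`, `high`): `n`,
#'   `slope`, `se`, and the band boundaries.
#' @export
stratify_for_plot <- function(cohort, factor_col, score_col = "pgrs",
                              outcome = "bmi_z") {
  assert_cols(cohort, c(outcome, score_col, factor_col))
  used <- c(outcome, score_col, factor_col)
  dat <- cohort[complete.cases(cohort[used]), used, drop = FALSE]
  m <- mean(dat[[score_col]]); s <- sd(dat[[score_col]])
  band <- cut(dat[[score_col]], c(-Inf, m - s, m + s, Inf),
              labels = c("low", "mid", "high"), right = FALSE)
  purrr::map_dfr(levels(band), function(b) {
    sub <- dat[band == b, , drop = FALSE]
    if (nrow(sub) < 3 || length(unique(sub[[factor_col]])) < 2) {
      return(tibble::tibble(band = b, n = nrow(sub), slope = NA_real_,
                            se = NA_real_, lo = m - s, hi = m + s))
    }
    sm <- coef(summary(lm(build_formula(outcome, factor_col), data = sub)))
    tibble::tibble(band = b, n = nrow(sub), slope = sm[2, 1], se = sm[2, 2],
                   lo = m - s, hi = m + s)
  })
}

#' Interaction plot across score bands
#'
#' Outcome-vs-factor regression lines per score band (low / mid / high at
#' mean +/- 1 SD of the score), visualising how the factor's slope changes
#' with genetic load.
#'
#' @inheritParams stratify_for_plot
#' @return A ggplot object.
#' @export
plot_interaction_bands <- function(cohort, factor_col, score_col = "pgrs",
                                   outcome = "bmi_z") {
  used <- c(outcome, score_col, factor_col)
  dat <- cohort[complete.cases(cohort[used]), used, drop = FALSE]
  m <- mean(dat[[score_col]]); s <- sd(dat[[score_col]])
  dat$band <- cut(dat[[score_col]], c(-Inf, m - s, m + s, Inf),
                  labels = c("low", "mid", "high"), right = FALSE)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[factor_col]],
                                    y = .data[[outcome]],
                                    colour = .data$band)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(colour = sprintf("%s band", score_col)) +
    ggplot2::theme_minimal()
}
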