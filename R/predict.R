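#' Stratified train/test split
#'
#' Disjoint, exhaustive split stratified by the binary outcome so class
#' ratios are preserved (each class's training count is
#' `round(train_frac * class size)`); deterministic under `seed`.
#'
#' @param cohort Data frame restricted to the two outcome classes.
#' @param outcome Binary outcome column name.
#' @param train_frac Training fraction (default 0.75).
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
train_test_split <- function(cohort, outcome, train_frac = 0.75, seed = 1L) {
  assert_cols(cohort, outcome, "cohort")
  y <- cohort[[outcome]]
  classes <- unique(y)
  if (length(classes) != 2) abort("Outcome must have exactly two classes.")
  if (any(table(y) < 2)) abort("Each outcome class needs at least 2 members.")
  with_seed(seed, {
    idx_train <- unlist(lapply(classes, function(cl) {
      rows <- which(y == cl)
      sample(rows, round(train_frac * length(rows)))
    }))
    list(train = cohort[sort(idx_train), , drop = FALSE],
         test = cohort[setdiff(seq_len(nrow(cohort)), idx_train), , drop = FALSE])
  })
}

#' ROC area under the curve with a DeLong confidence interval
#'
#' AUC in the rank (Mann-Whitney) formulation with ties counted one half,
#' i.e. the probability a case's risk exceeds a control's; 95% CI by
#' DeLong's method.
#'
#' @param risk Numeric predicted risks or scores.
#' @param labels Binary labels (0/1, logical, or two-level factor; the
#'   second level / 1 is the case class).
#' @return One-row tibble: `auc`, `ci_lo`, `ci_hi`, `n_cases`, `n_controls`.
#' @export
roc_auc <- function(risk, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) abort("Both classes must be present to compute an AUC.")
  r <- pROC::roc(response = labels, predictor = as.numeric(risk),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  tibble::tibble(auc = as.numeric(pROC::auc(r)),
                 ci_lo = ci[1], ci_hi = ci[3],
                 n_cases = sum(labels == 1), n_controls = sum(labels == 0))
}

#' Test-set AUC of each risk-factor model
#'
#' For each factor set: restrict to complete cases for that set, split into
#' train/test (stratified, seeded), fit a logistic model on the training
#' rows, and measure the AUC of its predicted risks on the test rows.
#' Cohorts containing a middle weight class must be filtered upstream: the
#' case/control framing assumes exactly two classes.
#'
#' @param cohort Data frame with the outcome and all candidate factors.
#' @param outcome Binary outcome column name.
#' @param factor_sets Named list of character vectors (each a covariate set
#'   defining one model).
#' @param train_frac Training fraction.
#' @param seed Seed for every split.
#' @return Tibble with one row per factor set: predictor label, test `auc`
#'   with DeLong CI, complete-case `n`, per-class counts and split sizes; a
#'   failed row carries the error message instead of estimates.
#' @export
evaluate_predictors <- function(cohort, outcome, factor_sets,
                                train_frac = 0.75, seed = 1L) {
  if (is.null(names(factor_sets))) {
    names(factor_sets) <- vapply(factor_sets, paste, character(1), collapse = "+")
  }
  if ("weight_status" %in% names(cohort) &&
      any(cohort$weight_status == "OW", na.rm = TRUE)) {
    abort("Cohort contains the overweight middle class; exclude it upstream so the outcome is case/control.")
  }
  purrr::imap_dfr(factor_sets, function(fs, label) {
    tryCatch({
      dat <- cohort[complete.cases(cohort[c(outcome, fs)]), c(outcome, fs), drop = FALSE]
      if (nrow(dat) == 0) abort("No complete cases for this factor set.")
      y <- dat[[outcome]]
      if (is.factor(y)) y <- as.integer(droplevels(y)) - 1L
      dat[[outcome]] <- as.integer(y)
      split <- train_test_split(dat, outcome, train_frac, seed)
      # separation is harmless here: predicted risks are only used to rank
      # test-set individuals, so a perfectly discriminating factor should
      # yield AUC 1, not an error
      fit <- suppressWarnings(glm(build_formula(outcome, fs),
                                  data = split$train, family = binomial()))
      risk <- predict(fit, newdata = split$test, type = "response")
      res <- roc_auc(risk, split$test[[outcome]])
      tibble::tibble(
        predictors = label, auc = res$auc, ci_lo = res$ci_lo, ci_hi = res$ci_hi,
        n = nrow(dat), n_controls = sum(dat[[outcome]] == 0),
        n_cases = sum(dat[[outcome]] == 1),
        n_train = nrow(split$train), n_test = nrow(split$test),
        error = NA_character_
      )
    }, error = function(e) {
      tibble::tibble(predictors = label, auc = NA_real_, ci_lo = NA_real_,
                     ci_hi = NA_real_, n = NA_integer_, n_controls = NA_integer_,
                     n_cases = NA_integer_, n_train = NA_integer_,
                     n_test = NA_integer_, error = conditionMessage(e))
    })
  })
}

#' Combine qualifying predictor models
#'
#' Individual models whose test AUC reaches `auc_min` are combined into one
#' logistic model containing the union of their covariates, fitted on the
#' complete-case intersection with a fresh stratified split.
#'
#' @inheritParams evaluate_predictors
#' @param auc_min AUC threshold a single-factor model must reach (default
#'   0.60).
#' @return One-row tibble like [evaluate_predictors()] plus a
#'   `qualifying` attribute naming the combined factor sets.
#' @export
combine_models <- function(cohort, outcome, factor_sets, auc_min = 0.6,
                           train_frac = 0.75, seed = 1L) {
  single <- evaluate_predictors(cohort, outcome, factor_sets, train_frac, seed)
  qual <- single$predictors[!is.na(single$auc) & single$auc >= auc_min]
  if (length(qual) == 0) {
    abort(sprintf("No individual model reached AUC >= %.2f; nothing to combine.", auc_min))
  }
  union_fs <- unique(unlist(factor_sets[qual]))
  out <- evaluate_predictors(cohort, outcome,
                             setNames(list(union_fs), paste(qual, collapse = " + ")),
                             train_frac, seed)
  attr(out, "qualifying") <- qual
  out
}
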