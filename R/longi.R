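#' Insulin-resistance cut-offs
#'
#' Inclusive HOMA-IR thresholds: 2.5 for the prepubertal stage (Tanner I),
#' and sex-specific pubertal thresholds (Tanner II-V) of 3.38 in boys and
#' 3.90 in girls.
#'
#' @param prepubertal,pubertal_boys,pubertal_girls Positive thresholds.
#' @return A list of class `ir_cutoffs`.
#' @export
ir_cutoffs <- function(prepubertal = 2.5, pubertal_boys = 3.38,
                       pubertal_girls = 3.90) {
  if (any(c(prepubertal, pubertal_boys, pubertal_girls) <= 0)) {
    abort("All HOMA-IR cut-offs must be positive.")
  }
  structure(list(prepubertal = prepubertal, pubertal_boys = pubertal_boys,
                 pubertal_girls = pubertal_girls),
            class = "ir_cutoffs")
}

#' Classify insulin resistance from HOMA-IR
#'
#' Vectorised, inclusive comparison: Tanner I children are IR when HOMA-IR
#' >= the prepubertal cut-off; Tanner II-V children when HOMA-IR >= the
#' sex-specific pubertal cut-off.
#'
#' @param homa HOMA-IR values (non-negative).
#' @param sex `"male"`/`"female"` (or `"boy"`/`"girl"`); required at
#'   pubertal stages.
#' @param tanner Tanner stage, `"I"`-`"V"` (factor, character or integer
#'   1-5).
#' @param cutoffs An [ir_cutoffs()] object.
#' @return Logical vector: `TRUE` = insulin resistant.
#' @export
#' @examples
#' classify_ir(c(2.5, 3.89, 3.90), c("male", "female", "female"),
#'             c("I", "III", "III"))
classify_ir <- function(homa, sex, tanner, cutoffs = ir_cutoffs()) {
  if (any(homa < 0, na.rm = TRUE)) abort("HOMA-IR must be non-negative.")
  tan <- normalize_tanner(tanner)
  pubertal <- tan >= 2L
  sex <- tolower(as.character(sex))
  boy <- sex %in% c("male", "boy", "m")
  girl <- sex %in% c("female", "girl", "f")
  if (any(pubertal & !boy & !girl)) {
    abort("Sex is required (male/female) for pubertal IR classification.")
  }
  cut <- ifelse(!pubertal, cutoffs$prepubertal,
                ifelse(boy, cutoffs$pubertal_boys, cutoffs$pubertal_girls))
  homa >= cut
}

normalize_tanner <- function(tanner) {
  if (is.numeric(tanner)) {
    tan <- as.integer(tanner)
  } else {
    tan <- match(toupper(as.character(tanner)), c("I", "II", "III", "IV", "V"))
  }
  if (any(is.na(tan) | tan < 1L | tan > 5L)) {
    abort("Tanner stage must be I-V (or 1-5).")
  }
  tan
}

#' Build a weight-status cut-off table
#'
#' Validates a table of age- and sex-specific BMI cut-offs for overweight
#' and obesity (e.g. the Cole et al. international cut-offs, supplied by the
#' user as data, not re-derived).
#'
#' @param table Data frame with columns `sex`, `age`, `ow_cutoff`,
#'   `ob_cutoff`.
#' @return The validated tibble with class `weight_cutoff_table`.
#' @export
weight_cutoff_table <- function(table) {
  assert_cols(table, c("sex", "age", "ow_cutoff", "ob_cutoff"), "cut-off table")
  if (any(table$ob_cutoff <= table$ow_cutoff)) {
    abort("Each obesity cut-off must exceed the overweight cut-off.")
  }
  structure(tibble::as_tibble(table), class = c("weight_cutoff_table",
                                                class(tibble::tibble())))
}

#' Classify weight status from BMI
#'
#' Looks up the nearest age row for the child's sex (half-year grids are
#' typical) and labels normal weight below the overweight cut-off,
#' overweight in `[ow, ob)` and obesity at or above the obesity cut-off
#' (inclusive upper class).
#'
#' @param bmi BMI values (kg/m^2).
#' @param age Ages in years.
#' @param sex `"male"`/`"female"`.
#' @param table A [weight_cutoff_table()].
#' @param max_age_gap Maximum tolerated distance to the nearest table age
#'   row (default 0.5 years).
#' @return Factor with levels `NW`, `OW`, `OB`.
#' @export
classify_weight <- function(bmi, age, sex, table, max_age_gap = 0.5) {
  stopifnot(inherits(table, "weight_cutoff_table"))
  n <- length(bmi)
  out <- character(n)
  for (i in seq_len(n)) {
    rows <- table[table$sex == sex[i], , drop = FALSE]
    if (nrow(rows) == 0) abort(sprintf("No cut-off rows for sex '%s'.", sex[i]))
    gap <- abs(rows$age - age[i])
    if (min(gap) > max_age_gap) {
      abort(sprintf("Age %.2f is outside the cut-off table range for sex '%s'.",
                    age[i], sex[i]))
    }
    r <- rows[which.min(gap), ]
    out[i] <- if (bmi[i] >= r$ob_cutoff) "OB" else if (bmi[i] >= r$ow_cutoff) "OW" else "NW"
  }
  factor(out, levels = c("NW", "OW", "OB"))
}

#' Trajectory-group mapping tables
#'
#' Scheme 1 maps joint (weight, IR) status at the pre- and post-pubertal
#' timepoints onto five groups: stable normal-weight non-IR children
#' (reference), overweight/obese children who were never IR, whose IR
#' resolved, who became IR, and who stayed IR. Combinations outside the
#' design (e.g. normal-weight children with IR, or weight-status changes
#' across the NW boundary) are marked unclassifiable. Scheme 2 uses weight
#' transitions only and is total: every `t0 -> t1` pair of
#' `{NW, OW, OB}` is its own label.
#'
#' @param scheme 1 (joint obesity and IR trajectories) or 2 (obesity only).
#' @return Tibble listing every mapped combination and its group label.
#' @export
trajectory_mapping <- function(scheme = 1) {
  if (scheme == 2) {
    grid <- expand.grid(t0_weight = c("NW", "OW", "OB"),
                        t1_weight = c("NW", "OW", "OB"),
                        stringsAsFactors = FALSE)
    return(tibble::as_tibble(grid) |>
             dplyr::mutate(group = paste0(.data$t0_weight, "_to_", .data$t1_weight)))
  }
  grid <- expand.grid(t0_weight = c("NW", "OW", "OB"), t0_ir = c(FALSE, TRUE),
                      t1_weight = c("NW", "OW", "OB"), t1_ir = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  owob <- function(w) w %in% c("OW", "OB")
  tibble::as_tibble(grid) |>
    dplyr::mutate(group = dplyr::case_when(
      .data$t0_weight == "NW" & !.data$t0_ir & .data$t1_weight == "NW" & !.data$t1_ir ~ "NW_nonIR_stable",
      owob(.data$t0_weight) & owob(.data$t1_weight) & !.data$t0_ir & !.data$t1_ir ~ "OWOB_nonIR_stable",
      owob(.data$t0_weight) & owob(.data$t1_weight) & .data$t0_ir & !.data$t1_ir ~ "OWOB_IR_resolved",
      owob(.data$t0_weight) & owob(.data$t1_weight) & !.data$t0_ir & .data$t1_ir ~ "OWOB_incident_IR",
      owob(.data$t0_weight) & owob(.data$t1_weight) & .data$t0_ir & .data$t1_ir ~ "OWOB_persistent_IR",
      TRUE ~ NA_character_
    ))
}

#' Assign trajectory groups from two-timepoint statuses
#'
#' Applies the explicit mapping of [trajectory_mapping()]. Combinations the
#' design does not cover raise an error listing them, never silently.
#'
#' @param t0_weight,t1_weight Weight status (`NW`/`OW`/`OB`) at baseline and
#'   follow-up.
#' @param t0_ir,t1_ir Logical IR status at each timepoint (ignored under
#'   scheme 2; required under scheme 1).
#' @param scheme 1 or 2 (see [trajectory_mapping()]).
#' @return Character vector of group labels.
#' @export
trajectory_groups <- function(t0_weight, t1_weight, t0_ir = NULL, t1_ir = NULL,
                              scheme = 1) {
  map <- trajectory_mapping(scheme)
  if (scheme == 2) {
    key <- paste(t0_weight, t1_weight)
    mkey <- paste(map$t0_weight, map$t1_weight)
  } else {
    if (is.null(t0_ir) || is.null(t1_ir)) abort("Scheme 1 requires IR status at both timepoints.")
    key <- paste(t0_weight, t0_ir, t1_weight, t1_ir)
    mkey <- paste(map$t0_weight, map$t0_ir, map$t1_weight, map$t1_ir)
  }
  idx <- match(key, mkey)
  if (any(is.na(idx))) {
    abort(sprintf("Status combination(s) not defined in the mapping: %s",
                  paste(unique(key[is.na(idx)]), collapse = "; ")))
  }
  out <- map$group[idx]
  if (any(is.na(out))) {
    abort(sprintf("Unclassifiable status combination(s) under scheme %d: %s",
                  scheme, paste(unique(key[is.na(out)]), collapse = "; ")))
  }
  out
}

#' Per-measurement deltas between two timepoints
#'
#' Elementwise differences of the named measurement columns between matched
#' baseline and follow-up rows, in the stated direction. Both directions
#' appear in published analyses (T1 - T0 for cardio-metabolic deltas,
#' T0 - T1 for treatment response), so the direction travels with the output
#' as the `"direction"` attribute.
#'
#' @param t0,t1 Data frames with an `id` column and shared measurement
#'   columns.
#' @param vars Measurement columns to difference (default: all shared
#'   numeric columns).
#' @param direction `"T1_minus_T0"` or `"T0_minus_T1"`.
#' @return Tibble with `id` and one delta column per measurement.
#' @export
compute_deltas <- function(t0, t1, vars = NULL,
                           direction = c("T1_minus_T0", "T0_minus_T1")) {
  direction <- match.arg(direction)
  assert_cols(t0, "id", "t0"); assert_cols(t1, "id", "t1")
  if (!setequal(t0$id, t1$id) || anyDuplicated(t0$id) || anyDuplicated(t1$id)) {
    abort("Timepoint tables must contain exactly the same ids, once each.")
  }
  if (is.null(vars)) {
    shared <- intersect(names(t0), names(t1))
    vars <- shared[vapply(t0[shared], is.numeric, logical(1)) &
                     vapply(t1[shared], is.numeric, logical(1))]
  }
  t1m <- t1[match(t0$id, t1$id), , drop = FALSE]
  sign <- if (direction == "T1_minus_T0") 1 else -1
  out <- tibble::tibble(id = t0$id)
  for (v in vars) out[[v]] <- sign * (t1m[[v]] - t0[[v]])
  attr(out, "direction") <- direction
  out
}

#' Tertile odds ratios for trajectory-group membership
#'
#' Per comparison group, a logistic regression of membership in that group
#' (vs the reference group) on the top-tertile score indicator plus
#' covariates, with Benjamini-Hochberg adjustment across the groups tested.
#'
#' @param data One row per individual with a `group` column, a `high_grs`
#'   indicator (see [dichotomize_top()]) and covariates.
#' @param reference Reference group label (default the stable normal-weight
#'   group).
#' @param covariates Covariate column names (default Tanner stage reached
#'   and origin).
#' @return Tibble with one row per comparison group: log-OR `estimate`,
#'   `or`, CI, `p_value`, `fdr`, and an `error` column flagging separation
#'   or other per-group failures.
#' @export
tertile_trajectory_or <- function(data, reference = "NW_nonIR_stable",
                                  covariates = c("tanner", "origin")) {
  assert_cols(data, c("group", "high_grs", covariates))
  if (!reference %in% data$group) abort(sprintf("Reference group '%s' is empty.", reference))
  comparison <- setdiff(unique(data$group), reference)
  if (length(comparison) == 0) abort("Need at least one comparison group.")
  rows <- purrr::map(comparison, function(g) {
    sub <- data[data$group %in% c(g, reference), , drop = FALSE]
    sub$member <- as.integer(sub$group == g)
    tryCatch({
      res <- fit_logistic(sub, "member", "high_grs", covariates)$result
      dplyr::mutate(dplyr::select(dplyr::rename(res, group = "term"), -"or_per_0.1"),
                    group = g, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(group = g, estimate = NA_real_, se = NA_real_,
                     statistic = NA_real_, p_value = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_, or = NA_real_,
                     or_ci_lo = NA_real_, or_ci_hi = NA_real_,
                     n_used = NA_integer_, error = conditionMessage(e))
    })
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$fdr[ok] <- bh_fdr(out$p_value[ok])
  out
}

#' Score association with longitudinal deltas
#'
#' One linear model per delta measurement with the score as exposure and the
#' stated covariates, Benjamini-Hochberg adjusted across measurements
#' (the shape of a per-measurement association table).
#'
#' @param deltas Tibble from [compute_deltas()] (plus `id`).
#' @param scores Tibble with `id` and the score column.
#' @param covariate_data Tibble with `id` and covariate columns.
#' @param measurements Delta columns to model (default: all non-id columns
#'   of `deltas` except covariate names).
#' @param score_col Score column name.
#' @param covariates Covariate column names.
#' @return Tibble of class `grs_scan`, one row per measurement.
#' @export
delta_association <- function(deltas, scores, covariate_data = NULL,
                              measurements = NULL, score_col = "pgrs",
                              covariates = NULL) {
  dat <- dplyr::inner_join(deltas, scores, by = "id")
  if (!is.null(covariate_data)) dat <- dplyr::inner_join(dat, covariate_data, by = "id")
  if (is.null(measurements)) {
    measurements <- setdiff(names(deltas), c("id", covariates, score_col))
  }
  rows <- purrr::map(measurements, function(m) {
    tryCatch(
      dplyr::mutate(
        dplyr::rename(fit_linear(dat, m, score_col, covariates)$result,
                      measurement = "term"),
        measurement = m, error = NA_character_),
      error = function(e) {
        tibble::tibble(measurement = m, estimate = NA_real_, se = NA_real_,
                       statistic = NA_real_, p_value = NA_real_,
                       ci_lo = NA_real_, ci_hi = NA_real_,
                       n_used = NA_integer_, error = conditionMessage(e))
      })
  })
  out <- dplyr::bind_rows(rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  if (any(ok)) out$fdr[ok] <- bh_fdr(out$p_value[ok])
  class(out) <- c("grs_scan", class(out))
  out
}

#' Derive HOMA-IR from fasting glucose and insulin
#'
#' `(glucose [mg/dL] x insulin [uU/mL]) / 405`; used only when a HOMA-IR
#' column is absent, and flagged as derived via the `"derived"` attribute.
#'
#' @param glucose Fasting glucose in mg/dL.
#' @param insulin Fasting insulin in uU/mL.
#' @return Numeric HOMA-IR values.
#' @export
homa_ir <- function(glucose, insulin) {
  out <- glucose * insulin / 405
  attr(out, "derived") <- TRUE
  out
}
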