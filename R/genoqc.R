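#' Per-SNP call rate
#'
#' Fraction of non-missing genotype calls per variant.
#'
#' @param genotypes Genotype tibble (`id` column plus one character column per
#'   SNP; `NA` marks a missing call).
#' @return Tibble with `snp_id` and `call_rate`.
#' @export
call_rate <- function(genotypes) {
  if (nrow(genotypes) == 0L) abort("Call rate is undefined for zero individuals.")
  snps <- snp_cols(genotypes)
  tibble::tibble(
    snp_id = snps,
    call_rate = unname(vapply(genotypes[snps], function(x) mean(!is.na(x)),
                              double(1)))
  )
}

#' Hardy-Weinberg exact test
#'
#' Exact two-sided test of Hardy-Weinberg proportions from genotype counts.
#' Conditional on the observed allele counts, the probability of every
#' attainable heterozygote count is evaluated (by the standard recurrence on
#' the number of heterozygotes) and the p-value is the sum of probabilities
#' of all configurations no more probable than the observed one, with ties
#' resolved by `<=` at a 1e-12 relative tolerance. A monomorphic variant has
#' a single attainable configuration, hence p = 1.
#'
#' @param n_rr Count of risk-allele homozygotes.
#' @param n_rh Count of heterozygotes.
#' @param n_hh Count of other-allele homozygotes.
#' @return Exact p-value in (0, 1].
#' @export
#' @examples
#' hwe_exact_test(20, 50, 30)
hwe_exact_test <- function(n_rr, n_rh, n_hh) {
  counts <- c(n_rr, n_rh, n_hh)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Genotype counts must be non-negative integers.")
  }
  n <- sum(counts)
  if (n == 0L) abort("All genotype counts are zero.")
  n_a <- 2 * n_rr + n_rh              # minor-allele-arbitrary: one allele's count
  n_b <- 2 * n_hh + n_rh
  rare <- min(n_a, n_b)
  if (rare == 0L) return(1)           # monomorphic: single configuration
  # attainable heterozygote counts share the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # unnormalised probabilities via the recurrence
  # P(h+2)/P(h) = 4 * n_rr(h) * n_hh(h) / ((h+2)(h+1))
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1L]
    hom_r <- (n_a - h) / 2
    hom_h <- (n_b - h) / 2
    logp[i] <- logp[i - 1L] + log(4 * hom_r * hom_h) - log((h + 2) * (h + 1))
  }
  prob <- exp(logp - max(logp))
  prob <- prob / sum(prob)
  obs <- match(n_rh, hets)
  if (is.na(obs)) abort("Heterozygote count inconsistent with allele totals.")
  min(1, sum(prob[prob <= prob[obs] * (1 + 1e-12)]))
}

#' Variant quality-control filter
#'
#' Retains variants whose call rate is at least `callrate_min` and whose
#' Hardy-Weinberg exact-test p-value is at least `hwe_alpha`. Call rate is
#' checked first, so a variant failing both is reported as a call-rate drop.
#' Per-individual call rate is reported informationally in the attribute
#' `"individual_call_rate"` but never used to drop anyone.
#'
#' @param genotypes Genotype tibble (see [call_rate()]).
#' @param panel Variant panel tibble; its `snp_id` set must match the
#'   genotype columns.
#' @param callrate_min Minimum per-SNP call rate (default 0.95).
#' @param hwe_alpha Hardy-Weinberg rejection threshold (default 1e-3).
#' @return List with `panel` (retained variants) and `report` (tibble:
#'   `snp_id`, `call_rate`, `hwe_p`, `status` in
#'   retained/dropped_callrate/dropped_hwe); thresholds are stored in the
#'   report's attributes.
#' @export
qc_filter <- function(genotypes, panel, callrate_min = 0.95, hwe_alpha = 1e-3) {
  snps <- snp_cols(genotypes)
  if (!setequal(snps, panel$snp_id)) {
    only_g <- setdiff(snps, panel$snp_id)
    only_p <- setdiff(panel$snp_id, snps)
    abort(sprintf(
      "Genotype/panel SNP sets differ. Only in genotypes: [%s]. Only in panel: [%s].",
      paste(only_g, collapse = ","), paste(only_p, collapse = ",")))
  }
  cr <- call_rate(genotypes)
  hwe_p <- vapply(panel$snp_id, function(s) {
    cnt <- genotype_counts(genotypes[[s]], panel$risk_allele[panel$snp_id == s],
                           panel$other_allele[panel$snp_id == s], s)
    if (sum(cnt) == 0L) NA_real_ else hwe_exact_test(cnt[1], cnt[2], cnt[3])
  }, double(1))
  report <- tibble::tibble(
    snp_id = panel$snp_id,
    call_rate = cr$call_rate[match(panel$snp_id, cr$snp_id)],
    hwe_p = hwe_p,
    status = dplyr::case_when(
      call_rate < callrate_min ~ "dropped_callrate",
      !is.na(hwe_p) & hwe_p < hwe_alpha ~ "dropped_hwe",
      TRUE ~ "retained"
    )
  )
  attr(report, "callrate_min") <- callrate_min
  attr(report, "hwe_alpha") <- hwe_alpha
  ind_cr <- rowMeans(!is.na(as.matrix(genotypes[snps])))
  attr(report, "individual_call_rate") <-
    tibble::tibble(id = genotypes$id, call_rate = ind_cr)
  keep <- report$snp_id[report$status == "retained"]
  list(panel = dplyr::filter(panel, .data$snp_id %in% keep), report = report)
}

# Count (risk-hom, het, other-hom) among non-missing calls; errors on calls
# containing an allele outside the panel's pair.
genotype_counts <- function(calls, risk, other, snp = "?") {
  obs <- calls[!is.na(calls)]
  if (length(obs) == 0L) return(c(0L, 0L, 0L))
  hom_r <- paste0(risk, risk)
  hom_o <- paste0(other, other)
  het <- paste(sort(c(risk, other)), collapse = "")
  bad <- !obs %in% c(hom_r, hom_o, het, paste0(other, risk), paste0(risk, other))
  if (any(bad)) {
    abort(sprintf("SNP %s has calls with alleles outside {%s,%s}: e.g. '%s'.",
                  snp, risk, other, obs[bad][1]))
  }
  c(sum(obs == hom_r),
    sum(!obs %in% c(hom_r, hom_o)),
    sum(obs == hom_o))
}

#' Convert genotype calls to risk-allele dosages
#'
#' Each cell becomes the number of risk alleles (0, 1 or 2) in the call,
#' oriented by the panel's `risk_allele`; missing calls propagate as `NA`.
#'
#' @param genotypes Genotype tibble.
#' @param panel Variant panel covering every genotype column.
#' @return Dosage tibble (`id` + numeric SNP columns).
#' @export
to_dosage <- function(genotypes, panel) {
  snps <- snp_cols(genotypes)
  missing_panel <- setdiff(snps, panel$snp_id)
  if (length(missing_panel) > 0) {
    abort(sprintf("Panel lacks SNP(s): %s", paste(missing_panel, collapse = ", ")))
  }
  out <- genotypes["id"]
  for (s in snps) {
    risk <- panel$risk_allele[panel$snp_id == s]
    other <- panel$other_allele[panel$snp_id == s]
    calls <- genotypes[[s]]
    parts <- strsplit(calls, "")
    obs <- !is.na(calls)
    ok <- !obs | vapply(parts, function(a) all(a %in% c(risk, other)), logical(1))
    if (any(!ok)) {
      i <- which(!ok)[1]
      abort(sprintf("Call '%s' for SNP %s, individual %s contains an allele outside {%s,%s}.",
                    calls[i], s, genotypes$id[i], risk, other))
    }
    dos <- rep(NA_real_, length(calls))
    dos[obs] <- vapply(parts[obs], function(a) as.numeric(sum(a == risk)), double(1))
    out[[s]] <- dos
  }
  out
}

#' Impute missing dosages by the observed risk-allele frequency
#'
#' Missing cells are replaced by twice the risk-allele frequency among the
#' observed calls of that variant (the column mean of observed dosages), so
#' imputed values may be fractional and column means are preserved.
#'
#' @param dosage Dosage tibble with possible `NA` cells.
#' @return Complete dosage tibble; the per-individual fraction of imputed
#'   genotypes is recorded in the `"imputed_fraction"` attribute.
#' @export
impute_missing <- function(dosage) {
  snps <- snp_cols(dosage)
  n_missing <- integer(nrow(dosage))
  for (s in snps) {
    x <- dosage[[s]]
    if (all(is.na(x))) abort(sprintf("SNP %s has no observed calls; cannot impute.", s))
    if (anyNA(x)) {
      n_missing <- n_missing + is.na(x)
      x[is.na(x)] <- mean(x, na.rm = TRUE)
      dosage[[s]] <- x
    }
  }
  attr(dosage, "imputed_fraction") <-
    tibble::tibble(id = dosage$id, imputed_fraction = n_missing / length(snps))
  dosage
}
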