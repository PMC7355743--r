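#' Compute the weighted polygenic risk score
#'
#' For each individual the score is the weighted sum over variants of the
#' risk-allele dosage times the per-allele weight,
#' `pGRS_j = sum_i beta_i * dosage_ji`. The score is a raw weighted sum; it
#' is deliberately not divided by the number of SNPs or the sum of weights.
#'
#' @param dosage Complete dosage tibble (`id` + numeric SNP columns; run
#'   [impute_missing()] first if calls are missing).
#' @param panel Variant panel whose `snp_id` set matches the dosage columns.
#' @return Tibble with `id` and `pgrs`.
#' @export
#' @examples
#' dos <- tibble::tibble(id = c("a", "b"), s1 = c(2, 0), s2 = c(1, 1))
#' pan <- tibble::tibble(snp_id = c("s1", "s2"), risk_allele = c("A", "C"),
#'                       other_allele = c("G", "T"), beta = c(0.05, 0.02))
#' compute_pgrs(dos, pan)
compute_pgrs <- function(dosage, panel) {
  snps <- snp_cols(dosage)
  if (!setequal(snps, panel$snp_id)) {
    abort("Dosage columns and panel `snp_id` sets differ; align the panel first.")
  }
  mat <- as.matrix(dosage[snps])
  if (anyNA(mat)) abort("Dosage matrix contains missing cells; impute first.")
  beta <- panel$beta[match(snps, panel$snp_id)]
  tibble::tibble(id = dosage$id, pgrs = as.numeric(mat %*% beta))
}

#' Assign quantile strata to scores
#'
#' Partitions individuals at the sample `1/k, ..., (k-1)/k` quantiles
#' (linear-interpolation convention, R type 7). Values tied with a cut point
#' are assigned to the lower stratum.
#'
#' @param scores Tibble with a `pgrs` column (e.g. from [compute_pgrs()]).
#' @param k Number of strata: 3 (tertiles) or 4 (quartiles).
#' @return `scores` with a `stratum` factor column `Q1..Qk`.
#' @export
quantile_strata <- function(scores, k = 4) {
  assert_cols(scores, "pgrs", "scores")
  if (!k %in% c(3, 4)) abort("`k` must be 3 (tertiles) or 4 (quartiles).")
  x <- scores$pgrs
  if (length(unique(x)) < k) {
    abort(sprintf("Need at least %d distinct score values to form %d strata.", k, k))
  }
  breaks <- c(-Inf, quantile(x, probs = seq_len(k - 1) / k, type = 7), Inf)
  scores$stratum <- cut(x, breaks = unique(breaks), right = TRUE,
                        labels = paste0("Q", seq_len(k)))
  attr(scores, "quantile_type") <- 7L
  attr(scores, "tie_rule") <- "lower"
  scores
}

#' Dichotomise the score at the top stratum
#'
#' Adds an indicator of membership in the top stratum (e.g. third tertile vs
#' the rest), the exposure used for trajectory odds-ratio models.
#'
#' @param scores Tibble with a `stratum` column from [quantile_strata()].
#' @return `scores` with an integer `high_grs` column (1 = top stratum).
#' @export
dichotomize_top <- function(scores) {
  assert_cols(scores, "stratum", "scores")
  top <- tail(levels(scores$stratum), 1)
  scores$high_grs <- as.integer(scores$stratum == top)
  scores
}

#' Distributional summary of the score
#'
#' Mean, standard deviation, and a Lilliefors-type normality check: the
#' Kolmogorov-Smirnov statistic against a normal with estimated mean and SD,
#' with the p-value calibrated by Monte Carlo under the estimated-parameter
#' null (seeded, so reproducible).
#'
#' @param scores Tibble with a `pgrs` column, n >= 5.
#' @param n_mc Number of Monte-Carlo null replicates (default 10000).
#' @param seed Seed for the Monte-Carlo calibration.
#' @return Tibble with `n`, `mean`, `sd`, `lilliefors_d`, `p_value`.
#' @export
score_summary <- function(scores, n_mc = 10000, seed = 1L) {
  assert_cols(scores, "pgrs", "scores")
  x <- scores$pgrs
  n <- length(x)
  if (n < 5) abort("Need at least 5 observations for the normality summary.")
  if (sd(x) == 0) abort("Score is constant; the normality statistic is degenerate.")
  d_obs <- lilliefors_d(x)
  d_null <- with_seed(seed, {
    vapply(seq_len(n_mc), function(i) lilliefors_d(rnorm(n)), double(1))
  })
  tibble::tibble(
    n = n, mean = mean(x), sd = sd(x), lilliefors_d = d_obs,
    p_value = (1 + sum(d_null >= d_obs)) / (n_mc + 1)
  )
}

# KS distance between the empirical cdf and the normal with estimated
# parameters (both one-sided deviations considered).
lilliefors_d <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / sd(x))
  p <- pnorm(z)
  max(seq_len(n) / n - p, p - (seq_len(n) - 1) / n)
}

#' Histogram of the score with a normal overlay
#'
#' @param scores Tibble with a `pgrs` column.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, bins = 30) {
  assert_cols(scores, "pgrs", "scores")
  m <- mean(scores$pgrs); s <- sd(scores$pgrs)
  ggplot2::ggplot(scores, ggplot2::aes(x = .data$pgrs)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = bins, fill = "grey70", colour = "white") +
    ggplot2::stat_function(fun = stats::dnorm, args = list(mean = m, sd = s),
                           colour = "firebrick") +
    ggplot2::labs(x = "polygenic risk score", y = "density") +
    ggplot2::theme_minimal()
}
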