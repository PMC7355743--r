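# Internal helpers shared across modules.

# Derive a child seed from a master seed by a fixed offset, keeping the result
# a valid 32-bit integer. Each sub-simulation draws from its own stream so
# that, e.g., adding SNPs does not perturb phenotype draws.
derive_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + offset * 100003) %% (.Machine$integer.max - 1L)) + 1L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Assemble `lhs ~ rhs1 + rhs2 + ...` from column names (backquoted so factor
# levels with spaces survive).
build_formula <- function(outcome, terms) {
  rhs <- if (length(terms) == 0L) "1" else paste(sprintf("`%s`", terms), collapse = " + ")
  as.formula(sprintf("`%s` ~ %s", outcome, rhs), env = globalenv())
}

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

snp_cols <- function(dosage) setdiff(names(dosage), "id")

# Two-sided Wald CI on the estimate scale.
wald_ci <- function(estimate, se, df = Inf, level = 0.95) {
  q <- if (is.finite(df)) qt(1 - (1 - level) / 2, df) else qnorm(1 - (1 - level) / 2)
  c(estimate - q * se, estimate + q * se)
}
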