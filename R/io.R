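#' Read a variant weights file
#'
#' Reads the 4-column tab-separated scoring file (`snp_id`, `risk_allele`,
#' `other_allele`, `beta`, header mandatory; extra columns such as
#' coordinates are kept) and validates it as a panel.
#'
#' @param path Path to the TSV file.
#' @return A validated panel tibble.
#' @export
read_weights <- function(path) {
  panel <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(panel, c("snp_id", "risk_allele", "other_allele", "beta"),
              sprintf("weights file '%s'", path))
  if ("chrom" %in% names(panel)) panel$chrom <- as.character(panel$chrom)
  validate_panel(panel)
}

validate_panel <- function(panel) {
  dup <- panel$snp_id[duplicated(panel$snp_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate snp_id in panel: %s", paste(unique(dup), collapse = ", ")))
  }
  if (any(panel$risk_allele == panel$other_allele)) {
    bad <- panel$snp_id[panel$risk_allele == panel$other_allele][1]
    abort(sprintf("risk_allele equals other_allele for SNP %s.", bad))
  }
  if (any(!is.finite(panel$beta))) abort("All betas must be finite.")
  tibble::as_tibble(panel)
}

#' Write a variant weights file
#'
#' @param panel Panel tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_weights <- function(panel, path) {
  readr::write_tsv(validate_panel(panel), path, progress = FALSE)
  invisible(path)
}

#' Read genotype calls from VCF or wide TSV
#'
#' VCF: biallelic SNP records with a GT subfield; `"./."` (or `".|."`) is
#' missing, both phased and unphased separators are accepted, and a
#' multi-allelic ALT raises an error naming the position. The allele-pair
#' strings are built from REF/ALT, so downstream orientation comes from the
#' weights panel, never from the file order. TSV: a wide table with an `id`
#' column and one allele-pair column per SNP (`NA` = missing).
#'
#' @param path Input path.
#' @param format `"vcf"` or `"tsv"` (default guessed from the extension).
#' @return Genotype tibble (`id` + one character column per SNP).
#' @export
read_genotypes <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    g <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    assert_cols(g, "id", sprintf("genotype file '%s'", path))
    return(tibble::as_tibble(g))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1, dimnames = list(NULL, names(fx)))
  fixed <- as.data.frame(fx, stringsAsFactors = FALSE)
  multi <- grepl(",", fixed$ALT, fixed = TRUE)
  if (any(multi)) {
    abort(sprintf("Multi-allelic record at %s:%s; only biallelic SNPs are supported.",
                  fixed$CHROM[multi][1], fixed$POS[multi][1]))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  out <- tibble::tibble(id = samples)
  for (i in seq_len(nrow(fixed))) {
    alleles <- c(fixed$REF[i], fixed$ALT[i])
    calls <- gsub("|", "/", gt[i, ], fixed = TRUE)
    parts <- strsplit(calls, "/", fixed = TRUE)
    cell <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".") || any(is.na(p))) return(NA_character_)
      paste(sort(alleles[as.integer(p) + 1L]), collapse = "")
    }, character(1))
    cell[is.na(calls)] <- NA_character_
    out[[fixed$ID[i]]] <- unname(cell)
  }
  out
}

#' Write genotype calls as a minimal VCF
#'
#' GT-only records, one sample column per individual, 1-based positions from
#' the panel; REF is the panel's other allele and ALT the risk allele, so a
#' `1` allele in GT is a risk allele. Missing calls are written `"./."`.
#'
#' @param genotypes Genotype tibble.
#' @param panel Panel tibble covering every genotype column (needs `chrom`
#'   and `pos`; defaults are filled in when absent).
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, panel, path) {
  dosage <- to_dosage(genotypes, panel)
  snps <- snp_cols(genotypes)
  pan <- panel[match(snps, panel$snp_id), , drop = FALSE]
  if (!"chrom" %in% names(pan)) pan$chrom <- "1"
  if (!"pos" %in% names(pan)) pan$pos <- seq_along(snps) * 1000L
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$id), collapse = "\t")
  )
  body <- vapply(seq_along(snps), function(i) {
    d <- dosage[[snps[i]]]
    gt <- ifelse(is.na(d), "./.", gt_code[d + 1L])
    paste(c(pan$chrom[i], pan$pos[i], snps[i], pan$other_allele[i],
            pan$risk_allele[i], ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Write a wide dosage TSV
#'
#' @param dosage Dosage tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(dosage, path) {
  readr::write_tsv(dosage, path, progress = FALSE, na = "NA")
  invisible(path)
}

#' Run the synthetic end-to-end pipeline
#'
#' Executes the stages in dependency order on a simulated cohort: panel and
#' genotype simulation, variant QC, dosage conversion and imputation, score
#' computation and strata, phenotype and environment simulation, the
#' score-BMI association, and the interaction scan. When `out_dir` is given,
#' stage outputs are written as TSV/VCF/JSON along with a run manifest
#' (package version, seed, thresholds, row counts) sufficient to re-execute
#' the deterministic stages identically.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param out_dir Optional output directory (created if needed).
#' @param callrate_min,hwe_alpha QC thresholds (see [qc_filter()]).
#' @return Named list of stage outputs, invisibly when writing to disk.
#' @export
run_pipeline <- function(config, out_dir = NULL, callrate_min = 0.95,
                         hwe_alpha = 1e-3) {
  stopifnot(inherits(config, "sim_config"))
  sim_p <- simulate_panel(config)
  sim_g <- simulate_genotypes(sim_p$truth, config)
  qc <- qc_filter(sim_g$genotypes, sim_p$panel, callrate_min, hwe_alpha)
  retained <- qc$panel$snp_id
  dosage <- to_dosage(sim_g$genotypes[c("id", retained)], qc$panel)
  dosage <- impute_missing(dosage)
  scores <- compute_pgrs(dosage, qc$panel) |> quantile_strata(k = 4)
  sim_ph <- simulate_phenotypes(dosage, qc$panel, config)
  cohort <- dplyr::inner_join(dplyr::select(sim_ph$cohort, -"pgrs"), scores, by = "id")
  cohort <- simulate_environment(cohort, config)
  assoc <- fit_linear(cohort, "bmi_z", "pgrs", c("origin", "tanner"))
  scan <- interaction_scan(cohort)
  out <- list(panel = sim_p$panel, qc_report = qc$report, dosage = dosage,
              scores = scores, cohort = cohort, association = assoc,
              interaction_scan = scan)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_weights(qc$panel, file.path(out_dir, "panel_retained.tsv"))
    readr::write_tsv(qc$report, file.path(out_dir, "qc_report.tsv"), progress = FALSE)
    write_dosage_tsv(dosage, file.path(out_dir, "dosage.tsv"))
    readr::write_tsv(scores, file.path(out_dir, "scores.tsv"), progress = FALSE)
    readr::write_tsv(cohort, file.path(out_dir, "cohort.tsv"), progress = FALSE)
    readr::write_tsv(scan, file.path(out_dir, "interaction_scan.tsv"), progress = FALSE)
    manifest <- list(
      package = "pedigrs",
      version = as.character(utils::packageVersion("pedigrs")),
      seed = config$seed,
      thresholds = list(callrate_min = callrate_min, hwe_alpha = hwe_alpha),
      n_snps_input = nrow(sim_p$panel),
      n_snps_retained = length(retained),
      n_individuals = nrow(dosage)
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(out))
  }
  out
}
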