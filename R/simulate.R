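#' Map a population MAF and relative risk to case and control MAFs
#'
#' Under the allelic relative-risk model for a rare disease, controls carry
#' the minor allele at (approximately) the population frequency `f`, while
#' the case frequency is inflated (or deflated) by the relative risk:
#' \deqn{f^+ = \frac{\lambda f}{1 + (\lambda - 1) f}, \qquad f^- = f.}
#' Neutral variants (`lam = 1`) are therefore exactly null, with identical
#' case and control frequencies.
#'
#' @param f Population minor allele frequency, in (0, 1).  Vectorised.
#' @param lam Relative risk (> 0).  Vectorised, recycled against `f`.
#' @return A list with numeric components `f_plus` (case MAF) and `f_minus`
#'   (control MAF).
#' @export
#' @examples
#' case_control_mafs(0.0001, 8)  # f_plus ~ 7.994e-4
case_control_mafs <- function(f, lam) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("`f` must lie in (0, 1)", call. = FALSE)
  if (any(!is.finite(lam)) || any(lam <= 0))
    stop("`lam` must be > 0", call. = FALSE)
  n <- max(length(f), length(lam))
  f <- rep_len(f, n); lam <- rep_len(lam, n)
  list(f_plus = lam * f / (1 + (lam - 1) * f), f_minus = f)
}

#' Construct a case-control genotype container
#'
#' @param dosages Integer matrix, subjects x variants, entries in
#'   \{0, 1, 2\} (minor-allele dosage).
#' @param status Binary vector, one per subject; 1 = case, 0 = control.
#' @param variant_ids Character vector of column labels.
#' @return An object of class `cc_genotypes` with fields `dosages`,
#'   `status`, `variant_ids`.
#' @export
cc_genotypes <- function(dosages, status,
                         variant_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(variant_ids)) variant_ids <- paste0("snp", seq_len(ncol(dosages)))
  status <- as.integer(status)
  if (length(status) != nrow(dosages))
    stop("`status` length must equal nrow(dosages)", call. = FALSE)
  if (!all(status %in% c(0L, 1L)))
    stop("`status` must be binary (0 = control, 1 = case)", call. = FALSE)
  if (!all(dosages %in% c(0L, 1L, 2L)))
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  if (length(variant_ids) != ncol(dosages))
    stop("`variant_ids` length must equal ncol(dosages)", call. = FALSE)
  storage.mode(dosages) <- "integer"
  colnames(dosages) <- variant_ids
  structure(list(dosages = dosages, status = status,
                 variant_ids = as.character(variant_ids)),
            class = "cc_genotypes")
}

#' @export
print.cc_genotypes <- function(x, ...) {
  cat("Case-control genotypes: ", sum(x$status), " cases, ",
      sum(1L - x$status), " controls, ", length(x$variant_ids),
      " variants\n", sep = "")
  invisible(x)
}

#' Keep a subset of variants, in the requested order
#'
#' @param geno A [cc_genotypes()] object.
#' @param variant_ids Variants to keep; must all be present.
#' @return A `cc_genotypes` object with columns reordered to `variant_ids`.
#' @export
subset_genotypes <- function(geno, variant_ids) {
  idx <- match(variant_ids, geno$variant_ids)
  if (anyNA(idx))
    stop("variants not present in genotypes: ",
         paste(variant_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  cc_genotypes(geno$dosages[, idx, drop = FALSE], geno$status,
               variant_ids = variant_ids)
}

#' Simulate one case-control gene dataset
#'
#' Each case subject's dosage at variant i is drawn Binomial(2, f+_i) and
#' each control's Binomial(2, f-_i), with case/control frequencies given by
#' [case_control_mafs()]; variants are independent (no linkage
#' disequilibrium) and Hardy-Weinberg equilibrium holds within each stratum.
#' Subjects are ordered cases first.
#'
#' @param setting A [gene_setting()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A list with components `genotypes` (a [cc_genotypes()]) and
#'   `truth` (the [expected_values()] record for the setting).
#' @export
simulate_gene <- function(setting, seed = NULL) {
  stopifnot(inherits(setting, "gene_setting"))
  if (!is.null(seed)) set.seed(seed)
  m <- length(setting$maf)
  cc <- case_control_mafs(setting$maf, setting$rr)
  np <- setting$n_cases; nm <- setting$n_controls
  dos_case <- matrix(rbinom(np * m, 2L, rep(cc$f_plus, each = np)), np, m)
  dos_ctrl <- matrix(rbinom(nm * m, 2L, rep(cc$f_minus, each = nm)), nm, m)
  geno <- cc_genotypes(rbind(dos_case, dos_ctrl),
                       status = c(rep(1L, np), rep(0L, nm)),
                       variant_ids = setting$variant_ids)
  list(genotypes = geno, truth = expected_values(setting))
}

#' Closed-form expected values of the post-hoc statistics
#'
#' For each variant, the unconditional expectation of the frequency
#' difference statistic is `E[D] = f+ - f-`, and that of its square is
#' `E[D^2] = (f+ - f-)^2 + Var(D)` with
#' \deqn{Var(\hat D_i) = \frac{f^+(1-f^+)}{2N^+} + \frac{f^-(1-f^-)}{2N^-}}
#' (binomial allele counts under Hardy-Weinberg equilibrium).  These are the
#' reference values against which conditional bias and MSE are measured.
#'
#' @param setting A [gene_setting()].
#' @return A data frame of class `truth_record` with columns `variant`,
#'   `maf`, `rr`, `f_plus`, `f_minus`, `expected_D`, `var_D`, `expected_D2`
#'   and `causal` (`rr != 1`).
#' @export
expected_values <- function(setting) {
  stopifnot(inherits(setting, "gene_setting"))
  cc <- case_control_mafs(setting$maf, setting$rr)
  var_d <- cc$f_plus * (1 - cc$f_plus) / (2 * setting$n_cases) +
    cc$f_minus * (1 - cc$f_minus) / (2 * setting$n_controls)
  d <- cc$f_plus - cc$f_minus
  out <- data.frame(variant = setting$variant_ids,
                    maf = setting$maf, rr = setting$rr,
                    f_plus = cc$f_plus, f_minus = cc$f_minus,
                    expected_D = d, var_D = var_d,
                    expected_D2 = d^2 + var_d,
                    causal = setting$rr != 1,
                    stringsAsFactors = FALSE)
  class(out) <- c("truth_record", "data.frame")
  out
}

#' Export genotypes as a dosage matrix TSV
#'
#' Column 1 is the subject identifier, column 2 the case/control status,
#' remaining columns are minor-allele dosages headed by variant ID.
#'
#' @param geno A [cc_genotypes()].
#' @param path Output file.
#' @param subject_ids Optional subject labels; defaults to `s1, s2, ...`.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(geno, path, subject_ids = NULL) {
  n <- nrow(geno$dosages)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  df <- data.frame(subject_id = subject_ids, status = geno$status,
                   geno$dosages, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export genotypes as a minimal VCF 4.2 plus a phenotype TSV
#'
#' Writes diploid unphased GT records (the counted allele as ALT) on a
#' synthetic single chromosome, and a two-column phenotype table
#' (`subject_id`, `status`).
#'
#' @param geno A [cc_genotypes()].
#' @param vcf_path,phenotype_path Output files (`phenotype_path = NULL`
#'   skips the phenotype table).
#' @param subject_ids Optional subject labels.
#' @return `vcf_path`, invisibly.
#' @export
write_vcf <- function(geno, vcf_path, phenotype_path = NULL,
                      subject_ids = NULL) {
  n <- nrow(geno$dosages); m <- ncol(geno$dosages)
  if (is.null(subject_ids)) subject_ids <- paste0("s", seq_len(n))
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c("##fileformat=VCFv4.2",
              "##source=wincurse",
              "##contig=<ID=1>",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", subject_ids), collapse = "\t"))
  rows <- vapply(seq_len(m), function(i) {
    paste(c("1", i, geno$variant_ids[i], "A", "T", ".", "PASS", ".", "GT",
            gt_codes[geno$dosages[, i] + 1L]), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), vcf_path)
  if (!is.null(phenotype_path))
    write.table(data.frame(subject_id = subject_ids, status = geno$status),
                phenotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(vcf_path)
}
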