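#' Read a phenotype table
#'
#' Expects a TSV with columns `subject_id` and `status`, where status is
#' binary (1 = case, 0 = control).
#'
#' @param path File path.
#' @return A data frame with character `subject_id` and integer `status`.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "status") %in% names(df)))
    stop("phenotype file must have columns `subject_id` and `status`",
         call. = FALSE)
  if (!all(df$status %in% c(0, 1)))
    stop("phenotype `status` must be binary 0/1", call. = FALSE)
  data.frame(subject_id = as.character(df$subject_id),
             status = as.integer(df$status), stringsAsFactors = FALSE)
}

#' Read gene-set definitions
#'
#' Expects a TSV with columns `gene_id` and `variant_id`; each gene's
#' variants must be unique, and their file order defines the within-gene
#' variant order used in all outputs.
#'
#' @param path File path.
#' @return A named list, one character vector of variant IDs per gene.
#' @export
read_gene_sets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "variant_id") %in% names(df)))
    stop("gene-set file must have columns `gene_id` and `variant_id`",
         call. = FALSE)
  sets <- split(as.character(df$variant_id), df$gene_id)
  for (g in names(sets)) {
    if (!length(sets[[g]]) || anyDuplicated(sets[[g]]))
      stop("gene ", g, " has empty or duplicated variant list",
           call. = FALSE)
  }
  sets
}

# Orient a dosage matrix to the minor allele by pooled sample frequency;
# a frequency of exactly 0.5 keeps the incoming (ALT) orientation.
orient_minor <- function(dosages) {
  freq <- colMeans(dosages) / 2
  flip <- freq > 0.5
  if (any(flip))
    dosages[, flip] <- 2L - dosages[, flip, drop = FALSE]
  dosages
}

#' Read case-control genotypes from VCF or dosage TSV
#'
#' For `format = "vcf"`, biallelic sites with GT fields are read (via the
#' vcfR package); multi-allelic sites are skipped with a warning.  For
#' `format = "tsv"`, the dosage-matrix layout of [write_dosage_tsv()] is
#' expected.  In both formats dosages are re-oriented to count the minor
#' allele as defined by the pooled sample frequency (a tie keeps the ALT
#' orientation), missing genotypes are set to dosage 0 with a message
#' reporting the count, and subjects are ordered as in the phenotype
#' table.
#'
#' @param path Genotype file.
#' @param format `"vcf"` or `"tsv"`.
#' @param phenotypes A phenotype data frame from [read_phenotypes()] (or a
#'   path to one).  Optional for TSV input, whose `status` column is then
#'   used; required for VCF.  Every genotyped subject must appear in it.
#' @return A [cc_genotypes()] object.
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           phenotypes = NULL) {
  format <- match.arg(format)
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(df)[1] != "subject_id")
      stop("dosage TSV must start with a `subject_id` column",
           call. = FALSE)
    has_status <- names(df)[2] == "status"
    first_var <- if (has_status) 3L else 2L
    subjects <- as.character(df$subject_id)
    dos <- as.matrix(df[, first_var:ncol(df), drop = FALSE])
    if (!is.null(phenotypes)) {
      idx <- match(phenotypes$subject_id, subjects)
      if (anyNA(idx))
        stop("phenotype subjects missing from genotype file: ",
             paste(phenotypes$subject_id[is.na(idx)], collapse = ", "),
             call. = FALSE)
      dos <- dos[idx, , drop = FALSE]
      status <- phenotypes$status
    } else if (has_status) {
      status <- as.integer(df$status)
    } else {
      stop("no phenotype table supplied and no `status` column present",
           call. = FALSE)
    }
    n_missing <- sum(is.na(dos))
    if (n_missing > 0) {
      message(n_missing, " missing dosages set to 0")
      dos[is.na(dos)] <- 0
    }
    return(cc_genotypes(orient_minor(dos), status,
                        variant_ids = colnames(dos)))
  }

  # VCF path
  if (is.null(phenotypes))
    stop("a phenotype table is required for VCF input", call. = FALSE)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package", call. = FALSE)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(vcf)
  if (any(!bi)) {
    warning(sum(!bi), " multi-allelic site(s) skipped", call. = FALSE)
    vcf <- vcf[bi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  ids <- ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"])
  # Count ALT alleles per (possibly phased) diploid GT string.
  count_alt <- function(g) {
    alleles <- strsplit(gsub("|", "/", g, fixed = TRUE), "/", fixed = TRUE)
    vapply(alleles, function(a) {
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a)) NA_integer_ else sum(a > 0L)
    }, integer(1))
  }
  subjects <- colnames(gt)
  missing_pheno <- setdiff(subjects, phenotypes$subject_id)
  if (length(missing_pheno))
    stop("VCF subjects absent from phenotype table: ",
         paste(missing_pheno, collapse = ", "), call. = FALSE)
  dos <- matrix(NA_integer_, nrow = nrow(phenotypes), ncol = nrow(gt),
                dimnames = list(NULL, ids))
  reorder <- match(phenotypes$subject_id, subjects)
  if (anyNA(reorder))
    stop("phenotype subjects missing from VCF: ",
         paste(phenotypes$subject_id[is.na(reorder)], collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(gt)))
    dos[, i] <- count_alt(gt[i, ])[reorder]
  n_missing <- sum(is.na(dos))
  if (n_missing > 0) {
    message(n_missing, " missing genotypes set to dosage 0")
    dos[is.na(dos)] <- 0L
  }
  cc_genotypes(orient_minor(dos), phenotypes$status, variant_ids = ids)
}

#' Run the full two-step analysis over a set of genes
#'
#' Applies the Step-1 test to every gene in the gene-set definition; genes
#' failing the significance gate stop there (no post-hoc analysis is
#' produced for them), while significant genes proceed to bootstrap bias
#' estimation and adjusted Step-2 statistics.  Writes `step1.tsv` (all
#' genes), `posthoc.tsv` (significant genes only), a JSON sidecar
#' `run.json` (alpha, B, seed, per-gene bootstrap counts) and a
#' `pipeline_log.txt` of skips and warnings to the output directory.
#'
#' @param config A YAML file path or a list with fields `genotypes`,
#'   `format` (`"tsv"`/`"vcf"`), `phenotypes`, `gene_sets`, `test`
#'   (`"burden"`/`"skat"`), `statistic` (`"D"`/`"D2"`), `alpha`, `B`,
#'   `seed`, `out_dir`.  Missing fields fail fast by name.
#' @return Invisibly, a list with `step1` (named list of `gbt_result`),
#'   `posthoc` (named list of `posthoc_stats` for significant genes) and
#'   the output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("genotypes", "format", "phenotypes", "gene_sets", "test",
                "statistic", "alpha", "B", "seed", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing))
    stop("missing config field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  phen <- read_phenotypes(config$phenotypes)
  geno_all <- read_genotypes(config$genotypes, format = config$format,
                             phenotypes = phen)
  sets <- read_gene_sets(config$gene_sets)

  step1 <- list(); posthoc <- list(); n_sig_boot <- list()
  for (g in names(sets)) {
    wanted <- sets[[g]]
    present <- wanted %in% geno_all$variant_ids
    if (!all(present)) {
      note("gene ", g, ": ", sum(!present),
           " variant(s) absent from genotypes, skipped: ",
           paste(wanted[!present], collapse = ", "))
      wanted <- wanted[present]
    }
    if (!length(wanted)) {
      note("gene ", g, ": no variants available, gene skipped")
      next
    }
    geno <- subset_genotypes(geno_all, wanted)
    res <- if (config$test == "burden")
      q_burden(geno, alpha = config$alpha)
    else q_skat(geno, alpha = config$alpha)
    step1[[g]] <- res
    if (!res$significant) {
      note("gene ", g, ": Step 1 not significant (p = ",
           signif(res$p_value, 4), "), stopping")
      next
    }
    run <- estimate_bias(geno, test_family = config$test,
                         statistic_family = config$statistic,
                         alpha = config$alpha, B = config$B,
                         seed = derive_seed(config$seed, match(g, names(sets))))
    if (run$n_significant == 0L)
      note("gene ", g, ": no significant bootstrap sample; ",
           "statistics left unadjusted")
    ns <- naive_stats(geno, config$statistic)
    posthoc[[g]] <- suppressWarnings(adjust_posthoc(ns, run))
    n_sig_boot[[g]] <- run$n_significant
  }

  paths <- list(step1 = file.path(config$out_dir, "step1.tsv"),
                posthoc = file.path(config$out_dir, "posthoc.tsv"),
                json = file.path(config$out_dir, "run.json"),
                log = file.path(config$out_dir, "pipeline_log.txt"))
  if (length(step1)) write_gbt_tsv(step1, paths$step1)
  if (length(posthoc)) write_posthoc_tsv(posthoc, paths$posthoc)
  jsonlite::write_json(list(alpha = config$alpha, B = config$B,
                            seed = config$seed,
                            n_significant_bootstraps = n_sig_boot),
                       paths$json, auto_unbox = TRUE, digits = NA)
  writeLines(log_lines, paths$log)
  invisible(list(step1 = step1, posthoc = posthoc, paths = paths))
}
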