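#' Naive post-hoc single-marker statistics (Step 2)
#'
#' For every variant of a gene that passed the Step-1 test, the naive
#' per-variant statistic is either the case-control minor allele frequency
#' difference \eqn{\hat D_i} (`family = "D"`, natural after a burden test)
#' or its square \eqn{\hat D_i^2} (`family = "D2"`, natural after a
#' variance-component test).  These statistics are computed on the same
#' data as Step 1 and are therefore subject to winner's curse; see
#' [estimate_bias()] and [adjust()].
#'
#' @param geno A [cc_genotypes()].
#' @param family `"D"` or `"D2"`.
#' @return An object of class `posthoc_stats`: a list with fields
#'   `variant_ids`, `statistic_family`, `naive`, and (after [adjust()])
#'   `adjusted`, `bias_estimate`, `n_significant_bootstraps`.
#' @export
naive_stats <- function(geno, family = c("D", "D2")) {
  family <- match.arg(family)
  d <- maf_difference(geno)$d_hat
  structure(list(variant_ids = geno$variant_ids,
                 statistic_family = family,
                 naive = if (family == "D") d else d^2,
                 adjusted = NULL, bias_estimate = NULL,
                 n_significant_bootstraps = NULL),
            class = "posthoc_stats")
}

#' @export
print.posthoc_stats <- function(x, ...) {
  cat("Post-hoc statistics (", x$statistic_family, ") for ",
      length(x$variant_ids), " variants",
      if (!is.null(x$adjusted))
        paste0("; adjusted using ", x$n_significant_bootstraps,
               " significant bootstraps"),
      "\n", sep = "")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.posthoc_stats <- function(x, ...) {
  data.frame(variant = x$variant_ids, family = x$statistic_family,
             naive = x$naive,
             adjusted = if (is.null(x$adjusted)) NA_real_ else x$adjusted,
             bias_estimate = if (is.null(x$bias_estimate)) NA_real_
                             else x$bias_estimate,
             rank_naive = rank_values(x$naive),
             rank_adjusted = if (is.null(x$adjusted)) NA_real_
                             else rank_values(x$adjusted),
             stringsAsFactors = FALSE)
}

# Rank by strength of evidence: 1 = largest |T|, ties get midranks.
rank_values <- function(x) rank(-abs(x), ties.method = "average")

#' Rank variants by strength of post-hoc evidence
#'
#' Variants are ranked by the absolute value of the per-variant statistic
#' (adjusted values when present, naive otherwise); rank 1 is the strongest
#' signal and ties receive midranks.  The absolute value makes
#' risk-decreasing causal variants rank as strong signals, and makes
#' ranking by `D2` coincide with ranking by `|D|` on the same data.
#'
#' @param stats A `posthoc_stats` object (or a bare numeric vector of
#'   statistics).
#' @return Numeric vector of ranks, one per variant.
#' @export
rank_variants <- function(stats) {
  x <- if (inherits(stats, "posthoc_stats")) {
    if (!is.null(stats$adjusted)) stats$adjusted else stats$naive
  } else stats
  rank_values(x)
}

# Are the k top-ranked variants all causal?  A tie group spanning the
# boundary counts as a success only if every variant tied into the top k is
# causal.
top_k_causal <- function(stat_values, causal, k) {
  a <- abs(stat_values)
  thresh <- sort(a, decreasing = TRUE)[k]
  top <- which(a >= thresh)
  length(top) >= k && all(causal[top])
}

#' Write per-variant post-hoc statistics to TSV
#'
#' @param stats A `posthoc_stats` object, or a named list of them
#'   (names = gene IDs).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_posthoc_tsv <- function(stats, path) {
  if (inherits(stats, "posthoc_stats")) stats <- list(gene = stats)
  df <- do.call(rbind, lapply(names(stats), function(g) {
    x <- stats[[g]]
    cbind(gene = g, as.data.frame(x),
          n_significant_bootstraps =
            if (is.null(x$n_significant_bootstraps)) NA_integer_
            else x$n_significant_bootstraps)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
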