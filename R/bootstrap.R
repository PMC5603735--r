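#' One stratified case-control bootstrap resample
#'
#' Cases and controls are resampled separately, with replacement, so the
#' bootstrap sample again contains exactly N+ cases and N- controls.  The
#' residual sample consists of the distinct subjects drawn zero times
#' (about a third of each stratum, expected fraction
#' `(1 - 1/N)^N -> exp(-1)`), keeping their stratum labels.
#'
#' @param geno A [cc_genotypes()].
#' @param seed Optional integer seed.
#' @return A list with components `bootstrap` and `residual` (both
#'   [cc_genotypes()]), plus the drawn `case_indices` / `control_indices`
#'   (row indices into `geno$dosages`).  Signals an error of class
#'   `wincurse_degenerate_bootstrap` if either residual stratum is empty.
#' @export
bootstrap_once <- function(geno, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  case_rows <- which(geno$status == 1L)
  ctrl_rows <- which(geno$status == 0L)
  np <- length(case_rows); nm <- length(ctrl_rows)
  if (np < 1L || nm < 1L)
    stop("need at least one case and one control", call. = FALSE)
  draw_c <- sample.int(np, np, replace = TRUE)
  draw_t <- sample.int(nm, nm, replace = TRUE)
  res_c <- setdiff(seq_len(np), draw_c)
  res_t <- setdiff(seq_len(nm), draw_t)
  if (!length(res_c) || !length(res_t))
    stop(structure(list(message = "empty residual stratum", call = NULL),
                   class = c("wincurse_degenerate_bootstrap", "error",
                             "condition")))
  boot_rows <- c(case_rows[draw_c], ctrl_rows[draw_t])
  res_rows <- c(case_rows[res_c], ctrl_rows[res_t])
  list(bootstrap = cc_genotypes(geno$dosages[boot_rows, , drop = FALSE],
                                geno$status[boot_rows], geno$variant_ids),
       residual = cc_genotypes(geno$dosages[res_rows, , drop = FALSE],
                               geno$status[res_rows], geno$variant_ids),
       case_indices = case_rows[draw_c],
       control_indices = ctrl_rows[draw_t])
}

#' Bootstrap estimation of winner's-curse bias (Step 2, Part 3)
#'
#' For `B` stratified bootstrap resamples of the subjects, the Step-1 test
#' is recomputed on each bootstrap sample (weights re-derived from that
#' sample's pooled frequencies, unless frozen).  For every bootstrap sample
#' that is itself significant at `alpha`, the bias of each per-variant
#' statistic is estimated as the bootstrap-sample statistic minus the
#' residual-sample statistic,
#' \eqn{\widehat{Bias}_b(\hat T_i) = \hat T^*_{ib} - \hat T^R_{ib}}.
#' Bootstrap samples that fail the significance gate mimic the selection
#' applied to the original data and are excluded from all summaries.
#'
#' This should only be run when the Step-1 test on `geno` itself was
#' significant (Part 1 of the correction); the function does not re-check
#' the gate.
#'
#' @param geno A [cc_genotypes()].
#' @param test_family `"burden"` or `"skat"` -- the Step-1 test to replay.
#' @param statistic_family `"D"` or `"D2"` -- the Step-2 statistic.
#' @param alpha Significance gate, reused from Step 1.
#' @param B Number of bootstrap resamples.
#' @param seed Optional integer seed.
#' @param freeze_weights If `TRUE`, reuse the original sample's weights in
#'   every bootstrap test instead of recomputing them per resample.
#' @param p_method Chi-square-mixture tail method for `"skat"`.
#' @return An object of class `bootstrap_run`: fields `n_bootstrap`,
#'   `alpha`, `per_bootstrap_bias` (B x m matrix, `NA` rows for
#'   non-significant or degenerate resamples), `significant` (logical B),
#'   `n_significant`, `n_degenerate`, `test_family`, `statistic_family`,
#'   `seed`.
#' @export
estimate_bias <- function(geno, test_family = c("burden", "skat"),
                          statistic_family = c("D", "D2"), alpha = 0.01,
                          B = 1000, seed = NULL, freeze_weights = FALSE,
                          p_method = "liu") {
  test_family <- match.arg(test_family)
  statistic_family <- match.arg(statistic_family)
  if (!is.null(seed)) set.seed(seed)
  m <- length(geno$variant_ids)
  case_rows <- which(geno$status == 1L)
  ctrl_rows <- which(geno$status == 0L)
  np <- length(case_rows); nm <- length(ctrl_rows)
  if (np < 1L || nm < 1L)
    stop("need at least one case and one control", call. = FALSE)

  # Carrier-only views: resampled allele counts only depend on rows with a
  # nonzero dosage, which for rare variants is a small minority.
  dc <- geno$dosages[case_rows, , drop = FALSE]; storage.mode(dc) <- "double"
  dt <- geno$dosages[ctrl_rows, , drop = FALSE]; storage.mode(dt) <- "double"
  carrier_c <- which(rowSums(dc) > 0)
  carrier_t <- which(rowSums(dt) > 0)
  dcc <- dc[carrier_c, , drop = FALSE]
  dtt <- dt[carrier_t, , drop = FALSE]

  frozen <- if (freeze_weights) {
    d0 <- maf_difference(geno)
    beta_weight(d0$f_pooled)
  } else NULL

  bias <- matrix(NA_real_, nrow = B, ncol = m,
                 dimnames = list(NULL, geno$variant_ids))
  significant <- logical(B)
  n_degenerate <- 0L
  stat_of <- function(cp, cm, n_p, n_m) {
    d <- cp / (2 * n_p) - cm / (2 * n_m)
    if (statistic_family == "D") d else d^2
  }
  b <- 0L
  while (b < B) {
    tab_c <- tabulate(sample.int(np, np, replace = TRUE), np)
    tab_t <- tabulate(sample.int(nm, nm, replace = TRUE), nm)
    res_c <- tab_c == 0; res_t <- tab_t == 0
    nrp <- sum(res_c); nrm <- sum(res_t)
    if (nrp == 0L || nrm == 0L) {            # unusable: no residual stratum
      n_degenerate <- n_degenerate + 1L
      if (n_degenerate > 100L + 10L * B)
        stop("too many degenerate bootstraps; strata too small to resample",
             call. = FALSE)
      next
    }
    b <- b + 1L
    cb_p <- drop(crossprod(dcc, tab_c[carrier_c]))
    cb_m <- drop(crossprod(dtt, tab_t[carrier_t]))
    core <- gbt_from_counts(cb_p, cb_m, np, nm, test_family,
                            weights = frozen, p_method = p_method)
    if (core$p_value < alpha) {
      cr_p <- drop(crossprod(dcc, as.double(res_c[carrier_c])))
      cr_m <- drop(crossprod(dtt, as.double(res_t[carrier_t])))
      bias[b, ] <- stat_of(cb_p, cb_m, np, nm) - stat_of(cr_p, cr_m, nrp, nrm)
      significant[b] <- TRUE
    }
  }
  structure(list(n_bootstrap = B, alpha = alpha,
                 per_bootstrap_bias = bias, significant = significant,
                 n_significant = sum(significant),
                 n_degenerate = n_degenerate,
                 test_family = test_family,
                 statistic_family = statistic_family, seed = seed),
            class = "bootstrap_run")
}

#' @export
print.bootstrap_run <- function(x, ...) {
  cat("Bootstrap bias run: B = ", x$n_bootstrap, ", ", x$n_significant,
      " significant at alpha = ", x$alpha, " (", x$test_family, " / ",
      x$statistic_family, ")\n", sep = "")
  invisible(x)
}

#' Winner's-curse adjustment of post-hoc statistics
#'
#' Subtracts from each naive statistic the summary (default: median) of its
#' bootstrap bias estimates over the significant bootstrap samples, with
#' sign clamping so the adjusted statistic can shrink to zero but never
#' cross it:
#' \deqn{\hat T_{adj} = \max(\hat T - med_b(\widehat{Bias}_b), 0) \;
#'   \mathrm{if}\; \hat T > 0; \quad
#'   \min(\hat T - med_b(\widehat{Bias}_b), 0) \; \mathrm{if}\; \hat T < 0,}
#' and \eqn{\hat T = 0} maps to 0.
#'
#' @param naive A `posthoc_stats` object from [naive_stats()].
#' @param run A `bootstrap_run` from [estimate_bias()] (same statistic
#'   family).
#' @param summary `"median"` (default) or `"mean"` over significant
#'   bootstraps.
#' @return The `posthoc_stats` object with `adjusted`, `bias_estimate` and
#'   `n_significant_bootstraps` filled in.  If no bootstrap sample was
#'   significant the naive values are returned unchanged (with a warning)
#'   and `adjusted = naive`.
#' @export
adjust <- function(naive, run, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  stopifnot(inherits(naive, "posthoc_stats"), inherits(run, "bootstrap_run"))
  if (naive$statistic_family != run$statistic_family)
    stop("statistic families of `naive` and `run` differ", call. = FALSE)
  naive$n_significant_bootstraps <- run$n_significant
  if (run$n_significant < 1L) {
    warning("no significant bootstrap samples; statistics left unadjusted",
            call. = FALSE)
    naive$adjusted <- naive$naive
    naive$bias_estimate <- rep(NA_real_, length(naive$naive))
    return(naive)
  }
  rows <- run$per_bootstrap_bias[run$significant, , drop = FALSE]
  fun <- if (summary == "median") median else mean
  b_est <- apply(rows, 2, fun)
  raw <- naive$naive - b_est
  naive$bias_estimate <- b_est
  naive$adjusted <- ifelse(naive$naive > 0, pmax(raw, 0),
                           ifelse(naive$naive < 0, pmin(raw, 0), 0))
  naive
}

# Alias so callers that take an `adjust` flag argument can still reach the
# function without the name being shadowed.
adjust_posthoc <- adjust
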