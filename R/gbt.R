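#' Beta(1, 25) variant weight
#'
#' The standard rare-variant weighting: the Beta(1, 25) density evaluated at
#' the minor allele frequency, `w = 25 (1 - f)^24`, which up-weights rarer
#' variants (w = 25 at f = 0, w = 0 at f = 1).
#'
#' @param f Minor allele frequency in \[0, 1\].  Vectorised.
#' @return Numeric vector of weights in \[0, 25\].
#' @export
#' @examples
#' beta_weight(c(0, 0.01, 1))
beta_weight <- function(f) {
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1))
    stop("`f` must lie in [0, 1]", call. = FALSE)
  dbeta(f, 1, 25)
}

#' Per-variant minor allele frequency differences
#'
#' Computes, for each variant, the sample case and control minor allele
#' frequencies \eqn{\hat f^+_i = C^+_i / 2N^+} and
#' \eqn{\hat f^-_i = C^-_i / 2N^-} (allele counts over diploid subjects),
#' their difference \eqn{\hat D_i = \hat f^+_i - \hat f^-_i}, and the pooled
#' frequency \eqn{(C^+_i + C^-_i) / (2N^+ + 2N^-)}.
#'
#' @param geno A [cc_genotypes()] with at least one case and one control.
#' @return A data frame with columns `variant`, `c_plus`, `c_minus`,
#'   `f_plus`, `f_minus`, `f_pooled`, `d_hat`.
#' @export
maf_difference <- function(geno) {
  np <- sum(geno$status); nm <- length(geno$status) - np
  if (np == 0L || nm == 0L)
    stop("degenerate design: need at least one case and one control",
         call. = FALSE)
  cp <- drop(crossprod(geno$dosages, geno$status))
  cm <- drop(crossprod(geno$dosages, 1L - geno$status))
  fp <- cp / (2 * np); fm <- cm / (2 * nm)
  data.frame(variant = geno$variant_ids, c_plus = cp, c_minus = cm,
             f_plus = fp, f_minus = fm,
             f_pooled = (cp + cm) / (2 * (np + nm)),
             d_hat = fp - fm, stringsAsFactors = FALSE)
}

# Survival function of a positive linear combination of independent 1-df
# chi-squares, sum(lambda_i * chisq_1).  "liu" matches the first four
# cumulants to a (possibly non-central) chi-square; "imhof" inverts the
# characteristic function numerically.
pchisq_mix <- function(q, lambda, method = c("liu", "imhof")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  if (!length(lambda)) return(1)
  if (length(lambda) == 1L)
    return(pchisq(q / lambda, df = 1, lower.tail = FALSE))
  if (method == "liu") {
    c1 <- sum(lambda); c2 <- sum(lambda^2)
    c3 <- sum(lambda^3); c4 <- sum(lambda^4)
    s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
    if (s1^2 > s2) {
      a <- 1 / (s1 - sqrt(s1^2 - s2))
      delta <- s1 * a^3 - a^2
      l <- a^2 - 2 * delta
    } else {
      delta <- 0
      l <- 1 / s2
    }
    mu_q <- c1; sigma_q <- sqrt(2 * c2)
    mu_x <- l + delta; sigma_x <- sqrt(2) * sqrt(l + 2 * delta)
    x <- (q - mu_q) / sigma_q * sigma_x + mu_x
    pchisq(x, df = l, ncp = delta, lower.tail = FALSE)
  } else {
    integrand <- function(u) {
      theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
      rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
      sin(theta) / (u * rho)
    }
    val <- integrate(integrand, 0, Inf, rel.tol = 1e-9,
                     stop.on.error = FALSE)$value
    min(max(0.5 + val / pi, 0), 1)
  }
}

# Shared count-level core of the Step-1 tests: everything is a function of
# the per-variant case/control minor allele counts and the stratum sizes.
# Pooled-frequency binomial variance is used as the null variance (score
# style); monomorphic variants (f_pooled = 0) drop out of both the
# statistic and the variance automatically.
gbt_from_counts <- function(c_plus, c_minus, n_cases, n_controls,
                            test_family = c("burden", "skat"),
                            weights = NULL, p_method = "liu") {
  test_family <- match.arg(test_family)
  fp <- c_plus / (2 * n_cases); fm <- c_minus / (2 * n_controls)
  f_pool <- (c_plus + c_minus) / (2 * (n_cases + n_controls))
  if (is.null(weights)) weights <- beta_weight(f_pool)
  d <- fp - fm
  v <- f_pool * (1 - f_pool) * (1 / (2 * n_cases) + 1 / (2 * n_controls))
  if (test_family == "burden") {
    q <- sum(weights * d)
    var_q <- sum(weights^2 * v)
    p <- if (var_q <= 0) 1 else 2 * pnorm(-abs(q) / sqrt(var_q))
  } else {
    q <- sum(weights * d^2)
    lam <- weights * v
    p <- if (all(lam <= 0)) 1 else pchisq_mix(q, lam, method = p_method)
  }
  list(q_value = q, p_value = p, weights = weights, null_var = v)
}

gbt_result <- function(core, test_family, alpha, m, n_cases, n_controls) {
  structure(list(test_family = test_family, q_value = core$q_value,
                 p_value = core$p_value, weights = core$weights,
                 alpha = alpha, significant = core$p_value < alpha,
                 m = m, n_cases = n_cases, n_controls = n_controls),
            class = "gbt_result")
}

#' @export
print.gbt_result <- function(x, ...) {
  cat(sprintf("%s test: Q = %.6g, p = %.4g (alpha = %g, %ssignificant)\n",
              x$test_family, x$q_value, x$p_value, x$alpha,
              if (x$significant) "" else "not "))
  invisible(x)
}

#' Weighted burden test (Step 1)
#'
#' The burden statistic is the weighted sum of signed case-control minor
#' allele frequency differences, \eqn{Q_{bw} = \sum_i w_i \hat D_i}.  Under
#' the null it is asymptotically Normal with mean zero and variance
#' \eqn{\sum_i w_i^2 \hat v_i}, where
#' \eqn{\hat v_i = \hat f_i (1-\hat f_i)(1/2N^+ + 1/2N^-)} uses the pooled
#' frequency; the p-value is two-sided.  Powerful when causal effects share
#' a direction.
#'
#' @param geno A [cc_genotypes()].
#' @param weights Per-variant weights; `NULL` (default) applies
#'   [beta_weight()] to the pooled sample MAF, the only frequency available
#'   in real data.  Supply `beta_weight(f)` with known population `f` to
#'   override in simulation studies.
#' @param alpha Significance level recorded in the result.
#' @return A `gbt_result` with fields `test_family`, `q_value`, `p_value`,
#'   `weights`, `alpha`, `significant`, `m`, `n_cases`, `n_controls`.
#' @seealso [q_skat()]
#' @export
q_burden <- function(geno, weights = NULL, alpha = 0.01) {
  d <- maf_difference(geno)
  np <- sum(geno$status); nm <- length(geno$status) - np
  if (all(d$c_plus + d$c_minus == 0))
    warning("all variants are monomorphic; p-value set to 1", call. = FALSE)
  core <- gbt_from_counts(d$c_plus, d$c_minus, np, nm, "burden", weights)
  gbt_result(core, "burden_weighted", alpha, nrow(d), np, nm)
}

#' Weighted variance-component (SKAT-type) test (Step 1)
#'
#' The variance-component statistic is the weighted sum of squared
#' case-control frequency differences,
#' \eqn{Q_{sw} = \sum_i w_i \hat D_i^2}.  Its asymptotic null distribution
#' is a positive linear combination of independent 1-df chi-squares with
#' coefficients \eqn{w_i \hat v_i}; the upper-tail probability is evaluated
#' by four-cumulant moment matching (`p_method = "liu"`) or by numerical
#' inversion of the characteristic function (`p_method = "imhof"`).
#' Powerful under mixed effect directions.
#'
#' @inheritParams q_burden
#' @param p_method Tail approximation for the chi-square mixture.
#' @return A `gbt_result`; see [q_burden()].
#' @export
q_skat <- function(geno, weights = NULL, alpha = 0.01,
                   p_method = c("liu", "imhof")) {
  p_method <- match.arg(p_method)
  d <- maf_difference(geno)
  np <- sum(geno$status); nm <- length(geno$status) - np
  if (all(d$c_plus + d$c_minus == 0))
    warning("all variants are monomorphic; p-value set to 1", call. = FALSE)
  core <- gbt_from_counts(d$c_plus, d$c_minus, np, nm, "skat", weights,
                          p_method = p_method)
  gbt_result(core, "skat_weighted", alpha, nrow(d), np, nm)
}

#' Write Step-1 results to TSV
#'
#' @param results A named list of `gbt_result` objects (names = gene IDs),
#'   or a single result.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gbt_tsv <- function(results, path) {
  if (inherits(results, "gbt_result")) results <- list(gene = results)
  df <- do.call(rbind, lapply(names(results), function(g) {
    r <- results[[g]]
    data.frame(gene = g, test_family = r$test_family, q_value = r$q_value,
               p_value = r$p_value, alpha = r$alpha,
               significant = r$significant, m = r$m, n_cases = r$n_cases,
               n_controls = r$n_controls, stringsAsFactors = FALSE)
  }))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
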