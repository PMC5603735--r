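# Shared fixtures and independent oracles, built in code.

# A small case-control dataset with the given per-variant allele counts,
# placing minor alleles as heterozygotes from the first subject on.
geno_from_counts <- function(c_plus, c_minus, n_cases, n_controls) {
  m <- length(c_plus)
  dos <- matrix(0L, n_cases + n_controls, m)
  for (i in seq_len(m)) {
    stopifnot(c_plus[i] <= n_cases, c_minus[i] <= n_controls)
    if (c_plus[i] > 0) dos[seq_len(c_plus[i]), i] <- 1L
    if (c_minus[i] > 0) dos[n_cases + seq_len(c_minus[i]), i] <- 1L
  }
  cc_genotypes(dos, c(rep(1L, n_cases), rep(0L, n_controls)))
}

# Swap case/control labels.
swap_labels <- function(geno) {
  cc_genotypes(geno$dosages, 1L - geno$status, geno$variant_ids)
}

# A moderately common dense dataset where asymptotics are comfortable.
dense_geno <- function(seed = 42, n_cases = 300, n_controls = 300, m = 5,
                       f = 0.12) {
  set.seed(seed)
  dos <- matrix(rbinom((n_cases + n_controls) * m, 2, f),
                n_cases + n_controls, m)
  cc_genotypes(dos, c(rep(1L, n_cases), rep(0L, n_controls)))
}

# Monte-Carlo null distribution of a GBT statistic for a fixed dataset:
# parametric draws of case/control allele counts at the pooled sample
# frequencies, with the observed dataset's weights held fixed (the
# asymptotic null is conditional on the weights).  Independent of the
# asymptotic p-value path it checks.
mc_null_pvalue <- function(geno, test_family, n_draws = 1e5, seed = 7) {
  d <- maf_difference(geno)
  np <- sum(geno$status); nm <- length(geno$status) - np
  obs <- wincurse:::gbt_from_counts(d$c_plus, d$c_minus, np, nm,
                                    test_family)
  w <- obs$weights
  set.seed(seed)
  m <- nrow(d)
  cp <- matrix(rbinom(m * n_draws, 2 * np, d$f_pooled), nrow = m)
  cm <- matrix(rbinom(m * n_draws, 2 * nm, d$f_pooled), nrow = m)
  d_null <- cp / (2 * np) - cm / (2 * nm)
  q_null <- if (test_family == "burden") colSums(w * d_null)
            else colSums(w * d_null^2)
  p_mc <- if (test_family == "burden") mean(abs(q_null) >= abs(obs$q_value))
          else mean(q_null >= obs$q_value)
  list(p_asym = obs$p_value, p_mc = p_mc, n_draws = n_draws)
}

# A hand-built bootstrap_run with a fully specified bias matrix.
fake_run <- function(bias_matrix, significant = rep(TRUE, nrow(bias_matrix)),
                     statistic_family = "D", alpha = 0.01) {
  structure(list(n_bootstrap = nrow(bias_matrix), alpha = alpha,
                 per_bootstrap_bias = bias_matrix,
                 significant = significant,
                 n_significant = sum(significant), n_degenerate = 0L,
                 test_family = "burden",
                 statistic_family = statistic_family, seed = NULL),
            class = "bootstrap_run")
}

# A hand-built evaluation_report carrying just what aggregate_tables needs.
fake_report <- function(bias_naive, bias_adjusted, mse_naive = bias_naive^2 + 1,
                        mse_adjusted = bias_adjusted^2 + 1,
                        power = 0.1, n_sig = 10, setting_id = "fake",
                        test_family = "burden", statistic_family = "D",
                        alpha = 0.01) {
  m <- length(bias_naive)
  structure(list(setting_id = setting_id, test_family = test_family,
                 statistic_family = statistic_family, alpha = alpha,
                 n_replicates = 100, n_significant_replicates = n_sig,
                 step1_power = power, adjusted = TRUE, B = 10, seed = 1,
                 per_variant = data.frame(
                   variant = paste0("v", seq_len(m)), causal = FALSE,
                   expected_value = 0, bias_naive = bias_naive,
                   bias_adjusted = bias_adjusted, mse_naive = mse_naive,
                   mse_adjusted = mse_adjusted,
                   mean_rank_naive = NA_real_,
                   mean_rank_adjusted = NA_real_),
                 top1_causal_naive = NA_real_, top2_causal_naive = NA_real_,
                 top1_causal_adjusted = NA_real_,
                 top2_causal_adjusted = NA_real_),
            class = "evaluation_report")
}
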