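test_that("run_study aggregates conditional moments coherently", {
  st <- gene_setting(maf = c(0.02, rep(0.005, 3)), rr = c(1, 2.5, 2.5, 1),
                     n_cases = 250, n_controls = 250, alpha = 0.05)
  rep1 <- run_study(st, "burden", "D", n_replicates = 300, B = 40,
                    seed = 4, adjust = TRUE, keep_replicates = TRUE)
  expect_gt(rep1$step1_power, 0)
  expect_lte(rep1$step1_power, 1)
  expect_equal(rep1$n_significant_replicates,
               nrow(rep1$naive_matrix))

  pv <- rep1$per_variant
  # mse = bias^2 + empirical variance of the statistic (exact decomposition)
  n <- rep1$n_significant_replicates
  emp_var <- apply(rep1$naive_matrix, 2, function(x) mean((x - mean(x))^2))
  expect_equal(pv$mse_naive, pv$bias_naive^2 + emp_var, tolerance = 1e-12)
  expect_true(all(pv$mse_naive >= pv$bias_naive^2 - 1e-15))
  expect_true(all(pv$mse_adjusted >= pv$bias_adjusted^2 - 1e-15))

  # ranks live in [1, m] and average to (m+1)/2 across variants
  expect_true(all(pv$mean_rank_naive >= 1 & pv$mean_rank_naive <= 4))
  expect_equal(mean(pv$mean_rank_naive), 2.5, tolerance = 1e-12)
  expect_equal(mean(pv$mean_rank_adjusted), 2.5, tolerance = 1e-12)

  # proportions are proportions
  tops <- c(rep1$top1_causal_naive, rep1$top2_causal_naive,
            rep1$top1_causal_adjusted, rep1$top2_causal_adjusted)
  expect_true(all(tops >= 0 & tops <= 1))
})

test_that("step-1 power is non-decreasing in alpha on identical data", {
  st <- gene_setting(maf = rep(0.01, 5), rr = c(2, 2, 1, 1, 1),
                     n_cases = 300, n_controls = 300)
  r_lo <- run_study(st, "burden", "D", alpha = 0.01, n_replicates = 400,
                    seed = 10, adjust = FALSE)
  r_hi <- run_study(st, "burden", "D", alpha = 0.1, n_replicates = 400,
                    seed = 10, adjust = FALSE)
  expect_gte(r_hi$step1_power, r_lo$step1_power)
})

test_that("without selection a null gene shows no bias", {
  st <- gene_setting(maf = rep(0.02, 4), rr = rep(1, 4), n_cases = 200,
                     n_controls = 200)
  # gate effectively open: every replicate is "significant"
  rep0 <- run_study(st, "burden", "D", alpha = 1 - 1e-12,
                    n_replicates = 600, seed = 3, adjust = FALSE)
  expect_equal(rep0$step1_power, 1)
  se <- sqrt(rep0$per_variant$mse_naive / rep0$n_significant_replicates)
  expect_true(all(abs(rep0$per_variant$bias_naive) < 4 * se))
})

test_that("a hopeless gate yields an NA report with a warning", {
  st <- gene_setting(maf = rep(0.01, 3), rr = rep(1, 3), n_cases = 50,
                     n_controls = 50)
  expect_warning(
    rep0 <- run_study(st, "burden", "D", alpha = 1e-15, n_replicates = 20,
                      seed = 5, adjust = FALSE),
    "no replicate")
  expect_equal(rep0$step1_power, 0)
  expect_true(all(is.na(rep0$per_variant$bias_naive)))
})

test_that("theoretical bias decomposition is linear and proportional", {
  st <- gene_setting(maf = c(0.01, 0.001, 0.001), rr = c(1, 2, 1))
  expect_equal(theoretical_bias(st, "D", bias_Q = 0, var_Q = 1), rep(0, 3))
  # equal weights: predicted bias scales with Var(T_i)
  tb <- theoretical_bias(st, "D", bias_Q = 2, var_Q = 0.5,
                         weights = rep(1, 3))
  tr <- expected_values(st)
  expect_equal(tb / tr$var_D, rep(4, 3))
  expect_error(theoretical_bias(st, "D", bias_Q = 1, var_Q = 0), "var_Q")
})

test_that("improvement tables count variant-by-setting cells", {
  # adjustment leaves everything unchanged: nothing improves
  r_same <- fake_report(bias_naive = c(0.1, -0.2), bias_adjusted = c(0.1, -0.2))
  t_same <- aggregate_tables(list(r_same))
  bias_row <- subset(t_same$overall, metric == "bias")
  expect_equal(bias_row$pct_improved, 0)
  expect_true(is.na(bias_row$median_improvement))

  # 9 of 10 improved
  bn <- seq(0.1, 1, by = 0.1)
  ba <- bn - 0.05; ba[10] <- bn[10] + 0.02
  t_mix <- aggregate_tables(list(fake_report(bn, ba)))
  bias_row <- subset(t_mix$overall, metric == "bias")
  expect_equal(bias_row$pct_improved, 0.9)
  expect_equal(bias_row$median_improvement, 0.05)
  expect_equal(bias_row$median_decline, 0.02)
  expect_equal(bias_row$ratio, 2.5)

  # improvement is judged on |bias|: a negative-bias variant that shrinks
  # toward zero counts as improved
  t_neg <- aggregate_tables(list(fake_report(c(-0.4, -0.4), c(-0.1, -0.6))))
  expect_equal(subset(t_neg$overall, metric == "bias")$pct_improved, 0.5)

  # reports with <= 1 significant replicate are excluded
  r_thin <- fake_report(c(0.5, 0.5), c(0, 0), n_sig = 1)
  expect_error(aggregate_tables(list(r_thin)), "> 1 significant")
  t_two <- aggregate_tables(list(r_same, r_thin))
  expect_equal(subset(t_two$overall, metric == "bias")$n_cells, 2)

  # power stratification places each report in its band
  r_low <- fake_report(c(0.2, 0.2), c(0.1, 0.1), power = 0.03)
  r_high <- fake_report(c(0.2, 0.2), c(0.1, 0.1), power = 0.6)
  t_strat <- aggregate_tables(list(r_low, r_high))
  bands <- subset(t_strat$by_power, metric == "bias")
  expect_setequal(bands$power_band, c("0-0.05", "0.5-1"))
})

test_that("reports serialise to TSV and JSON", {
  r <- fake_report(c(0.1, 0.2), c(0.05, 0.1))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(r, tsv_path = tsv, json_path = js)
  back <- read.delim(tsv)
  expect_equal(back$bias_naive, c(0.1, 0.2))
  meta <- jsonlite::read_json(js)
  expect_equal(meta$step1_power, 0.1)
  expect_equal(meta$setting_id, "fake")
})
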