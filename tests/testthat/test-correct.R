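test_that("stratified bootstrap keeps stratum sizes and is deterministic", {
  g <- dense_geno(seed = 6, n_cases = 80, n_controls = 60, m = 3)
  b1 <- bootstrap_once(g, seed = 42)
  b2 <- bootstrap_once(g, seed = 42)
  expect_identical(b1$case_indices, b2$case_indices)
  expect_identical(b1$control_indices, b2$control_indices)
  expect_equal(sum(b1$bootstrap$status), 80)
  expect_equal(sum(1 - b1$bootstrap$status), 60)
  # residual = distinct subjects never drawn, stratum labels kept
  expect_equal(nrow(b1$residual$dosages),
               (80 - length(unique(b1$case_indices))) +
                 (60 - length(unique(b1$control_indices))))
  expect_true(all(table(c(b1$case_indices, b1$control_indices)) >= 1))
})

test_that("a single-subject stratum makes the bootstrap degenerate", {
  g <- cc_genotypes(matrix(c(1L, 0L, 1L, 0L), 4, 1),
                    c(1L, 0L, 0L, 0L))
  expect_error(bootstrap_once(g, seed = 1),
               class = "wincurse_degenerate_bootstrap")
})

test_that("mean residual fraction matches (1 - 1/N)^N for the study design", {
  g <- dense_geno(seed = 10, n_cases = 1500, n_controls = 1500, m = 2,
                  f = 0.01)
  set.seed(77)
  np <- 1500
  frac <- replicate(1000, {
    draw <- sample.int(np, np, replace = TRUE)
    1 - length(unique(draw)) / np
  })
  expect_equal(mean(frac), (1 - 1 / np)^np, tolerance = 0.005)
  expect_gt(mean(frac), 0.36)
  expect_lt(mean(frac), 0.375)
  # and the same through bootstrap_once on the full 3000-subject design
  set.seed(78)
  frac2 <- replicate(50, {
    b <- bootstrap_once(g)
    nrow(b$residual$dosages) / 3000
  })
  expect_gt(mean(frac2), 0.36)
  expect_lt(mean(frac2), 0.375)
})

test_that("the fast bias estimator reproduces a brute-force bootstrap exactly", {
  # <= 30 subjects per stratum; gate open (alpha = 1) and half-open
  g <- dense_geno(seed = 21, n_cases = 30, n_controls = 25, m = 4, f = 0.25)
  for (cfg in list(list(alpha = 1, family = "D"),
                   list(alpha = 0.5, family = "D2"))) {
    B <- 20; seed <- 91
    run <- estimate_bias(g, "burden", cfg$family, alpha = cfg$alpha, B = B,
                         seed = seed)
    # brute force: replay the identical resampling stream through the
    # object-level path (bootstrap_once + q_burden + naive_stats)
    set.seed(seed)
    expected <- matrix(NA_real_, B, 4)
    for (b in seq_len(B)) {
      bs <- bootstrap_once(g)
      p <- q_burden(bs$bootstrap)$p_value
      if (p < cfg$alpha) {
        expected[b, ] <- naive_stats(bs$bootstrap, cfg$family)$naive -
          naive_stats(bs$residual, cfg$family)$naive
      }
    }
    expect_equal(unname(run$per_bootstrap_bias), expected, tolerance = 1e-12)
    expect_equal(run$n_significant, sum(!is.na(expected[, 1])))
  }
})

test_that("adjustment subtracts the median bias with sign clamping", {
  st <- naive_stats(geno_from_counts(c(6, 3, 0), c(0, 9, 0), 1500, 1500), "D")
  expect_equal(st$naive, c(0.002, -0.002, 0))
  bias <- rbind(c(0.0004, -0.0004, 0.001),
                c(0.0005, -0.0004, 0.002),
                c(0.0006, -0.0004, 0.003))
  adj <- adjust(st, fake_run(bias))
  expect_equal(adj$adjusted, c(0.002 - 0.0005, -0.002 + 0.0004, 0))
  expect_equal(adj$bias_estimate, c(0.0005, -0.0004, 0.002))

  # over-correction clamps at zero instead of crossing it
  st2 <- naive_stats(geno_from_counts(3, 0, 1500, 1500), "D")
  adj2 <- adjust(st2, fake_run(matrix(0.002, 3, 1)))
  expect_equal(adj2$adjusted, 0)

  # negative branch
  st3 <- naive_stats(geno_from_counts(0, 3, 1500, 1500), "D")
  adj3 <- adjust(st3, fake_run(matrix(-0.0004, 3, 1)))
  expect_equal(adj3$adjusted, -0.001 + 0.0004)

  # non-significant bootstrap rows are excluded from the median
  bias4 <- rbind(c(99), c(0.0005), c(0.0007))
  adj4 <- adjust(naive_stats(geno_from_counts(6, 0, 1500, 1500), "D"),
                 fake_run(bias4, significant = c(FALSE, TRUE, TRUE)))
  expect_equal(adj4$bias_estimate, 0.0006)
})

test_that("adjustment preserves sign for arbitrary bias draws", {
  set.seed(33)
  for (i in 1:25) {
    cp <- rbinom(5, 40, 0.2); cm <- rbinom(5, 40, 0.2)
    st <- naive_stats(geno_from_counts(cp, cm, 200, 200),
                      sample(c("D", "D2"), 1))
    bias <- matrix(stats::rnorm(50, sd = 0.05), 10, 5)
    adj <- adjust(st, fake_run(bias, statistic_family = st$statistic_family))
    expect_true(all(sign(adj$adjusted) %in% c(0, sign(adj$naive))))
    # when the median bias shares the naive sign, magnitude cannot grow
    same <- sign(adj$bias_estimate) == sign(adj$naive) & adj$naive != 0
    expect_true(all(abs(adj$adjusted[same]) <= abs(adj$naive[same])))
  }
})

test_that("zero usable bootstraps leaves statistics unadjusted with a warning", {
  g <- dense_geno(seed = 51, n_cases = 50, n_controls = 50, m = 3)
  run <- estimate_bias(g, "burden", "D", alpha = 1e-12, B = 10, seed = 2)
  expect_equal(run$n_significant, 0)
  st <- naive_stats(g, "D")
  expect_warning(adj <- adjust(st, run), "unadjusted")
  expect_equal(adj$adjusted, st$naive)
  expect_equal(adj$n_significant_bootstraps, 0)

  run0 <- estimate_bias(g, "burden", "D", alpha = 0.5, B = 0, seed = 2)
  expect_equal(run0$n_bootstrap, 0)
  expect_equal(run0$n_significant, 0)
})

test_that("under a selected null gene the bias estimate tracks the observed effect", {
  # condition a null gene on Step-1 significance, then check the bootstrap
  # bias estimate points in the direction of the (spurious) observed D
  st <- gene_setting(maf = rep(0.02, 4), rr = rep(1, 4), n_cases = 250,
                     n_controls = 250, alpha = 0.05)
  found <- 0; agree <- 0
  for (s in 1:400) {
    sim <- simulate_gene(st, seed = 9000 + s)
    r <- q_burden(sim$genotypes, alpha = 0.05)
    if (!r$significant) next
    found <- found + 1
    run <- estimate_bias(sim$genotypes, "burden", "D", alpha = 0.05,
                         B = 60, seed = 1)
    if (run$n_significant < 5) next
    adj <- suppressWarnings(adjust(naive_stats(sim$genotypes, "D"), run))
    big <- which.max(abs(adj$naive))
    if (sign(adj$bias_estimate[big]) == sign(adj$naive[big]))
      agree <- agree + 1
    if (found >= 8) break
  }
  expect_gte(found, 3)
  expect_gt(agree / found, 0.6)
})
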