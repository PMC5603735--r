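# wincurse

Winner's-curse correction for post-hoc single-marker analysis after
gene-based rare-variant tests of association.

## The problem

In case-control sequencing studies, gene-based tests (GBTs) aggregate the
signal of all variants in a gene because rare variants cannot be tested one
at a time with useful power. When a gene comes out significant, the follow-up
question — *which variants drive the association, and how strongly?* — is
usually answered by computing per-variant statistics on the same data. Those
statistics are biased by the conditioning on gene-level significance
("winner's curse"): they overstate effects, and they overstate them most for
the relatively common variants in the gene, so a common neutral variant can
out-rank the truly causal rare variants.

`wincurse` is for statistical geneticists running two-step (gene, then
variant) analyses of case-control data, and for methodologists studying
post-selection bias in rare-variant testing.

## The method

**Step 1.** Test each gene with a weighted burden statistic
`Q_bw = Σ_i w_i D̂_i` or a SKAT-type variance-component statistic
`Q_sw = Σ_i w_i D̂_i²`, where `D̂_i = f̂⁺_i − f̂⁻_i` is the case-control
difference in minor allele frequencies and `w_i = 25 (1 − f_i)²⁴` is the
Beta(1,25) weight. P-values are asymptotic: two-sided normal for the burden
test, a chi-square-mixture tail (four-cumulant matching or numerical
inversion) for the variance-component test.

**Step 2.** For genes significant at `α`, compute per-variant statistics
`T̂_i = D̂_i` or `D̂_i²`, then correct them by stratified bootstrap: resample
cases and controls with replacement `B` times; on each bootstrap sample
re-run the Step-1 test and keep only significant resamples (replaying the
selection); estimate the bias of each `T̂_i` as the bootstrap-sample
statistic minus the statistic on the *residual* sample (the ~37% of subjects
not drawn); subtract the per-variant median bias with sign clamping, so an
estimate can shrink to zero but never cross it. Adjusted statistics are then
used to re-rank variants.

## A worked example

The benchmark scenario: a 10-variant gene with five very rare risk variants
(MAF 0.0001, relative risk 8), four rare neutral variants and one common
neutral variant (MAF 0.01), tested with the weighted burden statistic at
α = 0.01 on 1,500 cases and 1,500 controls.

```r
library(wincurse)
setting <- canonical_settings()[["b_rare0.0001_common0.01_50:50:0"]]
report <- run_study(setting, test_family = "burden", statistic_family = "D",
                    alpha = 0.01, n_replicates = 2000, B = 200, seed = 11)

report$step1_power
#> [1] 0.1255
c(naive = report$top1_causal_naive, adjusted = report$top1_causal_adjusted)
#>    naive adjusted
#>    0.139    0.502
report$per_variant[6, c("mean_rank_naive", "mean_rank_adjusted")]
#>   mean_rank_naive mean_rank_adjusted
#> 6            1.35               3.49
```

Gene-level power is ~12.5%, so conditioning on significance distorts Step 2
badly: the top-ranked variant is causal in only 14% of significant
replicates, because the common neutral variant (snp6) absorbs the selection
bias and sits at mean rank 1.35. After the bootstrap adjustment the top
variant is causal half the time and snp6 drops to mean rank 3.5. The
conditional bias of snp6's frequency difference falls from 3.5 × 10⁻³ to
1.6 × 10⁻³, and that of a causal rare variant (snp1) from 1.8 × 10⁻⁴ to
1.2 × 10⁻⁵.

For real data: `read_genotypes()` (VCF or dosage TSV plus a phenotype
table), `read_gene_sets()`, and `run_pipeline()` (YAML-configurable; genes
that fail Step 1 are stopped before any post-hoc output). A thin CLI over
these functions is installed at `inst/scripts/wincurse.R` with subcommands
`simulate`, `test`, `adjust`, `evaluate` and `reproduce` (the latter reruns
the benchmark scenario and renders naive-vs-adjusted histogram panels per
variant as PNG).

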