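---
title: "Correcting winner's curse in post-hoc analysis of gene-based rare-variant tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting winner's curse in post-hoc analysis of gene-based rare-variant tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wincurse)
```

## The problem

Gene-based rare-variant tests (GBTs) aggregate association evidence across
the $m$ variants of a gene because single rare variants carry too little
information to test individually. Once a gene is declared significant, the
analyst's next question is *which* variants drive the signal and how large
their effects are. The natural move — computing per-variant statistics on
the same data — is subject to **winner's curse**: conditioning on the
gene-level test having crossed its significance threshold biases every
per-variant statistic toward stronger apparent association. The bias is
worst exactly where gene-based testing is most needed (low gene-level
power), and it is largest for the relatively *common* variants in the gene,
which can push a common neutral variant above truly causal rare variants in
a prioritization ranking.

`wincurse` implements a two-step analysis with a bootstrap-resampling
correction for this selection bias, plus the simulation and evaluation
machinery needed to study its behaviour.

## The two-step model

**Step 1 (gene level).** For case-control data with $N^+$ cases and $N^-$
controls, let $C^\pm_i$ be the minor-allele counts at variant $i$ and
$\hat f^\pm_i = C^\pm_i / 2N^\pm$ the stratum frequencies, with
$\hat D_i = \hat f^+_i - \hat f^-_i$. Two test families are provided, both
weighted by the Beta(1,25) density $w_i = 25 (1 - f_i)^{24}$ that
up-weights rare variants:

* the **burden** statistic $Q_{bw} = \sum_i w_i \hat D_i$, asymptotically
  $N\!\left(0, \sum_i w_i^2 \hat v_i\right)$ under the null with
  $\hat v_i = \hat f_i (1 - \hat f_i)\,(1/2N^+ + 1/2N^-)$ computed from the
  pooled frequency $\hat f_i$ (score-test style, valid under $H_0$);
  the p-value is two-sided because effect mixes may include
  risk-decreasing variants;
* the **variance-component (SKAT-type)** statistic
  $Q_{sw} = \sum_i w_i \hat D_i^2$, whose null is the positive mixture
  $\sum_i w_i \hat v_i \,\chi^2_1$, evaluated by four-cumulant moment
  matching (`p_method = "liu"`, the default) or by numerical inversion of
  the characteristic function (`p_method = "imhof"`).

**Step 2 (variant level).** Only for genes with $p < \alpha$, the
per-variant statistics are $\hat T_i = \hat D_i$ (natural after a burden
test) or $\hat T_i = \hat D_i^2$ (natural after a variance-component
test).

## The bootstrap correction

The selection bias of $\hat T_i$ is estimated by replaying the whole
selection event on resampled data:

1. draw $B$ stratified bootstrap samples (cases and controls resampled
   separately, sizes preserved); each leaves a **residual sample** of
   subjects drawn zero times, on average a fraction
   $(1 - 1/N)^N \approx e^{-1} \approx 0.368$ of each stratum;
2. recompute the Step-1 test on each bootstrap sample (weights re-derived
   from that sample's pooled frequencies); keep only bootstrap samples that
   are themselves significant at the same $\alpha$ — this is what makes the
   estimator target the *conditional* bias;
3. for kept samples, estimate the bias as
   $\widehat{\mathrm{Bias}}_b(\hat T_i) = \hat T^*_{ib} - \hat T^R_{ib}$,
   the bootstrap-sample statistic minus the residual-sample statistic, and
   adjust with sign clamping:
   $$\hat T_{i,\mathrm{adj}} =
     \begin{cases}
     \max\bigl(\hat T_i - \mathrm{med}_b\,\widehat{\mathrm{Bias}}_b(\hat T_i),\, 0\bigr) & \hat T_i > 0\\
     \min\bigl(\hat T_i - \mathrm{med}_b\,\widehat{\mathrm{Bias}}_b(\hat T_i),\, 0\bigr) & \hat T_i < 0.
     \end{cases}$$

The clamp guarantees the adjustment shrinks toward zero and never flips the
sign of the observed effect; `sign(adjusted) ∈ {0, sign(naive)}` is asserted
property-style in the test suite.

For independent variants the conditional bias decomposes as
$\mathrm{Bias}(\hat T_i) = \dfrac{\mathrm{Bias}(Q)}{V(Q)}\, w_i\,
\mathrm{Var}(T_i)$ (`theoretical_bias()`), which explains the common-variant
effect: $\mathrm{Var}(T_i)$ grows with MAF, so the common variants absorb
the most selection bias.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `alpha` | 0.01 | Step-1 gate, reused unchanged as the bootstrap gate so the replayed selection matches the real one. |
| `B` | 1000 (`estimate_bias`), 200 (`run_study`) | Bootstrap resamples. The median stabilizes quickly; 200 is adequate for ranking studies, and sensitivity of the median to `B` is covered in tests. |
| `summary` | `"median"` | Robust to the skewed bias distribution near the gate; `"mean"` available. |
| `weights` | Beta(1,25) of the *pooled sample* MAF | A real-data analysis has no population frequency; supplying `beta_weight(f)` with known `f` is supported for simulation work. |
| `freeze_weights` | `FALSE` | Bootstrap tests re-estimate weights from each resample, mirroring what the original analysis did to the original sample. |
| `p_method` | `"liu"` | No dependency, accurate to a few percent at $p \in [10^{-3}, 0.05]$ (checked against Monte-Carlo nulls); `"imhof"` available for tail accuracy. |

## The simulation engine

`canonical_settings()` builds a 50-scenario catalogue: ten
minor-allele-frequency architectures (all-rare; one common neutral + nine
rare; two common of which one is risk-increasing + eight rare; rare
frequency 0.0001 or 0.001, common 0.01 or 0.05) crossed with five
risk-increasing : neutral : risk-decreasing mixes (20:80:0, 50:50:0,
80:20:0, 20:60:20, 0:100:0). Relative risks are tied to frequency —
(0.05, 1.2), (0.01, 1.5), (0.001, 2), (0.0001, 8), reciprocals for
protective variants — and every scenario uses 1,500 cases and 1,500
controls with a 10-variant gene. Under the all-neutral mix all ten
settings are fully null; in the two-common architecture the designated
risk-increasing common variant is only causal when the mix allocates a
risk-increasing share.

Case and control frequencies derive from the rare-disease allelic
relative-risk mapping $f^+ = \lambda f / (1 + (\lambda - 1) f)$, $f^- = f$.
We chose this mapping because no disease prevalence is part of the
scenario definitions, it is the standard case-control mapping for
rare-variant simulation, and it makes neutral variants *exactly* null.
Genotypes are simulated at subject level — independent
$\mathrm{Binomial}(2, f^\pm_i)$ dosages (Hardy–Weinberg within stratum, no
linkage disequilibrium) — because the bootstrap must resample subjects.
Closed-form reference values (`expected_values()`) are
$E[\hat D_i] = f^+_i - f^-_i$ and
$E[\hat D_i^2] = (f^+_i - f^-_i)^2 + \mathrm{Var}(\hat D_i)$ with
$\mathrm{Var}(\hat D_i) = f^+_i(1-f^+_i)/2N^+ + f^-_i(1-f^-_i)/2N^-$; both
are verified against brute-force Monte-Carlo moments in the tests.

What the generator does **not** emulate: linkage disequilibrium (so the
covariance terms of the bias decomposition vanish by construction),
covariates and population structure, quantitative traits, genotyping error
and missingness. Passing simulation benchmarks therefore demonstrates the
selection-bias mechanics and the correction's behaviour under independence,
not performance on structured real data — though the bootstrap itself makes
no independence assumption.

## Numerical and design choices

* **Monomorphic variants** get weight 25 (the $f = 0$ weight) but
  contribute zero to statistics and null variances; an all-monomorphic gene
  returns $p = 1$ with a warning rather than `NaN`.
* **Ranking** uses $|\hat T_i|$ with midranks for ties, making ranking by
  $\hat D_i^2$ and by $|\hat D_i|$ coincide and letting protective causal
  variants rank as strong signals. A "top-$k$ causal" event requires every
  variant tied into the top $k$ to be causal — deterministic and
  conservative. Because adjusted statistics often clamp to exactly zero,
  ties are common after adjustment and this rule visibly depresses
  top-two-causal proportions relative to more liberal tie-breaking.
* **Residual-sample statistics** are computed with the residual sample's
  own case/control counts; frequency differences are scale-free in $N$, so
  no reweighting is needed.
* **Degenerate bootstraps** (an empty residual stratum, essentially
  impossible at $N = 3{,}000$) are skipped without counting toward $B$ and
  reported in the run object.
* **Seeding** is counter-based: replicate $r$ of a study derives its seed
  from the master seed and $r$, so any replicate (and its bootstrap run)
  can be regenerated in isolation.
* **Improvement accounting** in `aggregate_tables()` judges bias on
  $|\mathrm{bias}|$ (the only reading under which "improvement" is
  well-defined for negative-bias variants), takes medians over
  variant-by-setting cells, and excludes situations with fewer than two
  significant replicates, whose conditional moments are not estimable.

## Problem sizes used in the checks

The packaged checks reproduce the benchmark low-power scenario (five rare
risk variants at relative risk 8, four rare neutral, one common neutral;
burden test, $\alpha = 0.01$) at full size — 10,000 replicates with
$B = 200$ bootstraps per significant replicate, about a minute of
computation — and the study-wide improvement aggregates at reduced
replication: all 50 scenarios under both tests and both significance
levels (1% and 0.01%) with 400 replicates each and $B = 100$. The
reduced-scale aggregates are compared to the full-scale reference values
within ±20% relative bands. Oracle comparisons use $2 \times 10^5$-draw
parametric Monte-Carlo nulls for p-values, $10^6$-draw mixtures for the
chi-square tail, and exact brute-force bootstrap enumeration on a
55-subject instance.

## A worked example

```{r example, eval = FALSE}
library(wincurse)

setting <- canonical_settings()[["b_rare0.0001_common0.01_50:50:0"]]
report <- run_study(setting, test_family = "burden",
                    statistic_family = "D", alpha = 0.01,
                    n_replicates = 2000, B = 200, seed = 11)
report$step1_power              # ~0.12 gene-level power
report$top1_causal_naive        # ~0.14: naive top variant rarely causal
report$top1_causal_adjusted     # ~0.50 after adjustment
report$per_variant[6, c("mean_rank_naive", "mean_rank_adjusted")]
                                # common neutral variant: ~1.35 -> ~3.5
```

For real data, `read_genotypes()` ingests a VCF (via vcfR) or dosage TSV,
and `run_pipeline()` applies the gate structurally: genes failing Step 1
never reach the post-hoc output.

## Known limitations

* Asymptotic p-values degrade for genes composed solely of extremely rare
  variants (MAF $\sim 10^{-4}$ at $N = 3{,}000$), where allele counts are
  so discrete that both tests become conservative; empirical size is
  accurate whenever the gene contains at least one variant with a few
  expected carriers.
* No per-variant p-values or confidence intervals are produced for the
  adjusted statistics; post-selection inference for them is an open
  problem, and the adjusted values are intended for estimation and
  ranking.
* Extremely rare variants (singletons/doubletons) yield coarse, unstable
  per-variant statistics before or after adjustment.
* The correction targets per-variant statistics, not the gene-level effect
  size, and no LD-aware variant of the evaluation layer is provided.
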