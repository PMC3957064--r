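---
title: "Testing CNV disease association from SNP-array intensities with VTET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing CNV disease association from SNP-array intensities with VTET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(vtet)
```

## The problem

Genome-wide association studies genotyped on SNP arrays carry, at every
probe, two intensity summaries: the Log R Ratio (LRR), a log-scale measure
of total DNA amount that is zero in expectation at two copies, and the
B Allele Frequency (BAF), the fraction of signal attributable to the B
allele. Copy number variants (CNVs) shift both: a hemizygous deletion (CN1)
depresses the LRR and pushes BAF to 0/1; a three-copy duplication (CN3)
raises the LRR and moves heterozygous BAF clusters to 1/3 and 2/3.

The standard two-step analysis — call CNVs per sample, then test
case/control counts — works well for long CNVs but loses most of its power
when CNVs cover only a handful of probes, where calling sensitivity
collapses. Direct regression-style tests of intensities work only when all
carriers share the same boundaries (recurrent CNVs). `vtet` targets the
harder setting: **short CNVs (as few as 3 probes) that disrupt a given
region at varying locations in different carriers**, while remaining
effective for recurrent CNVs too.

## The method

Consider one region with $T$ probes, $m$ cases and $n$ controls, and
per-sample standardized intensities $x_{it}$ that behave as i.i.d.
$N(0,1)$ at copy-neutral probes.

**Step 1 — per-subject evidence.** For every sub-interval $[a,b]$ with at
least $L \ge 3$ probes, the mean-shift likelihood-ratio statistic is
$$z_{ab} = \sum_{t=a}^{b} x_t \,/\, \sqrt{b-a+1},$$
and the scan maximum is $U = \max_{b-a+1\ge L} s(z_{ab})$ with $s(z) = -z$
for deletions, $+z$ for duplications, $|z|$ for either. $U$ is converted to
an evidence p-value $p_i$ against the empirical null distribution of the
same maximum under i.i.d. $N(0,1)$ input — a Monte-Carlo table built once
per $(T, L, \text{mode})$ and shared by all subjects and permutations
(`build_null_table()`, default $10^6$ draws, resolving p-values to
$10^{-5}$ scale with the add-one estimator $(1 + \#\{U^{null} \ge U\}) /
(n_{sim}+1)$).

**Step 2 — the variable threshold exact test.** Subjects with $p_i \le q$
are *tentative carriers*; $a(q)$ and $b(q)$ count them in cases and
controls and Fisher's exact test gives $P(q)$. Because no single $q$ is
safe — liberal thresholds drown true carriers in false ones, stringent
thresholds miss them — the statistic minimizes over a grid,
$$Q = \min_{1 \le k \le K} P(q_k), \qquad
q_k = \frac{\text{expected false carriers}_k}{m+n},$$
with the default grid expecting $(5, 2, 1, 0.5, 0.1)$ false carriers
($K=5$; the classic single choice $q = 2/(m+n)$ is the second point).
Significance comes from permuting case/control labels: the $p_i$ never
involve the labels, so carrier sets are fixed and each permutation only
redistributes them between arms — a nested-hypergeometric draw per
threshold, $O(K)$ per permutation (verified identical to naive
recomputation in the test suite). Permutation stops after 10 exceedances
(the observed signal cannot be interesting then) or `max_permutations`,
and reports the add-one estimate $(1+s)/(1+B)$.

**BAF fusion for duplications.** A BAF in the informative window
$[0.2, 0.8]$ is converted to a standard-normal quantile of the folded
distance $d = |b - 0.5|$ under the null heterozygote model
$b \sim N(0.5, \eta_2)$:
$Y = \Phi^{-1}(2\Phi(d/\eta_2) - 1)$, clipped at $\pm 5$. $Y$ is $N(0,1)$
at two copies and large near the 1/3 and 2/3 duplication clusters. The
fused intensity is $Z = (X + Y)/\sqrt{2 + 2\rho}$ with the method constant
$\rho = -0.05$ (denominator $1.38$), so $Z \sim N(0,1)$ at two copies;
uninformative or missing BAF passes the LRR through unchanged. Duplication
and two-sided scans use $Z$; deletion scans use the LRR alone, since a
deletion's homozygous BAF is uninformative. The quantile transform is our
reconstruction from the stated null model — it reproduces every property
required of it (standard normal under two copies, large near 1/3 and 2/3)
— and `rho` is kept as the printed constant rather than re-estimated; the
empirical LRR–BAF-quantile correlation in our generator is ~0, which
changes `var(Z)` by only 5%.

**Genome-wide application.** `scan_genome()` tiles each autosome into
segments of `M` probes (default 50; a trailing stub shorter than $L$ is
merged into its predecessor), runs VTET per segment and mode, and controls
the family-wise error by Bonferroni — segment statistics are independent,
and e.g. a 10,957-segment scan needs $p \le 0.05/10957 = 4.6\times10^{-6}$.
QQ plots of the permutation p-values (`qq_points()`) are the standard
check against systematic intensity differences between arms.

## Tunable parameters

| parameter | default | meaning / why |
|---|---|---|
| `L` | 3 probes | shortest CNV worth scanning; below 3 probes single-probe noise dominates |
| `mode` | both | deletion ($-z$), duplication ($+z$), or either ($|z|$) |
| `n_sim` (null table) | $10^6$ | p-value resolution $\approx 10^{-5}$; $10^5$ in tests/examples |
| `expected_false` | 5, 2, 1, 0.5, 0.1 | carrier-calling grid in expected false carriers (unitless counts) |
| `sided` | one | the hypothesis is case enrichment; two-sided available |
| `min_successes` | 10 | sequential permutation stop; keeps null segments cheap |
| `max_permutations` | $10^4$–$10^6$ | resolution floor of the permutation p-value; keep $1/\max$ below the α of interest |
| `window`, `y_cap`, `rho` | [0.2, 0.8], 5, −0.05 | BAF informativeness, quantile clip, fusion constant |
| `M` | 50 probes | segment size for genome tiling |

Normalization (`normalize_lrr()`) rescales each sample's genome-wide LRR
to zero median and unit standard deviation, matching the copy-neutral
$N(0,1)$ assumption; a `"mad"` option uses $1.4826\cdot\text{MAD}$, which
ignores CNV-carrying outlier probes, for samples with heavy CNV load.
Normalization uses all autosomal probes (putative CNV regions are not
excluded — at realistic CNV loads they move the median and SD negligibly).

## The simulator

`simulate_study()` generates the exact conditions used to validate the
method: carrier flags Bernoulli($f$) in controls and Bernoulli($f_+$) in
cases with $f_+ = OR\,f/(OR\,f + 1 - f)$; each carrier gets a CN1 or CN3
event over `cnv_len` probes, placed uniformly at random (or at one shared
centered interval for recurrent designs); two haplotypes per subject with
per-probe B-allele frequencies drawn from $U[0.05, 0.5]$; LRR
$\sim N(\mu_c, \sigma_c)$ given copy number $c$ with
$\mu = (-3, -0.45, 0, 0.30, 0.50)$, $\sigma = (1, 0.26, 0.16, 0.19, 0.22)$
for $c = 0..4$; and BAF from the genotype-conditional mixture (homozygous:
half point mass at the boundary, half folded normal of scale
$\eta_1 = 0.02$; heterozygous clusters normal with scale $\eta_2 = 0.05$
at 0.5, 1/3 or 2/3; zero copies: uniform noise). CN1 retains, and CN3
duplicates, one haplotype chosen uniformly. Four-copy parameters are
carried but never simulated. In simulation pipelines the model
standardization $X = (\text{lrr} - \mu_2)/\sigma_2$ replaces the empirical
per-sample normalization, so copy-neutral probes are exactly $N(0,1)$.

What the generator deliberately omits: linkage between probes (the
parametric MAF model replaces a phased haplotype pool — adequate because
power is averaged over random intervals and the scan never uses genotype
phase), GC waves, batch and plate effects, and mosaic fractions. Passing
the validation suite therefore demonstrates correctness of the statistical
machinery under the stated intensity model, not robustness to array
artifacts; on real data the QQ diagnostic is the guard against the latter.

`ideal_test()` is Fisher's exact test on the *true* carrier status — the
power ceiling of any intensity-based procedure — and `estimate_power()`
reports both. At the deletion benchmark (1000 vs 1000 subjects, $T=20$,
$f=0.01$, OR 5, α = 0.001, 300 replicates, 10,000 permutations per test)
the suite checks that VTET power is within 15 percentage points of the
ideal ceiling for CNVs of ≥5 probes, is monotone in CNV length over
{3, 5, 8}, and moves by well under 10 points between $T=20$ and $T=40$
regions. Type-I error is checked on 1000 null replicates (200 vs 200,
$f = 0.01$ in both arms).

## Numerical and design choices

* **Exact scan.** All $O(T^2)$ intervals are enumerated via prefix sums
  (regions are 10–100 probes, so no pruning is needed); arg-max ties break
  lexicographically by $(a, b)$. The test suite checks equality with
  brute-force enumeration — arg-max intervals exactly, statistic values to
  $10^{-12}$ (prefix-sum and direct summation differ by one ulp).
* **Add-one estimators everywhere.** Both the Monte-Carlo evidence
  p-value and the permutation p-value use $(1+\text{hits})/(1+\text{draws})$
  with ties counted as hits: strictly positive, valid, conservative under
  discreteness.
* **Discreteness.** With rare carriers the permutation distribution of
  $Q$ has few atoms; `perm_p = 1` occurs with positive probability and the
  test is somewhat conservative (measured type-I ≈ 0.03 at α = 0.05 in the
  null design above). This is inherent to exact tests on small carrier
  counts and shows as QQ deflation, not inflation.
* **The closed-form tail approximation.** `siegmund_pvalue()` implements
  the printed random-walk boundary-crossing formula verbatim (λ = −0.583).
  Validated against the Monte-Carlo oracle at $T = 500$, the printed
  expression comes out negative with magnitude 0.25–0.65× the true
  p-value — the typeset formula has evidently lost a component — so it is
  shipped as a clearly-flagged diagnostic and Monte-Carlo tables are
  authoritative at every region size.
* **Missing data.** Probes with missing LRR exclude that subject from
  that region (with a warning) rather than scanning a gappy vector;
  missing BAF is merely uninformative and passes the LRR through.
* **Degenerate inputs.** Zero-variance samples fail normalization loudly;
  `T < L` regions, non-nested threshold grids and unlabeled subjects are
  structured errors.
* **Reproducibility.** Null tables, permutation streams and simulations
  are seed-scoped without clobbering the caller's RNG; per-segment streams
  derive from the master seed, so checkpointed resumes reproduce an
  uninterrupted scan bit for bit.

## A worked region

```{r example}
cfg <- simulation_config(m = 500, n = 500, T = 20, cnv_len = 5,
                         f = 0.01, OR = 5, cnv_type = "CN1", seed = 7)
sim <- simulate_study(cfg)
x <- standardize_lrr(sim$matrix)
tables <- list(
  both        = build_null_table(20, 3, "both",        n_sim = 1e5, seed = 1),
  deletion    = build_null_table(20, 3, "deletion",    n_sim = 1e5, seed = 2),
  duplication = build_null_table(20, 3, "duplication", n_sim = 1e5, seed = 3))
ev <- subject_region_pvalues(x, tables = tables, L = 3)
res <- vtet_region_test(ev, sim$phenotype, mode = "deletion",
                        params = vtet_params(seed = 11))
res
ideal_test(sim$truth, sim$phenotype)
```

The threshold table shows how tentative-carrier counts shrink as $q$
tightens while the case excess persists; `Q` is the best Fisher p-value
over the grid and `perm_p` its permutation-calibrated significance.

## Limitations

VTET assumes cases and controls share the same intensity distribution:
same platform, proportionally mixed plates. Systematic case/control
intensity differences produce spurious findings in *any*
intensity-based test; QQ plots are the first diagnostic. The package
analyzes autosomes only, does not call or genotype CNVs (it tests
regions), does not model CN4+, and offers Bonferroni (not FDR) control in
the genome scan, matching the independence of segment statistics.
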