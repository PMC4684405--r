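---
title: "Testing Hardy-Weinberg equilibrium and excess homozygosity on the X chromosome"
author: "xhweqc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing Hardy-Weinberg equilibrium and excess homozygosity on the X chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

At a biallelic X-linked locus with alleles M1/M2, males are hemizygous:
a male carries a single allele, M1 with frequency $p_m$. Females carry two
alleles; with M1 frequency $p_f$, $q_f = 1 - p_f$ and inbreeding
coefficient $\rho$, their genotype frequencies are

$$P(M_1M_1) = p_f^2 + \rho p_f q_f,\quad
  P(M_1M_2) = 2(1-\rho)p_f q_f,\quad
  P(M_2M_2) = q_f^2 + \rho p_f q_f.$$

$\rho = 0$ is Hardy-Weinberg equilibrium; $\rho > 0$ means excess
homozygosity, caused by population substructure (the Wahlund effect),
consanguinity, or genotyping artefacts such as null alleles — which is why
both $\rho > 0$ and $p_m \ne p_f$ are used to *filter* X-linked variants
before association analysis. We restrict $\rho$ to $[0, 1]$: the
boundary-at-zero testing problem is the case of practical interest, the
latent-variable representation below requires $\rho \ge 0$, and negative
$\rho$ (heterozygote excess) is still visible through the unclipped moment
estimator `rho_moment()`.

The observed data are counts $(n_{1m}, n_{0m})$ of male alleles and
$(n_{2f}, n_{1f}, n_{0f})$ of female genotypes. The likelihood is the
product of a male binomial and a female multinomial; the package works in
log space and drops the combinatorial constants, which cancel in every
likelihood ratio. Zero-count cells contribute nothing
($0\cdot\log 0 = 0$); a positive count on a zero-probability cell gives
$-\infty$.

Three null hypotheses are tested against the unconstrained alternative
($\rho \ge 0$):

* $H_0$: $p_m = p_f$ and $\rho = 0$ — the joint QC null (2 constraints);
* $H_{01}$: $p_m = p_f$, $\rho$ free (1 constraint);
* $H_{02}$: $\rho = 0$, frequencies free (1 constraint).

## Estimation

Under $H_0$ and $H_{02}$ the MLEs are closed form: the pooled frequency
$\hat p = (n_{1m} + 2n_{2f} + n_{1f})/(N_m + 2N_f)$, and
$\hat p_m = n_{1m}/N_m$, $\hat p_f = (2n_{2f} + n_{1f})/(2N_f)$.

Under the alternative and under $H_{01}$, $(\hat p_f, \hat\rho)$ has no
closed form in this parameterisation and is fitted by EM. Each female
homozygote cell is split into a latent "independent alleles" part and an
"identical by descent" part: $n_{2f} = w_1 + w_2$ with
$E(w_2) \propto \rho p_f q_f$, and $n_{0f} = w_3 + w_4$ likewise. The
E-step takes conditional expectations of $w_1,\dots,w_4$ at the current
parameters; the M-step updates

$$\hat p_f \leftarrow \frac{E(2w_1 + w_2) + n_{1f} + E(w_4)}{2N_f},\qquad
  \hat\rho \leftarrow \frac{E(w_2) + E(w_4)}{E(w_2) + E(w_4) + n_{1f}},$$

with the male term joining the numerator and denominator of the pooled
update under $H_{01}$. $\hat p_m = n_{1m}/N_m$ separates and is exact at
every iteration.

**Defaults** (`em_config()`): starting values are the moment estimates for
the frequencies and $\rho^{(0)} = 0.02$; convergence when every
parameter's absolute change falls below $10^{-7}$; at most 1000
iterations. These mirror the reference software for this family of tests,
so the conservative sizes reported below are properties of the statistics,
not of a different stopping rule.

**Degenerate female samples.** Monomorphic females leave $\rho$
unidentifiable: the fit returns the boundary frequency, $\hat\rho = 0$,
and a `boundary` flag. Samples with no female heterozygotes but both
homozygote classes are driven to $\hat\rho = 1$ by the iteration itself;
all-heterozygote samples to $\hat\rho = 0$. Starting frequencies of
exactly 0 or 1 are nudged into $[10^{-6}, 1-10^{-6}]$ so the E-step ratios
are defined. These rules keep every LRT defined on degenerate loci, which
batch QC requires.

**A numerical subtlety worth recording.** The EM stops on a
*parameter*-change criterion. At an interior optimum the resulting
log-likelihood deficit is quadratic in the parameter error and negligible,
but at a boundary optimum ($\hat\rho \to 0$) it is *linear*: stopping with
$|\Delta\rho| < 10^{-7}$ can leave the log-likelihood up to about
$10^{-7} \cdot n_{1f}$ short, and a run cut off by the iteration cap while
contracting geometrically towards the boundary can be short by up to about
$N\rho^{(0)}/\texttt{max\_iter}$. A likelihood ratio can therefore be
microscopically negative even though the hypotheses nest. We clip
negatives to zero within the bound
$\mathrm{tol}\,(10 + 2N) + 2N\rho^{(0)}/\texttt{max\_iter}$ and raise an
internal-consistency error beyond it — a fixed multiple of the tolerance
alone (an obvious alternative) is provably too tight at the boundary.
For the same reason, the tests that compare the EM against an independent
grid-search oracle tighten the tolerance to $10^{-10}$: the comparison
targets the estimator, not its stopping rule.

## Test statistics

The moment tests use
$\hat{\mathrm{Var}}(\hat p_m) = \hat p_m(1-\hat p_m)/N_m$ and
$\hat{\mathrm{Var}}(\hat p_f) = [\hat p_f - 2\hat p_f^2 +
\hat P(M_1M_1)]/(2N_f)$:

$$Z_1 = \frac{(\hat p_m - \hat p_f)^2}
  {\hat{\mathrm{Var}}(\hat p_m) + \hat{\mathrm{Var}}(\hat p_f)},\qquad
  Z_2 = \frac{N_f[\hat\Delta_f + \hat p_f\hat q_f/(2N_f)]^2}
  {\hat p_f^2 \hat q_f^2},$$

with $\hat\Delta_f = \hat P(M_1M_1) - \hat p_f^2$ the disequilibrium
coefficient ($\Delta_f = \rho p_f q_f$, so testing $\Delta_f = 0$ is
testing $\rho = 0$). $Z_0 = Z_1 + Z_2$ is $\chi^2_2$ under $H_0$ because
the components are independent there. The LRTs are twice the
log-likelihood differences of the nested fits, with $\chi^2_2$ (LRT0) or
$\chi^2_1$ (LRT1, LRT2) reference tails; no continuity correction. $Z_2$
and LRT2 use females only (the male terms cancel), which the tests assert
by fuzzing male counts. Statistics that are undefined at monomorphic loci
are reported as missing, not as errors, so per-locus batch runs continue.

Because $\rho = 0$ is a boundary point, the large-sample distribution of
LRT2 is a half-half mixture of a point mass at 0 and $\chi^2_1$ rather
than $\chi^2_1$, and LRT0 inherits part of the same problem; their
$\chi^2$ sizes at 5% are roughly 2-3% — conservative. The package's
simulation engine demonstrates this and the bootstrap repair; the
acceptance checks pin the sizes to the published reference values.

## Parametric bootstrap

`xhwe_boot()` calibrates a statistic against its exact null distribution:
fit the null model (pooled $\hat p$ for LRT0; female-only $\hat p_f$ for
LRT2, with male alleles held fixed at their observed values; the fitted
$(\hat p_{01}, \hat\rho_{01})$ for LRT1), regenerate $B$ datasets from it,
and report $\hat P = B^{-1}\sum_i I\{T_i^* > T\}$ — a strict inequality
with no $+1$ correction, exactly the convention whose published sizes we
reproduce. Ties at the boundary mass ($T = T_i^* = 0$) therefore do not
count as exceedances.

One distributional consequence is worth stating: under $H_{02}$ about half
the replicates have $T = \mathrm{LRT2} = 0$ exactly, so LRT2b p-values
have an atom near $1/2$ and are *not* uniform on $(0,1)$ — only their
lower tail is, which is what size control needs and what the size checks
verify. LRT0b p-values *are* approximately uniform (the joint statistic is
continuous, $\hat p_m \ne \hat p$ almost surely), and the test suite's
Kolmogorov-Smirnov uniformity check uses LRT0b for exactly this reason.

Reproducibility: every bootstrap stream is seeded deterministically from
the analysis seed and the replicate (or marker) index, so batch results
are independent of evaluation order — and of the internal chunking that
runs the resample EMs of ~32 replicates as one vectorised batch (the slow
geometric approach to the $\rho = 0$ boundary is the dominant EM cost, and
chunking amortises it).

## The simulation engine

`xhwe_scenario()` fixes the study conditions; its defaults are the
conditions of the experiments the package reproduces. A homogeneous
scenario draws $n_{1m} \sim \mathrm{Bin}(N_m, p_m)$ and female genotypes
from the multinomial at `female_genotype_freqs(p_f, rho)`, with
$p_f = p_m + \epsilon$ and $N_m = \mathrm{round}(N\,r_1/(r_1+r_2))$ (so
$N = 800$, $r = 2{:}1$ gives 533/267). The stratified scenario assigns
each of $N$ individuals independently to one of two subpopulations
(probability 0.5) and a sex (probability 0.5), draws within-subpopulation
genotypes at HWE ($\rho = 0$), and pools — the mixture then shows positive
$\hat\rho$ (Wahlund effect). Whether the sex split should be Bernoulli per
individual or fixed at $N/2$ is not determined by the description we
follow; Bernoulli is the default as printed, and
`fixed_sex_split = TRUE` provides the alternative. At $N = 1800$ the two
differ by about 1pp in LRT1 power and ~0.0002 in mean $\hat\rho_1$, which
is of the same order as the residual gap between our generator and some
published stratification-row values — a gap coherent across all three
$\rho$ estimators, i.e. attributable to the data-generating convention,
not the estimators.

`run_experiment()` reports rejection rates (rejecting when
$p \le \alpha$, so a degenerate $\alpha = 1$ rejects everything) with
binomial Monte-Carlo standard errors, per-test exclusion counts for
undefined replicates (excluded, not regenerated — regeneration would bias
the null distribution), and estimator summaries (mean, SD, bias, RMSE of
$\hat p_m, \hat p_{f1}, \hat\rho_1, \hat p_{01}, \hat\rho_{01},
\hat\rho_z$; note $\mathrm{RMSE}^2 = \mathrm{bias}^2 + \mathrm{variance}$
holds by construction and is asserted). `sample_size_search()` finds the
smallest female sample size reaching a target power by doubling then
bisecting on a grid, assuming monotone power. `run_experiment_grid()`
drives a batch of scenarios from a plain-text table and emits a delimited
table, one row per scenario-test pair.

**Problem sizes.** The asymptotic-test experiments in the test suite and
the acceptance script run at the study scale of 10000 replications. For
the bootstrap-calibrated entries we run 2000-2500 Monte-Carlo replications
with $B = 500$ resamples: at a 5% size this gives a Monte-Carlo SE of
about 0.45pp, ample against the tolerance bands used, and it keeps a full
run in minutes on one CPU. The comparison bands in the acceptance tests
widen correspondingly, never the other way around.

**What the generator does not emulate.** Real panels have missingness,
genotyping error, linkage between markers, and more than two ancestral
components; founders extracted from pedigrees can still share recent
ancestry. Passing the simulation checks therefore validates the
statistics under the stated sampling model, not robustness to those
artefacts — on real data the per-locus battery is a screen, and loci
flagged for excess homozygosity deserve scrutiny of clustering and
missingness before being dropped.

## PED input

`read_ped()` parses whitespace-delimited linkage pedigree files (six
leading columns, then allele pairs, `0` missing), reporting malformed
lines by number. Only genotyped founders (father and mother ids both `0`)
are counted — they are the mutually independent individuals the tests
assume. PED has no haploid representation, so male X genotypes are
written as homozygous pairs: identical codes count as one allele,
discordant non-missing codes are treated as genotyping errors and excluded
with a warning. M1 defaults to the minor allele among counted founders
(males once, females twice; ties to the lexicographically smaller code) —
the choice only relabels counts, and every p-value is invariant to the
relabelling, which the suite asserts. `analyze_file()` writes a
results-table with the counts, the estimates under the alternative and
under each null, all statistics and p-values, and the Bonferroni threshold
$\alpha/m$; its column layout is this package's own documented one.

## Dosage compensation

X-inactivation equalises expressed dosage between sexes; in
allele-counting terms each male allele counts twice (equivalently each
female allele counts one half). With `dosage_compensation = TRUE` the
pooled-frequency estimates and likelihood weight male terms by two, e.g.
$\hat p = (2n_{1m} + 2n_{2f} + n_{1f})/(2N_m + 2N_f)$, which changes LRT0
and LRT1 (and their bootstrap versions) only; $Z_1$, $Z_2$, $Z_0$ and
LRT2 are unaffected by construction (sex-separate variances or
females-only). The option modifies the statistics, not the generator: how
reference datasets for the published dosage-compensation experiments were
generated is ambiguous, so those numbers are reproduced only qualitatively
(the uncalibrated dosage-weighted LRT1 inflates; its bootstrap version
restores size).

## Known limitations

* Biallelic markers only; multi-allelic loci are rejected at the PED
  layer.
* Negative $\rho$ is observable through `rho_moment()` but not fitted:
  the likelihood machinery is built for the excess-homozygosity boundary
  problem.
* No standard errors for the MLEs (the tests are the inferential tool),
  and EM only — no Newton-type acceleration.
* The bootstrap p-value granularity is $1/B$; with the default
  $B = 1000$, p-values below $10^{-3}$ are reported as 0.
* Asymptotic p-values at very small $N_f$ are unreliable for all
  boundary-affected statistics; use the bootstrap variants there.
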