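---
title: "Two-sample and two-step Mendelian randomization with mrmediate"
author: "mrmediate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample and two-step Mendelian randomization with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

Mendelian randomization (MR) uses genetic variants as instrumental
variables for an exposure. For SNP $j$, let $\hat\beta_{Xj}$ (SE
$\sigma_{Xj}$) be its association with the exposure and $\hat\beta_{Yj}$
(SE $\sigma_{Yj}$) its association with the outcome, estimated in
non-overlapping samples (the two-sample design). Under the instrumental
assumptions — relevance, no confounding of the SNP–outcome relation, and
no effect on the outcome except through the exposure — each per-SNP Wald
ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal
effect $\theta$.

`mrmediate` implements this workflow for the drug-target setting: the
exposure is a biomarker signature of pharmacological target inhibition
(e.g. HbA1c lowering through a glucose-transporter gene), instruments are
cis variants near the target gene, and a two-step extension asks how much
of the exposure's effect on an outcome runs through an intermediate
trait such as a circulating metabolite.

## Instrument selection and harmonization

`select_instruments()` keeps SNPs with exposure $p$ below a threshold
(default $10^{-5}$) and prunes them to near-independence by greedy
clumping: candidates are sorted by ascending $p$ (ties broken by larger
$|\hat\beta/\sigma|$, then identifier, for determinism), the best SNP is
kept, and any SNP within the window (default 10,000 kb) with $r^2$ at or
above the ceiling (default 0.001) against a kept SNP is discarded. LD is
an explicit input (`ld_matrix()`), because squared correlations must come
from an external reference panel; without one the clump degrades to
one-SNP-per-window distance pruning. Instrument strength is summarized by
the per-SNP approximation $F = (\hat\beta/\sigma)^2$ — the
variance-explained form is not computable from a single summary row — and
`filter_weak()` removes instruments below $F = 10$, the conventional
weak-instrument bar.

`select_cis_instruments()` restricts a biomarker panel to a flank around
the target gene (default 100 kb each side — the window is a knob, since
"close to the gene" has no canonical width), optionally requires
expression support from a user-supplied eQTL panel (default threshold
$10^{-4}$, also a knob), and re-orients every SNP so that a positive
exposure beta is the biomarker-*lowering* effect of the coded allele,
the scale on which target inhibition is quantified.

`harmonize()` aligns outcome effects to the exposure's effect alleles:
identical pairs pass through, swapped pairs negate the outcome beta, and
pairs matching only after strand complement are complemented first.
Palindromic SNPs (A/T, C/G) are removed outright — their strand cannot be
resolved from alleles alone, and no allele-frequency rescue is attempted —
as are irreconcilable pairs. This is deliberately conservative; it makes
harmonization an involution and leaves every per-SNP ratio invariant to
how either source file coded its alleles (both properties are tested).

## Estimators

With $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$ (first-order weights; the
exposure SE is ignored, consistent with F-filtering):

* **Wald ratio** ($k=1$): $\hat\theta = \hat\beta_Y/\hat\beta_X$, SE
  $\sigma_Y/|\hat\beta_X|$.
* **IVW** ($k\ge2$): $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$,
  the weighted regression of outcome on exposure betas through the
  origin. Fixed-effects SE $(\sum w_j)^{-1/2}$; the multiplicative
  random-effects variant scales it by $\sqrt{\max(1, Q/(k-1))}$, leaving
  the point estimate unchanged. Fixed effects is the primary method;
  random effects is the fallback when heterogeneity persists.
* **MR-Egger** ($k\ge3$): weighted regression *with* an intercept after
  orienting all $\hat\beta_{Xj} \ge 0$; the intercept estimates average
  directional pleiotropy, the slope a pleiotropy-adjusted effect.
  SEs carry the residual scale $\max(1, \sqrt{RSS/(k-2)})$ — no
  super-precision is claimed when residuals underdisperse — and tests use
  $t_{k-2}$.
* **Weighted median** ($k\ge3$): interpolates the sorted ratios across
  cumulative weight midpoints at 0.5; consistent when at least half the
  weight is valid. SE from a parametric bootstrap (betas resampled about
  their observed values, default 1000 draws, seeded; default seed
  20240507).
* **Weighted / simple mode** ($k\ge3$): argmax of a normal-kernel
  density of the ratios with bandwidth
  $\phi \cdot 0.9\,\min(\mathrm{sd},\mathrm{mad})\,k^{-1/5}$, evaluated
  on a fixed 512-point grid spanning the ratios ±3 bandwidths, argmax
  ties broken toward the smaller ratio. When one spread measure is
  degenerate (a majority atom zeroes the mad) the other is used; when
  both are (all ratios equal) the estimate is that ratio with SE 0.
  Bootstrap SE as for the median.

For binary outcomes (log-odds betas) `mr_to_or()` exponentiates the
estimate and CI; quantitative outcomes are refused.

## Sensitivity analysis

`cochran_q()` computes $Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$,
chi-square with $k-1$ df under homogeneity. `egger_intercept_test()`
re-exports the Egger intercept with its $t_{k-2}$ test. `mr_presso()`
implements the residual-simulation outlier test: each SNP's residual
about its leave-one-out IVW prediction is compared, via parametric
simulation of both beta sets, with its null distribution; the global test
uses the standardized residual sum of squares, and per-SNP empirical
p-values below a Bonferroni bar (default $0.05/k$ — the originating
method leaves this to the user) declare outliers, after which the IVW is
re-estimated without them. Empirical p-values use $(1+x)/(n+1)$, so they
are never zero and are bounded below by $1/(n_{sim}+1)$; detection of an
outlier therefore requires $n_{sim} \gtrsim 20k$ at the default bar.
`leave_one_out()` and `funnel_data()` provide influence and asymmetry
tables; plotting is left to the caller. The pipeline policy is: remove
MR-PRESSO outliers, re-estimate, and if the Q test still rejects at 0.05
report random-effects IVW as primary.

## Two-step mediation

Step 1 estimates the exposure→mediator effect $a$ for every candidate and
screens at the Bonferroni level $\alpha/m$ over all $m$ candidates (for
$\alpha=0.05$: $3.57\times10^{-5}$ at $m=1400$, $2.98\times10^{-4}$ at
$m=168$). Step 2 instruments each passing mediator from its own GWAS
(same selection rules; optionally excluding the exposure gene region to
limit pathway overlap — the source of step-2 instruments is a stated
choice, since two-step designs vary here) and estimates the
mediator→outcome effect $b$, with a second Bonferroni screen over the
step-2 tests. Given the total effect $c$, `mediate()` reports

* indirect effect $ab$, with first-order delta SE
  $\sqrt{a^2\sigma_b^2 + b^2\sigma_a^2}$ (zero covariance between the
  steps, which come from non-overlapping samples);
* direct effect $c' = c - ab$ (the identity $ab + c' = c$ holds by
  construction);
* proportion mediated $ab/c$, whose delta SE by default also propagates
  $\sigma_c$ ($\sqrt{\sigma_{ab}^2/c^2 + (ab)^2\sigma_c^2/c^4}$); a flag
  switches to the $c$-fixed expansion $\sigma_{ab}/|c|$, since published
  analyses rarely state which expansion they used. Proportions outside
  $[-1, 1]$ are allowed but flagged as inconsistent mediation.

Proportions are reported on the additive (log-odds) scale even for binary
outcomes; this ignores non-collapsibility, as is standard in two-step MR,
and is documented rather than corrected.

## The synthetic-data generator

`simulate_study()` draws a shared SNP universe — $k_x$ exposure
instruments, plus $k_m$ instruments for each mediator — with per-SNP
instrument effects $\gamma_j \sim U[0.05, 0.15]$ (so F statistics land
well above 10; widen the range downward to inject weak instruments),
MAFs uniform on $[0.05, 0.5]$, and observed betas drawn independently per
trait about their true values with
$\sigma = 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$. True effects
follow the mediation diagram: mediator $a\gamma_j$ on exposure SNPs and
$\delta_j$ on its own; outcome $(c' + ab)\gamma_j$ plus a pleiotropic
offset $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha)$ on a configurable
fraction of exposure SNPs (added to the outcome only, so InSIDE holds by
construction), and $b\delta_j$ on mediator SNPs. Palindromic allele pairs
are injected at a configurable rate. Binary outcomes reuse the same SE
model on the log-odds scale with an effective sample size; this is an
approximation for method testing, not a case-control likelihood.

Default sample sizes mirror a drug-target mediation design: a large
biomarker GWAS for the exposure ($n_x = 344{,}182$), a moderate
metabolome GWAS for mediators ($n_m = 8{,}299$), and an imaging-scale
outcome GWAS ($n_y = 40{,}095$), with $k_x = 10$ exposure instruments and
$k_m = 20$ per mediator. LD is *not* simulated — instruments are drawn
independent, and SNPs are placed 20,000 kb apart so the default clump
never prunes them; the clumping code path is instead exercised by
hand-built LD fixtures (`make_fixtures()`). Consequently, passing tests
say nothing about proxy-SNP lookup, reference-panel mismatch, sample
overlap, or real LD structure; they validate the estimators, diagnostics
and decomposition under the stated generating model.

`sim_harmonized()` skips the allele bookkeeping and emits an
already-harmonized set; it drives the calibration and recovery suites.

## Numerical and testing choices

* Determinism: clumping tie-breaks as above; bootstrap and MR-PRESSO
  take explicit seeds; pipeline output files contain no timestamps, so a
  rerun with the same config and seed is byte-identical (timestamps
  appear only on console progress lines).
* Panels are serialized at 17 significant digits, so write/read
  round-trips are bit-exact, `NA` encodes missing EAF/N, and p-values
  implied by $|\hat\beta/\sigma|$ are floored at the smallest normal
  double so noiseless panels stay inside $(0, 1]$. Reported p-values
  more than 10-fold discrepant with $|\hat\beta/\sigma|$ trigger a
  validation warning, not rejection.
* Calibration suites (mean of Q, Egger-intercept type-I error, MR-PRESSO
  null rejection) idealize the exposure side ($n_x = 10^{10}$, i.e.
  negligible $\sigma_X$): the chi-square calibration of $Q$ is exact only
  when the weights are the true inverse variances, and with a realistic
  $n_x$ the first-order weights leave a structural excess of roughly
  $\theta^2 n_y/n_x$ on $\mathrm{E}[Q]/(k-1)$ — a property of
  summary-data MR itself, not of the implementation. Recovery and power
  suites keep the realistic sample sizes.
* Problem sizes in the test and acceptance suites: 500 replicates for
  IVW recovery ($k=50$), 2000 for Q calibration, 1000 for the Egger
  type-I rate, 500×500 simulations for the MR-PRESSO null, 200 for
  outlier recall, 300 for mediation recovery. These sizes put the
  Monte-Carlo error comfortably inside each check's tolerance while
  keeping the whole suite in the tens of seconds.

## Known limitations

* First-order Wald/IVW SEs ignore exposure uncertainty; with weak
  instruments they understate variance (hence the F filter and the
  documented calibration caveat above).
* MR-Egger's intercept test is mildly anticonservative when pleiotropy
  is homoskedastic but weights are not (a single residual scale cannot
  capture it); observed type-I error is ~7% at nominal 5% under the
  balanced-pleiotropy generator.
* One-mediator-at-a-time decomposition: no multivariable or network
  mediation, so overlapping mediators double-count shared pathways.
* No proxy-SNP lookup, no LD-aware simulation, no VCF/BGEN genotype
  parsing; summary statistics only.
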