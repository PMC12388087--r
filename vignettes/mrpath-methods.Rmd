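---
title: "Methods: two-sample MR, mediation, MVMR and colocalization in mrpath"
author: "mrpath authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR, mediation, MVMR and colocalization in mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

# The problem

Observational associations between the gut microbiome, circulating
metabolites and disease are confounded by diet, medication and reverse
causation. Two-sample Mendelian randomization (MR) sidesteps much of this by
using germline genetic variants as instrumental variables: a variant that
robustly shifts the abundance of a microbial taxon is randomized at
conception, so its downstream association with disease risk — estimated in
an independent cohort — carries causal information about the taxon itself,
provided the variant affects disease only through the taxon (the exclusion
restriction).

`mrpath` implements the complete summary-statistics workflow of such a
study: screening many exposures against one outcome, probing reverse
causation, decomposing effects through a mediator, estimating joint direct
effects, and testing whether two traits share a causal variant at a locus.
Only GWAS summary statistics are consumed; no individual-level data are
needed.

# Data model and harmonization

A trait is a `summary_stats` object: per-SNP records of effect and other
allele, effect-allele frequency (EAF), effect estimate (log-odds for binary
traits), standard error, p-value and sample size. Validation drops records
with impossible values and warns (without dropping) when a p-value is
inconsistent with its own `|beta|/se`, which usually indicates a corrupted
or re-rounded file.

Because different GWAS report effects on arbitrarily chosen alleles,
`harmonize()` aligns every shared SNP to the exposure's orientation: swapped
alleles negate the outcome beta and complement its EAF; strand-complement
labels (A/G vs T/C) are first complemented; palindromic SNPs (A/T, C/G) are
kept only when both EAFs fall on the same side of 0.5 and outside the
ambiguity zone `[0.42, 0.58]` — otherwise the strand cannot be inferred and
the SNP is dropped. The 0.42 limit is configurable; missing EAF on either
side of a palindrome drops the SNP, the conservative choice. Harmonization
is idempotent, and the simulator records the true orientation of every SNP
so this logic is tested against ground truth rather than against itself.

# Instrument selection

`select_instruments()` applies, in fixed order: the significance threshold
(1e-5 by default for 16S microbial taxa, whose GWAS signals rarely reach
genome-wide significance; 5e-8 for metabolites and disease traits), a
minor-allele-frequency filter (> 0.01), the single-SNP instrument-strength
filter `F = (beta/se)^2 >= 10`, and greedy LD clumping at r² < 0.001 within
a 10 Mb window: the remaining SNP with the smallest p-value is kept and
everything correlated with it discarded, repeatedly, with ties on p broken
lexicographically by SNP id so the result is order-independent. We
interpret the allele-frequency filter on the minor allele (an effect-allele
frequency of 0.999 tags just as rare a variant as 0.001). The per-SNP
F-statistic is the standard summary-data approximation; its analytic
expectation `2p(1-p)n·gamma² + 1` is verified against the simulator in the
test suite. Without an LD matrix, input is assumed pre-clumped — the common
situation when instruments come from a curated source.

# Univariable estimators

With one instrument the causal estimate is the Wald ratio
`beta_out/beta_exp`, with the first-order delta-method standard error
`se_out/|beta_exp|` (the second-order expansion is available and never
smaller). With J ≥ 2 instruments the inverse-variance-weighted (IVW)
estimate is the weighted regression of outcome betas on exposure betas
through the origin with weights `1/se_out²` — algebraically the
inverse-variance-weighted mean of the per-SNP Wald ratios. We default to
the multiplicative random-effects variant: the fixed-effect standard error
is scaled by `sqrt(Q/(J-1))` when Cochran's Q exceeds its degrees of
freedom, and never shrunk below the fixed-effect value. This is the
dominant community practice; pure fixed-effect is a configuration switch.

MR-Egger refits the same regression with a free intercept after orienting
every SNP so its exposure beta is non-negative; a non-zero intercept
estimates directional horizontal pleiotropy, and the slope is the
pleiotropy-adjusted effect. Inference for slope and intercept uses the
t-distribution with J−2 degrees of freedom (IVW uses the normal), the
conventional choices. Cochran's Q accompanies IVW (J−1 df) and Rücker's Q′
accompanies Egger (J−2 df).

Both regressions are implemented as explicit weighted least squares
(`(X'WX)^{-1}X'Wy` with the covariance floored at its fixed-effect value)
rather than through `lm()` post-processing; `lm()` serves as the
independent oracle in the tests, keeping implementation and check distinct.

Binary-outcome effects are log-odds throughout, so `exp(beta)` is an odds
ratio and `to_odds_scale()` attaches normal-theory 95% intervals.

# Mediation and multivariable MR

`two_step_mediation()` decomposes a total effect `beta_EO` through a
mediator using the product of coefficients: `indirect = beta_EM × beta_MO`,
`direct = beta_EO − indirect`, `proportion mediated = indirect/beta_EO`.
The accounting identities hold to machine precision by construction. The
delta-method standard error of the proportion treats the three estimates as
independent — customary in two-sample designs where each leg comes from
non-overlapping cohorts — and is reported but optional. A proportion
outside `[0, 1]` (sign-discordant indirect and total effects) is returned
with a flag rather than an error, since it is a legitimate, interpretable
outcome. The no-interaction assumption of two-step MR is not testable from
summary data; it is documented here and assumed. Reversed chains
(metabolite → taxon → disease) are the same machinery with roles swapped.

`mvmr()` estimates joint direct effects by weighted multiple regression,
without intercept, of outcome betas on the matrix of exposure betas. SNPs
must carry betas for every exposure; each exposure is re-oriented to a
common per-SNP effect allele before fitting. An exposure whose instrument
betas are identically zero carries no information and is reported `NA`
with a warning (the remaining exposures collapse to their nested model);
genuine collinearity is an error naming the offending exposures.
Covariate adjustment beyond what summary statistics support (age, sex,
inflammatory markers) is representable only as additional exposure columns
when such GWAS are supplied.

# Colocalization

A significant MR signal can still be an LD artifact: the instrument may tag
one causal variant for the exposure and a different, correlated variant for
the outcome. `colocalize()` evaluates the five standard hypotheses at a
locus (H0 no association, H1/H2 one trait only, H3 two distinct causal
variants, H4 one shared variant) from per-SNP Wakefield approximate Bayes
factors, `log ABF = 0.5[log(V/(V+W)) + z²W/(V+W)]`, with prior effect
standard deviations 0.15 for quantitative and 0.2 for binary traits and
per-SNP priors `p1 = p2 = 1e-4`, `p12 = 1e-5` — the conventional defaults;
none are stated by typical source studies. All accumulation is in log
space (log-sum-exp), so posteriors remain finite for z-scores of 50 and
beyond. `PPH4 > 0.75` is the default call. Loci are windows of ±500 kb
around a user-supplied anchor (e.g. a gene midpoint); gene models are
deliberately not bundled. All five posteriors are always reported — a
failed colocalization (low PPH4) is a result, not an error.

# The synthetic-data generator

`simulate_gwas()` emulates the statistical structure of consortium GWAS
under a known exposure → mediator → outcome chain, entirely on summary
scale. Default cohort sizes mirror the scales of the study design the
package targets: 18,340 for the 16S exposure, 7,824 for the metabolite
mediator, and 408,241 with 1,086 cases for the binary outcome. Effects on
the binary outcome are simulated directly on the log-odds summary scale —
two-sample MR consumes nothing else, and this keeps the generator fast and
exact. Per-SNP sampling standard errors follow `1/sqrt(2p(1-p)n)`
(quantitative) and `1/sqrt(2p(1-p)n·phi(1-phi))` (binary, case fraction
phi); z-score noise is equicorrelated within LD blocks; allele labels and
orientations are randomized and recorded.

Two deliberate design points:

* **Mediator-specific instruments.** A mediator instrumented only through
  the exposure is not identifiable: the mediator-outcome leg would absorb
  the exposure's direct path. The generator therefore gives the mediator
  its own instrument set (`n_med_instruments`, effects `delta`), disjoint
  from the exposure's, exactly as a real metabolite GWAS provides variants
  acting on the metabolite directly.
* **Positive-oriented instrument effects.** True instrument effects are
  drawn as `|N(0, sd²)|`, i.e. the effect allele is defined as the
  trait-increasing allele — a pure labeling convention that costs no
  generality but makes "directional pleiotropy of +0.05" a well-defined
  quantity for MR-Egger to recover (orientation otherwise randomizes its
  sign away).

Pleiotropy acts on the exposure's instruments (the exclusion-restriction
violation MR-Egger is designed to detect): `balanced` draws mean-zero
effects, `directional` shifts their mean. What the generator does **not**
emulate: realistic genome-wide LD, fine-scale allele-frequency spectra,
sample overlap between cohorts, population stratification, or
winner's-curse-inducing discovery/replication asymmetries. Passing
calibration on these simulations therefore demonstrates correctness of the
estimators under their stated assumptions, not robustness to every
pathology of real consortium data.

# Calibration choices and problem sizes

The test suite fixes all simulation seeds and uses problem sizes chosen to
make sampling error small relative to the asserted tolerances while keeping
the default run inside a few minutes: 1,000 replicates for IVW coverage
(asserted within [93%, 97%]), 2,500 null fits for the nominal type-I error
(asserted within [3%, 6.5%] — the random-effects SE floor makes the test
mildly conservative, so the rate sits slightly below 5%), 500 replicates
each for the Q-statistic null mean and for two-mediator MVMR recovery, and
200 full pipeline replicates of a 30%-mediation chain (asserted within ±10
percentage points). Simulated instrument strengths (`gamma_sd = 0.1` at the
default exposure cohort size, median F around 50-80) sit inside the F-range
such studies report. Published worked numbers — the 14.5% / 27.9% mediated
proportions and the odds-ratio tables for lysine and succinylcarnitine —
are reproduced from the printed constants via `mpn_mediation_constants()`
at printed precision.

# Known limitations

* Single-SNP F-statistics approximate instrument strength; without
  individual-level data the conditional (multivariable) F-statistic is not
  computed.
* Clumping requires a user-supplied LD matrix; the package does not compute
  LD from a reference panel, look up proxies, or perform Steiger filtering.
* The colocalization model assumes at most one causal variant per trait per
  locus; multi-signal fine-mapping is out of scope.
* Weighted-median/mode estimators and MR-PRESSO are not implemented; the
  sensitivity toolkit is Cochran's Q and the Egger intercept.
* Screening significance is the raw p-value at 0.05 to mirror common
  practice in this literature; BH q-values are attached for transparency
  but do not drive any decision.
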