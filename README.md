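# mrpath

Two-sample Mendelian randomization (MR) from GWAS summary statistics, with
the full downstream toolkit used in microbiome- and metabolome-wide causal
screens against a disease outcome: allele harmonization, instrument
selection with LD clumping, Wald-ratio/IVW/MR-Egger estimation with
heterogeneity and pleiotropy diagnostics, two-step mediation MR with the
proportion mediated, multivariable MR, and approximate-Bayes-factor
colocalization. A built-in simulator generates summary statistics under a
known exposure → mediator → outcome causal model so every estimator is
validated against ground truth.

## Who it is for

Analysts running hypothesis-free MR screens — e.g. 16S microbial taxa and
plasma metabolites against a hematologic malignancy — who need the whole
chain from raw summary-statistics files to tidy result tables, with the
statistical conventions of that literature (suggestive 1e-5 instrument
threshold for taxa, 5e-8 for metabolites, r² < 0.001 clumping, F ≥ 10,
method routing by instrument count).

## The statistics in brief

For instruments j = 1..J with SNP-exposure effects β_xj (se σ_xj) and
SNP-outcome effects β_yj (se σ_yj):

* **Wald ratio** (J = 1): β = β_y/β_x, se = σ_y/|β_x|.
* **IVW** (J ≥ 2): β = Σw_jβ_xjβ_yj / Σw_jβ_xj², w_j = 1/σ_yj² — weighted
  regression through the origin; multiplicative random-effects SE floored
  at the fixed-effect value; Cochran's Q for heterogeneity.
* **MR-Egger** (J ≥ 3): same regression with a free intercept after
  orienting β_xj ≥ 0; the intercept estimates directional pleiotropy.
* **Mediation**: indirect = β_EM·β_MO, proportion mediated =
  β_EM·β_MO/β_EO, delta-method SE.
* **MVMR**: weighted multiple regression of β_y on the matrix of exposure
  betas, no intercept.
* **Colocalization**: per-SNP Wakefield log-ABFs combined over the five
  hypotheses H0-H4; PPH4 > 0.75 calls a shared causal variant.

## Worked example

```r
library(mrpath)

# simulate a study: exposure -> mediator -> outcome with 30% mediation
sim <- simulate_gwas(sim_config(seed = 7, n_snp = 150, n_instruments = 25,
                                n_med_instruments = 25, gamma_sd = 0.1,
                                delta_sd = 0.2, beta_EM_true = 0.5,
                                beta_MO_true = 0.6, beta_direct_true = 0.7))

# univariable screen of the exposure against the outcome
run_screen(list(taxon = sim$exposure), sim$outcome)[, c("method", "n_snp", "beta", "se", "pvalue", "or")]
#> # A tibble: 1 × 6
#>   method n_snp  beta    se     pvalue    or
#>   <chr>  <int> <dbl> <dbl>      <dbl> <dbl>
#> 1 ivw       11 0.711 0.161 0.00000989  2.04

# full mediation chain
res <- run_mediation_chain(sim$exposure, sim$mediator, sim$outcome)
res[, c("beta_EO", "beta_EM", "beta_MO", "proportion_pct")]
#> # A tibble: 1 × 4
#>   beta_EO beta_EM beta_MO proportion_pct
#>     <dbl>   <dbl>   <dbl>          <dbl>
#> 1   0.711   0.341   0.564           27.1
```

The screen routed to IVW (11 instruments survived selection at 1e-5) and
flagged the exposure; the generating total effect is 1.0 on the log-odds
scale, and the single-replicate estimate 0.711 reflects sampling noise plus
the winner's curse of selecting significant instruments. The mediated
proportion (27.1% here, generating value 30%) is more stable because that
selection bias largely cancels between the numerator and denominator legs;
over 200 replicates the test suite shows its mean lands within ±10 points.

The published worked numbers for the *Eubacterium xylanophilum* →
{succinylcarnitine, lysine} → myeloproliferative-neoplasm pathways ship as
`mpn_mediation_constants()`:

```r
k <- mpn_mediation_constants()
two_step_mediation(list(beta = k$beta_EO, se = k$se_EO),
                   list(beta = k$succinylcarnitine$beta_EM, se = k$succinylcarnitine$se_EM),
                   list(beta = k$succinylcarnitine$beta_MO, se = k$succinylcarnitine$se_MO))$proportion_pct
#> [1] 14.47032
```

A thin command-line wrapper (subcommands `simulate`, `screen`, `mediate`,
`mvmr`, `coloc`) lives at `inst/cli/mrpath.R`.

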