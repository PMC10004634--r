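---
title: "Methods: empirical-null regulation calling and companion pharmacology statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: empirical-null regulation calling and companion pharmacology statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosreg)
```

# Overview

`phosreg` implements the quantitative analysis chain used to characterize a
selective covalent BTK inhibitor in ABC-DLBCL models: calling regulated
phosphosites from two label-swapped SILAC replicates, kinase-panel
selectivity arithmetic, logistic concentration–response fitting, microarray
differential expression with gene-wise-permutation GSEA, 2^−ΔΔCt qPCR
quantification, and xenograft efficacy/pharmacodynamics statistics. This
vignette records the statistical models, the tunable parameters, and the
design choices made where the underlying procedures left genuine freedom.

# The SILAC regulation-calling model

## Data model

Each phosphosite record carries a residue (S/T/Y), a MaxQuant-style
localization probability, and one treatment/control SILAC ratio per
biological replicate. Replicate 2 uses an inverted labeling scheme, so its
raw heavy/light ratio is the *reciprocal* of its treatment/control ratio;
`harmonize_label_swap()` inverts it exactly once, tracking completion in a
`harmonized` attribute so the operation is idempotent. Only class-I sites —
S/T/Y assignments with localization probability ≥ 0.75, boundary inclusive —
enter the analysis (`filter_class1()`).

## Empirical Gaussian null

The vast majority of phosphosites are unaffected by a selective inhibitor,
so the bulk of the log2-ratio distribution estimates the null. We histogram
the log2 ratios and fit a three-parameter Gaussian
$A \exp\{-(x-\mu)^2 / 2\sigma^2\}$ to the bin counts by unweighted least
squares (Levenberg–Marquardt). Fitting the *histogram peak* rather than
taking a sample standard deviation makes the estimate robust to the small
regulated minority in the tails, which would otherwise inflate
$\hat\sigma$.

Two samples can be fitted:

* `pooled_single_ratios` (default): the pooled log2 treatment/control
  ratios of both replicates. This is the scale on which the regulation
  thresholds are subsequently applied, so the default makes the derived
  cutoffs directly interpretable. With a centred null of
  $\sigma = 0.2233$, $k = 2.5$ gives the ratio thresholds
  $2^{\pm 2.5\sigma} = 1.472 / 0.679$.
* `ratio_of_ratios`: per-site $\log_2(r_1/r_2)$, a replicate-agreement
  diagnostic. Its standard deviation is $\sqrt{2}$ times the
  between-replicate noise component only — the shared per-site biology
  cancels — so a $\sigma$ estimated this way is *not* applicable to
  single-replicate ratios without rescaling. Both modes are exposed; the
  default is the one under which the published-scale thresholds are
  recoverable from the data they are applied to.

Binning defaults to Freedman–Diaconis (`grDevices::nclass.FD`),
overridable via `n_bins`. The fit requires ≥ 100 complete sites and
rejects zero-variance samples.

## Thresholds and the dual-replicate rule

`derive_thresholds()` sets $\mathrm{up} = 2^{\mu + k\sigma}$,
$\mathrm{down} = 2^{\mu - k\sigma}$ with $k = 2.5$ by default; for a
centred null the product of the two thresholds is exactly 1. A site is
called regulated only when **both** replicate ratios fall strictly beyond
the same threshold (`call_regulation()`); discordant directions and sites
with a missing replicate are never called. Strict inequalities mirror the
conventional "> up / < down" notation. Summaries count distinct proteins by
gene symbol, because site tables identify proteins that way; percentages
are rounded to one decimal and thresholds to three, matching standard
reporting precision.

## Operating characteristics

For a null site the probability that one replicate exceeds $2.5\sigma$ on a
given side is $\Phi(-2.5) \approx 0.62\%$. Replicates share the per-site
biological deviation, so the joint false-call probability is larger than
the independence product but still small: with the generator's default
variance split it is ≈ 0.2% per direction, i.e. well under the 1%
type-I budget the tests assert. On the sensitivity side, a true effect of
exactly $4\sigma$ leaves a per-replicate margin of $1.5\sigma$, which caps
joint sensitivity near $\Phi(1.5) \approx 0.93$ no matter how the variance
is split — a structural property of the dual-replicate rule, not an
implementation artifact. The generator's default effect size,
$|\log_2 \mathrm{FC}| = 1$ (ratios ≈ 0.5, the magnitude typical of
published regulated sites), corresponds to ≈ $4.5\sigma$ and yields
theoretical sensitivity ≈ 0.96; the property tests assert ≥ 0.95 averaged
over 20 seeded simulations at that default.

# The synthetic-data generators

`gen_silac_dataset()` draws per-site replicate log2 ratios as
$\delta_i + b_i + e_{ir}$: a planted effect $\delta_i \in \{0, \pm
\mathrm{effect}\}$, a shared site deviation $b_i \sim N(0, \sigma_b)$, and
independent replicate noise $e_{ir} \sim N(0, \sigma_e)$, with $\sigma_b$
chosen so the marginal null sd equals `null_sigma_log2` (default 0.223,
the value implied by the published thresholds). The within/between
replicate split is not identifiable from published thresholds alone, so
both components are exposed as parameters (default $\sigma_e = 0.10$).
Residues follow the 84.6/14.4/1.0 S/T/Y composition; localization
probabilities come from a beta mixture with ≈ 15% mass below 0.75 so the
class-I filter is genuinely exercised; replicate 2 is stored as the raw
reciprocal heavy/light ratio by default. Genes are drawn from a pool of
≈ 0.7 × n sites, giving the 1.5–2 sites-per-protein multiplicity of deep
phosphoproteomes.

`silac_study_standin()` instantiates the two published cell-line runs
synthetically: null $\sigma$ implied by each line's printed thresholds
(0.2233 and 0.2363), the published quantified-site counts (9,497 and
9,740), the published S/T/Y compositions, and planted regulated sites
(130 down + 7 up; 22 down) sized so that expected *called* counts — true
detections plus the Gaussian-tail false calls the rule admits — land at
the published 138/15 and 30. It is a stand-in for data that is not
shipped, and is labelled as such; what passing its checks shows is that
the pipeline recovers thresholds and counts *under the stated model*, not
that the model captures every feature of the real tables (heavier-than-
Gaussian tails, intensity-dependent variance, protein-level clustering of
regulated sites — see Limitations).

Other generators: `gen_dose_response()` (4PL + Gaussian noise, vehicle at
the bottom asymptote), `gen_expression()` (log-normal probe intensities,
planted alternating ±lfc shifts), `gen_gene_sets()` (random membership),
and `gen_growth_curves()` (exponential mean growth scaled by a per-dose
inhibition fraction, lognormal animal and measurement noise, diameters
back-solved from $V = LW^2/2$ at aspect ratio 1.5). All are fully
seed-deterministic.

# Pharmacology arithmetic

* **Percent inhibition** is the plate formula
  $[1 - (A-B)/(C-B)] \times 100$; it is affine-invariant and may exceed
  [0, 100].
* **Logistic fits** (`fit_logistic()`) run on $\log_{10}$ concentration
  with Levenberg–Marquardt least squares. 4PL frees all four parameters;
  2PL fixes top = 100, bottom = 0; sigmoid-Emax fixes bottom = 0 and frees
  Emax. Vehicle rows (concentration 0) are not placed at $\log 0$: they
  enter the objective as observations of the bottom asymptote, the
  numerical counterpart of plotting vehicle at −∞. The 95% CI for IC50 is
  a t-quantile delta interval on the $\log_{10}$ scale, back-transformed;
  calibration is verified by simulation (coverage in [90%, 99%] over 200
  runs). Non-convergence is flagged, never silently defaulted; a negative
  fitted Hill slope flags a wrong-signed response.
* **Selectivity folds** divide a kinase's IC50 by the reference kinase's.
  Formatting follows panel-table convention, inferred from the printed
  values themselves: ≥ 1 rounds half-up to an integer, < 1 keeps one
  decimal, and a censored numerator ">x" propagates as ">round(x/ref)".
  The unrounded float is always retained. Censored *references* are
  rejected.
* **Kinome hits** use strict > 65% inhibition (100 − %CTRL), sorted
  descending; **BioMAP annotation** requires two consecutive
  same-direction points outside the significance envelope with at least
  one |log10 ratio| > 0.1 (one point suffices for antiproliferative
  readouts). The envelope itself is an input, not estimated here.

# Transcriptomics

* **Normalization**: each sample is scaled so its 75th percentile equals
  the cohort reference. The reference is the geometric mean of per-sample
  75th percentiles — a choice (the exact vendor target is not specified
  anywhere authoritative) that makes the operation idempotent and
  symmetric in the samples; it is exposed for audit via the normalized
  matrix itself.
* **Welch DE**: "log-converted" is taken as log2, the field's fold-change
  convention. Group summaries are geometric means on the linear scale
  (equal to means of logs); the test is the closed-form Welch statistic
  with Satterthwaite df, vectorized, and verified against `stats::t.test`
  to 1e-10. BH q-values are reported alongside, but classification uses
  nominal p (< 0.01) with strict fold-change cutoffs (> 2, < 0.5), the
  convention under which the published probe counts were produced.
* **GSEA**: the weighted KS running sum (weight exponent p = 1) increments
  by $|r|^p / N_R$ at members and decrements by $1/(N - N_h)$ elsewhere;
  ES is the extremum. The null is *gene-wise* permutation — random gene
  sets of the same size against the fixed ranked list, the non-phenotype
  permutation mode — chosen because with many truly changed genes,
  sample permutation is anti-conservative. NES divides ES by the mean
  |null ES| of the same sign; the permutation p is the exceedance fraction
  among same-sign nulls (zero attainable); FDR compares pooled normalized
  null NES against observed NES separately by sign. The ranking metric is
  signal-to-noise with the conventional variance floor
  (sd ≥ 0.2·|mean|, and an absolute floor of 0.2). The permutation engine
  uses an $O(N_h \log N_h)$ positional form of the running-sum extremum,
  property-tested to agree exactly with the literal $O(N)$ oracle.
* **ΔΔCt**: $\Delta Ct = Ct_\mathrm{target} - Ct_\mathrm{ref}$ per sample,
  $\Delta\Delta Ct$ = group-mean difference vs the calibrator group, fold
  $= 2^{-\Delta\Delta Ct}$; multiplicative in additive Ct shifts.

# In-vivo statistics

* **Tumor volume**: $V = LW^2/2$, the standard ellipsoid caliper
  convention (the primary sources leave the formula implicit); swapped
  diameter pairs are auto-ordered with a warning.
* **TGI**: $(1 - \bar V_\mathrm{treated}/\bar V_\mathrm{vehicle}) \times
  100$ on absolute volumes at the comparison day, without baseline
  adjustment — the plain reading of "based on tumor volume".
* **Dunnett**: two-sided many-to-one comparisons from the pooled
  equal-variance error and the multivariate-t acceptance region with
  plug-in correlation $\rho_{ij} = \lambda_i\lambda_j$,
  $\lambda_i = \sqrt{n_i/(n_i+n_0)}$ (0.5 balanced), evaluated with
  `mvtnorm::pmvt` to 1e-6 absolute tolerance. Agreement with
  `multcomp::glht` and a familywise error of 0.05 ± simulation noise
  (5,000-replicate null) are both asserted in the tests.
  `dunnett_crit()` exposes the equicoordinate critical value so that
  large simulations can avoid per-replicate `pmvt` calls.
* **Dose trend**: OLS of final-day volume on dose across treated groups;
  degenerate zero-residual designs return p = 0 (exact nonzero slope) or
  p = 1 (exactly constant response) rather than NaN.
* **PD inhibition**: animals with > 30% 7-AAD-positive (dead) cells are
  excluded (strict), the signal is stimulated − unstimulated MFI, and
  group inhibition is relative to the control-group mean signal.

# Problem sizes and determinism

The test suite runs the full chain at desk scale: 20,000-site null
calibrations, study-scale (≈ 9,500-site) stand-ins for both cell lines,
200 noisy CI-calibration fits, a 5,000-replicate Dunnett null, 500-gene
to 20,000-probe expression matrices, and 200–500 permutations per GSEA
call — about half a minute in total. `scripts/acceptance.R` re-derives
every headline quantity from scratch at the same scales, seeding every
random draw from its `--seed` argument. All generators and analyses are
deterministic given (inputs, config, seed); the only numerically
stochastic component, `mvtnorm`'s quasi-Monte-Carlo t-probabilities, is
controlled to 1e-6.

# Known limitations

* The Gaussian null is an idealization; real SILAC ratio distributions
  have heavier tails and intensity-dependent variance, which would push
  more null sites past fixed thresholds than the simulation predicts.
* The generators do not emulate missing-value structure beyond optional
  NA injection, protein-level clustering of regulated sites (so synthetic
  distinct-protein counts sit closer to site counts than real tables do),
  peptide-level quantification, or probe-to-gene many-to-one mappings.
* Censoring algebra for selectivity supports censored numerators only.
* The GSEA FDR follows the sign-pooled convention and is meaningful in
  the many-sets regime; with a handful of sets the permutation p-values
  are the quantity to interpret.
* Two published selectivity integers cannot be reproduced from the
  printed IC50 columns (they derive from unrounded inputs); the package
  reproduces the other 50 of 52 cells exactly and documents the two
  divergences in its tests.
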