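---
title: "Proteome-wide Mendelian randomization: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteome-wide Mendelian randomization: models, diagnostics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`pwmr` implements a complete proteome-wide two-sample Mendelian
randomization (MR) workflow for screening circulating plasma proteins as
candidate drug targets for a complex outcome — here a quantitative
multisite chronic pain phenotype, the number of body sites (0–7) with
persistent pain. The package covers instrument selection, causal
estimation with diagnostics, three independent validation layers
(SMR/HEIDI, Bayesian colocalization, reverse MR with Steiger filtering),
a mediation screen for modifiable risk factors, phenome-wide MR, and an
evidence-tier classification — all exercised end-to-end on a built-in
synthetic GWAS summary-statistics generator with known ground truth.

## The causal model

Two-sample MR treats genetic variants as instruments: a variant $G$ that
alters circulating protein level $X$ and is independent of confounders
affects the outcome $Y$ only through $X$ (no horizontal pleiotropy). With
marginal GWAS estimates $\hat\beta_{GX}$ (protein) and $\hat\beta_{GY}$
(outcome) from non-overlapping samples, each instrument yields a Wald
ratio $\hat\theta_j = \hat\beta_{GY,j} / \hat\beta_{GX,j}$ with
first-order standard error $se_{GY,j}/|\hat\beta_{GX,j}|$. Multiple
instruments are pooled by inverse-variance weighting (IVW):

$$\hat\theta = \frac{\sum_j w_j \hat\theta_j}{\sum_j w_j},\qquad
  w_j = 1/se_j^2,\qquad se(\hat\theta) = 1/\sqrt{\textstyle\sum_j w_j}.$$

The multiplicative random-effects variant — the pipeline default, since
complex-trait analyses routinely show over-dispersion — scales the
standard error by $\sqrt{Q/(k-1)}$ whenever Cochran's
$Q=\sum_j w_j(\hat\theta_j-\hat\theta)^2$ exceeds its degrees of freedom,
and is otherwise identical to the fixed-effect fit. With a single
instrument both collapse exactly to the Wald ratio, a property the test
suite asserts at machine precision.

The first-order (delta) standard error ignores the sampling error of
$\hat\beta_{GX}$; this is standard practice for strong instruments and is
the reason the pipeline insists on an F-statistic filter (below). A
second-order option is deliberately not exposed: with the F > 10 gate the
correction is negligible relative to the outcome-side noise.

## Instrument selection

Candidate cis-pQTLs must clear, in order:

1. genome-wide significance, $p < 5\times10^{-8}$;
2. the cis window: within 1 Mb of the transcription start site of the
   protein-coding gene, on its chromosome (closed interval);
3. exclusion of the major histocompatibility complex (chr6 26–34 Mb,
   closed interval) whose extreme LD defeats both clumping and
   colocalization;
4. greedy LD clumping at $r^2 < 0.001$ within a 10,000 kb window
   (best p-value first; ties broken by chromosome, position, SNP id, so
   the output is invariant to input row order);
5. instrument strength $F > 10$, with
   $R^2 = 2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2$ and
   $F = R^2 (N-2)/(1-R^2)$.

$R^2$ is a variance fraction only when the trait is variance-standardized;
the configuration carries a `standardized_betas` flag and the pipeline
refuses to F-filter when it is false rather than silently producing
meaningless strengths. SNPs absent from the LD reference are treated as
unlinked but recorded, mirroring the practical situation where an external
LD panel does not cover every variant.

Harmonization aligns the outcome onto the exposure's effect allele,
negating effects and complementing frequencies for swapped records.
Palindromic SNPs (A/T, C/G) are dropped when either trait's effect-allele
frequency is within 0.08 of 0.5 — strand is then unknowable — and
otherwise oriented by which side of 0.5 the two frequencies fall on.
Indels are allowed but never treated as palindromic. Duplicate SNP ids
are a hard error, not a silent de-duplication: they signal an upstream
data fault. These palindrome conventions follow common two-sample MR
practice; published screens rarely document their choice, so the window
is a configuration parameter.

## Diagnostics

* **Heterogeneity.** Cochran's Q against the fixed-effect fit,
  $\chi^2_{k-1}$ reference; a small p-value suggests pleiotropy or
  invalid instruments, and triggers the random-effects standard error.
* **Directional pleiotropy.** The Egger intercept: weighted regression of
  outcome effects on exposure effects with a free intercept after
  orienting all exposure effects non-negative; the intercept t-test
  ($k-2$ df) detects a systematic pleiotropic shift. The unnamed
  "horizontal pleiotropy test" reported alongside heterogeneity in this
  workflow's literature is implemented as this intercept test.
* **MR-PRESSO-style outlier search.** The observed statistic is the
  weighted sum of squared leave-one-out residuals; its null distribution
  is built by parametric simulation (default 1000 draws, mandatory
  explicit seed — identical seeds give bit-identical p-values). Per-SNP
  outlier p-values use the same draws term by term with Bonferroni
  flagging. Monte-Carlo p-values use the add-one estimator
  $(1+\#\{\mathrm{sim}\ge\mathrm{obs}\})/(1+n_{\mathrm{sim}})$ so they
  are never exactly zero.
* **Steiger directionality.** Instruments should explain more variance in
  the exposure than in the outcome:
  $z = (\mathrm{atanh}\,r_X - \mathrm{atanh}\,r_Y)\big/
  \sqrt{1/(n_X-3)+1/(n_Y-3)}$ with $r$ the square root of the summed
  per-SNP $R^2$. Ties ($r_X = r_Y$) are resolved as *not* correct — the
  conservative choice, since a tie gives no evidence for the assumed
  direction.

## SMR and HEIDI

The SMR test asks whether the top cis-QTL's protein and outcome
associations are consistent with a shared signal:
$T_{\mathrm{SMR}} = z_{GX}^2 z_{GY}^2/(z_{GX}^2+z_{GY}^2) \sim \chi^2_1$.
$T$ is bounded by the smaller squared z-score, so SMR can never be more
significant than the weaker marginal association — asserted as a property
test.

HEIDI separates a single shared causal variant from LD-linked distinct
variants: comparison SNPs in intermediate LD with the top QTL
($0.05 < r^2 < 0.9$, exposure $p < 1.57\times10^{-3}$, at most 20 SNPs)
each give a ratio estimate $b_i$; under the shared-variant null the
deviations $d_i = b_i - b_{\mathrm{top}}$ are zero in expectation. Their
covariance follows from first-order delta propagation with LD-induced
z-score correlation on both traits, and
$T=\sum_i (d_i/sd(d_i))^2$ is referred to an eigenvalue-weighted
chi-square mixture. Fewer than three eligible SNPs yields a missing HEIDI
p-value, reported as `NA` and never counted as a failure — the situation
of a protein whose locus simply lacks linked secondary SNPs. The pass
threshold defaults to $p \ge 0.01$, the convention of the established SMR
software; screens often report HEIDI pass/fail without stating a cutoff,
so the threshold is configurable and logged.

The mixture tail probability is computed by Imhof's integral, integrated
chunkwise over a few oscillation periods at a time (a single adaptive
pass over a long range misses oscillation cancellation; the chunked sum
is accurate to about $10^{-4}$ against Monte-Carlo references). Equal
weights short-circuit to the exact scaled chi-square, and any integration
failure falls back to a Satterthwaite moment match.

## Bayesian colocalization

Under one-causal-variant-per-trait, each variant's evidence is a
Wakefield-style log approximate Bayes factor
$\tfrac12[\log(1-r) + r z^2]$, $r = sd_0^2/(sd_0^2+se^2)$; hypothesis
sums (H0 none, H1/H2 one trait, H3 two distinct variants, H4 one shared
variant) are accumulated in log space, with the H3 cross-product computed
as a log-space difference — never by naive subtraction of probabilities.
Priors default to $p_1=p_2=10^{-4}$, $p_{12}=10^{-5}$. Effect-prior
standard deviations are 0.15 for quantitative and 0.2 for binary traits —
the field's standard defaults — and both are surfaced in the
configuration and echoed to the run log, as is the coloc locus definition
(±500 kb around the lead cis-pQTL).

PPH4 > 0.8 is reported as *strong* evidence, but the tier rule passes a
locus at PPH4 > 0.6: in practice screens tier proteins with PPH4 well
below 0.8 as top-tier when PPH3+PPH4 is high (the single-causal-variant
assumption splits evidence between H3 and H4 at multi-signal loci), so
the operative threshold is ambiguous. Both thresholds are explicit
configuration fields, both are logged, and the PPH3+PPH4 column is
always reported alongside.

## Mediation

For a risk factor $R$, protein $M$ and outcome $Y$, three MR legs give
$\beta_1$ ($R\to M$), $\beta_2$ ($M\to Y$) and the total effect $c'$
($R \to Y$). The mediated effect is $\beta_1\beta_2$ with Sobel standard
error $\sqrt{\beta_2^2 se_1^2+\beta_1^2 se_2^2}$; the proportion mediated
$\beta_1\beta_2/c'$ gets a first-order delta interval treating the three
estimates as independent (three-term by default; a two-term variant
holding $c'$ fixed is available, and is the tighter of the two). The
independence assumption is exact only for non-overlapping samples; the
synthetic design satisfies it, real cohorts may not — a documented
limitation. A combination is *reliable* only when the Sobel p-value is
below 0.05, the mediated and total effects agree in sign, and the
total-effect leg shows no Egger pleiotropy ($p \ge 0.05$; an untestable
intercept, e.g. fewer than three instruments, counts as a pass because
absence of a test is not evidence of pleiotropy). Proportions are
reported as percentages.

## Evidence tiers

A deterministic function of six flags, property-tested over every
combination: no successful direction-consistent replication (unavailable
*or* failed) → Tier 3; replicated but failing any validation (SMR,
HEIDI, colocalization, reverse-MR null, Steiger) → Tier 2; replicated
and passing all → Tier 1. Treating a *failed* replication like a missing
one is a deliberate reading of "lacking replication evidence": the
published tier examples contain no replicated-but-failed case, and
placing such a protein in the weakest tier is the conservative option. A
replicated protein with a missing SMR flag is a pipeline bug and raises a
hard error rather than a tier.

## The synthetic generator

Genotypes are 0/1/2 dosages obtained by thresholding a latent Gaussian
AR(1) process (adjacent correlation $\rho$, default 0.8) at
Hardy–Weinberg genotype frequencies for per-SNP MAFs drawn from
(0.05, 0.45). Blocks are mutually independent and cycle across the
autosomes with chromosome 6 skipped, so synthetic loci never collide with
the MHC exclusion; the returned LD matrix is the empirical within-block
dosage correlation. Traits are built structurally (genetic component plus
scaled Gaussian noise to unit variance, error if the genetic variance
reaches 1), standardized, and summarized as per-SNP simple-regression
GWAS — which makes the $R^2$ formula above exactly applicable.

Scenario defaults are the study conditions: cohort sizes 50,000 per GWAS
at desk scale (the real resources are of order 54,219 for the discovery
pQTL panel, 619 for replication and 387,649 for the outcome; the
replication generator keeps 619, the others are scaled to minutes on one
CPU); 1% variance explained for a locus causal variant, 5% per cis-pQTL
in the study generator (cis effects on plasma proteins are large); causal
protein effect 0.2 SD per SD; mediation chain $\beta_1=0.2$ (0.3 in the
study generator), $\beta_2=0.3$, direct effect 0.14, so the true
proportion mediated is 30%; risk factors carry 10 independent
instruments, reflecting polygenic behavioural/anthropometric exposures.
The outcome is simulated quantitative throughout, matching a 0–7
pain-site count analyzed by linear regression; phenome-wide outcomes
carry case-count metadata for the >500-cases filter.

What the generator does **not** emulate — and hence what green tests do
not establish about real data: recombination-map LD (AR(1) blocks only),
sample overlap between cohorts, population stratification, imputation
noise, binary outcomes on the liability scale, and strand ambiguity (the
generator emits only non-palindromic alleles; palindrome handling is
tested on hand-built fixtures instead). Ground truth is written to a
separate `truth/` subdirectory and the scenario loader refuses to read
from it, so truth can never leak into analysis inputs.

For repeated-replicate calibrations (`calib_*`), genotype panels are
drawn once per calibration and phenotypic noise is redrawn per replicate:
each replicate's summary statistics are then an independent draw
conditional on one representative genotype realization, which keeps 2000
replicates at $n = 50{,}000$ within minutes without changing the sampling
distribution being calibrated. Calibration problem sizes (2000 null
replicates for IVW size, 500 for effect recovery, 1000 for HEIDI size at
$n=20{,}000$ with a 60-SNP locus, 200 mediation chains, 100 coloc and
Steiger replicates at $n=50{,}000$) were fixed as the package's study
conditions before results were inspected.

## Numerical conventions

* Confidence bounds use $z_{0.975}=1.959964$ throughout.
* p-values are floored at `1e-300` (GWAS) and `.Machine$double.xmin`
  (estimates) so they remain in $(0,1]$ and survive text round-trips.
* Log-sum-exp and log-difference arithmetic everywhere probabilities are
  combined; coloc posteriors sum to 1 within $10^{-10}$ by construction.
* LD matrices are validated on read: symmetry to $10^{-8}$, unit
  diagonal, $|r|\le 1$; asymmetric input is an error, not silently
  symmetrized.
* Clumping and instrument selection break all ties lexicographically, so
  every stage is reproducible and order-invariant; reports re-run under
  the same seed are byte-identical.

## Known limitations

Single-causal-variant colocalization (no SuSiE-style multi-signal
decomposition); no correlated-instrument IVW, weighted-median or mode
estimators; no trans-pQTL instruments; no binary-outcome liability
modelling in the main pipeline; the mediation interval assumes
independent legs; and the HEIDI pass threshold and coloc tier threshold
encode conventions, not estimated quantities — both are configuration,
not conclusions.
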