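---
title: "Models and methods behind magicmet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind magicmet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`magicmet` implements a complete analysis chain for multi-environment
trials (MET) of an 8-founder MAGIC population: spatial correction,
variance decomposition, phenotypic-plasticity estimation, QTL scans on
founder haplotype probabilities, and a two-step procedure for
QTL-by-environment interactions (QEI). This vignette explains each model,
its assumptions, the tunable parameters, and the design choices that were
genuinely open; it also states what the bundled synthetic generator does
and does not emulate.

## The synthetic MAGIC-MET generator

Every validation in the package runs on synthetic data with known ground
truth. The generator simulates, per line, its own 8-way funnel (four
2-way hybrids, two 4-way crosses, one 8-way cross) followed by three
generations of single-seed-descent selfing — the standard MAGIC design.
Meioses draw a Poisson number of crossovers with mean equal to the
chromosome length in Morgans and uniform positions (Haldane model, no
interference; the crossing scheme between the 8-way generation and
selfing is not standardised across MAGIC programmes, so the funnel depth
and the number of selfing generations are configurable rather than
asserted). Three selfings leave an expected residual heterozygosity of
$(1/2)^3 = 12.5\%$ per locus; because downstream mapping treats lines as
inbred, probabilities are emitted after sampling one homologue per line
and marker, giving the true founder probability $1-\varepsilon$ and every
other founder $\varepsilon/7$. Physical positions follow a linear
cM-to-bp map per chromosome; they matter only for interval reporting and
sweep intersection.

Phenotypes are generated at the replicate level as

$$y = \mu + E_j + \textstyle\sum_q x_{iq}\,
      (a_q + d_{qj} + s_q\,\mathrm{Cv}_j)
      + u_i + w_{ij} + r_{row} + p_{pos} + \epsilon,\qquad
  \epsilon \sim N(0, \sigma^2_{Rj}),$$

with founder-probability-weighted QTL contributions (main effects $a$,
per-environment deviations $d$, covariate sensitivities $s$ on the
z-scored covariate), a polygenic line effect $u_i$, a line-by-environment
deviation $w_{ij}$, and row/position effects shared by all plants in the
same greenhouse row or position. Control lines (parental/hybrid
stand-ins) carry fixed effects and no random line terms. The default
12-environment covariate table draws the seven climatic covariates
(minimal, maximal and mean temperature, thermal amplitude, sum of
degree-days, vapour-pressure deficit, relative humidity) from four
cluster centroids — a high-amplitude region, a temperate control group, a
mixed-stress group, and one extreme-heat environment — which produces the
strongly correlated covariates real greenhouses show (|r| up to ~0.99
between temperature summaries).

What the generator does **not** emulate: genotyping error at the SNP
level and the inference of founder probabilities (probabilities are
consumed as input), unbalanced line panels per environment, missing-data
patterns of real phenotyping, non-Gaussian traits, and linkage
disequilibrium between founders. Passing tests therefore demonstrate
correctness of the estimation machinery under the stated generative
model, not robustness to every artefact of real trials.

## Spatial correction

Within each environment the model
$y_{ijk} = \mu + C_i t_i + L_i (1 - t_i) + R_j + P_k + \epsilon_{ijk}$
is fitted by REML (lme4), with fixed control-line effects ($t_i$ flags
controls), a random MAGIC-line effect, and random row and position
effects. Row and position variances are tested by a likelihood-ratio test
against the reduced model; because the null value lies on the boundary of
the parameter space the statistic is referred to the mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. Where a component is significant
(default 5%), its BLUP is subtracted from the raw data; non-significant
environments pass through unchanged, and correction never changes the
number of records. Outliers are flagged beforehand by a robust z-score
(|value − median| > k × 1.4826 MAD within environment, k = 3.5 by
default); environments with fewer than five observations are left
unflagged with a warning. The outlier rule and the random (BLUP) reading
of the row/position effects are package choices — the source methodology
names neither a rule nor fixed-versus-random status, but "removing the
best linear unbiased prediction" implies random effects.

## Variance decomposition, prop.GxE, and heritability

The whole-design model adds fixed environment and control(-by-environment)
effects and random line and line-by-environment effects, with residuals
independent and *environment-specific*:
$\epsilon_{ij} \sim N(0, \sigma^2_{Ej})$. lme4 cannot estimate
heteroscedastic residuals and nlme cannot combine this fixed/random
control split with crossed terms, so the package fits the model with its
own REML engine: both random terms are nested within line, hence the
marginal covariance is block-diagonal by line and the REML log-likelihood
is assembled from small per-line blocks (one Cholesky per distinct block
structure per evaluation — balanced designs share a single pattern).
Optimisation is L-BFGS-B on log-variances, which keeps every component
non-negative; variances within a factor ~1e-9 of the scale are reported
as zero. Non-convergence triggers up to three restarts from perturbed
starting values.

From the fit, `prop_gxe` returns
$\sigma^2_{L\times E} / (\sigma^2_L + \sigma^2_{L\times E})$ and
`heritability` returns
$H^2 = \sigma^2_L / (\sigma^2_L + \sigma^2_{L\times E}/nb.E +
\bar\sigma^2_E/nb.R)$, where $nb.E$ is the number of environments,
$nb.R$ the mean replicate count over the whole design (non-integer
values allowed), and $\bar\sigma^2_E$ the mean of the per-environment
residual variances. The G-by-E likelihood-ratio test again uses the
boundary mixture. Parameter-recovery simulations (300 lines × 6
environments × 2 replicates, 100 replicates) recover every component
with relative bias well under 10%.

## Plasticity: joint regression and factorial regression

The environmental index is the mean performance of all lines observed in
an environment, centred across environments. The Finlay–Wilkinson model
is fitted in two steps — index first, then one OLS per line of its cell
means on the index — rather than as a joint bilinear fit; in the balanced
case the two coincide, and defining the index as the population mean
response implies the two-step reading. The intercept is the genotypic
mean, the coefficient the slope (population mean response plus
genotype-specific deviation; slopes average exactly 1 on balanced data),
and VAR is the residual variance with denominator $n-2$ (the residual
degrees of freedom of a two-parameter OLS; the source does not state the
denominator, nor whether residuals were re-centred). Lines observed in
fewer than 3 environments get the mean only.

Factorial regression replaces the index with one environmental
covariate: $y_{ij} = \mu + G_i + E_j + \alpha_i \mathrm{Cv}_j +
\epsilon_{ij}$. Covariates are z-scored across environments before
fitting so sensitivities are comparable between covariates (another
undocumented choice, made here once). The $\{\alpha_i\}$ carry a
sum-to-zero constraint — a shared sensitivity is absorbed by the
environment effects, so SCv is sensitivity *relative to the population
mean response*. Each covariate is tested singly; the F test compares the
sensitivity term against the additive two-way model, and its share of the
interaction sum of squares is SS(α·Cv)/SS(G×E) with SS(G×E) the residual
SS of the additive model. The winner is declared only at p ≤ 0.05. With
complete cells the OLS has a closed form (double-centred cell means
regressed on the centred covariate per line); incomplete cells fall back
to an explicit lm() fit — the two paths agree exactly on balanced data.
For scanning, VAR is log-transformed (zeros floored at a configurable
offset, default 1e-6) except for the fruit-set-style trait `fset`, which
uses a square root, matching its usual normalising transform.

A caution on covariate selection: when covariates are nearly collinear
across the handful of environments (the realistic default table), "the"
most impactful covariate is not statistically identifiable — several
covariates explain almost the same interaction SS. The package's
recovery experiment therefore draws its environments with independent
covariates; that is the identifiability condition of the experiment, not
a claim about real climates.

## QTL scans on founder probabilities

At each marker the phenotype is regressed on the eight founder
probability columns (Haley–Knott). Because probabilities sum to one, one
founder column is dropped during fitting (reference coding) and effects
are re-centred to sum to zero for reporting; a monomorphic marker is
flagged with LOD 0 and undefined effects. The score is
$\mathrm{LOD} = (n/2)\log_{10}(RSS_0/RSS_1)$; a perfect fit is reported
as +Inf in memory and capped at 1e4 with an infinity flag in serialized
output. Scans run at the markers (no between-marker grid). The
genome-wide threshold is $-\log_{10}(\alpha/\#\text{markers})$; peaks
are local maxima above it, two maxima are distinct QTLs only when the
profile dips at least 2 LOD below the lower of them (ties keep the
leftmost), and the confidence interval is the contiguous marker region
within 1 LOD of the peak, with endpoints at marker positions.

A known limitation, documented deliberately: this threshold rule
calibrates a statistic whose per-marker p-value is approximately
$10^{-\mathrm{LOD}}$, which holds for 1-df tests. The 8-founder scan is
a 7-df F test, whose null exceedance at such thresholds is two orders of
magnitude larger (about 0.02 per marker at 300 lines and a 3.6
threshold); genome-wide false-positive rates under the null are
therefore far above α for any non-trivial marker count. The package
implements the rule as specified — it is the field's practice for this
design — and quantifies the consequence in its calibration experiment
rather than silently altering the threshold. Where calibrated error
rates matter, the permutation-based QEI thresholds below are the model
to follow.

## The two-step QEI procedure

On line-by-environment cell means, the multi-environment marker model is

$$y_{ij} = \mu + E_j + \textstyle\sum_p \alpha_{p} x_{ip}
          + \textstyle\sum_p \beta_{pj} x_{ip} + G_i + \epsilon_{ij},
  \qquad \epsilon_{ij} \sim N(0, \sigma^2_{Rj}),$$

with a random genotype effect and per-environment residuals. The
variance components are estimated once under the no-marker null and held
fixed during scanning (a two-stage design; per-marker REML across
hundreds of markers and permutations would add nothing at this scale),
making each marker fit a generalised least-squares problem. The marker is
parametrised by its full per-environment founder effects; the main
effect (7 df), the interaction (7 × (nE−1) df) and the global effect
(7 × nE df) are Wald-F tests of contrasts of that block, with sum-to-zero
environment contrasts — testing a main effect in the presence of
interaction depends on the parametrisation, and the source does not state
one. Denominator degrees of freedom are the residual count of the GLS
fit. On complete cell means every line shares the same J × J covariance,
so all normal-equation blocks are Kronecker products of its inverse with
7 × 7 founder cross-products; per-marker factorisations are
permutation-invariant and cached, which is what makes genome-wide
permutation thresholds affordable. Lines with incomplete cell means are
dropped with a warning — a real-data analysis with systematic missingness
would need the general (slower) assembly.

Thresholds come from permutations that shuffle line identity between the
genotype tensor and the phenotypes, preserving each line's environment
profile and all phenotypic structure while breaking genotype-phenotype
linkage. Per permutation the maximum over markers of −log10 p is
recorded separately for the main, interaction and global statistics;
thresholds are the empirical 1−α quantiles (type 7). The forward pass
adds the most significant marker whose main *or* interaction component
exceeds its threshold, excludes markers within 10 cM (configurable) of a
selected cofactor, and repeats until none qualifies; the backward pass
fits all selected markers jointly and drops the weakest until all
remaining pass. Records are flagged as QEI **only** when the interaction
component passes — a main effect alone never produces a QEI. The global
pass then scans the joint parametrisation, conditioning on everything
already selected, to catch markers whose main and interaction components
are individually sub-threshold but jointly strong. The permutation
scheme and the per-statistic thresholds are package decisions; the
original procedure's permutation internals are not documented beyond the
count (1000; the package's experiments use 200 at desk scale: 100-120
markers, 4 environments, 120-200 lines, sizes chosen to keep the
200-replicate calibration practical on one core).

## Integration

Environments are clustered by Ward linkage (`ward.D2`) on Euclidean
distances of z-scored covariates, with constant covariates dropped. QTLs
of the same trait co-localize when their physical confidence intervals
intersect on the same chromosome; co-localization is closed transitively
(connected components), each unique QTL labelled by the union of its
members' category tags — the closure rule and any-overlap criterion are
documented package choices. Chromosome enrichment of plasticity QTLs is
a chi-square test against expectations proportional to marker counts per
chromosome (physical-length weighting available). Allelic-effect
concordance between two peaks is the Spearman rank correlation of their
8-founder effect vectors with an exact permutation p-value enumerated
over all 8! orderings (mid-ranks for ties). Sweep intersection reads BED
intervals (0-based half-open, converted to 1-based inclusive), keeps
QTLs with CI narrower than 2 Mbp plus all QEI entries, and reports
any-overlap per sweep label.

## Numerical choices and degenerate inputs

Probability slices must sum to 1 within 1e-6 (the generator achieves
1e-12); zero-length chromosomes, empty marker lists, single-row
environments, constant phenotypes, and constant covariates all follow
explicit contracts (no recombination, empty tensors, dropped terms, zero
LOD, skipped covariates) rather than erroring. REML convergence is
controlled by `factr = 1e4` in L-BFGS-B on log-variances; boundary
variances are floored to zero only for reporting. The REML engine's
restart policy and the scan's rank-deficiency flagging are exercised in
the test suite.
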