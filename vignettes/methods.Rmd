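---
title: "Models and methods behind qtlscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qtlscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qtlscape)
```

`qtlscape` analyses multi-site, multi-year field trials of a four-way
outbred mapping population: the progeny of two F1 hybrids, (A×B) × (C×D),
in which every individual carries one recombinant A/B haplotype and one
recombinant C/D haplotype. Genotype calls are phase-known grandparent pairs
(AC, AD, BC, BD), the situation produced by k-mer based genotyping that can
distinguish all four grandparents. This vignette explains the models, the
defaults and the numerical choices, and what the synthetic-data tests do and
do not establish about real data.

## The synthetic study

The generator's defaults emulate the trial design the package targets: 425
recombinant progeny cloned into 10 sites spanning roughly 17 degrees of
latitude, phenotyped for two years (environments are site-by-year
combinations). Meioses are simulated with no crossover interference, so the
Haldane map function `d = -50 log(1 - 2r)` links distances and
recombination fractions exactly; the same function is used when map
positions are estimated (Kosambi is available behind a flag, but simulation
and estimation always default to the same model). Genotyping noise is
independent per cell: a missingness Bernoulli (default 10%) and a
uniform-swap error Bernoulli (default 1%), emulating raw-call noise
upstream; there is no read-depth model because alignment and calling are
out of scope.

Two genome-shape choices deserve explanation:

* **Chromosome length, 21 cM.** Linkage groups are formed by the literal
  rule that *every* pairwise recombination fraction within a group must be
  below 0.25 (complete-linkage agglomeration). That rule caps the
  recoverable chromosome span at `haldane_cm(0.25) = 34.66` cM: a longer
  chromosome necessarily splits. At 21 cM the largest true
  within-chromosome `r` is 0.171, about 4.8 sampling standard deviations
  below the threshold at 850 meioses, so chromosomes essentially never
  split by chance. Real chromosomes are longer; on real data one would
  raise the threshold or group by chained linkage. The complete-linkage
  reading is kept because it is the stated rule.
* **Map-length tolerance is assessed on the whole map.** With 850 meioses
  on a 21-cM chromosome the *realized* crossover count is roughly
  Poisson(178), so the realized genetic length of any one chromosome varies
  with ~7.5% SD around its design value no matter how well it is estimated.
  Summed over chromosomes the SD drops to ~5%, which is why the package's
  recovery checks compare total map length (tolerance 15%) and require
  exact marker order (|Kendall tau| = 1) per group.

Weather is sinusoidal-seasonal with a mean annual temperature of
`47.2 - 0.97 * latitude` degrees C (about 16 degrees of change across the
transect, matching the scale of variation such a latitudinal design spans),
`tmax >= tmin` by construction, and phenology linear in latitude (green-up
`30 + 3.5 (lat - 27)`, flowering `180 + 2.5 (lat - 27)` Julian days). These
are idealisations: real weather has spatial autocorrelation beyond
latitude, drought years, and phenology responds to weather rather than to
latitude per se. Passing tests therefore demonstrate that the machinery
recovers planted structure, not that the models are adequate for any
particular real landscape.

## Map construction

Raw markers are filtered (missingness > 60% dropped), then binned: blocks
of 50 consecutive markers per chromosome collapse to the modal non-missing
call per progeny. A tie for the mode, or an all-missing block, yields a
missing call — the conservative reading when majority voting is
underdetermined. The windows are non-overlapping by default (a 50-fold
reduction of the matrix); an overlap step is configurable.

Pairwise recombination fractions exploit phase: each doubly observed
progeny contributes two scored meioses (an A/B and a C/D switch). Ordering
within a linkage group minimises the sum of adjacent recombination
fractions — an open travelling-salesman path — by greedy double-ended
construction plus 2-opt, then ripple polishing (window 4, all
permutations, sweeps to a fixed point, monotone in cost). On groups of up
to 8 markers the heuristic provably matches brute force in the test suite.
Runs of markers with identical call vectors (pairwise r = 0) carry no
ordering information whatsoever; they are ordered by physical position,
which is how binned maps are anchored in practice. Orientation is
canonicalised (lexicographically smaller end first).

## The multi-environment QTL model

Phenotypes are first averaged to one value per genotype × site × year, and
outliers culled against the model `value ~ line + site + line:site` fitted
across years (the full interaction makes fitted values the cell means;
externally studentized residuals with Bonferroni-corrected two-sided P <
0.05 are dropped). With a single year the model is saturated and culling is
skipped with a warning — the residual degrees of freedom come entirely
from year replication.

The baseline model is `trait = mu + E + g + g×E + e`. After averaging,
genotype main effects and genotype-by-environment deviations are absorbed
into a single environments × environments covariance of each genotype's
record vector. REML closed forms exist for the identity, diagonal and
unstructured candidates, and compound symmetry is profiled numerically; the
lowest BIC (penalty `k log n_genotypes`) wins. The scan then holds this
covariance fixed — standard multi-environment trial practice; covariance
re-estimation per position is disproportionately costly and changes little.

QTL predictors use ±0.5 coding: `x_a = +0.5` for the A allele (first
cross), `x_a2 = +0.5` for C (second cross), `x_d = 2 x_a x_a2`. An
estimated additive effect therefore equals the full allele-substitution
difference. Missing calls and grid pseudopositions take conditional
expectations given the nearest non-missing flanking markers under Haldane
transition probabilities (the two meioses are independent, so the dominance
expectation is the product).

Because every environment shares the same genotype design, generalized
least squares at one position reduces to per-environment least squares;
the covariance enters through the joint Wald statistic
`W = tr(C_qq^-1 B Sigma^-1 B')`. Since `Sigma` is estimated rather than
known, `W` is deflated by `(n - E - 2)/(n - 1)`, the factor that undoes the
mean bias of an inverted Wishart sample covariance. Without this correction
the genome-wide false-positive rate measurably exceeds its nominal level at
`n = 425, E = 10`; with it, null simulations run at or below nominal. The
same correction applies to the term-group tests of the final model.

Genome-wide significance divides alpha = 0.05 by the effective number of
tests, computed from the eigenvalues `lambda` of the position-by-position
predictor correlation matrix as `sum(I(lambda >= 1) + (lambda -
floor(lambda)))`. The correlation between positions averages the
first-cross and second-cross additive predictor correlations; the two decay
identically with linkage distance, and dominance contributes no additional
independent dimension at the resolution of this correction.

Composite interval mapping selects peaks greedily by significance (ties to
the lower position) subject to 30 cM minimum separation, then re-tests every
position with all cofactors at least 50 cM away (any distance on other
groups) included as full per-environment fixed terms, three rounds,
reporting whether the selection stabilised. The final model fits all
selected QTL with per-parent additive and dominance main effects plus
QTL × environment interactions, re-estimates the covariance once from
full-model residuals, and backward-eliminates the least significant term
group with P >= 0.05 — never removing a main effect while its interaction
remains. A QTL's G×E flag is simply whether any of its interaction groups
survived.

## Heritability and genetic correlations

The additive relationship matrix is `K = W W'` from the column-centred
(x_a, x_a2) scores, scaled to mean diagonal 1; missing scores are centred
to zero (mean imputation), constant markers dropped. Heritability uses the
standard one-parameter REML profile on the eigenbasis of K
(`y = mu + u + e`, `u ~ N(0, K sigma_A^2)`), with
`h^2 = sigma_A^2 / (sigma_A^2 + sigma_e^2)` — additive over total variance
on the genotype-mean scale, the operational scale after replicate
averaging. Per-environment and pooled modes are both provided since either
reading is defensible. Genetic correlations between two environments come
from a bivariate REML likelihood on the same eigenbasis, optimised over
`(sigma_A1^2, sigma_A2^2, atanh r_G, sigma_e1^2, sigma_e2^2)` — the
hyperbolic-tangent reparameterisation keeps the genetic covariance matrix
positive-definite throughout. Near-zero genetic variance in either trait
makes `r_G` undefined and is flagged rather than reported.

## Climate envelopes

Daily weather is aggregated to monthly station means of tmin, tmax and
precipitation before the first PCA — interpolating monthly statistics is
what a landscape analysis does with station networks, and daily-resolution
PCA across stations mostly re-learns the calendar. Growing seasons are
predicted from best-subsets (exhaustive, BIC, at most 4 terms, ties to the
smaller subset) regressions of green-up and flowering dates on the PC
scores, padded 14 days on each side; inverted windows are flagged and
excluded.

The 21 interval statistics split the season into three equal thirds, each
padded 5 days on both ends — one defensible reading of "equal-length,
5-day-overlapping intervals"; a shift-based reading is configurable. Per
interval: 95th-quantile tmax, 5th-quantile tmin, mean precipitation, and
hottest/coldest 14-day rolling mean temperatures and driest/wettest 14-day
rolling precipitation sums, complete windows only (an interval shorter than
14 days is an error, and seasons must span at least 42 days). Missing
station statistics are k = 5 nearest-neighbour imputed on standardized
shared columns. The envelope PCA retains leading axes that each explain
more than 5% of variance, capped at five.

Spatial interpolation is inverse-distance weighting with haversine
distances and power 2 (the conventional default; the source of station
values does not justify anything more elaborate), exact at station
locations, restricted to the convex hull of the field sites buffered by
200 km.

## Effect surfaces and trade-offs

Each QTL × cross-direction effect series (one estimate and SE per site) is
meta-regressed on each climate axis with fixed-effect weights `1/SE^2`; the
axis with the smallest slope P (Wald z) is retained. A residual
heterogeneity variant is deliberately omitted from the default: with ten
sites the heterogeneity variance is barely estimable, and the fixed-effect
fit is the transparent baseline. The family of chosen-axis P values is
Benjamini–Hochberg adjusted and gated at 0.05/5 — FDR adjustment *and* the
divisor, exactly as specified upstream, even though combining them is
unusually conservative.

Prediction surfaces apply the fitted line to every station's scores,
rasterize by IDW over the buffered hull, and mask cells whose prediction
leaves the envelope `[min(observed) - 2 max(SE), max(observed) + 2
max(SE)]`. "Two SEs of the distribution of observed effects" admits
several readings (per-site SE, SD of effects); max-SE padding is the
default because it is the most conservative of the point-wise readings,
and the alternatives are options.

Trade-off summaries first zero effects within 2 SE of zero (effects whose
model terms were dropped count as zero), then orient each series so its
largest-magnitude effect is positive. `best` is the maximum effect and
`worst` the absolute effect at the worst-performing site; `benefit`/`cost`
are the sums of positive and negative parts. A conditionally neutral allele
thus shows `worst = 0`, an antagonistically pleiotropic one `worst > 0`.
Cross-direction concordance calls an effect significant when it is at least
2 SD from the mean of the pooled effect distribution of its contrast (the
reference distribution is not otherwise specified) and tests same-sign
proportions with the exact binomial test. Survival contrasts report the
plain odds ratio `(alive1/dead1)/(alive2/dead2)` (Haldane–Anscombe 0.5
correction on zero cells) with Fisher's exact P.

The optimal-genotype summary keeps per-site effects beyond 2 SE of zero and
credits `|estimate|` to the lowland pool when the trait-increasing allele
is lowland (positive estimates under the coding: A or C) and to the upland
pool otherwise, reporting both sums and the lowland percentage.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages on synthetic data and writes every
stage's tables as CSV plus a manifest (config hash, per-stage seeds derived
deterministically from the root seed, md5 of every output). The same config
and seed give byte-identical files. The default demo is deliberately small
(200 progeny, 2 × 30 bins of 20 raw markers, 8 sites × 2 years, 23 weather
stations); the test suite exercises the full 425-progeny, 10-environment
design where the statistical claims are made: map recovery at 2 × 100 bins
of 50 raw markers, 200 null scans for the type-I rate, 100 simulations each
for power, coverage and G×E classification, 50 for heritability, and 200
for meta-regression coverage. These sizes make the whole suite run in a few
minutes while leaving the binomial uncertainty of each rate comfortably
inside its asserted band.

## Known limitations

* No crossover interference, no sex-specific maps, no segregation
  distortion; binning assumes correct physical marker order.
* The scan treats genotype effects through marker predictors with an
  environment-structured residual; a full per-genotype random effect is
  not fitted during scanning (it is absorbed by the covariance), which is
  standard for multi-environment scans but not identical to a one-stage
  mixed model.
* Complete-case handling across environments in the scan; heavily
  unbalanced phenotype tables should be analysed per subset.
* Fixed-effect meta-regression ignores residual heterogeneity beyond the
  per-site SEs.
* The climate generator has no spatial structure beyond latitude, so IDW
  and hull masking are exercised geometrically, not meteorologically.
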