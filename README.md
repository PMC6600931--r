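# qtlscape

Multi-environment QTL mapping and climate effect surfaces for four-way
outbred crosses.

## The problem

Locally adapted plant populations — such as northern upland and southern
lowland switchgrass (*Panicum virgatum*) ecotypes — differ at many loci whose
effects depend on the environment. Multi-site common-garden trials of a
four-way outbred mapping population, an (A×B) × (C×D) intercross in which
every progeny carries one recombinant A/B haplotype and one recombinant C/D
haplotype, make it possible to ask where each allele helps, where it hurts,
and how its effect tracks climate. `qtlscape` provides the full analysis
chain for such trials, for quantitative geneticists and breeders working
with outbred crosses phenotyped across environments:

1. **Linkage-map construction** from noisy phase-known grandparent-pair
   calls (AC/AD/BC/BD): missingness filtering, 50-marker consensus binning,
   complete-linkage grouping at pairwise recombination fraction r < 0.25,
   travelling-salesman-style marker ordering (greedy + 2-opt, with a
   brute-force-verified optimum on small groups), ripple polishing, and
   Haldane map distances.
2. **Multi-environment QTL mapping.** The phenotype model is
   `trait = mu + E + g + g×E + e` with an REML-selected residual covariance
   across environments (identity / diagonal / compound-symmetric /
   unstructured by BIC). Scans test per-parent additive contrasts
   (`alpha_a` for A vs B, `alpha_a2` for C vs D, coded ±0.5) and dominance
   (`alpha_d`) plus their environment interactions by generalized least
   squares; genome-wide significance uses a Bonferroni threshold on the
   effective number of independent tests (eigenvalue-based). Composite
   interval mapping re-scans with cofactors (30 cM peak separation, 50 cM
   cofactor proximity, three rounds), and a backward-selected final model
   `trait = mu + E + ΣQTL + Σ(QTL×E) + e` yields per-environment effects
   with standard errors and a G×E flag per QTL.
3. **Quantitative genetics.** Marker-based additive kinship, REML
   narrow-sense heritability `h² = σ²_A / (σ²_A + σ²_e)`, and bivariate
   REML genetic correlations of a trait between environments.
4. **Climate envelopes.** Growing seasons predicted per weather station from
   best-subsets (BIC) phenology models on weather principal components; 21
   growing-season interval statistics (7 statistics × 3 overlapping
   thirds); k = 5 nearest-neighbour imputation; envelope PCA retaining
   axes that each explain > 5% of variance.
5. **Effect surfaces.** Standard-error-weighted meta-regression of each
   QTL × cross-contrast effect on the climate axes, Benjamini–Hochberg
   gating at 0.05/5, inverse-distance-weighted rasters over a 200-km
   buffered convex hull of the field sites, masked outside the observed
   effect envelope.
6. **Trade-off statistics.** Best-site vs worst-site allelic effects,
   benefit/cost sums (antagonistic pleiotropy vs conditional neutrality),
   cross-direction concordance (exact binomial test), survival contrasts
   (odds ratio + Fisher exact test), and per-site optimal-genotype
   summaries pooling lowland (A, C) vs upland (B, D) allele contributions.

A first-class synthetic-data module simulates all of it with known truth —
four-way meioses without crossover interference, genotyping error and
missingness, environment-correlated residuals, QTL with constant,
sign-changing or conditionally neutral effects, and station weather along a
latitudinal gradient — so every stage is testable without any downloads.

## A worked example

```r
library(qtlscape)

# a 425-progeny cross: 2 chromosomes x 2,000 raw markers, 10 sites, one year
design <- cross_design(425, tibble::tibble(chrom = c("chr1", "chr2"),
                                           length_cM = 21, n_markers = 2000))
truth  <- sim_fourway_genotypes(design, seed = 1)
env    <- demo_env_design(n_sites = 10, years = 2016)
qtls   <- true_qtl("Q1", "chr1", 10, env$envs$env, a = 0.5)   # constant 0.5-SD QTL
pheno  <- sim_phenotypes(truth, qtls, env, seed = 2)

# corrupt the calls, then rebuild the linkage map from scratch
raw  <- corrupt_genotypes(truth, missing_rate = 0.10, error_rate = 0.01, seed = 3)
lmap <- build_linkage_map(raw, window_size = 50)
lmap
#> <linkage_map> 2 linkage group(s)
#>   linkage_group n_markers length_cM
#> 1             1        40      22.5
#> 2             2        40      22.4

# scan under the BIC-selected covariance
preds    <- encode_predictors(lmap$geno, map = lmap$map)
baseline <- select_covariance(pheno)
thr      <- effective_tests(preds)
cim      <- cim_scan(pheno, preds, baseline, thr$threshold)
cim$qtl[, c("pos", "chrom", "cM", "neglog10p")]
#> # A tibble: 1 × 4
#>   pos         chrom    cM neglog10p
#> 1 chr1_bin012 LG1    7.12      7.00

fit <- fit_final_model(pheno, preds, cim$qtl$pos, baseline)
dplyr::filter(tidy(fit), term == "a", env == "S01:2016")
#> # A tibble: 1 × 8
#>   qtl         env      term  estimate     se p_gxe gxe   retained
#> 1 chr1_bin012 S01:2016 a        0.483 0.0526    NA FALSE TRUE
```

Both 21-cM chromosomes are recovered as single linkage groups in correct
order. The scan profile is a plateau across the bins flanking the planted
QTL (the bin at 11.4 cM ties the selected peak to the seventh decimal of
the P value — localization of a 0.5-SD effect is genuinely flat at this
density), the backward selection drops the absent QTL×environment
interaction, and the A-vs-B substitution effect (truth 0.5) is estimated as
0.483 with standard error 0.053.
`autoplot(cim$profile)`, `autoplot(fit)` and `plot_tradeoffs()`
draw the scan, the reaction norms and the trade-off scatter; the full chain
(including climate envelopes and effect surfaces) runs via

```r
res <- run_pipeline(pipeline_config(seed = 1), outdir = "run1")
```

which writes every stage's tables and a manifest with per-stage seeds and
md5 checksums (identical seed, identical bytes).

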