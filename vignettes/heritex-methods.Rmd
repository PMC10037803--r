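---
title: "Models and methods behind heritex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heritex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heritex)
```

heritex analyses heritable transcriptomic variation in structured panels of
inbred lines: maize diversity panels are the motivating case, but nothing in
the code is species-specific. This vignette explains the statistical models,
the tunable parameters and their defaults, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## The data model

Three S4 containers carry the data. `GenotypeData` holds a samples x markers
alt-allele dosage matrix (values 0/1/2 or `NA`) with 1-based marker
coordinates and optional subpopulation labels; inbred lines are expected to
be essentially homozygous, and every estimator that treats lines as haploid
allele samples (Fst, pi, XP-CLR) excludes residual heterozygous calls.
`ExpressionData` couples a nonnegative samples x genes FPKM matrix to a
replicate map (sample to genotype); replication is what makes broad-sense
heritability estimable. `SpliceQuant` stores per-intron junction read counts
(`ucount`) and summed per-base intronic depth (`depth`); percent-spliced-in
is the derived quantity `PSI = ucount / (depth / size)`, missing exactly
when depth is zero. PSI is deliberately not capped at 1: the ratio can
exceed 1 by construction and downstream code never assumes an upper bound.

## Broad-sense heritability

Expression heritability is estimated per gene from the one-way
random-intercept model \(y_{ij} = \mu + u_i + e_{ij}\), with genotype
\(u_i \sim N(0, \sigma^2_G)\) and residual \(e_{ij} \sim N(0, \sigma^2_E)\),
and \(H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_E)\). The fit is restricted
maximum likelihood: for this model class the REML criterion can be profiled
down to a single variance-ratio parameter with everything else in closed
form, so `estimateH2()` optimizes one scalar and is exact and fast even for
unbalanced replicate counts. `lme4::lmer` and a method-of-moments ANOVA
estimator serve as independent oracles in the test suite; agreement is at
the 1e-4 level. Only genotypes with at least two replicates contribute.
Variance components are nonnegative by the boundary of the profile search,
so \(H^2 \in [0, 1]\) and is invariant under affine transformation of the
trait. FPKM values are log-transformed before fitting (`estimateH2Matrix`),
matching the lognormal noise model below.

Subpopulation comparisons (`compareSubpopH2`) estimate \(H^2\) separately
per subpopulation and flag genes whose estimate in the second population
falls below \(1 - 0.80 = 20\%\) of the first's; a softer 20%-reduction flag
is also reported because downstream sweep-overlap analyses use the milder
criterion. Distribution shifts across functional gene sets
(`goHeritabilityShift`) use a two-sample Kolmogorov-Smirnov test per term
(size bounds 25-499), Benjamini-Hochberg correction, and an additional
requirement that the term median differ from the background median by at
least 20% *relative to the background median* — the relative reading is a
design choice, stated here because an absolute reading would make the
criterion scale-dependent.

## QTL mapping

E-traits are per-genotype replicate means, Box-Cox transformed. The Box-Cox
lambda is chosen by profile likelihood on the grid \([-2, 2]\) in steps of
0.01 (the `lambda = 0` branch is the log), with an automatic shift when
values are nonpositive; output is standardized, which changes nothing
downstream since the association tests are affine-invariant.

`lmScan()` fits, per marker, OLS of the trait on dosage plus covariates
(five genotype principal components by default) and tests the dosage
coefficient two-sided. The implementation residualizes trait and dosages
against the covariates once (Frisch-Waugh) so a full scan is a handful of
matrix products; markers with missing calls fall back to per-marker fits on
pairwise-complete observations (at least 20). `lmmScan()` adds a single
random effect with covariance proportional to a kinship matrix, estimating
the variance ratio once per trait under the null via the spectral
decomposition of the kinship, then applying whitened (GLS) Wald tests per
marker — the standard two-step mixed-model GWAS approximation. Kinship is
the centered cross-product \(ZZ'/m\), and PCs come from the SVD of the same
centered matrix; missing dosages are mean-imputed inside these two
computations only.

Significant markers are consolidated by `groupPeaks()`: consecutive
significant SNPs closer than 1 Mb merge into a peak, peaks need at least 3
supporting SNPs, and the smallest-p member (ties: smaller position) is the
lead. A peak is *cis* for a gene when its lead lies within 1 Mb of the gene
span; when several peaks of one trait fall in the cis window only the
strongest keeps the label, so a trait has at most one cis-QTL. In-sample
variance explained (`computePve`) is reported with the explicit caveat that
it is upwardly biased. Traits with more than 10 peaks are excluded as
likely artefacts. sQTL mapping reuses the same machinery on PSI values
(untransformed) with an additional absolute effect-size floor of 0.05 per
alt allele, read as a magnitude criterion.

The genome-wide threshold is Bonferroni \(\alpha / M\) by default
(\(0.05 / 12{,}191{,}984 = 4.1\times 10^{-9}\), i.e. \(10^{-8.39}\), for
the motivating panel). `permutationThreshold()` provides the empirical
alternative: genotype sample labels are shuffled (trait and covariates
fixed), per-trait minimum p-values are pooled over traits and permutations,
and the threshold is the 95th percentile of their \(-\log_{10}\)
distribution. The default of 100 permutations is a compromise the test
suite validates against the closed form \(1 - (1 - t)^M\) available for
independent markers.

## Colocalization and splicing-expression coupling

Colocalization of a gene's cis-eQTL and cis-sQTL is assessed purely through
LD of the two lead SNPs: \(r^2 \ge 0.6\) counts as colocalized. No
posterior-based colocalization is attempted — the LD criterion is the
method being reimplemented. Expression-PSI coupling uses Spearman rank
correlation across genotype means (robust to the bounded-ratio character of
PSI; Pearson is available via the `method` argument), BH-corrected at
FDR < 0.05, and the imbalance between positive and negative couplings is
tested with a one-degree-of-freedom chi-square against equal proportions.

## ICA co-expression modules

Genes with \(H^2 > 0.05\) and expression SD > 1 enter the decomposition.
The component count is the smallest k whose top singular values carry 80%
of the variance of the per-gene-standardized matrix. The decomposition is
whitened fixed-point ICA with the logcosh contrast and symmetric
orthogonalization, implemented in the package (`runIca`); it is
deterministic under a seed, signs are fixed so each component's
largest-magnitude gene loading is positive, and non-convergence of the
iteration is flagged. Components are retained only if (a) 2-means
clustering of the per-sample coefficients yields two clusters of more than
10 samples each — rejecting components driven by a handful of outlier
samples — and (b) coefficient kurtosis exceeds 6. Kurtosis here is the
plain fourth standardized moment (Gaussian = 3), so 6 is a strong
non-Gaussianity filter; the definition is stated because "kurtosis > 6"
is ambiguous between raw and excess conventions, and the threshold is
configurable. Module membership standardizes gene loadings robustly
(median/MAD) and takes genes at BH FDR <= 0.01; 0.001 yields a stricter
core set, and both thresholds are exposed because the choice between them
is genuinely open. Component coefficients are collapsed to genotype BLUPs
(shrunken means from the same random-intercept machinery) and mapped by
GWAS; module-peak coupling is a one-sided Fisher test of membership
against peak e-trait status at a relaxed \(10^{-5}\) threshold, significant
at p <= 0.01. ICA is run on the per-gene standardized matrix — whether to
standardize was an open choice; standardization prevents high-variance
genes from dominating the whitening.

## Selective-sweep scan

Two-population differentiation is scanned in 100-kb windows stepped by
10 kb. Per-site Weir-Cockerham variance components treat inbred lines as
haploid allele samples (the two chromosomes of a fully inbred line are not
independent draws); windows aggregate by ratio of sums, the estimator with
better small-sample behaviour than averaging per-site ratios. Nucleotide
diversity is the unbiased per-site heterozygosity \(2\hat p(1-\hat p)
n/(n-1)\) summed over SNPs and divided by window length; absolute levels
underestimate sequence diversity because monomorphic sites are not
ascertained, but the tropical/temperate *ratio* used for QC shares the
convention in numerator and denominator.

XP-CLR follows the cross-population composite-likelihood model: the
object population's allele count at a site is binomial around a frequency
\(p_2\) that drifted from the observed reference frequency \(p_1\) with
neutral variance \(\omega\, p_1 (1 - p_1)\), where \(\omega\) is estimated
once genome-wide by method of moments. Under the sweep alternative a site
at recombination distance r from the swept locus escapes hitchhiking with
probability \(c = 1 - \exp(-\log(2N_e)\, r / s)\), and the effective drift
variance is inflated to (neutral variance)/c — the c -> 1 limit is exactly
the neutral model, and the selection grid explicitly contains that neutral
member, so the reported \(\mathrm{CLR} = 2(\max_s \ell_s - \ell_0)\) is
nonnegative by construction. Gaussian mass outside (0,1) is collapsed onto
point masses at the boundaries, where the binomial likelihood is evaluated
exactly; the interior integral is composite Simpson quadrature (600
intervals by default), verified in the tests against a 40,000-interval
oracle at the 1e-6 level. Sites in pairwise dosage correlation above 0.95
are down-weighted by group size; up to 100 sites within 0.0005 Morgans of
each grid point contribute. Genetic positions come from piecewise-linear
interpolation of a genetic map, with nearest-rate extrapolation flagged
beyond the anchors. Windows in the top decile of both window Fst and
window-averaged CLR, passing the pi-ratio QC (ratio at or above the
genome-wide mean), are highly differentiated; sweep candidate genes must
lie *entirely* within such windows for both statistics. The decile flag is
assigned by rank, so exactly \(\lceil 0.1 n \rceil\) windows carry each
flag regardless of ties.

## The synthetic-data generator

The generator exists so that every stage can be exercised end-to-end
against known truth. It emulates: two subpopulations of fully inbred lines
with Balding-Nichols allele-frequency divergence (dosages in {0, 2}, no
heterozygous calls); local LD through 50-kb haplotype blocks in which
markers copy a latent block allele with a 1.5% error rate (within-block
\(r^2 \approx 0.85\), blocks independent); planted cis effects calibrated
so that OLS of genotype-mean expression on the causal marker has the
stated expected R-squared (the copy-error noise attenuates realized
genome-wide Fst slightly below the nominal F, by roughly \((1-2
\epsilon)^2\), still within the calibration tolerance the tests assert);
lognormal expression noise partitioned so the
genotype-level variance fraction equals the target \(H^2\); co-expression
modules as a shared spiky factor driven by a low-frequency (MAF
0.05-0.085) marker, which makes the module's sample coefficients strongly
leptokurtic, as the kurtosis filter expects of a genotype-driven module;
Poisson junction/coverage counts whose expected PSI equals the
genotype-dependent target; planted 100-kb sweep windows with the swept
population pushed toward fixation (which also depresses its diversity, as
a real sweep would); and positive organismal traits as exponentiated
linear predictors. Local LD is not optional decoration: the multi-SNP
peak-support rule and LD-proxy criteria are unsatisfiable with independent
markers, so a generator without LD would test nothing. Planted cis markers
are restricted to blocks carrying at least three common markers
(`plantableCisMarkers`), because at desk-scale marker density an effect in
a one-marker block is undetectable under the three-SNP support rule — the
real panels these methods target are dense enough that every variant is
tagged many times over.

The generator does *not* emulate: read-level sequencing noise,
reference-bias or mapping artefacts, indels or multi-allelic sites,
genotype-by-environment interaction, LD between blocks or long-range
admixture LD, realistic gene-length and expression-level distributions, or
GO-term correlation structure. Passing tests therefore demonstrate
correctness of the estimators under the stated statistical model, not
robustness to every artefact of real RNA-seq data.

Default study conditions ("small" fixture): 200 genotypes x 2 replicates,
5,000 markers on 5 x 10-Mb chromosomes, equal subpopulation split at
F = 0.1, MAF floor 0.05, 2,000 genes (50 with planted cis-PVE 0.4, target
H-squared 0.8), 3 modules of 40 genes, 500 introns (25 with a 0.3 PSI
shift), one 100-kb sweep window at frequency gap 0.9. These sizes keep a
full pipeline run within minutes on one CPU while leaving each criterion
statistically meaningful; the acceptance checks use 300 genotypes for eQTL
recovery, 200 x 3 for heritability recovery, 10,000 markers for Fst
calibration, and 20 seeded 1,500-marker fixtures for sweep recovery —
problem sizes chosen as the package's own desk-scale study design.

## Numerical choices and degenerate inputs

Zero-variance markers are skipped in scans (`NA` results) and excluded from
kinship/PCs; constant traits error in `boxcoxTransform` and flag
`H2 = 0` in `estimateH2`. Peak-grouping ties (equal p) resolve to the
smaller position. `ldR2` uses pairwise-complete observations and returns
`NA` with a warning for zero-variance markers. Missing PSI values are
excluded pairwise, never imputed. The XP-CLR escape probability is clamped
to \([10^{-4}, 1]\) to keep variances finite at r = 0; the time-scale
constant uses \(N_e = 1000\) by default and is exposed as `log2N`.
Window-decile flags are rank-based; `qc_pass` uses the genome-wide mean of
the pi ratio. Seeds: every stochastic function takes an explicit seed or
inherits the session RNG; `simConfig(seed)` pins an entire fixture, and
`runPipeline` derives all stage seeds from the single config seed, which
is why reruns are byte-identical.

## Known limitations

In-sample PVE is biased upward; the permutation threshold pools across
genes rather than per-gene; the LD-based colocalization cannot distinguish
a shared causal variant from tight linkage of two variants; the XP-CLR
implementation pins the published model class but not the exact internal
boundary handling of the original tool, so absolute scores should not be
compared across implementations (decile ranks are); and GO annotations are
taken as given, with no ancestor propagation.
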