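---
title: "Quantifying the efficacy of selection in a selfing plant genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the efficacy of selection in a selfing plant genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

selscape implements a complete analysis chain for asking how effective
natural selection is across the genome of a predominantly selfing diploid
plant: how strongly deleterious new mutations are (the distribution of
fitness effects, DFE), what fraction of between-species substitutions was
driven by positive selection (alpha, and the adaptive rate omega), and
where recent selective sweeps have acted. This vignette explains the
models behind each stage, the parameters that matter, what the built-in
simulator does and does not emulate, and the numerical choices the
package makes.

## The data model

The entry point is a biallelic SNP callset (VCF with GT/DP/AD) from a
low-coverage resequencing panel, plus a reference FASTA, a GFF3 gene
annotation, an optional multi-species alignment (MAF) and an optional
genetic map (20-kb windows with cM/Mb). Individuals carry group labels
(the package defaults mirror a four-group design named COL, UTA, NOR and
WES) and a per-individual inbreeding coefficient; the analyses assume a
high selfing rate (F around 0.9), which motivates two simplifications
used throughout:

* genotypes are *haploidized* — one allele per individual per site,
  heterozygotes resolved by a seeded coin flip — instead of statistically
  phased, because in a mostly homozygous genome a random haplotype is
  nearly always the true haplotype;
* hard genotype calls replace genotype-likelihood machinery. Published
  comparisons on data of this type show per-window diversity from hard
  calls and from genotype likelihoods correlate at r > 0.95, and the
  package's own estimators are validated exactly against brute-force
  haplotype oracles.

Genotype filters reflect a low-coverage selfer: homozygous calls with
fewer than 2 reads are missing; heterozygous calls need at least 20 reads
and a minor/major allelic-depth ratio of at least 0.25 (allele-imbalanced
hets are mismapping artifacts). Site filters drop sites genotyped in
fewer than half of the individuals, with mean depth of 20 or more
(collapsed repeats), with 15% or more heterozygous calls (paralogy), or
inside annotated repeats. All thresholds are strict on the side printed
here; the complementary set is retained. Missing genotypes never count in
the heterozygosity numerator or denominator, while call-rate denominators
are all individuals.

One published inconsistency is resolved deliberately: the het
allelic-balance rule is sometimes stated as "major/minor depth < 0.25",
which is impossible (that ratio is at least 1). The evident intent is to
remove imbalanced heterozygotes, so the package implements minor/major
< 0.25.

## Site annotation

Each CDS position is labelled by codon degeneracy under the standard
genetic code (k-fold = k of the 4 bases preserve the amino acid),
strand-aware and phase-adjusted; positions with conflicting labels from
overlapping transcripts are excluded and counted. Non-coding positions
get one category with priority CDS > UTR > intron > intergenic; introns
are split into 30-bp margins (where splice-adjacent constraint
concentrates) and a center; intergenic sites carry their distance to the
nearest gene, with "proximal" meaning within 100 bp (inclusive — the
boundary convention is pinned by requiring a site 99 bp away to be
proximal).

Polarization uses two outgroups: the ancestral allele is the ingroup
allele shared with at least one outgroup; sites where both or neither
ingroup allele matches are left unpolarized. Polarized SNPs fall into
three GC-biased gene conversion classes — weak-to-strong (A/T to G/C,
WS), strong-to-weak (SW), and GC-conservative (WWSS). gBGC favors WS
fixations in proportion to local recombination, so analyses that want
selection alone are run on GC-conservative sites.

Recombination-rate bins follow the genetic map at 20-kb resolution; sites
inherit their window's rate. Fixed thresholds (default 3.2 and 6.4
cM/Mb, with intervals [0, 3.2), [3.2, 6.4], (6.4, Inf) matching the
printed "<3.2", "3.2 to 6.4", ">6.4") or equal-count terciles are
available; "equal-size bins" and printed thresholds cannot both be exact
on arbitrary data, so terciles break boundary ties by genomic order.
Mask intervals (for example an inversion unresolved on the map) exclude
their sites.

## Constraint scores and conserved segments

Constraint is scored GERP-style. A neutral tree is calibrated by maximum
likelihood (Jukes-Cantor) on 4-fold degenerate alignment columns — the
topology from neighbor joining, branch lengths in expected substitutions
per site. For every column, `E` is the calibrated tree length restricted
to the species actually aligned (a gapped species contributes nothing to
expectation or observation), `O = r_hat * E` with `r_hat` the ML rate
multiplier of that column on a grid over [0, 4], and the rejected
substitution score is `RS = E - O`. An invariant column scores `RS = E`;
columns at the neutral rate score near 0 on average, with a small
downward bias because a per-column ML rate is noisy — the bias shrinks
with alignment depth and is a few percent of `E` at 10-16 species.
Jukes-Cantor was chosen over richer models for its closed-form transition
probabilities and easy testability; the model sits behind one function
and is swappable.

Conserved segments are extracted by iteratively taking the
maximum-scoring contiguous interval of the RS track (ties: first found in
a left-to-right scan), removing it, and recursing into the flanks while
the interval's cumulative score clears a threshold; only segments longer
than 12 bp are kept, a strict rule (a 12-bp run is discarded). Because
neutral RS has near-zero drift, raw maximal intervals bridge across
distinct conserved tracts; a per-site drift penalty (default 0.3 times
the track's robust spread, `mad`) is subtracted before extraction so
neutral stretches are clearly score-negative and segments split at them.
The default threshold is twice the robust per-site spread — the original
tool's settings are not published, so both defaults are explicitly
non-reproducing choices and are configurable.
Segments spanning annotation boundaries are split by category and
sub-segments of 12 bp or shorter are dropped; the non-coding remainder is
the conserved non-coding sequence (CNS) set.

## Spectra and classical statistics

Spectra are built at a fixed haploid sample size per group (defaults
78/63/52/39 for the four default groups) by deterministic hypergeometric
projection — each site contributes its expected mass over derived-allele
counts of a subsample drawn without replacement; sites called in fewer
chromosomes than the target are discarded, and projected mass on the
monomorphic classes counts only toward callable length. Projection
preserves expected diversity, and every spectrum-based statistic (pi,
Watterson's theta, Tajima's D with the 1989 normalization, Fay & Wu's H
as `pi - theta_H`, unnormalized, with a normalized variant behind a
flag) is tested for exact equality against brute-force haplotype-level
implementations. FST is Weir & Cockerham's ratio-of-averages from the
1984 a/b/c variance components on diploid genotypes; dXY is the mean
between-group difference per callable site, and RND divides dXY by the
mean divergence of the two groups to an outgroup to damp mutation-rate
variation. Long-term Ne is `theta_syn / (4 mu g)` with defaults mu =
7e-9 per year and g = 2 years. Windows are 20 kb, 0-anchored,
non-overlapping; windows under 5 kb callable are masked, mirroring the
sweep-scan rule.

## Demography, DFE, and adaptive rates

The selection analyses are SFS-based, with 4-fold sites outside conserved
regions as the neutral reference and 0-fold sites as the selected class.

**Demography.** 1-, 2- and 3-epoch piecewise-constant histories are fit
to the neutral spectrum by maximum likelihood (Poisson per frequency
class, overall rate profiled out) and compared by AIC. The expected
neutral spectrum under any epoch history is computed exactly from
coalescent theory: the expected time with k ancestral lineages is
integrated through the epochs with matrix exponentials of the
lineage-death process, and branch-subtending probabilities convert times
to spectrum classes. Sizes are ratios to the ancestral size N1; times
are in units of N1 generations.

**Selected spectra.** For a scaled strength gamma = Ne*s (semidominant,
fitnesses 1, 1-s/2, 1-s), the constant-size expected spectrum is the
exact Poisson-random-field sojourn integral. Under non-equilibrium
demography the package evolves the full allele-frequency distribution of
a Wright-Fisher population at reference size N1 = 100 (selection and
times rescaled to preserve Ne*s), and anchors the result class-wise to
the exact constant-size solution — the discrete chain's boundary and
large-s biases cancel in the anchored ratio, and the neutral limit
reproduces the exact coalescent expectation by construction. This
anchoring matters: the raw discrete-N spectrum underestimates
high-frequency classes of strongly selected mutations by an amount that
visibly distorts frequency-stratified statistics such as alpha(x).

**DFE.** A gamma distribution over Ne*s is fit to the selected spectrum
with demography fixed from the neutral fit. The gamma is discretized on
a 200-point log grid over [1e-4, 1e5] (strengths beyond the engine's
rescaled-s cap share one spectrum, so cost stays bounded) and the
mixture is refit instantly for any (shape, mean). Critically, the fit
uses *absolute* Poisson rates calibrated by the neutral SNP yield per
site and the ratio of mutational targets: a spectrum-shape-only fit
cannot see strongly deleterious mass (those mutations barely segregate),
which leaves the DFE mean unidentified. With the absolute calibration,
shape and mean — and hence the reported Ne*s bin proportions (<1, 1-10,
10-100, >100) — are recovered from simulated data to within a few
percent. Reported bins come from the fitted gamma itself.

**Alpha and omega.** The DFE-corrected estimate predicts the
nonsynonymous substitutions contributed by neutral and deleterious
mutations — `dN_pred = dS (LN/LS) E_f[relative fixation rate]`, the
expectation over the fitted gamma of `2g / (exp(2g) - 1)` — and
attributes the excess to positive selection: `alpha = (dN_obs - dN_pred)
/ dN_obs`, `omega = alpha * (dN/dS)`. Negative values are meaningful
(segregating weakly deleterious variants inflate pN). Also provided: the
plain MK `alpha = 1 - (pN/pS)/(dN/dS)` after removing polymorphisms with
derived allele frequency below 15%, and the asymptotic MK fit `alpha(x)
= a + b exp(-c x)` over 20 frequency bins on (0, 1) with fit range [0.1,
0.9] and a linear fallback, whose asymptote removes the deleterious
contamination that concentrates at low frequency (the x -> 1 limit of
the sojourn-density ratio equals the relative fixation rate, which is
why the asymptote is consistent). Confidence intervals come from a
20-kb block bootstrap (200 replicates, percentile), and replicate sets
are compared across groups or classes by Mann-Whitney U tests with
Bonferroni adjustment.

Beneficial mutations are deliberately not part of the fitted DFE
(deleterious-gamma only), matching the two-step alpha procedure; sites in
a user-supplied balancing-selection mask never enter spectra or MK
tables.

## Sweep scans

**CLR.** A SweepFinder-style composite likelihood compares each 20-kb
grid point's local site frequencies against the genome-wide background
spectrum under a star-like sweep model: a lineage escapes the sweep with
probability `1 - exp(-A d)` at distance d, escapees carry background
variation projected to their number plus one founder lineage, and the
founder's allele is amplified to all non-escapees. The escape rate A is
maximized on a log grid (the A -> infinity limit recovers the background,
so CLR >= 0). Folded spectra are the default, which sidesteps
polarization error; physical distance with an implicitly uniform
recombination rate is used, as map-based distance adds little at 20-kb
grids. Grids with under 5 kb callable per 20-kb window are masked.

**iHS.** For every SNP with minor allele frequency above 0.05, EHH decay
is integrated (trapezoid) outward for ancestral- and derived-allele
carriers until EHH < 0.05, a gap > 200 kb, or 1 Mb; `ln(iHH_A/iHH_D)` is
standardized within 2% derived-allele-frequency bins (sparse bins merged
outward, 300-SNP minimum). The score is exactly antisymmetric under
swapping allele labels, and the MAF filter compares integer allele
counts so relabeling keeps the same SNP set.

**Significance.** Both statistics get empirical p-values `(1 + #{null >=
obs}) / (1 + M)` against scans of fragments simulated under the fitted
neutral demography with identical scan parameters, then
Benjamini-Hochberg FDR at q < 0.01. Candidate genes lie within 10 kb of
a significant grid or SNP (strict: a gene starting 10,001 bp away does
not qualify); "swept regions" are maximal runs of contiguous significant
grids — the region-merging rule behind published swept-fraction numbers
is not defined there, so this definition is the package's own.

## The simulator

Every stage is validated against `sim_config()` /
`simulate_coalescent()` and friends, which generate data with the
statistical structure the analyses assume:

* **Genealogies.** Fragments are cut into 5-kb blocks; each block gets
  an independent coalescent genealogy (structured island model across
  groups, piecewise-constant sizes by time rescaling). Linkage is
  complete within a block and free between blocks — a deliberately
  coarse LD model that suits a highly selfing species and keeps
  genealogy simulation exact and fast. Consequences: EHH decays somewhat
  too abruptly at block edges, and long-range LD is absent, so
  haplotype-scan power results transfer to real data only qualitatively.
* **SFS-level generators.** For spectrum experiments, each site gets its
  own genealogy (level times plus subtree sizes only) carrying on
  average 0.7 mutations, so site classes are effectively independent
  draws — this is what makes chi-squared goodness-of-fit against theory
  valid, and it cross-validates the exact coalescent spectrum machinery
  through a completely different code path.
* **Selection.** Selected-site spectra are drawn from the
  Poisson-random-field expected spectra (mixed over gamma draws of the
  DFE) rather than forward simulation: fast, with exact marginals, in
  the same model class the fitter inverts. The paired generator ties
  selected-class rates to the realized neutral yield and uses the
  realized gamma components for fixation rates, keeping polymorphism and
  divergence internally consistent. Because generator and fitter share
  the expected-spectrum engine for the selected class, DFE recovery
  tests validate the inference machinery (identification, optimization,
  calibration) rather than the engine itself; the engine is validated
  separately against coalescent simulation (neutral, any demography) and
  exact PRF integrals (selection, constant size).
* **Selfing** makes a fraction F of individuals fully autozygous (one
  sampled lineage used twice) and scales the sweep-escape recombination
  rate by (1 - F). Real selfers are autozygosity mosaics; whole-fragment
  autozygosity is adequate at desk scale.
* **Sweeps** use the star approximation: per haplotype, an exponential
  escape distance on each side with rate `r_eff ln(2N)/s`; within the
  swept span the haplotype copies the founder. `s = 0` is the identity.
* **Divergence** overlays Poisson substitutions on the outgroup lineage
  and labels every fixation neutral/deleterious/beneficial, so the true
  alpha is recomputable from bookkeeping alone.

Simulator defaults are the study conditions the package targets: four
groups at 78/63/52/39 individuals, per-site theta 0.002 (diversity about
2e-3), selfing F = 0.9, a 5 cM/Mb map scale, gamma DFE (shape 0.3, mean
Ne*s 400), outgroup divergence 0.02, and a two-epoch five-fold expansion
(duration 2 N1 generations) where an expansion is called for. Values not
printed in the source literature (tract lengths of the conserved-element
simulator, the expansion age, divergence depth) were chosen once as
field-typical and are documented here rather than tuned.

## Validation experiments and problem sizes

The test suite's deeper experiments, with the sizes used (chosen to keep
a full run in tens of minutes on one core):

* DFE recovery: 2e5 neutral SNPs at n = 40 under the two-epoch
  expansion, gamma DFE (0.3, 400), 96 mixture components, 160-point fit
  grid; fitted Ne*s bins (<1, 1-10, >10) land within 0.05 of truth.
* Adaptive-rate recovery: the same dataset with a 20% beneficial share
  of nonsynonymous fixations recovers DFE-corrected alpha within 0.07;
  a matched null dataset recovers 0 within 0.05. The asymptotic MK
  experiment runs at constant size (its claim is about deleterious
  contamination, not demography) with true alpha 0.25: the asymptote
  lands within 0.05 while the uncorrected MK estimate underestimates
  grossly.
* Sweep localization: 50 outcrossing 1-Mb fragments with an s = 0.05
  sweep at the center (effective footprint about 80 kb); the CLR argmax
  falls within 40 kb of the sweep in at least 80% of fragments.
  Outcrossing is used because a localization test needs the footprint
  inside the fragment; under F = 0.9 the same sweep shapes most of a
  megabase.
* Null calibration: per-fragment maximum CLR from null fragments versus
  a null reference set gives uniform empirical p-values (KS); BH at
  q = 0.01 on uniform p-values calls essentially nothing.
* Constraint discovery: 10-way alignment, 1e5 columns, conserved tracts
  (rate multiplier 0.2, mean length 50); segment recall and precision
  both at least 0.8, and the segment scanner is exactly equal to an
  exhaustive maximal-interval oracle on 1-kb tracks.

## Numerical choices and degenerate inputs

* Wright-Fisher reference size 100 (diploid); rescaled `s` capped at
  0.9 — strengths beyond the cap share a spectrum, which is effectively
  zero anyway.
* Demography optimizer: Nelder-Mead on log parameters, multi-start,
  ratios bounded to [0.02, 50], times to [1e-3, 20] N1 generations.
* DFE optimizer: Nelder-Mead on log(shape), log(mean) with box [0.02, 5]
  x [1e-3, 1e5]; a boundary-pinned optimum is flagged and warned.
* PRF integrals: adaptive quadrature with the integrand written in
  `expm1` form so strong selection neither overflows nor loses
  precision; for gamma > 30 the upper limit shrinks to 40/gamma.
* Spectra with zero segregating sites report D and H as missing, never
  0. Empty filter output warns rather than errors. An empty background
  spectrum, a missing null distribution, or fewer than 5 usable
  frequency bins for the asymptotic fit are hard errors.
* Ties in equal-count recombination terciles break by genomic order;
  ties in segment extraction by the scan order described above; the
  heterozygote haploidization draw, bootstrap resampling, null-fragment
  simulation and every simulator stage consume seeds derived
  deterministically from one master seed.

## Known limitations

* Between-block linkage is absent in the simulator, so iHS power (not
  calibration) is understated relative to data with realistic LD decay.
* The four-population isolation-with-migration null used in the source
  analyses has unpublished parameters; the simulator offers an island
  model with configurable migration instead, and sweep significance on
  real data should treat the null demography as a user responsibility.
* The constraint stage's segment-score threshold is a documented default
  (twice the neutral RS standard deviation), not a reproduction of the
  original tool's unpublished setting.
* Per-column ML rates make individual RS scores noisy; constraint calls
  should rest on segments, not single sites.
* The DFE fit assumes equal per-site mutation rates in the neutral and
  selected classes (their targets differ only in size); strong
  mutation-rate heterogeneity between 0-fold and 4-fold sites would bias
  the absolute calibration.
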