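---
title: "Methods: SGB abundance estimation and microbiome-behavior analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SGB abundance estimation and microbiome-behavior analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dogbiome)
```

# Overview

`dogbiome` implements a complete computational pipeline for studying
associations between the canine gut microbiome and behavioral or
performance traits in working-dog cohorts: shotgun reads are quality
filtered and cleaned of host DNA, species-level relative abundances are
estimated against a catalog of species-level genome bin (SGB)
representatives by a unique best-hit window-coverage estimator, microbiome
features are derived, and the features are scanned for trait associations
and fed to cross-validated gradient-boosted classifiers of binarized
traits.

Because real cohort data of this kind are large and access-controlled, the
package ships a synthetic-data module that generates every input — toy SGB
catalogs, a host genome, reads drawn from known abundance profiles, and
cohort metadata with planted species-trait effects — so that every stage
can be verified against ground truth. This vignette explains the models,
the tunable parameters and why their defaults are what they are, the
numerical choices, and what the synthetic validation does and does not
show about real data.

# The abundance estimator

## Unique best-hit mapping

Reads are assigned to catalog genomes only when their best placement is
unambiguous. The built-in mapper finds candidate placements by exact
k-mer seeding (default seed length 31) on both strands and scores each
candidate by ungapped extension with +1 per match and -1 per mismatch,
requiring the read to be fully contained in the genome. A read is

* **unique** when its maximum score occurs at exactly one
  (genome, position, strand) and clears `min_score_frac` (default 0.5)
  times the read length,
* **ambiguous** when the maximum is tied across two or more placements
  (such reads are counted nowhere), and
* **unmapped** otherwise.

The mapper is deliberately simple — no gaps, no quality weighting — so it
can be checked exactly against an exhaustive all-position, both-strand
scoring oracle; the test suite does this on hundreds of randomized
instances. Production-scale alignments from a bowtie-class aligner can be
supplied instead as SAM (`unique_best_map(..., sam =)`), in which case a
read is unique iff its best alignment score (`AS` tag) is achieved by
exactly one record. The seeded candidate search is equivalent to the
exhaustive oracle whenever every top-scoring placement shares at least one
exact 31-mer with the read — guaranteed for reads with at most one
substitution per 62 bp, and overwhelmingly likely at the 0.5% per-base
error rate the generator emulates; a rare error-dense read is conservatively
left unmapped.

## Dense mean cover

Each genome is tiled with fixed-width windows (default 1,000 bp; the last
window may be shorter; all coordinates are 0-based half-open). Unique
reads are counted per window by their leftmost base, counts are converted
to per-base densities (`count * read_length / window_width`, using each
window's actual width), and the **dense mean cover** is the two-sided
trimmed mean of the sorted densities with `trim_fraction` (default 0.25)
discarded at each tail. The trimmed mean is a robust central-coverage
estimate: it ignores both dead windows (deletions, unmappable repeats)
and coverage spikes (conserved segments attracting reads from relatives).
With `trim_fraction = 0` it reduces to the plain mean density, a
closed-form identity the tests exploit. Because windows tile the genome,
per-base density is already genome-size normalized; a variant that divides
again by total genome length is available
(`genome_size_mode = "per_base_over_length"`) since the two readings
differ only by a per-genome constant that cancels in relative abundance.

## Existence, relative abundance, and the detection cap

An SGB is concluded to exist in a sample iff its cover is positive, at
least `min_reads` (default 10) reads mapped uniquely to it, and at least
`min_nonzero_window_fraction` (default 0.05) of its windows carry a read.
These thresholds suppress phantom detections caused by a handful of reads
piling into one conserved window. Relative abundance is each existing
SGB's cover divided by the summed covers of all existing SGBs, so the
vector sums to 1 before capping.

The detection cap `tau = 1e-4` is applied in one of two modes:

* **floor** (default): every entry below `tau`, including zeros, is
  raised to `tau`. This keeps all samples comparable on a log scale, at
  the price that the vector no longer sums to 1 (recorded in the cap
  state).
* **zero**: entries below `tau` are zeroed and survivors renormalized.

Both modes are legitimate readings of "capped at 10^-4"; the floor is the
default because downstream feature work is log-scaled. Richness is always
evaluated on the raw, pre-floor abundances against `tau` — under the
floor every species would otherwise count as present.

# Read processing

Quality control drops reads containing any configured adapter substring
(the generator plants a fixed 33-mer so this is exactly testable), trims
read edges inward while base quality is below `edge_quality_threshold`
(default Q20; the scan stops at the first passing base — no sliding
window), then drops reads whose mean quality falls below
`min_mean_quality` (default Q20) or whose trimmed length falls below
`min_length_after_trim` (default 50 bp). These thresholds are standard
Illumina practice; they are configuration, not estimates.

Host reads are removed by a k-mer screen: a read is called host when at
least `host_match_fraction` (default 0.5) of its 31-mers (forward or
reverse complement) occur in the host genome's k-mer set. At these
settings a host read survives only if it carries two or more well-placed
sequencing errors; such reads are random with respect to the catalog and
end up unmapped, so residual host contamination does not bias abundances.
An externally produced SAM of reads-vs-host (inclusive bowtie-style
mapping) may be supplied instead, in which case any aligned read is
removed. Finally, samples are subsampled without replacement to a fixed
depth, 10 million reads by default, matching the depth-standardization
step the pipeline emulates.

# The catalog inclusion rule

SGB catalogs built by large-scale clustering can split small satellite
bins off a large species. The inclusion rule retains an SGB iff it is the
only bin carrying its genus label or it is backed by at least 5
assemblies. The rule is applied to the catalog as given, before window
indexing; kept and dropped sets are both reported. The synthetic
generator's default taxonomy satisfies the rule for every bin (mirroring
an already-curated reference set); the rule's decision table is exercised
on hand-built records in the tests.

# Microbiome features

The feature table holds one row per sample: a summary block plus every
species abundance. The default summary block has 13 columns — richness,
Shannon diversity (natural log, computed over detected species with
renormalized abundances), butyrate-producer sum (24 literature species,
represented by catalog flags), acetate-producer sum, the
Firmicutes/Bacteroidetes ratio (denominator zero yields a missing value,
not infinity; either phylum spelling "Bacteroidetes"/"Bacteroides" is
honored verbatim), five phylum aggregates and three Firmicutes family
aggregates. The precise composition of a 13-feature summary block is not
canonical, so the manifest is configurable; aggregates conserve total
abundance at every rank, which the tests verify. Beta diversity uses
Bray-Curtis dissimilarity with classical scaling (PCoA); negative
eigenvalues are reported and their axes dropped.

# Association scans

Categorical phenotypes are scanned feature-by-feature with the
Mann-Whitney test (two groups) or Kruskal-Wallis (more). The
Mann-Whitney p is exact by enumeration when both groups have at most 8
observations and no ties; otherwise the tie-corrected normal
approximation with continuity correction is used, which stays within 0.02
of the exact enumeration at the smallest group sizes the exact branch
hands over. Numeric pairs use Pearson correlation with the t transform on
n-2 degrees of freedom. Demographic pairs use Fisher's exact test
(two-sided, point-probability rule) when the table is 2x2 with any
expected count below 5, else chi-squared without continuity correction.

Each scan — one phenotype against all features — is one multiple-testing
family; this is the least surprising reading of correcting "when testing
multiple hypotheses" and is recorded in each record. Both Bonferroni and
Benjamini-Hochberg corrections are implemented and the method is an
explicit argument with no silent default between them, because the two
appear in different parts of the emulated protocol (Bonferroni at level
0.15 for correlation-style scans; FDR at 0.15 or 0.05 for family-level
scans). Features whose grouping leaves a group under 2 samples, or with
zero variance, are skipped with a logged reason rather than producing
undefined statistics.

# Prediction

Each trait is binarized after excluding puppies (age < 1 year, not yet
behaviorally mature). The default rule thresholds at the rounded-up
median score with `score >= threshold` labelled high; explicit thresholds
are honored and logged, and binary flags pass through. Classification
uses gradient-boosted trees (200 trees, depth 3, learning rate 0.1, 80%
row subsampling — declared defaults, not estimates) on the summary block
plus all species abundances. Folds are stratified by class and
deterministic under the seed; both the 3-fold ROC-AUC protocol and the
5-fold accuracy protocol are first-class. Per-fold ROC AUC (trapezoidal)
and accuracy at 0.5 are reported with mean and SD. Only microbiome
features enter the model; metadata is used solely for labels and the
puppy exclusion.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is
validated:

* **Catalog**: by default 30 random genomes of 50 kb across five phyla
  dominated by Firmicutes and Bacteroidetes, with 24 species flagged as
  butyrate producers and 10 as acetate producers, plus a random host
  genome. Random sequence has no GC skew, repeats, or shared homology —
  which makes unique mapping easier than in real communities.
* **Reads**: 200,000 per sample, 100 bp, drawn from genomes with
  probability proportional to abundance times genome length (so per-base
  coverage tracks abundance), from either strand, with 0.5% uniform
  substitution error, 10% host reads, and 5% junk reads (half carrying
  the known adapter, half uniformly low quality). Qualities are uniform
  per read; there is no paired-end structure, no indels, and no
  position-dependent error profile.
* **Cohort**: demographics emulate a working-dog program (11.8% puppies,
  53.4% female, ages log-normal around 3.8 +/- 2.4 years in 0.5-12, BCS
  centred on 5, Malinois-dominated breeds). The default cohort size
  follows the emulated study (n = 134); validation suites use 100-120.
  Trait scores discretize latent standard Gaussians into five
  equal-probability bins. Per-dog abundances are
  `normalize(b_g * exp(sigma * z + shift))` with catalog-level base
  abundances `b_g ~ Gamma(0.5)` (a Dirichlet(0.5)-type rank-abundance
  curve with rare taxa below the cap) and per-dog log-normal noise
  `sigma = 1`.
* **Planted effects**: an effect shifts the affected species' log
  abundance by `effect_size * sigma` in dogs above the trait's
  binarization threshold, before renormalization. Renormalization
  attenuates the realized difference in log *relative* abundance — for a
  2-sigma shift on 2 of 50 species the realized difference is about 1.9
  sigma, and it shrinks further when the affected species are abundant
  (their shift inflates the normalizing denominator). Group-mean checks
  therefore compare against simulated expectations, not the nominal
  shift.

Passing the validation suite shows the estimator and the statistical
machinery are correct under these conditions; it does not show that real
dog stool — with strain mixtures, shared gene content, contamination and
compositional noise — will be recovered equally well. The abundance
recovery correlation reported by the acceptance script (r > 0.99 between
log truth and log estimate) is an upper bound attainable only because the
synthetic genomes share no homology.

# Numerical choices and problem sizes

Determinism is a contract: every stage takes an explicit seed, stage
seeds are derived from the run seed by fixed offsets, and rerunning a
configuration reproduces every output byte (verified by hashing whole
output trees). Ties in the mapper make a read ambiguous rather than
breaking them arbitrarily. Degenerate inputs are warnings, not errors,
when the pipeline can continue (no SGB existing in a sample, subsampling
shortfall, identical samples in PCoA); they are hard errors when silence
would corrupt results (sequence/quality length mismatch, missing taxonomy
labels, a grouping that empties a class).

The validation suites run at deliberately desk-scale sizes chosen to keep
the full suite under a few minutes while leaving comfortable statistical
margins: mapper-oracle equivalence on 200 instances of 3 x 1.5 kb genomes
and 20 reads; abundance recovery at the generator's full defaults (one
200k-read sample); type-I control on 20 null cohorts of 100 dogs x 50
species; prediction contracts on cohorts of 120 dogs. The bundled
analysis scripts use a 60-dog cohort at 20,000 reads per dog.

# Known limitations

* The built-in mapper is exact-match seeded and ungapped; it is a
  verifiable stand-in for desk-scale work, not a replacement for
  bowtie-class aligners on real data (ship SAM instead).
* "Dense mean cover" is realized as a symmetric 25% trimmed mean; other
  robust central estimates would differ on skewed coverage profiles.
* The association layer is univariate by design; confounder-adjusted
  multivariate models are out of scope at these cohort sizes.
* The synthetic cohort's abundance distribution is a stand-in, not an
  estimate of any real cohort's distribution; effect sizes are expressed
  in its own latent units.
* Booster hyperparameters are fixed defaults; no tuning or model
  interpretation is provided.
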