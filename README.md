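# dogbiome

An R package implementing an end-to-end pipeline for studying the gut
microbiome of working dogs and its association with behavioral and
performance traits — from raw shotgun metagenomic reads to species-level
relative abundances, microbiome features, statistical association scans,
and cross-validated machine-learning prediction of binarized traits.

It is written for microbiome researchers who want a fully inspectable,
deterministic implementation of the species-level genome bin (SGB)
abundance protocol and its downstream statistics, validated at every stage
against synthetic data with known ground truth rather than against
unavailable cohort data.

## The method

**Abundance estimation.** Reads are quality filtered (adapter removal,
low-quality edge trimming, mean-quality and length thresholds), screened
against the host genome (31-mer screen, or an external SAM of host
alignments), and subsampled to a fixed depth (default 10⁷ reads). Against
a catalog of SGB representative genomes — retained when a bin *either
belongs to a unique genus or has ≥ 5 assemblies* — each read is assigned
only if its best placement is unique across the whole index; ambiguous
reads count nowhere. Unique reads are counted in fixed 1 kb windows
tiling each genome, window counts become per-base densities, and the
cover of genome *g* is the two-sided 25% trimmed mean of its window
densities ("dense mean cover"). Relative abundance is

> *p(g) = c(g) / Σ c(g′)* over all genomes *g′* concluded to exist in the
> sample (positive cover, ≥ 10 unique reads, ≥ 5% nonzero windows),

then capped at τ = 10⁻⁴ (floor mode for log-scale work, or zero-and-
renormalize).

**Features.** Richness *S* (species with raw abundance ≥ τ), Shannon
diversity *H = −Σ q ln q*, butyrate- and acetate-producer sums (24
literature butyrate species), the Firmicutes/Bacteroidetes ratio, taxon
aggregates at phylum/family/genus rank, and Bray–Curtis PCoA.

**Statistics.** Mann–Whitney / Kruskal–Wallis scans of features against
categorical traits, Pearson correlation for numeric pairs,
chi-squared/Fisher for demographics, with Bonferroni or
Benjamini–Hochberg correction per scan family (levels 0.15 / 0.05).

**Prediction.** Traits scored 1–5 are binarized (median rule by default),
puppies (< 1 year) are excluded, and gradient-boosted trees (xgboost) are
evaluated in stratified 3-fold (ROC AUC) and 5-fold (accuracy)
cross-validation on microbiome features only.

**Synthetic data.** A first-class generator produces toy SGB catalogs,
host genomes, reads drawn from known abundance profiles (with sequencing
error, host contamination and junk reads), and cohort metadata with
planted species→trait effects — so recovery, type-I control, power, and
prediction contracts are all testable against ground truth.

## Worked example

```r
library(dogbiome)

cc <- community_config(n_sgbs = 10, genome_length_bp = 20000,
                       n_reads = 50000, seed = 1)
catalog <- generate_reference_catalog(cc)
truth <- random_truth_profile(catalog, "dog_001")

reads <- simulate_sample_reads(catalog, truth, cc, seed = 2)
reads <- quality_filter(reads)$reads
reads <- host_screen(reads, catalog$host)

index <- build_window_index(catalog, 1000)
est <- sample_abundance(reads, catalog, index, sample_id = "dog_001")
round(rbind(truth = truth$abundance, estimate = est$p), 4)
#>          SGB_01 SGB_02 SGB_03 SGB_04 SGB_05 SGB_06 SGB_07 SGB_08 SGB_09 SGB_10
#> truth    0.0174 0.0203 0.1716 0.0038 0.0561 0.2978 0.1880 0.1922  1e-04 0.0528
#> estimate 0.0169 0.0202 0.1718 0.0034 0.0569 0.2983 0.1869 0.1928  0e+00 0.0529

alpha <- compute_alpha_diversity(est$p)
alpha$S; round(alpha$H, 3)
#> 9
#> 1.78
```

The estimate tracks the simulated truth to within sampling error
(log₁₀ correlation 0.9999 here); SGB_09, simulated at the detection cap
(10⁻⁴), is correctly not detected at this depth, so richness is 9 of 10.

## The analysis workflow

`analysis/` contains the numbered end-to-end study on a synthetic 60-dog
cohort with planted effects (+2 SD on two species for high motivation,
−1.5 SD on two species for high sociability):

```sh
Rscript analysis/01_simulate.R     # catalog, cohort, per-dog FASTQ (scratch/)
Rscript analysis/02_abundance.R    # QC -> host screen -> mapping -> abundance
Rscript analysis/03_features.R     # feature table + PCoA
Rscript analysis/04_associations.R # BH-corrected trait scans
Rscript analysis/05_prediction.R   # 3- and 5-fold boosted classification
```

Derived tables land in `results/`. On this cohort the scans recover the
planted species among the significant pairs and the prediction stage
ranks the planted traits at the top (motivation AUC 0.90 ± 0.08 at 3-fold
in the bundled run).

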