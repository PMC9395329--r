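#!/usr/bin/env Rscript
# Stage 3: abundance -> microbiome features. The 13-column summary block
# (richness, Shannon, SCFA-producer sums, F/B ratio, taxon aggregates)
# plus all species abundances, and Bray-Curtis PCoA of the cohort.

suppressMessages(library(dogbiome))

taxonomy <- read.delim("scratch/data/taxonomy.tsv")
taxonomy <- filter_sgbs(taxonomy)$kept
raw <- read.delim("results/abundance_raw.tsv", check.names = FALSE)
m <- as.matrix(raw[, -1])
rownames(m) <- raw$sample_id

# restrict the default manifest to aggregate labels this catalog carries
manifest <- default_feature_manifest()
ok <- vapply(manifest, function(f) {
  p <- regmatches(f, regexec("^(phylum|family|genus)_(.+)$", f))[[1]]
  length(p) == 0 || p[3] %in% taxonomy[[p[2]]]
}, TRUE)
feats <- assemble_feature_table(m, taxonomy, manifest = manifest[ok])
write.table(feats, "results/features.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pc <- beta_diversity_pcoa(m)
write.table(data.frame(sample_id = rownames(pc$coords), pc$coords,
                       check.names = FALSE),
            "results/pcoa_coordinates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Feature table:", nrow(feats), "dogs x", ncol(feats) - 1,
    "features (", sum(ok), "summary +", nrow(taxonomy), "species )\n")
cat(sprintf("Richness %.0f-%.0f, Shannon %.2f-%.2f, F/B ratio median %.2f\n",
            min(feats$richness), max(feats$richness), min(feats$shannon),
            max(feats$shannon), median(feats$fb_ratio, na.rm = TRUE)))
cat(sprintf("PCoA: first two axes carry %.0f%% of the positive inertia\n",
            100 * sum(pc$eigenvalues[1:2]) /
              sum(pc$eigenvalues[pc$eigenvalues > 0])))
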