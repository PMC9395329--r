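#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs — an SGB reference catalog with a host
# genome, a 60-dog cohort with two planted microbiome-trait effects, and
# per-dog shotgun FASTQ files. Everything downstream has ground truth.
# Raw simulated inputs (FASTQ/FASTA) go under scratch/; derived tables the
# later stages produce go under results/.

suppressMessages(library(dogbiome))

out <- "scratch/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cc <- community_config(n_sgbs = 20, genome_length_bp = 20000,
                       n_reads = 20000, host_genome_length_bp = 50000,
                       seed = 20)
catalog <- generate_reference_catalog(cc)
write_fasta(catalog$genomes, file.path(out, "catalog.fasta"))
write_fasta(c(host = catalog$host), file.path(out, "host.fasta"))
write.table(catalog$taxonomy, file.path(out, "taxonomy.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# planted effects: motivation raised by 2 SD on two Firmicutes, sociability
# lowered by 1.5 SD on two others — the signal the scan and the classifier
# should find
effects <- list(
  effect_spec("motivation", c("SGB_01", "SGB_02"), effect_size = 2),
  effect_spec("sociability", c("SGB_03", "SGB_04"), effect_size = 1.5,
              direction = -1))
coh <- generate_cohort(catalog, n_dogs = 60, effects = effects, seed = 21)
write.table(coh$metadata, file.path(out, "metadata.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(dog_id = rownames(coh$truths), coh$truths,
                       check.names = FALSE),
            file.path(out, "truth_profiles.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

dir.create(file.path(out, "reads"), showWarnings = FALSE)
for (i in seq_len(nrow(coh$metadata))) {
  id <- coh$metadata$dog_id[i]
  tp <- truth_profile(id, coh$truths[id, ],
                      host_fraction = cc$host_fraction)
  rs <- simulate_sample_reads(catalog, tp, cc, seed = 100 + i)
  write_fastq(rs, file.path(out, "reads", paste0(id, ".fastq")))
}

cat("Simulated", nrow(coh$metadata), "dogs over", nrow(catalog$taxonomy),
    "SGBs;", cc$n_reads, "reads/dog at", cc$host_fraction * 100,
    "% host and", cc$junk_fraction * 100, "% junk.\n")
cat("Planted: +2 SD on SGB_01/SGB_02 for high motivation; -1.5 SD on",
    "SGB_03/SGB_04 for high sociability.\n")
cat("Inputs written under", out, "\n")
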