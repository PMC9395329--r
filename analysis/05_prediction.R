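#!/usr/bin/env Rscript
# Stage 5: gradient-boosted prediction of binarized traits from microbiome
# features, after puppy exclusion, under both the 3-fold (ROC AUC) and
# 5-fold (accuracy) cross-validation protocols.

suppressMessages(library(dogbiome))

feats <- read.delim("results/features.tsv", check.names = FALSE)
meta <- read.delim("scratch/data/metadata.tsv")

rows <- list()
for (tr in c(dog_traits(), "gi_issues")) {
  for (k in c(3, 5)) {
    rep_ <- tryCatch(
      predict_trait(feats, meta, tr, k = k, seed = 1),
      error = function(e) e)
    if (inherits(rep_, "error")) {
      cat("skipped", tr, paste0("(k=", k, "): "), conditionMessage(rep_),
          "\n")
      next
    }
    rows[[paste(tr, k)]] <- data.frame(
      trait = tr, k = k, n_used = rep_$n_used,
      n_excluded_puppies = rep_$n_excluded_puppies,
      mean_auc = rep_$mean_auc, sd_auc = rep_$sd_auc,
      mean_accuracy = rep_$mean_accuracy, sd_accuracy = rep_$sd_accuracy,
      stringsAsFactors = FALSE)
  }
}
pred <- do.call(rbind, rows)
rownames(pred) <- NULL
write.table(pred, "results/predictions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("\n3-fold ROC AUC by trait:\n")
p3 <- pred[pred$k == 3, ]
for (i in order(-p3$mean_auc)) {
  cat(sprintf("  %-18s AUC %.2f +/- %.2f (n = %d, %d puppies excluded)\n",
              p3$trait[i], p3$mean_auc[i], p3$sd_auc[i], p3$n_used[i],
              p3$n_excluded_puppies[i]))
}
cat("Traits with planted effects (motivation, sociability) should rank",
    "near the top; unplanted traits should hover near chance.\n")
cat("Report written to results/predictions.tsv\n")
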