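test_that("alpha diversity matches closed forms", {
  a <- compute_alpha_diversity(c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))
  expect_equal(a$S, 4L)
  expect_equal(a$H, log(4))

  b <- compute_alpha_diversity(c(a = 1))
  expect_equal(b$S, 1L)
  expect_equal(b$H, 0)

  # -0.5 log 0.5 - 2 * 0.25 log 0.25
  d <- compute_alpha_diversity(c(a = 0.5, b = 0.25, c = 0.25))
  expect_equal(d$H, -(0.5 * log(0.5) + 0.5 * log(0.25)))

  # species under tau are not detected; S = 0 gives H = 0
  e <- compute_alpha_diversity(c(a = 1 - 5e-5, b = 5e-5), tau = 1e-4)
  expect_equal(e$S, 1L)
  expect_equal(compute_alpha_diversity(c(a = 0, b = 0))$H, 0)
})

test_that("Shannon is maximal at equi-abundance and falls as mass concentrates", {
  # one-parameter family: (0.25+t, 0.25-t/3, 0.25-t/3, 0.25-t/3)
  hs <- sapply(seq(0, 0.7, length.out = 8), function(t) {
    compute_alpha_diversity(c(a = 1 + 3 * t, b = 1 - t, c = 1 - t,
                              d = 1 - t) / 4)$H
  })
  expect_equal(hs[1], log(4))
  expect_true(all(diff(hs) < 0))
})

test_that("taxon aggregation sums members and conserves totals", {
  tax <- data.frame(sgb_id = c("s1", "s2", "s3"),
                    species = c("sp1", "sp2", "sp3"),
                    genus = c("g1", "g2", "g3"),
                    family = c("f1", "f1", "f2"),
                    phylum = c("Firmicutes", "Firmicutes", "Bacteroidetes"),
                    stringsAsFactors = FALSE)
  m <- matrix(c(0.3, 0.2, 0.5), 1, dimnames = list("S1", tax$sgb_id))
  agg <- aggregate_taxa(m, tax, "phylum")
  expect_equal(agg[1, "Firmicutes"], 0.5)

  # associativity: genus -> phylum equals direct phylum aggregation
  g <- aggregate_taxa(m, tax, "genus")
  via_genus <- c(Firmicutes = sum(g[1, c("g1", "g2")]),
                 Bacteroidetes = unname(g[1, "g3"]))
  expect_equal(via_genus, agg[1, names(via_genus)])

  # every rank's aggregates sum to the species total
  for (rk in c("phylum", "family", "genus")) {
    expect_equal(sum(aggregate_taxa(m, tax, rk)), sum(m))
  }

  tax$family[2] <- NA
  expect_error(aggregate_taxa(m, tax, "family"), "s2")
})

test_that("SCFA producer sums cover the worked cases", {
  cat_ <- feature_catalog()
  tax <- cat_$taxonomy
  m <- matrix(runif(2 * nrow(tax)), 2,
              dimnames = list(c("S1", "S2"), tax$sgb_id))
  expect_equal(scfa_producer_sum(m, character(0), tax), c(S1 = 0, S2 = 0))
  expect_equal(scfa_producer_sum(m, tax$species, tax), rowSums(m))

  but <- tax$species[tax$butyrate_flag]
  expect_length(but, 24)
  hand <- rowSums(m[, tax$sgb_id[tax$butyrate_flag], drop = FALSE])
  expect_equal(scfa_producer_sum(m, but, tax), hand)

  expect_error(scfa_producer_sum(m, "NotASpecies", tax), "absent")
})

test_that("F/B ratio divides phylum sums and guards the denominator", {
  tax <- data.frame(sgb_id = c("s1", "s2"), species = c("sp1", "sp2"),
                    genus = c("g1", "g2"), family = c("f1", "f2"),
                    phylum = c("Firmicutes", "Bacteroidetes"),
                    stringsAsFactors = FALSE)
  m <- matrix(c(0.5, 0.5,   0.6, 0.3,   0.4, 0), 3, 2, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), tax$sgb_id))
  r <- fb_ratio(m, tax)
  expect_equal(unname(r), c(1, 2, NA))

  # the alternative phylum spelling works verbatim
  tax$phylum[2] <- "Bacteroides"
  expect_equal(unname(fb_ratio(m, tax)[2]), 2)
})

test_that("Bray-Curtis and PCoA satisfy their identities", {
  x <- c(0.2, 0.5, 0.3)
  m <- rbind(S1 = x, S2 = x, S3 = c(1, 0, 0), S4 = c(0, 1, 0))
  colnames(m) <- paste0("t", 1:3)
  pc <- beta_diversity_pcoa(m)
  bc <- pc$bc
  expect_equal(bc["S1", "S2"], 0)           # identical profiles
  expect_equal(bc["S3", "S4"], 1)           # disjoint supports
  expect_true(all(bc >= 0 & bc <= 1))
  expect_equal(bc, t(bc))
  expect_equal(unname(diag(bc)), rep(0, 4))

  # coordinates reproduce the double-centered spectrum: pairwise coordinate
  # distances match the BC matrix up to the negative-eigenvalue part
  set.seed(3)
  m2 <- matrix(rexp(5 * 8), 5, 8,
               dimnames = list(paste0("S", 1:5), paste0("t", 1:8)))
  m2 <- m2 / rowSums(m2)
  pc2 <- beta_diversity_pcoa(m2)
  hand_bc <- outer(seq_len(5), seq_len(5), Vectorize(function(i, j) {
    sum(abs(m2[i, ] - m2[j, ])) / sum(m2[i, ] + m2[j, ])
  }))
  expect_equal(unname(pc2$bc), hand_bc, tolerance = 1e-10)
  if (all(pc2$eigenvalues > -1e-8)) {
    rec <- as.matrix(dist(pc2$coords))
    expect_equal(unname(rec), unname(pc2$bc), tolerance = 1e-8)
  }
  expect_equal(pc2$eigenvalues, sort(pc2$eigenvalues, decreasing = TRUE))

  # identical samples only: all-zero coordinates
  same <- rbind(S1 = x, S2 = x, S3 = x)
  colnames(same) <- paste0("t", 1:3)
  pc3 <- beta_diversity_pcoa(same)
  expect_true(all(pc3$coords == 0))
})

test_that("the assembled feature table has the 13-column summary block", {
  cat_ <- feature_catalog()
  coh <- generate_cohort(cat_, n_dogs = 12, seed = 2)
  ft <- assemble_feature_table(coh$truths, cat_$taxonomy)
  expect_s3_class(ft, "feature_table")
  expect_equal(attr(ft, "manifest"), default_feature_manifest())
  expect_length(default_feature_manifest(), 13)
  # sample_id + 13 summary + one column per species
  expect_equal(ncol(ft), 1 + 13 + nrow(cat_$taxonomy))
  expect_true(all(cat_$taxonomy$species %in% names(ft)))

  # determinism: identical TSVs from identical inputs
  f1 <- tempfile(); f2 <- tempfile()
  write.table(ft, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  ft2 <- assemble_feature_table(coh$truths, cat_$taxonomy)
  write.table(ft2, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(
    assemble_feature_table(coh$truths, cat_$taxonomy,
                           manifest = c("richness", "phylum_Nope")),
    "uncomputed feature")
})
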