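make_genomes <- function(seed = 1, n = 3, len = 1500) {
  set.seed(seed)
  stats::setNames(
    vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, ""),
    paste0("G", seq_len(n)))
}

test_that("unique, ambiguous and unmapped reads are classified correctly", {
  g <- make_genomes(seed = 2)
  # plant an identical segment in G1 and G2
  seg <- substr(g[[1]], 201, 320)
  substr(g[[2]], 601, 720) <- seg
  idx <- build_window_index(stats::setNames(nchar(g), names(g)), 500)

  unique_read <- substr(g[[3]], 701, 780)
  amb_read <- substr(seg, 11, 90)
  set.seed(9)
  junk <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE),
                collapse = "")
  rs <- read_set(c("u", "a", "j"), c(unique_read, amb_read, junk),
                 strrep("I", c(80, 80, 80)))
  m <- unique_best_map(rs, g, idx)
  expect_equal(m$status, c("unique", "ambiguous", "unmapped"))
  expect_equal(m$sgb_id[1], "G3")
  expect_equal(m$pos[1], 700)
  expect_equal(m$window[1], 1)
})

test_that("the seeded mapper matches the exhaustive oracle on random instances", {
  set.seed(123)
  for (i in 1:12) {
    inst <- make_oracle_instance(n_reads = 15)
    res <- mapper_oracle_agreement(inst)
    expect_equal(res[["agree"]], res[["n"]])
  }
})

test_that("external SAM mode declares unique only on a single best score", {
  g <- make_genomes()
  idx <- build_window_index(stats::setNames(nchar(g), names(g)), 500)
  rs <- read_set(c("r1", "r2", "r3"), rep(strrep("A", 50), 3),
                 rep(strrep("I", 50), 3))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    paste0("@SQ\tSN:", names(g), "\tLN:", nchar(g)),
    "r1\t0\tG1\t101\t42\t50M\t*\t0\t0\t*\t*\tAS:i:95",
    "r1\t256\tG2\t201\t0\t50M\t*\t0\t0\t*\t*\tAS:i:80",
    "r2\t0\tG1\t301\t42\t50M\t*\t0\t0\t*\t*\tAS:i:90",
    "r2\t256\tG3\t401\t0\t50M\t*\t0\t0\t*\t*\tAS:i:90",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam)
  m <- unique_best_map(rs, g, idx, sam = sam)
  expect_equal(m$status, c("unique", "ambiguous", "unmapped"))
  expect_equal(m$sgb_id[1], "G1")
  expect_equal(m$pos[1], 100)  # SAM 1-based -> 0-based

  bad <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6", "@SQ\tSN:NOPE\tLN:5000",
               "r1\t0\tNOPE\t1\t42\t50M\t*\t0\t0\t*\t*"), bad)
  expect_error(unique_best_map(rs, g, idx, sam = bad), "NOPE")
})

test_that("read conservation: unique + ambiguous + unmapped = input", {
  set.seed(5)
  inst <- make_oracle_instance(n_reads = 40)
  rs <- read_set(paste0("r", 1:40), inst$reads,
                 strrep("I", nchar(inst$reads)))
  idx <- build_window_index(
    stats::setNames(nchar(inst$genomes), names(inst$genomes)), 500)
  m <- unique_best_map(rs, inst$genomes, idx)
  expect_equal(sum(table(m$status)), 40)
  prof <- window_counts(m, idx)
  expect_equal(sum(unlist(prof$counts)), sum(m$status == "unique"))
})

test_that("dense mean cover reproduces its closed forms", {
  idx <- build_window_index(c(g = 8000), 1000)
  mk_prof <- function(cnt) {
    structure(list(counts = list(g = cnt), n_unique = c(g = sum(cnt))),
              class = "cover_profile")
  }
  # uniform counts: trimmed mean of a constant is the constant
  for (tf in c(0, 0.1, 0.25, 0.4)) {
    expect_equal(unname(dense_mean_cover(mk_prof(rep(5, 8)), idx, 100,
                                         trim_fraction = tf)), 0.5)
  }
  # worked example: (0,0,0,0,10,10,10,10), trim 0.25 -> central (0,0,1,1)
  expect_equal(unname(dense_mean_cover(mk_prof(c(0, 0, 0, 0, 10, 10, 10, 10)),
                                       idx, 100, trim_fraction = 0.25)), 0.5)
  # all-zero counts
  expect_equal(unname(dense_mean_cover(mk_prof(rep(0, 8)), idx, 100)), 0)
  # trim 0 equals the plain mean density on random profiles
  set.seed(7)
  for (i in 1:100) {
    cnt <- rpois(8, 3)
    expect_equal(
      unname(dense_mean_cover(mk_prof(cnt), idx, 100, trim_fraction = 0)),
      mean(cnt * 100 / 1000))
  }
  # genome-size mode divides by total genome length
  expect_equal(
    unname(dense_mean_cover(mk_prof(rep(5, 8)), idx, 100,
                            genome_size_mode = "per_base_over_length")),
    0.5 / 8000)
})

test_that("the terminal short window uses its actual width for density", {
  idx <- build_window_index(c(g = 1500), 1000)
  prof <- structure(list(counts = list(g = c(10, 5)),
                         n_unique = c(g = 15L)),
                    class = "cover_profile")
  # densities: 10*100/1000 = 1 and 5*100/500 = 1
  expect_equal(unname(dense_mean_cover(prof, idx, 100, trim_fraction = 0)), 1)
})

test_that("relative abundance normalizes over existing SGBs only", {
  mk <- function(covers, counts, n_unique) {
    prof <- structure(list(counts = counts, n_unique = n_unique),
                      class = "cover_profile")
    estimate_relative_abundance(covers, prof)
  }
  cnt20 <- rep(2L, 10)
  v <- mk(c(a = 2, b = 2), list(a = cnt20, b = cnt20),
          c(a = 20L, b = 20L))
  expect_equal(unname(v$p), c(0.5, 0.5))

  v <- mk(c(a = 3, b = 1, c = 0),
          list(a = cnt20, b = cnt20, c = rep(0L, 10)),
          c(a = 20L, b = 20L, c = 0L))
  expect_equal(unname(v$p), c(0.75, 0.25, 0))
  expect_equal(unname(v$exists), c(TRUE, TRUE, FALSE))
  expect_equal(sum(v$p), 1, tolerance = 1e-9)

  # existence thresholds: too few reads or too sparse windows
  v <- mk(c(a = 2, b = 0.2), list(a = cnt20, b = c(9L, rep(0L, 9))),
          c(a = 20L, b = 9L))
  expect_equal(unname(v$exists), c(TRUE, FALSE))

  expect_warning(
    v0 <- mk(c(a = 0, b = 0), list(a = rep(0L, 10), b = rep(0L, 10)),
             c(a = 0L, b = 0L)),
    "no SGB")
  expect_true(all(v0$p == 0))
})

test_that("relative abundance is invariant to rescaling of covers", {
  prof <- structure(list(counts = list(a = rep(3L, 10), b = rep(1L, 10)),
                         n_unique = c(a = 30L, b = 10L)),
                    class = "cover_profile")
  v1 <- estimate_relative_abundance(c(a = 3, b = 1), prof)
  v2 <- estimate_relative_abundance(c(a = 30, b = 10), prof)
  expect_equal(v1$p, v2$p)
})

test_that("the detection cap behaves in both floor and zero modes", {
  mkv <- function(p) {
    structure(list(sample_id = "s", cover = p, exists = p > 0, p = p,
                   cap_tau = NA_real_, cap_mode = NA_character_),
              class = "abundance_vector")
  }
  p <- c(a = 0.9, b = 0.09995, c = 5e-5, d = 0)
  f <- apply_detection_cap(mkv(p), 1e-4, "floor")
  expect_equal(unname(f$p[c("c", "d")]), c(1e-4, 1e-4))
  expect_true(all(f$p >= 1e-4))

  z <- apply_detection_cap(mkv(p), 1e-4, "zero")
  expect_equal(unname(z$p["c"]), 0)
  expect_equal(sum(z$p), 1, tolerance = 1e-12)
  expect_equal(unname(z$p["a"]), 0.9 / (0.9 + 0.09995))

  # no-op when everything clears tau
  ok <- c(a = 0.6, b = 0.4)
  expect_equal(apply_detection_cap(mkv(ok), 1e-4, "floor")$p, ok)
  expect_equal(apply_detection_cap(mkv(ok), 1e-4, "zero")$p, ok)

  expect_error(apply_detection_cap(mkv(p), 0), "tau")
  expect_error(apply_detection_cap(mkv(p), 2), "tau")
})

test_that("abundance recovery at depth is within binomial error", {
  cc <- community_config(n_sgbs = 3, genome_length_bp = 20000,
                         window_length_bp = 1000, n_reads = 30000,
                         host_fraction = 0, junk_fraction = 0,
                         base_error_rate = 0.002, seed = 21)
  cat_ <- generate_reference_catalog(cc)
  tp <- truth_profile("S", stats::setNames(c(0.6, 0.3, 0.1),
                                           cat_$taxonomy$sgb_id))
  rs <- simulate_sample_reads(cat_, tp, cc, seed = 6)
  idx <- build_window_index(cat_, 1000)
  v <- sample_abundance(rs, cat_, idx, sample_id = "S")
  n <- nrow(rs)
  for (g in names(tp$abundance)) {
    sd_g <- sqrt(tp$abundance[g] * (1 - tp$abundance[g]) / n)
    expect_lt(abs(v$p[g] - tp$abundance[g]), 3 * sd_g + 1e-3)
  }
})

test_that("doubling read depth leaves estimated abundances unchanged in expectation", {
  cc1 <- community_config(n_sgbs = 5, genome_length_bp = 10000,
                          window_length_bp = 1000, n_reads = 10000,
                          host_fraction = 0, junk_fraction = 0, seed = 31)
  cc2 <- community_config(n_sgbs = 5, genome_length_bp = 10000,
                          window_length_bp = 1000, n_reads = 20000,
                          host_fraction = 0, junk_fraction = 0, seed = 31)
  cat_ <- generate_reference_catalog(cc1)
  tp <- random_truth_profile(cat_, "S")
  idx <- build_window_index(cat_, 1000)
  v1 <- sample_abundance(simulate_sample_reads(cat_, tp, cc1, seed = 1),
                         cat_, idx)
  v2 <- sample_abundance(simulate_sample_reads(cat_, tp, cc2, seed = 2),
                         cat_, idx)
  expect_equal(unname(v1$p), unname(v2$p), tolerance = 0.05)
})
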