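# Independent oracles and tiny fixture builders used across the suite.

# Exhaustive all-position, both-strand mapping oracle: scores every fully
# contained placement by matches - mismatches and applies the same
# threshold/tie rules as the mapper. Intentionally brute force.
oracle_map_read <- function(read, genomes, min_score_frac = 0.5) {
  L <- nchar(read)
  min_score <- ceiling(min_score_frac * L)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  best <- -Inf
  n_best <- 0L
  hit <- list(sgb = NA_character_, pos = NA_integer_, strand = NA_integer_)
  for (g in names(genomes)) {
    gch <- strsplit(genomes[[g]], "")[[1]]
    Lg <- length(gch)
    if (Lg < L) next
    n_pos <- Lg - L + 1L
    for (strand in c(1L, -1L)) {
      rch <- strsplit(if (strand == 1L) read else rc, "")[[1]]
      # score every placement at once: accumulate per-offset match vectors
      matches <- integer(n_pos)
      for (j in seq_len(L)) {
        matches <- matches + (gch[j:(j + n_pos - 1L)] == rch[j])
      }
      sc <- 2L * matches - L
      mx <- max(sc)
      if (mx > best) {
        best <- mx
        n_best <- sum(sc == mx)
        hit <- list(sgb = g, pos = which.max(sc) - 1L, strand = strand)
      } else if (mx == best) {
        n_best <- n_best + sum(sc == mx)
      }
    }
  }
  status <- if (n_best == 0L || best < min_score) "unmapped"
            else if (n_best == 1L) "unique" else "ambiguous"
  list(status = status, sgb = hit$sgb, pos = hit$pos, strand = hit$strand,
       score = best, n_best = n_best)
}

# One random mapper-oracle instance: a few random genomes with an optional
# planted cross-genome duplication, reads drawn with at most one
# substitution (so every true placement carries an exact 31-mer seed) plus
# random unmappable reads.
make_oracle_instance <- function(n_genomes = 3, genome_len = 1500,
                                 n_reads = 30, read_len = 80,
                                 dup_len = 200) {
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
  genomes <- stats::setNames(
    vapply(seq_len(n_genomes), function(i) rand_dna(genome_len), ""),
    paste0("G", seq_len(n_genomes)))
  # plant a shared segment in genomes 1 and 2 to create ambiguous reads
  seg <- substr(genomes[[1]], 101, 100 + dup_len)
  substr(genomes[[2]], 301, 300 + dup_len) <- seg
  reads <- character(n_reads)
  for (i in seq_len(n_reads)) {
    kind <- sample(c("clean", "err1", "dup", "junk"), 1,
                   prob = c(0.35, 0.3, 0.2, 0.15))
    if (kind == "junk") {
      reads[i] <- rand_dna(read_len)
      next
    }
    g <- if (kind == "dup") 1L else sample.int(n_genomes, 1)
    start <- if (kind == "dup") sample(101:(100 + dup_len - read_len), 1)
             else sample.int(genome_len - read_len + 1, 1)
    r <- substr(genomes[[g]], start, start + read_len - 1)
    if (sample(c(TRUE, FALSE), 1)) {
      r <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(r)))
    }
    if (kind == "err1") {
      p <- sample.int(read_len, 1)
      old <- substr(r, p, p)
      substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
    }
    reads[i] <- r
  }
  list(genomes = genomes, reads = reads)
}

# count agreements between the mapper and the oracle on one instance
mapper_oracle_agreement <- function(inst, min_score_frac = 0.5) {
  rs <- read_set(paste0("r", seq_along(inst$reads)), inst$reads,
                 strrep("I", nchar(inst$reads)))
  idx <- build_window_index(
    stats::setNames(nchar(inst$genomes), names(inst$genomes)), 500)
  got <- unique_best_map(rs, inst$genomes, idx,
                         min_score_frac = min_score_frac)
  agree <- 0L
  for (i in seq_along(inst$reads)) {
    o <- oracle_map_read(inst$reads[i], inst$genomes, min_score_frac)
    same <- got$status[i] == o$status
    if (same && o$status == "unique") {
      same <- got$sgb_id[i] == o$sgb && got$pos[i] == o$pos
    }
    agree <- agree + as.integer(same)
  }
  c(agree = agree, n = length(inst$reads))
}

# Exact two-sided Mann-Whitney p by full enumeration (doubling the smaller
# tail, capped at 1); midranks for ties.
mw_exact_oracle <- function(x, y) {
  n1 <- length(x)
  all_v <- c(x, y)
  r <- rank(all_v)
  u_of <- function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(length(all_v), n1)
  us <- apply(combs, 2, u_of)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
# with the point-probability rule.
fisher_exact_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(ks, r1, n - r1, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg step-up by hand.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

int_to_qual_chr <- function(v) intToUtf8(v + 33L)

# run a one-feature rank-test scan on paired vectors
scan_one <- function(x, groups, exact_max = 8) {
  feats <- data.frame(sample_id = paste0("S", seq_along(x)), f = x)
  meta <- data.frame(sample_id = paste0("S", seq_along(x)), g = groups)
  rank_test_scan(feats, meta, "g", exact_max = exact_max)
}

# small shared fixtures -----------------------------------------------------
tiny_catalog <- function(n_sgbs = 12, genome_length_bp = 4000,
                         window_length_bp = 500, seed = 42, ...) {
  generate_reference_catalog(community_config(
    n_sgbs = n_sgbs, genome_length_bp = genome_length_bp,
    window_length_bp = window_length_bp, seed = seed, ...))
}

feature_catalog <- function(seed = 11) {
  generate_reference_catalog(community_config(
    n_sgbs = 50, genome_length_bp = 1000, window_length_bp = 500,
    seed = seed))
}
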