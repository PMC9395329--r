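# Synthetic community: toy SGB catalogs, a host genome, and shotgun reads
# drawn from a known relative-abundance profile, so the whole abundance
# pipeline can be checked against ground truth.

# Fixed adapter used for junk reads; matches common Illumina adapter length.
DEFAULT_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

#' Configuration for the synthetic community generator
#'
#' @param n_sgbs number of species-level genome bins (SGBs) in the toy
#'   catalog.
#' @param genome_length_bp length of each SGB genome.
#' @param n_reads reads simulated per sample.
#' @param read_length_bp read length.
#' @param base_error_rate per-base substitution probability.
#' @param host_fraction expected fraction of reads drawn from the host
#'   genome.
#' @param junk_fraction expected fraction of adapter-carrying or low-quality
#'   reads.
#' @param alpha concentration of the symmetric Dirichlet abundance prior.
#' @param adapter adapter sequence planted in junk reads.
#' @param window_length_bp window length the catalog will be indexed at;
#'   genomes must be at least one window long.
#' @param n_butyrate,n_acetate how many species to flag as butyrate/acetate
#'   producers (butyrate defaults to the 24 literature species the feature
#'   sum is built from).
#' @param host_genome_length_bp length of the synthetic host genome.
#' @param seed integer seed fixing every generated byte.
#' @return A `community_config` list.
#' @export
community_config <- function(n_sgbs = 30, genome_length_bp = 50000,
                             n_reads = 200000, read_length_bp = 100,
                             base_error_rate = 0.005, host_fraction = 0.1,
                             junk_fraction = 0.05, alpha = 0.5,
                             adapter = DEFAULT_ADAPTER,
                             window_length_bp = 1000,
                             n_butyrate = 24, n_acetate = 10,
                             host_genome_length_bp = 100000, seed = 1) {
  stopifnot(n_sgbs >= 1, genome_length_bp >= 1, n_reads >= 1,
            read_length_bp >= 1, base_error_rate >= 0, base_error_rate < 1,
            host_fraction >= 0, junk_fraction >= 0, alpha > 0,
            window_length_bp >= 1)
  if (host_fraction + junk_fraction >= 1) {
    stop("host_fraction + junk_fraction must be < 1")
  }
  if (genome_length_bp < window_length_bp) {
    stop("genome_length_bp must be at least one window (",
         window_length_bp, " bp)")
  }
  structure(list(n_sgbs = n_sgbs, genome_length_bp = genome_length_bp,
                 n_reads = n_reads, read_length_bp = read_length_bp,
                 base_error_rate = base_error_rate,
                 host_fraction = host_fraction,
                 junk_fraction = junk_fraction, alpha = alpha,
                 adapter = adapter, window_length_bp = window_length_bp,
                 n_butyrate = n_butyrate, n_acetate = n_acetate,
                 host_genome_length_bp = host_genome_length_bp,
                 seed = as.integer(seed)),
            class = "community_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Taxonomy scaffold: realistic phylum/family pools, dominated by Firmicutes
# and Bacteroidetes as in canine stool.
PHYLUM_POOL <- c(Firmicutes = 0.50, Bacteroidetes = 0.25,
                 Proteobacteria = 0.10, Actinobacteria = 0.10,
                 Fusobacteria = 0.05)
FAMILY_POOL <- list(
  Firmicutes = c("Lachnospiraceae", "Ruminococcaceae", "Lactobacillaceae",
                 "Clostridiaceae"),
  Bacteroidetes = c("Bacteroidaceae", "Prevotellaceae"),
  Proteobacteria = c("Enterobacteriaceae", "Sutterellaceae"),
  Actinobacteria = c("Coriobacteriaceae", "Bifidobacteriaceae"),
  Fusobacteria = c("Fusobacteriaceae"))

#' Generate a synthetic SGB reference catalog and host genome
#'
#' Produces `n_sgbs` random genomes with a species/genus/family/phylum
#' taxonomy (always containing Firmicutes and Bacteroidetes), assembly
#' counts, butyrate/acetate-producer flags, and one host genome distinct
#' from all SGB genomes. Every SGB satisfies the catalog inclusion rule
#' (unique genus or at least 5 assemblies), mirroring a pre-filtered
#' reference set. Deterministic under `config$seed`.
#'
#' @param config a [community_config()].
#' @return An `sgb_catalog`: list with `taxonomy` (data.frame),
#'   `genomes` (named character vector), `host` (character scalar) and the
#'   `config` used.
#' @export
generate_reference_catalog <- function(config) {
  stopifnot(inherits(config, "community_config"))
  set.seed(config$seed)
  n <- config$n_sgbs

  # round-robin phylum assignment at fixed proportions, Firmicutes and
  # Bacteroidetes guaranteed first
  counts <- diff(round(cumsum(c(0, PHYLUM_POOL)) * n))  # sums exactly to n
  phyla <- rep(names(PHYLUM_POOL), times = counts)[seq_len(n)]
  family <- unlist(Map(function(p, i) {
    pool <- FAMILY_POOL[[p]]
    pool[1L + (i %% length(pool))]
  }, phyla, seq_len(n) - 1L), use.names = FALSE)

  # every other SGB shares a genus with its neighbour; shared-genus SGBs get
  # >= 5 assemblies so the whole default catalog passes the inclusion rule
  genus <- sprintf("Genus_%02d", ceiling(seq_len(n) / 2))
  shared <- duplicated(genus) | duplicated(genus, fromLast = TRUE)
  n_assemblies <- ifelse(shared, sample(5:30, n, replace = TRUE),
                         sample(1:30, n, replace = TRUE))

  species <- sprintf("Species_%02d", seq_len(n))
  sgb_id <- sprintf("SGB_%02d", seq_len(n))

  # flag butyrate producers Firmicutes-first (most literature butyrate
  # producers are Firmicutes), then acetate producers
  ord <- order(phyla != "Firmicutes", seq_len(n))
  butyrate_flag <- logical(n)
  butyrate_flag[ord[seq_len(min(config$n_butyrate, n))]] <- TRUE
  acetate_flag <- logical(n)
  acetate_flag[ord[seq_len(min(config$n_acetate, n))]] <- TRUE

  genomes <- stats::setNames(
    vapply(seq_len(n), function(i) random_dna(config$genome_length_bp), ""),
    sgb_id)
  host <- random_dna(config$host_genome_length_bp)

  taxonomy <- data.frame(sgb_id = sgb_id, species = species, genus = genus,
                         family = family, phylum = phyla,
                         n_assemblies = n_assemblies,
                         genome_length_bp = config$genome_length_bp,
                         butyrate_flag = butyrate_flag,
                         acetate_flag = acetate_flag,
                         stringsAsFactors = FALSE)
  structure(list(taxonomy = taxonomy, genomes = genomes, host = host,
                 config = config),
            class = "sgb_catalog")
}

#' Construct a ground-truth abundance profile
#'
#' @param sample_id sample identifier.
#' @param abundance named non-negative vector over SGB ids; normalized to
#'   sum to 1.
#' @param host_fraction host fraction used when simulating this sample.
#' @param seed seed used when simulating this sample.
#' @return A `truth_profile` list.
#' @export
truth_profile <- function(sample_id, abundance, host_fraction = 0,
                          seed = NA_integer_) {
  stopifnot(all(abundance >= 0), sum(abundance) > 0,
            !is.null(names(abundance)))
  abundance <- abundance / sum(abundance)
  stopifnot(abs(sum(abundance) - 1) < 1e-9)
  structure(list(sample_id = sample_id, abundance = abundance,
                 host_fraction = host_fraction, seed = seed),
            class = "truth_profile")
}

#' Draw a random truth profile from the catalog's Dirichlet prior
#'
#' @param catalog an `sgb_catalog`.
#' @param sample_id sample identifier.
#' @param alpha Dirichlet concentration (defaults to the catalog config's).
#' @return A [truth_profile()].
#' @export
random_truth_profile <- function(catalog, sample_id = "S1", alpha = NULL) {
  if (is.null(alpha)) alpha <- catalog$config$alpha
  g <- stats::rgamma(nrow(catalog$taxonomy), shape = alpha, rate = 1)
  # guard against an all-zero draw at tiny alpha
  if (sum(g) == 0) g[1] <- 1
  truth_profile(sample_id,
                stats::setNames(g / sum(g), catalog$taxonomy$sgb_id))
}

#' Simulate one sample's shotgun reads from a known truth profile
#'
#' Non-host, non-junk reads are drawn uniformly from a genome chosen with
#' probability proportional to `true_abundance * genome_length` (so per-base
#' coverage is proportional to abundance), from either strand, with bases
#' substituted at `base_error_rate`. Host reads are drawn from the host
#' genome at `host_fraction`. Junk reads carry the configured adapter or
#' uniformly low base qualities. Provenance is recorded per read.
#'
#' @param catalog an `sgb_catalog` from [generate_reference_catalog()].
#' @param truth a [truth_profile()] over the catalog's SGBs.
#' @param config a [community_config()].
#' @param seed seed for this sample's draw.
#' @return A [read_set()] with `source` set to the true origin.
#' @export
simulate_sample_reads <- function(catalog, truth, config = catalog$config,
                                  seed = config$seed) {
  stopifnot(inherits(catalog, "sgb_catalog"), inherits(truth, "truth_profile"))
  ids <- catalog$taxonomy$sgb_id
  if (!identical(sort(names(truth$abundance)), sort(ids))) {
    stop("truth abundance vector does not match the catalog's SGB ids")
  }
  set.seed(seed)
  n <- config$n_reads
  rl <- config$read_length_bp

  u <- stats::runif(n)
  is_host <- u < config$host_fraction
  is_junk <- !is_host & u < config$host_fraction + config$junk_fraction
  junk_adapter <- is_junk & (stats::runif(n) < 0.5)
  junk_lowqual <- is_junk & !junk_adapter

  # microbial source genome: abundance x genome length
  glen <- nchar(catalog$genomes)[ids]
  w <- truth$abundance[ids] * glen
  src <- rep(NA_character_, n)
  mic <- !is_host & !is_junk
  src[mic] <- ids[sample.int(length(ids), sum(mic), replace = TRUE,
                             prob = w / sum(w))]
  src[is_host] <- "host"
  # adapter junk still gets a backbone sequence drawn from the community
  src[is_junk] <- ids[sample.int(length(ids), sum(is_junk), replace = TRUE,
                                 prob = w / sum(w))]

  seqs <- character(n)
  for (g in unique(src[!is_host])) {
    idx <- which(src == g & !is_host)
    L <- nchar(catalog$genomes[[g]])
    starts <- sample.int(L - rl + 1, length(idx), replace = TRUE)
    seqs[idx] <- substring(catalog$genomes[[g]], starts, starts + rl - 1)
  }
  if (any(is_host)) {
    idx <- which(is_host)
    L <- nchar(catalog$host)
    starts <- sample.int(L - rl + 1, length(idx), replace = TRUE)
    seqs[idx] <- substring(catalog$host, starts, starts + rl - 1)
  }

  # strand
  flip <- stats::runif(n) < 0.5
  if (any(flip)) seqs[flip] <- revcomp_chr(seqs[flip])

  # substitution errors, applied in vectorized rounds (one error per round;
  # rare within-read position collisions just re-substitute the same base)
  n_err <- stats::rbinom(n, rl, config$base_error_rate)
  bases <- c("A", "C", "G", "T")
  if (any(n_err > 0)) {
    for (round in seq_len(max(n_err))) {
      idx <- which(n_err >= round)
      pos <- sample.int(rl, length(idx), replace = TRUE)
      s <- seqs[idx]
      old <- substring(s, pos, pos)
      shift <- sample.int(3, length(idx), replace = TRUE)
      new <- bases[((match(old, bases) - 1L + shift) %% 4L) + 1L]
      new[is.na(new)] <- "A"  # non-ACGT base: overwrite with A
      substr(s, pos, pos) <- new
      seqs[idx] <- s
    }
  }

  # plant the adapter in adapter-junk reads
  if (any(junk_adapter)) {
    ad <- config$adapter
    la <- nchar(ad)
    if (la > rl) stop("adapter longer than read length")
    idx <- which(junk_adapter)
    starts <- sample.int(rl - la + 1, length(idx), replace = TRUE)
    for (j in seq_along(idx)) {
      s <- seqs[idx[j]]
      substr(s, starts[j], starts[j] + la - 1) <- ad
      seqs[idx[j]] <- s
    }
    src[idx] <- "junk_adapter"
  }

  # per-read uniform qualities: good reads Q33-40, low-quality junk Q2-12
  q <- sample(33:40, n, replace = TRUE)
  if (any(junk_lowqual)) {
    q[junk_lowqual] <- sample(2:12, sum(junk_lowqual), replace = TRUE)
    src[junk_lowqual] <- "junk_lowqual"
  }
  qmap <- vapply(0:60, int_to_qual, "")
  quals <- strrep(qmap[q + 1L], rl)

  read_set(id = sprintf("%s_r%07d", truth$sample_id, seq_len(n)),
           seq = seqs, qual = quals, source = src)
}
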