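# End-to-end orchestration: simulate (optional) -> QC -> host screen ->
# subsample -> abundance -> features -> association scans -> prediction,
# with one frozen config, seeded RNG and a manifest of every artifact.

#' Configuration for a full pipeline run
#'
#' Either a synthetic source (`community` + cohort settings) or paths to
#' real inputs (`reads_dir` with `<sample>.fastq`, `catalog_fasta`,
#' `taxonomy_tsv`, optional `host_fasta`, optional `metadata_tsv`). When
#' metadata is absent, association and prediction are skipped with
#' warnings.
#'
#' @param out_dir output directory.
#' @param seed master seed; every stage derives its seed from it.
#' @param synthetic generate inputs with the synthetic module?
#' @param community a [community_config()] (synthetic mode).
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param n_dogs cohort size (synthetic mode).
#' @param effects list of [effect_spec()]s (synthetic mode).
#' @param reads_dir,catalog_fasta,taxonomy_tsv,host_fasta,metadata_tsv
#'   input paths (real-data mode).
#' @param qc a [qc_config()].
#' @param tau,cap_mode detection-cap parameters.
#' @param association_method,association_level multiple-testing method
#'   (`"bonferroni"` or `"bh_fdr"`; no silent default between the two in
#'   scans — this is the pipeline-level choice) and level.
#' @param k_folds,booster prediction settings.
#' @param grouping trait grouping rule (`"median"` or named list of
#'   thresholds).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1, synthetic = TRUE,
                       community = community_config(),
                       cohort = cohort_config(), n_dogs = 24,
                       effects = list(),
                       reads_dir = NULL, catalog_fasta = NULL,
                       taxonomy_tsv = NULL, host_fasta = NULL,
                       metadata_tsv = NULL,
                       qc = qc_config(), tau = 1e-4, cap_mode = "floor",
                       association_method = "bh_fdr",
                       association_level = 0.15,
                       k_folds = 3, booster = booster_params(),
                       grouping = "median") {
  if (!synthetic) {
    paths <- list(reads_dir, catalog_fasta, taxonomy_tsv)
    if (any(vapply(paths, is.null, TRUE)) ||
        !all(file.exists(unlist(paths)))) {
      stop("real-data mode needs existing reads_dir, catalog_fasta ",
           "and taxonomy_tsv")
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, community = community,
                 cohort = cohort, n_dogs = n_dogs, effects = effects,
                 reads_dir = reads_dir, catalog_fasta = catalog_fasta,
                 taxonomy_tsv = taxonomy_tsv, host_fasta = host_fasta,
                 metadata_tsv = metadata_tsv, qc = qc, tau = tau,
                 cap_mode = cap_mode,
                 association_method = association_method,
                 association_level = association_level,
                 k_folds = k_folds, booster = booster,
                 grouping = grouping),
            class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis
#'
#' Executes every stage on the configured inputs and writes all
#' intermediate and final tables plus a `manifest.tsv` (parameters and md5
#' of every artifact) under `config$out_dir`. Rerunning with the same
#' config and seed reproduces every file byte for byte.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest path.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character()
  log_file <- function(p) artifacts <<- c(artifacts, p)

  # --- inputs: synthetic or from disk -------------------------------------
  if (config$synthetic) {
    catalog <- generate_reference_catalog(config$community)
    coh <- generate_cohort(catalog, n_dogs = config$n_dogs,
                           effects = config$effects,
                           config = config$cohort,
                           seed = config$seed + 1000L)
    metadata <- coh$metadata
    truths <- coh$truths
    log_file(write_fasta(catalog$genomes, out("catalog.fasta")))
    log_file(write_fasta(c(host = catalog$host), out("host.fasta")))
    log_file(write_tsv(catalog$taxonomy, out("taxonomy.tsv")))
    log_file(write_tsv(metadata, out("metadata.tsv")))
    log_file(write_tsv(
      data.frame(dog_id = rownames(truths), truths, check.names = FALSE),
      out("truth_profiles.tsv")))
    host <- catalog$host
    sample_ids <- metadata$dog_id
  } else {
    genomes <- read_fasta(config$catalog_fasta)
    taxonomy <- utils::read.delim(config$taxonomy_tsv,
                                  stringsAsFactors = FALSE)
    catalog <- structure(list(taxonomy = taxonomy, genomes = genomes,
                              host = NULL, config = NULL),
                         class = "sgb_catalog")
    host <- if (!is.null(config$host_fasta)) {
      unname(read_fasta(config$host_fasta))
    } else NULL
    metadata <- if (!is.null(config$metadata_tsv)) {
      utils::read.delim(config$metadata_tsv, stringsAsFactors = FALSE)
    } else NULL
    truths <- NULL
    fq <- list.files(config$reads_dir, pattern = "\\.fastq(\\.gz)?$",
                     full.names = TRUE)
    sample_ids <- sub("\\.fastq(\\.gz)?$", "", basename(fq))
  }

  # catalog inclusion rule + window index
  filt <- filter_sgbs(catalog$taxonomy)
  catalog$taxonomy <- filt$kept
  catalog$genomes <- catalog$genomes[filt$kept$sgb_id]
  log_file(write_tsv(filt$dropped, out("sgbs_dropped.tsv")))
  index <- build_window_index(catalog,
                              window_length_bp =
                                if (config$synthetic)
                                  config$community$window_length_bp
                                else 1000)

  # --- per-sample reads -> abundance --------------------------------------
  vectors <- list()
  qc_summary <- list()
  for (i in seq_along(sample_ids)) {
    sid <- sample_ids[i]
    reads <- if (config$synthetic) {
      tp <- truth_profile(sid, truths[sid, ],
                          host_fraction = config$community$host_fraction)
      simulate_sample_reads(catalog, tp, config$community,
                            seed = config$seed + 2000L + i)
    } else {
      read_fastq(file.path(config$reads_dir, paste0(sid, ".fastq")))
    }
    qcres <- quality_filter(reads, config$qc)
    kept <- qcres$reads
    if (!is.null(host)) kept <- host_screen(kept, host, config$qc)
    kept <- withCallingHandlers(
      subsample_reads(kept, depth = config$qc$subsample_depth,
                      seed = config$seed + 3000L + i),
      warning = function(w) invokeRestart("muffleWarning"))
    v <- sample_abundance(kept, catalog, index, sample_id = sid)
    vectors[[sid]] <- apply_detection_cap(v, tau = config$tau,
                                          mode = config$cap_mode)
    qc_summary[[sid]] <- data.frame(
      sample_id = sid, n_input = nrow(reads), n_qc = nrow(qcres$reads),
      n_after_host = nrow(kept), stringsAsFactors = FALSE)
  }
  log_file(write_tsv(do.call(rbind, qc_summary), out("qc_summary.tsv")))

  raw <- t(vapply(vectors, function(v) {
    p <- v$cover
    ex <- v$exists
    q <- stats::setNames(numeric(length(p)), names(p))
    if (any(ex)) q[ex] <- p[ex] / sum(p[ex])
    q
  }, numeric(length(vectors[[1]]$p))))
  rownames(raw) <- names(vectors)
  capped <- abundance_table(vectors)
  log_file(write_tsv(
    data.frame(sample_id = rownames(capped), capped, check.names = FALSE),
    out("abundance.tsv")))

  # --- features -----------------------------------------------------------
  # small catalogs may not carry every default aggregate label; restrict the
  # manifest to computable entries
  manifest <- default_feature_manifest()
  avail <- function(f) {
    m <- regmatches(f, regexec("^(phylum|family|genus)_(.+)$", f))[[1]]
    length(m) == 0 || m[3] %in% catalog$taxonomy[[m[2]]]
  }
  manifest <- manifest[vapply(manifest, avail, TRUE)]
  feats <- assemble_feature_table(raw, catalog$taxonomy, manifest = manifest,
                                  tau = config$tau)
  log_file(write_tsv(feats, out("features.tsv")))
  if (nrow(feats) >= 3) {
    pc <- beta_diversity_pcoa(raw)
    log_file(write_tsv(
      data.frame(sample_id = rownames(pc$coords), pc$coords,
                 check.names = FALSE),
      out("pcoa_coordinates.tsv")))
  }

  # --- association + prediction (need metadata) ---------------------------
  assoc <- NULL
  reports <- list()
  if (is.null(metadata)) {
    warning("no metadata: association and prediction stages skipped")
  } else {
    scans <- list()
    for (tr in intersect(c(dog_traits(), "bcs"), names(metadata))) {
      sc <- rank_test_scan(feats, metadata, tr)
      if (nrow(sc) > 0) {
        scans[[tr]] <- adjust_pvalues(sc, config$association_method,
                                      config$association_level)
      }
    }
    if ("age" %in% names(metadata)) {
      sc <- pearson_scan(feats, metadata, "age")
      if (nrow(sc) > 0) {
        scans[["age"]] <- adjust_pvalues(sc, config$association_method,
                                         config$association_level)
      }
    }
    assoc <- do.call(rbind, scans)
    rownames(assoc) <- NULL
    log_file(write_tsv(assoc, out("associations.tsv")))

    traits <- intersect(c(dog_traits(), "gi_issues"), names(metadata))
    rows <- list()
    for (tr in traits) {
      rule <- if (is.list(config$grouping) && !is.null(config$grouping[[tr]]))
        config$grouping[[tr]] else config$grouping
      rep <- tryCatch(
        predict_trait(feats, metadata, tr, rule = rule,
                      k = config$k_folds, seed = config$seed + 4000L,
                      params = config$booster),
        error = function(e) e)
      if (inherits(rep, "error")) {
        warning("prediction skipped for ", tr, ": ", conditionMessage(rep))
        next
      }
      reports[[tr]] <- rep
      rows[[tr]] <- data.frame(
        trait = tr, n_used = rep$n_used,
        n_excluded_puppies = rep$n_excluded_puppies, k = rep$k,
        mean_auc = rep$mean_auc, sd_auc = rep$sd_auc,
        mean_accuracy = rep$mean_accuracy, sd_accuracy = rep$sd_accuracy,
        stringsAsFactors = FALSE)
    }
    if (length(rows) > 0) {
      log_file(write_tsv(do.call(rbind, rows), out("predictions.tsv")))
    }
  }

  # --- manifest -----------------------------------------------------------
  params <- data.frame(
    key = c("seed", "synthetic", "n_samples", "window_length_bp", "tau",
            "cap_mode", "association_method", "association_level",
            "k_folds"),
    value = c(config$seed, config$synthetic, length(sample_ids),
              index$window_length_bp, format(config$tau), config$cap_mode,
              config$association_method, config$association_level,
              config$k_folds),
    stringsAsFactors = FALSE)
  files <- data.frame(key = paste0("md5:", basename(artifacts)),
                      value = unname(tools::md5sum(artifacts)),
                      stringsAsFactors = FALSE)
  manifest <- rbind(params, files)
  write_tsv(manifest, out("manifest.tsv"))

  invisible(list(catalog = catalog, metadata = metadata, truths = truths,
                 abundance = capped, abundance_raw = raw, features = feats,
                 associations = assoc, predictions = reports,
                 manifest = out("manifest.tsv")))
}
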