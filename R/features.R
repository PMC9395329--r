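# Microbiome feature derivation: alpha diversity, taxon aggregates,
# SCFA-producer sums, Firmicutes/Bacteroidetes ratio, Bray-Curtis PCoA, and
# the assembled per-sample feature table.

#' Richness and Shannon diversity of one abundance profile
#'
#' Richness `S` counts species with raw (pre-floor) relative abundance at
#' least `tau`; Shannon `H = -sum(q log q)` (nats) over the detected
#' species with their abundances renormalized to sum to 1. `S = 0` yields
#' `H = 0`.
#'
#' @param p named numeric vector of raw relative abundances (pre-cap).
#' @param tau detection threshold (default `1e-4`).
#' @return Named list `list(S, H)`.
#' @export
compute_alpha_diversity <- function(p, tau = 1e-4) {
  if (inherits(p, "abundance_vector")) p <- p$p
  detected <- p[p >= tau]
  S <- length(detected)
  if (S == 0) return(list(S = 0L, H = 0))
  q <- detected / sum(detected)
  H <- -sum(q * log(q))
  list(S = S, H = H)
}

#' Aggregate species abundances at a taxonomic rank
#'
#' @param abund samples x SGBs abundance matrix (colnames = SGB ids).
#' @param taxonomy taxonomy data.frame with `sgb_id` and the rank column.
#' @param rank `"phylum"`, `"family"` or `"genus"`.
#' @return Samples x labels matrix of summed abundances.
#' @export
aggregate_taxa <- function(abund, taxonomy, rank = c("phylum", "family",
                                                     "genus")) {
  rank <- match.arg(rank)
  abund <- as_abund_matrix(abund)
  lab <- taxonomy[[rank]][match(colnames(abund), taxonomy$sgb_id)]
  bad <- is.na(lab) | lab == ""
  if (any(bad)) {
    stop("missing ", rank, " label for SGB(s): ",
         paste(colnames(abund)[bad], collapse = ", "))
  }
  t(rowsum(t(abund), group = lab))
}

#' Summed abundance of SCFA-producing species
#'
#' @param abund samples x SGBs abundance matrix.
#' @param producers character vector of producer species names (e.g. the 24
#'   literature butyrate producers).
#' @param taxonomy taxonomy mapping `species` to `sgb_id`.
#' @return Numeric vector, one sum per sample.
#' @export
scfa_producer_sum <- function(abund, producers, taxonomy) {
  abund <- as_abund_matrix(abund)
  missing_sp <- setdiff(producers, taxonomy$species)
  if (length(missing_sp) > 0) {
    stop("producer species absent from the catalog: ",
         paste(missing_sp, collapse = ", "))
  }
  ids <- taxonomy$sgb_id[taxonomy$species %in% producers]
  rowSums(abund[, colnames(abund) %in% ids, drop = FALSE])
}

#' Firmicutes / Bacteroidetes ratio
#'
#' Summed Firmicutes abundance divided by summed Bacteroidetes abundance
#' (the taxonomy's phylum label is used verbatim, so a catalog labelling the
#' phylum "Bacteroides" works equally). A zero denominator yields `NA`.
#'
#' @param abund samples x SGBs abundance matrix.
#' @param taxonomy taxonomy with a `phylum` column.
#' @return Numeric vector, one ratio per sample (`NA` where undefined).
#' @export
fb_ratio <- function(abund, taxonomy) {
  agg <- aggregate_taxa(abund, taxonomy, "phylum")
  bac_label <- intersect(c("Bacteroidetes", "Bacteroides"), colnames(agg))
  if (!"Firmicutes" %in% colnames(agg) || length(bac_label) == 0) {
    stop("taxonomy must contain both Firmicutes and Bacteroidetes/",
         "Bacteroides phyla")
  }
  f <- agg[, "Firmicutes"]
  b <- agg[, bac_label[1]]
  ifelse(b > 0, f / b, NA_real_)
}

#' Bray-Curtis beta diversity and principal coordinates
#'
#' Pairwise Bray-Curtis dissimilarity followed by classical scaling
#' (double-centered `-BC^2/2`, eigendecomposition). Negative-eigenvalue
#' axes are reported but dropped from the coordinates.
#'
#' @param abund samples x SGBs abundance matrix (>= 3 samples).
#' @return List with `bc` (dissimilarity matrix), `coords` (samples x
#'   positive axes) and `eigenvalues` (all, decreasing).
#' @export
beta_diversity_pcoa <- function(abund) {
  abund <- as_abund_matrix(abund)
  stopifnot(nrow(abund) >= 3)
  d <- vegan::vegdist(abund, method = "bray")
  if (all(d == 0)) {
    coords <- matrix(0, nrow(abund), 1,
                     dimnames = list(rownames(abund), "PCo1"))
    return(list(bc = as.matrix(d), coords = coords,
                eigenvalues = rep(0, nrow(abund) - 1)))
  }
  sc <- stats::cmdscale(d, k = nrow(abund) - 1, eig = TRUE)
  eig <- sort(sc$eig, decreasing = TRUE)
  pos <- which(sc$eig > sqrt(.Machine$double.eps))
  coords <- sc$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(bc = as.matrix(d), coords = coords, eigenvalues = eig)
}

#' The default 13-column summary-feature manifest
#'
#' Richness, Shannon diversity, butyrate- and acetate-producer sums, the
#' F/B ratio, five phylum aggregates and three Firmicutes family
#' aggregates.
#'
#' @return Character vector of 13 feature names.
#' @export
default_feature_manifest <- function() {
  c("richness", "shannon", "butyrate_producers", "acetate_producers",
    "fb_ratio",
    "phylum_Firmicutes", "phylum_Bacteroidetes", "phylum_Proteobacteria",
    "phylum_Actinobacteria", "phylum_Fusobacteria",
    "family_Lachnospiraceae", "family_Ruminococcaceae",
    "family_Lactobacillaceae")
}

#' Assemble the per-sample feature table
#'
#' One row per sample: the summary-feature block named by `manifest`
#' (entries are `richness`, `shannon`, `butyrate_producers`,
#' `acetate_producers`, `fb_ratio`, or `<rank>_<label>` aggregates) followed
#' by every species abundance. Computed from raw (pre-cap) relative
#' abundances; richness/detection are evaluated against `tau`.
#'
#' @param abund samples x SGBs raw abundance matrix.
#' @param taxonomy the catalog taxonomy (flags `butyrate_flag` /
#'   `acetate_flag` supply the default producer lists).
#' @param manifest summary-feature names (default
#'   [default_feature_manifest()], 13 columns).
#' @param tau detection threshold for richness/Shannon.
#' @param butyrate,acetate optional explicit producer species lists.
#' @return A `feature_table` data.frame: `sample_id`, summary block,
#'   species columns (named by species label).
#' @export
assemble_feature_table <- function(abund, taxonomy,
                                   manifest = default_feature_manifest(),
                                   tau = 1e-4, butyrate = NULL,
                                   acetate = NULL) {
  abund <- as_abund_matrix(abund)
  if (is.null(butyrate)) butyrate <- taxonomy$species[taxonomy$butyrate_flag]
  if (is.null(acetate)) acetate <- taxonomy$species[taxonomy$acetate_flag]
  aggs <- list(phylum = aggregate_taxa(abund, taxonomy, "phylum"),
               family = aggregate_taxa(abund, taxonomy, "family"),
               genus = aggregate_taxa(abund, taxonomy, "genus"))
  alpha <- apply(abund, 1, compute_alpha_diversity, tau = tau)

  out <- data.frame(sample_id = rownames(abund), stringsAsFactors = FALSE)
  for (f in manifest) {
    out[[f]] <- switch(
      f,
      richness = vapply(alpha, `[[`, 0L, "S"),
      shannon = vapply(alpha, `[[`, 0.0, "H"),
      butyrate_producers = scfa_producer_sum(abund, butyrate, taxonomy),
      acetate_producers = scfa_producer_sum(abund, acetate, taxonomy),
      fb_ratio = fb_ratio(abund, taxonomy),
      {
        m <- regmatches(f, regexec("^(phylum|family|genus)_(.+)$", f))[[1]]
        if (length(m) == 0 || !m[3] %in% colnames(aggs[[m[2]]])) {
          stop("manifest names an uncomputed feature: ", f)
        }
        aggs[[m[2]]][, m[3]]
      })
  }
  species <- taxonomy$species[match(colnames(abund), taxonomy$sgb_id)]
  sp <- as.data.frame(abund)
  names(sp) <- species
  out <- cbind(out, sp)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  attr(out, "manifest") <- manifest
  out
}

as_abund_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) x <- abundance_table(x)
  if (is.data.frame(x)) x <- as.matrix(x)
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
  x
}
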