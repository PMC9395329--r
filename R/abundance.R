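# The core abundance estimator: unique best-hit read assignment, per-window
# counts, dense mean cover, existence calls, relative abundance, and the
# detection cap.

#' Unique best-hit mapping of reads against the SGB catalog
#'
#' Built-in mode seeds candidate placements with exact k-mer matches on both
#' strands and scores each candidate by ungapped extension (+1 match, -1
#' mismatch, read fully contained). A read is `unique` iff its maximum score
#' is reached at exactly one (SGB, position, strand) and clears
#' `min_score_frac * read_length`; ties at the top score make it
#' `ambiguous`; everything else is `unmapped`. External mode ingests a SAM
#' of reads-vs-catalog and calls a read unique iff its best alignment score
#' (AS tag) is achieved by exactly one record.
#'
#' @param reads a [read_set()].
#' @param catalog an `sgb_catalog`, or a named character vector of genome
#'   sequences.
#' @param index a `window_index` over the catalog (used for window
#'   ordinals).
#' @param seed_length exact-match seed length (default 31).
#' @param min_score_frac minimum best score as a fraction of read length.
#' @param sam optional path to a SAM file of reads aligned to the catalog
#'   (external mode).
#' @return A `mapping_result` data.frame: `read_id`, `status`
#'   (`unique`/`ambiguous`/`unmapped`), `sgb_id`, `pos` (0-based leftmost),
#'   `strand`, `window` (0-based ordinal), `score`.
#' @export
unique_best_map <- function(reads, catalog, index, seed_length = 31,
                            min_score_frac = 0.5, sam = NULL) {
  stopifnot(inherits(reads, "read_set"))
  genomes <- if (inherits(catalog, "sgb_catalog")) catalog$genomes else catalog
  stopifnot(!is.null(names(genomes)))
  if (!is.null(sam)) {
    res <- sam_unique_best(reads, names(genomes), sam)
  } else {
    m <- cpp_map_reads(reads$seq, unname(genomes), as.integer(seed_length),
                       min_score_frac)
    res <- data.frame(
      read_id = reads$id,
      status = c("unmapped", "unique", "ambiguous")[m$status + 1L],
      sgb_id = names(genomes)[m$sgb],
      pos = m$pos, strand = m$strand, score = m$score,
      stringsAsFactors = FALSE)
  }
  res$window <- ifelse(res$status == "unique",
                       res$pos %/% index$window_length_bp, NA_integer_)
  class(res) <- c("mapping_result", "data.frame")
  res
}

# External mode: unique iff the best AS is achieved by exactly one record;
# without AS tags, unique iff exactly one aligned record.
sam_unique_best <- function(reads, sgb_ids, sam) {
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  r <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos"), tag = "AS"))[[1]]
  aligned <- bitwAnd(r$flag, 4L) == 0L
  rn <- as.character(r$rname)
  unknown <- setdiff(unique(rn[aligned]), sgb_ids)
  if (length(unknown) > 0) {
    stop("SAM references contig(s) absent from the catalog: ",
         paste(unknown, collapse = ", "))
  }
  score <- r$tag$AS
  if (is.null(score)) score <- rep(0L, length(r$qname))
  res <- data.frame(read_id = reads$id, status = "unmapped",
                    sgb_id = NA_character_, pos = NA_integer_,
                    strand = NA_integer_, score = NA_integer_,
                    stringsAsFactors = FALSE)
  idx <- which(aligned)
  if (length(idx) > 0) {
    by_read <- split(idx, r$qname[idx])
    for (qn in names(by_read)) {
      i <- by_read[[qn]]
      sc <- score[i]
      sc[is.na(sc)] <- 0L
      best <- max(sc)
      at_best <- i[sc == best]
      row <- match(qn, res$read_id)
      if (is.na(row)) next
      if (length(at_best) == 1L) {
        res$status[row] <- "unique"
        res$sgb_id[row] <- rn[at_best]
        res$pos[row] <- r$pos[at_best] - 1L  # SAM is 1-based
        res$strand[row] <- ifelse(bitwAnd(r$flag[at_best], 16L) != 0L,
                                  -1L, 1L)
        res$score[row] <- best
      } else {
        res$status[row] <- "ambiguous"
        res$score[row] <- best
      }
    }
  }
  res
}

#' Per-window unique-read counts
#'
#' @param mapping a `mapping_result` from [unique_best_map()].
#' @param index the `window_index` used for mapping.
#' @return A `cover_profile`: list with `counts` (per-SGB integer vector of
#'   per-window unique-read counts) and `n_unique` (per-SGB unique-read
#'   totals).
#' @export
window_counts <- function(mapping, index) {
  stopifnot(inherits(mapping, "mapping_result"))
  nw <- n_windows(index)
  u <- mapping[mapping$status == "unique", , drop = FALSE]
  counts <- lapply(names(nw), function(g) {
    w <- u$window[u$sgb_id == g]
    tabulate(w + 1L, nbins = nw[[g]])
  })
  names(counts) <- names(nw)
  structure(list(counts = counts,
                 n_unique = vapply(counts, sum, 0L)),
            class = "cover_profile")
}

#' Dense mean cover per SGB
#'
#' Window counts are converted to per-base read densities
#' (`count * read_length / window_length`, using each window's actual
#' width), sorted, the lowest and highest `trim_fraction` of windows are
#' discarded, and the mean of the central windows is taken. SGBs with no
#' unique reads get cover 0. With `genome_size_mode = "per_base_over_length"`
#' the density is additionally divided by total genome length.
#'
#' @param profile a `cover_profile`.
#' @param index the `window_index`.
#' @param read_length_bp read length used for density conversion.
#' @param trim_fraction fraction trimmed from each tail (default 0.25, in
#'   `[0, 0.5)`).
#' @param genome_size_mode `"per_base"` (default) or
#'   `"per_base_over_length"`.
#' @return Named numeric vector of covers `c_g`.
#' @export
dense_mean_cover <- function(profile, index, read_length_bp,
                             trim_fraction = 0.25,
                             genome_size_mode = c("per_base",
                                                  "per_base_over_length")) {
  stopifnot(inherits(profile, "cover_profile"),
            trim_fraction >= 0, trim_fraction < 0.5)
  genome_size_mode <- match.arg(genome_size_mode)
  out <- vapply(names(profile$counts), function(g) {
    cnt <- profile$counts[[g]]
    if (length(cnt) == 0) stop("empty window vector for ", g)
    if (all(cnt == 0)) return(0)
    w <- index$windows[[g]]
    dens <- cnt * read_length_bp / (w$end - w$start)
    dens <- sort(dens)
    k <- floor(trim_fraction * length(dens))
    central <- dens[seq.int(k + 1L, length(dens) - k)]
    m <- mean(central)
    if (genome_size_mode == "per_base_over_length") {
      m <- m / sum(w$end - w$start)
    }
    m
  }, 0.0)
  out
}

#' Relative abundance with existence criterion
#'
#' An SGB is concluded to exist in a sample iff its cover is positive, at
#' least `min_reads` reads mapped uniquely to it, and at least
#' `min_nonzero_window_fraction` of its windows carry a read. Relative
#' abundance is the cover divided by the summed covers of all existing
#' SGBs; non-existing SGBs get 0.
#'
#' @param covers named cover vector from [dense_mean_cover()].
#' @param profile the `cover_profile` the covers came from.
#' @param min_reads minimum unique reads (default 10).
#' @param min_nonzero_window_fraction minimum fraction of nonzero windows
#'   (default 0.05).
#' @param sample_id optional sample identifier.
#' @return An `abundance_vector`: list with `sample_id`, `cover`, `exists`,
#'   `p` (relative abundances, summing to 1 when any SGB exists), and cap
#'   state (`cap_tau`, `cap_mode`, `NA` until [apply_detection_cap()]).
#' @export
estimate_relative_abundance <- function(covers, profile, min_reads = 10,
                                        min_nonzero_window_fraction = 0.05,
                                        sample_id = NA_character_) {
  stopifnot(inherits(profile, "cover_profile"),
            identical(names(covers), names(profile$counts)))
  nz_frac <- vapply(profile$counts, function(cnt) mean(cnt > 0), 0.0)
  exists <- covers > 0 & profile$n_unique >= min_reads &
    nz_frac >= min_nonzero_window_fraction
  p <- stats::setNames(numeric(length(covers)), names(covers))
  if (any(exists)) {
    p[exists] <- covers[exists] / sum(covers[exists])
  } else {
    warning("no SGB passes the existence criterion; all-zero abundances")
  }
  structure(list(sample_id = sample_id, cover = covers, exists = exists,
                 p = p, cap_tau = NA_real_, cap_mode = NA_character_),
            class = "abundance_vector")
}

#' Apply the detection cap
#'
#' Mode `"floor"` (default): every relative abundance below `tau`
#' (including zeros) is raised to `tau`, for log-scale downstream use; the
#' vector no longer sums to 1 and the cap state records this. Mode
#' `"zero"`: entries below `tau` are zeroed and the survivors renormalized
#' to sum to 1.
#'
#' @param v an `abundance_vector`.
#' @param tau detection cap (default `1e-4`).
#' @param mode `"floor"` or `"zero"`.
#' @return The capped `abundance_vector`.
#' @export
apply_detection_cap <- function(v, tau = 1e-4, mode = c("floor", "zero")) {
  stopifnot(inherits(v, "abundance_vector"))
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1) {
    stop("detection cap tau must be a single value in (0, 1)")
  }
  mode <- match.arg(mode)
  p <- v$p
  if (mode == "floor") {
    p[p < tau] <- tau
  } else {
    p[p < tau] <- 0
    if (sum(p) > 0) p <- p / sum(p)
  }
  v$p <- p
  v$cap_tau <- tau
  v$cap_mode <- mode
  v
}

#' Full per-sample abundance estimation
#'
#' Convenience chain: [unique_best_map()] -> [window_counts()] ->
#' [dense_mean_cover()] -> [estimate_relative_abundance()], without the cap
#' (apply [apply_detection_cap()] downstream).
#'
#' @param reads QC'd, host-screened [read_set()].
#' @param catalog an `sgb_catalog` or named genome vector.
#' @param index a `window_index`.
#' @param read_length_bp read length for density conversion (defaults to
#'   the modal read length).
#' @param sample_id sample identifier.
#' @param ... passed to [unique_best_map()], [dense_mean_cover()] and
#'   [estimate_relative_abundance()] by name.
#' @return An `abundance_vector`.
#' @export
sample_abundance <- function(reads, catalog, index,
                             read_length_bp = NULL,
                             sample_id = NA_character_, ...) {
  dots <- list(...)
  take <- function(f) dots[intersect(names(dots), names(formals(f)))]
  if (is.null(read_length_bp)) {
    tab <- table(nchar(reads$seq))
    read_length_bp <- as.numeric(names(tab)[which.max(tab)])
  }
  mapping <- do.call(unique_best_map,
                     c(list(reads, catalog, index), take(unique_best_map)))
  profile <- window_counts(mapping, index)
  covers <- do.call(dense_mean_cover,
                    c(list(profile, index, read_length_bp),
                      take(dense_mean_cover)))
  do.call(estimate_relative_abundance,
          c(list(covers, profile, sample_id = sample_id),
            take(estimate_relative_abundance)))
}

#' Stack abundance vectors into a samples x SGBs table
#'
#' @param vectors list of `abundance_vector`s.
#' @return Numeric matrix, rownames = sample ids, colnames = SGB ids.
#' @export
abundance_table <- function(vectors) {
  stopifnot(length(vectors) > 0)
  ids <- names(vectors[[1]]$p)
  m <- t(vapply(vectors, function(v) v$p[ids], numeric(length(ids))))
  rownames(m) <- vapply(vectors, function(v) v$sample_id, "")
  colnames(m) <- ids
  m
}
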