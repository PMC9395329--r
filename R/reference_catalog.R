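# Catalog curation: the SGB inclusion rule and the fixed-width window index
# over representative genomes.

#' Apply the SGB inclusion rule
#'
#' An SGB is retained iff it is the only SGB carrying its genus label, or it
#' has at least `min_assemblies` assemblies. The rule guards against
#' artificially split bins: a bin sharing a genus with others must be backed
#' by enough assemblies to justify being its own species-level bin.
#'
#' @param taxonomy data.frame with at least `sgb_id`, `genus` and
#'   `n_assemblies` columns (an `sgb_catalog$taxonomy` works).
#' @param min_assemblies assembly-count threshold (default 5).
#' @return List with `kept` and `dropped` subsets of `taxonomy`.
#' @export
filter_sgbs <- function(taxonomy, min_assemblies = 5) {
  stopifnot(is.data.frame(taxonomy),
            all(c("sgb_id", "genus", "n_assemblies") %in% names(taxonomy)))
  if (anyNA(taxonomy$genus) || any(taxonomy$genus == "")) {
    stop("missing genus label for SGB(s): ",
         paste(taxonomy$sgb_id[is.na(taxonomy$genus) |
                                 taxonomy$genus == ""], collapse = ", "))
  }
  unique_genus <- !(duplicated(taxonomy$genus) |
                      duplicated(taxonomy$genus, fromLast = TRUE))
  keep <- unique_genus | taxonomy$n_assemblies >= min_assemblies
  list(kept = taxonomy[keep, , drop = FALSE],
       dropped = taxonomy[!keep, , drop = FALSE])
}

#' Build a fixed-width window index over genomes
#'
#' Windows are half-open 0-based intervals `[start, end)` tiling each genome;
#' every window has length `window_length_bp` except possibly the terminal
#' one. Window count per genome is `ceiling(length / window_length_bp)`.
#'
#' @param genome_lengths named integer vector of genome lengths (names are
#'   SGB ids), or an `sgb_catalog` whose genome lengths are used.
#' @param window_length_bp window width (default 1000).
#' @return A `window_index`: list with `window_length_bp` and `windows`, a
#'   per-SGB list of data.frames (`start`, `end`).
#' @export
build_window_index <- function(genome_lengths, window_length_bp = 1000) {
  stopifnot(window_length_bp >= 1)
  if (inherits(genome_lengths, "sgb_catalog")) {
    genome_lengths <- stats::setNames(nchar(genome_lengths$genomes),
                                      names(genome_lengths$genomes))
  }
  stopifnot(!is.null(names(genome_lengths)), all(genome_lengths >= 1))
  if (any(genome_lengths < window_length_bp)) {
    warning("window length ", window_length_bp,
            " bp exceeds the shortest genome; single-window genomes allowed")
  }
  windows <- lapply(genome_lengths, function(L) {
    starts <- seq.int(0L, L - 1L, by = window_length_bp)
    data.frame(start = starts, end = pmin(starts + window_length_bp, L))
  })
  structure(list(window_length_bp = window_length_bp, windows = windows),
            class = "window_index")
}

#' Window count per SGB
#' @param index a `window_index`.
#' @return Named integer vector.
#' @export
n_windows <- function(index) {
  vapply(index$windows, nrow, 0L)
}
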