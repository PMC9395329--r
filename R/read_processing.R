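# Read processing: adapter/quality filtering with edge trimming, host-read
# removal, and fixed-depth subsampling.

#' Quality-control configuration
#'
#' @param min_mean_quality minimum mean Phred quality after trimming.
#' @param edge_quality_threshold bases below this Phred score are trimmed
#'   inward from both read edges (scan stops at the first base meeting the
#'   threshold).
#' @param min_length_after_trim minimum surviving read length (bp).
#' @param adapter_sequences reads containing any of these substrings are
#'   dropped.
#' @param subsample_depth target read depth for [subsample_reads()]
#'   (default 10 million).
#' @param host_kmer_length k-mer length of the built-in host screen.
#' @param host_match_fraction fraction of a read's k-mers that must hit the
#'   host k-mer set for the read to be called host.
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_mean_quality = 20, edge_quality_threshold = 20,
                      min_length_after_trim = 50,
                      adapter_sequences = DEFAULT_ADAPTER,
                      subsample_depth = 10000000L,
                      host_kmer_length = 31, host_match_fraction = 0.5) {
  stopifnot(min_mean_quality >= 0, edge_quality_threshold >= 0,
            min_length_after_trim >= 0, subsample_depth >= 1,
            host_kmer_length >= 4, host_match_fraction >= 0,
            host_match_fraction <= 1)
  structure(list(min_mean_quality = min_mean_quality,
                 edge_quality_threshold = edge_quality_threshold,
                 min_length_after_trim = min_length_after_trim,
                 adapter_sequences = adapter_sequences,
                 subsample_depth = as.integer(subsample_depth),
                 host_kmer_length = host_kmer_length,
                 host_match_fraction = host_match_fraction),
            class = "qc_config")
}

#' Adapter and quality filtering with edge trimming
#'
#' Reads containing any configured adapter substring are dropped. Remaining
#' reads are trimmed inward from each edge while base quality is below
#' `edge_quality_threshold`, then dropped if mean quality falls below
#' `min_mean_quality` or the trimmed length below `min_length_after_trim`.
#' Survivor order is preserved.
#'
#' @param reads a [read_set()].
#' @param qc a [qc_config()].
#' @return List with `reads` (surviving, possibly trimmed, [read_set()]) and
#'   `log` (data.frame: id, disposition in
#'   `{kept, adapter, low_quality, too_short}`, trimmed_length).
#' @export
quality_filter <- function(reads, qc = qc_config()) {
  stopifnot(inherits(reads, "read_set"), inherits(qc, "qc_config"))
  n <- nrow(reads)
  disposition <- rep("kept", n)
  out_seq <- reads$seq
  out_qual <- reads$qual

  has_adapter <- rep(FALSE, n)
  for (ad in qc$adapter_sequences) {
    has_adapter <- has_adapter | grepl(ad, reads$seq, fixed = TRUE)
  }
  disposition[has_adapter] <- "adapter"

  trimmed_length <- nchar(reads$seq)
  # fast path: reads with no base below the edge threshold need no trimming,
  # and (threshold >= min_mean_quality) pass the mean filter outright
  has_low_base <- if (qc$edge_quality_threshold >= 1) {
    below <- sprintf("[\\x21-\\x%02x]",
                     min(125L, 33L + as.integer(qc$edge_quality_threshold) - 1L))
    grepl(below, reads$qual, perl = TRUE)
  } else {
    rep(FALSE, n)
  }
  clean <- !has_adapter & !has_low_base &
    qc$edge_quality_threshold >= qc$min_mean_quality &
    trimmed_length >= qc$min_length_after_trim
  for (i in which(!has_adapter & !clean)) {
    q <- qual_to_int(reads$qual[i])
    ok <- q >= qc$edge_quality_threshold
    first <- match(TRUE, ok)
    if (is.na(first)) {
      trimmed_length[i] <- 0L
      disposition[i] <- "too_short"
      next
    }
    last <- length(q) + 1L - match(TRUE, rev(ok))
    q <- q[first:last]
    trimmed_length[i] <- length(q)
    if (length(q) < qc$min_length_after_trim) {
      disposition[i] <- "too_short"
    } else if (mean(q) < qc$min_mean_quality) {
      disposition[i] <- "low_quality"
    } else {
      out_seq[i] <- substr(reads$seq[i], first, last)
      out_qual[i] <- substr(reads$qual[i], first, last)
    }
  }

  keep <- disposition == "kept"
  out <- read_set(reads$id[keep], out_seq[keep], out_qual[keep],
                  reads$source[keep])
  list(reads = out,
       log = data.frame(id = reads$id, disposition = disposition,
                        trimmed_length = trimmed_length,
                        stringsAsFactors = FALSE))
}

#' Remove host reads
#'
#' Built-in mode: a read is removed when at least `host_match_fraction` of
#' its k-mers (forward or reverse complement) occur in the host genome's
#' k-mer set. External mode: a read is removed when it has any alignment
#' record in a supplied SAM of reads-vs-host (emulating an inclusive
#' bowtie-class mapping).
#'
#' @param reads a [read_set()].
#' @param host host genome sequence(s) as a character vector (built-in
#'   mode), or `NULL`.
#' @param qc a [qc_config()].
#' @param sam path to a SAM file of reads aligned to the host (external
#'   mode), or `NULL`.
#' @return The retained [read_set()].
#' @export
host_screen <- function(reads, host = NULL, qc = qc_config(), sam = NULL) {
  stopifnot(inherits(reads, "read_set"))
  if (is.null(host) && is.null(sam)) {
    stop("host_screen needs a host genome or a SAM of host alignments")
  }
  if (!is.null(sam)) {
    aligned <- sam_aligned_read_ids(sam)
    keep <- !(reads$id %in% aligned)
  } else {
    if (sum(nchar(host)) < qc$host_kmer_length) {
      return(reads)  # empty/degenerate host: nothing can match
    }
    frac <- cpp_kmer_hit_fraction(reads$seq, host, qc$host_kmer_length)
    keep <- frac < qc$host_match_fraction
  }
  out <- reads[keep, , drop = FALSE]
  class(out) <- c("read_set", "data.frame")
  out
}

# qnames with at least one aligned record in a SAM file
sam_aligned_read_ids <- function(sam) {
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(what = c("qname", "flag")))[[1]]
  unmapped <- bitwAnd(res$flag, 4L) != 0L
  unique(res$qname[!unmapped])
}

#' Subsample reads to a fixed depth
#'
#' Draws exactly `depth` reads uniformly without replacement (original order
#' preserved), deterministically under `seed`. When fewer than `depth`
#' reads are available all reads are kept and a warning is emitted.
#'
#' @param reads a [read_set()].
#' @param depth target depth (default 10 million).
#' @param seed integer seed.
#' @return A [read_set()] with `min(nrow(reads), depth)` reads.
#' @export
subsample_reads <- function(reads, depth = 10000000L, seed = 1) {
  stopifnot(inherits(reads, "read_set"), depth >= 1)
  if (nrow(reads) <= depth) {
    if (nrow(reads) < depth) {
      warning("only ", nrow(reads), " reads available; requested depth ",
              depth, " - keeping all reads")
    }
    return(reads)
  }
  set.seed(seed)
  keep <- sort(sample.int(nrow(reads), depth))
  out <- reads[keep, , drop = FALSE]
  class(out) <- c("read_set", "data.frame")
  out
}
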