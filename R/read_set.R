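#' Construct a read set
#'
#' A `read_set` is the package's container for a sample's shotgun reads:
#' a data.frame with columns `id`, `seq`, `qual` (Phred+33 quality string)
#' and `source` (provenance: an SGB id, `"host"`, `"junk_adapter"`,
#' `"junk_lowqual"`, or `NA` when unknown, e.g. for real data).
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of read sequences (A/C/G/T/N).
#' @param qual character vector of Phred+33 quality strings, same lengths
#'   as `seq`.
#' @param source optional character vector of read provenance.
#' @return A `read_set` object (data.frame).
#' @export
read_set <- function(id, seq, qual, source = NA_character_) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad) > 0) {
    stop("malformed read record (sequence/quality length mismatch): ",
         id[bad[1]])
  }
  out <- data.frame(id = as.character(id), seq = as.character(seq),
                    qual = as.character(qual),
                    source = rep_len(as.character(source), length(id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set with", nrow(x), "reads",
      if (nrow(x) > 0) paste0("(length ", min(nchar(x$seq)), "-",
                              max(nchar(x$seq)), " bp)") else "", "\n")
  invisible(x)
}

#' Read a FASTQ file into a read_set
#'
#' @param path FASTQ file (gzip accepted).
#' @return A [read_set()].
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  read_set(id = names(x), seq = as.character(x),
           qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a read_set to FASTQ
#'
#' @param reads a [read_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Phred+33 helpers used across QC and simulation.
qual_to_int <- function(q) utf8ToInt(q) - 33L
int_to_qual <- function(v) intToUtf8(v + 33L)

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
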