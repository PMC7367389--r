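#' Circular genome container
#'
#' A minimal container for a circular DNA sequence with 1-based, inclusive
#' coordinates. Position arithmetic is modular on `[1..length]`; the sequence
#' is stored 5'->3' on the major coding strand (J-strand), matching the usual
#' presentation of metastriate tick mitochondrial genomes.
#'
#' @param sequence DNA string over {A,C,G,T} (case-insensitive on input,
#'   stored upper-case).
#' @param id sequence identifier.
#' @return an object of class `circular_genome` with fields `id`, `sequence`
#'   and `length`.
#' @export
#' @examples
#' g <- circular_genome("ACGTACGT", id = "toy")
#' g$length
circular_genome <- function(sequence, id = "genome") {
  sequence <- toupper(sequence)
  check_dna(sequence, "genome sequence")
  structure(list(id = id, sequence = sequence, length = nchar(sequence)),
            class = "circular_genome")
}

#' @export
print.circular_genome <- function(x, ...) {
  cat(sprintf("<circular_genome> %s: %d bp circular\n", x$id, x$length))
  invisible(x)
}

#' Read a (circular) genome from FASTA
#'
#' Reads the first record of a FASTA file into a [circular_genome()].
#'
#' @param path FASTA file.
#' @return a `circular_genome`.
#' @export
read_genome_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  circular_genome(as.character(set[[1L]]),
                  id = sub("\\s.*$", "", names(set)[1L]))
}

#' Write a genome to FASTA
#'
#' @param genome a `circular_genome`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Length of an annotated feature on a circular genome
#'
#' Coordinates are 1-based inclusive. A feature with `end < start` wraps the
#' origin, so its length is `(N - start + 1) + end`.
#'
#' @param start,end 1-based inclusive coordinates in `[1..genome_length]`.
#' @param genome_length circular genome size N.
#' @return feature length in bp.
#' @export
#' @examples
#' feature_length(1150, 2686, 15094)   # 1537
#' feature_length(14717, 1089, 15094)  # wraps the origin: 1467
feature_length <- function(start, end, genome_length) {
  stopifnot(length(start) == length(end))
  n <- genome_length
  if (any(start < 1L | start > n | end < 1L | end > n)) {
    stop("coordinates outside [1..", n, "]", call. = FALSE)
  }
  ifelse(end >= start, end - start + 1L, (n - start + 1L) + end)
}

#' Extract the sequence of an annotated feature
#'
#' Returns the J-strand subsequence for a `+` feature and its reverse
#' complement (read 5'->3') for a `-` feature, wrapping the origin when
#' `end < start`.
#'
#' @param genome a `circular_genome`.
#' @param feature a list/row with `start`, `end` and `strand` (`"+"`/`"-"`).
#' @return DNA string whose length equals [feature_length()].
#' @export
extract_feature_sequence <- function(genome, feature) {
  s <- substr_circ(genome$sequence, feature$start, feature$end)
  if (identical(feature$strand, "-")) revcomp(s) else s
}
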