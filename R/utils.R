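#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
#'   readDNAStringSet writeXStringSet getGeneticCode
#' @importFrom stats rbinom rmultinom runif setNames
#' @importFrom utils read.delim write.table packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA character strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors, which is what most of this package passes
#' around.
#'
#' @param x character vector of DNA sequences (A/C/G/T, case-insensitive).
#' @return character vector of reverse complements, upper-case.
#' @export
#' @examples
#' revcomp("AGGT")
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nz <- nchar(x) > 0L
  if (any(nz)) {
    out[nz] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(toupper(x[nz]))))
  }
  out
}

check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  }
  if (grepl("[^ACGT]", seq)) {
    stop(what, " contains characters outside {A,C,G,T}", call. = FALSE)
  }
  invisible(seq)
}

# 1-based modular position on a circle of size n: maps any integer to [1..n]
wrap1 <- function(pos, n) ((pos - 1L) %% n) + 1L

# circular substring, 1-based inclusive, end < start means wrap the origin
substr_circ <- function(seq, start, end) {
  n <- nchar(seq)
  if (start < 1L || start > n || end < 1L || end > n) {
    stop("coordinates outside [1..", n, "]", call. = FALSE)
  }
  if (end >= start) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, n), substr(seq, 1L, end))
  }
}

# is `word` a whole-number repetition of a shorter word?
is_primitive_unit <- function(word) {
  m <- nchar(word)
  if (m == 1L) return(TRUE)
  for (d in seq_len(m %/% 2)) {
    if (m %% d == 0L && strrep(substr(word, 1L, d), m %/% d) == word) {
      return(FALSE)
    }
  }
  TRUE
}

# all rotations of a DNA word
rotations <- function(word) {
  m <- nchar(word)
  vapply(seq_len(m), function(i) {
    paste0(substr(word, i, m), substr(word, 1L, i - 1L))
  }, character(1))
}

# write a TSV with a reproducibility header comment
write_tsv_report <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  stamp <- c(
    sprintf("# mitostr %s", as.character(utils::packageVersion("mitostr"))),
    if (length(meta)) paste0("# ", names(meta), "=", unname(meta))
  )
  writeLines(stamp, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# md5 of a configuration list, for output provenance headers
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), f)
  unname(tools::md5sum(f))
}

#' Path to a packaged example/fixture file
#'
#' @param file file name under `inst/extdata`; with no argument, lists the
#'   available files.
#' @return a file path, or a character vector of file names.
#' @export
mitostr_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "mitostr")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}
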