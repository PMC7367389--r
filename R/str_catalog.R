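#' STR locus constructor
#'
#' An STR locus is a maximal run of a primitive repeat unit. The position is
#' the genomic position of the first nucleotide of the reference STR; the
#' locus is classified by unit length m and copy number n as an "m x n" STR
#' (a 1 x n STR is a homopolymer / polynucleotide).
#'
#' @param position 1-based genomic position of the first nucleotide.
#' @param unit primitive repeat unit (DNA word, length m >= 1).
#' @param copies copy number n >= 2.
#' @return object of class `str_locus`.
#' @export
str_locus <- function(position, unit, copies) {
  unit <- toupper(unit)
  check_dna(unit, "repeat unit")
  if (!is_primitive_unit(unit)) {
    stop("unit '", unit, "' is not primitive", call. = FALSE)
  }
  if (copies < 2L) stop("copy number must be >= 2", call. = FALSE)
  structure(list(position = as.integer(position), unit = unit,
                 copies = as.integer(copies),
                 array_length = nchar(unit) * as.integer(copies)),
            class = "str_locus")
}

#' @export
print.str_locus <- function(x, ...) {
  cat(sprintf("<str_locus> %s at %d (%s STR, %d bp)\n",
              format_str(x$unit, x$copies), x$position,
              classify_str(x), x$array_length))
  invisible(x)
}

#' Format / parse the bracketed STR notation
#'
#' `format_str` renders unit and copy number as `"[AT]5"`;
#' `parse_str` accepts `"[AT]5"` and the typeset variant `"[AT]_5_"`.
#'
#' @param unit repeat unit; @param copies copy number.
#' @return `format_str`: a string; `parse_str`: list with `unit` and `copies`.
#' @export
#' @examples
#' format_str("AT", 5)      # "[AT]5"
#' parse_str("[G]_8_")$copies
format_str <- function(unit, copies) {
  sprintf("[%s]%d", toupper(unit), as.integer(copies))
}

#' @rdname format_str
#' @param text bracketed STR notation.
#' @export
parse_str <- function(text) {
  m <- regmatches(text, regexec("^\\[([ACGTacgt]+)\\]_?([0-9]+)_?$", text))[[1]]
  if (length(m) != 3L || !nzchar(m[2L])) {
    stop("cannot parse STR notation: '", text, "'", call. = FALSE)
  }
  list(unit = toupper(m[2L]), copies = as.integer(m[3L]))
}

#' Classify an STR by unit length and copy number
#'
#' @param locus an `str_locus` (or any list with `unit` and `copies`).
#' @return the "m x n" class label, e.g. `"2 x 5"`.
#' @export
classify_str <- function(locus) {
  sprintf("%d x %d", nchar(locus$unit), locus$copies)
}

#' Canonical rotation of a repeat unit
#'
#' The catalogue reports each unit as it appears at the locus start (the
#' position convention fixes the first nucleotide); for cross-locus
#' comparison this accessor returns the lexicographically smallest rotation.
#'
#' @param unit repeat unit.
#' @return canonical rotation of `unit`.
#' @export
canonical_unit <- function(unit) {
  min(rotations(toupper(unit)))
}

default_min_copies <- function(m) if (m == 1L) 5L else 3L

#' Scan a sequence for short tandem repeats
#'
#' Finds every maximal run of a primitive repeat unit meeting the copy-number
#' and array-length thresholds. Maximality means that extending the run by
#' one full unit to the left or right breaks the repetition; primitivity
#' means the unit is not itself a whole-number repetition of a shorter word
#' (so `AAAA` is `[A]4`, never `[AA]2`). On a circular sequence, runs
#' crossing the origin are reported once, at their true start.
#'
#' @param seq DNA string (or a `circular_genome`).
#' @param circular treat the sequence as circular (default `TRUE` when a
#'   `circular_genome` is given, else `FALSE`).
#' @param min_copies_by_unit_len named integer vector mapping unit length m to
#'   the minimum copy number; lengths not named fall back to the default
#'   (n >= 5 for m = 1, n >= 3 for m >= 2).
#' @param min_array_len minimum array length in bp for units of length >= 2.
#' @param max_unit_len maximum unit length m to scan (default 6).
#' @return data.frame with columns `position`, `unit`, `copies`,
#'   `array_length`, `class`, sorted by position.
#' @export
#' @examples
#' find_strs("ATATATATAT")            # one [AT]5 locus
find_strs <- function(seq, circular = NULL,
                      min_copies_by_unit_len = NULL,
                      min_array_len = 8L, max_unit_len = 6L) {
  if (inherits(seq, "circular_genome")) {
    if (is.null(circular)) circular <- TRUE
    seq <- seq$sequence
  }
  if (is.null(circular)) circular <- FALSE
  seq <- toupper(seq)
  check_dna(seq)
  n <- nchar(seq)
  s2 <- if (circular) paste0(seq, seq) else seq
  min_copies <- function(m) {
    key <- as.character(m)
    if (!is.null(min_copies_by_unit_len) && key %in% names(min_copies_by_unit_len)) {
      as.integer(min_copies_by_unit_len[[key]])
    } else {
      default_min_copies(m)
    }
  }
  out <- list()
  for (m in seq_len(min(max_unit_len, n %/% 2L))) {
    # candidate starts: position i where the next m bases repeat the unit
    imax <- if (circular) n else n - 2L * m + 1L
    if (imax < 1L) next
    i <- seq_len(imax)
    u1 <- substring(s2, i, i + m - 1L)
    u2 <- substring(s2, i + m, i + 2L * m - 1L)
    cand <- i[u1 == u2]
    for (p in cand) {
      unit <- substring(s2, p, p + m - 1L)
      if (!is_primitive_unit(unit)) next
      # left-maximality at base resolution: the preceding base must break the
      # period, otherwise p is a phase-shifted interior start of the tract
      # (so "ATATATATAT" yields [AT]5 once, not also [TA]4)
      last <- substring(unit, m, m)
      if (circular) {
        q <- wrap1(p - 1L, n)
        if (substring(seq, q, q) == last) next
      } else {
        if (p > 1L && substring(s2, p - 1L, p - 1L) == last) next
      }
      # count copies rightwards (cap at one full circle)
      kmax <- if (circular) n %/% m else (n - p + 1L) %/% m
      k <- 2L
      while (k < kmax &&
             substring(s2, p + k * m, p + (k + 1L) * m - 1L) == unit) {
        k <- k + 1L
      }
      if (k < min_copies(m)) next
      if (m >= 2L && k * m < min_array_len) next
      out[[length(out) + 1L]] <- list(position = p, unit = unit, copies = k)
    }
  }
  if (!length(out)) {
    return(data.frame(position = integer(), unit = character(),
                      copies = integer(), array_length = integer(),
                      class = character(), stringsAsFactors = FALSE))
  }
  df <- data.frame(position = vapply(out, `[[`, integer(1), "position"),
                   unit = vapply(out, `[[`, character(1), "unit"),
                   copies = vapply(out, `[[`, integer(1), "copies"),
                   stringsAsFactors = FALSE)
  df$array_length <- nchar(df$unit) * df$copies
  df$class <- sprintf("%d x %d", nchar(df$unit), df$copies)
  df <- df[order(df$position, nchar(df$unit)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Annotate an STR catalogue with gene names
#'
#' Joins catalogue positions against an annotation set: each locus is labelled
#' with the name(s) of the feature(s) whose interval contains its first
#' position (composite antisense segments and intergenic filler excluded by
#' default).
#'
#' @param catalog data.frame from [find_strs()].
#' @param ann an `annotation_set`.
#' @param exclude regex of feature names that are not genes.
#' @return the catalogue with a `gene` column added.
#' @export
annotate_str_catalog <- function(catalog, ann,
                                 exclude = "AS|^HAS|^LAS|^Intergenic|^R[0-9]") {
  f <- ann$features[!grepl(exclude, ann$features$name), , drop = FALSE]
  n <- ann$genome_length
  catalog$gene <- vapply(catalog$position, function(p) {
    hit <- (f$end >= f$start & p >= f$start & p <= f$end) |
      (f$end < f$start & (p >= f$start | p <= f$end))
    paste(f$name[hit], collapse = "/")
  }, character(1))
  catalog
}

#' Write an STR catalogue as TSV
#'
#' @param catalog data.frame from [find_strs()] (optionally annotated).
#' @param path output file.
#' @param meta named character vector for the provenance header.
#' @return the path, invisibly.
#' @export
write_str_catalog <- function(catalog, path, meta = character()) {
  write_tsv_report(catalog, path, meta)
}
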