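#' Normalise a pileup-style allele label
#'
#' Published tables often typeset pileup allele labels with spaces and a
#' Unicode minus sign ("+ 1G", "−1A"). This maps them to the ASCII
#' dialect used throughout the package: `Ref`, `*`, single bases, `+1G`,
#' `-2AA`.
#'
#' @param label character vector of labels.
#' @return normalised labels.
#' @export
normalize_allele_label <- function(label) {
  x <- gsub("[−–—]", "-", label)
  x <- gsub("[[:space:]]+", "", x)
  x <- ifelse(toupper(x) %in% c("REF", "."), "Ref", toupper(x))
  bad <- !grepl("^(REF|Ref|\\*|[ACGTN]|[+-][0-9]+[ACGTN]+)$", x)
  if (any(bad)) {
    stop("unrecognised allele label(s): ",
         paste(unique(label[bad]), collapse = ", "), call. = FALSE)
  }
  x
}

#' Describe a single allele label
#'
#' @param label a normalised allele label (see [normalize_allele_label()]).
#' @return list of class `allele_descriptor` with `kind` (one of
#'   `reference_match`, `substitution`, `insertion`, `deletion`,
#'   `deletion_placeholder`), `sequence` (inserted/deleted bases or the
#'   substituted base) and the canonical `label`.
#' @export
parse_allele_label <- function(label) {
  x <- normalize_allele_label(label)
  if (x == "Ref") {
    d <- list(kind = "reference_match", sequence = "", label = "Ref")
  } else if (x == "*") {
    d <- list(kind = "deletion_placeholder", sequence = "", label = "*")
  } else if (grepl("^[ACGTN]$", x)) {
    d <- list(kind = "substitution", sequence = x, label = x)
  } else {
    m <- regmatches(x, regexec("^([+-])([0-9]+)([ACGTN]+)$", x))[[1]]
    k <- as.integer(m[3L])
    if (nchar(m[4L]) != k) {
      stop("indel length prefix ", k, " does not match sequence '",
           m[4L], "'", call. = FALSE)
    }
    d <- list(kind = if (m[2L] == "+") "insertion" else "deletion",
              sequence = m[4L], label = x)
  }
  class(d) <- "allele_descriptor"
  d
}

#' Parse one line of samtools pileup text
#'
#' Decodes the classic 6-column pileup dialect: `chrom pos ref depth bases
#' [quals]`. In the bases field, `.`/`,` are reference matches, `ACGTacgt`
#' substitutions, `+N<seq>`/`-N<seq>` insertions/deletions attached to the
#' preceding read base (that read is counted as the indel allele), `*` a
#' deletion-consumed placeholder, `^X` a read start (the mapping-quality byte
#' is skipped) and `$` a read end. Strand case is collapsed; per-label counts
#' are returned.
#'
#' @param line a single pileup line.
#' @return object of class `pileup_column`: list with `chrom`, `pos`, `ref`,
#'   `depth` and `counts` (named integer vector over canonical labels).
#' @export
#' @examples
#' col <- parse_pileup_line("mt\t10\tA\t9\t.....+1A..-1A.")
#' col$counts
parse_pileup_line <- function(line) {
  f <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 5L) {
    stop("pileup line has fewer than 5 fields: '", line, "'", call. = FALSE)
  }
  pos <- as.integer(f[2L])
  depth <- as.integer(f[4L])
  bases <- f[5L]
  if (grepl("\\^$", bases)) {
    stop("dangling '^' at end of bases field, position ", pos, call. = FALSE)
  }
  s <- gsub("\\^.", "", bases)        # read-start marks carry a quality byte
  s <- gsub("$", "", s, fixed = TRUE) # read-end marks
  labels <- character(0)
  drop <- integer(0)                  # base chars consumed by an indel
  im <- gregexpr("[+-][0-9]+", s)[[1L]]
  if (im[1L] != -1L) {
    lens <- attr(im, "match.length")
    for (j in seq_along(im)) {
      p <- im[j]
      k <- as.integer(substr(s, p + 1L, p + lens[j] - 1L))
      sq <- substr(s, p + lens[j], p + lens[j] + k - 1L)
      if (nchar(sq) != k || grepl("[^ACGTNacgtn]", sq)) {
        stop("indel length/sequence mismatch in bases field at position ",
             pos, call. = FALSE)
      }
      if (p == 1L) {
        stop("indel with no preceding read base at position ", pos,
             call. = FALSE)
      }
      labels <- c(labels, paste0(substr(s, p, p), k, toupper(sq)))
      drop <- c(drop, p - 1L, p:(p + lens[j] + k - 1L))
    }
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  if (length(drop)) chars <- chars[-drop]
  bad <- !chars %in% c(".", ",", "*", "A", "C", "G", "T", "N",
                       "a", "c", "g", "t", "n")
  if (any(bad)) {
    stop("unexpected character(s) '", paste(unique(chars[bad]), collapse = ""),
         "' in bases field at position ", pos, call. = FALSE)
  }
  chars <- toupper(chars)
  chars[chars %in% c(".", ",")] <- "Ref"
  labels <- c(labels, chars)
  counts <- table(labels)
  counts <- stats::setNames(as.integer(counts), names(counts))
  if (sum(counts) != depth) {
    stop("parsed allele counts (", sum(counts), ") disagree with depth (",
         depth, ") at position ", pos, call. = FALSE)
  }
  structure(list(chrom = f[1L], pos = pos, ref = toupper(f[3L]),
                 depth = depth, counts = counts),
            class = "pileup_column")
}

#' @export
print.pileup_column <- function(x, ...) {
  cat(sprintf("<pileup_column> %s:%d ref=%s depth=%d (%d allele labels)\n",
              x$chrom, x$pos, x$ref, x$depth, length(x$counts)))
  invisible(x)
}

#' Read a pileup file
#'
#' @param path pileup text file (blank lines and `#` comments ignored).
#' @return list of `pileup_column`, named by position.
#' @export
read_pileup <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  cols <- lapply(lines, parse_pileup_line)
  names(cols) <- vapply(cols, function(c) as.character(c$pos), character(1))
  cols
}

#' Construct a pileup column from allele counts
#'
#' The inverse of [parse_pileup_line()]: given canonical allele labels and
#' counts, builds a column whose encoded bases field re-parses to the same
#' counts.
#'
#' @param pos 1-based position; @param ref reference base;
#' @param counts named integer vector over canonical labels
#'   (`Ref`, bases, `*`, `+1A`, ...).
#' @param chrom chromosome name.
#' @return a `pileup_column`.
#' @export
pileup_column <- function(pos, ref, counts, chrom = "mt") {
  counts <- stats::setNames(as.integer(counts), names(counts))
  counts <- counts[counts > 0L]
  structure(list(chrom = chrom, pos = as.integer(pos), ref = toupper(ref),
                 depth = sum(counts), counts = counts),
            class = "pileup_column")
}

encode_bases_field <- function(counts) {
  parts <- character(0)
  for (lab in names(counts)) {
    k <- counts[[lab]]
    enc <- if (lab == "Ref") {
      strrep(".", k)
    } else if (lab == "*") {
      strrep("*", k)
    } else if (grepl("^[ACGTN]$", lab)) {
      strrep(lab, k)
    } else {
      strrep(paste0(".", lab), k)   # indel attached to a reference-match base
    }
    parts <- c(parts, enc)
  }
  paste(parts, collapse = "")
}

#' Write pileup columns to a file
#'
#' Emits 6-column pileup text (a uniform placeholder quality string is
#' written) that round-trips bit-exactly through [parse_pileup_line()] at the
#' allele-count level.
#'
#' @param columns list of `pileup_column`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pileup <- function(columns, path) {
  lines <- vapply(columns, function(col) {
    sprintf("%s\t%d\t%s\t%d\t%s\t%s", col$chrom, col$pos, col$ref, col$depth,
            encode_bases_field(col$counts), strrep("~", min(col$depth, 1L)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Expand a pileup allele against a reference STR
#'
#' Insertions/deletions of a whole number of repeat units yield a concrete
#' STR allele `[unit]n'` with `n' = n +/- k/m` (any rotation of the unit is
#' accepted, since an indel can be reported at any phase of the array);
#' substitutions and non-unit indels are returned as raw alleles.
#'
#' @param locus an `str_locus` (the reference STR).
#' @param allele an allele label or `allele_descriptor`.
#' @return list of class `expanded_allele` with `class` (one of `reference`,
#'   `cnv_whole_unit`, `substitution`, `other_indel`, `placeholder`),
#'   `copies` (for STR alleles, else `NA`), `delta_copies`, `delta_bases`
#'   and a display `label` (`"[G]9"` for STR alleles, the raw label
#'   otherwise).
#' @export
#' @examples
#' expand_variant(str_locus(1810, "G", 8), "+1G")$label   # "[G]9"
expand_variant <- function(locus, allele) {
  d <- if (inherits(allele, "allele_descriptor")) allele
       else parse_allele_label(allele)
  m <- nchar(locus$unit)
  n <- locus$copies
  res <- switch(d$kind,
    reference_match = list(class = "reference", copies = n,
                           delta_copies = 0L, delta_bases = 0L,
                           label = format_str(locus$unit, n)),
    deletion_placeholder = list(class = "placeholder", copies = NA_integer_,
                                delta_copies = NA_integer_,
                                delta_bases = NA_integer_, label = "*"),
    substitution = list(class = "substitution", copies = NA_integer_,
                        delta_copies = NA_integer_, delta_bases = 0L,
                        label = d$label),
    { # insertion / deletion
      k <- nchar(d$sequence)
      sign <- if (d$kind == "insertion") 1L else -1L
      if (d$kind == "deletion" && k >= locus$array_length) {
        stop("deletion of ", k, " bp exceeds the ", locus$array_length,
             " bp STR array", call. = FALSE)
      }
      unit_mult <- k %% m == 0L &&
        any(vapply(rotations(locus$unit), function(r)
          strrep(r, k %/% m) == d$sequence, logical(1)))
      if (unit_mult) {
        dcopies <- sign * (k %/% m)
        list(class = "cnv_whole_unit", copies = n + dcopies,
             delta_copies = dcopies, delta_bases = sign * k,
             label = format_str(locus$unit, n + dcopies))
      } else {
        list(class = "other_indel", copies = NA_integer_,
             delta_copies = NA_integer_, delta_bases = sign * k,
             label = d$label)
      }
    })
  res$raw_label <- d$label
  class(res) <- "expanded_allele"
  res
}

#' Left-normalise indel alleles onto their STR anchor column
#'
#' Aligners report homopolymer/STR indels at varying offsets within an array;
#' the allele table for a locus is tallied on a single column at the STR
#' position. This moves every insertion/deletion observed at any column
#' inside an array to the column at the array's first position (creating it
#' from reference matches if absent), so that single-column accounting sees
#' all of the locus's indel evidence.
#'
#' @param columns list of `pileup_column` (named by position).
#' @param catalog STR catalogue data.frame ([find_strs()]).
#' @return the adjusted column list.
#' @export
left_normalize_indels <- function(columns, catalog) {
  pos_of <- vapply(columns, `[[`, integer(1), "pos")
  for (i in seq_len(nrow(catalog))) {
    p0 <- catalog$position[i]
    span <- p0 + seq_len(catalog$array_length[i]) - 1L
    anchor <- which(pos_of == p0)
    if (!length(anchor)) next
    for (j in which(pos_of %in% setdiff(span, p0))) {
      cts <- columns[[j]]$counts
      ind <- grepl("^[+-]", names(cts))
      if (!any(ind)) next
      moved <- cts[ind]
      a <- columns[[anchor]]$counts
      for (lab in names(moved)) {
        a[lab] <- (if (lab %in% names(a)) a[[lab]] else 0L) + moved[[lab]]
      }
      # reads carrying the moved indels cover the anchor as matches: re-label
      # that share of the anchor's Ref tally (clamped for safety; depths in
      # practice agree because the reads span the whole short array)
      take <- min(sum(moved), if ("Ref" %in% names(a)) a[["Ref"]] else 0L)
      a["Ref"] <- (if ("Ref" %in% names(a)) a[["Ref"]] else 0L) - take
      a <- a[a > 0L]
      columns[[anchor]]$counts <- a
      columns[[anchor]]$depth <- sum(a)
      keep <- cts[!ind]
      # on the donor column those reads are now plain matches
      keep["Ref"] <- (if ("Ref" %in% names(keep)) keep[["Ref"]] else 0L) +
        sum(moved)
      columns[[j]]$counts <- keep
      columns[[j]]$depth <- sum(keep)
    }
  }
  columns
}
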