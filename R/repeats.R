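#' Repeat-unit library
#'
#' Named repeat unit types (e.g. R28/R34/R44, 28/34/44-bp units of the
#' tandem-repeat arrays flanking the tick mitochondrial transposon-like
#' element).
#'
#' @param units named character vector of unit sequences.
#' @return object of class `unit_library`.
#' @export
unit_library <- function(units) {
  if (is.null(names(units)) || anyDuplicated(names(units)) ||
      any(!nzchar(names(units)))) {
    stop("units must have unique non-empty names", call. = FALSE)
  }
  units <- toupper(units)
  for (u in units) check_dna(u, "repeat unit")
  structure(list(units = units), class = "unit_library")
}

#' Read/write a unit library as named FASTA
#'
#' @param path FASTA file.
#' @return `read_unit_library`: a `unit_library`.
#' @export
read_unit_library <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  unit_library(stats::setNames(as.character(set), names(set)))
}

#' @rdname read_unit_library
#' @param lib a `unit_library`.
#' @export
write_unit_library <- function(lib, path) {
  set <- Biostrings::DNAStringSet(lib$units)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Decompose a tandem-repeat array into library units
#'
#' Greedy left-to-right matching of named unit types, allowing up to
#' `max_mismatch_per_unit` substitutions per unit; one partial unit (a
#' prefix of some library unit) is permitted at the array end and counted as
#' one copy, mirroring the field convention for Sanger-consensus repeat
#' arrays.
#'
#' @param seq the array sequence.
#' @param lib a `unit_library`.
#' @param max_mismatch_per_unit allowed substitutions per matched unit.
#' @return object of class `array_decomposition`: list with `blocks`
#'   (data.frame type/copies), `partial` (trailing partial-unit type or
#'   `NA`), `pattern` (e.g. `"[R34]2-[R28]3-[R34]1"`) and `total_copies`.
#' @export
#' @examples
#' lib <- unit_library(c(U = "ACGTT"))
#' decompose_array(strrep("ACGTT", 3), lib)$pattern
decompose_array <- function(seq, lib, max_mismatch_per_unit = 0L) {
  seq <- toupper(seq)
  check_dna(seq, "array sequence")
  n <- nchar(seq)
  pos <- 1L
  runs <- list()       # (type, copies)
  partial <- NA_character_
  push <- function(type) {
    k <- length(runs)
    if (k && runs[[k]]$type == type) {
      runs[[k]]$copies <<- runs[[k]]$copies + 1L
    } else {
      runs[[k + 1L]] <<- list(type = type, copies = 1L)
    }
  }
  while (pos <= n) {
    matched <- FALSE
    # prefer continuing the current run, then longer units (greedy)
    ord <- names(lib$units)[order(-nchar(lib$units))]
    if (length(runs)) {
      cur <- runs[[length(runs)]]$type
      ord <- c(cur, setdiff(ord, cur))
    }
    for (ty in ord) {
      u <- lib$units[[ty]]
      m <- nchar(u)
      if (pos + m - 1L <= n &&
          hamming(substr(seq, pos, pos + m - 1L), u) <= max_mismatch_per_unit) {
        push(ty)
        pos <- pos + m
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      # trailing partial unit: remainder must be a prefix of some unit
      rem <- substr(seq, pos, n)
      pref <- names(lib$units)[vapply(lib$units, function(u)
        nchar(rem) < nchar(u) &&
          hamming(substr(u, 1L, nchar(rem)), rem) <= max_mismatch_per_unit,
        logical(1))]
      if (length(pref)) {
        partial <- pref[1L]
        pos <- n + 1L
      } else {
        stop("array not decomposable from offset ", pos, call. = FALSE)
      }
    }
  }
  blocks <- data.frame(
    type = vapply(runs, `[[`, character(1), "type"),
    copies = vapply(runs, `[[`, integer(1), "copies"),
    stringsAsFactors = FALSE)
  # a trailing partial counts as one copy of its type
  if (!is.na(partial)) {
    k <- nrow(blocks)
    if (k && blocks$type[k] == partial) {
      blocks$copies[k] <- blocks$copies[k] + 1L
    } else {
      blocks <- rbind(blocks, data.frame(type = partial, copies = 1L))
    }
  }
  pattern <- paste(sprintf("[%s]%d", blocks$type, blocks$copies),
                   collapse = "-")
  structure(list(blocks = blocks, partial = partial, pattern = pattern,
                 total_copies = sum(blocks$copies), input = seq),
            class = "array_decomposition")
}

#' @export
print.array_decomposition <- function(x, ...) {
  cat(sprintf("<array_decomposition> %s (%d copies%s)\n", x$pattern,
              x$total_copies,
              if (!is.na(x$partial)) ", trailing partial" else ""))
  invisible(x)
}

#' Modal decomposition over a read multiset
#'
#' Sanger sequencing of a heterogeneous repeat array reports a consensus; the
#' in-silico analogue is the most frequent (modal) decomposition pattern over
#' a set of array sequences, with the majority copy number.
#'
#' @param seqs character vector of array sequences.
#' @inheritParams decompose_array
#' @return the modal `array_decomposition` with a `support` count attached.
#' @export
modal_decomposition <- function(seqs, lib, max_mismatch_per_unit = 0L) {
  decs <- lapply(seqs, decompose_array, lib = lib,
                 max_mismatch_per_unit = max_mismatch_per_unit)
  pats <- vapply(decs, `[[`, character(1), "pattern")
  tab <- sort(table(pats), decreasing = TRUE)
  modal <- decs[[which(pats == names(tab)[1L])[1L]]]
  modal$support <- as.integer(tab[1L])
  modal
}

#' Do two unit lists stand in reverse-complement relation?
#'
#' True when every left unit equals the reverse complement of some right
#' unit, up to rotation of the unit phase (arrays excised at arbitrary
#' boundaries shift the phase).
#'
#' @param left_units,right_units character vectors of unit sequences.
#' @return list with `match` (logical) and `offsets` (for each left unit, the
#'   rotation offset of the matching reverse-complemented right unit, or
#'   `NA`).
#' @export
revcomp_unit_match <- function(left_units, right_units) {
  stopifnot(length(left_units) > 0L, length(right_units) > 0L)
  offsets <- vapply(left_units, function(lu) {
    for (ru in right_units) {
      rot <- rotations(revcomp(ru))
      hit <- which(rot == toupper(lu))
      if (length(hit)) return(hit[1L] - 1L)
    }
    NA_integer_
  }, integer(1))
  list(match = !anyNA(offsets), offsets = offsets)
}

#' Find inverted-repeat flanked (transposon-like) elements
#'
#' Two modes. Given an `annotation_set`, pairs annotated repeat arrays (names
#' `R<number>`) whose order implies an inverted-repeat flanked element and
#' reports the ordered gene list between them (composite antisense segments,
#' intergenic filler and the repeats themselves excluded). Given a
#' `circular_genome`, performs a seed-and-extend scan for maximal pairs of
#' reverse-complementary segments at least `min_ir_len` long, flanking a
#' non-empty insert.
#'
#' @param x a `circular_genome` or an `annotation_set`.
#' @param ann optional `annotation_set` used to name insert genes after a
#'   sequence scan.
#' @param min_ir_len minimum inverted-repeat length in bp (sequence mode).
#' @param max_spacing maximum insert length in bp (sequence mode).
#' @param exclude regex of non-gene feature names for insert listing.
#' @return list of `transposon_like_element` objects, each with `left`
#'   (start/end of the left IR), `right`, `insert` (start/end), and
#'   `insert_genes` (character vector, possibly empty).
#' @export
find_ir_elements <- function(x, ann = NULL, min_ir_len = 30L,
                             max_spacing = 6000L,
                             exclude = "AS|^HAS|^LAS|^Intergenic|^R[0-9]") {
  if (inherits(x, "annotation_set")) {
    return(ir_elements_from_annotation(x, exclude))
  }
  stopifnot(inherits(x, "circular_genome"))
  elements <- ir_elements_from_sequence(x, min_ir_len, max_spacing)
  if (!is.null(ann)) {
    for (i in seq_along(elements)) {
      elements[[i]]$insert_genes <-
        genes_in_interval(ann, elements[[i]]$insert$start,
                          elements[[i]]$insert$end, exclude)
    }
  }
  elements
}

new_tle <- function(left, right, insert, insert_genes = character()) {
  structure(list(left = left, right = right, insert = insert,
                 insert_genes = insert_genes),
            class = "transposon_like_element")
}

#' @export
print.transposon_like_element <- function(x, ...) {
  cat(sprintf("<transposon_like_element> IRs %d-%d / %d-%d, insert %d-%d",
              x$left$start, x$left$end, x$right$start, x$right$end,
              x$insert$start, x$insert$end))
  if (length(x$insert_genes)) {
    cat(": ", paste(x$insert_genes, collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

genes_in_interval <- function(ann, from, to, exclude) {
  f <- ann$features[!grepl(exclude, ann$features$name) &
                      !ann$features$dna_region, , drop = FALSE]
  n <- ann$genome_length
  mid <- ifelse(f$end >= f$start, (f$start + f$end) / 2,
                wrap1(as.integer((f$start + f$end + n) / 2), n))
  inside <- if (to >= from) mid >= from & mid <= to else mid >= from | mid <= to
  f <- f[inside, , drop = FALSE]
  f <- f[order((mid[inside] - from) %% n), , drop = FALSE]
  unique(f$name)
}

ir_elements_from_annotation <- function(ann, exclude) {
  f <- ann$features[grepl("^R[0-9]+$", ann$features$name), , drop = FALSE]
  if (nrow(f) < 2L) return(list())
  f <- f[order(f$start), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(f) - 1L)) {
    for (j in (i + 1L):nrow(f)) {
      insert <- list(start = f$end[i] + 1L, end = f$start[j] - 1L)
      out[[length(out) + 1L]] <- new_tle(
        left = list(start = f$start[i], end = f$end[i], name = f$name[i]),
        right = list(start = f$start[j], end = f$end[j], name = f$name[j]),
        insert = insert,
        insert_genes = genes_in_interval(ann, insert$start, insert$end,
                                         exclude))
    }
  }
  out
}

# Seed-and-extend scan for reverse-complement segment pairs.
#
# A left/right pair of reverse-complementary arms lives on one anti-diagonal
# d = left_pos + right_end: seeds (exact k-mer revcomp matches) are grouped
# by diagonal, merged, and extended base-by-base to maximality. Tandem-repeat
# arms are periodic, so phase-shifted diagonals carry shorter echoes of the
# true pair; pairs whose arms are contained in a longer pair's arms are
# dropped. The scan is linear-coordinate (IR pairs spanning the origin are
# not reported).
ir_elements_from_sequence <- function(genome, min_ir_len, max_spacing) {
  seq <- genome$sequence
  n <- genome$length
  k <- as.integer(min_ir_len)
  if (k < 8L) stop("min_ir_len must be at least 8", call. = FALSE)
  if (n < 2L * k + 1L) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  idx <- split(starts, kmers)
  rc <- revcomp(kmers)
  base <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp_of <- c(A = "T", C = "G", G = "C", T = "A")
  seeds_i <- integer(0); seeds_d <- integer(0)
  slot <- match(rc, names(idx))   # hashed once; list-by-name would be O(n^2)
  for (i in starts) {
    if (is.na(slot[i])) next
    js <- idx[[slot[i]]]
    js <- js[js >= i + k]               # arms must not overlap
    if (!length(js)) next
    seeds_i <- c(seeds_i, rep.int(i, length(js)))
    seeds_d <- c(seeds_d, i + js + k - 1L)   # diagonal id
  }
  if (!length(seeds_i)) return(list())
  cands <- list()
  for (d in unique(seeds_d)) {
    ii <- sort(seeds_i[seeds_d == d])
    # merge seed runs on this diagonal (gaps > k start a new run)
    brk <- c(TRUE, diff(ii) > k)
    run_id <- cumsum(brk)
    for (r in unique(run_id)) {
      ri_ <- ii[run_id == r]
      le <- min(ri_); li <- max(ri_) + k - 1L
      # inward extension
      while (li + 1L < d - li - 1L &&
             base[li + 1L] == comp_of[[base[d - li - 1L]]]) li <- li + 1L
      # outward extension
      while (le > 1L && d - le + 1L <= n &&
             base[le - 1L] == comp_of[[base[d - le + 1L]]]) le <- le - 1L
      rs <- d - li; re <- d - le
      arm <- li - le + 1L
      spacing <- rs - li - 1L
      if (arm < k || spacing < 1L || spacing > max_spacing) next
      cands[[length(cands) + 1L]] <-
        list(le = le, li = li, rs = rs, re = re, arm = arm)
    }
  }
  if (!length(cands)) return(list())
  # periodic arms echo on every diagonal congruent mod the unit length: drop
  # pairs whose arms lie (>= 90%) within a longer kept pair's arms
  ovl_frac <- function(a1, a2, b1, b2) {
    ov <- min(a2, b2) - max(a1, b1) + 1L
    max(0L, ov) / (a2 - a1 + 1L)
  }
  cands <- cands[order(-vapply(cands, `[[`, integer(1), "arm"))]
  kept <- list()
  for (c0 in cands) {
    shadowed <- any(vapply(kept, function(kp)
      ovl_frac(c0$le, c0$li, kp$le, kp$li) >= 0.9 &&
        ovl_frac(c0$rs, c0$re, kp$rs, kp$re) >= 0.9,
      logical(1)))
    if (!shadowed) kept[[length(kept) + 1L]] <- c0
  }
  lapply(kept, function(c0) new_tle(
    left = list(start = c0$le, end = c0$li),
    right = list(start = c0$rs, end = c0$re),
    insert = list(start = c0$li + 1L, end = c0$rs - 1L)))
}

#' Junction probe sequences of an inverted-repeat element
#'
#' The two reference probes join each IR arm to the insert in reference
#' orientation; the two inversion probes arise when the insert between the
#' IRs is reverse-complemented. Each probe spans the *whole* IR arm plus `k`
#' bases of flanking sequence on both sides. Spanning the full arm is
#' essential: the arms are mutual reverse complements, so a probe covering
#' only part of an arm is identical to the reverse complement of the
#' opposite junction's probe and cannot witness orientation (this is why
#' reads longer than the repeat arrays are needed to see such inversions).
#'
#' @param genome a `circular_genome`.
#' @param element a `transposon_like_element`.
#' @param k flank length beyond each arm end.
#' @return named character vector of four probes (`ref_left`, `ref_right`,
#'   `inv_left`, `inv_right`), each of length `arm + 2k`.
#' @export
junction_kmers <- function(genome, element, k) {
  seq <- genome$sequence
  n <- genome$length
  ins <- substr_circ(seq, element$insert$start, element$insert$end)
  ins_rc <- revcomp(ins)
  if (nchar(ins) < k) stop("insert shorter than flank k", call. = FALSE)
  left_arm <- substr_circ(seq, element$left$start, element$left$end)
  right_arm <- substr_circ(seq, element$right$start, element$right$end)
  outer_left <- substr_circ(seq, wrap1(element$left$start - k, n),
                            wrap1(element$left$start - 1L, n))
  outer_right <- substr_circ(seq, wrap1(element$right$end + 1L, n),
                             wrap1(element$right$end + k, n))
  c(ref_left = paste0(outer_left, left_arm, substr(ins, 1L, k)),
    ref_right = paste0(substr(ins, nchar(ins) - k + 1L, nchar(ins)),
                       right_arm, outer_right),
    inv_left = paste0(outer_left, left_arm, substr(ins_rc, 1L, k)),
    inv_right = paste0(substr(ins_rc, nchar(ins_rc) - k + 1L, nchar(ins_rc)),
                       right_arm, outer_right))
}

#' Count read support for reference vs inverted junctions
#'
#' Exact containment of the four junction probes ([junction_kmers()]) in each
#' read, in either orientation. Counts are evidence for the two element
#' orientations, not a genotype call.
#'
#' @param reads character vector of read sequences.
#' @param element a `transposon_like_element`.
#' @param genome a `circular_genome`.
#' @param k junction flank in bp; reads must be longer than the probe,
#'   i.e. longer than `arm + 2k`.
#' @return named integer vector: `ref_junction_count`,
#'   `inverted_junction_count` (summed over both junctions of each
#'   orientation).
#' @export
inversion_junction_support <- function(reads, element, genome, k = 25L) {
  if (!length(reads)) stop("no reads supplied", call. = FALSE)
  arm <- element$left$end - element$left$start + 1L
  if (min(nchar(reads)) <= arm + 2L * k) {
    stop("k = ", k, " with a ", arm, " bp arm requires reads longer than ",
         arm + 2L * k, " bp", call. = FALSE)
  }
  jk <- junction_kmers(genome, element, k)
  haystack <- paste(reads, revcomp(reads), sep = " ")
  count <- vapply(jk, function(pat)
    sum(grepl(pat, haystack, fixed = TRUE)), integer(1))
  c(ref_junction_count = unname(count["ref_left"] + count["ref_right"]),
    inverted_junction_count = unname(count["inv_left"] + count["inv_right"]))
}

#' Reverse-complement the insert of an IR element within its genome
#'
#' Models the inversion state of a transposon-like element: the insert
#' between the two inverted repeats is replaced by its reverse complement.
#'
#' @param genome a `circular_genome`.
#' @param element a `transposon_like_element`.
#' @return the inverted `circular_genome`.
#' @export
invert_element <- function(genome, element) {
  s <- genome$sequence
  from <- element$insert$start
  to <- element$insert$end
  if (to < from) stop("wrap-around inserts are not supported", call. = FALSE)
  circular_genome(paste0(substr(s, 1L, from - 1L),
                         revcomp(substr(s, from, to)),
                         substr(s, to + 1L, nchar(s))),
                  id = paste0(genome$id, "_inv"))
}
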