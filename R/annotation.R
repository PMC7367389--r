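#' Load a precise-annotation table
#'
#' Reads a TSV with columns `Gene`, `Strand`, `Start`, `End`, `Length` and an
#' optional `DNARegion` flag into an annotation set. A precise annotation
#' partitions both strands of a circular genome into named features at 1-bp
#' resolution; features flagged as DNA regions (e.g. a control region
#' annotated at the DNA rather than RNA level) are carried along but excluded
#' from strand-tiling validation.
#'
#' Coordinates are 1-based inclusive; `End < Start` encodes a feature that
#' wraps the origin. The genome length is taken as the maximum annotated
#' coordinate unless `genome_length` is supplied. Each row's declared
#' `Length` is cross-checked against the length computed from coordinates.
#'
#' @param path TSV file. Thousands separators (commas) in numeric columns are
#'   tolerated.
#' @param genome_length optional known circular genome size; defaults to the
#'   maximum annotated coordinate.
#' @return an object of class `annotation_set`: list with `genome_length` and
#'   a data.frame `features` (name, strand, start, end, length, dna_region).
#' @export
load_annotation_table <- function(path, genome_length = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  need <- c("Gene", "Strand", "Start", "End", "Length")
  if (!all(need %in% names(df))) {
    stop("annotation table must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  num <- function(x) {
    v <- suppressWarnings(as.integer(gsub(",", "", as.character(x))))
    v
  }
  feats <- data.frame(
    name = as.character(df$Gene),
    strand = as.character(df$Strand),
    start = num(df$Start),
    end = num(df$End),
    declared_length = num(df$Length),
    dna_region = if ("DNARegion" %in% names(df)) {
      as.logical(num(df$DNARegion))
    } else {
      grepl("\\*$", df$Gene)
    },
    stringsAsFactors = FALSE
  )
  feats$name <- sub("\\*$", "", feats$name)
  feats$strand <- ifelse(grepl("-", feats$strand), "-", "+")
  bad <- which(is.na(feats$start) | is.na(feats$end) | is.na(feats$declared_length))
  if (length(bad)) {
    stop("malformed annotation row(s) at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path, call. = FALSE)
  }
  n <- if (is.null(genome_length)) max(feats$start, feats$end) else genome_length
  feats$length <- feature_length(feats$start, feats$end, n)
  mism <- which(feats$length != feats$declared_length)
  if (length(mism)) {
    stop("declared vs computed length mismatch for feature(s): ",
         paste(sprintf("%s (declared %d, computed %d)", feats$name[mism],
                       feats$declared_length[mism], feats$length[mism]),
               collapse = "; "), call. = FALSE)
  }
  feats$declared_length <- NULL
  structure(list(genome_length = n, features = feats),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d features on a %d bp circle (%d DNA-region)\n",
              nrow(x$features), x$genome_length, sum(x$features$dna_region)))
  invisible(x)
}

# contiguous runs of positions with a given coverage predicate, merged across
# the origin when circular
runs_where <- function(flag, circular = TRUE) {
  n <- length(flag)
  if (!any(flag)) {
    return(data.frame(start = integer(), end = integer(), length = integer()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep])
  if (circular && nrow(out) > 1L && out$start[1L] == 1L &&
      out$end[nrow(out)] == n) {
    # merge the run that wraps the origin
    out$start[1L] <- out$start[nrow(out)]
    out$length[1L] <- out$length[1L] + out$length[nrow(out)]
    out <- out[-nrow(out), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Validate gap-free / overlap-free strand coverage
#'
#' For each strand independently, checks that the non-DNA-region features tile
#' the full circle with neither uncovered (gap) nor doubly covered (overlap)
#' positions. A valid precise annotation yields an empty report on both
#' strands.
#'
#' @param ann an `annotation_set`.
#' @return list of class `coverage_report` with per-strand data.frames `gaps`
#'   and `overlaps` (start, end, length; circular intervals merged across the
#'   origin) and a logical `valid`.
#' @export
validate_strand_coverage <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  n <- ann$genome_length
  report <- list()
  for (st in c("+", "-")) {
    f <- ann$features[ann$features$strand == st & !ann$features$dna_region, ,
                      drop = FALSE]
    cov <- integer(n)
    for (i in seq_len(nrow(f))) {
      if (f$end[i] >= f$start[i]) {
        idx <- f$start[i]:f$end[i]
      } else {
        idx <- c(f$start[i]:n, 1L:f$end[i])
      }
      cov[idx] <- cov[idx] + 1L
    }
    report[[st]] <- list(gaps = runs_where(cov == 0L),
                         overlaps = runs_where(cov >= 2L))
  }
  report$valid <- all(vapply(report[c("+", "-")], function(r)
    nrow(r$gaps) == 0L && nrow(r$overlaps) == 0L, logical(1)))
  class(report) <- "coverage_report"
  report
}

#' @export
print.coverage_report <- function(x, ...) {
  for (st in c("+", "-")) {
    cat(sprintf("strand %s: %d gap(s), %d overlap(s)\n", st,
                nrow(x[[st]]$gaps), nrow(x[[st]]$overlaps)))
  }
  cat(if (isTRUE(x$valid)) "annotation tiles both strands completely\n"
      else "annotation is NOT a valid precise annotation\n")
  invisible(x)
}

#' Export an annotation set as GFF3
#'
#' Feature type goes in column 3 (`gene`), strand in column 7; the DNA-region
#' flag is carried as a `dna_region` attribute. Wrap-around features are
#' emitted with their stored start/end and an `Is_circular`-style note, since
#' GFF3 has no native circular coordinates.
#'
#' @param ann an `annotation_set`.
#' @param path output file.
#' @param seqid sequence identifier for column 1.
#' @return the path, invisibly.
#' @export
write_annotation_gff3 <- function(ann, path, seqid = "genome") {
  f <- ann$features
  attrs <- sprintf("ID=%s;Name=%s;dna_region=%s%s",
                   make.unique(f$name), f$name,
                   ifelse(f$dna_region, "true", "false"),
                   ifelse(f$end < f$start, ";wraps_origin=true", ""))
  lines <- sprintf("%s\tmitostr\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   seqid, f$start, f$end, f$strand, attrs)
  writeLines(c("##gff-version 3",
               sprintf("##sequence-region %s 1 %d", seqid, ann$genome_length),
               lines), path)
  invisible(path)
}
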