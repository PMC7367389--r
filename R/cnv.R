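#' Build the allele table for one STR locus
#'
#' Aggregates the pileup column at the STR position (after indel
#' left-normalisation; see [left_normalize_indels()]) into an allele table:
#' expanded alleles ordered by depth descending, ties broken by label. The
#' reference allele is the most frequent one — at deep coverage of a single
#' individual's mtDNA this is the genome's own STR.
#'
#' @param columns list of `pileup_column` covering the locus (or a single
#'   column).
#' @param locus an `str_locus`.
#' @return object of class `allele_table`: list with `locus`, `entries`
#'   (data.frame label/class/copies/delta_copies/depth), `reference` (top
#'   entry label), `total_depth`, and `empty` flag when no reads cover the
#'   locus.
#' @export
tabulate_alleles <- function(columns, locus) {
  if (inherits(columns, "pileup_column")) columns <- list(columns)
  pos_of <- vapply(columns, `[[`, integer(1), "pos")
  hit <- which(pos_of == locus$position)
  if (!length(hit) || columns[[hit[1L]]]$depth == 0L) {
    return(structure(list(locus = locus, entries = NULL, reference = NA,
                          total_depth = 0L, empty = TRUE),
                     class = "allele_table"))
  }
  counts <- columns[[hit[1L]]]$counts
  exp <- lapply(names(counts), function(lab) expand_variant(locus, lab))
  df <- data.frame(
    label = vapply(exp, `[[`, character(1), "label"),
    raw_label = vapply(exp, `[[`, character(1), "raw_label"),
    class = vapply(exp, `[[`, character(1), "class"),
    copies = vapply(exp, `[[`, integer(1), "copies"),
    delta_copies = vapply(exp, `[[`, integer(1), "delta_copies"),
    depth = as.integer(counts),
    stringsAsFactors = FALSE
  )
  # identical expanded alleles (e.g. +2TA / +2AT at two phases) merge;
  # grouping is done by hand because NA copies (substitutions) must survive
  agg <- do.call(rbind, lapply(split(df, df$label), function(g) {
    g$depth[1L] <- sum(g$depth)
    g$raw_label[1L] <- paste(unique(g$raw_label), collapse = ",")
    g[1L, , drop = FALSE]
  }))
  agg <- agg[order(-agg$depth, agg$label), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(locus = locus, entries = agg,
                 reference = agg$label[1L],
                 total_depth = sum(agg$depth), empty = FALSE),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<allele_table> empty (no coverage)\n")
    return(invisible(x))
  }
  cat(sprintf("<allele_table> %s at %d: depth %d, alt ratio %.4f\n",
              format_str(x$locus$unit, x$locus$copies), x$locus$position,
              x$total_depth, alt_allele_ratio(x)))
  print(x$entries)
  invisible(x)
}

#' Alternative-allele ratio of an allele table
#'
#' The summed depth of all non-reference alleles divided by the total depth
#' at the STR position; the reference is the most frequent allele, so the
#' ratio lies in `[0, 1)`.
#'
#' @param table an `allele_table`.
#' @return a fraction in `[0, 1)`.
#' @export
alt_allele_ratio <- function(table) {
  if (isTRUE(table$empty) || table$total_depth == 0L) {
    stop("alternative-allele ratio undefined at zero depth", call. = FALSE)
  }
  (table$total_depth - table$entries$depth[1L]) / table$total_depth
}

#' Classify a single allele against a reference STR unit
#'
#' @param locus an `str_locus`; @param allele allele label.
#' @return one of `reference`, `cnv_whole_unit`, `substitution`,
#'   `other_indel`, `placeholder`.
#' @export
classify_allele <- function(locus, allele) {
  expand_variant(locus, allele)$class
}

#' Call STR copy-number variation from allele tables
#'
#' Applies the ratio selection rule: a locus is selected when its
#' alternative-allele ratio exceeds `threshold` (default 1%). The ratio sums
#' all alternative alleles, substitutions included.
#'
#' @param tables list of `allele_table` (from [tabulate_alleles()] or
#'   [read_str_allele_fixture()]).
#' @param threshold selection threshold on the alternative-allele ratio.
#' @return data.frame of class `str_variant_calls`: one row per locus with
#'   position, unit, copies, ref_label, class, total_depth, ref_depth,
#'   alt_ratio, n_alleles, n_cnv_alleles and selected; the per-locus allele
#'   tables are attached as attribute `"tables"`.
#' @export
str_variant_calls <- function(tables, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1) {
    stop("selection threshold must lie in (0, 1)", call. = FALSE)
  }
  rows <- lapply(tables, function(t) {
    if (isTRUE(t$empty)) {
      return(data.frame(position = t$locus$position, unit = t$locus$unit,
                        copies = t$locus$copies,
                        ref_label = NA_character_, class = classify_str(t$locus),
                        total_depth = 0L, ref_depth = 0L,
                        alt_ratio = NA_real_, n_alleles = 0L,
                        n_cnv_alleles = 0L, selected = FALSE,
                        stringsAsFactors = FALSE))
    }
    r <- alt_allele_ratio(t)
    data.frame(position = t$locus$position, unit = t$locus$unit,
               copies = t$locus$copies, ref_label = t$reference,
               class = classify_str(t$locus),
               total_depth = t$total_depth, ref_depth = t$entries$depth[1L],
               alt_ratio = r, n_alleles = nrow(t$entries),
               n_cnv_alleles = sum(t$entries$class == "cnv_whole_unit"),
               selected = r > threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tables") <- tables
  attr(out, "threshold") <- threshold
  class(out) <- c("str_variant_calls", class(out))
  out
}

#' Call STR CNV from an STR catalogue and pileup columns
#'
#' Convenience wrapper: left-normalises indels onto each catalogued array's
#' first position, tabulates one allele table per locus and applies the
#' selection rule.
#'
#' @param catalog STR catalogue data.frame ([find_strs()]).
#' @param columns list of `pileup_column` ([read_pileup()]).
#' @param threshold selection threshold (default 0.01, i.e. the 1% rule).
#' @param normalize left-normalise indel alleles first (default `TRUE`).
#' @return an `str_variant_calls` data.frame (see [str_variant_calls()]).
#' @export
call_str_cnv <- function(catalog, columns, threshold = 0.01,
                         normalize = TRUE) {
  if (normalize) columns <- left_normalize_indels(columns, catalog)
  tables <- lapply(seq_len(nrow(catalog)), function(i) {
    tabulate_alleles(columns,
                     str_locus(catalog$position[i], catalog$unit[i],
                               catalog$copies[i]))
  })
  str_variant_calls(tables, threshold)
}

#' Scan calls for candidate SNPs
#'
#' Lists substitution alleles whose individual frequency reaches
#' `per_allele_threshold`. Deep mitochondrial STR data typically yields an
#' empty report at 1%: the DNA variation is copy-number variation of repeat
#' units, not point substitutions.
#'
#' @param calls an `str_variant_calls` object.
#' @param per_allele_threshold minimum individual allele frequency
#'   (default 0.01). Zero lists every substitution allele.
#' @return data.frame with position, allele, depth and frequency.
#' @export
snp_scan <- function(calls, per_allele_threshold = 0.01) {
  tables <- attr(calls, "tables")
  rows <- lapply(tables, function(t) {
    if (isTRUE(t$empty)) return(NULL)
    e <- t$entries[t$entries$class == "substitution", , drop = FALSE]
    if (!nrow(e)) return(NULL)
    freq <- e$depth / t$total_depth
    keep <- freq >= per_allele_threshold & freq > 0
    if (!any(keep)) return(NULL)
    data.frame(position = t$locus$position, allele = e$label[keep],
               depth = e$depth[keep], frequency = freq[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(position = integer(), allele = character(),
                      depth = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read a published-style STR allele fixture table
#'
#' Ingests a TSV with columns `Position`, `Gene`, `Ref` (bracketed STR
#' notation), `Allele` (slash-separated pileup-dialect labels, typeset
#' variants tolerated) and `Depth` (slash-separated counts, thousands commas
#' tolerated), and expands each row into an `allele_table`.
#'
#' @param path TSV file; defaults to the packaged *D. silvarum* table.
#' @return named list of `allele_table` (names are positions), each carrying
#'   a `gene` field.
#' @export
read_str_allele_fixture <- function(path = mitostr_example("dsilvarum_str_alleles.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  tables <- lapply(seq_len(nrow(df)), function(i) {
    ref <- parse_str(df$Ref[i])
    locus <- str_locus(df$Position[i], ref$unit, ref$copies)
    labels <- normalize_allele_label(strsplit(df$Allele[i], "/", fixed = TRUE)[[1]])
    depths <- as.integer(gsub(",", "", strsplit(df$Depth[i], "/", fixed = TRUE)[[1]]))
    if (length(labels) != length(depths)) {
      stop("allele/depth count mismatch in row ", i, " of ", path,
           call. = FALSE)
    }
    col <- pileup_column(locus$position, substr(locus$unit, 1L, 1L),
                         stats::setNames(depths, labels))
    t <- tabulate_alleles(list(col), locus)
    t$gene <- df$Gene[i]
    t
  })
  names(tables) <- as.character(df$Position)
  tables
}

#' Serialise calls in the published one-row-per-position layout
#'
#' @param calls an `str_variant_calls` object.
#' @param path output TSV.
#' @param meta named character vector for the provenance header.
#' @return the path, invisibly.
#' @export
write_calls_table_layout <- function(calls, path, meta = character()) {
  tables <- attr(calls, "tables")
  df <- do.call(rbind, lapply(tables, function(t) {
    if (isTRUE(t$empty)) return(NULL)
    lab <- t$entries$raw_label
    lab[1L] <- "Ref"
    data.frame(Position = t$locus$position,
               Gene = if (!is.null(t$gene)) t$gene else "",
               Ref = format_str(t$locus$unit, t$locus$copies),
               Allele = paste(lab, collapse = "/"),
               Depth = paste(t$entries$depth, collapse = "/"),
               AltRatio = sprintf("%.1f%%", 100 * alt_allele_ratio(t)),
               stringsAsFactors = FALSE)
  }))
  write_tsv_report(df, path, meta)
}

#' Serialise calls in long format (one allele per row)
#'
#' @inheritParams write_calls_table_layout
#' @export
write_calls_long <- function(calls, path, meta = character()) {
  tables <- attr(calls, "tables")
  df <- do.call(rbind, lapply(tables, function(t) {
    if (isTRUE(t$empty)) return(NULL)
    data.frame(position = t$locus$position,
               ref = format_str(t$locus$unit, t$locus$copies),
               allele = t$entries$label, class = t$entries$class,
               depth = t$entries$depth,
               frequency = t$entries$depth / t$total_depth,
               stringsAsFactors = FALSE)
  }))
  write_tsv_report(df, path, meta)
}
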