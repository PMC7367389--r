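#' Apply an STR copy-number change to a genome
#'
#' Resizes the repeat array at `locus` by `delta_copies` whole units; the
#' genome length changes by `delta_copies * m`.
#'
#' @param genome a `circular_genome`.
#' @param locus an `str_locus`.
#' @param delta_copies signed integer; deletions must leave at least one copy
#'   (`delta_copies >= -(copies - 1)`).
#' @return the mutated `circular_genome`.
#' @export
apply_cnv <- function(genome, locus, delta_copies) {
  delta_copies <- as.integer(delta_copies)
  if (delta_copies < -(locus$copies - 1L)) {
    stop("deletion of ", -delta_copies, " units exceeds the ", locus$copies,
         "-copy array", call. = FALSE)
  }
  n <- genome$length
  m <- nchar(locus$unit)
  arr_end <- locus$position + locus$array_length - 1L
  obs <- substr_circ(genome$sequence, locus$position, wrap1(arr_end, n))
  if (obs != strrep(locus$unit, locus$copies)) {
    stop("genome does not carry ", format_str(locus$unit, locus$copies),
         " at position ", locus$position, call. = FALSE)
  }
  if (delta_copies == 0L) return(genome)
  new_array <- strrep(locus$unit, locus$copies + delta_copies)
  if (arr_end <= n) {
    seq2 <- paste0(substr(genome$sequence, 1L, locus$position - 1L),
                   new_array,
                   substr(genome$sequence, arr_end + 1L, n))
  } else {
    # array wraps the origin: rotate so it doesn't, edit, rotate back
    rot <- paste0(substr(genome$sequence, locus$position, n),
                  substr(genome$sequence, 1L, locus$position - 1L))
    seq2 <- paste0(new_array, substr(rot, locus$array_length + 1L, n))
  }
  circular_genome(seq2, id = genome$id)
}

#' Translate a CDS until the first stop codon
#'
#' Scans codons under the requested genetic code (default NCBI table 5,
#' invertebrate mitochondrial: TAA/TAG stop, TGA = Trp, AGA/AGG = Ser,
#' ATA = Met) and reports the CDS length up to and including the first stop
#' and the protein length excluding it. Many mitochondrial genes end on an
#' incomplete, polyadenylation-completed stop; when no stop is reached the
#' result is flagged `stop_found = FALSE` (reported downstream as stop_loss).
#'
#' @param cds DNA string beginning at the start codon.
#' @param code genetic code id passed to [Biostrings::getGeneticCode()]
#'   (default `"5"`).
#' @return list with `cds_bp` (bp consumed including the stop, `NA` if no
#'   stop), `protein_aa`, `protein` (amino-acid string scanned) and
#'   `stop_found`.
#' @export
#' @examples
#' translate_to_stop("ATGAAATAA")   # 9 bp, 2 aa ("MK")
translate_to_stop <- function(cds, code = "5") {
  cds <- toupper(cds)
  check_dna(cds, "CDS")
  if (nchar(cds) < 3L) stop("CDS shorter than one codon", call. = FALSE)
  gc <- Biostrings::getGeneticCode(code)
  ncod <- nchar(cds) %/% 3L
  starts <- 3L * (seq_len(ncod) - 1L) + 1L
  aa <- unname(gc[substring(cds, starts, starts + 2L)])
  stop_at <- which(aa == "*")[1L]
  if (is.na(stop_at)) {
    list(cds_bp = NA_integer_, protein_aa = ncod,
         protein = paste(aa, collapse = ""), stop_found = FALSE)
  } else {
    list(cds_bp = 3L * stop_at, protein_aa = stop_at - 1L,
         protein = paste(aa[seq_len(stop_at - 1L)], collapse = ""),
         stop_found = TRUE)
  }
}

#' Coding consequence of an STR copy-number change inside a gene
#'
#' Mutates the gene's CDS in sequence space (so circular-coordinate shifts
#' never arise), translates from the annotated gene start under the
#' invertebrate mitochondrial code and classifies the change:
#' `synonymous_length` (delta 0), `in_frame` (delta bases a multiple of 3),
#' `frameshift_truncation` (frame broken, premature stop reached) or
#' `stop_loss` (no stop before the end of the available sequence).
#'
#' For an N-strand gene the CDS is the reverse complement of the annotated
#' interval and the array appears unit-reverse-complemented at the mirrored
#' offset; translation always proceeds 5'->3' in CDS space.
#'
#' @param genome a `circular_genome`.
#' @param feature annotation feature (list/row with name, strand, start,
#'   end) whose CDS contains the locus.
#' @param locus an `str_locus` (J-strand coordinates).
#' @param delta_copies signed copy-number change.
#' @param code genetic code id (default `"5"`).
#' @return object of class `coding_consequence`: list with `gene`, `variant`
#'   label, `delta_bases`, `consequence`, `cds_bp`, `protein_aa` and the
#'   reference `ref_cds_bp`/`ref_protein_aa`.
#' @export
coding_consequence <- function(genome, feature, locus, delta_copies,
                               code = "5") {
  n <- genome$length
  m <- nchar(locus$unit)
  flen <- feature_length(feature$start, feature$end, n)
  # offset (0-based) of the array's first base within the annotated interval
  off_j <- (locus$position - feature$start) %% n
  arr_end <- wrap1(locus$position + locus$array_length - 1L, n)
  if (off_j + locus$array_length > flen) {
    stop("STR locus at ", locus$position, " lies outside the ",
         feature$name, " CDS", call. = FALSE)
  }
  cds <- extract_feature_sequence(genome, feature)
  if (identical(feature$strand, "-")) {
    unit_cds <- revcomp(locus$unit)
    off <- (feature$end - arr_end) %% n
  } else {
    unit_cds <- locus$unit
    off <- off_j
  }
  arr <- substr(cds, off + 1L, off + locus$array_length)
  # the in-CDS array is some rotation-phase of the unit; re-anchor on it
  phase_ok <- vapply(rotations(unit_cds), function(r)
    strrep(r, locus$copies) == arr, logical(1))
  if (!any(phase_ok)) {
    stop("annotated CDS does not carry ", format_str(locus$unit, locus$copies),
         " at the expected offset", call. = FALSE)
  }
  unit_cds <- rotations(unit_cds)[which(phase_ok)[1L]]
  if (delta_copies < -(locus$copies - 1L)) {
    stop("deletion exceeds the array", call. = FALSE)
  }
  mut_cds <- paste0(substr(cds, 1L, off),
                    strrep(unit_cds, locus$copies + delta_copies),
                    substr(cds, off + locus$array_length + 1L, nchar(cds)))
  ref_tr <- translate_to_stop(cds, code)
  mut_tr <- translate_to_stop(mut_cds, code)
  delta_bases <- delta_copies * m
  consequence <- if (delta_bases %% 3L == 0L) {
    if (delta_copies == 0L) "synonymous_length" else "in_frame"
  } else if (mut_tr$stop_found) {
    "frameshift_truncation"
  } else {
    "stop_loss"
  }
  structure(list(gene = feature$name,
                 variant = format_str(locus$unit, locus$copies + delta_copies),
                 position = locus$position, delta_copies = delta_copies,
                 delta_bases = delta_bases, consequence = consequence,
                 cds_bp = mut_tr$cds_bp, protein_aa = mut_tr$protein_aa,
                 ref_cds_bp = ref_tr$cds_bp, ref_protein_aa = ref_tr$protein_aa),
            class = "coding_consequence")
}

#' @export
print.coding_consequence <- function(x, ...) {
  cat(sprintf("<coding_consequence> %s %s at %d (%+d unit%s): %s",
              x$gene, x$variant, x$position, x$delta_copies,
              if (abs(x$delta_copies) == 1L) "" else "s", x$consequence))
  if (!is.na(x$cds_bp)) {
    cat(sprintf(" -> %d-bp CDS, %d-aa protein", x$cds_bp, x$protein_aa))
  }
  cat("\n")
  invisible(x)
}

#' Consequence report for selected CNV calls inside coding genes
#'
#' @param genome a `circular_genome`.
#' @param ann an `annotation_set` (coding features matched by containing
#'   interval).
#' @param calls an `str_variant_calls` object.
#' @param genes optional character vector restricting the report.
#' @param code genetic code id.
#' @return data.frame, one row per (locus, CNV allele).
#' @export
consequence_report <- function(genome, ann, calls, genes = NULL, code = "5") {
  tables <- attr(calls, "tables")
  rows <- list()
  for (t in tables) {
    if (isTRUE(t$empty)) next
    p <- t$locus$position
    f <- ann$features
    hit <- which(((f$end >= f$start & p >= f$start & p <= f$end) |
                    (f$end < f$start & (p >= f$start | p <= f$end))) &
                   !f$dna_region &
                   !grepl("AS|^HAS|^LAS|^Intergenic|^R[0-9]|tRNA|rRNA|^CR",
                          f$name))
    if (!length(hit)) next
    feat <- as.list(f[hit[1L], ])
    if (!is.null(genes) && !feat$name %in% genes) next
    cnv <- t$entries[t$entries$class == "cnv_whole_unit", , drop = FALSE]
    for (i in seq_len(nrow(cnv))) {
      cc <- coding_consequence(genome, feat, t$locus, cnv$delta_copies[i],
                               code)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = cc$gene, position = cc$position, variant = cc$variant,
        depth = cnv$depth[i], delta_bases = cc$delta_bases,
        consequence = cc$consequence, cds_bp = cc$cds_bp,
        protein_aa = cc$protein_aa, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), position = integer(),
                      variant = character(), depth = integer(),
                      delta_bases = integer(), consequence = character(),
                      cds_bp = integer(), protein_aa = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}
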