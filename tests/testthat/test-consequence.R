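test_that("apply_cnv resizes arrays and validates inputs", {
  g <- circular_genome(paste0("CC", strrep("G", 8), "TT"))
  locus <- str_locus(3, "G", 8)
  expect_equal(apply_cnv(g, locus, +1)$length, g$length + 1)
  expect_equal(apply_cnv(g, locus, +1)$sequence,
               paste0("CC", strrep("G", 9), "TT"))
  expect_equal(apply_cnv(g, locus, 0)$sequence, g$sequence)
  expect_error(apply_cnv(g, locus, -8), "exceeds")
  expect_error(apply_cnv(g, str_locus(1, "A", 2), -1), "does not carry")

  g2 <- circular_genome(paste0("CC", strrep("TA", 9), "GG"))
  expect_equal(apply_cnv(g2, str_locus(3, "TA", 9), -1)$length, g2$length - 2)

  # wrap-around array: [A]6 crossing the origin of a 20-mer
  set.seed(5)
  g3 <- circular_genome(paste0("AAA", paste(sample(c("C", "G"), 14, TRUE),
                                            collapse = ""), "AAA"))
  mut <- apply_cnv(g3, str_locus(18, "A", 6), +2)
  expect_equal(mut$length, 22)
  cat3 <- find_strs(mut, min_copies_by_unit_len = c(`1` = 5))
  expect_equal(cat3$copies[cat3$unit == "A"], 8)
})

test_that("apply_cnv +1 then -1 is the identity", {
  set.seed(17)
  truth <- generate_genome(seed = 31)
  for (i in seq_len(nrow(truth$str_truth))) {
    r <- truth$str_truth[i, ]
    locus <- str_locus(r$position, r$unit, r$copies)
    up <- apply_cnv(truth$genome, locus, +1)
    locus_up <- str_locus(r$position, r$unit, r$copies + 1)
    back <- apply_cnv(up, locus_up, -1)
    expect_equal(back$sequence, truth$genome$sequence)
  }
})

test_that("translate_to_stop follows the invertebrate mitochondrial code", {
  expect_equal(translate_to_stop("ATGAAATAA")[c("cds_bp", "protein_aa")],
               list(cds_bp = 9L, protein_aa = 2L))
  expect_equal(translate_to_stop("ATGAAATAA")$protein, "MK")
  # TGA is Trp, not stop, under code table 5
  expect_equal(translate_to_stop("TGATAA")[c("cds_bp", "protein_aa")],
               list(cds_bp = 6L, protein_aa = 1L))
  # AGA/AGG are Ser; ATA is Met
  expect_equal(translate_to_stop("ATAAGAAGGTAG")$protein, "MSS")
  expect_false(translate_to_stop("ATGAAA")$stop_found)
  expect_error(translate_to_stop("AT"), "shorter")
  expect_error(translate_to_stop("ATGNNN"), "outside")
})

test_that("translate_to_stop matches a naive codon-walk oracle", {
  set.seed(77)
  for (i in 1:100) {
    cds <- random_dna(3 * sample(10:300, 1), at = 0.7)
    got <- translate_to_stop(cds)
    want <- oracle_translate(cds)
    expect_equal(got$cds_bp, if (is.na(want$cds_bp)) NA_integer_ else want$cds_bp)
    expect_equal(got$protein_aa, want$protein_aa)
    expect_equal(got$stop_found, want$stop_found)
  }
})

# a synthetic CDS carrying a homopolymer whose +1 expansion frameshifts into
# an early stop; built codon-by-codon so the expectations are enumerable:
#   ref   ATG GGG GGG GCT AAG GTT TAC TCT TAA   (8 aa + stop, no early stop)
#   +1 G  ATG GGG GGG GGC TAA ...               (stop at codon 5)
synthetic_gene <- function() {
  cds <- paste0("ATG", "GGG", "GGG", "GCT", "AAG", "GTT", "TAC", "TCT", "TAA")
  stopifnot(nchar(cds) %% 3 == 0)
  cds
}

test_that("coding_consequence classifies frameshift vs in-frame on J-strand", {
  cds <- synthetic_gene()
  flank5 <- "CCTCC"
  genome <- circular_genome(paste0(flank5, cds, "CCTCC"))
  feat <- list(name = "toy", strand = "+", start = nchar(flank5) + 1,
               end = nchar(flank5) + nchar(cds))
  locus <- str_locus(nchar(flank5) + 4, "G", 7)

  cc0 <- coding_consequence(genome, feat, locus, 0)
  expect_equal(cc0$consequence, "synonymous_length")
  cc1 <- coding_consequence(genome, feat, locus, +1)
  expect_equal(cc1$consequence, "frameshift_truncation")
  # oracle: translate the mutated CDS directly
  mut <- paste0("ATG", strrep("G", 8), "CTAAGGTTTACTCTTAA")
  want <- oracle_translate(mut)
  expect_equal(cc1$cds_bp, want$cds_bp)
  expect_equal(cc1$protein_aa, want$protein_aa)

  cc3 <- coding_consequence(genome, feat, locus, +3)
  expect_equal(cc3$consequence, "in_frame")
  expect_equal(cc3$protein_aa, cc3$ref_protein_aa + 1)

  cc_loss <- coding_consequence(genome, feat, locus, -1)
  want2 <- oracle_translate(paste0("ATG", strrep("G", 6), "CTAAGGTTTACTCTTAA"))
  expect_equal(cc_loss$consequence,
               if (want2$stop_found) "frameshift_truncation" else "stop_loss")
  expect_error(coding_consequence(genome, feat, str_locus(1, "C", 2), 1),
               "outside")
})

test_that("N-strand genes translate from the reverse complement", {
  cds <- synthetic_gene()
  flank <- "CCTCC"
  rc <- mitostr::revcomp(cds)
  genome <- circular_genome(paste0(flank, rc, flank))
  feat <- list(name = "toyN", strand = "-", start = nchar(flank) + 1,
               end = nchar(flank) + nchar(cds))
  # the [G]7 run appears as [C]7 on the J-strand
  jpos <- nchar(flank) + nchar(cds) - (4 + 7 - 1) + 1
  locus <- str_locus(jpos, "C", 7)
  cc1 <- coding_consequence(genome, feat, locus, +1)
  want <- oracle_translate(paste0("ATG", strrep("G", 8), "CTAAGGTTTACTCTTAA"))
  expect_equal(cc1$consequence, "frameshift_truncation")
  expect_equal(cc1$cds_bp, want$cds_bp)
  expect_equal(cc1$protein_aa, want$protein_aa)
})

test_that("frame rule holds across random unit sizes", {
  set.seed(13)
  for (i in 1:30) {
    m <- sample(1:4, 1)
    unit <- random_dna(m)
    if (!mitostr:::is_primitive_unit(unit)) next
    k <- sample(5:8, 1)
    d <- sample(c(-2, -1, 1, 2, 3), 1)
    cds <- paste0("ATG", strrep(unit, k), random_dna(60, at = 0.6), "TAATAA")
    pad <- (3 - nchar(cds) %% 3) %% 3
    cds <- paste0(cds, strrep("A", pad))
    genome <- circular_genome(paste0("GGCGG", cds, "GGCGG"))
    feat <- list(name = "g", strand = "+", start = 6, end = 5 + nchar(cds))
    locus <- str_locus(9, unit, k)
    cc <- coding_consequence(genome, feat, locus, d)
    if ((d * m) %% 3 == 0) {
      expect_true(cc$consequence %in% c("in_frame", "synonymous_length"))
    } else {
      expect_true(cc$consequence %in% c("frameshift_truncation", "stop_loss"))
    }
  }
})
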