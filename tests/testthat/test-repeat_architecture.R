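make_lib <- function(seed = 61) {
  set.seed(seed)
  unit_library(c(R28 = random_dna(28, at = 0.7),
                 R34 = random_dna(34, at = 0.7),
                 R44 = random_dna(44, at = 0.7)))
}

test_that("array decomposition reconstructs pure, hybrid and partial arrays", {
  lib <- make_lib()
  u34 <- lib$units[["R34"]]
  u28 <- lib$units[["R28"]]

  pure <- decompose_array(strrep(u34, 5), lib)
  expect_equal(pure$pattern, "[R34]5")
  expect_equal(pure$total_copies, 5)
  expect_true(is.na(pure$partial))

  hybrid <- decompose_array(paste0(strrep(u34, 2), strrep(u28, 3), u34), lib)
  expect_equal(hybrid$pattern, "[R34]2-[R28]3-[R34]1")

  partial <- decompose_array(paste0(strrep(u34, 2), substr(u34, 1, 17)), lib)
  expect_equal(partial$blocks$copies, 3)   # partial unit counted as one
  expect_equal(partial$partial, "R34")

  expect_error(decompose_array(paste0("NOPE", u34), lib))
  expect_error(decompose_array(chartr("ACGT", "TGCA", u34), lib),
               "offset 1")
})

test_that("decomposition reconstruction is exact and mismatch-tolerant", {
  lib <- make_lib(62)
  set.seed(63)
  for (i in 1:20) {
    types <- sample(names(lib$units), sample(1:3, 1))
    blocks <- lapply(types, function(t) strrep(lib$units[[t]], sample(1:4, 1)))
    seq <- paste(unlist(blocks), collapse = "")
    dec <- decompose_array(seq, lib)
    rebuilt <- paste(mapply(function(ty, k) strrep(lib$units[[ty]], k),
                            dec$blocks$type, dec$blocks$copies), collapse = "")
    expect_equal(rebuilt, seq)
  }
  # one substitution inside a unit is absorbed with a mismatch budget
  u <- lib$units[["R28"]]
  mut <- paste0(u, sub("A", "G", u), u)
  expect_error(decompose_array(mut, lib, max_mismatch_per_unit = 0))
  expect_equal(decompose_array(mut, lib, max_mismatch_per_unit = 1)$pattern,
               "[R28]3")
})

test_that("modal decomposition summarises a heterogeneous read multiset", {
  lib <- make_lib(64)
  u <- lib$units[["R44"]]
  seqs <- c(rep(strrep(u, 5), 6), rep(strrep(u, 4), 3), strrep(u, 2))
  modal <- modal_decomposition(seqs, lib)
  expect_equal(modal$pattern, "[R44]5")
  expect_equal(modal$support, 6)
})

test_that("reverse-complement unit relation is detected up to rotation", {
  set.seed(65)
  u <- random_dna(34)
  expect_true(revcomp_unit_match(u, revcomp(u))$match)
  # phase rotation of the partner unit still matches
  rot <- paste0(substr(revcomp(u), 12, 34), substr(revcomp(u), 1, 11))
  res <- revcomp_unit_match(u, rot)
  expect_true(res$match)
  expect_false(revcomp_unit_match("ACGTT", "ACGTT")$match)
})

test_that("annotation mode pairs the annotated repeats around their insert", {
  ann <- load_annotation_table(table2_path())
  els <- find_ir_elements(ann)
  expect_equal(length(els), 1)
  e <- els[[1]]
  expect_equal(c(e$left$start, e$left$end), c(5825, 5987))
  expect_equal(c(e$right$start, e$right$end), c(9391, 9559))
  expect_equal(e$insert_genes,
               c("ND1", "tRNA-Leu", "16S rRNA", "tRNA-Val", "12S rRNA",
                 "CR1", "tRNA-Ile", "tRNA-Gln"))
})

test_that("sequence scan finds exactly the planted IR pair", {
  truth <- generate_genome(seed = 71)
  e <- truth$ir_truth$element
  els <- find_ir_elements(truth$genome, min_ir_len = 30)
  expect_equal(length(els), 1)
  expect_equal(els[[1]]$left, list(start = e$left$start, end = e$left$end))
  expect_equal(els[[1]]$right, list(start = e$right$start, end = e$right$end))
  # the two arms really are reverse complements
  left_seq <- substr(truth$genome$sequence, e$left$start, e$left$end)
  right_seq <- substr(truth$genome$sequence, e$right$start, e$right$end)
  expect_equal(right_seq, oracle_revcomp(left_seq))
  # scanning the reverse complement mirrors the element
  n <- truth$genome$length
  rc_els <- find_ir_elements(circular_genome(oracle_revcomp(truth$genome$sequence)),
                             min_ir_len = 30)
  expect_equal(length(rc_els), 1)
  expect_equal(rc_els[[1]]$left$start, n - e$right$end + 1)
  expect_equal(rc_els[[1]]$right$end, n - e$left$start + 1)
  # a repeat-free genome yields nothing
  set.seed(72)
  expect_equal(length(find_ir_elements(circular_genome(random_dna(2000)),
                                       min_ir_len = 30)), 0)
})

test_that("junction support witnesses orientation in the degenerate cases", {
  truth <- generate_genome(seed = 73)
  e <- truth$ir_truth$element
  reads0 <- simulate_reads(truth, read_len = 250, depth = 60,
                           inversion_fraction = 0, seed = 74)
  s0 <- inversion_junction_support(reads0, e, truth$genome, k = 25)
  expect_gt(s0[["ref_junction_count"]], 0)
  expect_equal(s0[["inverted_junction_count"]], 0)

  inv_truth <- truth
  inv_truth$genome <- invert_element(truth$genome, e)
  reads1 <- simulate_reads(inv_truth, read_len = 250, depth = 60,
                           inversion_fraction = 0, seed = 75)
  s1 <- inversion_junction_support(reads1, e, truth$genome, k = 25)
  expect_equal(s1[["ref_junction_count"]], 0)
  expect_gt(s1[["inverted_junction_count"]], 0)

  expect_error(inversion_junction_support(reads0, e, truth$genome, k = 200),
               "longer than")
})

test_that("junction support recovers a planted inversion fraction", {
  truth <- generate_genome(seed = 76)
  e <- truth$ir_truth$element
  frac <- 0.05
  reads <- simulate_reads(truth, read_len = 250, depth = 400,
                          inversion_fraction = frac, seed = 77)
  s <- inversion_junction_support(reads, e, truth$genome, k = 25)
  n <- s[["ref_junction_count"]] + s[["inverted_junction_count"]]
  est <- s[["inverted_junction_count"]] / n
  expect_lt(abs(est - frac), 3 * sqrt(frac * (1 - frac) / n))
})
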