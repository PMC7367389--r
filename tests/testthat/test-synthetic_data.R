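test_that("genome generation is deterministic, feasible and as configured", {
  t1 <- generate_genome(seed = 101)
  t2 <- generate_genome(seed = 101)
  expect_identical(t1$genome$sequence, t2$genome$sequence)
  expect_equal(t1$genome$length, 15000)

  # requested planted features are present at the recorded coordinates
  for (i in seq_len(nrow(t1$str_truth))) {
    r <- t1$str_truth[i, ]
    expect_equal(substr(t1$genome$sequence, r$position,
                        r$position + nchar(r$unit) * r$copies - 1),
                 strrep(r$unit, r$copies))
  }
  # realized AT fraction within 2% of the requested 0.78 at 15 kb
  at <- mean(strsplit(t1$genome$sequence, "")[[1]] %in% c("A", "T"))
  expect_lt(abs(at - 0.78), 0.02)

  expect_error(generate_genome(length = 500, seed = 1), "exceed")
  expect_error(generate_genome(), "seed")
})

test_that("slippage distribution is exact, normalised and matches Monte-Carlo", {
  m0 <- slippage_model(p = 0, g = 10)
  d0 <- slippage_distribution(8, m0)
  expect_equal(unname(d0[["8"]]), 1)

  m1 <- slippage_model(p = 0.01, g = 1)
  d1 <- slippage_distribution(8, m1)
  expect_equal(unname(d1[c("7", "8", "9")]), c(0.01, 0.98, 0.01))

  # normalisation across a parameter sweep
  for (p in c(0.001, 0.05, 0.3)) {
    for (g in c(0, 1, 5, 20)) {
      d <- slippage_distribution(6, slippage_model(p = p, g = g))
      expect_equal(sum(d), 1, tolerance = 1e-12)
    }
  }

  # g = 20 walk against a 1e6-sample Monte-Carlo oracle, 3 sigma per class
  p <- 0.05; g <- 20; n0 <- 8; nsim <- 1e6
  exact <- slippage_distribution(n0, slippage_model(p = p, g = g))
  mc <- oracle_slippage_mc(n0, p, g, nsim, seed = 2024)
  for (k in seq_along(mc)) {
    pk <- exact[[as.character(k)]]
    sigma <- sqrt(pk * (1 - pk) / nsim)
    expect_lt(abs(mc[k] - pk), 3 * sigma + 1e-9)
  }
})

test_that("simulated pileups honour depth, truth frequencies and error rate", {
  truth <- generate_genome(seed = 103)
  model <- slippage_model(p = 0.02, g = 2, e = 0)
  cols <- simulate_pileup(truth, depth = 50000, model, seed = 104,
                          n_noise_columns = 20)
  expect_true(all(vapply(cols, `[[`, integer(1), "depth") == 50000))
  # e = 0: no substitution alleles anywhere
  labs <- unlist(lapply(cols, function(c) names(c$counts)))
  expect_false(any(labs %in% c("A", "C", "G", "T")))

  # depth 1 gives exactly one allele per column
  one <- simulate_pileup(truth, depth = 1, model, seed = 105,
                         n_noise_columns = 5)
  expect_true(all(vapply(one, function(c) sum(c$counts), integer(1)) == 1L))

  # planted frequencies recovered within binomial error at 1e5x
  depth <- 100000
  cols2 <- simulate_pileup(truth, depth, model, seed = 106,
                           n_noise_columns = 0)
  freqs <- true_allele_frequencies(truth, model)
  for (fl in freqs) {
    col <- cols2[[as.character(fl$locus$position)]]
    p_ref <- fl$freqs[[as.character(fl$locus$copies)]]
    sigma <- sqrt(p_ref * (1 - p_ref) / depth)
    expect_lt(abs(col$counts[["Ref"]] / depth - p_ref), 3 * sigma)
  }

  # substitution noise appears at rate e on background columns
  noisy <- simulate_pileup(truth, depth = 20000, slippage_model(e = 0.01),
                           seed = 107, n_noise_columns = 30)
  bg <- noisy[!names(noisy) %in% as.character(truth$str_truth$position)]
  sub_frac <- mean(vapply(bg, function(c)
    sum(c$counts[names(c$counts) %in% c("A", "C", "G", "T")]) / c$depth,
    numeric(1)))
  expect_lt(abs(sub_frac - 0.01), 0.002)
})

test_that("simulated pileups round-trip through the pileup dialect", {
  truth <- generate_genome(seed = 108)
  tmp <- tempfile(fileext = ".pileup")
  cols <- simulate_pileup(truth, depth = 5000,
                          slippage_model(p = 0.01, g = 3, e = 1e-3),
                          seed = 109, n_noise_columns = 10, path = tmp)
  back <- read_pileup(tmp)
  expect_equal(length(back), length(cols))
  for (nm in names(cols)) {
    a <- cols[[nm]]$counts; b <- back[[nm]]$counts
    expect_identical(a[order(names(a))], b[order(names(b))])
  }
})

test_that("read simulation covers the circle at the requested depth", {
  truth <- generate_genome(seed = 110)
  reads <- simulate_reads(truth, read_len = 150, depth = 50,
                          inversion_fraction = 0, seed = 111)
  total <- sum(nchar(reads))
  expect_lt(abs(total / truth$genome$length - 50) / 50, 0.05)
  expect_true(all(nchar(reads) == 150))
  # determinism
  reads2 <- simulate_reads(truth, read_len = 150, depth = 50,
                           inversion_fraction = 0, seed = 111)
  expect_identical(reads, reads2)
  expect_error(simulate_reads(truth, read_len = 150, depth = 1,
                              inversion_fraction = 0), "seed")
})

test_that("pipeline closure: no spurious selections in a noise-free world", {
  truth <- generate_genome(seed = 112)
  cols <- simulate_pileup(truth, depth = 50000, slippage_model(p = 0, e = 0),
                          seed = 113, n_noise_columns = 30)
  catalog <- find_strs(truth$genome)
  calls <- call_str_cnv(catalog, cols, threshold = 0.01)
  covered <- calls[calls$total_depth > 0, ]
  expect_true(all(covered$alt_ratio == 0))
  expect_equal(sum(calls$selected, na.rm = TRUE), 0)
})
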