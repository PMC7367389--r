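# Independent oracles and small generators used across the suite. These are
# deliberately naive re-derivations (character-vector loops, enumeration,
# Monte-Carlo) and share no code with the package implementations they check.

random_dna <- function(n, at = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)),
        collapse = "")
}

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Brute-force STR scanner: enumerate every (start, unit length m <= 6),
# greedily extend whole-unit copies, then filter primitive units, thresholds
# and base-level left-maximality (the preceding base must break the period).
oracle_find_strs <- function(seq, max_unit_len = 6,
                             min_copies = function(m) if (m == 1) 5 else 3,
                             min_array_len = 8) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  primitive <- function(u) {
    m <- length(u)
    if (m == 1) return(TRUE)
    for (d in seq_len(m - 1)) {
      if (m %% d == 0 && all(u == rep_len(u[seq_len(d)], m))) return(FALSE)
    }
    TRUE
  }
  hits <- list()
  for (p in seq_len(n)) {
    for (m in seq_len(max_unit_len)) {
      if (p + 2 * m - 1 > n) next
      u <- ch[p:(p + m - 1)]
      if (!primitive(u)) next
      k <- 1
      while (p + (k + 1) * m - 1 <= n &&
             all(ch[(p + k * m):(p + (k + 1) * m - 1)] == u)) k <- k + 1
      if (k < min_copies(m)) next
      if (m >= 2 && k * m < min_array_len) next
      if (p > 1 && ch[p - 1] == u[m]) next   # interior phase of the tract
      hits[[length(hits) + 1]] <-
        data.frame(position = p, unit = paste(u, collapse = ""),
                   copies = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(position = integer(), unit = character(),
                      copies = integer(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, hits)
  df <- df[order(df$position, nchar(df$unit)), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Naive codon walk under the invertebrate mitochondrial code, from an
# explicit stop/aa table (not Biostrings).
oracle_translate <- function(cds) {
  stops <- c("TAA", "TAG")
  ncod <- nchar(cds) %/% 3
  for (i in seq_len(ncod)) {
    codon <- substr(cds, 3 * i - 2, 3 * i)
    if (codon %in% stops) {
      return(list(cds_bp = 3 * i, protein_aa = i - 1, stop_found = TRUE))
    }
  }
  list(cds_bp = NA, protein_aa = ncod, stop_found = FALSE)
}

# Monte-Carlo slippage walk (reflecting lazy walk on copy number).
oracle_slippage_mc <- function(n0, p, g, nsim, seed) {
  set.seed(seed)
  state <- rep(n0, nsim)
  for (i in seq_len(g)) {
    u <- runif(nsim)
    up <- u < p
    down <- u >= p & u < 2 * p & state > 1
    state <- state + up - down
  }
  tabulate(state, nbins = n0 + g) / nsim
}

# random pileup column (canonical label counts) for round-trip fuzzing
random_column <- function(pos) {
  labs <- c("Ref", "A", "C", "G", "T", "*",
            paste0("+", nchar(c("A", "TA", "AAA")), c("A", "TA", "AAA")),
            paste0("-", nchar(c("A", "TT")), c("A", "TT")))
  pick <- sample(labs, sample(1:6, 1))
  if (!"Ref" %in% pick) pick <- c("Ref", pick)
  counts <- setNames(sample(1:50, length(pick), replace = TRUE), pick)
  pileup_column(pos, sample(c("A", "C", "G", "T"), 1), counts)
}

table2_path <- function() mitostr_example("dsilvarum_annotation.tsv")
table3_path <- function() mitostr_example("dsilvarum_str_alleles.tsv")
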