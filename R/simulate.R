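#' Replication-slippage model
#'
#' A minimal generative model for STR copy-number heteroplasmy: during each
#' of `g` propagation events the polymerase slips with probability `p` per
#' event, changing the copy number by +1 or -1 (a lazy random walk, its
#' down-moves reflected at one copy); point-substitution noise occurs at rate
#' `e` per base. The walk reproduces the +/-1-dominant allele spectra seen in
#' deep mitochondrial STR pileups.
#'
#' @param p per-event slippage probability for each direction (so a step is
#'   +1 w.p. `p`, -1 w.p. `p`, 0 w.p. `1 - 2p`); requires `p <= 0.5`.
#' @param g number of propagation events (walk steps).
#' @param e substitution error rate per sequenced base.
#' @return object of class `slippage_model`.
#' @export
slippage_model <- function(p = 0.01, g = 3L, e = 1e-4) {
  stopifnot(p >= 0, p <= 0.5, e >= 0, e <= 1, g >= 0)
  structure(list(p = p, g = as.integer(g), e = e), class = "slippage_model")
}

#' Copy-number distribution after slippage
#'
#' Exact distribution of the copy number after `g` lazy-walk events starting
#' from `n0` copies, computed by convolution. Down-moves at one copy are
#' reflected (the mass stays at one).
#'
#' @param n0 starting copy number (>= 2).
#' @param model a [slippage_model()].
#' @return named numeric vector: probabilities over copy numbers
#'   `1 .. n0 + g`, summing to one.
#' @export
#' @examples
#' slippage_distribution(8, slippage_model(p = 0.01, g = 1))
slippage_distribution <- function(n0, model) {
  stopifnot(n0 >= 2)
  p <- model$p
  g <- model$g
  kmax <- n0 + g
  prob <- numeric(kmax)
  prob[n0] <- 1
  if (g > 0L && p > 0) {
    for (step in seq_len(g)) {
      up <- c(0, prob[-kmax]) * p
      down <- c(prob[-1L], 0) * p
      stay <- prob * (1 - 2 * p)
      stay[1L] <- stay[1L] + prob[1L] * p   # reflected down-move at 1
      prob <- up + down + stay
    }
  }
  stats::setNames(prob, seq_len(kmax))
}

#' Generate a synthetic circular genome with planted features
#'
#' Emulates a small AT-rich circular mitochondrial genome carrying short
#' tandem repeats and one inverted-repeat flanked element: a random backbone
#' at the requested AT fraction, planted STR arrays at spaced positions
#' (each flanked by period-breaking guard bases so the run is maximal), and
#' optionally a pair of mutually reverse-complementary tandem-repeat arrays
#' flanking an insert segment.
#'
#' @param length genome size in bp (default 15000).
#' @param at_fraction backbone AT fraction (default 0.78).
#' @param strs data.frame with columns `unit`, `copies` (one row per planted
#'   STR); the default plants a [G]8, an [A]9 and a [TA]9.
#' @param ir list describing the IR element, or `NULL` for none:
#'   `unit_len` (repeat unit length, default 34), `copies` (default 5) and
#'   `insert_len` (insert size in bp, default 600).
#' @param seed mandatory random seed.
#' @return list of class `synthetic_truth`: `genome` (a `circular_genome`),
#'   `str_truth` (data.frame position/unit/copies), and `ir_truth` (a
#'   `transposon_like_element` plus `unit`, or `NULL`).
#' @export
generate_genome <- function(length = 15000L, at_fraction = 0.78,
                            strs = data.frame(
                              unit = c("G", "A", "TA"),
                              copies = c(8L, 9L, 9L),
                              stringsAsFactors = FALSE),
                            ir = list(unit_len = 34L, copies = 5L,
                                      insert_len = 600L),
                            seed) {
  if (missing(seed)) stop("a seed is required for simulation", call. = FALSE)
  set.seed(seed)
  n <- as.integer(length)
  p_at <- at_fraction / 2
  p_gc <- (1 - at_fraction) / 2
  backbone <- sample(DNA_BASES, n, replace = TRUE,
                     prob = c(p_at, p_gc, p_gc, p_at))
  # budget check: planted features must fit with guards and spacing
  str_bp <- sum(nchar(strs$unit) * strs$copies) + 2L * nrow(strs)
  ir_bp <- if (is.null(ir)) 0L else
    2L * ir$unit_len * ir$copies + ir$insert_len + 4L
  if (str_bp + ir_bp > n %/% 2L) {
    stop("planted features exceed half the genome length", call. = FALSE)
  }
  other_base <- function(b) sample(setdiff(DNA_BASES, b), 1L)
  slots <- floor(seq(1L, n - max(2000L, ir_bp + 10L),
                     length.out = nrow(strs) + 2L))
  truth <- strs
  truth$position <- NA_integer_
  for (i in seq_len(nrow(strs))) {
    u <- toupper(strs$unit[i])
    k <- strs$copies[i]
    arr <- strsplit(strrep(u, k), "")[[1]]
    pos <- slots[i] + 1L
    backbone[pos:(pos + length(arr) - 1L)] <- arr
    # guards: break the period one base out on each side
    backbone[pos - 1L] <- other_base(substr(u, nchar(u), nchar(u)))
    backbone[pos + length(arr)] <- other_base(substr(u, 1L, 1L))
    truth$position[i] <- pos
  }
  ir_truth <- NULL
  if (!is.null(ir)) {
    unit <- paste(sample(DNA_BASES, ir$unit_len, replace = TRUE,
                         prob = c(p_at, p_gc, p_gc, p_at)), collapse = "")
    left <- strrep(unit, ir$copies)
    right <- revcomp(left)
    arm <- nchar(left)
    lpos <- slots[nrow(strs) + 1L]
    rpos <- lpos + arm + ir$insert_len   # insert = [lpos+arm, rpos-1]
    if (rpos + arm + 1L > n) stop("IR element does not fit", call. = FALSE)
    backbone[lpos:(lpos + arm - 1L)] <- strsplit(left, "")[[1]]
    backbone[rpos:(rpos + arm - 1L)] <- strsplit(right, "")[[1]]
    # boundary bases are pinned so the planted coordinates are exactly the
    # maximal reverse-complement pair: each arm must neither extend as a
    # repeat nor extend the IR match inward/outward by chance complement
    comp1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[[b]]
    pick <- function(banned) sample(setdiff(DNA_BASES, banned), 1L)
    u1 <- substr(unit, 1L, 1L)
    u_last <- substr(unit, nchar(unit), nchar(unit))
    lg <- pick(u_last)                     # left guard
    fi <- pick(u1)                         # insert first base
    il <- pick(c(comp1(u1), comp1(fi)))    # insert last base
    rg <- pick(c(comp1(u_last), comp1(lg)))  # right guard
    backbone[lpos - 1L] <- lg
    backbone[lpos + arm] <- fi
    backbone[rpos - 1L] <- il
    backbone[rpos + arm] <- rg
    ir_truth <- list(
      element = new_tle(left = list(start = lpos, end = lpos + arm - 1L),
                        right = list(start = rpos, end = rpos + arm - 1L),
                        insert = list(start = lpos + arm, end = rpos - 1L)),
      unit = unit, inversion_fraction = 0)
  }
  genome <- circular_genome(paste(backbone, collapse = ""), id = "synthetic")
  structure(list(genome = genome, str_truth = truth, ir_truth = ir_truth,
                 at_fraction = at_fraction, seed = seed),
            class = "synthetic_truth")
}

#' Per-locus true allele frequencies under a slippage model
#'
#' @param truth a `synthetic_truth`.
#' @param model a `slippage_model`.
#' @return list (one per planted STR) with `locus` and `freqs` (named over
#'   copy numbers, zero-probability classes dropped).
#' @export
true_allele_frequencies <- function(truth, model) {
  lapply(seq_len(nrow(truth$str_truth)), function(i) {
    row <- truth$str_truth[i, ]
    fr <- slippage_distribution(row$copies, model)
    list(locus = str_locus(row$position, row$unit, row$copies),
         freqs = fr[fr > 0])
  })
}

#' Simulate a deep pileup over the planted STR loci
#'
#' At each planted STR position the allele counts are drawn multinomially
#' from the locus's slippage-model frequencies (copy-number classes become
#' `Ref`/`+k`/`-k` alleles). Elsewhere, `n_noise_columns` background columns
#' carry substitution noise at rate `e` per base. Columns are returned and
#' optionally written via [write_pileup()].
#'
#' @param truth a `synthetic_truth`.
#' @param depth sequencing depth per column.
#' @param model a `slippage_model`.
#' @param seed mandatory seed.
#' @param n_noise_columns background (non-STR) columns to simulate
#'   (default 50; whole-genome pileups at 1e5x are impractically large).
#' @param path optional output pileup file.
#' @return list of `pileup_column` (STR columns first).
#' @export
simulate_pileup <- function(truth, depth, model, seed,
                            n_noise_columns = 50L, path = NULL) {
  if (missing(seed)) stop("a seed is required for simulation", call. = FALSE)
  set.seed(seed)
  stopifnot(depth >= 1)
  seq <- truth$genome$sequence
  freqs <- true_allele_frequencies(truth, model)
  cols <- lapply(freqs, function(fl) {
    locus <- fl$locus
    m <- nchar(locus$unit)
    copies <- as.integer(names(fl$freqs))
    counts <- as.integer(stats::rmultinom(1L, depth, fl$freqs))
    labels <- vapply(copies, function(cp) {
      d <- cp - locus$copies
      if (d == 0L) "Ref"
      else if (d > 0L) paste0("+", d * m, strrep(locus$unit, d))
      else paste0("-", -d * m, strrep(locus$unit, -d))
    }, character(1))
    keep <- counts > 0L
    pileup_column(locus$position, substr(seq, locus$position, locus$position),
                  stats::setNames(counts[keep], labels[keep]))
  })
  if (n_noise_columns > 0L) {
    banned <- unlist(lapply(freqs, function(fl)
      fl$locus$position + seq_len(fl$locus$array_length) - 1L))
    pool <- setdiff(seq_len(truth$genome$length), banned)
    at <- sort(sample(pool, min(n_noise_columns, length(pool))))
    noise <- lapply(at, function(p) {
      ref <- substr(seq, p, p)
      nsub <- stats::rbinom(1L, depth, model$e)
      cts <- c(Ref = depth - nsub)
      if (nsub > 0L) {
        subs <- table(sample(setdiff(DNA_BASES, ref), nsub, replace = TRUE))
        cts <- c(cts, stats::setNames(as.integer(subs), names(subs)))
      }
      pileup_column(p, ref, cts)
    })
    cols <- c(cols, noise)
  }
  names(cols) <- vapply(cols, function(c) as.character(c$pos), character(1))
  if (!is.null(path)) write_pileup(cols, path)
  cols
}

#' Simulate reads from a circular genome with optional element inversions
#'
#' Uniform sampling of read start positions around the circle; a stated
#' fraction of molecules carry the inverted element (insert
#' reverse-complemented between the IRs). Reads are reported on the forward
#' strand of their molecule.
#'
#' @param truth a `synthetic_truth` with a planted IR element.
#' @param read_len read length in bp.
#' @param depth target mean coverage depth.
#' @param inversion_fraction fraction of molecules in the inverted state.
#' @param seed mandatory seed.
#' @param path optional FASTA output.
#' @return character vector of reads.
#' @export
simulate_reads <- function(truth, read_len = 150L, depth = 100L,
                           inversion_fraction = 0, seed, path = NULL) {
  if (missing(seed)) stop("a seed is required for simulation", call. = FALSE)
  set.seed(seed)
  g <- truth$genome
  if (read_len >= g$length) stop("reads longer than the genome", call. = FALSE)
  n_reads <- as.integer(round(depth * g$length / read_len))
  ref2 <- paste0(g$sequence, g$sequence)
  inv2 <- if (inversion_fraction > 0) {
    gi <- invert_element(g, truth$ir_truth$element)
    paste0(gi$sequence, gi$sequence)
  } else NULL
  starts <- sample.int(g$length, n_reads, replace = TRUE)
  inverted <- stats::runif(n_reads) < inversion_fraction
  reads <- character(n_reads)
  reads[!inverted] <- substring(ref2, starts[!inverted],
                                starts[!inverted] + read_len - 1L)
  if (any(inverted)) {
    reads[inverted] <- substring(inv2, starts[inverted],
                                 starts[inverted] + read_len - 1L)
  }
  if (!is.null(path)) {
    set <- Biostrings::DNAStringSet(reads)
    names(set) <- sprintf("read%06d%s", seq_len(n_reads),
                          ifelse(inverted, "_inv", ""))
    Biostrings::writeXStringSet(set, path)
  }
  reads
}
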