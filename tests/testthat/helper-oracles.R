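# Independent oracles, implemented apart from the package's kernels.

# Plain-R affine-gap local alignment score (single orientation).
oracle_sw <- function(q, s, match = 1, mismatch = -3, open = 5, ext = 2) {
  n <- nchar(q); m <- nchar(s)
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    E[i, j] <- max(H[i - 1, j] - open - ext, E[i - 1, j] - ext)
    F[i, j] <- max(H[i, j - 1] - open - ext, F[i, j - 1] - ext)
    sub <- if (qc[i - 1] == sc[j - 1] && qc[i - 1] != "N") match else mismatch
    H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
    best <- max(best, H[i, j])
  }
  best
}

# Exhaustive memoised recursion for maximum-weight nested pairing.
oracle_fold_score <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "")[[1]]; n <- length(ch)
  w <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) 3
    else if ((a == "A" && b == "T") || (a == "T" && b == "A")) 2
    else if ((a == "G" && b == "T") || (a == "T" && b == "G")) 1
    else 0
  }
  memo <- new.env(parent = emptyenv())
  f <- function(i, j) {
    if (j - i <= min_loop) return(0)
    key <- paste0(i, "_", j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- max(f(i + 1, j), f(i, j - 1))
    ww <- w(ch[i], ch[j])
    if (ww > 0) best <- max(best, ww + f(i + 1, j - 1))
    for (k in (i + 1):(j - 1)) best <- max(best, f(i, k) + f(k + 1, j))
    memo[[key]] <- best
    best
  }
  f(1, n)
}

# Best local score over both subject strands, via the package.
top_local_score <- function(q, s) {
  h <- local_align(q, s, min_score = 1L)
  if (nrow(h)) max(h$raw_score) else 0
}

# A hairpin-forming near-palindromic MITE locus plus precise reads, shared
# by annotation tests.
make_precise_locus <- function(seed, divergence = 0.10, depth = 500,
                               strand_bias = "plus_only", mir_len = 24L,
                               excision = "precise") {
  fam <- generate_te_family("MITE", 220L, 100L, 2L, divergence, seed = seed,
                            family_id = "famX")
  truth <- plant_insertions(list(famX = fam), c(chr = 4000L), c(famX = 2L),
                            seed = seed + 1)
  loc <- truth$hairpin_loci[1, ]
  hp <- extract_interval(truth, "chr", loc$start - 15L, loc$end + 15L)
  mw <- c(33L, 33L + mir_len)
  sw <- palindrome_star_window(mw, nchar(hp))
  reads <- simulate_srna_reads(hp, list(
    strand_bias = strand_bias,
    length_weights = stats::setNames(1, as.character(mir_len)),
    excision = excision, mir_window = mw, star_window = sw),
    depth = depth, n_datasets = 2L, seed = seed + 2)
  list(fam = fam, truth = truth, hairpin = hp, reads = reads,
       mir_window = mw, star_window = sw)
}

# Shared default pipeline run (computed once per test session).
.report_cache <- new.env(parent = emptyenv())
cached_report <- function() {
  if (is.null(.report_cache$rep))
    .report_cache$rep <- run_pipeline(default_config(seed = 1L))
  .report_cache$rep
}
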