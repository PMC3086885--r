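# Small-RNA expression profiling on hairpins: perfect-match placement,
# TPQ normalization, strand-bias category, genome multiplicity and
# length-distribution type.

#' Place reads on a hairpin by perfect matching, both strands
#'
#' Every exact substring occurrence of a read on the hairpin (strand `+`)
#' or of its reverse complement (strand `-`) is reported with its 0-based
#' offset on the hairpin's forward coordinates. No mismatches or indels are
#' tolerated; a read may place multiple times.
#'
#' @param reads character vector of read sequences (may repeat).
#' @param hairpin hairpin (stem-loop) sequence.
#' @return data.frame `sequence`, `strand`, `offset` (one row per placement).
#' @export
map_perfect <- function(reads, hairpin) {
  reads <- unique(reads)
  L <- nchar(hairpin)
  rc <- revcomp(hairpin)
  seq_v <- list(); str_v <- list(); off_v <- list()
  for (l in sort(unique(nchar(reads)))) {
    if (l < 1 || l > L) next
    rs <- reads[nchar(reads) == l]
    subs_p <- substring(hairpin, 1:(L - l + 1), l:L)
    subs_m <- substring(rc, 1:(L - l + 1), l:L)
    for (r in rs) {
      op <- which(subs_p == r) - 1L
      if (length(op)) {
        k <- length(seq_v) + 1L
        seq_v[[k]] <- rep(r, length(op)); str_v[[k]] <- rep("+", length(op))
        off_v[[k]] <- op
      }
      # read maps minus at offset o iff it occurs in revcomp(hairpin) at
      # offset o' = L - l - o
      om <- which(subs_m == r) - 1L
      if (length(om)) {
        k <- length(seq_v) + 1L
        seq_v[[k]] <- rep(r, length(om)); str_v[[k]] <- rep("-", length(om))
        off_v[[k]] <- L - l - om
      }
    }
  }
  if (!length(seq_v))
    return(data.frame(sequence = character(), strand = character(),
                      offset = integer(), stringsAsFactors = FALSE))
  out <- data.frame(sequence = unlist(seq_v), strand = unlist(str_v),
                    offset = unlist(off_v), stringsAsFactors = FALSE)
  out <- out[order(out$sequence, out$strand, out$offset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcripts-per-quarter-million normalization
#'
#' @param count raw read count(s).
#' @param dataset_total total reads in the dataset (> 0).
#' @return `count * 250000 / dataset_total`.
#' @export
#' @examples
#' normalize_tpq(4, 1e6)  # 1
normalize_tpq <- function(count, dataset_total) {
  if (any(dataset_total <= 0)) stop("dataset_total must be > 0")
  count * 250000 / dataset_total
}

#' Strand-bias category of a hairpin's small-RNA expression
#'
#' With total abundances P (plus) and M (minus): `plus_only` if M = 0,
#' `minus_only` if P = 0, `plus_major` if the minus fraction is positive but
#' at most `minor_fraction` ("negligible"), symmetric `minus_major`, else
#' `both` (comparable expression from both strands).
#'
#' @param plus_abundance,minus_abundance total abundance per strand.
#' @param minor_fraction abundance fraction below which the minority strand
#'   counts as negligible (default 0.10).
#' @return one of `"plus_only"`, `"minus_only"`, `"plus_major"`,
#'   `"minus_major"`, `"both"`.
#' @export
#' @examples
#' classify_strand_bias(500, 20)   # plus_major
classify_strand_bias <- function(plus_abundance, minus_abundance,
                                 minor_fraction = 0.10) {
  P <- plus_abundance; M <- minus_abundance
  if (P + M <= 0) stop("no placements: both strand abundances are zero")
  if (M == 0) return("plus_only")
  if (P == 0) return("minus_only")
  f <- M / (P + M)
  if (f <= minor_fraction) return("plus_major")
  if (1 - f <= minor_fraction) return("minus_major")
  "both"
}

#' Mean genome multiplicity of a read set
#'
#' Counts exact occurrences of each unique read on both strands of the
#' genome and returns the unweighted mean over reads with at least one hit.
#' Reads with zero hits are excluded from the mean and counted separately.
#'
#' @param reads character vector of read sequences.
#' @param genome named character vector of chromosome sequences.
#' @return list with `mean_genome_hits`, `per_read` (sequence, hits) and
#'   `n_zero_hit`.
#' @export
genome_multiplicity <- function(reads, genome) {
  reads <- unique(reads)
  gset <- Biostrings::DNAStringSet(unlist(genome))
  gset_rc <- Biostrings::reverseComplement(gset)
  hits <- setNames(numeric(length(reads)), reads)
  for (l in unique(nchar(reads))) {
    rs <- reads[nchar(reads) == l]
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(rs))
    hits[rs] <- rowSums(Biostrings::vcountPDict(pd, gset)) +
      rowSums(Biostrings::vcountPDict(pd, gset_rc))
  }
  pos <- hits[hits >= 1]
  list(mean_genome_hits = if (length(pos)) mean(pos) else NA_real_,
       per_read = data.frame(sequence = reads, hits = unname(hits),
                             stringsAsFactors = FALSE),
       n_zero_hit = sum(hits == 0))
}

#' Length-distribution type of a hairpin's small-RNA products
#'
#' A dataset is usable iff its total abundance is at least `usable_min`
#' (below that, the length distribution cannot be determined). Per usable
#' dataset the dominant class is short (20-22 nt, the 21-nt-like class),
#' long (23-24 nt, the 24-nt-like class) or outside 20-24 nt, where
#' dominance means the class holds more than `major_fraction` of abundance.
#'
#' @param histograms matrix of abundances, rows = datasets, columns named
#'   by read length (nt).
#' @param usable_min minimum dataset total for usability (default 10).
#' @param major_fraction dominance threshold (default 0.5).
#' @return `"low"` (no usable dataset), `"other"` (some usable dataset
#'   dominated by lengths outside 20-24), `"major21"` / `"major24"`
#'   (unanimous short / long dominance), else `"mixed"`.
#' @export
classify_length_distribution <- function(histograms, usable_min = 10,
                                         major_fraction = 0.5) {
  if (is.null(dim(histograms))) histograms <- rbind(histograms)
  lens <- as.integer(colnames(histograms))
  if (any(is.na(lens))) stop("histogram columns must be named by length")
  totals <- rowSums(histograms)
  usable <- which(totals >= usable_min)
  if (!length(usable)) return("low")
  short <- lens %in% 20:22
  long <- lens %in% 23:24
  outside <- !(lens %in% 20:24)
  verdicts <- vapply(usable, function(i) {
    f <- histograms[i, ] / totals[i]
    if (sum(f[outside]) > major_fraction) return("other")
    if (sum(f[short]) > major_fraction) return("short")
    if (sum(f[long]) > major_fraction) return("long")
    "none"
  }, character(1))
  if (any(verdicts == "other")) return("other")
  if (all(verdicts == "short")) return("major21")
  if (all(verdicts == "long")) return("major24")
  "mixed"
}

#' Compare genome multiplicities of TE-MIRs and canonical miRNAs
#'
#' One-sided Mann-Whitney U test of whether TE-MIR small-RNA genome
#' multiplicities exceed those of canonical miRNAs.
#'
#' @param temir_means numeric vector of TE-MIR mean genome hits.
#' @param canonical_means numeric vector for canonical miRNAs.
#' @return the one-sided p-value.
#' @export
compare_multiplicity <- function(temir_means, canonical_means) {
  if (!length(temir_means) || !length(canonical_means))
    stop("both samples must be non-empty")
  if (length(unique(c(temir_means, canonical_means))) == 1L) {
    warning("degenerate samples: all values tied; p = 1")
    return(1)
  }
  suppressWarnings(
    wilcox.test(temir_means, canonical_means,
                alternative = "greater")$p.value)
}

#' Build the expression profile of a hairpin from a read table
#'
#' Places reads by perfect matching, sums abundance per strand (a read
#' placing on both strands contributes to both, as exhaustive mapping
#' does), and derives the strand-bias category, per-dataset length
#' histograms, the length-distribution type and (if a genome is supplied)
#' the mean genome multiplicity of the placed reads.
#'
#' @param hairpin_id label for the hairpin.
#' @param hairpin hairpin sequence.
#' @param reads data.frame `sequence`, `dataset_id`, `count`.
#' @param genome optional named character vector for multiplicity.
#' @param genome_hits optional precomputed per-read hit counts (named
#'   numeric, as from [genome_multiplicity()]`$per_read`); overrides
#'   `genome`.
#' @param minor_fraction,usable_min,major_fraction classifier knobs.
#' @param len_range read-length range tracked in histograms.
#' @return an object of class `expression_profile`.
#' @export
expression_profile <- function(hairpin_id, hairpin, reads, genome = NULL,
                               genome_hits = NULL,
                               minor_fraction = 0.10, usable_min = 10,
                               major_fraction = 0.5, len_range = 18:30) {
  pl <- map_perfect(reads$sequence, hairpin)
  ab <- tapply(reads$count, reads$sequence, sum)          # across datasets
  placed <- unique(pl$sequence)
  P <- sum(ab[unique(pl$sequence[pl$strand == "+"])])
  M <- sum(ab[unique(pl$sequence[pl$strand == "-"])])
  strand_category <- if (P + M > 0)
    classify_strand_bias(P, M, minor_fraction) else NA_character_
  datasets <- sort(unique(reads$dataset_id))
  hist <- matrix(0, nrow = length(datasets), ncol = length(len_range),
                 dimnames = list(datasets, as.character(len_range)))
  sub <- reads[reads$sequence %in% placed, , drop = FALSE]
  if (nrow(sub)) {
    sub$len <- nchar(sub$sequence)
    sub <- sub[sub$len %in% len_range, , drop = FALSE]
    for (i in seq_len(nrow(sub)))
      hist[sub$dataset_id[i], as.character(sub$len[i])] <-
        hist[sub$dataset_id[i], as.character(sub$len[i])] + sub$count[i]
  }
  length_type <- classify_length_distribution(hist, usable_min, major_fraction)
  mult <- if (!is.null(genome_hits) && length(placed)) {
    h <- genome_hits[placed]
    h <- h[!is.na(h)]
    pos <- h[h >= 1]
    list(mean_genome_hits = if (length(pos)) mean(pos) else NA_real_,
         per_read = data.frame(sequence = names(h), hits = unname(h),
                               stringsAsFactors = FALSE),
         n_zero_hit = sum(h == 0))
  } else if (!is.null(genome) && length(placed))
    genome_multiplicity(placed, genome) else NULL
  # per-read abundance attached to placements for downstream duplex calling
  if (nrow(pl)) pl$abundance <- as.numeric(ab[pl$sequence])
  structure(list(hairpin_id = hairpin_id, hairpin = hairpin,
                 placements = pl, plus_abundance = P, minus_abundance = M,
                 strand_category = strand_category,
                 length_histograms = hist, length_type = length_type,
                 mean_genome_hits = if (is.null(mult)) NA_real_ else
                   mult$mean_genome_hits,
                 multiplicity = mult,
                 dataset_totals = tapply(reads$count, reads$dataset_id, sum)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat("Expression profile:", x$hairpin_id, "\n")
  cat(sprintf("  placements: %d (P=%g, M=%g) strand: %s\n",
              nrow(x$placements), x$plus_abundance, x$minus_abundance,
              x$strand_category))
  cat(sprintf("  length type: %s  mean genome hits: %s\n", x$length_type,
              format(x$mean_genome_hits, digits = 3)))
  invisible(x)
}

#' Aggregate per-dataset length spectra over a cohort of profiles
#'
#' @param profiles list of [expression_profile()] objects.
#' @return matrix of abundance fractions (rows = datasets, columns =
#'   lengths); each row sums to 1.
#' @export
aggregate_length_spectrum <- function(profiles) {
  if (!length(profiles)) stop("need at least one profile")
  tot <- NULL
  for (p in profiles) {
    h <- p$length_histograms
    if (is.null(tot)) tot <- h else {
      all_ds <- union(rownames(tot), rownames(h))
      m <- matrix(0, length(all_ds), ncol(h),
                  dimnames = list(all_ds, colnames(h)))
      m[rownames(tot), ] <- tot
      m[rownames(h), ] <- m[rownames(h), ] + h
      tot <- m
    }
  }
  sweep(tot, 1, pmax(rowSums(tot), 1e-300), "/")
}
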