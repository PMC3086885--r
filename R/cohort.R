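# Self-contained per-locus cohort simulation: each locus gets its own TE
# family, a mini-genome carrying the family's copies, an sRNA read set, and
# the planted typicality truth. Used to measure classifier and screen
# recovery without building a full multi-family genome.

#' Simulate a cohort of hairpin loci with planted typical/atypical truth
#'
#' Typical loci are low-copy, plus-biased and precisely excised; atypical
#' loci draw one or more failure modes: high genomic copy number, smeared
#' excision, or comparable expression from both strands. Each locus is
#' simulated independently with its own family and mini-genome.
#'
#' @param n_typical,n_atypical cohort composition.
#' @param seed master seed; each locus derives a child seed.
#' @param depth sRNA read instances per dataset.
#' @param n_datasets sRNA datasets per locus.
#' @param copy_low,copy_high genomic copy numbers for low/high-copy loci.
#' @param divergence_low,divergence_high family divergence for typical
#'   (older, well-diverged MITEs) and high-copy (young, homogeneous)
#'   families.
#' @param te_len,tir_len family geometry (near-full palindromes).
#' @param flank flanking nt around the extracted hairpin.
#' @return list of per-locus records: `locus_id`, `truth_typical`,
#'   `failure_mode`, `hairpin`, `reads`, `genome`, `family`,
#'   `mir_window`, `star_window`.
#' @export
simulate_screen_cohort <- function(n_typical, n_atypical, seed = 1,
                                   depth = 300L, n_datasets = 2L,
                                   copy_low = 2L, copy_high = 40L,
                                   divergence_low = 0.10,
                                   divergence_high = 0.005,
                                   te_len = 220L, tir_len = 100L,
                                   flank = 15L) {
  modes <- c("high_copy", "smeared", "both_strand", "high_copy+smeared")
  out <- list()
  n <- n_typical + n_atypical
  for (i in seq_len(n)) {
    s <- child_seed(seed, i)
    typical <- i <= n_typical
    mode <- if (typical) "none" else modes[1 + (i %% length(modes))]
    high <- grepl("high_copy", mode)
    fam <- generate_te_family("MITE", te_len, tir_len,
      n_copies = if (high) copy_high else copy_low,
      divergence = if (high) divergence_high else divergence_low,
      seed = s, family_id = sprintf("fam%03d", i))
    n_copies <- length(fam$copies)
    truth <- plant_insertions(setNames(list(fam), fam$family_id),
      chrom_lengths = c(chr = max(6000L, 3L * n_copies * te_len)),
      copy_numbers = setNames(length(fam$copies), fam$family_id),
      seed = child_seed(s, 1))
    loc <- truth$hairpin_loci[1, ]
    hp <- extract_interval(truth, loc$chrom, max(0, loc$start - flank),
                           min(nchar(truth$genome[[loc$chrom]]),
                               loc$end + flank))
    L <- nchar(hp)
    mlen <- 24L
    mw <- c(flank + 18L, flank + 18L + mlen)
    sw <- palindrome_star_window(mw, L)
    smeared <- grepl("smeared", mode)
    both <- mode == "both_strand"
    profile <- list(
      strand_bias = if (both) "both" else if (typical && i %% 2 == 0)
        "plus_major" else if (typical) "plus_only" else "plus_major",
      length_weights = c("23" = 0.08, "24" = 0.8, "25" = 0.04, "21" = 0.08),
      excision = if (smeared) "smeared" else "precise",
      mir_window = mw, star_window = sw)
    reads <- simulate_srna_reads(hp, profile, depth = depth,
                                 n_datasets = n_datasets,
                                 seed = child_seed(s, 2))
    out[[i]] <- list(locus_id = sprintf("locus%03d", i),
                     truth_typical = typical, failure_mode = mode,
                     hairpin = hp, reads = reads, genome = truth$genome,
                     family = fam, mir_window = mw, star_window = sw)
  }
  out
}

#' Profile, annotate and screen one cohort locus
#'
#' Convenience wrapper running the full per-locus analysis path:
#' expression profile (with genome multiplicity), hairpin fold, duplex
#' call and typical screen.
#'
#' @param locus one record from [simulate_screen_cohort()].
#' @param hit_max,minor_fraction,dominance_min,window_concentration_min
#'   screening thresholds (paper defaults).
#' @return list with `profile`, `structure`, `duplex`, `screen`.
#' @export
screen_cohort_locus <- function(locus, hit_max = 20, minor_fraction = 0.10,
                                dominance_min = 5,
                                window_concentration_min = 0.75) {
  prof <- expression_profile(locus$locus_id, locus$hairpin, locus$reads,
                             genome = locus$genome,
                             minor_fraction = minor_fraction)
  st <- fold_hairpin(locus$hairpin)
  dup <- tryCatch(
    call_duplex(st, prof$placements, dominance_min = dominance_min,
                window_concentration_min = window_concentration_min),
    error = function(e) base::structure(
      list(precise = FALSE, geometry_ok = FALSE, star_found = FALSE,
           dominance_ratio = NA_real_, window_concentration = NA_real_),
      class = "duplex_call"))
  scr <- screen_typical(prof, dup, hit_max = hit_max)
  list(profile = prof, structure = st, duplex = dup, screen = scr)
}
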