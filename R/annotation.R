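# Hairpin folding (weighted Nussinov), miR/miR* duplex excision calling,
# the typical TE-MIR screen, and inverted-TE-pair architecture detection.

#' Fold a hairpin by weighted base-pair maximization
#'
#' Maximum-weight nested pairing (Nussinov dynamic programming) with pair
#' weights G:C = 3, A:U = 2, G:U = 1 and a minimum hairpin loop of
#' `min_loop` unpaired nt. Only the stem/arm geometry is consumed
#' downstream, so a base-pair maximization model is used rather than full
#' thermodynamics; the `folder` hook lets callers substitute an external
#' pair-table provider.
#'
#' @param sequence DNA/RNA sequence (>= 40 nt).
#' @param min_loop minimum unpaired loop length (default 3).
#' @param folder optional function `sequence -> list(score, pair_table)`
#'   (pair_table 1-based partner, 0 = unpaired) replacing the built-in DP.
#' @return object of class `hairpin_structure`: `sequence`, `pair_table`,
#'   `fold_score`, and `stem_arms` (1-based inclusive 5' and 3' arm
#'   intervals of the dominant stem).
#' @export
fold_hairpin <- function(sequence, min_loop = 3L, folder = NULL) {
  if (nchar(sequence) < 40) stop("sequence too short to fold (< 40 nt)")
  res <- if (is.null(folder))
    .nussinov_cpp(toupper(sequence), as.integer(min_loop))
  else folder(sequence)
  pt <- res$pair_table
  arms <- stem_arms_from_pairs(pt)
  structure(list(sequence = sequence, pair_table = pt,
                 fold_score = res$score, stem_arms = arms),
            class = "hairpin_structure")
}

# Dominant stem: pick the innermost pair enclosed by the most pairs, then
# take every pair nested around it; arms are the coordinate ranges of the
# two sides (1-based inclusive).
stem_arms_from_pairs <- function(pt) {
  i <- which(pt > 0 & seq_along(pt) < pt)
  if (!length(i)) return(NULL)
  pairs <- cbind(i, pt[i])
  inner <- pairs[!vapply(seq_len(nrow(pairs)), function(k)
    any(pairs[, 1] > pairs[k, 1] & pairs[, 2] < pairs[k, 2]), logical(1)),
    , drop = FALSE]
  nest <- vapply(seq_len(nrow(inner)), function(k)
    sum(pairs[, 1] <= inner[k, 1] & pairs[, 2] >= inner[k, 2]), integer(1))
  anchor <- inner[which.max(nest), ]
  stem <- pairs[pairs[, 1] <= anchor[1] & pairs[, 2] >= anchor[2], ,
                drop = FALSE]
  list(arm5 = c(min(stem[, 1]), max(stem[, 1])),
       arm3 = c(min(stem[, 2]), max(stem[, 2])))
}

#' Call a miR/miR* duplex from placements on a folded hairpin
#'
#' The most abundant plus-strand read is the miR candidate. Its pairing
#' partners on the opposite arm (via the pair table), shifted 3'-ward by
#' 2 nt, define the expected miR* interval of a Dicer duplex with 2-nt 3'
#' overhangs. Excision is precise iff the dominance ratio (miR abundance
#' over the strongest other plus-strand read overlapping it, floor 1)
#' reaches `dominance_min`, the miR + miR* windows concentrate at least
#' `window_concentration_min` of plus-strand abundance, and duplex geometry
#' holds (miR mostly paired, a star-supporting read within
#' `overhang_tol` nt of the expected interval).
#'
#' @param structure a [fold_hairpin()] result.
#' @param placements placement data.frame with `sequence`, `strand`,
#'   `offset`, `abundance` (e.g. from [expression_profile()]).
#' @param dominance_min minimum dominance ratio (default 5).
#' @param window_concentration_min minimum windowed abundance fraction
#'   (default 0.75).
#' @param overhang_tol tolerance (nt) on the 2-nt 3' overhang (default 1).
#' @param window_pad padding (nt) when attributing reads to windows.
#' @return object of class `duplex_call`.
#' @export
call_duplex <- function(structure, placements, dominance_min = 5,
                        window_concentration_min = 0.75, overhang_tol = 1L,
                        window_pad = 4L) {
  plus <- placements[placements$strand == "+", , drop = FALSE]
  if (!nrow(plus)) stop("no plus-strand placements")
  ab <- tapply(plus$abundance, plus$sequence, max)
  top_seq <- names(ab)[which.max(ab)]
  top_ab <- max(ab)
  cand <- plus[plus$sequence == top_seq, , drop = FALSE]
  pt <- structure$pair_table
  # among multiple placements of the top read, take the most paired one
  paired_frac <- vapply(seq_len(nrow(cand)), function(k) {
    iv <- (cand$offset[k] + 1L):(cand$offset[k] + nchar(top_seq))
    mean(pt[iv] > 0)
  }, numeric(1))
  best <- which.max(paired_frac)
  mir_s <- cand$offset[best]
  mir_e <- mir_s + nchar(top_seq)           # 0-based half-open
  geometry_ok <- paired_frac[best] >= 0.5
  star_iv <- NULL; star_read <- NA_character_; star_found <- FALSE
  shift5 <- NA_integer_; shift3 <- NA_integer_
  if (geometry_ok) {
    ip <- ((mir_s + 1L):mir_e)
    ip <- ip[pt[ip] > 0]
    # anti-diagonal of the duplex: i + partner(i) is constant on a clean
    # stem; the median is robust to stray long-range pairs of the fold
    c2 <- round(median(ip + pt[ip]))
    # expected star, 0-based half-open: partner span shifted 3'-ward by 2
    star_iv <- c(c2 - mir_e + 1L, c2 - mir_s + 1L)
    others <- plus[plus$sequence != top_seq, , drop = FALSE]
    if (nrow(others)) {
      ok <- abs(others$offset - star_iv[1]) <= overhang_tol &
        abs(others$offset + nchar(others$sequence) - star_iv[2]) <= overhang_tol
      if (any(ok)) {
        hit <- others[ok, , drop = FALSE]
        j <- which.max(hit$abundance)
        star_read <- hit$sequence[j]
        star_found <- TRUE
        shift5 <- hit$offset[j] - (star_iv[1] - 2L)
        shift3 <- hit$offset[j] + nchar(star_read) - (star_iv[2] - 2L)
      }
    }
  }
  # dominance: strongest other plus read overlapping the miR placement
  others <- plus[plus$sequence != top_seq, , drop = FALSE]
  overl <- others[others$offset < mir_e &
                  others$offset + nchar(others$sequence) > mir_s, ,
                  drop = FALSE]
  dominance_ratio <- top_ab / max(if (nrow(overl)) max(overl$abundance) else 0, 1)
  # window concentration over unique plus reads (vectorized over placements)
  uab <- tapply(plus$abundance, plus$sequence, max)
  o <- plus$offset; e <- o + nchar(plus$sequence)
  row_in <- o >= mir_s - window_pad & e <= mir_e + window_pad
  if (!is.null(star_iv))
    row_in <- row_in | (o >= star_iv[1] - window_pad &
                        e <= star_iv[2] + window_pad)
  read_in <- tapply(row_in, plus$sequence, any)
  concentration <- sum(uab[names(read_in)[read_in]]) / sum(uab)
  precise <- geometry_ok && star_found &&
    dominance_ratio >= dominance_min &&
    concentration >= window_concentration_min
  base::structure(list(mir_interval = c(mir_s, mir_e), star_interval = star_iv,
                 mir_read = top_seq, star_read = star_read,
                 dominance_ratio = dominance_ratio,
                 window_concentration = concentration,
                 overhang_3p = c(shift5, shift3),
                 geometry_ok = geometry_ok, star_found = star_found,
                 precise = precise),
            class = "duplex_call")
}

#' @export
print.duplex_call <- function(x, ...) {
  cat(sprintf(
    "Duplex call: miR [%d,%d) %s\n  dominance %.1f, concentration %.2f, precise: %s\n",
    x$mir_interval[1], x$mir_interval[2], x$mir_read,
    x$dominance_ratio, x$window_concentration, x$precise))
  invisible(x)
}

#' Screen a TE-MIR for typical (bona fide miRNA) status
#'
#' A TE-MIR is typical iff (1) the mean genome hit of its small RNAs is at
#' most `hit_max`, (2) its small RNAs come purely or predominantly from the
#' plus strand, and (3) precise miR/miR* duplex excision is documented.
#'
#' @param profile an [expression_profile()].
#' @param duplex_call a [call_duplex()] result for the same hairpin.
#' @param hit_max genome-hit ceiling (default 20).
#' @return object of class `typical_screen`: the three booleans and the
#'   verdict (`"typical"` iff all three hold).
#' @export
screen_typical <- function(profile, duplex_call, hit_max = 20) {
  passes_hit <- !is.na(profile$mean_genome_hits) &&
    profile$mean_genome_hits <= hit_max
  passes_strand <- profile$strand_category %in% c("plus_only", "plus_major")
  passes_excision <- isTRUE(duplex_call$precise)
  structure(list(hairpin_id = profile$hairpin_id,
                 passes_hit = passes_hit, passes_strand = passes_strand,
                 passes_excision = passes_excision,
                 verdict = if (passes_hit && passes_strand && passes_excision)
                   "typical" else "atypical"),
            class = "typical_screen")
}

#' Classify hairpin locus architecture from TE homology
#'
#' Aligns the locus (with flanks) against each family consensus.
#' `single_palindrome` iff one HSP covers at least `arm_cover_min` of the
#' stem span (both arms); `inverted_pair` iff two non-overlapping HSPs to
#' the same family on opposite strands each cover at least `arm_cover_min`
#' of one arm; `neither` otherwise.
#'
#' @param locus_seq locus sequence including flanks.
#' @param te_families named list of `te_family` objects (consensi searched).
#' @param structure optional pre-computed [fold_hairpin()] of `locus_seq`.
#' @param scheme a [scoring_scheme()].
#' @param e_max E-value cutoff for supporting HSPs (default 0.005).
#' @param arm_cover_min arm coverage threshold (default 0.6).
#' @return list with `architecture` and the supporting `hsps`.
#' @export
detect_inverted_te_pair <- function(locus_seq, te_families, structure = NULL,
                                    scheme = scoring_scheme(), e_max = 0.005,
                                    arm_cover_min = 0.6) {
  if (is.null(structure)) structure <- fold_hairpin(locus_seq)
  arms <- structure$stem_arms
  if (is.null(arms)) return(list(architecture = "neither", hsps = NULL))
  hsps <- list()
  for (f in names(te_families)) {
    h <- local_align(locus_seq, te_families[[f]]$consensus, scheme,
                     query_id = "locus", subject_id = f)
    h <- h[h$evalue <= e_max, , drop = FALSE]
    if (nrow(h)) hsps[[length(hsps) + 1L]] <- h
  }
  hsps <- if (length(hsps)) do.call(rbind, hsps) else NULL
  if (is.null(hsps)) return(list(architecture = "neither", hsps = NULL))
  cover <- function(q1, q2, iv) {  # q 0-based half-open vs iv 1-based incl.
    lo <- max(q1 + 1L, iv[1]); hi <- min(q2, iv[2])
    max(0L, hi - lo + 1L) / (iv[2] - iv[1] + 1L)
  }
  span <- c(arms$arm5[1], arms$arm3[2])
  single <- vapply(seq_len(nrow(hsps)), function(k)
    cover(hsps$q_start[k], hsps$q_end[k], span) >= arm_cover_min, logical(1))
  if (any(single))
    return(list(architecture = "single_palindrome",
                hsps = hsps[single, , drop = FALSE]))
  for (f in unique(hsps$subject_id)) {
    hf <- hsps[hsps$subject_id == f, , drop = FALSE]
    a5 <- hf[vapply(seq_len(nrow(hf)), function(k)
      cover(hf$q_start[k], hf$q_end[k], arms$arm5) >= arm_cover_min,
      logical(1)), , drop = FALSE]
    a3 <- hf[vapply(seq_len(nrow(hf)), function(k)
      cover(hf$q_start[k], hf$q_end[k], arms$arm3) >= arm_cover_min,
      logical(1)), , drop = FALSE]
    for (i in seq_len(nrow(a5))) for (j in seq_len(nrow(a3))) {
      opp <- a5$subject_strand[i] != a3$subject_strand[j]
      disjoint <- a5$q_end[i] <= a3$q_start[j] || a3$q_end[j] <= a5$q_start[i]
      if (opp && disjoint)
        return(list(architecture = "inverted_pair",
                    hsps = rbind(a5[i, ], a3[j, ])))
    }
  }
  list(architecture = "neither", hsps = hsps)
}
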