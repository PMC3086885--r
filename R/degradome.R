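# Degradome (PARE) 5'-tag mapping, cleavage-category classification at
# predicted sites, and the per-target 1-7 summary score.

#' Build a degradome profile by mapping 5' tags onto a cDNA
#'
#' Tags are matched exactly on the plus strand of the cDNA; each match
#' increments the count at the 0-based position of the tag's 5' end. A tag
#' matching at several positions increments all of them.
#'
#' @param tags character vector of tag sequences (>= 15 nt each), or a
#'   data.frame with `sequence` and `count`.
#' @param cdna target cDNA sequence.
#' @param cdna_id label for the cDNA.
#' @return object of class `degradome_profile`: `cdna_id`, `counts`
#'   (integer vector over 0-based positions, named by position), `length`,
#'   `total`.
#' @export
map_tags <- function(tags, cdna, cdna_id = "cdna") {
  if (is.data.frame(tags)) {
    seqs <- tags$sequence; cnts <- tags$count
  } else {
    seqs <- tags; cnts <- rep(1L, length(tags))
  }
  if (length(seqs) && any(nchar(seqs) < 15))
    stop("degradome tags must be >= 15 nt")
  subj <- Biostrings::DNAString(cdna)
  counts <- integer(nchar(cdna))
  for (i in seq_along(seqs)) {
    m <- Biostrings::matchPattern(seqs[i], subj)
    for (p in Biostrings::start(m)) counts[p] <- counts[p] + cnts[i]
  }
  degradome_profile(cdna_id, which(counts > 0) - 1L,
                    counts[counts > 0], nchar(cdna))
}

#' Construct a degradome profile from (position, count) records
#'
#' @param cdna_id label for the cDNA.
#' @param positions 0-based tag 5'-end positions.
#' @param counts tag counts per position.
#' @param length cDNA length.
#' @return object of class `degradome_profile`.
#' @export
degradome_profile <- function(cdna_id, positions, counts, length) {
  if (any(positions < 0) || any(positions >= length))
    stop("position out of range")
  if (any(counts < 0)) stop("counts must be non-negative")
  v <- integer(length)
  for (i in seq_along(positions))
    v[positions[i] + 1L] <- v[positions[i] + 1L] + as.integer(counts[i])
  base::structure(list(cdna_id = cdna_id, counts = v, length = length,
                       total = sum(v)),
                  class = "degradome_profile")
}

#' Predicted cleavage position of a pairing alignment
#'
#' The guide-directed cleavage site is the target coordinate paired to the
#' tenth nucleotide from the sRNA's 5' end. Tags whose 5' end equals this
#' coordinate are cleavage evidence.
#'
#' @param alignment a [pairing_score()] result.
#' @return the 0-based cleavage position on the aligned sequence.
#' @export
predicted_cleavage_position <- function(alignment) {
  if (is.na(alignment$cleavage_offset))
    stop("sRNA position 10 falls in a bulge; no cleavage position")
  alignment$cleavage_offset
}

#' Classify cleavage evidence at a position into categories 1-3
#'
#' Relative to the transcript's expressed positions (those with at least
#' one tag): category 1 if the site's count ties the maximum, category 2 if
#' it exceeds the median but is below the maximum, category 3 otherwise
#' (at least one tag, at most the median). No tag at the site gives `NA`
#' (no evidence).
#'
#' @param profile a `degradome_profile`.
#' @param position 0-based position to interrogate.
#' @return integer 1, 2 or 3, or `NA` for no evidence.
#' @export
classify_category <- function(profile, position) {
  if (position < 0 || position >= profile$length)
    stop("position out of range")
  c0 <- profile$counts[position + 1L]
  if (c0 == 0) return(NA_integer_)
  expressed <- profile$counts[profile$counts > 0]
  if (c0 == max(expressed)) return(1L)
  if (c0 > median(expressed)) return(2L)
  3L
}

#' Summarize detected cleavage categories as the 1-7 score
#'
#' Categories detected for a target map to a single score: all three
#' categories give 7; 1 and 2 give 6; 1 and 3 give 5; only 1 gives 4;
#' 2 and 3 give 3; only 2 gives 2; only 3 gives 1; none gives 0.
#' Equivalently the score is the bit sum 4.[1] + 2.[2] + 1.[3].
#'
#' @param categories_detected integer subset of {1, 2, 3} (NAs dropped).
#' @return integer score 0-7.
#' @export
#' @examples
#' summary_score(c(1, 3))  # 5
summary_score <- function(categories_detected) {
  cats <- unique(categories_detected[!is.na(categories_detected)])
  if (length(setdiff(cats, 1:3)))
    stop("categories must be within {1, 2, 3}")
  sum(c(4L, 2L, 1L)[cats])
}

#' Score targets across degradome datasets
#'
#' For each target gene and degradome dataset, gathers all predicted sites
#' with pairing score at most `score_max`, classifies the cleavage evidence
#' at each predicted position, unions the detected categories (multiple
#' sRNAs binding one transcript contribute jointly) and emits the 1-7
#' summary score. Datasets are scored independently; counts never mix.
#'
#' @param predictions data.frame from [predict_targets()] (needs
#'   `gene_id`, `score`, `cleavage_pos`).
#' @param degradome_sets named list: per dataset, a named list of
#'   `degradome_profile` objects keyed by gene/cDNA id.
#' @param score_max maximum pairing score considered (default 4).
#' @return data.frame `gene_id`, `dataset_id`, `categories` (comma string),
#'   `summary_score`.
#' @export
score_targets <- function(predictions, degradome_sets, score_max = 4) {
  preds <- predictions[predictions$score <= score_max &
                       !is.na(predictions$cleavage_pos), , drop = FALSE]
  genes <- unique(predictions$gene_id)
  rows <- list()
  for (ds in names(degradome_sets)) {
    profs <- degradome_sets[[ds]]
    for (g in genes) {
      prof <- profs[[g]]
      if (is.null(prof)) next
      pos <- unique(preds$cleavage_pos[preds$gene_id == g])
      cats <- integer(0)
      for (p in pos) {
        cc <- classify_category(prof, p)
        if (!is.na(cc)) cats <- union(cats, cc)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, dataset_id = ds,
        categories = paste(sort(cats), collapse = ","),
        summary_score = summary_score(cats), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene_id = character(), dataset_id = character(),
                      categories = character(), summary_score = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
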