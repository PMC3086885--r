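# Plant sRNA-target complementarity scoring (TargetFinder/Allen-style
# penalties), a nearest-neighbor duplex energy proxy with MFE ratio, target
# prediction over CDS sets, and the TE-MIR x target interaction matrix.

default_pair_penalties <- function() {
  list(mismatch = 1, gu = 0.5, bulge = 2, core_start = 2L, core_end = 13L)
}

#' Score sRNA-target complementarity with the plant penalty scheme
#'
#' Optimal gapped anti-parallel pairing of the sRNA (5'->3') against a
#' target site, under penalties mismatch 1, G:U 0.5, bulge 2 (at most one
#' bulge per strand), with every penalty doubled at sRNA positions 2-13
#' from the 5' end (the core). The score is the minimized total penalty;
#' 0 means perfect reverse complementarity.
#'
#' @param srna sRNA sequence, 5'->3', 18-26 nt (DNA letters; T plays U).
#' @param site target subsequence (sense strand of the mRNA/CDS).
#' @param penalties list as from `default_pair_penalties()`.
#' @return object of class `pairing_alignment`: `score`, `path` (per-sRNA
#'   position ops: W = Watson-Crick, G = G:U, X = mismatch, S = sRNA bulge,
#'   T = target bulge), `site_start`/`site_end` (0-based half-open on
#'   `site`), `cleavage_offset` (0-based position on `site` paired to sRNA
#'   position 10, NA if bulged), `mfe_observed`, `mfe_perfect`, `mfe_ratio`.
#' @export
#' @examples
#' pairing_score("ACGAUGCAUGCAUGCAUGCAU", revcomp("ACGATGCATGCATGCATGCAT"))
pairing_score <- function(srna, site, penalties = default_pair_penalties()) {
  srna <- toupper(chartr("U", "T", srna))
  site <- toupper(chartr("U", "T", site))
  if (nchar(srna) < 18 || nchar(srna) > 26)
    stop("sRNA length must be 18-26 nt")
  if (nchar(site) < nchar(srna) - 2) stop("degenerate site")
  hits <- .scan_sites_cpp(srna, site, penalties$mismatch, penalties$gu,
                          penalties$bulge, penalties$core_start,
                          penalties$core_end, Inf)
  if (!nrow(hits)) stop("no pairing found")
  k <- which.min(hits$score)
  h <- hits[k, ]
  mfe_obs <- path_mfe(srna, site, h$site_end, h$path)
  mfe_perf <- perfect_mfe(srna)
  base::structure(list(srna = srna, site = site, score = h$score,
                       path = h$path,
                       site_start = h$site_start, site_end = h$site_end,
                       cleavage_offset = if (h$cleavage_pos >= 0)
                         h$cleavage_pos else NA_integer_,
                       mfe_observed = mfe_obs, mfe_perfect = mfe_perf,
                       mfe_ratio = mfe_ratio(mfe_obs, mfe_perf)),
                  class = "pairing_alignment")
}

# RNA nearest-neighbor Watson-Crick stack energies (kcal/mol), keyed by the
# top-strand (sRNA 5'->3') dinucleotide; GU-containing stacks use a flat
# weak value. Only differences/ratios are consumed downstream.
wc_stack_table <- c(
  AA = -0.93, AC = -2.24, AG = -2.08, AT = -1.10,
  CA = -2.11, CC = -3.26, CG = -2.36, CT = -2.08,
  GA = -2.35, GC = -3.42, GG = -3.26, GT = -2.24,
  TA = -1.33, TC = -2.35, TG = -2.11, TT = -0.93)
gu_stack_energy <- -1.2

# Energy proxy of the duplex described by an op path: sum of stacks between
# consecutive paired sRNA positions not separated by a bulge.
path_mfe <- function(srna, site, site_end, path) {
  ops <- strsplit(path, "", fixed = TRUE)[[1]]
  i <- 0L
  e <- 0
  prev_pair <- NA  # sRNA index of previous op if it was a pair
  prev_type <- ""
  for (op in ops) {
    if (op %in% c("W", "G", "X")) {
      i <- i + 1L
      if (op != "X" && identical(prev_pair, i - 1L) && prev_type != "X") {
        b1 <- substr(srna, i - 1L, i - 1L)
        b2 <- substr(srna, i, i)
        e <- e + if (prev_type == "W" && op == "W")
          wc_stack_table[[paste0(b1, b2)]] else gu_stack_energy
      }
      if (op != "X") { prev_pair <- i; prev_type <- op }
      else { prev_pair <- NA; prev_type <- "X" }
    } else if (op == "S") {
      i <- i + 1L
      prev_pair <- NA; prev_type <- op
    } else {  # target bulge breaks stacking
      prev_pair <- NA; prev_type <- op
    }
  }
  e
}

#' Duplex free-energy proxy of an sRNA against a site
#'
#' Nearest-neighbor stack sum over the optimal pairing found by
#' [pairing_score()]; more negative is more stable. For a fixed sRNA the
#' perfect complement minimizes it.
#'
#' @param srna sRNA sequence 5'->3'.
#' @param site target site sequence.
#' @param penalties pairing penalties.
#' @return energy proxy (<= 0) in kcal/mol-like units.
#' @export
duplex_mfe <- function(srna, site, penalties = default_pair_penalties()) {
  pairing_score(srna, site, penalties)$mfe_observed
}

perfect_mfe <- function(srna) {
  srna <- toupper(chartr("U", "T", srna))
  n <- nchar(srna)
  ch <- strsplit(srna, "", fixed = TRUE)[[1]]
  sum(wc_stack_table[paste0(ch[-n], ch[-1])])
}

#' Minimum-free-energy ratio of an observed duplex to the perfect duplex
#'
#' @param mfe_observed duplex energy of the sRNA-site pairing (<= 0).
#' @param mfe_perfect duplex energy of the sRNA against its perfect
#'   complement (< 0).
#' @return `100 * mfe_observed / mfe_perfect` (percent).
#' @export
#' @examples
#' mfe_ratio(-21.9, -30)  # 73
mfe_ratio <- function(mfe_observed, mfe_perfect) {
  if (any(mfe_perfect >= 0)) stop("mfe_perfect must be negative")
  100 * mfe_observed / mfe_perfect
}

#' Predict sRNA targets over a CDS set at plant thresholds
#'
#' Scans every CDS for candidate sites of every sRNA and keeps pairs with
#' pairing score at most `score_max` and MFE ratio at least `ratio_min`
#' (the standard plant thresholds are 4 and 73). Overlapping candidate
#' sites of the same sRNA are collapsed to the best one.
#'
#' @param srnas data.frame with `sequence`, `hairpin_id`, `strand` (sRNA
#'   origin on its hairpin) and optionally `abundance`.
#' @param cds_set named character vector of CDS/cDNA sequences.
#' @param score_max maximum pairing score (default 4).
#' @param ratio_min minimum MFE ratio percent (default 73).
#' @param strands `"plus"` to consider only plus-strand sRNAs (the default,
#'   matching mature-product orientation) or `"both"`.
#' @param penalties pairing penalties.
#' @return data.frame of kept predictions: `srna`, `hairpin_id`, `gene_id`,
#'   `site_start`, `site_end` (0-based half-open on the cDNA), `score`,
#'   `mfe_ratio`, `cleavage_pos` (0-based on the cDNA, NA if sRNA position
#'   10 is bulged), `path`.
#' @export
predict_targets <- function(srnas, cds_set, score_max = 4, ratio_min = 73,
                            strands = c("plus", "both"),
                            penalties = default_pair_penalties()) {
  strands <- match.arg(strands)
  if (strands == "plus") srnas <- srnas[srnas$strand == "+", , drop = FALSE]
  srnas <- unique(srnas[, c("sequence", "hairpin_id"), drop = FALSE])
  rows <- list()
  for (i in seq_len(nrow(srnas))) {
    s <- toupper(chartr("U", "T", srnas$sequence[i]))
    if (nchar(s) < 18 || nchar(s) > 26) next
    perf <- perfect_mfe(s)
    for (g in names(cds_set)) {
      hits <- .scan_sites_cpp(s, cds_set[[g]], penalties$mismatch,
                              penalties$gu, penalties$bulge,
                              penalties$core_start, penalties$core_end,
                              score_max)
      if (!nrow(hits)) next
      hits$mfe_ratio <- vapply(seq_len(nrow(hits)), function(k)
        mfe_ratio(path_mfe(s, cds_set[[g]], hits$site_end[k], hits$path[k]),
                  perf), numeric(1))
      hits <- hits[hits$mfe_ratio >= ratio_min, , drop = FALSE]
      if (!nrow(hits)) next
      # collapse overlapping windows: greedy by score then ratio
      hits <- hits[order(hits$score, -hits$mfe_ratio), , drop = FALSE]
      kept <- logical(nrow(hits))
      for (k in seq_len(nrow(hits))) {
        if (!any(kept & hits$site_start < hits$site_end[k] &
                 hits$site_end > hits$site_start[k])) kept[k] <- TRUE
      }
      hits <- hits[kept, , drop = FALSE]
      hits$srna <- s
      hits$hairpin_id <- srnas$hairpin_id[i]
      hits$gene_id <- g
      rows[[length(rows) + 1L]] <- hits
    }
  }
  if (!length(rows))
    return(data.frame(srna = character(), hairpin_id = character(),
                      gene_id = character(), site_start = integer(),
                      site_end = integer(), score = numeric(),
                      mfe_ratio = numeric(), cleavage_pos = integer(),
                      path = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$cleavage_pos <- ifelse(out$cleavage_pos >= 0, out$cleavage_pos,
                             NA_integer_)
  rownames(out) <- NULL
  out[, c("srna", "hairpin_id", "gene_id", "site_start", "site_end",
          "score", "mfe_ratio", "cleavage_pos", "path")]
}

#' Build the TE-MIR x initial-target interaction matrix
#'
#' Cells combine homology (HSPs from [find_initial_targets()]) with
#' predicted targeting. An HSP is an MTPH (MIR-target-pair HSP) iff at
#' least one sRNA of that TE-MIR has a kept prediction on that gene's CDS.
#'
#' @param hsp_table HSP data.frame (`query_id` = TE-MIR, `subject_id` =
#'   gene).
#' @param predictions kept predictions from [predict_targets()].
#' @param gene_classes data.frame `gene_id`, `gene_class`.
#' @return list with `cells` (mir_id, gene_id, n_hsps, min_evalue, mtph,
#'   best_score, best_ratio), `class_summary` (per-class gene counts and
#'   MTPH rates), `mtph_hsp_count` and `mtph_hsp_fraction`.
#' @export
build_interaction_matrix <- function(hsp_table, predictions, gene_classes) {
  if (nrow(hsp_table)) {
    dangling <- setdiff(unique(hsp_table$subject_id), gene_classes$gene_id)
    if (length(dangling))
      stop("genes missing from gene_classes: ",
           paste(dangling, collapse = ", "))
  }
  key <- unique(hsp_table[, c("query_id", "subject_id"), drop = FALSE])
  cells <- data.frame(mir_id = key$query_id, gene_id = key$subject_id,
                      stringsAsFactors = FALSE)
  n <- nrow(cells)
  cells$n_hsps <- integer(n); cells$min_evalue <- numeric(n)
  cells$mtph <- logical(n)
  cells$best_score <- rep(NA_real_, n); cells$best_ratio <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    sel <- hsp_table$query_id == cells$mir_id[i] &
      hsp_table$subject_id == cells$gene_id[i]
    cells$n_hsps[i] <- sum(sel)
    cells$min_evalue[i] <- min(hsp_table$evalue[sel])
    p <- predictions[predictions$hairpin_id == cells$mir_id[i] &
                     predictions$gene_id == cells$gene_id[i], , drop = FALSE]
    if (nrow(p)) {
      cells$mtph[i] <- TRUE
      cells$best_score[i] <- min(p$score)
      cells$best_ratio[i] <- max(p$mfe_ratio)
    }
  }
  cells$gene_class <- gene_classes$gene_class[
    match(cells$gene_id, gene_classes$gene_id)]
  cls <- unique(cells$gene_class)
  class_summary <- do.call(rbind, lapply(cls, function(cl) {
    sub <- cells[cells$gene_class == cl, , drop = FALSE]
    genes <- unique(sub$gene_id)
    mtph_genes <- unique(sub$gene_id[sub$mtph])
    data.frame(gene_class = cl, n_genes = length(genes),
               n_mtph_genes = length(mtph_genes),
               mtph_gene_rate = length(mtph_genes) / max(length(genes), 1),
               stringsAsFactors = FALSE)
  }))
  mtph_hsps <- sum(cells$n_hsps[cells$mtph])
  list(cells = cells, class_summary = class_summary,
       mtph_hsp_count = mtph_hsps,
       mtph_hsp_fraction = if (nrow(hsp_table))
         mtph_hsps / nrow(hsp_table) else NA_real_)
}
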