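#' Nucleotide local-alignment scoring scheme with Karlin-Altschul statistics
#'
#' Bundles the match/mismatch/gap scores used by the Smith-Waterman search
#' with the Karlin-Altschul parameters (lambda, K) that convert a raw score
#' into an E-value. Defaults mimic classic blastn: match +1, mismatch -3,
#' gap open 5, gap extend 2.
#'
#' When `lambda`/`K` are not supplied they are taken from a small table of
#' published values for common parameterizations (the gapped +1/-3, 5/2
#' scheme has lambda 1.28, K 0.46); for schemes outside the table, lambda is
#' computed by solving the ungapped Karlin-Altschul identity
#' \eqn{\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1} at uniform base composition
#' and K falls back to a conservative 0.35.
#'
#' @param match positive match reward.
#' @param mismatch negative mismatch score.
#' @param gap_open,gap_extend non-negative gap penalties; a gap of length L
#'   costs `gap_open + gap_extend * L`.
#' @param lambda,K optional Karlin-Altschul parameters overriding the table.
#' @return an object of class `scoring_scheme`.
#' @export
#' @examples
#' scoring_scheme()$lambda
scoring_scheme <- function(match = 1L, mismatch = -3L,
                           gap_open = 5L, gap_extend = 2L,
                           lambda = NULL, K = NULL) {
  if (match <= 0 || mismatch >= 0) stop("need match > 0 > mismatch")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  # expected per-position score must be negative at uniform background
  if (match / 4 + 3 * mismatch / 4 >= 0)
    stop("expected score under background must be < 0")
  if (is.null(lambda) || is.null(K)) {
    ka <- karlin_params(match, mismatch, gap_open, gap_extend)
    if (is.null(lambda)) lambda <- ka$lambda
    if (is.null(K)) K <- ka$K
  }
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, K = K),
            class = "scoring_scheme")
}

# Published gapped parameters (as shipped by blastn for common schemes),
# keyed by match/mismatch/open/extend; fallback computes ungapped lambda.
karlin_params <- function(match, mismatch, gap_open, gap_extend) {
  tab <- list(
    "1/-3/5/2"  = c(lambda = 1.28,  K = 0.46),
    "1/-3/0/0"  = c(lambda = 1.374, K = 0.711),
    "1/-2/5/2"  = c(lambda = 1.28,  K = 0.46),
    "1/-2/0/0"  = c(lambda = 1.28,  K = 0.46),
    "2/-3/5/2"  = c(lambda = 0.62,  K = 0.39)
  )
  key <- paste(match, mismatch, gap_open, gap_extend, sep = "/")
  if (!is.null(tab[[key]]))
    return(list(lambda = unname(tab[[key]]["lambda"]),
                K = unname(tab[[key]]["K"])))
  lam <- uniroot(function(l) exp(l * match) / 4 + 3 * exp(l * mismatch) / 4 - 1,
                 c(1e-6, 10), tol = 1e-12)$root
  list(lambda = lam, K = 0.35)
}

#' Karlin-Altschul E-value of a raw local-alignment score
#'
#' \eqn{E = K m n e^{-\lambda S}} for search-space sizes m (query) and
#' n (subject/database).
#'
#' @param raw_score integer raw alignment score.
#' @param m,n effective query and subject/database lengths (>= 1).
#' @param scheme a [scoring_scheme()].
#' @return the expected number of chance HSPs at or above `raw_score`.
#' @export
#' @examples
#' evalue_of(20, 120, 1e5, scoring_scheme())
evalue_of <- function(raw_score, m, n, scheme = scoring_scheme()) {
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1")
  scheme$K * m * n * exp(-scheme$lambda * raw_score)
}

#' Smith-Waterman local alignment returning BLAST-like HSPs
#'
#' Full dynamic-programming local alignment (no heuristic seeding) of a
#' query against both strands of a subject. Multiple high-scoring segment
#' pairs (HSPs) are produced by iteratively masking the subject interval of
#' the previous optimum and re-searching. `N` never matches.
#'
#' @param query,subject DNA strings over {A,C,G,T,N}.
#' @param scheme a [scoring_scheme()].
#' @param min_score minimum raw score for a reported HSP.
#' @param max_hsps cap on HSPs per strand.
#' @param query_id,subject_id labels carried into the output.
#' @param search_n effective database length for the E-value (defaults to
#'   the subject length; pass the total library length for library searches).
#' @return a data.frame of HSPs (0-based half-open coordinates on the
#'   forward strands) with columns `query_id, subject_id, q_start, q_end,
#'   s_start, s_end, subject_strand, raw_score, evalue, identity_fraction`,
#'   sorted by increasing E-value.
#' @export
#' @examples
#' local_align("ACGTACGTACGT", "ACGTACGTACGT")
local_align <- function(query, subject, scheme = scoring_scheme(),
                        min_score = 8L, max_hsps = 25L,
                        query_id = "query", subject_id = "subject",
                        search_n = nchar(subject)) {
  check_dna(query, "query"); check_dna(subject, "subject")
  n <- nchar(subject)
  res <- list()
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") subject else revcomp(subject)
    h <- .sw_hsps_cpp(query, subj, scheme$match, scheme$mismatch,
                      scheme$gap_open, scheme$gap_extend,
                      as.integer(min_score), as.integer(max_hsps))
    if (nrow(h) == 0) next
    if (strand == "-") {
      tmp <- h$s_start
      h$s_start <- n - h$s_end
      h$s_end <- n - tmp
    }
    h$subject_strand <- strand
    res[[strand]] <- h
  }
  if (length(res) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      subject_strand = character(), raw_score = integer(),
                      evalue = numeric(), identity_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out$query_id <- query_id
  out$subject_id <- subject_id
  out$evalue <- evalue_of(out$raw_score, nchar(query), search_n, scheme)
  out <- out[order(out$evalue, -out$raw_score, out$s_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("query_id", "subject_id", "q_start", "q_end", "s_start", "s_end",
          "subject_strand", "raw_score", "evalue", "identity_fraction")]
}

#' Screen miRNA stem-loops against a repeat library for TE origin
#'
#' A hairpin is called a TE-MIR iff it has at least one HSP against the
#' repeat library with E-value at or below `e_max` (default 0.005). The
#' class of the best-E subject is reported, along with the class frequency
#' table over all TE-MIR calls.
#'
#' @param hairpins named character vector of stem-loop sequences.
#' @param repeat_lib data.frame with columns `id`, `sequence`, `te_class`.
#' @param e_max E-value cutoff for TE-MIR status.
#' @param scheme a [scoring_scheme()].
#' @param min_score raw-score floor passed to [local_align()].
#' @return a list with `calls` (per-hairpin verdicts), `class_freq`
#'   (te_class table over TE-MIRs) and `hsps` (all HSPs found).
#' @export
find_te_mirs <- function(hairpins, repeat_lib, e_max = 0.005,
                         scheme = scoring_scheme(), min_score = 8L) {
  if (nrow(repeat_lib) == 0) stop("repeat library is empty")
  if (is.null(names(hairpins))) names(hairpins) <- paste0("hairpin", seq_along(hairpins))
  lib_n <- sum(nchar(repeat_lib$sequence))
  hsps <- list()
  for (h in names(hairpins)) {
    for (k in seq_len(nrow(repeat_lib))) {
      hs <- local_align(hairpins[[h]], repeat_lib$sequence[k], scheme,
                        min_score = min_score, query_id = h,
                        subject_id = repeat_lib$id[k], search_n = lib_n)
      if (nrow(hs)) {
        hs$te_class <- repeat_lib$te_class[k]
        hsps[[length(hsps) + 1L]] <- hs
      }
    }
  }
  hsps <- if (length(hsps)) do.call(rbind, hsps) else NULL
  calls <- data.frame(hairpin_id = names(hairpins), is_te_mir = FALSE,
                      best_subject = NA_character_, te_class = NA_character_,
                      best_evalue = NA_real_, n_hsps = 0L,
                      stringsAsFactors = FALSE)
  if (!is.null(hsps)) {
    keep <- hsps[hsps$evalue <= e_max, , drop = FALSE]
    for (i in seq_len(nrow(calls))) {
      mine <- keep[keep$query_id == calls$hairpin_id[i], , drop = FALSE]
      if (nrow(mine)) {
        best <- mine[which.min(mine$evalue), ]
        calls$is_te_mir[i] <- TRUE
        calls$best_subject[i] <- best$subject_id
        calls$te_class[i] <- best$te_class
        calls$best_evalue[i] <- best$evalue
        calls$n_hsps[i] <- nrow(mine)
      }
    }
  }
  class_freq <- table(calls$te_class[calls$is_te_mir])
  list(calls = calls, class_freq = class_freq, hsps = hsps)
}

#' Discover initial-target genes of TE-MIRs in a CDS set
#'
#' Aligns each TE-MIR stem-loop against every CDS; HSPs at `e_hsp` are
#' tabulated and genes holding at least one HSP at `e_gene` become initial
#' targets. Genes annotated as hypothetical proteins are excluded from the
#' target list (their HSPs remain in the table).
#'
#' @param te_mirs named character vector of TE-MIR stem-loop sequences.
#' @param cds_set named character vector of CDS/cDNA sequences.
#' @param gene_annotations data.frame with `gene_id`, `description`.
#' @param e_hsp E-value cutoff for tabulated HSPs (default 0.05).
#' @param e_gene stricter per-gene cutoff for initial-target status (0.01).
#' @param scheme a [scoring_scheme()].
#' @param min_score raw-score floor passed to [local_align()].
#' @return list with `hsp_table` and `initial_targets` (gene_id,
#'   description, gene_class, min_evalue, n_hsps).
#' @export
find_initial_targets <- function(te_mirs, cds_set, gene_annotations,
                                 e_hsp = 0.05, e_gene = 0.01,
                                 scheme = scoring_scheme(), min_score = 8L) {
  missing <- setdiff(names(cds_set), gene_annotations$gene_id)
  if (length(missing))
    stop("genes missing from annotations: ", paste(missing, collapse = ", "))
  db_n <- sum(nchar(cds_set))
  rows <- list()
  for (m in names(te_mirs)) {
    for (g in names(cds_set)) {
      hs <- local_align(te_mirs[[m]], cds_set[[g]], scheme,
                        min_score = min_score, query_id = m,
                        subject_id = g, search_n = db_n)
      hs <- hs[hs$evalue <= e_hsp, , drop = FALSE]
      if (nrow(hs)) rows[[length(rows) + 1L]] <- hs
    }
  }
  hsp_table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query_id = character(), subject_id = character(),
               q_start = integer(), q_end = integer(), s_start = integer(),
               s_end = integer(), subject_strand = character(),
               raw_score = integer(), evalue = numeric(),
               identity_fraction = numeric(), stringsAsFactors = FALSE)
  ann <- gene_annotations
  ann$gene_class <- classify_gene_annotation(ann$description)
  hypo <- grepl("hypothetical", ann$description, ignore.case = TRUE)
  strong <- hsp_table[hsp_table$evalue <= e_gene, , drop = FALSE]
  gene_ids <- setdiff(unique(strong$subject_id), ann$gene_id[hypo])
  targets <- ann[match(gene_ids, ann$gene_id),
                 c("gene_id", "description", "gene_class"), drop = FALSE]
  if (nrow(targets)) {
    targets$min_evalue <- vapply(targets$gene_id, function(g)
      min(strong$evalue[strong$subject_id == g]), numeric(1))
    targets$n_hsps <- vapply(targets$gene_id, function(g)
      sum(hsp_table$subject_id == g), integer(1))
  } else {
    targets$min_evalue <- numeric(0); targets$n_hsps <- integer(0)
  }
  rownames(targets) <- NULL
  list(hsp_table = hsp_table, initial_targets = targets)
}

#' Classify a gene description into TE-related / non-TE / expressed-unknown
#'
#' Keyword rule: descriptions containing transposon-family vocabulary are
#' `TE_related`; bare "expressed protein"/"unknown" annotations are
#' `expressed_unknown`; everything else is `non_TE`.
#'
#' @param description character vector of gene description strings.
#' @param te_keywords keywords (regex-escaped literals) marking TE proteins.
#' @return character vector of classes.
#' @export
#' @examples
#' classify_gene_annotation(c("retrotransposon protein, putative",
#'                            "expressed protein",
#'                            "MYB family transcription factor"))
classify_gene_annotation <- function(description,
    te_keywords = c("transposon", "retrotransposon", "transposase", "MULE",
                    "hAT", "CACTA", "MuDR", "helitron", "mariner", "Tc1",
                    "gypsy", "copia", "LINE-type", "MITE")) {
  pat_te <- paste0("(", paste(te_keywords, collapse = "|"), ")")
  is_te <- grepl(pat_te, description, ignore.case = TRUE)
  is_unk <- grepl("expressed protein|unknown", description, ignore.case = TRUE)
  ifelse(is_te, "TE_related", ifelse(is_unk, "expressed_unknown", "non_TE"))
}
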