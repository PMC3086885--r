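test_that("E-values follow the Karlin-Altschul formula", {
  sch <- scoring_scheme()  # gapped +1/-3 open 5 ext 2: lambda 1.28, K 0.46
  expect_equal(sch$lambda, 1.28)
  expect_equal(sch$K, 0.46)
  expect_equal(evalue_of(20, 120, 1e5, sch),
               0.46 * 120 * 1e5 * exp(-1.28 * 20))
  # doubling the database doubles E at fixed score
  expect_equal(evalue_of(15, 100, 2e4, sch), 2 * evalue_of(15, 100, 1e4, sch))
  # monotone decreasing in score, vanishing in the limit
  expect_true(all(diff(evalue_of(1:40, 100, 1e4, sch)) < 0))
  expect_lt(evalue_of(1000, 100, 1e4, sch), 1e-300)
  # ungapped lambda solves the identity at uniform background
  sch2 <- scoring_scheme(2, -5, 0, 0)
  expect_equal(exp(sch2$lambda * 2) / 4 + 3 * exp(-sch2$lambda * 5) / 4, 1,
               tolerance = 1e-8)
  expect_error(scoring_scheme(match = 1, mismatch = 1), "match")
  expect_error(evalue_of(10, 0, 100, sch), ">= 1")
})

test_that("local alignment finds self-matches and strand symmetry", {
  h <- local_align("ACGTACGTACGT", "ACGTACGTACGT")
  expect_identical(h$raw_score[1], 12L)
  expect_equal(h$identity_fraction[1], 1)
  expect_identical(h$subject_strand[1], "+")
  q <- "ACGGTTCAGGCATTACGGATCGAT"
  h2 <- local_align(q, revcomp(q))
  expect_identical(h2$subject_strand[1], "-")
  expect_equal(h2$identity_fraction[1], 1)
  expect_identical(h2$raw_score[1], nchar(q))
  # N never matches
  h3 <- local_align("ACGTNNNNACGT", "ACGTNNNNACGT", min_score = 1L)
  expect_lt(h3$raw_score[1], 12L)
  expect_error(local_align("", "ACGT"), "non-empty")
})

test_that("top local score matches independent implementations", {
  set.seed(42)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -3,
                                                     baseOnly = TRUE)
  for (k in 1:60) {
    q <- random_dna(sample(8:30, 1)); s <- random_dna(sample(8:30, 1))
    o <- max(oracle_sw(q, s), oracle_sw(q, revcomp(s)))
    b <- max(0,
      Biostrings::pairwiseAlignment(q, s, type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
        scoreOnly = TRUE),
      Biostrings::pairwiseAlignment(q, revcomp(s), type = "local",
        substitutionMatrix = submat, gapOpening = 5, gapExtension = 2,
        scoreOnly = TRUE))
    top <- top_local_score(q, s)
    expect_identical(top, as.integer(o))
    if (o > 0) expect_identical(top, as.integer(b))
  }
})

test_that("strand involution mirrors coordinates and keeps scores", {
  set.seed(43)
  for (k in 1:20) {
    q <- random_dna(40); s <- random_dna(60)
    a <- local_align(q, s, min_score = 4L)
    b <- local_align(q, revcomp(s), min_score = 4L)
    expect_identical(nrow(a) > 0, nrow(b) > 0)
    if (nrow(a)) {
      expect_identical(max(a$raw_score), max(b$raw_score))
      unique_top <- sum(a$raw_score == max(a$raw_score)) == 1 &&
        sum(b$raw_score == max(b$raw_score)) == 1
      if (unique_top) {
        ta <- a[which.max(a$raw_score), ]
        tb <- b[which.max(b$raw_score), ]
        expect_identical(ta$s_start, 60L - tb$s_end)
        expect_identical(ta$s_end, 60L - tb$s_start)
        expect_identical(ta$q_start, tb$q_start)
        expect_true(ta$subject_strand != tb$subject_strand)
      }
    }
  }
})

test_that("chance HSP counts stay within the Karlin-Altschul bound", {
  set.seed(44)
  q <- random_dna(100)
  subjects <- replicate(200, random_dna(100))
  ev <- unlist(lapply(subjects, function(s) local_align(q, s)$evalue))
  for (t in c(0.05, 0.005))
    expect_lte(sum(ev <= t), 3 * t * length(subjects))
})

test_that("TE-MIR calling recovers planted repeats and rejects decoys", {
  fam <- generate_te_family("MITE", 200L, 90L, 5L, 0.05, seed = 30,
                            family_id = "famM")
  rt <- generate_te_family("retrotransposon", 300L, 0L, 3L, 0.05, seed = 31,
                           family_id = "famR")
  lib <- data.frame(id = c("famM", "famR"),
                    sequence = c(fam$consensus, rt$consensus),
                    te_class = c("MITE", "retrotransposon"),
                    stringsAsFactors = FALSE)
  set.seed(32)
  hp_te <- paste0(random_dna(30), fam$copies[[1]], random_dna(30))
  hp_rand <- random_dna(260)
  res <- find_te_mirs(c(planted = hp_te, decoy = hp_rand), lib)
  expect_true(res$calls$is_te_mir[res$calls$hairpin_id == "planted"])
  expect_identical(res$calls$te_class[res$calls$hairpin_id == "planted"],
                   "MITE")
  expect_false(res$calls$is_te_mir[res$calls$hairpin_id == "decoy"])
  # e_max = Inf admits anything with an HSP
  res2 <- find_te_mirs(c(planted = hp_te, decoy = hp_rand), lib,
                       e_max = Inf)
  expect_true(all(res2$calls$is_te_mir | res2$calls$n_hsps == 0))
  expect_error(find_te_mirs(c(a = hp_te), lib[0, ]), "empty")
})

test_that("initial-target discovery excludes hypotheticals and honours E cutoffs", {
  fam <- generate_te_family("MITE", 200L, 90L, 3L, 0.03, seed = 33,
                            family_id = "famM")
  set.seed(34)
  hp <- paste0(random_dna(20), fam$copies[[1]], random_dna(20))
  frag <- substr(fam$copies[[2]], 30, 179)  # cognate 150-nt fragment
  cds <- c(target = paste0(random_dna(150), frag, random_dna(150)),
           hypo = paste0(random_dna(150), frag, random_dna(150)),
           clean = random_dna(450))
  ann <- data.frame(gene_id = c("target", "hypo", "clean"),
                    description = c("MYB family transcription factor",
                                    "hypothetical protein",
                                    "expressed protein"),
                    stringsAsFactors = FALSE)
  res <- find_initial_targets(c(mir1 = hp), cds, ann)
  expect_true("target" %in% res$initial_targets$gene_id)
  expect_false("hypo" %in% res$initial_targets$gene_id)
  expect_false("clean" %in% res$initial_targets$gene_id)
  expect_identical(res$initial_targets$gene_class[
    res$initial_targets$gene_id == "target"], "non_TE")
  # e_gene = 0 empties the target list but keeps the HSP table
  res0 <- find_initial_targets(c(mir1 = hp), cds, ann, e_gene = 0)
  expect_identical(nrow(res0$initial_targets), 0L)
  expect_gt(nrow(res0$hsp_table), 0L)
  expect_error(find_initial_targets(c(mir1 = hp), cds, ann[1:2, ]),
               "missing")
})

test_that("gene descriptions classify by keyword rule", {
  expect_identical(
    classify_gene_annotation(c("retrotransposon protein, putative",
                               "expressed protein",
                               "MYB family transcription factor",
                               "hAT dimerisation domain, transposase",
                               "unknown protein")),
    c("TE_related", "expressed_unknown", "non_TE", "TE_related",
      "expressed_unknown"))
})
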