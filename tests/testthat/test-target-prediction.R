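# A fixed 21-mer whose positions are easy to reason about: position 15 is
# G (can form G:U), position 5 (T) and 14 (G) take clean mismatches.
SRNA <- "ACGATGCATGCGTGGGTGCAT"

test_that("pairing penalties follow the plant scheme with core doubling", {
  site <- revcomp(SRNA)
  pa <- pairing_score(SRNA, site)
  expect_equal(pa$score, 0)
  expect_identical(pa$path, paste(rep("W", 21), collapse = ""))

  # G:U at sRNA position 15 (outside the core): the paired target base of
  # position k sits at site offset 21 - k
  site_gu <- site
  substr(site_gu, 21 - 15 + 1, 21 - 15 + 1) <- "T"  # C -> T under G
  pa_gu <- pairing_score(SRNA, site_gu)
  expect_equal(pa_gu$score, 0.5)

  # mismatch at position 5 (core): penalty 1 doubled
  site_mm <- site
  substr(site_mm, 21 - 5 + 1, 21 - 5 + 1) <- "C"   # A -> C under T: mismatch
  pa_mm <- pairing_score(SRNA, site_mm)
  expect_equal(pa_mm$score, 2)

  # a mismatch at position 14 (outside core) costs exactly half
  site_mm14 <- site
  substr(site_mm14, 21 - 14 + 1, 21 - 14 + 1) <- "A"  # C -> A under G
  expect_equal(pairing_score(SRNA, site_mm14)$score,
               pa_mm$score / 2)
  expect_error(pairing_score("ACGT", site), "18-26")
})

test_that("the duplex energy proxy behaves like a stacking model", {
  site <- revcomp(SRNA)
  pa <- pairing_score(SRNA, site)
  expect_equal(pa$mfe_observed, pa$mfe_perfect)
  expect_equal(pa$mfe_ratio, 100)
  gc <- paste(rep("GC", 10), collapse = "")  # 20-mer GC-rich
  au <- paste(rep("AT", 10), collapse = "")
  expect_lt(duplex_mfe(gc, revcomp(gc)), duplex_mfe(au, revcomp(au)))
  # random sites rarely reach the 73% ratio threshold
  set.seed(80)
  ratios <- replicate(60, pairing_score(SRNA, random_dna(23))$mfe_ratio)
  expect_lt(mean(ratios >= 73), 0.05)
})

test_that("MFE ratio is the plain percentage of the perfect duplex", {
  expect_equal(mfe_ratio(-30, -30), 100)
  expect_equal(mfe_ratio(-21.9, -30), 73)
  expect_equal(mfe_ratio(0, -30), 0)
  expect_error(mfe_ratio(-10, 0), "negative")
})

test_that("target prediction keeps only score/ratio-qualified sites", {
  set.seed(81)
  cds <- paste0(random_dna(120), revcomp(SRNA), random_dna(120))
  srnas <- data.frame(sequence = SRNA, hairpin_id = "mir1", strand = "+",
                      stringsAsFactors = FALSE)
  pred <- predict_targets(srnas, c(g1 = cds))
  expect_identical(nrow(pred), 1L)
  expect_identical(pred$site_start, 120L)
  expect_identical(pred$site_end, 141L)
  expect_equal(pred$score, 0)
  # cleavage position: 10 nt upstream of the site's 3'-most coordinate
  expect_identical(pred$cleavage_pos, 141L - 10L)
  # minus-strand sRNAs only participate in "both" mode
  srnas_m <- data.frame(sequence = SRNA, hairpin_id = "mir1", strand = "-",
                        stringsAsFactors = FALSE)
  expect_identical(nrow(predict_targets(srnas_m, c(g1 = cds))), 0L)
  expect_identical(nrow(predict_targets(srnas_m, c(g1 = cds),
                                        strands = "both")), 1L)
})

test_that("prediction sets are monotone in both thresholds", {
  set.seed(82)
  srnas <- data.frame(sequence = SRNA, hairpin_id = "m", strand = "+",
                      stringsAsFactors = FALSE)
  # sites with graded damage
  mk_site <- function(nmut) {
    s <- revcomp(SRNA)
    pos <- sample(21, nmut)
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
    }
    s
  }
  cds <- setNames(vapply(0:9, function(k)
    paste0(random_dna(40), mk_site(k %% 4), random_dna(40)), character(1)),
    paste0("g", 0:9))
  p3 <- predict_targets(srnas, cds, score_max = 3)
  p4 <- predict_targets(srnas, cds, score_max = 4)
  key <- function(p) paste(p$gene_id, p$site_start)
  expect_true(all(key(p3) %in% key(p4)))
  r80 <- predict_targets(srnas, cds, ratio_min = 80)
  r73 <- predict_targets(srnas, cds, ratio_min = 73)
  expect_true(all(key(r80) %in% key(r73)))
})

test_that("planted near-complementary sites are recovered at the thresholds", {
  set.seed(83)
  n <- 60; found <- 0
  for (k in seq_len(n)) {
    srna <- random_dna(21)
    site <- revcomp(srna)
    # one mismatch and one G:U, both outside the core (positions 14-21)
    p_mm <- sample(14:21, 1)
    o <- 21 - p_mm + 1
    substr(site, o, o) <- setdiff(c("A", "C", "G", "T"), substr(site, o, o))[1]
    p_gu <- sample(setdiff(14:21, p_mm), 1)
    if (substr(srna, p_gu, p_gu) %in% c("G", "T")) {
      o2 <- 21 - p_gu + 1
      substr(site, o2, o2) <- if (substr(srna, p_gu, p_gu) == "G") "T" else "G"
    }
    cds <- paste0(random_dna(100), site, random_dna(100))
    pred <- predict_targets(
      data.frame(sequence = srna, hairpin_id = "m", strand = "+"),
      c(g = cds))
    if (nrow(pred) && any(pred$site_start == 100L)) found <- found + 1
  }
  expect_gte(found / n, 0.95)
})

test_that("the interaction matrix flags MTPHs per HSP cell", {
  hsp <- data.frame(query_id = c("m1", "m1", "m2"),
                    subject_id = c("g1", "g1", "g2"),
                    evalue = c(1e-10, 1e-4, 1e-6),
                    stringsAsFactors = FALSE)
  pred <- data.frame(hairpin_id = "m1", gene_id = "g1", score = 1,
                     mfe_ratio = 90, stringsAsFactors = FALSE)
  classes <- data.frame(gene_id = c("g1", "g2"),
                        gene_class = c("non_TE", "TE_related"),
                        stringsAsFactors = FALSE)
  im <- build_interaction_matrix(hsp, pred, classes)
  c11 <- im$cells[im$cells$mir_id == "m1" & im$cells$gene_id == "g1", ]
  expect_true(c11$mtph)
  expect_identical(c11$n_hsps, 2L)
  c22 <- im$cells[im$cells$mir_id == "m2", ]
  expect_false(c22$mtph)  # HSP but no kept prediction: lost pairing
  expect_identical(im$mtph_hsp_count, 2L)
  expect_equal(im$mtph_hsp_fraction, 2 / 3)
  # empty prediction set: nothing is an MTPH
  im0 <- build_interaction_matrix(hsp, pred[0, ], classes)
  expect_false(any(im0$cells$mtph))
  expect_error(build_interaction_matrix(hsp, pred, classes[1, ]), "missing")
})
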