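test_that("perfect-match placement reports every occurrence, no mismatches", {
  set.seed(50); hp <- random_dna(120)
  r_plus <- substr(hp, 11, 31)
  r_minus <- revcomp(substr(hp, 41, 64))
  pl <- map_perfect(c(r_plus, r_minus), hp)
  expect_identical(pl$offset[pl$sequence == r_plus & pl$strand == "+"], 10L)
  expect_identical(pl$offset[pl$sequence == r_minus & pl$strand == "-"], 40L)
  # one mismatch anywhere kills the placement
  bad <- r_plus
  substr(bad, 5, 5) <- setdiff(c("A", "C", "G", "T"),
                               substr(bad, 5, 5))[1]
  expect_identical(nrow(map_perfect(bad, hp)), 0L)
  # multiple occurrences all reported
  hp2 <- paste0(hp, substr(hp, 1, 40))
  pl2 <- map_perfect(r_plus, hp2)
  expect_identical(sort(pl2$offset), c(10L, 130L))
})

test_that("TPQ normalization is count * 250000 / total", {
  expect_equal(normalize_tpq(4, 1e6), 1)
  expect_equal(normalize_tpq(250000, 250000), 250000)
  expect_equal(normalize_tpq(0, 10), 0)
  expect_error(normalize_tpq(1, 0), "> 0")
})

test_that("strand-bias categories follow the five-way rule", {
  expect_identical(classify_strand_bias(500, 0), "plus_only")
  expect_identical(classify_strand_bias(0, 500), "minus_only")
  expect_identical(classify_strand_bias(500, 20), "plus_major")  # 0.038
  expect_identical(classify_strand_bias(20, 500), "minus_major")
  expect_identical(classify_strand_bias(300, 280), "both")       # 0.48
  # boundary: exactly the minor fraction still counts as major
  expect_identical(classify_strand_bias(90, 10), "plus_major")
  expect_error(classify_strand_bias(0, 0), "no placements")
})

test_that("genome multiplicity counts exact hits on both strands", {
  set.seed(51); g <- c(chr = random_dna(4000))
  r1 <- substr(g[["chr"]], 101, 124)
  res <- genome_multiplicity(r1, g)
  expect_equal(res$mean_genome_hits, 1)
  # reads with hit counts {1, 3} average to 2
  g2 <- c(chr = paste0(g[["chr"]], r1, "TTTT", r1))
  r2 <- substr(g[["chr"]], 501, 524)
  res2 <- genome_multiplicity(c(r1, r2), g2)
  expect_equal(sort(res2$per_read$hits), c(1, 3))
  expect_equal(res2$mean_genome_hits, 2)
  # a minus-strand read counts through its reverse complement
  res3 <- genome_multiplicity(revcomp(r2), g)
  expect_equal(res3$mean_genome_hits, 1)
  # planted zero-divergence copies multiply hits accordingly
  fam <- generate_te_family("MITE", 120L, 15L, 50L, 0, seed = 52,
                            family_id = "f")
  tr <- plant_insertions(list(f = fam), c(chr = 40000L), c(f = 50L),
                         seed = 53)
  rd <- substr(fam$consensus, 31, 54)
  res4 <- genome_multiplicity(rd, tr$genome)
  expect_gte(res4$mean_genome_hits, 50)
})

test_that("length-distribution typing follows the five-type rule", {
  mk <- function(...) {
    rows <- list(...)
    m <- matrix(0, length(rows), 13,
                dimnames = list(NULL, as.character(18:30)))
    for (i in seq_along(rows)) m[i, names(rows[[i]])] <- rows[[i]]
    m
  }
  expect_identical(classify_length_distribution(
    mk(c("24" = 90, "21" = 10), c("24" = 45, "23" = 5))), "major24")
  expect_identical(classify_length_distribution(
    mk(c("21" = 80, "20" = 20), c("22" = 60, "21" = 40))), "major21")
  expect_identical(classify_length_distribution(
    mk(c("21" = 90, "20" = 10), c("24" = 90, "23" = 10))), "mixed")
  expect_identical(classify_length_distribution(
    mk(c("24" = 5), c("21" = 4))), "low")
  expect_identical(classify_length_distribution(
    mk(c("18" = 80, "24" = 20))), "other")
  # an unusable dataset is ignored, not counted against unanimity
  expect_identical(classify_length_distribution(
    mk(c("24" = 90), c("21" = 5))), "major24")
})

test_that("multiplicity comparison is a one-sided rank test", {
  set.seed(54)
  temir <- runif(20, 90, 110)
  canon <- runif(20, 0.5, 2)
  expect_lt(compare_multiplicity(temir, canon), 1e-5)
  expect_gt(compare_multiplicity(canon, temir), 0.99)
  same <- runif(30, 1, 10)
  p <- compare_multiplicity(same, same)
  expect_gt(p, 0.4); expect_lt(p, 0.6)
  expect_warning(p1 <- compare_multiplicity(rep(3, 5), rep(3, 5)),
                 "degenerate")
  expect_equal(p1, 1)
  expect_error(compare_multiplicity(numeric(0), 1), "non-empty")
})

test_that("aggregated length spectra are proper frequency rows", {
  set.seed(55); hp <- random_dna(150)
  reads <- data.frame(
    sequence = c(substr(hp, 1, 21), substr(hp, 31, 54)),
    dataset_id = "ds1", count = c(50L, 50L), stringsAsFactors = FALSE)
  p <- expression_profile("h", hp, reads)
  spec <- aggregate_length_spectrum(list(p))
  expect_equal(sum(spec["ds1", ]), 1, tolerance = 1e-9)
  expect_equal(spec["ds1", "21"], 0.5)
  expect_equal(spec["ds1", "24"], 0.5)
  single <- reads[1, , drop = FALSE]
  p2 <- expression_profile("h2", hp, single)
  spec2 <- aggregate_length_spectrum(list(p2))
  expect_equal(spec2["ds1", "21"], 1)
  # cohort-level spectrum recovers the generator weight within 3 points
  locus <- random_dna(300)
  reads3 <- simulate_srna_reads(locus, list(
    strand_bias = "plus_only",
    length_weights = c("21" = 0.4, "24" = 0.6), excision = "smeared"),
    depth = 12000L, seed = 56)
  p3 <- expression_profile("h3", locus, reads3)
  spec3 <- aggregate_length_spectrum(list(p3))
  expect_lt(abs(spec3["ds1", "24"] - 0.6), 0.03)
})

test_that("profiles tie placements, strand class and histograms together", {
  loc <- make_precise_locus(60, strand_bias = "plus_only")
  p <- expression_profile("hp", loc$hairpin, loc$reads,
                          genome = loc$truth$genome)
  expect_identical(p$strand_category, "plus_only")
  expect_identical(p$length_type, "major24")
  expect_lte(p$mean_genome_hits, 20)
  expect_true(all(rowSums(p$length_histograms) > 0))
})
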