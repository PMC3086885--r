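test_that("TE family generation honours class geometry and divergence", {
  fam0 <- generate_te_family("MITE", 260L, 14L, 1L, 0, seed = 3)
  expect_identical(fam0$copies[[1]], fam0$consensus)
  tir <- substr(fam0$consensus, 1, 14)
  expect_identical(substr(fam0$consensus, 247, 260), revcomp(tir))

  fam <- generate_te_family("MITE", 260L, 14L, 50L, 0.05, seed = 4)
  ident <- vapply(fam$copies, function(cp) {
    a <- strsplit(cp, "")[[1]]; b <- strsplit(fam$consensus, "")[[1]]
    mean(a == b)
  }, numeric(1))
  expect_true(abs(mean(ident) - 0.95) < 0.02)

  rt <- generate_te_family("retrotransposon", 300L, 0L, 10L, 0.1, seed = 5)
  expect_false(substr(rt$consensus, 281, 300) ==
                 revcomp(substr(rt$consensus, 1, 20)))

  expect_error(generate_te_family("MITE", 30L, 14L), "tir_len")
  expect_error(generate_te_family("virus", 100L), "arg")
  expect_error(generate_te_family("MITE", 260L, 14L, divergence = 0.5),
               "divergence")
})

test_that("insertion planting records truth and honours pairing/genic bias", {
  fam <- generate_te_family("MITE", 120L, 15L, 10L, 0.05, seed = 6,
                            family_id = "famA")
  t1 <- plant_insertions(list(famA = fam), c(chr = 5000L), c(famA = 1L),
                         seed = 7)
  expect_identical(nrow(t1$insertions), 1L)

  t2 <- plant_insertions(list(famA = fam), c(chr = 20000L), c(famA = 10L),
                         inverted_pair_fraction = 1, seed = 8)
  expect_identical(sum(t2$hairpin_loci$architecture == "inverted_pair"), 5L)
  expect_identical(nrow(t2$insertions), 10L)
  for (loc in which(t2$hairpin_loci$architecture == "inverted_pair")) {
    l <- t2$hairpin_loci[loc, ]
    members <- t2$insertions[t2$insertions$start >= l$start &
                             t2$insertions$end <= l$end, ]
    expect_identical(nrow(members), 2L)
    expect_setequal(members$strand, c("+", "-"))
    expect_identical(unique(members$family_id), l$family_id)
  }

  genes <- data.frame(gene_id = "g1", chrom = "chr", start = 2000L,
                      end = 3000L, cds_start = 2100L, cds_end = 2900L,
                      stringsAsFactors = FALSE)
  t3 <- plant_insertions(list(famA = fam), c(chr = 20000L), c(famA = 6L),
                         genic_bias = 1, genes = genes, seed = 9)
  g <- t3$genes[1, ]
  for (i in seq_len(nrow(t3$insertions)))
    expect_true(t3$insertions$start[i] < g$end &&
                t3$insertions$end[i] > g$start)
})

test_that("every planted TE is recoverable from the truth record", {
  fam <- generate_te_family("MITE", 150L, 20L, 8L, 0.1, seed = 10,
                            family_id = "famB")
  tr <- plant_insertions(list(famB = fam), c(c1 = 8000L, c2 = 5000L),
                         c(famB = 8L), inverted_pair_fraction = 0.5,
                         seed = 11)
  for (i in seq_len(nrow(tr$insertions))) {
    ins <- tr$insertions[i, ]
    got <- extract_interval(tr, ins$chrom, ins$start, ins$end, ins$strand)
    expect_true(got %in% fam$copies)
  }
})

test_that("generators are byte-deterministic for a fixed seed", {
  fa <- generate_te_family("MITE", 200L, 30L, 5L, 0.1, seed = 12)
  fb <- generate_te_family("MITE", 200L, 30L, 5L, 0.1, seed = 12)
  expect_identical(fa, fb)
  loc <- make_precise_locus(77)
  loc2 <- make_precise_locus(77)
  expect_identical(loc$truth$genome, loc2$truth$genome)
  expect_identical(loc$reads, loc2$reads)
  d1 <- simulate_degradome(random_dna(200), 50L, seed = 13)
  d2 <- simulate_degradome(paste(rep("A", 200), collapse = ""), 50L,
                           seed = 13)
  expect_identical(d1, d2)  # depends only on length and seed
})

test_that("smeared read sets reproduce the requested length spectrum", {
  locus <- "x"
  set.seed(1); locus <- random_dna(300)
  w <- c("21" = 0.3, "22" = 0.2, "24" = 0.5)
  reads <- simulate_srna_reads(locus, list(
    strand_bias = "plus_only", length_weights = w, excision = "smeared"),
    depth = 10000L, seed = 14)
  freq <- tapply(reads$count, nchar(reads$sequence), sum) / sum(reads$count)
  for (l in names(w))
    expect_lt(abs(freq[[l]] - w[[l]]), 0.03)
})

test_that("strand bias and excision mode shape the simulated reads", {
  set.seed(2); locus <- random_dna(260)  # random locus: strands unambiguous
  on_plus <- function(r) vapply(r, function(x)
    grepl(x, locus, fixed = TRUE), logical(1))
  r1 <- simulate_srna_reads(locus, list(
    strand_bias = "plus_only", length_weights = c("24" = 1),
    excision = "precise", mir_window = c(20L, 44L),
    star_window = c(200L, 224L)), depth = 1000L, seed = 15)
  expect_true(all(on_plus(r1$sequence)))
  modal <- names(which.max(tapply(r1$count, nchar(r1$sequence), sum)))
  expect_identical(modal, "24")

  r2 <- simulate_srna_reads(locus, list(
    strand_bias = "both", length_weights = c("21" = 0.5, "24" = 0.5),
    excision = "smeared"), depth = 1000L, seed = 16)
  minus_ab <- sum(r2$count[!on_plus(r2$sequence)])
  f <- minus_ab / sum(r2$count)
  expect_true(f >= 0.35 && f <= 0.65)

  # dominant precise read far exceeds any other plus-strand read
  r3 <- simulate_srna_reads(locus, list(
    strand_bias = "plus_only", length_weights = c("21" = 1),
    excision = "precise", mir_window = c(20L, 41L)), depth = 1000L,
    seed = 17)
  dom <- substr(locus, 21, 41)
  ab <- tapply(r3$count, r3$sequence, sum)
  expect_gte(ab[[dom]], 5 * max(ab[names(ab) != dom]))

  expect_error(simulate_srna_reads(locus, list(
    strand_bias = "plus_only", length_weights = c("24" = 1),
    excision = "precise", mir_window = c(250L, 280L)), seed = 1),
    "window")
  expect_error(simulate_srna_reads(locus, list(
    strand_bias = "plus_only", length_weights = numeric(0),
    excision = "smeared"), seed = 1), "spectrum")
})

test_that("degradome simulation plants the peak where asked", {
  set.seed(3); cdna <- random_dna(400)
  d1 <- simulate_degradome(cdna, 120L, signal_reads = 50L,
                           noise_positions = 0L, seed = 18)
  expect_identical(d1$position[which.max(d1$count)], 120L)
  expect_identical(nrow(d1), 1L)
  d2 <- simulate_degradome(cdna, 120L, signal_reads = 50L,
                           noise_positions = 10L, noise_reads = 5L,
                           seed = 19)
  expect_identical(d2$position[which.max(d2$count)], 120L)
  expect_true(all(d2$count[d2$position != 120L] <= 5L))
  d3 <- simulate_degradome(cdna, 10L, signal_reads = 3L,
                           noise_positions = 1L, noise_reads = 3L, seed = 20)
  expect_true(max(d3$count) <= 3L)
  expect_error(simulate_degradome(cdna, 400L), "range")
})

test_that("TE embedding in CDS respects the overlap mode", {
  gm <- list(gene_id = "g", sequence = random_dna(600), cds_start = 100L,
             cds_end = 500L)
  te <- random_dna(120)
  b <- embed_te_in_cds(gm, te, "boundary_spanning", seed = 21)
  expect_true(b$te_start < b$cds_end && b$te_end > b$cds_start)  # intersects
  expect_true(b$te_start < b$cds_start)                           # and exits
  expect_true(b$te_overlaps_cds_boundary)
  expect_identical(substr(b$sequence, b$te_start + 1L, b$te_end), te)

  i <- embed_te_in_cds(gm, te, "fully_internal", seed = 22)
  expect_true(i$te_start >= i$cds_start && i$te_end <= i$cds_end)
  expect_false(i$te_overlaps_cds_boundary)

  short <- list(gene_id = "g2", sequence = random_dna(150), cds_start = 20L,
                cds_end = 130L)
  expect_error(embed_te_in_cds(short, random_dna(200), "fully_internal"),
               "longer")
})
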