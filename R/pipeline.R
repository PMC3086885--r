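# End-to-end orchestration: simulate -> homology -> profile -> annotate ->
# predict -> degradome, with report tables shaped like the study's figures
# (TE class frequencies, strand categories, hit histogram, length spectra,
# the typical-screen table, the interaction matrix, cleavage scores).

#' Default run configuration for the synthetic TE-MIR study
#'
#' Defines the study conditions: a two-chromosome background genome plus a
#' gene chromosome, eight TE families mixing low-copy well-diverged hairpin
#' MITEs (typical-MIR candidates), young high-copy MITEs (hairpin siRNA
#' loci), an inverted-pair-forming retrotransposon and background DNA
#' elements; three sRNA datasets; two degradome datasets; and the printed
#' analysis thresholds (E <= 0.005 for TE-MIR status, E <= 0.05/0.01 for
#' initial targets, genome hit <= 20, pairing score <= 4, MFE ratio >= 73,
#' usable dataset total >= 10).
#'
#' @param seed master seed; every stage derives child seeds from it.
#' @return a nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  len24 <- c("21" = 0.08, "23" = 0.08, "24" = 0.80, "25" = 0.04)
  len21 <- c("20" = 0.08, "21" = 0.80, "22" = 0.08, "24" = 0.04)
  lenmix <- c("20" = 0.10, "21" = 0.35, "23" = 0.10, "24" = 0.35, "26" = 0.10)
  fam <- function(id, class, len, tir, copies, div, pair_frac = 0,
                  regime = NULL)
    list(family_id = id, te_class = class, length = len, tir_len = tir,
         copies = copies, divergence = div, pair_fraction = pair_frac,
         regime = regime)
  reg <- function(excision, strand, weights, mir_len)
    list(excision = excision, strand_bias = strand,
         length_weights = weights, mir_len = mir_len)
  list(
    seed = as.integer(seed),
    thresholds = list(e_temir = 0.005, e_hsp = 0.05, e_gene = 0.01,
                      hit_max = 20, score_max = 4, ratio_min = 73,
                      usable_min = 10, minor_fraction = 0.10,
                      dominance_min = 5, window_concentration_min = 0.75,
                      overhang_tol = 1),
    stages = list(homology = TRUE, profile = TRUE, annotate = TRUE,
                  predict = TRUE, degradome = TRUE),
    generator = list(
      chrom_lengths = c(chr1 = 60000L, chr2 = 40000L),
      flank = 15L, n_decoys = 3L, n_datasets = 3L, depth = 600L,
      max_loci_per_family = 3L, gene_len = 600L, cds = c(100L, 500L),
      top_reads_per_hairpin = 5L,
      families = list(
        fam("MITE_typ1", "MITE", 220L, 100L, 2L, 0.10,
            regime = reg("precise", "plus_only", len24, 24L)),
        fam("MITE_typ2", "MITE", 220L, 100L, 3L, 0.10,
            regime = reg("precise", "plus_major", len21, 21L)),
        fam("MITE_typ3", "MITE", 220L, 100L, 3L, 0.10,
            regime = reg("precise", "plus_only", len24, 24L)),
        fam("MITE_high1", "MITE", 220L, 100L, 35L, 0.005,
            regime = reg("smeared", "both", lenmix, 24L)),
        fam("MITE_high2", "MITE", 220L, 100L, 25L, 0.005,
            regime = reg("smeared", "both", lenmix, 24L)),
        fam("RETRO_inv", "retrotransposon", 260L, 0L, 10L, 0.10,
            pair_frac = 0.4,
            regime = reg("precise", "plus_major", len21, 21L)),
        fam("DNA_bg", "other_DNA", 250L, 20L, 12L, 0.10),
        fam("UNCL_typ", "unclassified", 200L, 90L, 2L, 0.10,
            regime = reg("precise", "plus_only", len24, 24L))),
      genes = list(
        list(gene_id = "gene01", description = "MYB family transcription factor",
             source = "MITE_typ1", frag_divergence = 0.02,
             mode = "boundary_spanning"),
        list(gene_id = "gene02", description = "cytochrome P450, putative",
             source = "MITE_typ3", frag_divergence = 0.02,
             mode = "boundary_spanning"),
        list(gene_id = "gene03", description = "expressed protein",
             source = "UNCL_typ", frag_divergence = 0.02,
             mode = "boundary_spanning"),
        list(gene_id = "gene04", description = "retrotransposon protein, putative",
             source = "RETRO_inv", frag_divergence = 0.12,
             mode = "boundary_spanning"),
        list(gene_id = "gene05", description = "transposase, putative",
             source = "MITE_high1", frag_divergence = 0.02,
             mode = "fully_internal"),
        list(gene_id = "gene06", description = "expressed protein",
             source = "MITE_typ2", frag_divergence = 0.02,
             mode = "boundary_spanning"),
        list(gene_id = "gene07", description = "MADS-box transcription factor",
             source = NA, frag_divergence = NA, mode = NA),
        list(gene_id = "gene08", description = "hypothetical protein",
             source = "MITE_typ1", frag_divergence = 0.02,
             mode = "boundary_spanning")),
      degradome = list(
        n_noise = 10L, noise_max = 5L,
        # per dataset, per gene: planted evidence at the true cleavage
        # position: "strong" = dominant peak (category 1), "medium" =
        # above-median signal under a larger off-site peak (category 2),
        # "weak" = at-or-below-median trickle (category 3), "none".
        plan = list(
          deg1 = list(gene01 = "strong", gene02 = "medium",
                      gene03 = "strong", gene06 = "strong"),
          deg2 = list(gene01 = "strong", gene02 = "weak",
                      gene03 = "strong", gene06 = "weak")))))
}

#' Load a run configuration from YAML, merged over the defaults
#'
#' @param path YAML file; keys override [default_config()] entries.
#' @param seed optional seed overriding both.
#' @return a configuration list.
#' @export
read_run_config <- function(path, seed = NULL) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  cfg <- modifyList(cfg, user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

# ---- simulate stage ---------------------------------------------------

simulate_inputs <- function(config) {
  gen <- config$generator
  seed <- config$seed
  fams <- list()
  pair_frac <- numeric(0)
  for (k in seq_along(gen$families)) {
    fs <- gen$families[[k]]
    fams[[fs$family_id]] <- generate_te_family(
      fs$te_class, fs$length, fs$tir_len, fs$copies, fs$divergence,
      seed = child_seed(seed, 100 + k), family_id = fs$family_id)
    pair_frac[fs$family_id] <- fs$pair_fraction %||% 0
  }
  copy_numbers <- vapply(gen$families, function(f) f$copies, integer(1))
  names(copy_numbers) <- vapply(gen$families, `[[`, character(1), "family_id")
  truth <- plant_insertions(fams, gen$chrom_lengths, copy_numbers,
                            inverted_pair_fraction = pair_frac,
                            seed = child_seed(seed, 2))
  regimes <- setNames(lapply(gen$families, `[[`, "regime"),
                      names(copy_numbers))
  # annotated hairpin set: up to max_loci_per_family per family with a regime
  flank <- gen$flank
  meta <- list(); hairpins <- character(0)
  for (f in names(fams)) {
    if (is.null(regimes[[f]])) next
    loci <- truth$hairpin_loci[truth$hairpin_loci$family_id == f, ,
                               drop = FALSE]
    if (!nrow(loci)) next
    loci <- head(loci, gen$max_loci_per_family)
    for (i in seq_len(nrow(loci))) {
      hp_id <- sprintf("MIR_%s_%d", f, i)
      sq <- extract_interval(truth, loci$chrom[i],
                             max(0, loci$start[i] - flank),
                             min(nchar(truth$genome[[loci$chrom[i]]]),
                                 loci$end[i] + flank))
      hairpins[hp_id] <- sq
      meta[[length(meta) + 1L]] <- data.frame(
        hairpin_id = hp_id, locus_id = loci$locus_id[i], family_id = f,
        architecture = loci$architecture[i], stringsAsFactors = FALSE)
    }
  }
  hairpin_meta <- do.call(rbind, meta)
  with_seed(child_seed(seed, 3), {
    for (d in seq_len(gen$n_decoys))
      hairpins[sprintf("DECOY_%d", d)] <- random_dna(220L)
  })
  # sRNA reads per annotated hairpin, pooled
  reads <- list()
  windows <- list()
  for (i in seq_len(nrow(hairpin_meta))) {
    hp_id <- hairpin_meta$hairpin_id[i]
    f <- hairpin_meta$family_id[i]
    rg <- regimes[[f]]
    L <- nchar(hairpins[[hp_id]])
    mw <- c(flank + 18L, flank + 18L + rg$mir_len)
    sw <- palindrome_star_window(mw, L)
    prof <- list(strand_bias = rg$strand_bias,
                 length_weights = rg$length_weights,
                 excision = rg$excision, mir_window = mw, star_window = sw)
    reads[[i]] <- simulate_srna_reads(hairpins[[hp_id]], prof,
                                      depth = gen$depth,
                                      n_datasets = gen$n_datasets,
                                      seed = child_seed(seed, 1000 + i))
    windows[[hp_id]] <- list(mir = mw, star = sw)
  }
  reads <- do.call(rbind, reads)
  reads <- stats::aggregate(count ~ sequence + dataset_id, reads, sum)
  reads <- reads[order(reads$dataset_id, reads$sequence), , drop = FALSE]
  rownames(reads) <- NULL
  # gene models on a dedicated gene chromosome
  genes <- list(); gene_seqs <- character(0); site_truth <- list()
  for (k in seq_along(gen$genes)) {
    gs <- gen$genes[[k]]
    gseed <- child_seed(seed, 2000 + k)
    gm <- with_seed(gseed, list(gene_id = gs$gene_id,
                                sequence = random_dna(gen$gene_len),
                                cds_start = gen$cds[1], cds_end = gen$cds[2]))
    if (!is.na(gs$source)) {
      src_rows <- hairpin_meta[hairpin_meta$family_id == gs$source, ,
                               drop = FALSE]
      hp <- hairpins[[src_rows$hairpin_id[1]]]
      win <- windows[[src_rows$hairpin_id[1]]]
      copy_len <- nchar(hp) - 2L * flank
      # cognate fragment: antisense copy window covering the miR region
      ws <- win$mir[1] - flank; we <- win$mir[2] - flank
      a <- max(0L, ws - 60L); b <- min(copy_len, we + 60L)
      frag <- revcomp(substr(hp, flank + a + 1L, flank + b))
      frag <- with_seed(child_seed(gseed, 1),
                        mutate_seq(frag, gs$frag_divergence))
      gm <- embed_te_in_cds(gm, frag, gs$mode, seed = child_seed(gseed, 2),
                            boundary_offset = if (gs$mode ==
                              "boundary_spanning") 20L else NULL)
      # planted site and guided cleavage position, in cDNA (=CDS) coords
      fs <- b - we; fe <- b - ws
      site_start <- gm$te_start + fs - gm$cds_start
      site_end <- gm$te_start + fe - gm$cds_start
      site_truth[[gs$gene_id]] <- list(
        gene_id = gs$gene_id, hairpin_id = src_rows$hairpin_id[1],
        site_start = site_start, site_end = site_end,
        cleavage_pos = site_end - 10L)
    }
    genes[[k]] <- gm
    gene_seqs[gs$gene_id] <- gm$sequence
  }
  spacer <- with_seed(child_seed(seed, 4), random_dna(200L))
  chrU <- paste0(spacer, paste(unlist(gene_seqs), collapse = spacer), spacer)
  genome <- c(truth$genome, chrU = chrU)
  # gene coordinates on chrU for the truth record / GFF
  offs <- cumsum(c(nchar(spacer),
                   head(nchar(gene_seqs) + nchar(spacer), -1)))
  gene_df <- do.call(rbind, lapply(seq_along(genes), function(k) {
    gm <- genes[[k]]
    data.frame(gene_id = gm$gene_id, chrom = "chrU",
               start = offs[k], end = offs[k] + nchar(gm$sequence),
               cds_start = offs[k] + gm$cds_start,
               cds_end = offs[k] + gm$cds_end,
               te_overlaps_cds_boundary =
                 isTRUE(gm$te_overlaps_cds_boundary),
               stringsAsFactors = FALSE)
  }))
  truth$genes <- gene_df
  cds_set <- vapply(genes, function(gm)
    substr(gm$sequence, gm$cds_start + 1L, gm$cds_end), character(1))
  names(cds_set) <- vapply(genes, `[[`, character(1), "gene_id")
  annotations <- data.frame(
    gene_id = names(cds_set),
    description = vapply(gen$genes, `[[`, character(1), "description"),
    stringsAsFactors = FALSE)
  # degradome datasets
  deg <- gen$degradome
  degradome_sets <- list()
  di <- 0L
  for (ds in names(deg$plan)) {
    di <- di + 1L
    profs <- list()
    for (g in names(cds_set)) {
      L <- nchar(cds_set[[g]])
      kind <- deg$plan[[ds]][[g]] %||% "none"
      st <- site_truth[[g]]
      dseed <- child_seed(seed, 3000 + 50 * di + match(g, names(cds_set)))
      noise <- simulate_degradome(cds_set[[g]],
                                  cleavage_pos = if (!is.null(st))
                                    st$cleavage_pos else 0L,
                                  signal_reads = 0L,
                                  noise_positions = deg$n_noise,
                                  noise_reads = deg$noise_max, seed = dseed)
      extra <- NULL
      if (!is.null(st) && kind != "none") {
        cp <- st$cleavage_pos
        extra <- switch(kind,
          strong = data.frame(position = cp, count = 50L),
          medium = data.frame(position = c(cp, (cp + 50L) %% L),
                              count = c(8L, 60L)),
          weak = data.frame(position = c(cp, (cp + 50L) %% L),
                            count = c(1L, 40L)))
      }
      tab <- rbind(noise, extra)
      profs[[g]] <- degradome_profile(g, tab$position, tab$count, L)
    }
    degradome_sets[[ds]] <- profs
  }
  list(truth = truth, families = fams, genome = genome,
       hairpins = hairpins, hairpin_meta = hairpin_meta,
       windows = windows, reads = reads, cds_set = cds_set,
       annotations = annotations, degradome_sets = degradome_sets,
       site_truth = site_truth)
}

# ---- pipeline ---------------------------------------------------------

#' Run the full TE-MIR pipeline on synthetic inputs
#'
#' Executes the enabled stages in dependency order on data generated from
#' the configuration's seed, and assembles the report tables. Outputs are
#' deterministic given the seed.
#'
#' @param config configuration from [default_config()] or
#'   [read_run_config()].
#' @param out_dir optional directory; when given, input files (FASTA, GFF3,
#'   TSV, truth JSON) and report tables are written there.
#' @return an object of class `temir_report`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  th <- config$thresholds
  stages <- config$stages
  sim <- simulate_inputs(config)
  repeat_lib <- data.frame(
    id = names(sim$families),
    sequence = vapply(sim$families, `[[`, character(1), "consensus"),
    te_class = vapply(sim$families, `[[`, character(1), "te_class"),
    stringsAsFactors = FALSE)
  tables <- list(); counts <- list(n_hairpins = length(sim$hairpins))
  temir <- NULL; profiles <- NULL; screens <- NULL
  targets <- NULL; predictions <- NULL
  if (isTRUE(stages$homology)) {
    temir <- find_te_mirs(sim$hairpins, repeat_lib, e_max = th$e_temir)
    cf <- as.data.frame(temir$class_freq, stringsAsFactors = FALSE)
    names(cf) <- c("te_class", "n")
    tables$te_class_freq <- cf
    counts$n_te_mirs <- sum(temir$calls$is_te_mir)
  }
  temir_ids <- if (!is.null(temir))
    temir$calls$hairpin_id[temir$calls$is_te_mir] else character(0)
  if (isTRUE(stages$profile) && length(temir_ids)) {
    all_mult <- genome_multiplicity(unique(sim$reads$sequence), sim$genome)
    hitvec <- setNames(all_mult$per_read$hits, all_mult$per_read$sequence)
    profiles <- lapply(temir_ids, function(h)
      expression_profile(h, sim$hairpins[[h]], sim$reads,
                         genome_hits = hitvec,
                         minor_fraction = th$minor_fraction,
                         usable_min = th$usable_min))
    names(profiles) <- temir_ids
    sc <- vapply(profiles, `[[`, character(1), "strand_category")
    tables$strand_freq <- as.data.frame(table(strand_category = sc),
                                        stringsAsFactors = FALSE)
    hits <- vapply(profiles, `[[`, numeric(1), "mean_genome_hits")
    bins <- cut(hits, c(0, 1, 5, 10, 20, 50, Inf),
                labels = c("1", "2-5", "6-10", "11-20", "21-50", ">50"))
    tables$hit_histogram <- as.data.frame(table(mean_genome_hits = bins),
                                          stringsAsFactors = FALSE)
    spec <- aggregate_length_spectrum(profiles)
    tables$length_spectra <- data.frame(dataset_id = rownames(spec),
                                        spec, check.names = FALSE,
                                        row.names = NULL)
    counts$n_profiled <- length(profiles)
  }
  if (isTRUE(stages$annotate) && !is.null(profiles)) {
    rows <- list()
    for (h in temir_ids) {
      prof <- profiles[[h]]
      st <- fold_hairpin(sim$hairpins[[h]])
      dup <- tryCatch(
        call_duplex(st, prof$placements, dominance_min = th$dominance_min,
                    window_concentration_min = th$window_concentration_min,
                    overhang_tol = th$overhang_tol),
        error = function(e) base::structure(
          list(precise = FALSE, mir_read = NA_character_,
               star_read = NA_character_),
          class = "duplex_call"))
      scr <- screen_typical(prof, dup, hit_max = th$hit_max)
      arch <- detect_inverted_te_pair(sim$hairpins[[h]], sim$families,
                                      structure = st, e_max = th$e_temir)
      rows[[h]] <- data.frame(
        hairpin_id = h, strand_category = prof$strand_category,
        mean_genome_hits = round(prof$mean_genome_hits, 2),
        length_type = prof$length_type,
        passes_hit = scr$passes_hit, passes_strand = scr$passes_strand,
        passes_excision = scr$passes_excision, verdict = scr$verdict,
        mir_seq = dup$mir_read %||% NA_character_,
        star_seq = dup$star_read %||% NA_character_,
        architecture = arch$architecture, stringsAsFactors = FALSE)
    }
    tables$typical_table <- do.call(rbind, c(rows, make.row.names = FALSE))
    screens <- tables$typical_table
    counts$n_typical <- sum(screens$verdict == "typical")
  }
  if (isTRUE(stages$predict) && length(temir_ids)) {
    te_seqs <- sim$hairpins[temir_ids]
    targets <- find_initial_targets(te_seqs, sim$cds_set, sim$annotations,
                                    e_hsp = th$e_hsp, e_gene = th$e_gene)
    counts$n_hsps <- nrow(targets$hsp_table)
    counts$n_initial_targets <- nrow(targets$initial_targets)
    srnas <- top_hairpin_reads(profiles,
                               config$generator$top_reads_per_hairpin)
    target_cds <- sim$cds_set[targets$initial_targets$gene_id]
    predictions <- predict_targets(srnas, target_cds,
                                   score_max = th$score_max,
                                   ratio_min = th$ratio_min)
    counts$n_predictions <- nrow(predictions)
    gene_classes <- targets$initial_targets[, c("gene_id", "gene_class")]
    strong <- targets$hsp_table[
      targets$hsp_table$subject_id %in% targets$initial_targets$gene_id, ,
      drop = FALSE]
    im <- build_interaction_matrix(strong, predictions, gene_classes)
    tables$interaction_matrix <- im$cells
    tables$mtph_class_summary <- im$class_summary
    counts$n_mtph_hsps <- im$mtph_hsp_count
  }
  if (isTRUE(stages$degradome) && !is.null(predictions)) {
    tables$cleavage_scores <- score_targets(predictions, sim$degradome_sets,
                                            score_max = th$score_max)
    counts$n_category1_targets <- length(unique(
      tables$cleavage_scores$gene_id[
        grepl("(^|,)1(,|$)", tables$cleavage_scores$categories)]))
  }
  report <- base::structure(
    list(tables = tables, counts = counts, thresholds = th,
         seed = config$seed,
         version = as.character(utils::packageVersion("temir")),
         sim = sim, temir = temir, profiles = profiles,
         targets = targets, predictions = predictions),
    class = "temir_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(sim$genome, file.path(out_dir, "genome.fa"))
    write_fasta(setNames(repeat_lib$sequence,
                         paste(repeat_lib$id, repeat_lib$te_class)),
                file.path(out_dir, "repeats.fa"))
    write_fasta(sim$hairpins, file.path(out_dir, "hairpins.fa"))
    write_fasta(sim$cds_set, file.path(out_dir, "cds.fa"))
    write_truth_gff3(sim$truth, file.path(out_dir, "annotation.gff3"))
    write_srna_tsv(sim$reads, file.path(out_dir, "srna.tsv"))
    deg_rows <- list()
    for (ds in names(sim$degradome_sets))
      for (g in names(sim$degradome_sets[[ds]])) {
        p <- sim$degradome_sets[[ds]][[g]]
        pos <- which(p$counts > 0) - 1L
        deg_rows[[length(deg_rows) + 1L]] <- data.frame(
          dataset_id = ds, cdna_id = g, position = pos,
          count = p$counts[pos + 1L], stringsAsFactors = FALSE)
      }
    write_degradome_tsv(do.call(rbind, deg_rows),
                        file.path(out_dir, "degradome.tsv"))
    write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
    write_report(report, out_dir)
  }
  report
}

# top plus-strand reads per profiled hairpin, as predict_targets input
top_hairpin_reads <- function(profiles, n_top = 5L) {
  rows <- list()
  for (h in names(profiles)) {
    pl <- profiles[[h]]$placements
    pl <- pl[pl$strand == "+", , drop = FALSE]
    if (!nrow(pl)) next
    ab <- sort(tapply(pl$abundance, pl$sequence, max), decreasing = TRUE)
    sel <- names(head(ab, n_top))
    sel <- sel[nchar(sel) >= 18 & nchar(sel) <= 26]
    if (length(sel))
      rows[[h]] <- data.frame(sequence = sel, hairpin_id = h, strand = "+",
                              stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(sequence = character(), hairpin_id = character(),
                      strand = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out
}

#' Write a pipeline report to TSV tables plus a JSON summary
#'
#' Every table file carries header comment lines echoing the thresholds
#' actually used (no silent defaults). The JSON summary holds the per-stage
#' record counts, parameter echo and package version.
#'
#' @param report a `temir_report`.
#' @param out_dir writable output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- paste0("# thresholds: ",
                paste(names(report$thresholds),
                      unlist(report$thresholds), sep = "=",
                      collapse = " "))
  for (nm in names(report$tables)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    con <- file(path, "w")
    writeLines(c(paste0("# table: ", nm), hdr), con)
    write.table(report$tables[[nm]], con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  jsonlite::write_json(
    list(seed = report$seed, version = report$version,
         thresholds = report$thresholds, counts = report$counts,
         tables = names(report$tables)),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.temir_report <- function(x, ...) {
  cat("temir pipeline report (seed ", x$seed, ")\n", sep = "")
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %s\n", nm, x$counts[[nm]]))
  cat("  tables:", paste(names(x$tables), collapse = ", "), "\n")
  invisible(x)
}
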