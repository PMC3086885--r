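# Synthetic ground-truth generators: TE families, genomes with planted
# insertions, TE-in-CDS gene models, small-RNA read sets and degradome tags.
# All coordinates are 0-based half-open internally; GFF3 output is 1-based.

#' Generate a transposable-element family with mutated copies
#'
#' Builds a random consensus of the requested class and `n_copies` copies
#' mutated by substitutions placed uniformly at rate `divergence`. MITE
#' consensi are palindromic over their terminal inverted repeats (the first
#' `tir_len` nt are the reverse complement of the last `tir_len` nt); set
#' `tir_len` close to `(length - loop) / 2` to obtain hairpin-forming,
#' near-fully palindromic MITEs.
#'
#' @param te_class one of `"MITE"`, `"retrotransposon"`, `"other_DNA"`,
#'   `"unclassified"`.
#' @param length consensus length (>= 2 * tir_len + 20).
#' @param tir_len terminal inverted repeat length (0 for none; >= 10 for MITE).
#' @param n_copies number of mutated copies to draw.
#' @param divergence per-position substitution rate in [0, 0.3].
#' @param seed RNG seed (deterministic output for a fixed seed).
#' @param family_id label for the family.
#' @return an object of class `te_family`: list with `family_id`, `te_class`,
#'   `consensus`, `tir_len`, `divergence` and `copies` (character vector).
#' @export
generate_te_family <- function(te_class, length, tir_len = 0L, n_copies = 1L,
                               divergence = 0, seed = NULL,
                               family_id = paste0(te_class, "_fam")) {
  te_class <- match.arg(te_class,
    c("MITE", "retrotransposon", "other_DNA", "unclassified"))
  if (length < 2 * tir_len + 20) stop("tir_len too large for length")
  if (te_class == "MITE" && tir_len < 10) stop("MITE requires tir_len >= 10")
  if (divergence < 0 || divergence > 0.3) stop("divergence must be in [0, 0.3]")
  with_seed(seed, {
    consensus <- random_dna(length)
    if (tir_len > 0) {
      head_tir <- substr(consensus, 1, tir_len)
      substr(consensus, length - tir_len + 1, length) <- revcomp(head_tir)
    }
    copies <- vapply(seq_len(n_copies), function(i)
      mutate_seq(consensus, divergence), character(1))
    structure(list(family_id = family_id, te_class = te_class,
                   consensus = consensus, tir_len = as.integer(tir_len),
                   divergence = divergence, copies = copies),
              class = "te_family")
  })
}

# substitutions only, each position independently at rate `rate`
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  }
  paste(ch, collapse = "")
}

#' Plant TE insertions into a synthetic genome with full ground truth
#'
#' Assembles i.i.d.-uniform background chromosomes and splices in TE copies.
#' A fraction of each family's copies is planted as juxtaposed inverted
#' pairs: two cognate copies in opposite orientation separated by a short
#' spacer, the architecture that lets two TEs each contribute one arm of a
#' stem-loop. Single insertions of near-fully palindromic families (MITEs
#' whose TIRs cover most of their length) are recorded as
#' `single_palindrome` hairpin loci.
#'
#' @param families named list of [generate_te_family()] objects.
#' @param chrom_lengths named integer vector of background lengths.
#' @param copy_numbers named integer vector: insertions per family.
#' @param inverted_pair_fraction fraction of a family's copies consumed by
#'   inverted-pair loci (each pair uses two copies); a scalar, or a named
#'   vector giving per-family fractions.
#' @param genic_bias probability that an insertion point falls within a
#'   gene span (requires `genes`).
#' @param genes optional data.frame of gene models in background
#'   coordinates: `gene_id, chrom, start, end, cds_start, cds_end`.
#' @param spacer_range inverted-pair spacer length range in nt.
#' @param seed RNG seed.
#' @return an object of class `genome_truth`: list with `genome` (named
#'   character vector), `insertions`, `hairpin_loci`, `genes` data.frames
#'   and the `families` used. All coordinates 0-based half-open.
#' @export
plant_insertions <- function(families, chrom_lengths, copy_numbers,
                             inverted_pair_fraction = 0, genic_bias = 0,
                             genes = NULL, spacer_range = c(5L, 50L),
                             seed = NULL) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  total_ins <- sum(vapply(names(copy_numbers), function(f)
    copy_numbers[[f]] * nchar(families[[f]]$consensus), numeric(1)))
  if (total_ins >= 0.5 * sum(chrom_lengths))
    stop("overflow: total inserted length exceeds half the genome")
  if (genic_bias > 0 && is.null(genes))
    stop("genic_bias > 0 requires gene models")
  with_seed(seed, {
    # build insertion units: singles and inverted pairs
    units <- list()
    for (f in names(copy_numbers)) {
      fam <- families[[f]]
      n <- copy_numbers[[f]]
      fr <- if (length(inverted_pair_fraction) > 1 ||
                !is.null(names(inverted_pair_fraction))) {
        if (f %in% names(inverted_pair_fraction))
          inverted_pair_fraction[[f]] else 0
      } else inverted_pair_fraction
      n_pairs <- floor(fr * n / 2)
      n_single <- n - 2L * n_pairs
      copy_pool <- rep_len(fam$copies, n)
      ci <- 0L
      take <- function() { ci <<- ci + 1L; copy_pool[ci] }
      if (n_pairs > 0) for (p in seq_len(n_pairs)) {
        a <- take(); b <- take()
        sp <- random_dna(sample(spacer_range[1]:spacer_range[2], 1))
        units[[length(units) + 1L]] <- list(
          type = "inverted_pair", family_id = f,
          parts = list(list(seq = a, strand = "+"),
                       list(seq = sp, strand = NA),
                       list(seq = revcomp(b), strand = "-")))
      }
      palindromic <- fam$tir_len * 2 >= 0.6 * nchar(fam$consensus)
      if (n_single > 0) for (s in seq_len(n_single)) {
        units[[length(units) + 1L]] <- list(
          type = if (palindromic) "single_palindrome" else "single",
          family_id = f,
          parts = list(list(seq = take(), strand = "+")))
      }
    }
    # assign each unit a chromosome and a background insertion point
    chroms <- names(chrom_lengths)
    unit_chrom <- character(length(units))
    unit_pos <- integer(length(units))
    for (u in seq_along(units)) {
      if (!is.null(genes) && runif(1) < genic_bias) {
        g <- genes[sample(nrow(genes), 1), ]
        unit_chrom[u] <- g$chrom
        unit_pos[u] <- g$start + sample.int(max(g$end - g$start - 1L, 1L), 1)
      } else {
        unit_chrom[u] <- sample(chroms, 1, prob = chrom_lengths)
        unit_pos[u] <- sample.int(chrom_lengths[[unit_chrom[u]]] - 1L, 1)
      }
    }
    genome <- setNames(vector("character", length(chroms)), chroms)
    ins <- list(); loci <- list()
    out_genes <- genes
    for (cc in chroms) {
      bg <- random_dna(chrom_lengths[[cc]])
      sel <- which(unit_chrom == cc)
      sel <- sel[order(unit_pos[sel])]
      pieces <- character(0); cursor <- 0L; offset <- 0L
      shifts <- if (!is.null(genes)) {
        function(p) offset  # evaluated at insertion time below
      } else NULL
      gene_rows <- if (!is.null(genes)) which(genes$chrom == cc) else integer(0)
      gshift_start <- rep(0L, length(gene_rows))
      gshift_end <- rep(0L, length(gene_rows))
      gshift_cs <- rep(0L, length(gene_rows))
      gshift_ce <- rep(0L, length(gene_rows))
      for (u in sel) {
        p <- unit_pos[u]
        pieces <- c(pieces, substr(bg, cursor + 1L, p))
        cursor <- p
        unit_start <- p + offset
        at <- unit_start
        part_coords <- list()
        for (part in units[[u]]$parts) {
          w <- nchar(part$seq)
          pieces <- c(pieces, part$seq)
          part_coords[[length(part_coords) + 1L]] <-
            list(start = at, end = at + w, strand = part$strand)
          at <- at + w
        }
        unit_len <- at - unit_start
        offset <- offset + unit_len
        # record insertions (spacer parts have NA strand; skip them)
        for (pc in part_coords) {
          if (is.na(pc$strand)) next
          ins[[length(ins) + 1L]] <- data.frame(
            family_id = units[[u]]$family_id, chrom = cc,
            start = pc$start, end = pc$end, strand = pc$strand,
            stringsAsFactors = FALSE)
        }
        if (units[[u]]$type %in% c("inverted_pair", "single_palindrome")) {
          loci[[length(loci) + 1L]] <- data.frame(
            locus_id = sprintf("locus_%s_%d", cc, length(loci) + 1L),
            architecture = units[[u]]$type, chrom = cc,
            start = unit_start, end = unit_start + unit_len,
            family_id = units[[u]]$family_id, stringsAsFactors = FALSE)
        }
        # genes: insertion before a gene shifts it; inside inflates its end
        if (length(gene_rows)) for (gi in seq_along(gene_rows)) {
          g <- genes[gene_rows[gi], ]
          if (p < g$start) {
            gshift_start[gi] <- gshift_start[gi] + unit_len
            gshift_end[gi] <- gshift_end[gi] + unit_len
          } else if (p < g$end) {
            gshift_end[gi] <- gshift_end[gi] + unit_len
          }
          if (p < g$cds_start) {
            gshift_cs[gi] <- gshift_cs[gi] + unit_len
            gshift_ce[gi] <- gshift_ce[gi] + unit_len
          } else if (p < g$cds_end) {
            gshift_ce[gi] <- gshift_ce[gi] + unit_len
          }
        }
      }
      pieces <- c(pieces, substr(bg, cursor + 1L, chrom_lengths[[cc]]))
      genome[[cc]] <- paste(pieces, collapse = "")
      if (length(gene_rows)) {
        out_genes$start[gene_rows] <- genes$start[gene_rows] + gshift_start
        out_genes$end[gene_rows] <- genes$end[gene_rows] + gshift_end
        out_genes$cds_start[gene_rows] <- genes$cds_start[gene_rows] + gshift_cs
        out_genes$cds_end[gene_rows] <- genes$cds_end[gene_rows] + gshift_ce
      }
    }
    insertions <- if (length(ins)) do.call(rbind, ins) else
      data.frame(family_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    hairpin_loci <- if (length(loci)) do.call(rbind, loci) else
      data.frame(locus_id = character(), architecture = character(),
                 chrom = character(), start = integer(), end = integer(),
                 family_id = character(), stringsAsFactors = FALSE)
    if (!is.null(out_genes) && nrow(out_genes)) {
      out_genes$te_overlaps_cds_boundary <- vapply(seq_len(nrow(out_genes)),
        function(i) {
          g <- out_genes[i, ]
          sub <- insertions[insertions$chrom == g$chrom, , drop = FALSE]
          any(sub$start < g$cds_end & sub$end > g$cds_start &
              (sub$start < g$cds_start | sub$end > g$cds_end))
        }, logical(1))
    }
    structure(list(genome = genome, insertions = insertions,
                   hairpin_loci = hairpin_loci, genes = out_genes,
                   families = families),
              class = "genome_truth")
  })
}

#' Extract a planted sequence interval from a genome truth record
#'
#' @param truth a `genome_truth` object.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"` (minus returns the reverse complement).
#' @return the genomic substring.
#' @export
extract_interval <- function(truth, chrom, start, end, strand = "+") {
  s <- substr(truth$genome[[chrom]], start + 1L, end)
  if (strand == "-") revcomp(s) else s
}

#' Embed a TE copy in a gene model's coding sequence
#'
#' Rewrites a gene-local sequence so that the TE interval overlaps the CDS
#' either across exactly one CDS edge (`boundary_spanning`: the TE
#' intersects coding sequence and extends into non-coding sequence) or
#' fully inside it (`fully_internal`).
#'
#' @param gene_model list with `gene_id`, `sequence` (gene-local DNA) and
#'   0-based half-open `cds_start`, `cds_end`.
#' @param te_copy TE sequence to insert.
#' @param overlap_mode `"boundary_spanning"` or `"fully_internal"`.
#' @param seed RNG seed for the overlap offset.
#' @param boundary_offset optional fixed offset (nt into the TE) at which
#'   the CDS edge is placed in boundary_spanning mode; random if NULL.
#' @return the updated gene model with `te_start`, `te_end` and the
#'   `te_overlaps_cds_boundary` truth flag.
#' @export
embed_te_in_cds <- function(gene_model, te_copy,
                            overlap_mode = c("boundary_spanning",
                                             "fully_internal"),
                            seed = NULL, boundary_offset = NULL) {
  overlap_mode <- match.arg(overlap_mode)
  L <- nchar(gene_model$sequence)
  w <- nchar(te_copy)
  if (w > L) stop("TE longer than available gene span")
  cs <- gene_model$cds_start; ce <- gene_model$cds_end
  with_seed(seed, {
    if (overlap_mode == "boundary_spanning") {
      if (w < 20) stop("TE too short to span a boundary meaningfully")
      # insert at the CDS 5' edge, then move the CDS start inside the TE
      d <- if (!is.null(boundary_offset)) as.integer(boundary_offset)
           else sample(10:(w - 10), 1)
      if (d < 1 || d >= w) stop("boundary_offset outside the TE")
      seq2 <- paste0(substr(gene_model$sequence, 1, cs), te_copy,
                     substr(gene_model$sequence, cs + 1L, L))
      gene_model$sequence <- seq2
      gene_model$te_start <- cs
      gene_model$te_end <- cs + w
      gene_model$cds_start <- cs + d
      gene_model$cds_end <- ce + w
      gene_model$te_overlaps_cds_boundary <- TRUE
    } else {
      if (ce - cs < 2) stop("CDS has no interior")
      p <- cs + sample.int(ce - cs - 1L, 1)
      seq2 <- paste0(substr(gene_model$sequence, 1, p), te_copy,
                     substr(gene_model$sequence, p + 1L, L))
      gene_model$sequence <- seq2
      gene_model$te_start <- p
      gene_model$te_end <- p + w
      gene_model$cds_end <- ce + w
      gene_model$te_overlaps_cds_boundary <- FALSE
    }
    gene_model
  })
}

#' Simulate small-RNA reads from a locus with known expression structure
#'
#' Two excision regimes. `precise` emulates miRNA-like biogenesis: one
#' dominant read per window (miR and, if given, miR*), carrying
#' `concentration` (resp. `star_share`) of the strand's abundance, plus
#' geometrically decaying shifted variants. `smeared` emulates hairpin
#' siRNA production: read starts uniform along the locus with lengths drawn
#' from the requested spectrum. Strand bias is controlled by the planted
#' category: minority-strand abundance fraction 0 (`plus_only`),
#' `minor_strand_fraction` (`plus_major` / mirrored for minus), or 0.5
#' (`both`).
#'
#' @param locus_seq the locus sequence (plus strand).
#' @param profile list with `strand_bias` (one of the five categories),
#'   `length_weights` (named numeric over nt lengths 18-30), `excision`
#'   (`"precise"` or `"smeared"`), and for precise mode `mir_window`
#'   (0-based half-open on the locus), optional `star_window`,
#'   `concentration` (default 0.65), `star_share` (0.2),
#'   `minor_strand_fraction` (0.05).
#' @param depth total read instances per dataset.
#' @param n_datasets number of independently resampled datasets.
#' @param seed RNG seed.
#' @param dataset_prefix prefix for dataset ids.
#' @return data.frame with columns `sequence`, `dataset_id`, `count`.
#' @export
simulate_srna_reads <- function(locus_seq, profile, depth = 1000L,
                                n_datasets = 1L, seed = NULL,
                                dataset_prefix = "ds") {
  L <- nchar(locus_seq)
  lw <- profile$length_weights
  if (is.null(lw) || sum(lw) <= 0) stop("empty length spectrum")
  lens <- as.integer(names(lw))
  if (any(is.na(lens))) stop("length_weights must be named by length")
  excision <- match.arg(profile$excision, c("precise", "smeared"))
  sb <- match.arg(profile$strand_bias,
    c("plus_only", "minus_only", "plus_major", "minus_major", "both"))
  mf <- profile$minor_strand_fraction %||% 0.05
  minus_frac <- switch(sb, plus_only = 0, minus_only = 1,
                       plus_major = mf, minus_major = 1 - mf, both = 0.5)
  conc <- profile$concentration %||% 0.65
  star_share <- profile$star_share %||% 0.2
  if (excision == "precise") {
    mw <- profile$mir_window
    if (is.null(mw) || mw[1] < 0 || mw[2] > L) stop("miR window outside locus")
    sw <- profile$star_window
    if (!is.null(sw) && (sw[1] < 0 || sw[2] > L)) stop("star window outside locus")
  }
  with_seed(seed, {
    out <- list()
    for (d in seq_len(n_datasets)) {
      ds <- paste0(dataset_prefix, d)
      tab <- new.env(parent = emptyenv())
      add <- function(seq, n) {
        if (n <= 0 || !nzchar(seq)) return(invisible())
        cur <- if (!is.null(tab[[seq]])) tab[[seq]] else 0L
        tab[[seq]] <- cur + as.integer(n)
      }
      draw_smeared <- function(n, strand_minus_frac) {
        if (n <= 0) return(invisible())
        ls <- lens[sample.int(length(lens), n, replace = TRUE, prob = lw)]
        st <- runif(n) < strand_minus_frac
        for (i in seq_len(n)) {
          w <- ls[i]
          if (w >= L) w <- L - 1L
          o <- sample.int(L - w + 1L, 1) - 1L
          r <- substr(locus_seq, o + 1L, o + w)
          add(if (st[i]) revcomp(r) else r, 1L)
        }
      }
      if (excision == "smeared") {
        draw_smeared(depth, minus_frac)
      } else {
        mw <- profile$mir_window; sw <- profile$star_window
        # dominant strand carries the duplex; mirror for minus-dominant bias
        dom_minus <- sb %in% c("minus_only", "minus_major")
        dom_total <- round(depth * (if (sb == "both") 0.5 else
          if (dom_minus) minus_frac else 1 - minus_frac))
        other_total <- depth - dom_total
        orient <- function(r) if (dom_minus) revcomp(r) else r
        mir_read <- substr(locus_seq, mw[1] + 1L, mw[2])
        # without a star window the star share folds into the dominant
        # read, keeping the variant budget (and dominance ratio) stable
        n_mir <- round(dom_total * (conc + if (is.null(sw)) star_share else 0))
        add(orient(mir_read), n_mir)
        n_star <- 0L
        if (!is.null(sw)) {
          star_read <- substr(locus_seq, sw[1] + 1L, sw[2])
          n_star <- round(dom_total * star_share)
          add(orient(star_read), n_star)
        }
        # geometric-decaying shifted variants around the miR window
        rem <- dom_total - n_mir - n_star
        k <- 1L
        while (rem > 0 && k <= 8L) {
          n_k <- min(rem, max(1L, round(rem * 0.5)))
          sh <- sample(c(-3:-1, 1:3), 1)
          dl <- sample(c(-1L, 0L, 1L), 1)
          s0 <- max(0L, mw[1] + sh)
          e0 <- min(L, mw[2] + sh + dl)
          if (e0 - s0 >= 15) add(orient(substr(locus_seq, s0 + 1L, e0)), n_k)
          rem <- rem - n_k
          k <- k + 1L
        }
        # minority strand: scattered low-abundance reads
        draw_smeared(other_total, if (dom_minus) 0 else 1)
      }
      seqs <- ls(tab)
      if (length(seqs))
        out[[length(out) + 1L]] <- data.frame(
          sequence = seqs, dataset_id = ds,
          count = vapply(seqs, function(s) tab[[s]], integer(1)),
          stringsAsFactors = FALSE, row.names = NULL)
    }
    res <- if (length(out)) do.call(rbind, out) else
      data.frame(sequence = character(), dataset_id = character(),
                 count = integer(), stringsAsFactors = FALSE)
    res <- res[order(res$dataset_id, res$sequence), , drop = FALSE]
    rownames(res) <- NULL
    res
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expected miR* window on a near-palindromic hairpin locus
#'
#' For a hairpin whose arms are reverse-complementary across the full locus,
#' the partner of window `[s, e)` is `[L - e, L - s)`; shifting it 3'-ward
#' by 2 nt gives the canonical miR/miR* duplex with 2-nt 3' overhangs.
#'
#' @param mir_window 0-based half-open miR window.
#' @param locus_len locus length.
#' @return 0-based half-open star window.
#' @export
palindrome_star_window <- function(mir_window, locus_len) {
  c(locus_len - mir_window[2] + 2L, locus_len - mir_window[1] + 2L)
}

#' Simulate a degradome 5'-tag profile with a planted cleavage peak
#'
#' @param cdna target cDNA sequence (used only for its length).
#' @param cleavage_pos 0-based position carrying the planted signal.
#' @param signal_reads tag count at the planted position.
#' @param noise_positions number of background positions (drawn without
#'   replacement away from the signal).
#' @param noise_reads maximum tag count per noise position (counts are
#'   drawn uniformly from 1..noise_reads).
#' @param seed RNG seed.
#' @return data.frame with `position` (0-based 5'-end position) and `count`.
#' @export
simulate_degradome <- function(cdna, cleavage_pos, signal_reads = 50L,
                               noise_positions = 10L, noise_reads = 5L,
                               seed = NULL) {
  L <- nchar(cdna)
  if (cleavage_pos < 0 || cleavage_pos >= L) stop("position out of range")
  with_seed(seed, {
    pos <- integer(0); cnt <- integer(0)
    if (signal_reads > 0) { pos <- cleavage_pos; cnt <- as.integer(signal_reads) }
    if (noise_positions > 0) {
      pool <- setdiff(0:(L - 1L), cleavage_pos)
      np <- sample(pool, min(noise_positions, length(pool)))
      nc <- sample.int(max(noise_reads, 1L), length(np), replace = TRUE)
      nc <- pmin(nc, noise_reads)
      pos <- c(pos, np); cnt <- c(cnt, as.integer(nc))
    }
    o <- order(pos)
    data.frame(position = pos[o], count = cnt[o])
  })
}
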