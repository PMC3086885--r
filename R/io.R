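# Readers/writers for the pipeline's interchange formats: FASTA via
# Biostrings, GFF3 via rtracklayer, TSV tables, truth JSON.

#' Write named sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read FASTA into a named character vector
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*", "", names(x)))
}

#' Write genome-truth annotation to GFF3
#'
#' Emits repeat_region features for every planted TE insertion (with
#' `family_id` in the attributes) and gene/mRNA/CDS features for gene
#' models. Internal 0-based half-open coordinates become 1-based inclusive.
#'
#' @param truth a `genome_truth` object.
#' @param path output GFF3 file.
#' @return the path, invisibly.
#' @export
write_truth_gff3 <- function(truth, path) {
  f <- data.frame(chrom = character(), start = integer(), end = integer(),
                  strand = character(), type = character(),
                  ID = character(), family_id = character(),
                  stringsAsFactors = FALSE)
  ins <- truth$insertions
  if (nrow(ins))
    f <- rbind(f, data.frame(chrom = ins$chrom, start = ins$start,
                             end = ins$end, strand = ins$strand,
                             type = "repeat_region",
                             ID = sprintf("te%05d", seq_len(nrow(ins))),
                             family_id = ins$family_id,
                             stringsAsFactors = FALSE))
  g <- truth$genes
  if (!is.null(g) && nrow(g)) {
    mk <- function(type, s, e, id)
      data.frame(chrom = g$chrom, start = s, end = e, strand = "+",
                 type = type, ID = id, family_id = NA_character_,
                 stringsAsFactors = FALSE)
    f <- rbind(f, mk("gene", g$start, g$end, g$gene_id),
               mk("mRNA", g$start, g$end, paste0(g$gene_id, ".1")),
               mk("CDS", g$cds_start, g$cds_end,
                  paste0(g$gene_id, ".1.cds")))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(f$chrom, levels = unique(f$chrom)),
    ranges = IRanges::IRanges(start = f$start + 1L, end = f$end),
    strand = f$strand, type = f$type, ID = f$ID, family_id = f$family_id,
    phase = ifelse(f$type == "CDS", 0L, NA_integer_))
  rtracklayer::export.gff3(gr, path)
  invisible(path)
}

#' Write / read a small-RNA read table (sequence, dataset_id, count)
#' @param reads data.frame with `sequence`, `dataset_id`, `count`.
#' @param path TSV file.
#' @return the path, invisibly.
#' @export
write_srna_tsv <- function(reads, path) {
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_srna_tsv
#' @export
read_srna_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(sequence = "character",
                            dataset_id = "character", count = "integer"))
}

#' Write / read a degradome tag table (cdna_id, position, count)
#' @param tags data.frame with `cdna_id`, `position` (0-based), `count`.
#' @param path TSV file.
#' @return the path, invisibly.
#' @export
write_degradome_tsv <- function(tags, path) {
  write.table(tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_degradome_tsv
#' @export
read_degradome_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write the ground-truth sidecar JSON for a synthetic genome
#' @param truth a `genome_truth` object.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  payload <- list(
    chromosomes = lapply(truth$genome, nchar),
    insertions = truth$insertions,
    hairpin_loci = truth$hairpin_loci,
    genes = truth$genes)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
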