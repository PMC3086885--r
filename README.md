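# temir

Identification and validation of transposable-element-derived plant miRNA
genes (TE-MIRs).

## The problem

Plant genomes carry thousands of hairpin-forming repeats — above all MITEs
(miniature inverted-repeat transposable elements) — whose fold-back
transcripts are diced into small RNAs that look exactly like miRNAs. Some
annotated plant miRNA genes are in fact such repeats, and a few of them
appear to be genuine miRNA genes caught mid-domestication: low-copy,
plus-strand-biased loci that precisely excise a miR/miR\* duplex and guide
cleavage of the very protein-coding genes their cognate TE created by
inserting into coding sequence. `temir` is a tested, reusable
implementation of that whole analysis chain for anyone studying TE→miRNA
domestication, hairpin siRNA loci, or plant small-RNA annotation.

## What it computes

* **TE-MIR screen** — Smith–Waterman local alignment (full DP, affine
  gaps, both strands) of miRNA stem-loops against a repeat library with
  Karlin–Altschul statistics, `E = K·m·n·e^(−λS)`; a hairpin is a TE-MIR
  iff some HSP reaches `E ≤ 0.005`.
* **Expression profiles** — perfect-match read placement; strand-bias
  category (`plus_only`, `minus_only`, `plus_major`, `minus_major`,
  `both`), mean genome multiplicity, length-distribution type (`low`,
  `major21`, `major24`, `mixed`, `other`); TPQ (transcripts per quarter
  million) normalization.
* **Typical-miRNA screen** — genome hit ≤ 20, plus-strand bias, and
  precise miR/miR\* duplex excision (2-nt 3′ overhangs) on a
  base-pair-maximization fold; single-palindrome vs juxtaposed
  inverted-TE-pair locus architecture.
* **Initial targets** — genes whose CDS holds TE-MIR homology
  (HSPs at `E ≤ 0.05`, genes at `E ≤ 0.01`, hypothetical proteins
  removed), classed as TE-related / non-TE / expressed-unknown.
* **Target prediction** — plant penalty scheme (mismatch 1, G:U 0.5,
  bulge 2, doubled at sRNA positions 2–13) with a nearest-neighbor duplex
  MFE ratio; pairs kept at `score ≤ 4`, `MFE ratio ≥ 73%`; the
  MIR×target MTPH interaction matrix.
* **Degradome validation** — 5′-tag profiles on target cDNAs; the tag
  count opposite sRNA nucleotide 10 is ranked into categories 1/2/3 and
  the per-target category set is summarized as the score
  {1,2,3}→7, {1,2}→6, {1,3}→5, {1}→4, {2,3}→3, {2}→2, {3}→1.
* **Synthetic data** — TE families, genomes with planted insertions and
  ground-truth JSON, hairpin loci (palindromic or inverted-pair), sRNA
  read sets with controllable strand bias / length spectrum / excision
  precision, TE-in-CDS gene models, and degradome tag profiles, so every
  stage is testable offline.

## Worked example

```r
library(temir)
report <- run_pipeline(default_config(seed = 1))
print(report)
#> temir pipeline report (seed 1)
#>   n_hairpins             21
#>   n_te_mirs              18
#>   n_profiled             18
#>   n_typical              10
#>   n_hsps                 28
#>   n_initial_targets      6
#>   n_predictions          22
#>   n_mtph_hsps            13
#>   n_category1_targets    3
```

Of 21 annotated stem-loops (18 planted TE loci + 3 random decoys), exactly
the 18 TE loci are called TE-MIRs; 10 pass the typical-miRNA screen. Six
genes qualify as initial targets (the planted hypothetical-protein and
TE-free genes are correctly excluded), 13 of 28 HSPs are MTPHs, and 3
targets show a category-1 cleavage signal. The machine version of the
per-locus annotation table:

```r
head(report$tables$typical_table[, c(1:4, 8, 11)], 6)
#>        hairpin_id strand_category mean_genome_hits length_type  verdict      architecture
#> 1 MIR_MITE_typ1_1       plus_only             1.19     major24  typical single_palindrome
#> 2 MIR_MITE_typ1_2       plus_only             1.00     major24  typical single_palindrome
#> 3 MIR_MITE_typ2_1            both             1.57     major21 atypical single_palindrome
#> 4 MIR_MITE_typ2_2      plus_major             1.03     major21  typical single_palindrome
#> 5 MIR_MITE_typ2_3      plus_major             1.03     major21 atypical single_palindrome
#> 6 MIR_MITE_typ3_1       plus_only             1.00     major24  typical single_palindrome
```

Low-copy diverged MITE loci with precise excision come out typical;
high-copy young families (mean genome hits 33–41, both-strand smeared
expression) come out atypical, as do loci whose palindromic arms make
read placement strand-ambiguous. Degradome scoring per target and
dataset:

```r
report$tables$cleavage_scores
#>    gene_id dataset_id categories summary_score
#> 1   gene01       deg1          1             4
#> 2   gene06       deg1        1,3             5
#> 3   gene02       deg1          2             2
#> ...
```

Individual operations are exported and composable, e.g.

```r
pa <- pairing_score("ACGATGCATGCGTGGGTGCAT",
                    revcomp("ACGATGCATGCGTGGGTGCAT"))
pa$score      # 0  (perfect complement)
pa$mfe_ratio  # 100
summary_score(c(1, 3))  # 5
```

A thin command-line interface wraps the same functions
(`exec/temir run|simulate|homology|targets|profile|predict|degradome`);
`temir simulate` writes FASTA/GFF3/TSV inputs plus a ground-truth JSON
sidecar, and every stage reads those formats back.

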