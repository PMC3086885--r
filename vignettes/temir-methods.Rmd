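---
title: "Identifying TE-derived plant miRNA genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying TE-derived plant miRNA genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Plant genomes are littered with hairpin-forming repeats, above all MITEs
(miniature inverted-repeat transposable elements), whose transcripts fold
back on themselves and are diced into small RNAs. Those hairpin-derived
siRNAs are chemically indistinguishable from miRNAs, so an annotated miRNA
stem-loop with homology to a transposable element (a *TE-MIR*) may be a
genuine miRNA gene caught mid-domestication — or a garden-variety siRNA
locus. `temir` implements the analysis chain that separates the two and
follows the regulatory consequences:

1. **Homology screen** — stem-loops with at least one high-scoring segment
   pair (HSP) against a repeat library at E ≤ 0.005 are TE-MIRs, labelled
   by the class of the best-matching element.
2. **Small-RNA profiling** — reads are placed on each hairpin by perfect
   matching on both strands; each locus gets a strand-bias category
   (plus\_only / minus\_only / plus\_major / minus\_major / both), a mean
   genome multiplicity, and a length-distribution type (low / 21-major /
   24-major / mixed / other).
3. **Annotation screen** — a TE-MIR is a *typical* (bona fide) miRNA gene
   iff its sRNAs average ≤ 20 genome hits, come purely or predominantly
   from the plus strand, and show precise excision of a miR/miR\* duplex
   with 2-nt 3′ overhangs from the folded hairpin.
4. **Initial targets** — protein-coding genes whose CDS contains sequence
   homologous to the TE-MIR (HSPs at E ≤ 0.05; genes qualify at E ≤ 0.01;
   hypothetical proteins excluded). These arise when a cognate TE copy
   inserts into coding sequence, typically spanning a coding/non-coding
   boundary.
5. **Targeting** — plant-style complementarity scoring (mismatch 1,
   G:U 0.5, bulge 2, penalties doubled at sRNA positions 2–13) with a
   duplex-energy ratio; pairs kept at score ≤ 4 and MFE ratio ≥ 73%. An
   HSP whose gene is also a predicted target of the cognate TE-MIR's
   sRNAs is an MTPH (MIR–target-pair HSP).
6. **Degradome validation** — 5′ tags of uncapped transcripts are piled on
   each target cDNA; the tag count at the position complementary to sRNA
   nucleotide 10 is ranked against the transcript (category 1 = ties the
   maximum, 2 = above the median of expressed positions, 3 = expressed but
   at or below the median), and the per-target category set is summarized
   as a score: {1,2,3} → 7, {1,2} → 6, {1,3} → 5, {1} → 4, {2,3} → 3,
   {2} → 2, {3} → 1, none → 0.

Everything runs on synthetic data with known ground truth; no external
database is downloaded.

## Alignment statistics

`local_align()` is a full Smith–Waterman (Gotoh affine-gap) dynamic
program, not a seeded heuristic: at desk scale the exact DP is affordable
and exactly testable. Additional HSPs per pair are obtained by masking the
subject interval of the previous optimum and re-searching; masking only
the subject side lets one query region legitimately hit several copies of
a repeat. E-values follow Karlin–Altschul, `E = K·m·n·exp(−λS)`, with
`m`, `n` the raw query and database lengths (no edge-effect correction; a
null-calibration test bounds the consequence). λ and K for the default
blastn-like scheme (+1/−3, gap 5/2) come from the same published table
blastn itself ships (λ = 1.28, K = 0.46); for schemes outside the table λ
is solved exactly from the ungapped identity at uniform base composition
and K falls back to a conservative 0.35 — E-values are then slightly
conservative, which only makes the screens stricter.

## Folding model

`fold_hairpin()` maximizes weighted nested base pairs (Nussinov DP;
G:C = 3, A:U = 2, G:U = 1, minimum loop 3). Downstream code consumes only
the stem geometry — which arm a read sits on and where its pairing partner
lies — so a base-pair-maximization model suffices and can be verified
against exhaustive recursion; a `folder` hook accepts an external
thermodynamic folder where true minimum free energies matter. Because pair
maximization admits ties, the expected miR\* interval is derived from the
*median* anti-diagonal `i + partner(i)` of the duplex rather than the
extreme partner coordinates, which is robust to stray long-range pairs.

## Operationalized thresholds

The analysis criteria are qualitative in places; the package fixes them as
configurable parameters:

* **"Negligible" minority strand** — abundance fraction ≤ 0.10
  (`minor_fraction`).
* **Length-class dominance** — > 0.5 of a usable dataset's abundance
  (`major_fraction`); a dataset is usable at ≥ 10 reads (`usable_min`).
  The 21-nt-like class is lengths 20–22, the 24-nt-like class 23–24;
  dominance by anything outside 20–24 yields type "other".
* **"Much higher than weakly expressed variants"** — dominance ratio ≥ 5
  between the top read and the strongest other read overlapping it.
* **Read concentration** — miR + miR\* windows (± 4 nt padding) must hold
  ≥ 0.75 of plus-strand abundance for precise excision.
* **Dicer geometry** — 2-nt 3′ overhangs with ± 1 nt tolerance; the miR
  candidate must have ≥ 50% of its positions paired.
* **Architecture calls** — an HSP covering ≥ 60% of the whole stem span is
  a single palindromic element; two same-family, opposite-strand,
  non-overlapping HSPs each covering ≥ 60% of one arm are a juxtaposed
  inverted pair.
* **Degradome categories** — ties with the transcript maximum count as
  category 1 (uniqueness is not required); the median is taken over
  expressed positions only, so a single expressed position is its own
  maximum. The empty category set scores 0 (no-evidence, displayed as an
  absent bar). Strand-bias is judged on abundance summed across sRNA
  datasets, with per-dataset histograms retained in the profile.

The significance test for the multiplicity contrast between TE-MIRs and
canonical miRNAs is a one-sided Mann–Whitney U test
(`compare_multiplicity()`).

## The duplex energy proxy

`duplex_mfe()` sums nearest-neighbor stack energies (Turner-style
Watson–Crick values, a flat −1.2 kcal/mol for stacks involving G:U,
terminal penalties ignored) over the pairing found by the penalty DP.
Because the MFE *ratio* divides two sums over the same table, systematic
offsets largely cancel; perfect complementarity gives exactly 100%. The
site scanner anchors the sRNA 5′ end at every cDNA position and runs a
bounded-gap DP (≤ 1 bulge per strand, no terminal bulges), matching common
plant target-prediction practice while keeping runtime linear in the
transcriptome.

## What the synthetic data emulates — and what it does not

The generator (`generate_te_family()`, `plant_insertions()`,
`simulate_srna_reads()`, `simulate_degradome()`, `embed_te_in_cds()`)
reproduces the features the pipeline actually keys on:

* **TE families** as consensus + substitution-mutated copies. Hairpin
  MITEs are modelled as near-fully palindromic (TIRs covering ≥ 60% of the
  element). Background genome sequence is i.i.d. uniform A/C/G/T — no
  isochore or composition model — because homology-search specificity is
  what matters downstream.
* **Divergence defaults**: 0.10 for old, low-copy hairpin families and
  0.005 for young, high-copy ones. These were fixed a priori from two
  biological considerations: domesticated MITE loci are old enough to have
  drifted visibly from their family consensus (and from their own arm's
  reverse complement, which keeps perfect-match read placement
  strand-unambiguous), while proliferating young families are nearly
  homogeneous, which is precisely what makes their sRNAs multi-mapping.
* **Expression regimes**: `precise` concentrates a configurable share
  (default 0.65) of the dominant strand's abundance on one miR read plus a
  0.2 share on the miR\* and geometric-decaying shifted variants — the
  "one major species plus weak variants" pattern; `smeared` scatters reads
  uniformly. Strand-bias categories map to minority-strand fractions
  {0, 0.05, 0.5}. Datasets are independent resamplings sharing the truth,
  like replicate public sRNA databases.
* **Degradome tags** as a planted peak at the position opposite sRNA
  nucleotide 10 plus bounded background noise.
* **Initial targets** by embedding a cognate TE fragment — in antisense
  orientation, as TE insertion orientation is arbitrary — across a CDS
  edge (`boundary_spanning`) or inside it.

Not modelled: sequencing error, RNA-seq-style expression levels,
population genetics of TE proliferation, spliced isoform structure, and
true thermodynamic folding. Passing tests therefore demonstrate that the
*decision rules* recover planted truth under realistic geometry and
sampling noise, not that the pipeline is robust to base-calling artifacts
or to hairpins whose biology violates the generator's assumptions.

## Problem sizes and numerical choices

The default end-to-end study uses two 60/40-kb background chromosomes plus
a dedicated gene chromosome, eight TE families (five hairpin MITEs split
between low-copy/diverged and high-copy/homogeneous, one inverted-pair
retrotransposon, one background DNA element, one unclassified palindromic
element), three sRNA datasets of 600 reads per locus, two degradome
datasets, and eight gene models covering the non-TE / TE-related /
expressed-unknown annotation classes, one hypothetical protein (exercising
the exclusion rule) and one TE-free negative. Cohort-style validations use
200 independently simulated loci (screen recovery), 50 replicates per
planted category (classifier recovery), and 200 replicates of planted
sites and degradome peaks. These sizes put every recovery estimate's
binomial standard error well below the margins being asserted while the
whole suite stays desk-scale.

Determinism: every stage derives child seeds from the master seed with a
fixed affine map (kept below 2^31), so a full run is byte-identical across
reruns; generators restore the caller's RNG state. Ties in the alignment
and folding DPs break by fixed case order; the duplex caller prefers the
most-paired placement of the top read.

The "low" expression type is by definition a property of loci with fewer
than 10 reads per dataset, so its recovery is tested at depth 8 while the
other four length types are tested at depth ≥ 100.

## Known limitations

* The architecture detector reports a *single palindromic element* for an
  inverted pair of a palindromic family — one plus-strand HSP then spans
  both arms, which is indistinguishable from (and structurally equivalent
  to) a single palindrome; the truth generator therefore only plants
  inverted pairs of non-palindromic families by default.
* Iterative subject masking yields locally optimal non-overlapping HSPs
  but not the full Waterman–Eggert suboptimal-alignment set.
* Perfect-match read placement means highly diverged loci shed reads
  rather than placing them approximately, exactly as in the original
  mapping protocol (no mismatch-tolerant mode is provided).
* The interaction matrix treats alternative-splicing isoforms as
  independent cDNAs; no isoform reconciliation is attempted.
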