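---
title: "Dating de novo gene birth in giant virus genomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating de novo gene birth in giant virus genomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microevo)
```

## The scientific problem

Pandoraviruses carry the largest known viral genomes (about 2 Mb, G+C-rich),
and every newly sequenced strain brings in protein-coding genes never seen
before — the family pan-genome keeps growing while the core set of genes
shared by all strains stays small. The leading explanation is *de novo* gene
birth: intergenic DNA harbours random open reading frames ("protogenes")
whose transcription is occasionally switched on, after which the new protein
either disappears again or is retained under weak purifying selection.

`microevo` packages the comparative analyses used to interrogate that
hypothesis on a pair of near-identical strains sitting in a larger labeled
phylogeny:

1. cluster proteins across strains and compute pan/core accumulation curves
   over all genome combinations;
2. identify the genes unique to one strain of a close pair, and **date** each
   one by searching the protein against the *non-coding* regions of the
   other strains (a tblastn-style six-frame translated search) — a trace in
   a relative's intergenic DNA pushes the gene's creation node deeper into
   the tree;
3. contrast the compositional signatures of the newborn genes (CAI, G+C,
   length, amino-acid composition) with the established proteome;
4. estimate pairwise dN/dS (NG86) for ortholog pairs, stratified by
   creation node;
5. call and classify non-coding RNAs from stranded coverage;
6. detect the large structural features of these genomes: the terminal
   palindrome and TIR-flanked (hAT-type) transposons.

A forward evolution simulator generates annotated genomes along the labeled
tree with known ground truth for every stage, so each estimator is tested
against the history that produced its input.

## Coordinate and data conventions

All intervals are 0-based half-open internally; GFF3's 1-based inclusive
coordinates are converted only at I/O (`read_strain_annotation()` /
`write_strain_annotation()`). Genomes are linear. A CDS with phase > 0 is
trimmed at its coding 5' end; a CDS whose length is not a multiple of 3
after trimming is kept but flagged pseudogenized, since such decaying
genes are themselves part of the biology here.

The bundled tree (`pandoravirus_tree()`) reproduces the ten-strain topology
with internal nodes labeled 1–9 by depth (node 1 the root, node 2 the
clade-A root, node 9 the ancestor of p. celtis and p. quercus). Branch
lengths are not printed in the source material, so the bundled values are
illustrative; every analysis here consumes the labeled topology, and the
simulation experiments state their own branch-length scaling.

## The translated non-coding search

The dating step needs a protein-vs-genome search that is sensitive to
decayed, frame-broken traces but statistically controlled. The package
uses:

* exact 4-aa seeds between the query and all six frame translations;
* ungapped BLOSUM62 extension with an X-drop of 20;
* Karlin–Altschul E-values, `E = K·m·n·exp(−λS)` with the classic ungapped
  parameters λ = 0.318, K = 0.13; hits are reported at `E ≤ 1e-3`.

Ungapped extension is a deliberate choice: it keeps λ and K analytic, and
the threshold is a screening rule, not a precise statistic. A hit lying
mostly (> 50%) inside a same-strand, *in-frame* CDS is masked out — it
would simply re-find an annotated gene — while hits in intergenic DNA,
UTRs, antisense overlaps and alternative reading frames are kept, because
those are exactly the contexts in which traces of newborn genes appear.
Seed length 4, X-drop 20 and the E cutoff are all function arguments.

Creation-node assignment is most-recent-common-ancestor of the focal leaf
and every evidence leaf, where evidence combines annotated homologs and
non-coding traces (the published unique-gene table merges both kinds in one
column). Whether a single deep trace should suffice is genuinely open; an
`assign_creation_node(strict = TRUE)` variant instead requires evidence in
every descendant leaf of the assigned node, without presuming which reading
is intended.

## Protein clustering

Clustering is thresholded single linkage over global (Needleman–Wunsch)
alignments with BLOSUM62, gap open 11 / extend 1 — transparent,
deterministic, and checkable against brute-force set arithmetic, unlike a
full MCL pipeline. `pairwise_protein_identity()` reports identity as
identical columns over aligned (gap-free) columns, and coverage as aligned
columns over the shorter sequence.

One numerical subtlety drives the edge rule: for compositionally biased
proteins (these genomes are ~64% G+C, which skews the amino-acid alphabet),
global alignments of *unrelated* sequences become gap-fragmented, and
per-column identity over the surviving columns routinely reaches 30%. In a
single-linkage graph such chance edges percolate and fuse unrelated
families. The edge criterion therefore measures identity over the shorter
sequence (identity × coverage ≥ `min_identity`, plus coverage ≥
`min_coverage`): full-length normalization suppresses fragmented chance
alignments while leaving genuine homologs (whose alignments are nearly
full-length at the divergences of interest) unaffected. Defaults are 30%
identity and 50% coverage; both are arguments, and cluster membership at
these settings should be read with the usual protocol-sensitivity caveat
that applies to any clustering of this kind. One caveat specific to
synthetic data: proteins whose residues are drawn iid from a single skewed
composition have a *higher* chance-identity floor than real proteomes
(measured effective-identity ceiling ≈ 0.37 between unrelated simulated
proteins), so the simulator-truth experiments run clustering at 0.40, above
that floor; the default remains the standard 0.30 for real sequences.

Pan/core accumulation enumerates all strain combinations exhaustively up to
12 genomes (beyond that an explicit seeded sampling mode must be chosen).
The per-genome pan increment is the mean pan size at G genomes minus the
mean over all (G−1)-subsets.

## dN/dS estimation

`dnds_pair()` implements Nei–Gojobori (1986) pathway counting with
Jukes–Cantor correction. Site counting gives each codon position one site,
split into synonymous and nonsynonymous fractions over its non-stop
single-nucleotide neighbours, so S + N sites always equal 3 per codon.
Difference counting averages over all shortest mutational pathways between
two codons, excluding pathways through stops and re-weighting the rest
equally. A transition-weighted site-counting variant (in the spirit of
Yang–Nielsen 2000) is available through the `kappa` argument; the default
is the classic estimator, chosen because it is analytic and can be checked
exhaustively against an enumeration oracle over all 61 × 61 codon pairs
(the test suite does exactly that).

The published filters are applied verbatim: an estimate counts only if
dN > 0, dS > 0, dS ≤ 2 and dN/dS ≤ 10. A proportion p ≥ 3/4 leaves the
Jukes–Cantor distance undefined and fails the filters. Codon alignments
come from protein-guided global alignment with gapped columns removed.
Node stratification assigns each ortholog pair to the MRCA of the strains
carrying its cluster, independent of the trace-based dating used for the
unique-gene table.

## Compositional signatures

CAI follows Sharp & Li: relative adaptiveness `w` is each codon's count
over the maximum in its synonymous family (computed from a reference gene
set; zero counts floored at 0.01 so the geometric mean stays defined), and
a gene's CAI is the geometric mean of `w` over its codons, dropping the
terminal stop and including Met/Trp neutrally at w = 1. The natural
reference set is the focal strain's core-cluster genes; the reference is an
explicit argument because the choice is a protocol decision, not a given.

The amino-acid composition test pools residue counts over each set
(matching df = 19 for 20 categories), takes expected counts from the
background frequencies scaled to the novel set's total, and uses the
Pearson statistic; a residue absent from the background receives a 0.5
pseudocount in both sets. The CAI/G+C/length contrasts use two-sided
Wilcoxon rank-sum tests with the normal approximation and tie correction —
appropriate at the 30-vs-1000 set sizes this analysis meets, where the
exact test buys nothing.

## ncRNA calling

One expression floor is used throughout: median coverage strictly greater
than 5, the same rule that validates protein-coding transcripts (a median
of exactly 5 fails). ncRNA calls are maximal same-strand runs of per-base
coverage above the floor that do not touch a same-strand CDS; runs shorter
than 200 nt are dropped. A call is *antisense* iff opposite-strand CDS
overlap exceeds half its length — strictly, so an exactly-half overlap is
intergenic. Cross-strain ncRNA homology (reciprocal best local nucleotide
alignment at ≥ 80% identity and ≥ 50% coverage) has no published
thresholds; the defaults are documented assumptions, and a position-based
pairing mode is provided as an alternative.

## Structural features

The dotplot is exact-word based (default word 15, both orientations, words
merged along diagonals into maximal collinear segments) — sufficient to
expose collinearity breaks, inversions and repeats at these genome sizes
without a scoring scheme. The terminal palindrome finder evaluates every
candidate half-length in one pass via an FFT cross-correlation of
nucleotide indicator vectors (a prefix palindrome of length 2k pairs
positions summing to 2k+1), so the longest prefix whose first half matches
the reverse complement of its second half within a 5% mismatch budget is
found exactly, with no grid approximation.

TIR candidates are intervals whose terminal repeats are reverse
complements: discovery requires an exact inverted core of `tir_min` bp
(default 15, in the short-TIR range typical of hAT elements), after which
the repeat is extended inward while the mismatch budget (default 2) holds;
overlapping candidates resolve to the longest TIR, then leftmost. Because
discovery is exact-core-based, a TIR whose first `tir_min` bases already
contain mismatches is not discoverable — a stated sensitivity limit, traded
for a scan that runs on a desk machine. Every reported candidate is
re-verifiable with `verify_tir_candidates()`.

## The simulator and what passing tests mean

`simulate_family()` evolves a root genome of alternating CDS and intergenic
segments down the labeled tree. Coding segments follow a symmetric
Goldman–Yang-style codon model (single-nucleotide changes, transitions
weighted by kappa = 2, nonsynonymous changes by the gene's omega, no paths
through stops, one unit of branch length = one expected substitution per
nucleotide site). The source material fits no such model; it is purely a
generator whose regimes the model-agnostic NG86 estimator must recover.
Intergenic DNA drifts under Jukes–Cantor plus indels (geometric lengths,
p = 0.5, capped at 10 nt, rate 0.02 events/site per unit branch length —
enough churn to degrade deep traces, which is what makes trace decay with
node depth reproducible). Gene births insert protogene-derived ORFs
(intergenic composition, G+C calibrated by root-finding so the realized
stop-free codon distribution hits the target fraction) at random intergenic
positions; deaths demote a CDS to drifting non-coding DNA rather than
deleting it, so the "traces of dead genes in non-coding regions" experiment
has something to find. Per-branch RNG substreams derive from the master
seed, so adding a leaf does not perturb other branches' draws.

Defaults encode the observed compositions (coding G+C 0.644, intergenic
0.575) and plausible-but-illustrative rates: no birth/death rates are
published, so `birth_rate = 1` per branch and `death_rate = 0.05` per gene
per branch are documented choices, not inferences. Ancestral protein
lengths are log-normal around ~330 aa and newborn lengths around ~120 aa,
matching the magnitudes of the real background and novel-gene length
distributions. ncRNA loci get independent per-leaf on/off states
(`ncrna_on_prob = 0.5`), mimicking fast-fluctuating transcription of
non-coding sequence.

What the simulator does **not** emulate: read-level sequencing noise,
recombination, transposition dynamics (transposons are planted, not
mobilized), codon-usage heterogeneity along the genome, and selection on
non-coding DNA. Passing recovery tests therefore demonstrates internal
consistency of the estimators under the stated generative assumptions —
they do not certify performance on real sequencing data, where alignment
error and annotation noise add failure modes the simulation cannot expose.

## Study conditions used by the tests and acceptance script

Problem sizes were fixed in advance to keep each experiment's Monte-Carlo
error well inside its acceptance band: dN/dS recovery uses 3000 aligned
codons per replicate (symmetric branches of 0.15 substitutions/site) with
20 replicates per omega in the test suite and 10 in the acceptance script;
trace-dating recovery simulates families on the bundled tree with branch
lengths scaled by 0.25 (protein traces ~70–90% identical, the
"microevolution range"), 6 ancestral genes, birth rate 0.6 and death rate
0.1 per branch, 20 replicates in tests and 8 in the acceptance script; the
chi-square null calibration uses 3800 novel residues against a 100,000
residue reference pool. The exhaustive NG86 oracle covers all 61 × 61
codon pairs; the accumulation oracle covers up to 5 genomes.

## Known limitations

* The translated search is ungapped; a heavily indel-riddled trace
  fragments into several hits, and sensitivity at deep divergence is lower
  than gapped tblastn.
* Karlin–Altschul parameters are the ungapped BLOSUM62 defaults, not
  composition-adjusted; E-values on strongly biased sequences are
  approximate (the calibration test bounds the practical effect).
* Single-linkage clustering inherits the usual transitivity artifacts;
  the core/pan counts depend on thresholds, as the protocol-sensitivity
  spread in published core-genome estimates illustrates.
* The dotplot reports exact word matches only; diverged repeats below the
  word length are invisible.
* UTR-dependent hit contexts require UTR features in the annotation; when
  absent, such hits classify as intergenic or ncRNA overlap instead.
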