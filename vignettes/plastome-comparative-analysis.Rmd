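---
title: "Comparative plastome analysis with plastidkit: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plastome analysis with plastidkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastidkit)
```

## Scope

`plastidkit` implements the analysis chain used in comparative chloroplast
genomics to turn a set of closely related plastomes into candidate molecular
markers: quadripartite structure and IR-junction comparison, microsatellite
(SSR) and large-repeat surveys, alignment divergence statistics, sliding-window
hotspot discovery, and a light phylogeny stage. Assembly, annotation and
multiple sequence alignment are upstream of the package: genomes arrive as
FASTA, annotations as GFF3 (or a flat feature table), and the whole-genome MSA
as aligned FASTA. Everything downstream of those files is computed here, and a
seeded simulator generates complete toy datasets with known truth so that every
stage can be verified without real data.

## Quadripartite detection and canonical orientation

A plastome is circular with structure LSC + IRa + SSC + IRb, where IRa is the
reverse complement of IRb. The package defines the IR operationally as the
longest pair of disjoint maximal exact inverted repeats of at least
`min_ir_len` (default 1000 bp) on the circular sequence; maximal means
extension in either direction meets a mismatch. This matches how published IR
lengths are conventionally reported and makes region lengths reproducible from
sequence alone. Circularity is handled by searching the doubled sequence and
reducing coordinates modulo the genome length. Search is seed-and-extend: exact
20-mers shared between the doubled genome and its reverse complement identify
candidate diagonals, which are extended to maximal exact runs.

The genome is then rotated so LSC (the longer single-copy arc) starts at
base 1, in order LSC, IRa, SSC, IRb. Strand is chosen so that the majority of
LSC CDS bases sit on the forward strand when an annotation is available;
without one, the orientation with the lexicographically smaller LSC sequence is
used, which is arbitrary but deterministic. Ties between equal-length candidate
IR pairs are broken by preferring the pair that best separates a long and a
short single-copy arc, then by lowest start; a residual tie is an error rather
than a silent choice.

Junction analysis reports, for each of the four region boundaries, every gene
whose span crosses it with the bp falling on each side, pairwise overlaps
between crossing genes, and — for junctions inside intergenic spacers — the
flanking genes and gap lengths. Gap lengths are reported rather than
interpreted, since conventions for counting "noncoding bases at the border"
differ between publications.

## SSR scanning

Perfect SSRs only, with the MISA-style unit-count minima: 10 units for
mononucleotides, 5 for dinucleotides, 4 for trinucleotides, 3 for tetra-,
penta- and hexanucleotides. A hit is a maximal perfect tandem run of a
primitive motif (minimal period equals motif length; `ATATATATAT` is (AT)5,
never (ATAT)2), truncated to whole units, reported at the leftmost phase of its
run. Adjacent runs at the same period can overlap by up to period−1 bases; the
scanner consumes left to right so reported hits never overlap at the same
period, mirroring how a left-to-right regex scan behaves. Compound or
interrupted SSRs are not merged — reported tract lengths of 10–24 bp in
published plastome surveys are consistent with perfect tracts.

Context is assigned as CDS if a tract overlaps a CDS exon by at least 1 bp,
intron if it lies between exons of an annotated gene, else IGS; tRNA/rRNA
bodies count as IGS, since genic-but-non-CDS context is not separable in
typical plastome tables. SSRs inside the IRs are counted once per occurrence
(both copies), and a tract crossing a region border is labelled
junction-spanning. Cross-species loci are formed by projecting each species'
hits onto alignment columns through that species' gap map and single-linkage
merging of overlapping column intervals; a locus is polymorphic when at least
two species differ in motif, unit count, or presence.

## Large repeats at bounded Hamming distance

Four match types are surveyed: forward (direct copy), reverse, complement, and
palindromic (reverse complement), with copy length at least 30 bp and Hamming
distance at most 3 (at least 90% identity) by default — REPuter-style settings.
A hit is a *maximal pair*: extending either end would exceed the mismatch
budget or leave the sequence. Detection is seed-and-extend with exact seeds of
length `floor(min_len / (k + 1))`; by pigeonhole every qualifying window
carries an exact seed on its comparison diagonal, so the enumeration is
complete. The genome's own IRa/IRb pair would dominate any survey as one giant
palindromic hit, so hits whose copies are the annotated IR pair (or mirrored
positions inside it) are excluded from summaries by default; published
per-genome repeat counts are clearly post-IR-exclusion. Counts are of pairs,
not copies. Hits with equal type, length and region combination collapse into
repeat loci, and length histograms use bins 30–39, 40–49, 50–59 and ≥ 60 bp.

One property worth noting: the number of maximal pairs is *not* monotone in
the mismatch budget — two maximal hits separated by a single mismatch merge
into one longer hit at the next budget. What does hold, and what the tests
assert, is containment: every hit at budget *k* extends to a hit at *k*+1.

## Divergence statistics

Site classification uses the standard definitions: a column is excluded if any
row carries a gap or N (ambiguity codes other than N are treated as N),
variable with two or more observed bases, parsimony-informative when at least
two bases each occur in at least two rows. Nucleotide diversity is Nei's π,
the mean pairwise proportion of differing sites, computed under complete
deletion (the DnaSP default); pairwise p-distances and difference counts use
pairwise deletion (the MEGA default). Using the two tools' native deletion
modes in their respective statistics reproduces the conventions of published
tables; both site counts (raw columns and analyzed sites) are reported because
"number of sites" in alignment tables can exceed genome length when gapped
columns are included. Note that π over distinct unordered pairs is not
invariant under duplicating every row — the duplicate pairs contribute zero
distance but enter the C(n,2) denominator, rescaling π by 2(n−1)/(2n−1); the
test suite asserts this exact relationship rather than a naive invariance.

Region-wise tables project the reference genome's partition through its
alignment row; gap columns interior to a region belong to that region. The IR
row uses the IRa span, matching the convention of reporting one IR copy.

## Hotspot discovery

Windows of 600 columns advance in steps of 200 over the alignment (truncated
final windows are included and flagged), with per-window S (polymorphic sites)
and π. The selection threshold is `mean(S) + k_sd * sd(S)` with `k_sd = 2`;
windows with S strictly above threshold are selected and overlapping or
exactly abutting windows merge into regions. The standard deviation is the
population form (divide by n) — the natural choice for a descriptive scan over
a fixed window list — and is switchable to the sample form. The threshold is
applied to S, following the rule as stated for polymorphic sites, although π
profiles are emitted alongside for plotting. Merged regions are reported at
merged-window extents; published marker tables often trim boundaries further,
so lengths here can exceed printed lengths for the same markers. Regions are
named from the reference annotation: the containing gene (with a/b suffixes
when one gene yields several disjoint regions, as happens for large genes like
ycf1), or flanking and overlapped genes joined with hyphens for intergenic
spans.

## Phylogeny stage

The phylogeny stage is deliberately desk-scale: neighbor joining on the
p-distance matrix (via ape, with taxa ordered by label for determinism), Fitch
parsimony scores of fixed topologies, and Robinson–Foulds comparisons (via
phangorn). It exists to verify topology recovery claims — exactly on synthetic
data, qualitatively on real data — not to replace full ML/MP/Bayesian
inference, which is out of scope along with bootstrap support and model
selection.

## The simulator: what it emulates and what it does not

`sim_config()` defaults define the study conditions: a 20 kb toy plastome
(LSC 11 kb, IR 3.5 kb, SSC 2 kb — about a 7.5-fold scale-down of a real
150 kb plastome, keeping the LSC > IR > SSC proportions), ~63% A+T as observed
across Liliaceae plastomes, a gene layout reproducing the qualitative junction
biology (a gene crossing LSC/IRa, two genes overlapping across IRa/SSC by
25 bp, a large gene crossing SSC/IRb), one planted SSR per motif period 1–5
plus an intronic and an IR-resident one, one planted repeat of each type at
≥ 30 bp with controlled mismatches, eight taxa on a balanced two-clade tree
with 0.01 expected substitutions/site per branch, and three 800 bp hotspot
intervals at 10× the background rate in the single-copy regions. Flanking
bases around every planted element are adjusted so the element is exactly
maximal at its recorded extent — the planted truth then *is* the detector's
correct answer, not merely contained in it.

Evolution is substitution-only Jukes–Cantor: along a branch of length *t* a
site changes to each other base with probability (1 − e^(−4tm/3))/4, where
*m* is the site's rate multiplier (hotspot multiplier, IR damping 0.2, or 1).
Branch lengths are therefore in expected substitutions per site and compose
multiplicatively along paths, giving the closed-form two-taxon expectation
E[p] = 0.75(1 − e^(−4T/3)) used as a calibration check. Mutations are applied
to LSC, IRa and SSC, and IRb is rewritten as the reverse complement of IRa, so
the IR copies evolve in concert and stay exact mirror images — emulating the
strong IR conservation of real plastomes. Because no indels are generated, the
identity alignment is the true alignment, which is what lets the divergence
and hotspot stages be verified without an external aligner (an MSA of the
species sequences is trivially themselves).

What the simulator does not emulate — and what passing tests therefore do not
establish about real data: indels and alignment error, rate heterogeneity
beyond the two multipliers, base-compositional drift, gene content variation,
IR expansion/contraction between species (boundaries can shift by a base or
two through chance re-pairing at junctions, but not by design), recombination,
and imperfect/compound SSRs. Results on real plastomes additionally depend on
the upstream aligner's behaviour in repeat-rich spacers.

## Numerical and design choices

* Internal coordinates are 0-based half-open; all report output is 1-based
  inclusive. BED output stays 0-based per the format.
* The alignment gap character is `-` only; `.` is rejected rather than
  silently translated.
* Gene symbols are matched case-sensitively (ycf1, ndhF, rps19, trnH, psbA).
* Degenerate inputs fail loudly: all-N sequences for A+T content, alignments
  with no analyzable column, species pairs with no comparable site, a single
  window (sd undefined), fewer than 3 taxa for NJ (the pipeline skips the tree
  stage with a log note in that case).
* Determinism: the analysis pipeline contains no randomness; the simulator
  consumes one integer seed, and the same seed yields a bit-identical bundle.

## Problem sizes used in the tests

The test suite verifies the scanners against exhaustive oracles at sizes where
the oracles are exact and fast in interpreted R: SSRs on seeded sequences up
to 5 kb against a regex-enumeration oracle; repeats on ~250 bp sequences
against an all-window oracle for every type and every budget 0–3; partition
recovery on 500 seeded toy plastomes of 4–6 kb; Fitch against explicit state
enumeration up to 6 taxa; hotspot recovery over 100 seeded replicates of the
default 20 kb, 8-taxon study. The package itself has no such limits; the
pipeline runs comfortably on real-sized (150 kb) plastomes.
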