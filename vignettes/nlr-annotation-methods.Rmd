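---
title: "Methods: motif-grammar NLR annotation and comparative screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif-grammar NLR annotation and comparative screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resistance-gene enrichment sequencing (RenSeq) with long reads yields a few
thousand contigs enriched for nucleotide-binding leucine-rich-repeat (NLR)
immune receptor genes from species that lack a reference genome. Turning that
assembly into a usable NLR catalog takes a chain of small, well-defined
decisions: which contigs are redundant copies of each other, where each NLR
locus starts and ends, whether it is complete or a pseudogene, which Type
(I-V) its protein belongs to, where it sits on the species' chromosomes, and
how its integrated domains compare across relatives. `nlrkit` implements that
chain as composable tibble-in/tibble-out verbs plus one orchestrating
pipeline, and ships a synthetic-data generator so every stage is testable
against planted ground truth.

## Locus model and completeness rule

NLR genes are recognised through an ordered chain of conserved amino-acid
motifs: coiled-coil (CC) motifs, then the NB-ARC block beginning with the
Walker-A P-loop, then leucine-rich-repeat (LRR) motifs. The scanner
(`scan_motifs()`) translates every contig in all six reading frames and
reports each window whose identity to a motif consensus reaches that motif's
score threshold (default 0.8 as a fraction of identical residues). Scanning
is case-insensitive, so soft-masked sequence is handled without coordinate
changes, and strand-symmetric.

`chain_loci()` groups same-strand hits walked 5'→3' into loci. A chain breaks
when the gap to the next hit exceeds `max_gap_bp` (default 3000 bp, the same
scale as the flank used for protein prediction), or when a fresh P-loop hit
arrives after the chain already holds an LRR hit. The second rule is what
separates tandem NLRs closer than the chaining gap: a canonical chain never
revisits the P-loop after entering its LRR block, so a new P-loop marks a new
gene. This is the minimal border grammar consistent with the observation that
NLR annotation must split adjacent genes on long contigs.

A locus is **complete** iff its chain carries the P-loop motif, the NB-ARC
start motif, and at least one LRR motif; otherwise partial. Orthogonally it
is a **pseudogene** when the chain span contains an in-frame stop codon (in
the modal reading frame of its hits) or when same-strand hits disagree in
frame (the footprint of a frameshift). Both signals are restricted to the
motif span because nothing finer is defendable from first principles: outside
the span we cannot distinguish a stop codon from intergenic background.

## Protein prediction

`predict_protein()` extends each locus by `flank` bp (default 3000, clipped
at contig ends), collects open reading frames on the locus strand that
overlap the locus, and lets the homolog database arbitrate: the homolog with
the highest semi-global identity (ties broken by longer homolog coverage)
selects the reading, and the start codon nearest the homolog's aligned start
is chosen. A single GT..AG intron is recovered when the homolog alignment
shows a contiguous inserted block: donor and acceptor candidates near the
block boundaries are enumerated (codon-preserving splices only) and the
splice maximising identity is kept. This deliberately replaces a full
ab-initio gene finder: with a close homolog available the homology-guided ORF
is exact, and loci without a credible homolog (identity below 40%) are
flagged `unpredicted` rather than guessed at. One intron is the model's
ceiling; multi-intron genes are out of scope.

## Domain classification

Two annotation sources (an R-gene domain pipeline for CC/NB-ARC/integrated
domains; a superfamily scan for LRRs) are merged by `merge_domain_sources()`:
rows above the e-value ceiling (default 1e-3) are dropped and same-name
overlapping intervals are unioned. Classification then follows a fixed
grammar: no NB-ARC — not an NLR; any domain outside the canonical set
{CC, NB-ARC, LRR} — NLR-ID (Type V); otherwise CC/LRR presence selects CNL,
NL, CN or N. The canonical set is a name whitelist with a configurable alias
map because the two scanners use different vocabularies and no published
mapping exists; the alias map is the explicit, inspectable version of that
judgement call. Integrated domains are assigned to the N or C terminal by
their position relative to the merged NB-ARC span, `ambiguous` when they
overlap it. Summary percentages round half-up to one decimal, the convention
of printed class tables.

For synthetic runs the motif scanner doubles as a coarse domain caller
(`domains_from_motifs()`): spans of CC/NB/LRR motif matches become the three
canonical domains and each ID motif becomes an atypical domain. On real data
one would substitute genuine scanner output; the module surface is the same.

## Phylogeny

Trees are built on the extracted NB-ARC domain, the only region alignable
across the whole catalog. Distances are p-distances from global pairwise
alignments (mismatches over aligned non-gap columns); the implementation
deliberately avoids requiring a multiple alignment, and an externally
aligned profile can be supplied through the same functions. The
neighbor-joining implementation is the classical Saitou-Nei agglomeration
with two explicit numerical policies: exact Q-ties are broken by the
lexicographically smallest pair of subtree labels, making results fully
deterministic, and negative branch-length estimates are clamped to zero with
a `"clamped"` attribute rather than silently. On additive matrices the tree
reproduces input distances exactly (the test suite checks to 1e-9 and against
an independently coded textbook oracle as well as `ape::nj`).

Bootstrap support resamples columns of the profile implied by aligning every
sequence to the longest one; support is the percentage of replicate trees
containing each internal bipartition. The anchor-profile is an approximation
to a full MSA — insertions relative to the anchor are dropped — which is
accurate when the sequences are homologous over most of their length, as
NB-ARC domains are. 1000 replicates is the conventional published setting
and the package default; desk-scale demonstrations in the test suite use
50-300 replicates, which the binomial error of a support value (at most
±1.6 points at 1000 replicates, ±5 at 100) makes a measured choice, not a
compromise of correctness.

## De-redundancy and rescue

Capture assemblies contain near-identical contigs from alleles, recent
duplications and assembly redundancy. `remove_redundant()` is a greedy
longest-first clusterer in the cd-hit mould: identity is semi-global
(end-gap-free) alignment identity, because capture contigs differ mainly by
end truncation, and a contig whose identity to a retained representative
exceeds the threshold (default 95%) is removed. A k-mer containment
prefilter decides which pairs are aligned at all; on random-background
synthetic data unrelated contigs share essentially no 12-mers, so the filter
prunes work without changing decisions.

Removal can discard genuine loci, so `rescue_removed()` re-annotates every
removed contig: contigs with no complete NLR stay dropped; a complete NLR
more than 99% identical to an already-annotated one is a true duplicate and
stays dropped; complete NLRs at 95-99% identity are rescued into the catalog.
Note that random near-duplicate mutation usually pseudogenises the copy (a
3% substitution rate expects several chain-span stop codons), so rescues are
rare on default synthetic data; the rescue rules are exercised with crafted
fixtures whose mutations avoid stops.

## Chromosome assignment and the screens

In-silico location takes, per query and reference genome, the best hit
(bitscore, then identity, then lexicographically smallest chromosome) and
assigns the majority chromosome number across genomes; `Un` chromosomes do
not vote and ties stay unassigned. The majority rule is the combination that
reproduces every row of the published physical-location worked example where
a majority exists. `congruence_report()` tabulates in-silico groups per
physical translocation-line arm and flags arms whose modal group differs
from the arm's own number — the signature by which the ancestral 4L/7S
translocation discordance (4VL markers hitting group 7) surfaces.

The orthologue screen keeps NLRs strictly above 80% identity and 60%
coverage against a cloned R gene and on the query's homoeologous group; the
expression screen keeps NLRs with a transcript strictly above 95% identity
and 90% CDS coverage. Both are monotone in their thresholds by construction.
Splice patterns are compared on junction offset lists (alignment gaps of at
least 30 bp against the unspliced gene), with a 3 bp tolerance for alignment
jitter at repeated bases — robust to sequencing error inside exons, which a
raw alignment comparison is not. Private indels (the basis of
presence/absence PCR markers) must appear with the same type and length at
the same query position against *every* orthologue.

## The synthetic generator: what it emulates and what it does not

`generate_contig_set()` plants motif-grammar loci in i.i.d. background
sequence at 45% GC — a neutral background chosen so that motif false
positives are measurable and essentially zero. Defaults mirror the published
survey's composition: 19% partial loci, 27% pseudogenes (half premature-TAA,
half 1-bp frameshift, both placed in a linker mid-chain), 6.7%
integrated-domain fusions, 11% tandem-pair contigs, 3.5% near-duplicate
contigs at 97% identity, 12% of complete loci transcribed with a 0.002
per-base error rate, and a 0.9 probability that a 4VL locus reroutes to
group 7 in the hit table ("largely discordant"). Motifs are planted as exact
substrings; detection difficulty comes only from configured mutations, so
ground truth stays unambiguous. Introns are single, codon-length and
stop-free in the reading frame — that keeps the pseudogene evidence
(in-frame stop / frame inconsistency) an exact statement rather than a
heuristic. Partial loci drop the LRR block (CC-NB, class CN) or both head
and LRR (class N); dropping only the head would leave a locus that still
satisfies the completeness rule, which is why that variant does not exist.

What the generator does **not** emulate: read-level error profiles and
capture bias (loci appear exactly once unless duplicated), repeat families
beyond low-complexity runs, multi-intron structure, UTRs, and real motif
degeneracy (consensus matching with a mismatch budget stands in for PSSM
scoring). Passing the recovery tests therefore demonstrates that the
algorithms are correct on data satisfying the model's assumptions — not that
the motif library itself is sensitive on diverged real NLRs, which is a
property of the (pluggable) motif definitions, not of this code.

One numerical subtlety: a motif library and a contig set built from the same
user seed must not replay the same RNG stream, or a linker could reproduce an
ID consensus verbatim and plant a phantom integrated domain. The library
generator therefore scrambles its seed before drawing.

## Problem sizes and determinism

The packaged demonstrations run at desk scale, chosen once: recovery checks
use 200 planted loci (seed 42) in ~250 contigs, where locus recovery is
exact (precision = recall = 1.0 and label agreement 1.0); the end-to-end
determinism check runs 50 loci with 100 bootstrap replicates twice and
compares reports byte for byte. Every stochastic step draws from an
explicitly passed seed through `withr::with_seed()`, so a config fully
determines all outputs, including file bytes.

## Known limitations

* Completeness labels depend on the motif library's flags; a library without
  a meaningful P-loop/NB-start distinction degrades the rule.
* The anchor-profile bootstrap underestimates alignment uncertainty relative
  to resampling a true MSA.
* The intron model (single, codon-preserving) is a floor, not a ceiling, of
  real gene structure; multi-exon genes will be predicted as their largest
  homolog-consistent single-splice form.
* TIR-class NLRs are out of scope (the target flora is monocot); proteins are
  classified CNL even where a TIR-like motif is present.
* `remove_redundant()` does not detect reverse-complement redundancy; capture
  assemblies are normally strand-consistent per contig cluster.
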