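# nlrkit

Annotation and comparative analysis of NLR resistance-gene repertoires from
long-read enrichment-sequencing (SMRT-RenSeq) assemblies.

Plant genomes defend themselves with nucleotide-binding leucine-rich-repeat
(NLR) immune receptors. RenSeq captures and sequences the NLR complement of a
species without a reference genome, yielding a few thousand contigs that
must then be turned into a gene catalog. `nlrkit` is for researchers doing
exactly that — typically on wild crop relatives mined for disease-resistance
genes — and implements the full post-assembly chain as composable, tested R
functions:

* **Contig preparation** — greedy longest-first de-redundancy at a percent
  identity cutoff (default 95%), rescue rules for removed contigs that carry
  genuine loci, DUST-style low-complexity soft-masking.
* **Locus annotation** — six-frame scanning for an ordered library of
  CC/NB/LRR amino-acid motifs, chaining of hits into loci with a
  border-split before a fresh P-loop, completeness and pseudogene calls.
* **Protein prediction** — homology-guided ORF selection over a ±3000 bp
  extension with recovery of a single GT..AG intron.
* **Domain classification** — merge of two domain-annotation sources
  (e-value ≤ 1e-3), the NB-ARC gate, Type I–V classes, integrated-domain
  (NLR-ID) detection with N/C terminal assignment, linked-pair detection.
* **Phylogeny** — NB-ARC extraction, alignment p-distances, an explicit
  deterministic neighbor-joining implementation, column-resampling bootstrap.
* **Location & screens** — homoeologous-group assignment by per-genome best
  hit and majority vote, congruence with physical translocation-line data,
  orthologue (>80% id / >60% cov) and expression (>95% id / >90% cov)
  screens, private-indel marker candidates, cross-species integrated-domain
  comparison.
* **Synthetic data** — a generator that plants motif-grammar NLR loci
  (complete / partial / pseudogene, tandem clusters, NLR-ID fusions,
  near-duplicate contigs, homoeology-discordant hit tables, noisy
  transcripts) with known ground truth, so the whole pipeline is testable
  offline.

The core annotation rule: a locus is *complete* iff its motif chain contains
the Walker-A P-loop, the NB-ARC start motif, and ≥1 LRR motif; it is a
*pseudogene* iff an in-frame stop codon or a frame inconsistency occurs
within the motif span. Classes follow domain composition: CNL (CC–NB–LRR),
NL, CN, N, and NLR-ID for any protein carrying a domain outside
{CC, NB-ARC, LRR}.

## Worked example

Simulate a 50-locus RenSeq assembly and run the full pipeline (bootstrap
reduced to 100 replicates for a desk-scale run):

```r
library(nlrkit)

cfg <- pipeline_config(seed = 42, bootstrap = 100,
                       synthetic = synthetic_config(seed = 42, n_loci = 50,
                                                    n_contigs = 60))
run <- run_nlr_pipeline(cfg)
print(run)
#> <nlr_run>
#> # A tibble: 9 × 4
#>   stage       n_in n_out detail
#>   <chr>      <int> <int> <chr>
#> 1 simulate      50    63 "seed=42"
#> 2 dedup         63    60 "identity=95"
#> 3 annotate      60    50 "max_gap_bp=3000"
#> 4 rescue         3     0 ""
#> 5 predict       31    31 "flank=3000"
#> 6 classify      31    31 ""
#> 7 tree          31    31 "bootstrap=100"
#> 8 locate        50    50 ""
#> 9 expression     6     6 ""
```

Reading the manifest: 50 planted loci produced 63 contigs (tandem pairs
share a contig; 3 near-duplicates were added on top of the 60 requested);
dedup removed exactly the 3 near-duplicates; all 50 loci were re-found; the
31 complete, non-pseudogene loci got exact protein predictions, NB-ARC trees
and class calls; 6 loci had a transcript passing the expression screen.

```r
glance(run)
#> # A tibble: 1 × 8
#>   n_contigs n_retained n_rescued n_loci n_complete n_nlr n_nlr_id n_expressed
#> 1        63         60         0     50         31    31        3           6

run$class_summary
#> # A tibble: 6 × 3
#>   nlr_class     n   pct
#> 1 CNL          28  90.3
#> 2 NL            0   0
#> 3 CN            0   0
#> 4 N             0   0
#> 5 NLR-ID        3   9.7
#> 6 Total        31 100
```

`tidy(run)` gives one row per locus (coordinates, completeness, class,
homolog metrics, expression), `autoplot(run$class_summary)` the class bar
chart, and `render_reports(run, "out/")` the full set of TSV/GFF3/Newick
reports. Published-style worked-example tables (chromosome locations with
translocation-line arms, R-gene orthologue screens, cross-species
integrated-domain membership) ship under `inst/extdata/` and load with
`read_location_table()`, `read_orthologue_table()` and
`read_id_membership()`.

A thin command-line front end (`inst/scripts/nlrkit.R`) exposes the stages
as subcommands (`simulate`, `dedup`, `annotate`, `classify`, `tree`,
`locate`, `screen`, `compare-ids`, `run`) for shell use.

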