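# clipsplice

An R package for identifying the **direct targets of an RNA-binding
splicing regulator** by integrating three genome-wide measurements:

1. **iCLIP** — where does the protein bind? Barcoded iCLIP reads are
   deduplicated, crosslink sites are called at single-nucleotide resolution
   under the truncation model, each site receives a permutation-based
   positional FDR, and significant sites are merged into binding clusters
   scored by motif enrichment.
2. **Knockdown RNA-seq** — which cassette exons respond when the regulator
   is depleted? PSI is estimated from junction evidence and differential
   splicing is tested between control and knockdown.
3. **Differentiation RNA-seq** — which of those exons actually change
   during the developmental transition of interest?

An exon that is knockdown-responsive, changes during differentiation, and
carries a binding cluster within the exon or its 500-nt intronic flanks is
called a **direct target**. Downstream expression consequences are assessed
with Welch's t-test on FPKM tables and hypergeometric enrichment of
ChIP-bound genes among induced transcripts.

Because the real experiments need deep sequencing, the package ships a
**synthetic-data module** that generates a genome, annotation, truncation-
model iCLIP reads (with PCR duplicates and random barcodes), junction
counts, FPKM tables, and ChIP clusters with a known ground-truth manifest —
so the entire pipeline runs, and is tested, end to end with no downloads.

## The statistics in brief

* **Crosslink sites.** A plus-strand read starting at genomic position *s*
  marks a crosslink at *s − 1* (the nucleotide transcript-upstream of the
  read start); heights count unique molecules after barcode deduplication.
* **Positional FDR.** Within a gene with *T* crosslink events, positions
  are compared against `n_perm` uniform placements of *T* events over the
  gene span: FDR(*h*) = E[permuted #positions with height ≥ *h*] /
  observed #positions with height ≥ *h*, capped at 1 and made monotone.
  Sites with FDR < 0.01 are significant; sites extended ±20 nt and merged
  form clusters, kept when they carry ≥ 4 significant reads.
* **Motif enrichment.** Pentamer counts in ±30-nt windows around intronic
  sites versus width-matched random intervals from the same introns:
  *z* = (observed − null mean) / null sd, for all 1024 pentamers.
* **PSI.** With inclusion junctions *I1*, *I2* and exclusion *E*,
  *m* = (*I1* + *I2*)/2 and PSI = 100·*m*/(*m* + *E*). ΔPSI is tested with
  a two-sided Fisher exact test on pooled counts; events pass at
  *p* < 0.05 and |ΔPSI| ≥ 15.
* **Enrichment.** Upper-tail hypergeometric probability of *k* marked
  genes in a sample of *n* from *N* genes of which *K* are marked.

## Worked example

```r
library(clipsplice)

cfg <- simulation_config()     # study-scale defaults, seed = 1
res <- run_pipeline(cfg)
res
#> <clip_pipeline>
#>   reads: 26861 (13580 unique molecules)
#>   crosslink sites: 12110 (50 significant at FDR < 0.01)
#>   clusters: 50 (50 with >= 4 significant reads)
#>   top pentamer: TCTCT (z = 41.9)
#>   knockdown-responsive events: 70; differentiation-changed: 100
#>   direct targets: 40 (25 repressed, 15 activated)
#>   ChIP enrichment in induced genes: p = 1.45e-05

evaluate_recovery(res)
#> # A tibble: 1 × 5
#>   n_true n_called n_correct sensitivity precision
#>    <int>    <int>     <int>       <dbl>     <dbl>
#> 1     40       40        40           1         1
```

The simulation plants 50 binding sites (each a CU-rich pentamer written
into the sense sequence of the upstream intron flank), of which 40 sit in
events that are also knockdown-responsive and differentiation-changed —
the planted direct targets. The run above calls exactly those 40, splits
them into the planted 25 repressed / 15 activated, ranks the planted
pentamer first of 1024, and finds ChIP binding enriched among induced
genes. `tidy(res)` gives the per-event table, `glance(res)` the one-row
summary, and `autoplot(res)` the knockdown-versus-differentiation quadrant
scatter with direct targets circled.

Individual stages are ordinary data-frame functions and compose with the
pipe, e.g.

```r
sim <- simulate_dataset(cfg)
sim$reads |>
  deduplicate_reads() |>
  call_crosslink_sites() |>
  assign_site_fdr(sim$genes) |>
  dplyr::filter(significant) |>
  build_clusters() |>
  filter_clusters(min_reads = 4)
```

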