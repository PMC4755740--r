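---
title: "Methods: calling direct splicing-regulator targets with clipsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling direct splicing-regulator targets with clipsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

clipsplice identifies the direct targets of an RNA-binding splicing
regulator (the motivating case is a polypyrimidine-tract-binding repressor
acting on cassette exons during neuronal differentiation) by requiring
three independent lines of evidence to converge on the same exon:

* the protein **binds** near the exon (iCLIP clusters within the exon body
  or its 500-nt intronic flanks),
* the exon **responds** when the protein is depleted (knockdown ΔPSI), and
* the exon **changes** during the differentiation of interest
  (differentiation ΔPSI, same direction).

This vignette describes each model, its assumptions, the tunable
parameters, the numerical conventions, and what the synthetic data do and
do not establish about behaviour on real data.

```{r, eval = FALSE}
library(clipsplice)
res <- run_pipeline(simulation_config())
autoplot(res)
```

# iCLIP: from reads to binding clusters

**Deduplication.** In iCLIP library preparation, each reverse-transcription
product carries a random barcode, and PCR amplifies position + barcode
together. Reads identical in (chromosome, crosslink-defining start, strand,
barcode) are therefore treated as copies of one molecule and collapsed.
The crosslink-defining start is the alignment start on the plus strand and
the alignment end on the minus strand, because the biological truncation
point is the 5′ end of the read in transcript coordinates. Reads without a
barcode cannot be assigned to a molecule and are rejected (counted, not
silently dropped).

**Crosslink sites.** cDNAs truncate at the crosslinked nucleotide, so the
crosslink sits one nucleotide transcript-upstream of the read start: a
plus-strand read starting at genomic position $s$ marks $s-1$; for a
minus-strand alignment $[a, b)$ the package places the crosslink at $b$.
The minus-strand convention is a design choice: truncation is 5′ of the
read in transcript orientation, and with half-open coordinates the first
transcribed nucleotide of a minus-strand read is $b-1$, so the nucleotide
upstream of it is $b$.

**Positional FDR.** Within each gene, let $T$ be the total number of
unique-molecule crosslink events and $L$ the gene-span length. Each of
`n_perm` (default 100) permutations places $T$ events uniformly at random
over the $L$ positions. For every height $h$,

$$\mathrm{FDR}(h) \;=\;
  \frac{\mathbb{E}_\text{perm}\left[\#\{\text{positions with height} \ge h\}\right]}
       {\#\{\text{observed positions with height} \ge h\}},$$

capped at 1. Tail counting makes the numerator and denominator individually
monotone, but their ratio need not be, so a running minimum over increasing
$h$ is applied; this never changes whether the top of the distribution is
called significant. Sites with FDR < 0.01 are significant. Randomization
is over the *whole gene span* (exons and introns): the choice is recorded
as a design decision because crosslinks are observed on transcripts, but
the uniform-span null is conservative for our simulations, where background
is uniform over the span by construction. Sites not assignable to any gene
are excluded from the FDR computation and reported.

Under uniform saturation (every position covered once, $T = L$) the
permuted number of occupied positions concentrates near $L(1-e^{-1})$, so
the FDR is about 0.63 — far above any reasonable cutoff, as it should be,
though not exactly 1.

**Clusters.** Significant sites are extended 20 nt on both sides and
overlapping extensions merged per chromosome and strand. Two conventions
matter here. First, merging requires a genuine overlap of at least one
nucleotide; abutting intervals (gap 0) stay separate, which matches the
"overlapping sites" reading and keeps the merge a proper closure operation
(tests verify idempotence against a connected-component oracle). Second,
the ≥ 4-read support filter counts *reads* (the summed unique-read heights
of member sites), not sites — the filter's unit is stated in reads, and a
single tall site can satisfy it.

**Pentamer enrichment.** For every significant site inside an intron, the
±30-nt window (clipped to the intron) is read in the sense orientation of
the host gene, and all overlapping pentamers are counted over all windows.
The null draws, per randomization replicate, one interval of the same
width uniformly from the same intron for each window, so the null is
matched for intron composition and window-width distribution;
$z = (\text{obs} - \hat\mu_0)/\hat\sigma_0$ over `n_rand` (default 100)
replicates. Sites in exons or UTRs are excluded, because the null is
defined on introns. When $\hat\sigma_0 = 0$ the z-score is 0 if the
observed count equals the null mean and signed infinity otherwise, with a
`degenerate` flag — a sentinel, not a number to interpret. Pentamers are
reported in the DNA alphabet; read T as U when comparing with RNA motifs.

# Splicing: PSI, differential splicing, quadrants

**PSI.** Junction evidence for a cassette trio comprises upstream and
downstream inclusion junction counts $I_1, I_2$ and the exclusion junction
count $E$. Replicates are pooled (the motivating study pooled siRNA
replicates to increase depth), then with $m = (I_1+I_2)/2$,

$$\mathrm{PSI} = 100 \cdot \frac{m}{m + E}.$$

This ratio estimator replaces an external Bayesian tool by design: the
trio-evidence ratio is the standard closed form, is unbiased under the
binomial sampling model the generator implements, and keeps the estimator
auditable. Events with zero pooled support are flagged unevaluated rather
than divided.

**Differential splicing.** ΔPSI = PSI(b) − PSI(a) in percent points. The
p-value is a two-sided Fisher exact test on the 2×2 table of rounded $m$
versus $E$ across the two conditions; rounding is needed because $m$ is a
half-integer average, and at the depths involved it changes nothing
detectable. The exact-test choice is a stand-in — the source analysis does
not state its test — so all calibration claims rest on simulation: at
depth 200 the null false-positive rate is ≈ 3% (Fisher is conservative)
and power for |ΔPSI| = 40 is ≈ 1. Events pass at raw $p < 0.05$ and
|ΔPSI| ≥ 15; no multiple-testing correction is applied, mirroring the
source filtering (recorded, not endorsed).

**Quadrants and direction.** With the sign conventions ΔPSI(kd) =
knockdown − control and ΔPSI(diff) = differentiated − progenitor, an exon
with both shifts ≥ +15 is a repressed neuronal exon (depleting the
repressor de-represses it, and differentiation — which lowers the
repressor — increases it); both ≤ −15 is an activated neuronally skipped
exon. A direct-target call additionally requires a binding cluster and
concordant signs; events where the two contrasts pass with opposite signs
are flagged conflicts and excluded from tallies.

# Expression and ChIP integration

Fold change is the ratio of group mean FPKM (test over reference) with a
0.1-FPKM pseudocount in both numerator and denominator, guarding against
zero-FPKM genes; significance is Welch's unequal-variance t-test on the
raw FPKM values, two-sided. When both groups have zero variance the test
is undefined; the package adopts $p = 1$ for equal means and $p = 0$
otherwise, so planted degenerate fixtures behave predictably. Genes with
fewer than two replicates in a group are skipped and counted. Classes are
assigned at each requested cutoff (defaults 2.0 and 1.5) as induced /
repressed / unchanged.

ChIP clusters are DNA-level features, so gene assignment is
strand-agnostic: a gene is bound when any cluster overlaps its span
extended 1 kb on both sides. Enrichment of bound genes among a sample
(e.g. induced genes) versus the expressed background uses the upper-tail
hypergeometric probability. "Expressed" defaults to mean FPKM ≥ 1 in
either group — the background population is not defined in the motivating
analysis, so the floor is a package decision, exposed as a parameter.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions for every calibration claim in the test suite.

* **Annotation.** 300 genes of five exons on four chromosomes, exons
  80–250 nt, introns 1100–2500 nt (long enough that a 500-nt flank plus
  site window always fits), intergenic spacing 4 kb (so 1-kb ChIP windows
  of neighbours never touch). The middle internal exon of each gene is its
  designated cassette event.
* **Event classes.** 50 events receive one planted crosslink site in the
  upstream intron flank; 25 + 15 of these are also knockdown-responsive
  and differentiation-changed (the planted direct targets, repressed and
  activated), the other 10 are bound but splicing-unchanged. 30 events are
  responsive and changed but unbound, and 30 change in differentiation
  only — the classes that exercise precision. True |ΔPSI| is uniform on
  [25, 45].
* **iCLIP reads.** Per planted site, Poisson(30) unique molecules start
  one nucleotide downstream of the site (truncation model); background
  molecules arise at 5 per kb of gene span, uniformly. Every molecule gets
  an independent 9-nt random barcode, drawn so molecules sharing a start
  position never collide — this makes "deduplication recovers the
  molecule count" an exact identity the tests assert, rather than a
  probabilistic one. PCR adds Poisson(1) extra copies per molecule,
  inheriting position and barcode. The barcode architecture of the real
  protocol is not specified beyond "random portions"; the generator's
  model is a stand-in and is flagged as such.
* **Motif.** The pentamer TCTCT is written into the sense sequence at
  three offsets around each planted site, so motif recovery has a known
  right answer (rank 1 of 1024).
* **Junction counts.** Per event, condition, and replicate (two
  replicates, expected depth 200), each of $n \sim$ Poisson(depth)
  transcripts is included with probability PSI/100; included transcripts
  contribute both inclusion junctions ($I_1 = I_2 = k$), skipped ones the
  exclusion junction. Counts are generated directly rather than as reads
  to keep desk-scale runtime; read-level RNA-seq simulation is a non-goal.
* **Expression.** Per-gene log-normal FPKM (baseline meanlog uniform on
  [log 5, log 150], sdlog 0.25), with 40 genes induced 3-fold, 20 induced
  1.7-fold (called at the 1.5 cutoff but not at 2.0), and 10 repressed;
  3 wild-type versus 5 mutant replicates, matching the motivating design.
* **ChIP.** Induced genes are bound with probability 0.45, others 0.15 (a
  threefold enrichment, the size of effect the integration stage should
  detect); bound genes receive one 200-nt cluster inside their span, and a
  few unbound genes receive decoy clusters 2 kb past their span to verify
  the 1-kb window excludes them.

**What the simulations do not show.** The generator's background is
uniform within gene spans, reads are error-free and uniquely mapped,
barcodes never collide, junction counts are exactly binomial, and FPKM
noise is exactly log-normal. Passing calibration under these conditions
validates the statistics' implementation and their behaviour under their
own assumptions; it does not establish robustness to mappability
artefacts, crosslinking sequence bias, overdispersed counts, or isoform
complexity in real libraries. The pipeline's thresholds (FDR 0.01, ≥ 4
reads, |ΔPSI| ≥ 15, $p < 0.05$) are taken from the motivating analysis,
not retuned on the simulations.

# Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; GTF I/O converts to/from
  1-based inclusive, BED is native. "Upstream"/"downstream" are always in
  transcript orientation.
* One model per gene: the transcript with the greatest summed exon length,
  ties broken lexicographically by transcript id (a deterministic
  tie-break, so re-reading a written annotation reproduces the model).
* Flanks are clipped at the neighbouring exon; whether the motivating
  analysis clipped is unstated, and clipping keeps "intronic flank" literally
  intronic. A fully clipped flank is an explicitly empty interval and can
  never overlap anything.
* Empty inputs propagate as empty outputs with the right columns, never as
  errors: an empty read file yields zero sites, clusters, and bound events.
* Malformed records (start ≥ end, unknown strand, missing barcode) are
  rejected with the offending record identified.

# Problem sizes

The test suite and acceptance script use the generator defaults (300
genes, 50 planted sites, depth 200) for end-to-end checks; 1000 events at
depth 200 for estimator bias; 100 and 1000 seeded simulations for power
and type-I calibration; 20 seeds × 100 permutations for FDR calibration;
1000 random interval sets, a 10,000-read set, and the complete $N \le 20$
hypergeometric grid for oracle equivalence. These sizes were chosen so
each claim has enough replication to be stable at the asserted tolerances
while remaining a desk-scale computation.

# Known limitations

* Only cassette-exon events are modelled; alternative 5′/3′ splice sites
  and retained introns are out of scope.
* The FDR randomization region (whole gene span) and the exact-test choice
  for differential splicing are stand-ins for undocumented steps of the
  motivating analysis; both are recorded as design decisions above.
* Clusters are assigned to at most one gene; overlapping same-strand gene
  models would need a disambiguation rule the generator never produces.
* No multiple-testing correction is applied to splicing p-values or
  enrichment tests, by design fidelity rather than statistical preference.
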