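---
title: "Building CAGE promoter atlases: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building CAGE promoter atlases: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cageatlas)
```

# The problem

Cap analysis of gene expression (CAGE) sequences the 5' ends of capped
transcripts, so each mapped tag marks a transcription start position at
base-pair resolution. Across a panel of related cell types — here modelled
on myeloid differentiation, from hematopoietic progenitors through
monocytes, granulocytes and dendritic cells — CAGE simultaneously
quantifies *which* promoters a gene uses and *how much* each one is used,
and, as a by-product, detects enhancers through the balanced, divergent,
low-level transcription (eRNA) they produce.

`cageatlas` implements the full desk-scale analysis chain:

1. **TSS atlas** — cluster per-base tag counts into strand-specific tag
   clusters, normalise to tags per million (TPM), keep clusters reaching
   at least 5 TPM in some sample, and classify each cluster as
   `promoter` / `intragenic` / `intergenic` against gene models.
2. **Promoter usage** — TSS-per-gene statistics, per-sample versus
   atlas-wide usage contrasts (two-sided Fisher exact test), and
   per-cell-type signature gene calls.
3. **Coexpression** — Pearson correlation graphs on log2(TPM+1) clustered
   with the Markov cluster algorithm (MCL), including the stage-ordered
   trajectory variant.
4. **Enrichment** — an own log2-odds PWM scanner plus hypergeometric
   tests with Benjamini–Hochberg FDR, for motifs and for interval
   (peak-set) overlaps.
5. **Enhancers** — calls from divergent tag-cluster pairs, cell-type
   restriction, and target-gene linking by expression correlation.
6. **Synthetic data** — a generator that plants all of the above as
   recoverable ground truth.

# TSS calling: distance clustering instead of peak decomposition

Large CAGE consortia derive TSS peaks with a decomposition-based peak
identification algorithm that splits composite signals using many
samples. That algorithm is upstream consortium infrastructure, not part of this
package's scope; `cluster_tags()` substitutes deterministic
single-linkage clustering of pooled tag positions per (chromosome,
strand): two positions join a cluster iff their gap is at most `max_gap`
(default 20 bp). The substitution is deliberate — it is reproducible,
parameter-transparent and testable, and downstream statistics only need
*stable promoter-level units*, not optimal peak decomposition. The cost
is that genuinely overlapping promoters closer than `max_gap` merge into
one cluster; alternate promoters at realistic separations (≥ 600 bp in
the synthetic world, typically ≥ hundreds of bp in real annotations)
are unaffected.

Key atlas parameters:

| parameter | default | meaning |
|---|---|---|
| `max_gap` | 20 bp | single-linkage gap for tag clustering |
| `min_tpm` | 5 TPM | inclusive expression filter ("at least 5 tags/million") |
| promoter window | 500 bp | summit-to-5'-end distance for `promoter` class |

Annotation is strand-aware and uses precedence promoter > intragenic >
intergenic, nearest 5' end wins, distance ties broken by the
lexicographically smaller gene id (arbitrary but reproducible).
Antisense clusters near a 5' end are *not* promoters: divergent
antisense transcription is the enhancer caller's signal, and promoter
status would wrongly consume it.

A note on library sizes: TPM is defined against the sample's total
mapped tag count. For real tracks that is the track total; the synthetic
generator, which emits only the planted fraction of a library, records
the nominal depth in the sample sheet (`library_size` column), and the
CLI uses it when present.

# Alternate promoter statistics

`tss_per_gene()` counts gene-assigned clusters per gene.
`usage_fisher()` contrasts one sample's expressed TSS and gene counts
with the atlas totals on the 2×2 table
`[[n_tss_sample, n_gene_sample], [n_tss_atlas − n_tss_sample,
n_gene_atlas − n_gene_sample]]`. Published promoterome analyses of this kind report the
per-sample-vs-atlas contrast only as a Fisher test without stating the
2×2 construction; this construction is therefore isolated in one documented
function so it can be swapped. The two-sided p-value sums all
hypergeometric outcomes no more probable than the observed table — the
same rule as `stats::fisher.test` — and is verified exhaustively against
a full-enumeration oracle for every table with N ≤ 60.

Signature calls use fold-change against the mean of all other samples
(`fold = 4`, floor `min_tpm = 5`), with gene expression defined as the
sum of the gene's TSS cluster TPMs (an aggregation such analyses usually leave implicit).

# Coexpression graphs and MCL

Correlations are computed on log2(TPM + 1). Expression heat maps in this field are
drawn on the log2 scale, but the correlation input scale is rarely
stated; raw-TPM correlations are dominated by a handful of high
expressers, so the log scale is the defensible default. Default cutoffs
are the values established for myeloid CAGE panels: 0.58 for
sample-to-sample graphs, 0.9 for TSS-level graphs, MCL inflation 2.2.

`mcl()` is the classic algorithm: unit self-loops, column-stochastic
normalisation, repeated expansion (matrix power 2) and inflation
(entry-wise power, renormalise), pruning entries below `1e-5`, until the
matrix change drops under `1e-8`; clusters are weakly connected
components of the limit matrix's non-zero structure. All numerical
details are exposed as parameters; only the inflation value is a
field-established constant, the rest follow the canonical MCL
description. Two properties are enforced by tests: the output is a
partition, and nodes of different connected components never co-cluster.
Cluster filtering keeps clusters with ≥ 20 TSS members *and* ≥ 5
distinct genes; the conventional "at least 20 tags" filter is read as 20 TSS nodes
(the graph's nodes are TSSs) — if it meant raw tag counts the filter
would be nearly vacuous at atlas scale, but the alternative reading is
noted here.

The implementation uses dense matrices, which is appropriate for the
desk-scale graphs this package targets (10³–10⁴ nodes); a six-figure
node count would need a sparse expansion step.

# Motif and overlap enrichment

External motif tools are replaced by a transparent in-package
scanner: score = Σ log2(p(base)/background) over the motif columns, both
strands (the reverse strand scores the reverse complement), hit iff
score ≥ `score_fraction` (0.8) × maximum attainable score. `N` bases
contribute 0, keeping scores comparable across windows that touch
assembly gaps. JASPAR count matrices become probabilities with
pseudocount 1 per cell. Enrichment is a hypergeometric upper tail on
hit/no-hit membership — foreground = the TSS cluster set under test,
background = all filtered atlas TSSs (the all-TSS background is the simplest defensible choice that
needs no sequence matching; a GC-matched background is future work) — with BH correction across the terms of
each call. The summit window is ±300 bp, a typical proximal-promoter
scan width; it is a parameter, not a claim.

# Enhancer calling

A candidate is a (reverse-strand, forward-strand) cluster pair, reverse
summit left of forward summit, separation ≤ 400 bp. Candidates within
500 bp of any transcript 5' end or overlapping any gene body are
rejected; what remains is scored by pooled directionality
`D = (F − R)/(F + R)`, called iff `|D| ≤ 0.8` (inclusive) and pooled
expression reaches 2 TPM in at least one sample; overlapping candidates
resolve to the highest-expression pair. Pooled (not per-sample) counts
define D because per-sample D is dominated by shot noise at eRNA levels.
The caller takes the *unfiltered* annotated atlas: eRNAs are low-level
by nature and the 5-TPM promoter filter would discard exactly the signal
being sought; the caller's own `min_tpm` gate handles noise.

`restriction_call()` labels an enhancer with a cell type iff its mean
TPM is ≥ 5 in that type and < 1 in every other type. `link_genes()`
correlates the enhancer's log2(TPM+1) profile with every promoter-class
cluster within 500 kb and links genes at r ≥ 0.7, best first.

# The synthetic world

The generator's defaults *are* the stated test world: 5 cell types × 3
replicates (replicated cell-type panels at a desk scale of 15 libraries), 200 genes on 5 × 1 Mb chromosomes, 8 coexpression
modules, 25% of genes with an alternate promoter, 30 bidirectional
enhancers, library sizes 1–4 million tags (the depth range of typical
CAGE libraries), negative-binomial counts with dispersion 0.1 (a typical
replicate-level overdispersion for tag-count data), on
level 50 TPM, off level 0.2 TPM, background noise 5 × 10⁻⁵ positions/bp
emitted as single-sample singletons (CAGE background is sporadic
singleton tags), seed 42.

Structure that the generator plants, and what recovery tests may use:

* **Modules.** Modules 1–5 are each active in one cell type; modules 6–8
  span two adjacent types. Two same-type modules would have *identical*
  activity patterns and be unrecoverable by any correlation method, so
  distinct type-sets are part of the stated world, not a convenience.
  Alternate promoters are assigned to a module with a *disjoint*
  type-set ("differently regulated"), which is also what makes the
  per-sample TSS/gene ratio sit below the atlas-wide ratio.
* **Enhancers.** Two divergent single-summit emitters 180 bp apart
  (within the 400 bp pairing window), splitting the on-level TPM between
  strands according to `enhancer_balance` (default 0, i.e. balanced),
  active in one cell type, placed in intergenic gaps with ≥ 800 bp
  clearance. Each enhancer is paired with the nearest "partner" gene on
  its chromosome sharing its activity pattern, recorded in the truth
  tables for linking tests. Because all same-type features share one
  on/off pattern, the top *single* link is tie-broken by noise; the
  linking test therefore requires the truth gene to be within 0.05 of
  the best correlation rather than strictly first.
* **Motifs.** Each module TSS carries its module's 8-bp consensus 50 bp
  upstream of the summit with probability 0.9, planted into an otherwise
  uniform random genome.
* **Tag geometry.** Tags spread 1–20 bp downstream of the summit with
  geometric decay, so tag clustering is exercised non-trivially.
* **Trajectory.** `simulate_stage_matrix()` plants three shape families
  over 5 ordered stages (monotone ramp, mid pulse, late switch-off;
  maximum between-family profile correlation 0.33), amplitude 4 log2
  units, Gaussian noise sd 0.25, plus flat genes.

What the synthetic world does **not** emulate — hence what a green test
does not establish: mapping artifacts and multi-mapping tags, CAGE's
G-addition bias, GC or mappability covariates in motif backgrounds,
composite/overlapping promoters closer than `max_gap`, broad-versus-
sharp promoter shape classes, enhancers shared across several cell
types, and any real genome's repeat structure. Recovery at ARI 1.0 on
this world demonstrates correctness of the machinery, not performance
on real FANTOM-scale data.

# Numerical choices and degenerate inputs

* All thresholds are inclusive (`≥ 5` TPM, `≥ 20` members, `≥ 5` genes,
  `|D| ≤ 0.8`) — matching "at least" wording throughout.
* Fisher/hypergeometric p-values are clamped into (0, 1]; two-sided
  Fisher uses a 1 + 1e-7 relative tolerance against floating-point ties.
* Empty CTSS input yields an empty atlas, not an error; an empty
  foreground in enrichment *is* an error (a p-value would be
  meaningless).
* Zero-variance expression profiles get no correlation edges and are
  flagged; they are skipped (with nothing reported) in enhancer linking.
* MCL columns zeroed by pruning are restored to their pre-prune argmax;
  non-convergence at `max_iter` returns the current interpretation with
  a warning.
* Ties: summit ties go to the leftmost position; gene-assignment ties to
  the smaller gene id; both arbitrary but deterministic.
* Determinism: a `sim_config` (including seed) maps to byte-identical
  output files; MCL and all callers are deterministic given their input.

# Known limitations

* Dense MCL limits graphs to roughly 10⁴ nodes on 8 GiB.
* The enrichment background is not GC-matched; on real genomes motif
  enrichment against an all-TSS background inherits composition biases.
* The Fisher 2×2 construction for promoter-usage contrasts is one of
  several defensible choices; it is isolated in `usage_fisher()` for
  exactly that reason.
* The enhancer caller's constants (400 bp pairing, |D| ≤ 0.8, 2 TPM) are
  reproducible defaults in the lineage of published bidirectional-eRNA
  callers, and are not claimed to reproduce any specific published
  enhancer count.
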