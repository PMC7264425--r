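---
title: "Region-resolved methylation and expression comparison: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-resolved methylation and expression comparison: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regmeth)
```

## The problem

Plant genomes carry cytosine methylation in three sequence contexts — CG,
CHG and CHH (H = A, C or T) — and active DNA demethylases (in Arabidopsis:
ROS1, DML2, DML3) prune that methylation at specific loci. Asking whether a
demethylase mutant (e.g. *ros1*, or the *rdd* triple mutant) hypermethylates
a panel of genes such as the NLR disease-resistance family reduces to a
concrete computational pipeline:

1. anchor analysis windows on each gene — the 200-bp and 500-bp upstream
   regions (UPR200/UPR500, immediately 5' of the transcription start site)
   and the gene body region (GBR, TSS through the transcription end site);
2. summarise per-cytosine bisulfite-sequencing calls into one *weighted
   methylation level* per (gene, window, context);
3. compare genotypes with fixed percentage-point thresholds; and
4. relate the methylation calls to expression changes classified from FPKM
   tables and qPCR fold changes.

`regmeth` implements each stage as a small, composable function, plus a
seeded simulator that generates complete synthetic studies with planted
effects so that the whole pipeline can be validated without any sequencing
data.

## Region derivation

Gene models are taken from the `gene` feature lines of a GFF3 file; the
feature's own span and strand define TSS and TES, so isoform choice never
arises. For an L-bp upstream window, a `+` strand gene with TSS $t$ gets
$[\max(1, t-L),\, t-1]$ and a `-` strand gene $[t+1,\, \min(\mathrm{len},
t+L)]$. Windows are clipped at chromosome ends; a window clipped to nothing
is kept in the output with a `zero_length` flag and yields undefined levels
downstream rather than an error. Upstream windows are deliberately *not*
trimmed when they reach into a neighbouring gene: any trimming rule would be
an extra modelling assumption, and the untrimmed window is the conservative,
reproducible choice.

Internally all interval arithmetic uses the Bioconductor convention (1-based
closed coordinates in `GRanges`); conversion to BED's 0-based half-open
convention happens only at the export boundary, through rtracklayer. Keeping
a single convention inside the package and converting exactly once at I/O is
what removes off-by-one errors in practice.

## Weighted methylation level

For a region $R$ and context $c$, with coverage-filtered cytosines $i \in R$
of context $c$ carrying $m_i$ methylated and $u_i$ unmethylated read calls,

$$\mathrm{level}(R, c) = \frac{\sum_i m_i}{\sum_i (m_i + u_i)}.$$

This *weighted* form (pooled counts, not a mean of per-cytosine ratios) is
the standard region summary: it is robust to coverage heterogeneity, reaches
the boundary values 0 and 1, depends only on count sums (hence is invariant
to record order and additive over split inputs), and moves monotonically
when fully (un)methylated cytosines are added. A region with no covered
cytosines of the requested context has an undefined (`NA`) level and is
reported as such, never dropped.

Two conventions deserve note:

* **Coverage filter.** Cytosines need at least 4 reads (configurable,
  inclusive) to enter a level. The filter is applied per strand-specific
  cytosine; read counts are never pooled across the two cytosines of a
  symmetric CG dyad, matching the layout of the per-cytosine report being
  consumed.
* **Strands in regions.** Cytosines on both DNA strands inside a window
  contribute to its level regardless of the gene's strand — methylation is a
  property of the locus, and restricting to the gene strand would halve the
  data with no offsetting benefit.

## Context calling

On `+`, a position is a cytosine if the reference base is `C`; the context
is `CG` if the next base is `G`, `CHG` for C-H-G, otherwise `CHH`. On `-`
the reference base must be `G` and the rules apply to the complemented
upstream bases. The *minimal determining window* is used: a trailing `C`
followed by `G` is still a confident `CG` call, but if any base actually
needed for the decision is `N` or beyond the sequence end, the position is
reported as undeterminable (`NA`) rather than defaulting to `CHH`.

## Genotype comparison

Differences are expressed in percentage points, $\Delta = 100
(\mathrm{level}_{mut} - \mathrm{level}_{wt})$, and calls use absolute
differences, not ratios — a region going from near zero to 40% methylation
is the canonical positive here, and ratios are unstable at near-zero
baselines. Thresholds are inclusive and configurable per window kind, with
defaults of 10 pp for the upstream windows and 5 pp for gene bodies, the two
operating points commonly applied to promoter-proximal versus gene-body
changes. Genes are additionally binned at a 0.1-level boundary ("group 1"
strictly above 0.1, "group 2" otherwise; the boundary itself falls in group
2 because group 1 is defined strictly), and `group_proportions` summarises
the bin occupancy over genes with defined levels.

## Expression classification

FPKM is computed as $10^9 \cdot \mathrm{count} / (\mathrm{length}_{bp}
\cdot \mathrm{library})$. A gene with both genotypes below 1 FPKM is
`not_expressed`; otherwise the mutant/wild-type ratio classifies it as `up`
($\ge 1.1$), `down` ($\le 0.9$) or `unchanged`. A wild-type FPKM of exactly
zero with an expressed mutant is labelled `up` with an undefined ratio — the
direction is unambiguous even though the ratio is not. The generic
differential-expression filter is strict on fold change (more than twofold,
either direction) and inclusive on FDR ($\le 0.05$); Benjamini–Hochberg
adjustment is exposed as `bh_adjust` (a validating front-end over
`stats::p.adjust`). qPCR fold changes use Livak's $2^{-\Delta\Delta C_t}$
with replicate $C_t$ values averaged per condition before differencing (the
Livak convention), which makes the fold change invariant to any constant
shift applied to all four means.

## Integration

`methylation_expression_links` joins hyper/hypo calls with expression labels
for one (window kind, context) pair — link semantics are never aggregated
across kinds, since promoter and gene-body effects are distinct questions —
and labels each gene `negative` (hyper∧down or hypo∧up), `positive`
(hyper∧up or hypo∧down) or `none`. Gene universes are intersected, never
imputed; genes present in only one input are counted in an `n_missing`
attribute. `consistent_direction_genes` partitions two mutants' label maps
into up-in-both / down-in-both / discordant / other.

## The simulator: what it emulates, and what it does not

The synthetic-data module generates a full desk-scale study: genome
(i.i.d. sequence), annotation, two-genotype per-cytosine reports, FPKM
tables and Ct tables, all deterministic given one integer seed (each
generator derives its own stream from it, so artefacts are byte-identical
across repeated runs).

Default conditions, chosen once as a realistic stand-in for a two-genotype
plant methylome study of a ~144-gene panel:

| parameter | default | why |
|---|---|---|
| chromosomes | 2 × 250 kb | smallest genome that holds 144 spaced genes with clean windows |
| GC fraction | 0.36 | Arabidopsis-like base composition |
| genes | 144, 1.5–3 kb, ≥600 bp apart | panel size of interest; spacing keeps every UPR500 free of neighbours |
| coverage | Poisson, λ = 50 reads/cytosine | deeply covered modern BS-Seq |
| baselines (CG/CHG/CHH) | 0.24 / 0.10 / 0.03 | the characteristic CG ≫ CHG > CHH ordering of plant gene-proximal methylation |
| dispersion κ | 20 | visible within-region heterogeneity; κ → ∞ recovers the binomial limit used in closed-form checks |
| FPKM baseline | lognormal(log 10, 0.8) | moderately expressed genes with realistic spread |
| FPKM noise σ | 0.05 | multiplicative replicate-level noise |

Per cytosine, the true level is the context baseline plus any planted
percentage-point shift whose window contains it (shifts accumulate where
planted windows overlap, clamped to [0, 1] — so a UPR200 nested inside a
planted UPR500 inherits the shift); the realised methylation probability is
Beta($p\kappa$, $(1-p)\kappa$), coverage is Poisson, and methylated reads
are binomial. Zero-coverage cytosines are still written, as real reports do,
so the coverage filter is genuinely exercised. The truth table records the
mean per-cytosine true level of every (gene, kind, context), which is the
estimand of the weighted level under uniform expected coverage.

What the simulator does **not** emulate: read-level artefacts (incomplete
bisulfite conversion, mapping bias, PCR duplicates), methylation
autocorrelation along the chromosome, CG-island structure, transposable
elements, or biological replicate variance. Passing the planted-effect
recovery tests therefore demonstrates that the *pipeline arithmetic and
thresholds* behave as specified under the stated noise model — not that the
thresholds have any particular sensitivity/specificity on real data, where
between-replicate variance and non-uniform coverage dominate.

## Validation strategy and problem sizes

The test suite checks, among others: exact agreement of `summarize_region`
with an independent brute-force loop on 1,000 random instances of ≤50
cytosines; all threshold boundaries (coverage = 4 kept, level = 0.1 →
group 2, Δ = ±10 pp called, fold change = 2 rejected); strand symmetry of
region derivation under coordinate mirroring; minus-strand context calls
against a plus-strand oracle on the reverse complement; planted-effect
recovery (recall ≥ 0.95, false-positive rate ≤ 0.05 at the 10-pp threshold)
on a genome-wide simulation of 144 genes with 50 planted +40-pp CG shifts at
UPR500 under λ = 50, and on 20 count-level replicates at 100
cytosines/region; expression recall ≥ 0.95 for 50 of 500 genes planted at
ratio 1.5 with σ = 0.05; and byte-identical simulator artefacts under a
repeated seed. These problem sizes were chosen so the full suite runs in
about two minutes on one CPU while leaving the Monte-Carlo margins wide
(the planted +40-pp effect sits 15+ standard errors above the 10-pp
threshold at the default coverage).

## Known limitations

* Fixed-threshold calls carry no statistical test; regions with few covered
  cytosines get noisier levels and no widened threshold. (The per-region
  counts are reported so users can filter on `n_cytosines`.)
* Baseline true levels are uniform per context in the simulator, so
  group-proportion summaries on synthetic data are degenerate unless the
  user plants between-gene variation via `planted_dm`.
* Undefined levels propagate as `NA` through comparison and linking; no
  imputation is ever attempted.
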