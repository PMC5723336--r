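---
title: "Gene-centric quantification by phylogenetic read placement: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-centric quantification by phylogenetic read placement: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Functional marker genes — here the nitrogen-cycle genes narG, nirK/nirS,
qnorB/norB, nosZ, hzo, amoA, nxrB, nrfA — are patchily distributed across
microbial lineages, often horizontally transferred, and frequently sit next
to close paralogs (narG beside nxrA, nxrB beside narH) that a naive homology
search cannot distinguish. `placeprof` quantifies such genes directly from
short metagenomic reads, without assembly or primer bias, by

1. **recruiting** reads to a gene with a translated local-alignment search,
2. **placing** each recruited read onto a curated reference phylogeny of
   full-length protein sequences by per-edge maximum likelihood,
3. **excluding** reads whose best placement falls in the tree's outgroup
   (the close-paralog trap above), and
4. **normalizing** placed-read counts, per sample, to the same sample's
   placed-read count for the universal single-copy gene rpoB.

The headline statistic is

```
% prokaryotic community = (gene reads / gene length) / (rpoB reads / rpoB length) * 100
```

Because rpoB occurs exactly once in every bacterial and archaeal genome, the
length-normalized ratio estimates the fraction of the prokaryotic community
whose genomes carry the gene. Genes known to be duplicated within a genome
(e.g. the two distinct SAR11 nitrate reductases) are divided by their
copies-per-genome per clade before totals are re-summed. The estimate is
relative: it deliberately says nothing about absolute cell densities, which
change with depth.

"Gene length" and "rpoB length" are the median ungapped amino-acid lengths
of the ingroup reference sequences. The median (rather than the alignment
width or the mean) keeps the normalization stable under fragmentary
references and all-gap alignment padding.

# Recruitment

Reads are translated in all six frames (standard bacterial code; codons
containing `N` become `X`, stops `*`) and every frame is scored against
every ungapped reference with an exhaustive affine-gap Smith–Waterman —
reference sets are tens of sequences, so no seeding heuristic is needed and
scores are exact. Raw scores are converted to e-values with Karlin–Altschul
statistics, `E = K·m·n·exp(−λS)`, with λ = 0.267 and K = 0.041 by default
(the standard gapped BLOSUM62/11/1 calibration; both are configurable). A
read is recruited when its best frame/reference combination reaches
`E < 1e-5`; the best combination is chosen by lowest e-value with ties
broken by higher score, then lower frame index.

The recruited read is trimmed to the locally aligned extent, which removes
any overhang of up- or downstream sequence beyond the reference gene, and
residual stops or ambiguities inside the kept segment are masked to `X`
rather than deleted, preserving the codon registration that placement needs.
Reads shorter than 33 amino acids (100 bp) after trimming are dropped. The
33-aa threshold is exact at the boundary: a 32-aa hit is excluded, a 33-aa
hit kept.

# Placement

Recruited reads are registered onto the reference alignment's columns by a
profile alignment: each column is scored as the frequency-weighted BLOSUM62
score of the read residue against the residues observed in that column, and
the read is aligned global-in-read / local-in-profile with affine gaps
(open 11, extend 1). Reference columns are never modified; read residues
that would need a new column are dropped, and all-gap reference columns are
skipped free. Mates of the same fragment are combined into one query: union
of their coverage, with conflicting residues masked to `X`. A combined pair
is placed — and later counted — once.

Placement itself evaluates, for every edge of the reference tree, the
likelihood of the tree with the query attached at the edge midpoint by a
pendant branch:

* Substitution model: LG, WAG or JTT exchangeabilities (shipped as
  plain-text data files) with matrix-supplied stationary frequencies, rate
  matrix rescaled to one expected substitution per unit branch length, and
  discrete-gamma rate heterogeneity (k = 4 equal-probability categories,
  shape α = 1 by default; rates are the conditional means of the quantile
  intervals, so they average exactly to 1). Model choice per gene is
  explicit configuration rather than automated selection.
* Likelihoods come from Felsenstein pruning with per-site scaling (log
  scale factors accumulated separately, so no site underflows to zero).
  Gaps and `X` are missing data. The engine precomputes, once per reference
  package and model, the inside (post-order) and outside (pre-order) partial
  likelihoods of the reference tree, so scoring an edge for a query costs
  one elementwise product per rate category over the query's covered
  columns only — columns the query does not cover contribute a constant,
  edge-independent factor.
* Phase 1 scores every edge with a fixed pendant length of 0.1
  substitutions/site; phase 2 re-optimizes the pendant length for the best
  `max(5, ceil(0.1 · E))` edges by one-dimensional search on
  `[1e-8, 2]` to tolerance 1e-4 (`stats::optimize`, golden-section with
  parabolic interpolation). Only the pendant branch is optimized — the
  attachment stays at the midpoint and the edge's two halves are not
  re-fit. This is the fast variant of the published evolutionary-placement
  heuristic; it keeps the per-edge search one-dimensional and, on the
  synthetic benchmarks, recovers the source edge as reliably as a much more
  expensive full three-branch optimization would need to.
* Likelihood weight ratios are computed over all evaluated edges (every
  edge is evaluated in phase 1, so the denominator is the whole tree); the
  best edge is the arg-max of the log-likelihood with ties broken by the
  smaller edge id, making placements fully deterministic.

Edges are numbered 0..E−1 in deterministic postorder (children visited in
the order written in the Newick file), the numbering used in the emitted
jplace v3 files. The Newick root is bookkeeping only; the model is
reversible, so the likelihood — verified in the tests — is invariant to
re-rooting.

# Outgroup exclusion and clade aggregation

Each reference package labels monophyletic clades (the phylotypes/OTUs whose
depth profiles one wants) and an outgroup of closely related non-target
genes. Each labeled clade owns the edges strictly inside its MRCA's subtree
*plus the MRCA's stem edge* — a query diverging just below a clade's
ancestor is biologically that lineage. Remaining ingroup edges are
`unassigned_ingroup`: they count toward the gene's total but toward no named
clade. A placement whose best edge lies in the outgroup edge set is
discarded entirely. Clade delineation is a curation input, not an algorithm:
the package validates monophyly and disjointness but does not draw OTU
boundaries itself.

# The synthetic-data generator

Because the real metagenomes (tens of millions of read pairs per sample)
are not reproducible at package-test scale, every stage is validated against
seeded synthetic communities with known ground truth:

* Reference packages are simulated on random clade-structured trees (three
  labeled ingroup clades of four leaves; a four-leaf outgroup on a long
  stem, 0.6 substitutions/site) under the same LG+Γ model the placement
  engine assumes, 250 aa for marker genes and 400 aa for rpoB — typical
  protein lengths for these genes.
* Communities are genome lists with relative abundances; every genome
  carries rpoB at exactly one copy (the assumption the normalization relies
  on), and marker genes are assigned to leaves of the gene trees at
  configurable copy number. Gene DNA is obtained by reverse-translating the
  leaf protein with uniform codon usage.
* Reads are 125-bp pairs from fragments of normal(220, 30) bp drawn from
  gene instances with probability proportional to abundance × copies ×
  length, with independent per-base substitution errors (0.5% by default,
  matching post-QC Illumina error rates) and a 10% uniform-random background
  fraction to exercise recruitment specificity. The default scenario sizes
  (700–2500 pairs) keep each benchmark under a few minutes while leaving
  several hundred placed rpoB reads for stable denominators.

What the generator does *not* emulate — and what passing benchmarks
therefore do not demonstrate — includes indel sequencing errors (a
substitution-only model is the default; an indel mode exists for
stress-testing frame trimming), GC and coverage bias, chimeras, strain-level
microdiversity around the reference leaves, and genuinely novel diversity
absent from the reference trees. Synthetic reads come *from* the reference
leaves, so benchmark recruitment and placement rates are upper bounds on
real-data performance.

# Numerical and design choices

* Transition matrices come from the cached symmetric eigendecomposition of
  the rescaled rate matrix; tiny negative entries from round-off are clamped
  to zero. `P(0) = I`, unit row sums, stationarity and detailed balance are
  asserted to 1e-10–1e-12 in the tests.
* The likelihood engine is validated three ways: against brute-force
  enumeration over internal states on all tree shapes up to four leaves
  (1e-10 relative), against an independent phylogenetics package on larger
  trees (1e-8), and via re-rooting invariance.
* Smith–Waterman scores are validated exactly against a naive
  three-matrix DP oracle under three scoring schemes.
* De-duplication of identical reference amino-acid sequences keeps the
  first occurrence as representative (documented order dependence) and maps
  every id to its representative, mirroring what tree-building pipelines do
  to reference alignments.
* Degenerate inputs: empty read sets produce zero-count rows with an
  undefined (`NA`) percent marker rather than zero or an error when the
  rpoB denominator is empty; all-`X` (zero-information) queries are refused
  at placement with an explicit error; per-sample failures are isolated so
  one corrupt sample cannot abort a run.
* The particle/free-living comparison is reported both as side-by-side
  percents and as a convenience log2 ratio with a 0.1-percent pseudo-count
  (keeping 0-vs-0 at 0); the percents are the primary readout.
* "Reads" in the normalization are placed queries (a combined mate pair
  counts once). A summed-aligned-residue alternative was considered and
  rejected as the default because read counts are what the e-value filter
  and the outgroup filter operate on; per-sample rpoB is always the
  denominator for that same sample.

# Limitations

Placement accuracy degrades for reads under ~60 informative residues and
for queries equidistant from several reference clades; the likelihood
weight ratios in the jplace output quantify that uncertainty, but the
abundance tables use only the best edge. Copy-number correction requires
external knowledge of copies per genome per clade. The % community statistic
inherits rpoB's single-copy assumption; lineages with unusual RNA-polymerase
arrangements would bias it. Reference-package quality — alignment, tree,
clade labels, outgroup choice — dominates everything downstream and is the
user's responsibility.
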