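---
title: "Methods: multi-tissue lncRNA characterisation with lncscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tissue lncRNA characterisation with lncscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncscape)
```

# Scope

`lncscape` characterises long non-coding RNAs (lncRNAs) from five inputs: a
gene-level TPM matrix over a tissue panel, a GTF annotation with biotypes
(`mRNA`, `lincRNA`, `antisense`), a RepeatMasker-style transposable-element
(TE) table, a 1:1 ortholog map with matched-tissue expression for a second
species, and a per-base conservation-score track. The package consumes
quantified expression; read alignment and quantification, orthology
inference and GO enrichment are upstream/downstream of its scope.

This vignette documents the statistical procedures, their assumptions, the
tunable parameters, and the design choices made where the design was
genuinely open.

# Tissue specificity: the tau score

For a gene with TPM values $x_1, \dots, x_n$ over $n$ tissues,

$$\tau = \frac{\sum_{i=1}^n (1 - \hat x_i)}{n - 1}, \qquad
  \hat x_i = \frac{x_i}{\max_i x_i},$$

so $\tau = 1$ for a gene expressed in a single tissue and $\tau = 0$ for a
uniformly expressed gene. Choices:

* **Expression floor** (`floor_tpm`, default 1 TPM). Values below the floor
  are set to 0 *before* scoring. This keeps $n$ constant across genes while
  removing sub-detection noise; a gene whose floored vector is all zero is
  reported as not expressed (`tau = NA`) rather than scored. Flooring can
  only raise tau (it zeroes non-maximal coordinates), a property the test
  suite asserts.
* **Specificity call** (`tau_threshold`, default 0.95, inclusive). The
  boundary $\tau = 0.95$ counts as specific; the comparison is exposed as
  `inclusive` for a strict variant. Each specific gene is assigned to its
  tissue of maximal (floored) expression; ties break deterministically to
  the first tissue in column order and are flagged.
* **First/second ratio.** The ratio $\max(x)/\max_2(x)$ is reported per
  gene alongside tau. We do not enforce any fixed correspondence between a
  tau cut-off and a ratio cut-off: no such equivalence follows from the
  formula in general, so both quantities are reported and either can be
  thresholded.
* **"Expressed"** means max TPM strictly above `expressed_tpm` (default 1);
  per-tissue proportions of specific genes are taken over genes expressed
  in that tissue, with zero-denominator tissues flagged.

Tissue-subset specificity (e.g. within nervous-system tissues only) is the
same computation on the sliced matrix (`subset_tau()`), which the tests
verify against a slice-then-score oracle.

# Tissue correlation structure

`tissue_spearman_matrix()` computes all pairwise Spearman correlations
between tissue columns over a biotype-restricted gene universe. Genes with
zero expression everywhere are dropped first: all-zero rows carry no rank
information and would only add ties. Whether to filter more aggressively
(e.g. by mean TPM) is left as explicit configuration; the default is the
minimal filter.

`cluster_tissues()` feeds the correlation matrix itself to
complete-linkage agglomerative clustering on Euclidean distances between
its rows — the common `hclust(dist(cor(m)))` idiom, reproduced literally
rather than converting correlation to a distance, so results match the
field's default invocation. Complete linkage guarantees monotone merge
heights (asserted in tests). Tissues are put in lexicographic order before
clustering so that the result is invariant to input column order and ties
break deterministically. Outputs are a merge table, leaf order and a
Newick export; heatmap rendering is deliberately left to the caller.

# Transposable-element content

Per gene, exons of all transcripts are **projected** onto the genome: the
union of exon intervals, merged (touching intervals merge, as half-open
semantics make them contiguous). TE content of a region (exon projection
or promoter) is the fraction of its bases covered by a TE family, with the
family's copies merged first so overlapping insertions count each base
once. Strand is ignored (RepeatMasker convention). Promoters are
fixed-size windows (default 5 kb) upstream of the gene span's strand-aware
5' boundary, clipped to the chromosome; windows that vanish entirely after
clipping are flagged degenerate and excluded from fractions. Promoter
windows are *not* trimmed when they overlap a neighbouring gene; this is a
documented choice, not an omission.

Only the four major classes (DNA, LTR, LINE, SINE) are admitted; family
fractions use content *fractions* rather than raw bp so genes of different
sizes are comparable — the choice is configuration-visible because the
feature matrix builder (`te_feature_matrix()`) consumes whatever fractions
it is given.

# Ridge-regularized canonical correlation

To relate tissue expression to TE composition, `rcc()` solves

$$\max_{a, b} \; \frac{a' \Sigma_{XY} b}
  {\sqrt{a'(\Sigma_{XX} + \lambda_1 I)a}\sqrt{b'(\Sigma_{YY} + \lambda_2 I)b}}$$

by whitening the regularized covariances (symmetric inverse square roots)
and taking the SVD of the whitened cross-covariance. At
$\lambda_1 = \lambda_2 = 0$ this is classical CCA and the tests require
agreement with two independent routes (a QR-based oracle and
`stats::cancor`) to $10^{-8}$; rank-deficient blocks at $\lambda = 0$ are
rejected with an instruction to use a positive ridge. Canonical
correlations are non-increasing in the penalties (asserted over a grid).

Defaults: $\lambda_1 = \lambda_2 = 0.1$, `ncomp = 3`. The penalties are
deliberately fixed and documented rather than tuned per dataset; both are
exposed in the configuration. Before the analysis the expression block is
$\log_{10}(\mathrm{TPM}+1)$-transformed and both blocks are centred and
unit-scaled — standard practice that puts TPMs and content fractions on
comparable scales. The Y block concatenates exon-projection and promoter
family fractions as separate features, so the two region types can load
differently.

For the clustered-image-map style display, the cross-correlation table is
$\mathrm{cor}(X, Z)\,\mathrm{cor}(Y, Z)'$ with $Z = (U + V)/2$ the
averaged canonical variates over the retained components.

# Positional lncRNA:mRNA pairs and co-expression

`find_pairs()` emits every lncRNA:mRNA pair on one chromosome whose
gene-span gap is at most the window (default 1 Mb). The window is measured
between the closest span boundaries, not TSSs or midpoints — the gene-level
convention of positional classifiers. Classification retains three
subclasses:

* `antisense_exonic` — overlapping spans, opposite strands, exon
  projections intersecting by at least 1 bp. Intron-only antisense overlap
  is excluded: without exonic overlap the case for direct interaction is
  weak and the retained-subclass convention drops it.
* `divergent` / `convergent` — disjoint spans, opposite strands, facing
  boundaries both 5' (head-to-head) or both 3' (tail-to-tail). For
  disjoint opposite-strand genes these are the only two possibilities,
  which the classifier asserts internally.
* Same-strand pairs are excluded entirely, guarding against lncRNAs that
  are really unannotated UTRs of their neighbour.

Retained pairs are correlated over tissues (Spearman) and adjusted with
Benjamini–Hochberg in **one family across all tested pairs of all
classes**. A pair is significantly co-expressed when $|\rho| > 0.5$ and
adjusted $p < 0.05$ (both strict). Pairs with a never-expressed or
constant-expression member are dropped before testing with reason codes,
and the BH family covers tested pairs only.

**Spearman p-values.** For $n \le 12$ untied observations the two-sided
p-value comes from the exact permutation distribution of
$S = \sum_i (r_i - s_i)^2$, computed once per $n$ by a subset dynamic
program over $T = \sum_i i\,\pi(i)$ (an $O(2^n n \sum i^2)$ enumeration of
all $n!$ permutations, cached). For larger $n$ or tied data the usual
t-approximation on $n-2$ degrees of freedom is used. The exact route
matters at $k = 11$ matched tissues in the comparative module, where the
approximation is visibly off in the tails.

Two descriptive analyses operate on significant pairs: the distance
profile (mean pair distance per $|\rho|$ bin plus a Spearman trend
statistic between $|\rho|$ and distance, and rank-sum comparisons between
named subsets such as negative- vs positive-correlation pairs) and the
partner-rank analysis (for lncRNAs with two or more significant partners,
the distance rank of the best-correlated partner, flagging lncRNAs whose
best partner is not the nearest gene).

# Cross-species expression conservation

Replicate libraries are averaged per tissue (arithmetic mean of TPM).
Each 1:1 ortholog pair is correlated over the matched tissue panel (11
tissues by default; exact permutation p-value) and classified by p-value
alone: `high` ($p < 0.05$), `intermediate` ($0.05 \le p < 0.2$),
`divergent` ($p \ge 0.2$). The boundary $p = 0.2$ falls in the divergent
bin — the class definitions in circulation leave it unassigned, and
half-open bins make the partition exhaustive. Constant vectors give class
`unscored`. Orthology itself is consumed as an input table, never
computed.

Per-gene conservation is the **median** per-base score over the exon
projection; unscored bases are skipped and counted, zero scored bases give
`NA`, and the even-count median is the mean of the two middle values.
Duplicate transcripts cannot change the projection, hence not the median
(asserted). Gene-set contrasts use the Wilcoxon rank-sum test, by default
the tie-corrected normal approximation without continuity correction (so
identical samples give a one-tailed p of 0.5), with an exact option for
small sets.

# The synthetic-data generators

Every pipeline input can be generated with known ground truth; all
generators are pure functions of (configuration, seed) and byte-identical
on re-run, and every planted attribute is recoverable from the truth
object without regeneration.

* **Annotation** (`generate_annotation()`): gene loci are laid out on
  non-overlapping 25-kb slots (1–10 exons, 1–3 transcripts per gene).
  Antisense genes are nested inside a host mRNA's longest exon on the
  opposite strand, guaranteeing exonic overlap; quotas of lincRNAs are
  planted adjacent to an mRNA in head-to-head or tail-to-tail orientation
  at controlled gaps of roughly 1–10 kb.
* **Expression** (`generate_expression()`): log-normal baselines with a
  biotype offset (lncRNA 20× below mRNA by default, mirroring the order of
  magnitude seen in real panels) and multiplicative log-normal noise with
  CV 0.2 by default. Planted tissue-specific genes are high in one tissue
  (default fold 50 over a 0.1-TPM background, so off-tissues fall below
  the 1-TPM floor). Planted co-expressed pairs share a per-tissue latent
  factor whose weight is chosen analytically from the Gaussian-copula
  inversion $\rho_P = 2\sin(\pi \rho_S/6)$ so the *Spearman* correlation
  hits its target in expectation. Optional anatomical-system blocks give
  tissues of a block shared per-gene loadings, which is what makes
  within-system tissues cluster together. Non-planted genes are recorded
  as regime `broad` when their baseline is comfortably above the floor
  (default 5 TPM) and `low` otherwise — a gene cannot be meaningfully
  "broad" below detection, and recovery statements are made against these
  truth regimes.
* **TE landscape** (`generate_te_landscape()`): background copies placed
  uniformly to hit a target coverage (default 0.35 before merging) with a
  canine-flavoured family mix; optional *enrichment* raises one family's
  expected content fraction inside named regions by a factor (the factor
  may vary per region, which is how TE content can be coupled to a
  tissue's expression); optional *depletion* thins background copies
  inside named regions, emulating purifying selection so the default
  pipeline reproduces the genome > lncRNA-exon > mRNA-exon TE ordering.
* **Ortholog panel** (`generate_ortholog_panel()`): per stratum (target
  rank correlations 0.9 / 0.5 / 0.0), latent bivariate normal vectors with
  the copula-inverted Pearson correlation, transformed monotonically to
  TPM-like values (rank correlation is preserved by construction).
* **Conservation track** (`generate_conservation_track()`): windowed
  Gaussian background scores (25-bp windows) plus additive per-biotype
  offsets over exon projections. Bases shared by overlapping genes (an
  antisense gene inside its host mRNA) receive both offsets — overlapping
  genes genuinely share bases — so recovery contrasts use lincRNA vs mRNA.

**What the generators do not emulate:** read-level noise, length and GC
biases of quantification, isoform switching, batch structure across
libraries, tied TPMs from low counts, and correlated evolution of TE
content with conservation. Passing recovery tests therefore demonstrates
that the estimators and thresholds behave correctly under the generating
model, not that the biological conclusions transfer to any particular
real dataset.

# The staged pipeline

`run_stage(stage, config)` with stages `simulate`, `tau`, `cluster`,
`te`, `pairs`, `coexpr`, `conserve`, `report` (or `all`) persists each
stage's artifacts as TSV/JSON in the output directory; any stage can be
re-run idempotently from upstream artifacts, and a missing prerequisite
names the stage to run first. All randomness derives from the single
configuration seed (stage-specific seeds are fixed offsets of it), and the
configuration is serialized alongside the outputs for provenance. The
default simulated panel — 2 chromosomes × 2.5 Mb, 80 mRNAs, 60 lincRNAs,
10 antisense genes, 26 tissues, 100 ortholog pairs per stratum — was sized
so a full run completes in well under a minute while every stage still has
enough data to be statistically meaningful; all sizes are configurable.

# Numerical notes and limitations

* Public coordinates are 0-based half-open throughout (BED convention);
  GTF I/O converts to/from 1-based inclusive at the boundary.
* The exact Spearman null is limited to $n \le 12$ (the DP is exponential
  in $n$); beyond that the t-approximation is used deliberately.
* BH adjustment is *not* idempotent in general; tests assert order
  preservation and bounds instead.
* `rcc()` assumes more observations than the effective rank of each
  block at $\lambda = 0$; with few genes use positive penalties.
* The pair classifier is gene-level: isoform-resolved classification and
  sense-overlap rescue are out of scope, as are trans (inter-chromosomal)
  co-expression and network construction.
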