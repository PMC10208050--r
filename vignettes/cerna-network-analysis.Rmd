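---
title: "ceRNA network analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceRNA network analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The analysis model

`cernet` implements a degree-based competing-endogenous-RNA (ceRNA)
screen. The biological premise is sponge competition: a lncRNA that binds
many miRNAs relieves repression on the mRNAs those miRNAs target, so a
lncRNA with many network partners among *differentially expressed* genes
is a candidate regulator of the condition under study. The pipeline is a
composition of well-defined stages, each exposed as a function over
tibbles:

1. **Preprocessing** of a probe-level intensity matrix: removal of
   unexpressed rows, `log2` transform, quantile normalization, mean-collapse
   of probes to genes, and an mRNA/lncRNA split from a probe annotation.
2. **Two-group differential expression** per biotype.
3. **Interaction integration**: a lncRNA–miRNA sponge table restricted to
   the DE lncRNAs, and two miRNA–mRNA target databases intersected
   (a pair counts only if both databases contain it) and restricted to DE
   mRNAs.
4. **Tripartite network** assembly with iterative pruning, degree ranking
   of lncRNAs, and per-lncRNA subnetworks.
5. **Over-representation** of network/subnetwork mRNAs against a GMT
   library.
6. **RT-qPCR quantification** by `2^-ΔCt` for wet-lab validation data.

## Statistical components and their assumptions

**Welch's t-test (unpaired default).** Expression after `log2` is treated
as approximately Gaussian per gene; Welch's form drops the equal-variance
assumption at essentially no cost, which matters after per-gene collapse
where variances differ. Degrees of freedom follow Welch–Satterthwaite.
The two-timepoint design could in principle be patient-paired; whether
pairing applies is a property of the dataset, so a `paired = TRUE` mode
(one-sample t on within-pair differences, pairing by column order) is
provided and the unpaired form is the default. Genes with zero variance
in both groups carry no evidence and are assigned `p = 1` rather than an
error.

**Benjamini–Hochberg.** `adjust_bh()` delegates to
`stats::p.adjust(method = "BH")`; the test suite verifies it against a
brute-force min-tail oracle and checks permutation equivariance. The
passing rule is strict on both sides, `|logFC| > lfc_min` and
`q < fdr_max`, so boundary values fail.

**The FDR default is 0.05, and it is a visible parameter.** Published
two-timepoint screens of this kind are not always internally consistent
about whether the DE cut-off was FDR < 0.01 or < 0.05; the headline
DEM/DEL counts in the literature this design follows are attached to 0.05,
so that is the default, with `fdr_max` surfaced in `cerna_config()` for
anyone who prefers the stricter value.

**Quantile normalization, not full RMA.** RMA is a CEL-file-level
algorithm (background correction, quantile normalization, median-polish
summarization). This package deliberately starts from an
already-summarized probe matrix — its input contract — so it applies the
step of RMA that is meaningful at that level: quantile normalization
across samples, with ties averaged (`limma::normalizeQuantiles(ties =
TRUE)`), which makes the operation deterministic and idempotent. A
consequence worth knowing: on *small* matrices with a large planted-effect
fraction, forcing identical column distributions visibly attenuates
group shifts. At realistic gene counts (thousands of genes, ≤ 10%
affected) the attenuation is negligible; the test suite asserts power at
the DE stage on exactly log2 data and treats the tiny full-pipeline runs
as plumbing checks, not power measurements.

**Probe collapse by the mean.** "Use the mean expression per probe" is
read as: a gene's value in a sample is the arithmetic mean of its probes'
values, computed before DE testing, which keeps gene-level DE well
defined. Collapsing before rather than after testing is a choice; with
per-gene means and Welch tests the difference is small.

**Hypergeometric over-representation.** Enrichment uses the one-sided
hypergeometric upper tail (equivalently Fisher's exact one-tail), the
standard over-representation statistic, computed through
`stats::phyper(lower.tail = FALSE)` for numerical stability and verified
against exact binomial-coefficient enumeration for all configurations
with universe size ≤ 30. Web enrichment services layer additional rank
corrections on top of Fisher's test; since only `-log10(p)` bars are the
reported interface of such services, the plain hypergeometric test is
used and documented. The default universe is the set of gene-level mRNAs
that survived the expression filter — the population actually eligible to
be in the query — rather than a whole-genome background, which would
anti-conservatively inflate enrichment.

**qPCR.** Replicates are averaged on the Ct (cycle) scale, the field
convention; `ΔCt = Ct(target) − Ct(reference)` with no efficiency
correction (none is modelled in the data this supports), and relative
expression is `2^-ΔCt`. Useful invariants follow directly: a constant Ct
shift applied to every gene of a sample cancels, and lowering a target's
Ct by one cycle exactly doubles its relative expression. Group comparison
dispatches on the number of groups — Welch t for two, one-way ANOVA for
more — and records which test ran; whether to compare on the linear or
log2 scale of `2^-ΔCt` is unsettled in practice, so both are available
(`log_scale =` flag) with linear as default.

## Network construction rules

Edges are undirected: the graph is a visualization-and-ranking structure,
and direction is recoverable from node types. Pruning is iterative to a
fixed point: miRNAs must keep at least one lncRNA *and* one mRNA
neighbour, then stranded lncRNAs/mRNAs are dropped, repeating until
stable. Without this, miRNAs dangling on one side would inflate lncRNA
degrees with partners that cannot mediate competition. Ranking ties are
broken lexicographically so every output is byte-reproducible.
`extract_subnetwork()` keeps the anchor lncRNA, its miRNAs, and all mRNA
targets of those miRNAs; by construction the union of all subnetworks
recovers the parent edge set, which the tests assert on random instances.

Expression-direction consistency (ceRNA theory expects lncRNA and mRNA
co-directional) is *not* enforced: no miRNA expression data enters this
design, so such a filter would be unverifiable; degree ranking follows
the network alone.

## The synthetic-data generator

The generator exists so that every downstream stage can be tested against
planted truth without any external download. It emulates, at configurable
scale, a two-timepoint bone-marrow microarray study plus the interaction
and annotation resources around it:

| Parameter | Default | Meaning |
|---|---|---|
| `n_genes`, `frac_lncrna` | 2000, 0.10 | gene universe and lncRNA share |
| `probes_per_gene` | 2 | probes mapped per gene |
| `n_samples_per_group` | 20 | samples at day 0 and day 8 |
| `n_de_mrna`, `n_de_lncrna` | 150, 20 | planted DE genes |
| `effect_size` | 2 | planted shift, log2-units |
| `noise_sd` | 0.5 | measurement noise, log2-units |
| `baseline_mean` | 8 | baseline log2 intensity |
| `n_mirnas` | 60 | miRNA universe |
| `n_hub_lncrnas`, `hub_degree` | 5, 8 | planted hubs and their sponge degree |
| `bg_interaction_prob` | 0.01 | background interaction rate |
| `db_overlap_frac` | 0.5 | background pairs present in both target DBs |
| `n_gene_sets`, `set_size_range` | 50, 15–50 | gene-set library |
| `n_enriched_sets` | 3 | sets planted over the DE mRNAs |

Source studies of this design rarely publish effect-size or variance
estimates, so `effect_size = 2` and `noise_sd = 0.5` are this package's
choices: a four-standard-deviation mean shift is a clearly-detectable but
not caricatured microarray effect at n = 20 per group, and it makes the
planted regime a meaningful probe of FDR control rather than a triviality.
Noise is Gaussian on the log2 scale — the simplest model consistent with
the t-test's assumptions, and the scale on which the pipeline operates.
Planted hub-supporting miRNA–mRNA pairs are written to both target
databases so that hubs survive the validated-by-both rule by
construction; background pairs obey `db_overlap_frac`. Hub lncRNAs
receive no background partners, so a hub's sponge degree is exactly
`hub_degree`. Gene symbols are synthetic (`MRNA0001`, `LNC0001`,
`MIR0001`) to avoid implying claims about real genes.

The qPCR generator defaults mirror a typical validation cohort — one
15-donor control group and three case groups of 9, 17 and 7 — with three
technical replicates, replicate noise of 0.25 cycles, a reference gene
near Ct 20 and targets near Ct 25; case-group target Ct is shifted by
`−log2(fold change)` so quantification recovers the plant.

What the generator does **not** emulate: probe-level hybridization
physics, batch or array-spatial artifacts, heavy-tailed noise,
correlation between genes, or realistic identifier vocabularies. Passing
tests therefore demonstrate correctness of the *computations* and
calibration under the stated noise model — not robustness to every
pathology of real microarray data.

## Numerical and determinism choices

- Quantile-normalization ties take the mean of the target values their
  ranks span; the operation is idempotent to machine precision.
- `log2_transform()` refuses to run twice (a double-log guard) and
  refuses non-positive values under the log.
- All generator randomness is scoped with `withr::with_seed`; the four
  generators draw from fixed offsets of the configured seed, so
  regenerating any one input does not depend on call order.
- Network node and edge tables are kept in a canonical sort; exports of
  the same network are byte-identical, and two pipeline runs with the same
  seed differ only in timestamps (manifest and log).
- Identifier matching in interaction tables is exact string equality
  after whitespace trimming; cross-vocabulary mappings (e.g. miRNA family
  labels vs mature names) are never guessed — an explicit alias map can
  be supplied and applied with `apply_alias_map()`.

## Problem sizes used by the tests

The shipped test-bed measures statistical behaviour at deliberately
desk-sized scales, chosen as the smallest instances where the quantities
of interest are stable: FDR/power at 1,000 genes × 40 samples over 50
seeds (10% planted effects), null calibration at 5,000 genes, hub and
enrichment recovery over 20 seeds of ~120–200-gene studies, and network
invariants over 100 random instances. `scripts/acceptance.R` recomputes
all of these from scratch at the same sizes.

## Known limitations

- Degree is the only hub criterion, matching the screen this design
  follows; no betweenness or statistical ceRNA-pair test is included.
- No moderated-variance (empirical-Bayes) DE: with ≥ 10 samples per
  group, gene-wise Welch tests are adequately powered, and the simple
  test keeps the oracle story exact.
- Counts reported by published screens of this kind depend on specific
  database versions and accessions; this package reproduces the *method*,
  and its quantitative guarantees are stated against planted synthetic
  truth.
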