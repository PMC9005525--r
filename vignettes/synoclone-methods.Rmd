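---
title: "Methods: paired blood/synovial-fluid single-cell analysis with synoclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired blood/synovial-fluid single-cell analysis with synoclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synoclone)
```

# Scope and design

`synoclone` implements a complete analysis pipeline for paired
peripheral-blood (PB) and synovial-fluid (SF) single-cell RNA-seq with
matched single-cell TCR-seq, of the kind used to study inflammatory
arthritis as an immune-related adverse event of checkpoint-inhibitor
therapy. The pipeline covers:

* quality control and multi-step doublet flagging,
* normalization, graph-based clustering and marker-rule annotation,
* clonotype calling, clonal expansion, and cluster-pair repertoire-overlap
  testing,
* ligand-receptor interaction calling from a curated pair list, and
* the closed-form immune-assay scores used alongside such studies
  (Treg percent suppression, bead-standardized migration ratio, CDAI).

Patient-derived datasets of this kind are under controlled access, so the
package ships a synthetic-data generator that emulates the paired-sample
study structure with planted, machine-checkable ground truth. Every claim
the test suite makes is a property of that generator's output, not of any
patient dataset; what passing tests show about real data is discussed at
the end.

# The synthetic generator

`generate_dataset()` draws a genes-by-cells UMI matrix, per-cell metadata,
and a V(D)J contig table from explicit specifications.

**Counts.** Each cluster's expression is negative binomial per gene:
signature genes at `signature_mean` (default 5 expected UMIs), everything
else at `background_mean` (default 0.005), with NB size `dispersion`
(default 2). The NB is the standard overdispersed model for UMI counts,
and makes dispersion a testable knob. The low cross-cluster background is
a deliberate choice: hybrid-marker doublet detection (below) counts
off-lineage genes at UMI > 0, and the detector's advertised specificity is
a property of how rarely a singlet expresses another cluster's markers.
The default panel is small (a marker panel plus ~150 background filler
genes and three mitochondrial genes), so per-cell gene counts are tens,
not thousands; QC gene-count bounds must be read against the panel in use.

**Compartments.** Each patient contributes `n_cells_per_sample` cells per
cluster, assigned to SF with probability `compartment_bias` — this models
clusters "distinctly present" in blood or joint fluid, e.g. a
blood-enriched CX3CR1-high effector CD8 cluster (bias 0.15) versus a
synovial-enriched CXCR3-high cluster (bias 0.85) in the demo.

**Doublets.** A doublet is the gene-wise sum of two randomly chosen parent
cells from different clusters, appended at `doublet_rate` times the
singlet count (the generator accepts rates up to 0.2; the demo uses 0.05).
This matches the two signals the flagging procedure exploits: hybrid
marker content and an inflated library.

**TCR contigs.** Only T-lineage clusters receive contigs. A configurable
fraction of each T cluster's cells (default 0.69, matching the reported
fraction of CD3+ T cells with at least one productive chain in the study
design this emulates) carries a clone. A clone is a paired TRA+TRB chain
signature (V gene, J gene, CDR3 nucleotide sequence); clone sizes are
geometric (`1 + rgeom(p)`, default p = 0.5). Per-cluster expansion
distributions are not reported in the literature this emulates, so the
geometric is a modeling choice, not an inference. Sharing specs plant
`n_shared_clones` clones with at least one cell in each cluster of a pair:
one cell per side is reserved first, then expansion extras are allocated,
so planted shared counts are exact in the emitted table. Nonproductive
contigs are extra rows on existing cells (clonotype calling discards them,
so they perturb nothing), and multi-chain clones (an extra TRB) are
planted only as private clones so they cannot silently break planted
sharing counts.

**Ligand-receptor planting.** LR genes are expressed only where a plant
spec says so, as Bernoulli(on-fraction) times a positive count. Positive
pairs must have both on-fractions above the caller's 0.20 threshold and
decoys at least one at or below it, which is what makes exact
recovery (no false positives, no false negatives) a meaningful test.

All randomness flows from one integer seed through a single local RNG
(`with_seed()`), and fixture serialization is byte-deterministic.

# Quality control and doublet flagging

`compute_cell_qc()` reports genes detected, total UMIs, and the
mitochondrial percentage (gene symbols with prefix `MT-`,
case-insensitive; the mito gene list itself is not standardized, so prefix
matching is the convention used). Cells with zero UMIs get 0% mito — they
are removed by the gene filter regardless.

`apply_qc_filters()` removes cells with fewer than 200 detected genes
(debris, empty drops), more than 6500 (likely multiplets), or more than
15% mitochondrial UMIs (dying cells). All three comparisons are strict, so
boundary cells (exactly 200 genes, exactly 15.0%) are retained; rules
combine as a union and the filter is idempotent.

`flag_doublets()` applies the four-step union: (1) the high-complexity
rule again; (2) hybrid markers — a cell whose cluster has lineage L but
which expresses at least `k_hybrid = 2` genes of a different lineage set
at UMI > 0 (one gene is too noisy for UMI data; two is the default, and
the count is exposed); (3) hybrid clusters — a cluster whose cells are
positive for two or more lineage sets is flagged wholesale; (4) an
optional externally computed doublet score above a cutoff. External
doublet scoring algorithms are deliberately not re-implemented; the score
is an input column, so any algorithm can feed step 4. The procedure
iterates — flags change cluster positivity, which can create new flags —
until a fixed point (the iteration count in the underlying procedure is
not standardized; `max_iter` defaults to 5). A cluster positive for no
lineage set is an error by default; `run_pipeline()` instead flags such
clusters wholesale (`unassigned_action = "flag"`), since a lineage-less
cluster in a clustered dataset is the signature of a doublet cluster.

# Normalization and clustering

Counts are library-size scaled to 10,000 and log-transformed. Base 2 is
used so that expression units are `log2(normalized UMI + 1)` everywhere,
matching the unit in which the interactome threshold is defined. The
scheme itself (scale + log) is the de-facto standard; no claim is made
that it is uniquely correct.

`cluster_cells()` runs: highly-variable-gene selection by
variance-stabilized dispersion rank (observed variance over a loess trend
of log-variance on log-mean; with small panels the trend is unstable and
plain variance ranking is used), per-gene z-scaling clipped at ±10 to
bound outlier leverage, PCA, a k-nearest-neighbor graph in PC space, a
shared-nearest-neighbor graph with Jaccard weights (self counted as a
neighbor, edges below 1/15 pruned), and Louvain modularity optimization at
the requested resolution. Any modularity-with-resolution community
detector satisfies the package's determinism and recovery properties;
Louvain via igraph is the implementation. Cells are internally sorted by
barcode before graph construction, so the partition is invariant to input
column order, and labels `C1, C2, ...` are assigned by decreasing cluster
size.

Three presets carry the round parameters used in the emulated design:
major round (40 PCs, 200 neighbors, resolution 0.6), NK/NKT/T
subclustering (30, 30, 0.8), and Treg subclustering (30, 30, 0.1).
Principal-component counts are parameters, not automated elbow detection —
the choice of 40/30/30 is an input to this package, not something it
re-derives. `subcluster()` reruns the pipeline on a label subset and
namespaces the result by parent. On the bundled ~2,000-cell fixtures the
tests run the major round with `k_neighbors = 30`, since 200 neighbors is
calibrated to datasets two orders of magnitude larger.

# Markers, annotation, composition

`find_markers()` tests each cluster against the rest per gene (genes
expressed in at least 20% of either side) with a Wilcoxon rank-sum test on
log-normalized values: exact enumeration of group assignments for very
small datasets (at most 16 cells, where enumeration is cheap and handles
ties exactly), otherwise the tie-corrected normal approximation. The
rank-sum test is the conventional default for scRNA-seq DE; log2 fold
change is the difference of group means in log2 space; q-values are
Benjamini-Hochberg across all tests jointly.

`annotate_clusters()` is deliberately declarative: a rule is a label with
required and forbidden marker genes, and a cluster gets the unique rule
all of whose required genes are significant markers (q < 0.05, fold change
above the rule's minimum) with no forbidden gene significant. Two matching
rules give `"ambiguous"`, none gives `"unassigned"` — annotation never
guesses.

`compartment_composition()` computes per-sample cluster fractions (summing
to 1 by construction) and compares compartments per cluster with a
two-sided paired t test across patients (or unpaired when pairing is
unavailable); with three or more groups it switches to one-way ANOVA with
Bonferroni-adjusted pairwise t tests.

# Repertoire overlap

`call_clonotypes()` keeps only productive contigs and defines clone
identity as exact equality of the (chain, V, J, CDR3-nucleotide) signature
set — the conservative reading of repertoire identity; no fuzzy CDR3
matching. Cells carrying extra productive chains form their own
multi-chain clones unless signatures match exactly; cells with no
productive chain are dropped. Clonal fraction is a clone's share of the
clone-bearing cells in a sample. `top_expanded()` ranks clones per
compartment (or per sample — the scoping convention is not standardized,
so both are exposed) with deterministic tie-breaks: larger total count
first, then lexicographic clone id.

`overlap_test()` is the statistical core. For each unordered cluster pair,
the 2x2 table is `[[shared, A-only], [B-only, universe - union]]` over the
dataset's clone universe, and the one-sided enrichment p-value is the
hypergeometric upper tail — exactly the one-sided Fisher exact test.
The table construction over the clone universe is this package's
normative choice (the construction is typically left unstated in figure
legends); it, the one-cell occupancy threshold, and the q < 0.05
significance cutoff are all parameters. BH correction runs across all
tested pairs. Under the matched null (clones assigned to clusters
independently), the fraction of simulations with any significant pair
stays within the FDR budget; with 20 clones planted as shared between one
pair in a ~500-clone universe the planted pair is the top-q pair at
q < 0.05 in at least 19 of 20 seeds. Note that pair-level significance
requires the universe to be large relative to the per-cluster
repertoires: in the 6-cluster demo, where only three T clusters carry the
whole universe, the expected chance overlap is already large and the
planted pair is (correctly) not called significant — the 10-cluster
benchmark specs (`sharing_benchmark_specs()`) provide the regime where the
test has power.

# Interactome

A gene is "expressed" in a cluster when strictly more than 20% of its
cells have `log2(normalized UMI + 1) > 0`; both cuts are strict as
printed in the convention this implements, and the boundary case (exactly
20%) is tested. `match_lr_pairs()` emits a call when the ligand is
expressed in the sender and the receptor in the receiver, both directions,
self-pairs allowed, with optional role restrictions. The interaction score
is the product of mean log-normalized ligand and receptor expression —
a package-defined surrogate that preserves the intended semantics
(stronger both-sided expression scores higher, and the score is zero
exactly when either side is silent); it is documented as a surrogate
because the original scoring method's formula is external to the sources
this package works from. No separate significance test is attached to
threshold calls; significance semantics come from the differential
interactome, which matches significant cluster DEGs (q < 0.05) against the
pair list and annotates which side is differential. A minimal chemokine
pair list (CXCL9/10/11-CXCR3, CXCL16-CXCR6, CX3CL1-CX3CR1) ships for
demos; real analyses should supply a full curated list as TSV.

# Assay scores

* `percent_suppression(with, without)` = `100 - 100 * with / without`.
  Negative values (enhancement of proliferation by Tregs) are biologically
  meaningful and returned unclamped; the score is undefined at
  `without = 0`.
* `migration_ratio()` divides bead-standardized migrated-cell events in
  the chemokine condition by the control condition; it is invariant to
  rescaling both bead counts together.
* `cdai()` sums patient global (0-10), physician global (0-10), and
  swollen/tender 28-joint counts. The attainable maximum is 76 (the
  component maxima sum to 76, and that is the definition used here, even
  though a 0-72 range is sometimes quoted alongside the same components).
  Bands use half-open intervals [0, 2.8], (2.8, 10], (10, 22], (22, Inf),
  which are exhaustive and mutually exclusive over all attainable totals;
  integer totals always fall in the printed bands.
* `paired_compare()` provides the one-sided Wilcoxon matched-pairs
  signed-rank test — zeros dropped (the classic treatment), exact p by
  enumeration of all 2^n sign assignments for up to 15 informative pairs,
  tie-corrected normal approximation with continuity correction above —
  and the two-sided paired t test, with identical inputs handled as the
  degenerate p = 1 case.

# Pipeline, determinism, problem sizes

`run_pipeline()` executes read → QC → clustering → doublet removal →
markers/annotation → clonotypes/overlap → interactome from a YAML config,
writing TSVs plus a `manifest.json` of parameters, seed and input/output
checksums; stage failures leave prior outputs and an `error.json`. Two
runs with the same config and seed produce byte-identical TSVs. Optional
inputs (LR list, marker rules, contigs) switch their stages off with a
logged notice rather than failing.

The demo (`make_demo()`) generates the default fixture: 6 clusters x 8
patients x 40 cells with 5% doublets (~2,000 cells, ~200-gene panel). Its
config scales QC gene bounds to that panel (a 200-gene minimum is
meaningless when the panel itself is ~200 genes) while package defaults
keep the full-transcriptome values. Test and acceptance problem sizes —
~2,000-cell clustering fixtures, 20-seed sharing recovery over ~500-clone
universes, 200 null simulations, exhaustive Fisher enumeration to
universe 30 — were chosen to exercise each property at the smallest scale
where it is statistically meaningful.

# What passing tests do and do not show

The generator plants well-separated NB clusters, disjoint marker panels,
independent cells, and batch-free samples. Passing recovery tests
therefore validate the *machinery* — filters cut where they claim,
the clustering pipeline recovers separable structure deterministically,
the overlap test matches its exact oracle, planted truth is recovered
without false calls. They do not certify performance on real tissue:
real data has correlated programs (cell cycle, stress), ambient RNA,
batch effects (the pipeline exposes a hook where batch correction would
sit; correction itself is out of scope), doublets between
transcriptionally similar subtypes that hybrid-marker logic cannot see,
and clone-phenotype correlations subtler than planted sharing. The
statistical components (Fisher/BH, Wilcoxon variants, t tests) carry
their guarantees to real data; the recovery rates do not.
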