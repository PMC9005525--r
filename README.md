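# synoclone

Paired blood/synovial-fluid single-cell transcriptome and TCR repertoire
analysis, as a tested, reusable R pipeline.

## The problem

In inflammatory arthritis arising as an immune-related adverse event of
checkpoint-inhibitor cancer therapy, the central questions are *which*
immune populations accumulate in the joint, *whether* the expanded T-cell
clones in synovial fluid (SF) are the same clones circulating in
peripheral blood (PB), and *what* recruits them. Answering these from
paired PB/SF single-cell RNA-seq plus single-cell TCR-seq requires a
chain of analyses: QC and doublet removal, clustering and marker-based
annotation, clonotype calling and repertoire-overlap testing,
ligand-receptor interaction inference, and the closed-form scores of the
accompanying functional assays. `synoclone` implements that chain for
analysts working with this study design, together with a synthetic-data
generator with planted ground truth so every stage is testable without
controlled-access patient data.

## The statistics at the core

**Repertoire overlap.** Clonotypes are defined by exact paired-chain
identity (V gene, J gene, CDR3 nucleotide sequence per productive chain).
For clusters *A* and *B* over a clone universe of size *N*, the overlap
test is a one-sided Fisher's exact test on

    [[ shared,            A-only         ],
     [ B-only,  N - |A ∪ B|              ]]

whose enrichment p-value is the hypergeometric upper tail
P[X ≥ shared | N, |A|, |B|], followed by Benjamini-Hochberg FDR control
across all cluster pairs (significant at q < 0.05).

**Interactome.** A ligand or receptor is "expressed" in a cluster when
strictly more than 20% of cells have log2(normalized UMI + 1) > 0; a call
(L, R, sender → receiver) is emitted when both sides pass, and scored by
the product of mean log-normalized expression.

**Assay scores.** Percent suppression = 100 − 100 · (% responding with
Treg)/(% responding without Treg); migration ratio =
(events_chemokine/beads_chemokine)/(events_control/beads_control); CDAI =
patient global (0–10) + physician global (0–10) + swollen (0–28) +
tender (0–28), banded remission ≤ 2.8 < low ≤ 10 < moderate ≤ 22 < high.
Paired comparisons use the exact one-sided Wilcoxon signed-rank test
(full 2^n sign-assignment enumeration for n ≤ 15) or the paired t test.

## Worked example

```r
library(synoclone)

demo <- make_demo("demo", seed = 1)   # synthetic paired PB/SF study
res  <- run_pipeline(demo$config)
```

The demo generates 6 immune clusters across 8 patients (~2,000 cells, 5%
planted doublets), then runs the full pipeline, logging:

```
[synoclone] QC: 2016 cells in, 101 removed, 1915 kept
[synoclone] clustering: 6 clusters over 1915 cells
[synoclone] doublets: 105 flagged, 1810 cells retained
[synoclone] annotation: C1=CXCR3hi effector CD8 T, C2=Myeloid,
            C3=CX3CR1hi effector CD8 T, C4=NK, C5=CD4 T, C6=B cells
[synoclone] repertoire: 303 clones, 0 significant cluster pairs
[synoclone] interactome: 4 calls
```

All six planted lineages are recovered and annotated. The interactome
calls are exactly the planted chemokine axes — myeloid ligands to the
synovial-enriched CXCR3-high effector CD8 cluster — with the planted
CX3CL1/CX3CR1 decoy (receptor below threshold) correctly absent:

```r
res$interactions[, c("ligand", "receptor", "sender", "receiver", "score")]
#>   ligand receptor sender receiver    score
#> 1  CXCL9    CXCR3     C2       C1 25.50972
#> 2 CXCL10    CXCR3     C2       C1 25.01121
#> 3 CXCL11    CXCR3     C2       C1 24.21957
#> 4 CXCL16    CXCR6     C2       C1 13.57127
```

The two effector CD8 clusters share 19 of the 20 planted clones after QC:

```r
head(res$overlap[order(res$overlap$q_bh), ], 1)
#>   cluster_a cluster_b n_shared n_clones_a n_clones_b p_one_sided q_bh
#> 1        C1        C3       19        104        103   0.9999954    1
```

Note the pair is *not* statistically significant here: with only three
T clusters carrying a 303-clone universe, an overlap of 19 is below the
chance expectation. Pair-level significance needs a universe large
relative to each cluster's repertoire — `sharing_benchmark_specs()`
builds that regime (10 T clusters, ~500 clones), where the planted pair
is the top hit at q < 1e-5.

The assay scores are closed-form:

```r
percent_suppression(20, 80)               # 75
migration_ratio(300, 150, 10000, 20000)   # 4
cdai(5, 5, 6, 6)                          # CDAI 22.0 (moderate)
paired_compare(c(42,35,28,40,31,37,33),
               c(30,28,25,31,30,29,30),
               "wilcoxon_one_sided")      # W = 0, p = 1/2^7 = 0.0078125
```

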