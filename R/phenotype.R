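# Normalization, graph-based clustering, cluster markers, declarative
# marker-rule annotation, and compartment composition statistics.

#' Library-size normalization and log transform
#'
#' Per cell, counts are scaled to `scale` total UMIs and log-transformed:
#' `log2(x / total_umis * scale + 1)`. Cells with zero total UMIs map to all
#' zeros. Log base 2 is used so expression units are `log2(normalized UMI + 1)`
#' throughout the package.
#'
#' @param matrix a `cell_gene_matrix` (raw counts).
#' @param scale library-size scale factor.
#' @return sparse matrix (genes x cells) of log2-normalized expression.
#' @export
normalize_log <- function(matrix, scale = 1e4) {
  m <- matrix$counts
  total <- Matrix::colSums(m)
  fac <- ifelse(total > 0, scale / total, 0)
  norm <- m %*% Matrix::Diagonal(x = fac)
  norm <- methods::as(norm, "CsparseMatrix")
  norm@x <- log2(norm@x + 1)
  dimnames(norm) <- dimnames(m)
  norm
}

#' Clustering parameters
#'
#' Bundles the knobs of one clustering round. The three named presets carry
#' the parameter sets used for the major round (40 PCs, 200 neighbors,
#' resolution 0.6), the NK/NKT/T subclustering round (30, 30, 0.8), and the
#' Treg subclustering round (30, 30, 0.1).
#'
#' @param n_pcs number of principal components.
#' @param k_neighbors neighbors for the kNN/SNN graph.
#' @param resolution modularity resolution parameter.
#' @param n_hvg number of highly variable genes.
#' @param seed integer seed for community detection.
#' @param round optional preset: `"major"`, `"nk_t_sub"`, or `"treg_sub"`;
#'   when given, unset parameters take the preset's values.
#' @return a `clustering_params` object.
#' @export
clustering_params <- function(n_pcs = NULL, k_neighbors = NULL,
                              resolution = NULL, n_hvg = 2000, seed = 1,
                              round = NULL) {
  presets <- list(
    major = list(n_pcs = 40, k_neighbors = 200, resolution = 0.6),
    nk_t_sub = list(n_pcs = 30, k_neighbors = 30, resolution = 0.8),
    treg_sub = list(n_pcs = 30, k_neighbors = 30, resolution = 0.1)
  )
  if (!is.null(round)) {
    if (!round %in% names(presets)) {
      stopf("unknown round '%s' (use %s)", round,
            paste(names(presets), collapse = ", "))
    }
    p <- presets[[round]]
    n_pcs <- n_pcs %||% p$n_pcs
    k_neighbors <- k_neighbors %||% p$k_neighbors
    resolution <- resolution %||% p$resolution
  }
  if (is.null(n_pcs) || is.null(k_neighbors) || is.null(resolution)) {
    stopf("n_pcs, k_neighbors and resolution must be set (directly or via a round preset)")
  }
  stopifnot(n_pcs >= 1, k_neighbors >= 1, resolution > 0, n_hvg >= 1)
  if (n_pcs > n_hvg) stopf("n_pcs must not exceed n_hvg")
  structure(
    list(n_hvg = n_hvg, n_pcs = n_pcs, k_neighbors = k_neighbors,
         resolution = resolution, seed = as.integer(seed),
         round = round %||% "custom"),
    class = "clustering_params"
  )
}

# HVG selection: variance-stabilized dispersion ranking. A loess trend of
# log-variance on log-mean is fit across genes; genes are ranked by observed /
# trend variance. With few genes (no stable trend) plain variance is used.
select_hvg <- function(norm, n_hvg) {
  mu <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- pmax(ex2 - mu^2, 0) * ncol(norm) / max(1, ncol(norm) - 1)
  keep <- which(v > 0 & mu > 0)
  if (!length(keep)) return(character(0))
  score <- rep(-Inf, nrow(norm))
  if (length(keep) >= 30) {
    fit <- tryCatch(
      loess(log10(v[keep]) ~ log10(mu[keep]), span = 0.3, degree = 2),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      score[keep] <- v[keep] / 10^predict(fit)
    } else {
      score[keep] <- v[keep]
    }
  } else {
    score[keep] <- v[keep]
  }
  ord <- order(score, decreasing = TRUE)
  rownames(norm)[ord[seq_len(min(n_hvg, length(keep)))]]
}

# z-score per gene across cells, clipped at +/- clip to bound outlier
# leverage before PCA.
scale_clip <- function(norm, genes, clip = 10) {
  x <- as.matrix(norm[genes, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  sdv[sdv == 0] <- 1
  z <- (x - mu) / sdv
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

# kNN (excluding self) by Euclidean distance in PC space; ties broken by
# column order for determinism.
knn_indices <- function(emb, k) {
  n <- nrow(emb)
  d2 <- as.matrix(stats::dist(emb))^2
  diag(d2) <- Inf
  t(apply(d2, 1, function(r) order(r)[seq_len(k)]))
}

# SNN graph with Jaccard weights over kNN sets (self included, as is
# conventional); edges with weight < prune are dropped.
snn_graph <- function(nn, prune = 1 / 15) {
  n <- nrow(nn)
  k <- ncol(nn) + 1L # self counts as a neighbor
  i <- rep(seq_len(n), each = ncol(nn) + 1L)
  j <- as.integer(t(cbind(seq_len(n), nn)))
  a <- Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(a)
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                      weighted = TRUE)
}

#' Cluster cells on an SNN graph by modularity optimization
#'
#' Pipeline: highly-variable-gene selection by variance-stabilized dispersion
#' rank, per-gene z-scaling clipped at +/-10, PCA, k-nearest-neighbor graph in
#' PC space, shared-nearest-neighbor (Jaccard-weighted) graph, and Louvain
#' modularity community detection at the requested resolution. Cell order is
#' canonicalized internally (cells sorted by barcode) so the partition is
#' invariant to input column permutation; cluster labels `C1, C2, ...` are
#' assigned in decreasing cluster size.
#'
#' @param normalized log-normalized matrix from [normalize_log()].
#' @param params a [clustering_params()] object.
#' @return a `cluster_assignment`: data.frame with columns `barcode`,
#'   `cluster`, with the round id and parameters in attributes.
#' @export
cluster_cells <- function(normalized, params) {
  stopifnot(inherits(params, "clustering_params"))
  n <- ncol(normalized)
  if (n < params$k_neighbors + 1) {
    stopf("need at least k_neighbors + 1 = %d cells, got %d",
          params$k_neighbors + 1, n)
  }
  ord <- order(colnames(normalized))
  norm <- normalized[, ord, drop = FALSE]

  hvg <- select_hvg(norm, params$n_hvg)
  if (!length(hvg)) stopf("no variable genes found")
  z <- scale_clip(norm, hvg)

  n_pcs <- params$n_pcs
  max_pcs <- min(nrow(z), ncol(z)) - 1L
  if (n_pcs > max_pcs) {
    warnf("reducing n_pcs from %d to %d (limited by data size)", n_pcs, max_pcs)
    n_pcs <- max_pcs
  }
  pca <- prcomp(t(z), center = FALSE, scale. = FALSE, rank. = n_pcs)
  emb <- pca$x[, seq_len(n_pcs), drop = FALSE]

  nn <- knn_indices(emb, params$k_neighbors)
  g <- snn_graph(nn)
  memb <- with_seed(params$seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = params$resolution))
  })
  # canonical labels: decreasing size, ties by first occurrence
  tab <- table(memb)
  sizes <- as.integer(tab)
  first <- vapply(names(tab), function(l) min(which(memb == l)), integer(1))
  lab_order <- names(tab)[order(-sizes, first)]
  relab <- setNames(paste0("C", seq_along(lab_order)), lab_order)
  out <- data.frame(barcode = colnames(norm),
                    cluster = unname(relab[as.character(memb)]),
                    stringsAsFactors = FALSE)
  out <- out[match(colnames(normalized), out$barcode), ]
  rownames(out) <- NULL
  structure(out, class = c("cluster_assignment", "data.frame"),
            round = params$round, params = params)
}

#' Subcluster a subset of clusters
#'
#' Runs [cluster_cells()] on only the cells assigned to `parent_labels`;
#' resulting labels are namespaced by the parent label set.
#'
#' @param normalized log-normalized matrix covering at least the parent cells.
#' @param assignment a `cluster_assignment` from a previous round.
#' @param parent_labels nonempty subset of `assignment`'s labels.
#' @param params a [clustering_params()] object.
#' @return a `cluster_assignment` for the subset cells.
#' @export
subcluster <- function(normalized, assignment, parent_labels, params) {
  if (!length(parent_labels)) stopf("parent_labels must be nonempty")
  unknown <- setdiff(parent_labels, unique(assignment$cluster))
  if (length(unknown)) stopf("unknown parent label(s): %s",
                             paste(unknown, collapse = ", "))
  bcs <- assignment$barcode[assignment$cluster %in% parent_labels]
  if (!length(bcs)) stopf("no cells under the given parent labels")
  sub <- cluster_cells(normalized[, bcs, drop = FALSE], params)
  prefix <- paste(sort(parent_labels), collapse = "+")
  sub$cluster <- paste0(prefix, ".", sub$cluster)
  attr(sub, "round") <- paste0("sub:", prefix)
  sub
}

# Wilcoxon rank-sum two-sided p for group membership `in_group` given
# precomputed ranks of one gene across all cells. Normal approximation with
# tie correction; exact enumeration over all group assignments when the total
# number of cells is small (<= exact_max).
ranksum_p <- function(ranks, in_group, exact_max = 16) {
  n <- length(ranks)
  n1 <- sum(in_group)
  n2 <- n - n1
  if (n1 == 0 || n2 == 0) return(NA_real_)
  w <- sum(ranks[in_group])
  ew <- n1 * (n + 1) / 2
  if (n <= exact_max) {
    combs <- combn(n, n1)
    ws <- colSums(matrix(ranks[combs], nrow = n1))
    return(mean(abs(ws - ew) >= abs(w - ew) - 1e-9))
  }
  ties <- table(ranks)
  tie_term <- sum(ties^3 - ties)
  varw <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (varw <= 0) return(1)
  z <- (w - ew) / sqrt(varw)
  2 * pnorm(-abs(z))
}

#' Cluster marker genes (cluster-vs-rest differential expression)
#'
#' For each cluster, genes expressed (UMI > 0) in at least `min_frac` of
#' in-cluster or of out-of-cluster cells are tested cluster-vs-rest with a
#' Wilcoxon rank-sum test on log-normalized values (exact enumeration for
#' very small datasets, tie-corrected normal approximation otherwise).
#' `log2_fc` is the difference of in/out means of log2-normalized expression.
#' Benjamini-Hochberg q-values are computed across all tests jointly.
#'
#' @param normalized log-normalized matrix.
#' @param assignment a `cluster_assignment`.
#' @param min_frac minimum expressing-cell fraction (in- or out-group) for a
#'   gene to be tested.
#' @param exact_max total-cell count at or below which the exact permutation
#'   null is enumerated.
#' @return `marker_result` data.frame with columns `gene`, `cluster`,
#'   `log2_fc`, `pct_in`, `pct_out`, `p_value`, `q_value`, sorted per cluster
#'   by q then decreasing |log2_fc|.
#' @export
find_markers <- function(normalized, assignment, min_frac = 0.2,
                         exact_max = 16) {
  cl <- setNames(assignment$cluster, assignment$barcode)[colnames(normalized)]
  levels <- sort(unique(cl))
  if (length(levels) < 2) stopf("need at least two clusters")
  x <- as.matrix(normalized)
  pos <- x > 0
  # per-gene ranks across all cells, computed once
  ranks <- t(apply(x, 1, rank))
  out <- list()
  for (cc in levels) {
    idx <- cl == cc
    if (sum(idx) < 3) {
      warnf("cluster '%s' has fewer than 3 cells; skipped", cc)
      next
    }
    pct_in <- rowMeans(pos[, idx, drop = FALSE])
    pct_out <- rowMeans(pos[, !idx, drop = FALSE])
    test_genes <- which(pct_in >= min_frac | pct_out >= min_frac)
    if (!length(test_genes)) next
    mean_in <- rowMeans(x[test_genes, idx, drop = FALSE])
    mean_out <- rowMeans(x[test_genes, !idx, drop = FALSE])
    pvals <- vapply(test_genes, function(g) {
      ranksum_p(ranks[g, ], idx, exact_max = exact_max)
    }, numeric(1))
    out[[cc]] <- data.frame(
      gene = rownames(x)[test_genes], cluster = cc,
      log2_fc = mean_in - mean_out,
      pct_in = pct_in[test_genes], pct_out = pct_out[test_genes],
      p_value = pvals, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) stopf("no testable genes in any cluster")
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res <- res[order(res$cluster, res$q_value, -abs(res$log2_fc)), ]
  rownames(res) <- NULL
  class(res) <- c("marker_result", "data.frame")
  res
}

#' Marker rule for cluster annotation
#'
#' @param label cell-type label the rule assigns.
#' @param required genes that must all be significant markers of the cluster.
#' @param forbidden genes that must not be significant markers.
#' @param min_log2_fc minimum log2 fold change for a marker to count.
#' @return a `marker_rule` object.
#' @export
marker_rule <- function(label, required, forbidden = character(0),
                        min_log2_fc = 0.25) {
  stopifnot(is.character(label), length(label) == 1, length(required) >= 1)
  if (length(intersect(required, forbidden))) {
    stopf("rule '%s': required and forbidden genes overlap", label)
  }
  structure(list(label = label, required = required, forbidden = forbidden,
                 min_log2_fc = min_log2_fc),
            class = "marker_rule")
}

#' Read marker rules from a YAML file
#'
#' Expected structure: a list of entries with fields `label`, `required`,
#' optional `forbidden` and `min_log2_fc`.
#'
#' @param path YAML file path.
#' @return list of [marker_rule()] objects.
#' @export
read_marker_rules <- function(path) {
  raw <- yaml::read_yaml(path)
  lapply(raw, function(r) {
    marker_rule(label = r$label,
                required = as.character(r$required),
                forbidden = as.character(r$forbidden %||% character(0)),
                min_log2_fc = r$min_log2_fc %||% 0.25)
  })
}

#' Annotate clusters with declarative marker rules
#'
#' A cluster's significant markers are the genes with `q_value < q_cutoff`
#' and `log2_fc >= min_log2_fc` (per rule). Each cluster receives the label
#' of the unique rule whose required genes are all significant markers and
#' none of whose forbidden genes are; clusters matching several rules get
#' `"ambiguous"`, clusters matching none get `"unassigned"`.
#'
#' @param markers a `marker_result` from [find_markers()].
#' @param rules list of [marker_rule()] objects with unique labels.
#' @param q_cutoff marker significance cutoff.
#' @return named character vector: cluster label to cell-type label.
#' @export
annotate_clusters <- function(markers, rules, q_cutoff = 0.05) {
  labels <- vapply(rules, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stopf("duplicate rule labels")
  clusters <- sort(unique(markers$cluster))
  out <- setNames(character(length(clusters)), clusters)
  for (cc in clusters) {
    sub <- markers[markers$cluster == cc, ]
    hits <- vapply(rules, function(r) {
      sig <- sub$gene[sub$q_value < q_cutoff & sub$log2_fc >= r$min_log2_fc]
      all(r$required %in% sig) && !any(r$forbidden %in% sig)
    }, logical(1))
    out[cc] <- if (sum(hits) == 1) labels[hits] else if (sum(hits) > 1) "ambiguous" else "unassigned"
  }
  out
}

#' Cluster composition by compartment, with per-cluster tests
#'
#' Computes, per sample, the fraction of the sample's cells in each cluster,
#' then compares fractions between compartments per cluster: a two-sided
#' paired t test across patients when `paired = TRUE` (requires both
#' compartments for every patient), otherwise an unpaired two-sided t test.
#' With three or more groups a one-way ANOVA is run per cluster and
#' Bonferroni-adjusted pairwise t tests are attached.
#'
#' @param assignment a `cluster_assignment`.
#' @param cell_meta per-barcode metadata (`barcode`, `patient`,
#'   `compartment`, `sample_id`).
#' @param paired use a paired test across patients (two-group case only).
#' @param group metadata column defining the groups (default
#'   `"compartment"`).
#' @return list with `fractions` (sample x cluster data.frame) and `tests`
#'   (per-cluster data.frame with group means, SEMs, statistic and p-value;
#'   plus `pairwise` when more than two groups).
#' @export
compartment_composition <- function(assignment, cell_meta, paired = TRUE,
                                    group = "compartment") {
  meta <- cell_meta[match(assignment$barcode, cell_meta$barcode), ]
  df <- data.frame(sample_id = meta$sample_id, patient = meta$patient,
                   grp = meta[[group]], cluster = assignment$cluster,
                   stringsAsFactors = FALSE)
  tab <- table(df$sample_id, df$cluster)
  frac <- sweep(tab, 1, rowSums(tab), "/")
  samp <- unique(df[, c("sample_id", "patient", "grp")])
  samp <- samp[match(rownames(frac), samp$sample_id), ]
  groups <- sort(unique(samp$grp))
  clusters <- colnames(frac)

  sem <- function(x) sd(x) / sqrt(length(x))
  tests <- list()
  pairwise <- list()
  for (cc in clusters) {
    y <- frac[, cc]
    if (length(groups) == 2) {
      g1 <- y[samp$grp == groups[1]]
      g2 <- y[samp$grp == groups[2]]
      if (paired) {
        p1 <- samp$patient[samp$grp == groups[1]]
        p2 <- samp$patient[samp$grp == groups[2]]
        unmatched <- c(setdiff(p1, p2), setdiff(p2, p1))
        if (length(unmatched)) {
          stopf("paired comparison impossible; unmatched patient(s): %s",
                paste(unique(unmatched), collapse = ", "))
        }
        g2 <- g2[match(p1, p2)]
        d <- g1 - g2
        if (sd(d) == 0) {
          tt <- list(statistic = c(t = 0), p.value = 1)
        } else {
          tt <- t.test(g1, g2, paired = TRUE)
        }
      } else {
        if (sd(c(g1, g2)) == 0) {
          tt <- list(statistic = c(t = 0), p.value = 1)
        } else {
          tt <- t.test(g1, g2)
        }
      }
      tests[[cc]] <- data.frame(
        cluster = cc,
        mean_1 = mean(g1), mean_2 = mean(g2),
        sem_1 = sem(g1), sem_2 = sem(g2),
        statistic = unname(tt$statistic), p_value = tt$p.value,
        stringsAsFactors = FALSE
      )
    } else {
      fit <- aov(y ~ samp$grp)
      an <- summary(fit)[[1]]
      tests[[cc]] <- data.frame(
        cluster = cc, statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1],
        stringsAsFactors = FALSE
      )
      pw <- pairwise.t.test(y, samp$grp, p.adjust.method = "bonferroni",
                            pool.sd = FALSE)
      pairwise[[cc]] <- pw$p.value
    }
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  if (length(groups) == 2) {
    names(tests)[names(tests) %in% c("mean_1", "mean_2", "sem_1", "sem_2")] <-
      c(paste0("mean_", groups), paste0("sem_", groups))
  }
  out <- list(fractions = as.data.frame.matrix(frac), groups = groups,
              tests = tests)
  if (length(pairwise)) out$pairwise <- pairwise
  out
}
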