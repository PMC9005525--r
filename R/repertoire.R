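# Clonotype calling from contig tables, clonal expansion, and cluster-pair
# repertoire-overlap testing (one-sided Fisher's exact test with
# Benjamini-Hochberg FDR control).

#' Call clonotypes from a contig table
#'
#' Nonproductive contigs are discarded; each cell's chain signature is the
#' set of its retained (chain, V gene, J gene, CDR3 nucleotide) tuples, and
#' clone identity is exact signature equality. Cells carrying more than one
#' TRA or TRB keep all productive chains in the signature and therefore form
#' their own multi-chain clones unless signatures match exactly. Cells with
#' no productive chain are absent from the result.
#'
#' @param contigs a `contig_table` (see [read_contigs()]).
#' @param cell_meta optional per-barcode metadata with `barcode` and
#'   `sample_id`; enables per-sample counts and clonal fractions.
#' @return a `clonotype_table`: list with `clones` (data.frame `clone_id`,
#'   `signature`, `n_cells`, `n_chains`), `cells` (data.frame `barcode`,
#'   `clone_id`), and, when metadata is given, `sample_counts` (clone x
#'   sample matrix).
#' @export
call_clonotypes <- function(contigs, cell_meta = NULL) {
  prod <- contigs[contigs$productive %in% TRUE, , drop = FALSE]
  if (nrow(prod)) {
    key <- paste(prod$chain, prod$v_gene, prod$j_gene, prod$cdr3_nt, sep = "|")
    sig_by_cell <- vapply(split(key, prod$barcode), function(k) {
      paste(sort(unique(k)), collapse = ";")
    }, character(1))
  } else {
    sig_by_cell <- setNames(character(0), character(0))
  }
  sigs <- sort(unique(sig_by_cell))
  clone_ids <- setNames(sprintf("CT%05d", seq_along(sigs)), sigs)
  cells <- data.frame(barcode = names(sig_by_cell),
                      clone_id = unname(clone_ids[sig_by_cell]),
                      signature = unname(sig_by_cell),
                      stringsAsFactors = FALSE)
  cells <- cells[order(cells$barcode), ]
  rownames(cells) <- NULL
  n_cells <- table(factor(cells$clone_id, levels = clone_ids))
  clones <- data.frame(
    clone_id = unname(clone_ids), signature = sigs,
    n_cells = as.integer(n_cells[clone_ids]),
    n_chains = lengths(strsplit(sigs, ";", fixed = TRUE)),
    stringsAsFactors = FALSE
  )
  rownames(clones) <- NULL
  out <- list(clones = clones, cells = cells)
  if (!is.null(cell_meta)) {
    samp <- cell_meta$sample_id[match(cells$barcode, cell_meta$barcode)]
    if (anyNA(samp)) stopf("cell_meta does not cover all clone-bearing barcodes")
    out$sample_counts <- table(factor(cells$clone_id, levels = clones$clone_id),
                               samp)
  }
  structure(out, class = "clonotype_table")
}

#' @export
print.clonotype_table <- function(x, ...) {
  cat(sprintf("clonotype_table: %d clones over %d cells\n",
              nrow(x$clones), nrow(x$cells)))
  invisible(x)
}

#' Clonal fraction of each clonotype within a sample
#'
#' A clone's fraction is its cell count in the sample divided by the total
#' number of clone-bearing cells in that sample; fractions over clones sum
#' to 1 per sample.
#'
#' @param clonotypes a `clonotype_table` built with `cell_meta`.
#' @param sample_id sample to evaluate.
#' @return named numeric vector of fractions (clones with at least one cell
#'   in the sample).
#' @export
clonal_fraction <- function(clonotypes, sample_id) {
  if (is.null(clonotypes$sample_counts)) {
    stopf("clonotype_table lacks sample counts; call call_clonotypes() with cell_meta")
  }
  sc <- clonotypes$sample_counts
  if (!sample_id %in% colnames(sc)) stopf("unknown sample '%s'", sample_id)
  v <- sc[, sample_id]
  v <- v[v > 0]
  if (!sum(v)) stopf("sample '%s' has no clone-bearing cells", sample_id)
  v / sum(v)
}

#' Top expanded clones and their per-cluster distribution
#'
#' Ranks clones by cell count within each scope (compartment or sample) in
#' decreasing order; ties are broken by larger total cell count across all
#' scopes, then by lexicographic clone id. Returns the top `n` per scope
#' together with a clone-by-cluster cell-count matrix.
#'
#' @param clonotypes a `clonotype_table`.
#' @param assignment a `cluster_assignment` covering the clone-bearing cells.
#' @param cell_meta per-barcode metadata (`barcode`, `compartment`,
#'   `sample_id`).
#' @param n number of clones per scope (default 100, the "top 100 expanded
#'   clones" convention).
#' @param scope `"per_compartment"` or `"per_sample"`.
#' @return list with `top` (data.frame `scope`, `clone_id`, `n_cells`,
#'   `rank`) and `cluster_counts` (clone x cluster matrix over the selected
#'   clones).
#' @export
top_expanded <- function(clonotypes, assignment, cell_meta, n = 100,
                         scope = c("per_compartment", "per_sample")) {
  if (n <= 0) stopf("n must be positive")
  scope <- match.arg(scope)
  cells <- clonotypes$cells
  meta <- cell_meta[match(cells$barcode, cell_meta$barcode), ]
  scope_val <- if (scope == "per_compartment") meta$compartment else meta$sample_id
  total <- table(cells$clone_id)

  tops <- list()
  for (sv in sort(unique(scope_val))) {
    cnt <- table(cells$clone_id[scope_val == sv])
    if (!length(cnt)) next
    df <- data.frame(clone_id = names(cnt), n_cells = as.integer(cnt),
                     total = as.integer(total[names(cnt)]),
                     stringsAsFactors = FALSE)
    df <- df[order(-df$n_cells, -df$total, df$clone_id), ]
    df <- head(df, n)
    df$rank <- seq_len(nrow(df))
    df$scope <- sv
    tops[[sv]] <- df[, c("scope", "clone_id", "n_cells", "rank")]
  }
  top <- do.call(rbind, tops)
  rownames(top) <- NULL

  sel <- unique(top$clone_id)
  cl <- setNames(assignment$cluster, assignment$barcode)[cells$barcode]
  keep <- cells$clone_id %in% sel & !is.na(cl)
  cluster_counts <- table(factor(cells$clone_id[keep], levels = sel), cl[keep])
  list(top = top, cluster_counts = cluster_counts)
}

#' Cluster-pair shared-clonotype count matrix
#'
#' A clone occupies every cluster in which it has at least `min_cells`
#' member cells. Entry (i, j), i != j, counts clones present in both
#' clusters; the diagonal counts clones present in cluster i.
#'
#' @param clonotypes a `clonotype_table`.
#' @param assignment a `cluster_assignment`; clone-bearing cells without a
#'   cluster label are ignored.
#' @param min_cells member cells needed for a clone to occupy a cluster.
#' @return symmetric integer matrix (clusters x clusters).
#' @export
overlap_matrix <- function(clonotypes, assignment, min_cells = 1) {
  cells <- clonotypes$cells
  cl <- setNames(assignment$cluster, assignment$barcode)[cells$barcode]
  keep <- !is.na(cl)
  cnt <- table(cells$clone_id[keep], cl[keep])
  occ <- cnt >= min_cells
  m <- t(occ) %*% occ # clusters x clusters shared-clone counts
  storage.mode(m) <- "integer"
  as.matrix(m)
}

#' One-sided Fisher overlap test per cluster pair
#'
#' For every unordered cluster pair with clones on both sides, tests whether
#' the observed number of shared clonotypes exceeds what independent draws
#' from the clone universe would give. The 2x2 table is
#' \code{[[shared, A-only], [B-only, universe - union]]} and the one-sided
#' (enrichment) Fisher exact p-value is the hypergeometric upper tail
#' \code{P[X >= shared]} with the universe as population, cluster A's clones
#' as successes and cluster B's clone count as draws. Benjamini-Hochberg
#' q-values are computed across all tested pairs.
#'
#' @param overlap a matrix from [overlap_matrix()].
#' @param universe_size total number of distinct clonotypes in the dataset.
#' @param q_cutoff significance cutoff on BH q-values.
#' @return `overlap_result` data.frame with columns `cluster_a`, `cluster_b`,
#'   `n_shared`, `n_clones_a`, `n_clones_b`, `universe_size`, `p_one_sided`,
#'   `q_bh`, `significant`.
#' @export
overlap_test <- function(overlap, universe_size, q_cutoff = 0.05) {
  stopifnot(is.matrix(overlap), nrow(overlap) == ncol(overlap))
  cl <- colnames(overlap)
  diag_n <- diag(overlap)
  rows <- list()
  for (i in seq_along(cl)) {
    for (j in seq_along(cl)) {
      if (j <= i) next
      if (diag_n[i] == 0 || diag_n[j] == 0) next
      shared <- overlap[i, j]
      a <- diag_n[i]; b <- diag_n[j]
      if (shared > min(a, b)) {
        stopf("shared count %d exceeds min(|%s|, |%s|) = %d",
              shared, cl[i], cl[j], min(a, b))
      }
      if (a + b - shared > universe_size) {
        stopf("universe_size %d smaller than the union of pair (%s, %s)",
              universe_size, cl[i], cl[j])
      }
      p <- phyper(shared - 1, a, universe_size - a, b, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_a = cl[i], cluster_b = cl[j], n_shared = shared,
        n_clones_a = a, n_clones_b = b, universe_size = universe_size,
        p_one_sided = p, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stopf("no testable cluster pairs")
  res <- do.call(rbind, rows)
  res$q_bh <- p.adjust(res$p_one_sided, method = "BH")
  res$significant <- res$q_bh < q_cutoff
  rownames(res) <- NULL
  class(res) <- c("overlap_result", "data.frame")
  res
}
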