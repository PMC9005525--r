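# Reading the standard 10x-style inputs and the cell-filtering /
# multi-step doublet-flagging procedure.

new_cell_gene_matrix <- function(counts, gene_ids, gene_symbols, cell_meta) {
  stopifnot(nrow(counts) == length(gene_ids),
            nrow(counts) == length(gene_symbols))
  if (is.null(rownames(counts))) rownames(counts) <- gene_symbols
  bc <- as.character(colnames(counts) %||% character(0))
  if (anyDuplicated(bc)) stopf("duplicate barcodes in count matrix")
  stopifnot(identical(sort(bc), sort(as.character(cell_meta$barcode))))
  cell_meta <- cell_meta[match(bc, cell_meta$barcode), , drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(
    list(counts = counts, gene_ids = gene_ids, gene_symbols = gene_symbols,
         barcodes = bc, cell_meta = cell_meta),
    class = "cell_gene_matrix"
  )
}

#' @export
print.cell_gene_matrix <- function(x, ...) {
  cat(sprintf("cell_gene_matrix: %d genes x %d cells (%d samples)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id))))
  invisible(x)
}

#' Subset a cell-gene matrix to a set of barcodes
#'
#' @param matrix a `cell_gene_matrix`.
#' @param barcodes barcodes to keep (order preserved).
#' @return a `cell_gene_matrix` restricted to `barcodes`.
#' @export
subset_cells <- function(matrix, barcodes) {
  miss <- setdiff(barcodes, matrix$barcodes)
  if (length(miss)) stopf("unknown barcode(s): %s", paste(head(miss, 5), collapse = ", "))
  new_cell_gene_matrix(
    counts = matrix$counts[, barcodes, drop = FALSE],
    gene_ids = matrix$gene_ids, gene_symbols = matrix$gene_symbols,
    cell_meta = matrix$cell_meta[match(barcodes, matrix$cell_meta$barcode), , drop = FALSE]
  )
}

find_input_file <- function(dir_path, name) {
  plain <- file.path(dir_path, name)
  gz <- paste0(plain, ".gz")
  if (file.exists(plain)) plain else if (file.exists(gz)) gz else NA_character_
}

read_lines_any <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    readLines(con)
  } else {
    readLines(path)
  }
}

#' Read a 10x-convention count matrix directory
#'
#' Expects `matrix.mtx`, `barcodes.tsv` and `features.tsv` (gzipped variants
#' accepted transparently); `metadata.tsv` with columns `barcode`, `patient`,
#' `compartment`, `sample_id` is joined when present, otherwise metadata
#' fields are set to `"unknown"`.
#'
#' @param dir_path directory containing the matrix files.
#' @return a `cell_gene_matrix`.
#' @export
read_matrix <- function(dir_path) {
  if (!dir.exists(dir_path)) stopf("directory '%s' does not exist", dir_path)
  paths <- vapply(c("matrix.mtx", "barcodes.tsv", "features.tsv"),
                  function(nm) find_input_file(dir_path, nm), character(1))
  miss <- names(paths)[is.na(paths)]
  if (length(miss)) stopf("missing input file(s) in '%s': %s", dir_path,
                          paste(miss, collapse = ", "))
  m <- if (grepl("\\.gz$", paths[["matrix.mtx"]])) {
    con <- gzfile(paths[["matrix.mtx"]], "rt")
    on.exit(close(con), add = TRUE)
    Matrix::readMM(con)
  } else {
    Matrix::readMM(paths[["matrix.mtx"]])
  }
  m <- methods::as(m, "CsparseMatrix")
  barcodes <- read_lines_any(paths[["barcodes.tsv"]])
  feat_lines <- read_lines_any(paths[["features.tsv"]])
  feat <- if (length(feat_lines)) {
    do.call(rbind, strsplit(feat_lines, "\t", fixed = TRUE))
  } else {
    matrix(character(0), ncol = 2)
  }
  if (length(barcodes) != ncol(m)) {
    stopf("barcodes.tsv lists %d barcodes but matrix.mtx declares %d columns",
          length(barcodes), ncol(m))
  }
  if (nrow(feat) != nrow(m)) {
    stopf("features.tsv lists %d genes but matrix.mtx declares %d rows",
          nrow(feat), nrow(m))
  }
  if (anyDuplicated(barcodes)) stopf("duplicate barcodes in barcodes.tsv")
  gene_ids <- if (nrow(feat)) feat[, 1] else character(0)
  gene_symbols <- if (nrow(feat)) feat[, ncol(feat)] else character(0)
  dimnames(m) <- list(gene_symbols, barcodes)

  meta_path <- find_input_file(dir_path, "metadata.tsv")
  if (!is.na(meta_path)) {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
    need <- c("barcode", "patient", "compartment", "sample_id")
    miss <- setdiff(need, names(meta))
    if (length(miss)) stopf("metadata.tsv missing column(s): %s", paste(miss, collapse = ", "))
    miss_bc <- setdiff(barcodes, meta$barcode)
    if (length(miss_bc)) {
      extra <- data.frame(barcode = miss_bc, patient = "unknown",
                          compartment = "unknown", sample_id = "unknown",
                          stringsAsFactors = FALSE)
      meta <- rbind(meta[, need], extra)
    }
    meta <- meta[match(barcodes, meta$barcode), need]
  } else {
    meta <- data.frame(barcode = barcodes, patient = "unknown",
                       compartment = "unknown", sample_id = "unknown",
                       stringsAsFactors = FALSE)
  }
  new_cell_gene_matrix(m, gene_ids, gene_symbols, meta)
}

#' Read a V(D)J contig table
#'
#' Parses a TSV (or CSV) of per-chain contig records as emitted by standard
#' V(D)J alignment pipelines. `productive` is parsed as a logical; chains
#' other than TRA/TRB are retained and marked in a `non_abg_flag` column.
#'
#' @param path file path.
#' @return a `contig_table` data.frame with columns `barcode`, `chain`,
#'   `v_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa`, `productive`, `umis`,
#'   `non_abg_flag`.
#' @export
read_contigs <- function(path) {
  if (!file.exists(path)) stopf("contig file '%s' does not exist", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("barcode", "chain", "v_gene", "j_gene", "cdr3_nt", "cdr3_aa",
            "productive", "umis")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("contig table missing required column(s): %s",
                          paste(miss, collapse = ", "))
  df <- df[, need]
  if (!is.logical(df$productive)) {
    df$productive <- toupper(as.character(df$productive)) %in% c("TRUE", "T", "YES", "1")
  }
  df$umis <- as.integer(df$umis)
  df$non_abg_flag <- !(df$chain %in% c("TRA", "TRB"))
  class(df) <- c("contig_table", "data.frame")
  df
}

#' QC thresholds
#'
#' Defaults follow the filtering rules used throughout this pipeline: cells
#' aligned to fewer than 200 genes (low-complexity libraries), more than 6500
#' genes (likely doublets), or with more than 15 percent mitochondrial UMIs
#' (likely dying cells) are removed. All comparisons are strict, so boundary
#' cells are retained.
#'
#' @param min_genes,max_genes gene-count bounds (strict).
#' @param max_pct_mito mitochondrial-percentage bound (strict), in percent.
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes,
#'   matched case-insensitively.
#' @param external_doublet_cutoff optional cutoff for an externally computed
#'   doublet score (strict `>`).
#' @return a `qc_thresholds` object.
#' @export
qc_thresholds <- function(min_genes = 200, max_genes = 6500,
                          max_pct_mito = 15, mito_prefix = "MT-",
                          external_doublet_cutoff = NULL) {
  if (!(min_genes < max_genes)) stopf("min_genes must be < max_genes")
  if (!(max_pct_mito > 0 && max_pct_mito < 100)) {
    stopf("max_pct_mito must be in (0, 100)")
  }
  structure(
    list(min_genes = min_genes, max_genes = max_genes,
         max_pct_mito = max_pct_mito, mito_prefix = mito_prefix,
         external_doublet_cutoff = external_doublet_cutoff),
    class = "qc_thresholds"
  )
}

#' Per-cell QC metrics
#'
#' Computes, per barcode: the number of genes with at least one UMI, the
#' total UMI count, and the percentage of UMIs from mitochondrial genes
#' (identified by symbol prefix, case-insensitive). Cells with zero total
#' UMIs get `percent_mito = 0`.
#'
#' @param matrix a `cell_gene_matrix`.
#' @param thresholds a [qc_thresholds()] object (supplies `mito_prefix`).
#' @return data.frame with columns `barcode`, `genes_detected`, `total_umis`,
#'   `percent_mito`.
#' @export
compute_cell_qc <- function(matrix, thresholds = qc_thresholds()) {
  m <- matrix$counts
  genes_detected <- Matrix::colSums(m > 0)
  total <- Matrix::colSums(m)
  mito <- startsWith(toupper(matrix$gene_symbols), toupper(thresholds$mito_prefix))
  mito_umis <- if (any(mito)) Matrix::colSums(m[mito, , drop = FALSE]) else rep(0, ncol(m))
  pct <- ifelse(total > 0, 100 * mito_umis / total, 0)
  data.frame(barcode = colnames(m),
             genes_detected = as.integer(genes_detected),
             total_umis = as.numeric(total),
             percent_mito = as.numeric(pct),
             stringsAsFactors = FALSE)
}

#' Apply QC filters to a cell-gene matrix
#'
#' Removes cells failing any of: `genes_detected < min_genes`,
#' `percent_mito > max_pct_mito`, `genes_detected > max_genes` (union
#' semantics; all inequalities strict, boundary cells retained).
#'
#' @param matrix a `cell_gene_matrix`.
#' @param qc_table output of [compute_cell_qc()] covering all barcodes.
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `matrix` (filtered `cell_gene_matrix`) and `report`
#'   (a `filter_report`: counts removed per rule and jointly).
#' @export
apply_qc_filters <- function(matrix, qc_table, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  miss <- setdiff(matrix$barcodes, qc_table$barcode)
  if (length(miss)) stopf("qc_table does not cover %d barcode(s)", length(miss))
  qc <- qc_table[match(matrix$barcodes, qc_table$barcode), ]
  low <- qc$genes_detected < thresholds$min_genes
  high <- qc$genes_detected > thresholds$max_genes
  mito <- qc$percent_mito > thresholds$max_pct_mito
  removed <- low | high | mito
  report <- structure(
    list(n_input = length(removed),
         n_removed = sum(removed),
         n_kept = sum(!removed),
         by_rule = c(low_genes = sum(low), high_mito = sum(mito),
                     high_genes = sum(high))),
    class = "filter_report"
  )
  list(matrix = subset_cells(matrix, matrix$barcodes[!removed]),
       report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("QC filter: %d cells in, %d removed (%d low-gene, %d high-mito, %d high-gene), %d kept\n",
              x$n_input, x$n_removed, x$by_rule[["low_genes"]],
              x$by_rule[["high_mito"]], x$by_rule[["high_genes"]], x$n_kept))
  invisible(x)
}

#' Multi-step doublet flagging
#'
#' Flags likely doublets by the union of four rules: (1) high library
#' complexity (`genes_detected > max_genes`); (2) hybrid markers: a cell in a
#' cluster of lineage L expresses at least `k_hybrid` genes (UMI > 0) from a
#' different lineage marker set; (3) hybrid cluster: a cluster whose
#' (unflagged) cells are positive for two or more lineage sets is flagged
#' wholesale; (4) an optional external doublet score above a cutoff. The
#' procedure is iterated, recomputing cluster lineage on unflagged cells,
#' until no new flags appear.
#'
#' A cluster is "positive" for a lineage set when at least `lineage_fraction`
#' of its unflagged cells express one or more of the set's genes; its lineage
#' is the unique positive set. A cluster with no positive set raises an error
#' listing the unassigned clusters.
#'
#' @param matrix a `cell_gene_matrix`.
#' @param clusters named character vector (barcode to cluster label) or a
#'   `cluster_assignment`; must cover all barcodes.
#' @param lineage_marker_sets named list of character gene sets.
#' @param external_scores optional named numeric vector of per-barcode doublet
#'   scores.
#' @param k_hybrid off-lineage expressed-gene count that makes a cell hybrid.
#' @param max_genes high-complexity cutoff (strict `>`).
#' @param external_cutoff cutoff for `external_scores` (strict `>`).
#' @param lineage_fraction fraction of cells defining cluster positivity for
#'   a lineage set.
#' @param max_iter maximum flag/recompute iterations.
#' @param unassigned_action what to do with a cluster positive for no
#'   lineage set: `"error"` (default) or `"flag"`, which treats it as a
#'   hybrid cluster -- doublets are expected to form distinct clusters with
#'   mixed expression, so in pipeline context a lineage-less cluster is
#'   flagged wholesale rather than aborting the run.
#' @return data.frame with columns `barcode`, `cluster`,
#'   `flag_high_complexity`, `flag_hybrid_marker`, `flag_hybrid_cluster`,
#'   `flag_external`, `is_doublet`.
#' @export
flag_doublets <- function(matrix, clusters, lineage_marker_sets,
                          external_scores = NULL, k_hybrid = 2,
                          max_genes = 6500, external_cutoff = NULL,
                          lineage_fraction = 0.5, max_iter = 5,
                          unassigned_action = c("error", "flag")) {
  unassigned_action <- match.arg(unassigned_action)
  if (inherits(clusters, "cluster_assignment")) {
    clusters <- setNames(clusters$cluster, clusters$barcode)
  }
  bcs <- matrix$barcodes
  miss <- setdiff(bcs, names(clusters))
  if (length(miss)) stopf("clusters missing for %d barcode(s)", length(miss))
  cl <- clusters[bcs]
  if (!length(lineage_marker_sets) || is.null(names(lineage_marker_sets))) {
    stopf("lineage_marker_sets must be a named list of gene sets")
  }

  m_pos <- matrix$counts > 0
  sets <- lapply(lineage_marker_sets, function(g) intersect(g, matrix$gene_symbols))
  empty <- names(sets)[vapply(sets, length, integer(1)) == 0]
  if (length(empty)) {
    warnf("lineage set(s) with no genes in the matrix dropped: %s",
          paste(empty, collapse = ", "))
    sets <- sets[setdiff(names(sets), empty)]
  }
  if (length(sets) < 2) stopf("need at least two non-empty lineage marker sets")
  # per-cell count of expressed genes in each lineage set (sets x cells)
  set_counts <- do.call(rbind, lapply(sets, function(g) {
    Matrix::colSums(m_pos[g, , drop = FALSE])
  }))

  genes_detected <- Matrix::colSums(m_pos)
  flag_high <- genes_detected > max_genes

  flag_ext <- rep(FALSE, length(bcs))
  if (!is.null(external_scores) && !is.null(external_cutoff)) {
    sc <- external_scores[bcs]
    flag_ext <- !is.na(sc) & sc > external_cutoff
  }

  flag_hybrid_marker <- rep(FALSE, length(bcs))
  flag_hybrid_cluster <- rep(FALSE, length(bcs))
  cluster_lineage <- NULL
  cl_levels <- unique(cl)

  for (iter in seq_len(max_iter)) {
    flagged <- flag_high | flag_ext | flag_hybrid_marker | flag_hybrid_cluster
    # cluster positivity per lineage set on unflagged cells
    pos_mat <- matrix(FALSE, nrow = length(sets), ncol = length(cl_levels),
                      dimnames = list(names(sets), cl_levels))
    for (cc in cl_levels) {
      idx <- which(cl == cc & !flagged)
      if (!length(idx)) next
      frac <- rowMeans(set_counts[, idx, drop = FALSE] > 0)
      pos_mat[, cc] <- frac >= lineage_fraction
    }
    n_pos <- colSums(pos_mat)
    if (iter == 1) {
      unassigned <- cl_levels[n_pos == 0]
      if (length(unassigned) && unassigned_action == "error") {
        stopf("cluster(s) without a lineage assignment: %s",
              paste(unassigned, collapse = ", "))
      }
      cluster_lineage <- setNames(rep(NA_character_, length(cl_levels)),
                                  cl_levels)
    }
    upd <- cl_levels[n_pos >= 1]
    for (cc in upd) cluster_lineage[cc] <- names(sets)[which(pos_mat[, cc])[1]]
    # a cluster positive for >= 2 sets, or (in "flag" mode) for none, is
    # flagged wholesale as a hybrid cluster
    hybrid_levels <- cl_levels[n_pos >= 2]
    if (unassigned_action == "flag") {
      hybrid_levels <- c(hybrid_levels, cl_levels[n_pos == 0 & is.na(cluster_lineage)])
    }
    new_hybrid_cluster <- cl %in% hybrid_levels
    # hybrid-marker: >= k_hybrid expressed genes of an off-lineage set
    own <- cluster_lineage[cl]
    off_hit <- vapply(seq_along(bcs), function(i) {
      any(set_counts[setdiff(names(sets), own[i]), i] >= k_hybrid)
    }, logical(1))
    new_hybrid_marker <- off_hit & !new_hybrid_cluster

    changed <- any(new_hybrid_marker & !flag_hybrid_marker) ||
      any(new_hybrid_cluster & !flag_hybrid_cluster)
    flag_hybrid_marker <- flag_hybrid_marker | new_hybrid_marker
    flag_hybrid_cluster <- flag_hybrid_cluster | new_hybrid_cluster
    if (!changed) break
  }

  data.frame(
    barcode = bcs, cluster = unname(cl),
    flag_high_complexity = unname(flag_high),
    flag_hybrid_marker = unname(flag_hybrid_marker),
    flag_hybrid_cluster = unname(flag_hybrid_cluster),
    flag_external = unname(flag_ext),
    is_doublet = unname(flag_high | flag_hybrid_marker |
                          flag_hybrid_cluster | flag_ext),
    stringsAsFactors = FALSE
  )
}
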