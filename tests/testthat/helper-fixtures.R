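# Shared fixture builders for the test suite. All fixtures are generated in
# code; nothing is read from disk except files the tests themselves write.

# Dense matrix (with dimnames) -> cell_gene_matrix, with default metadata.
make_cgm <- function(counts, meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("cell%03d", seq_len(ncol(counts)))
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("G%03d", seq_len(nrow(counts)))
  }
  if (is.null(meta)) {
    meta <- data.frame(barcode = colnames(counts), patient = "P1",
                       compartment = "PB", sample_id = "P1_PB",
                       stringsAsFactors = FALSE)
  }
  synoclone:::new_cell_gene_matrix(
    counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
    gene_ids = rownames(counts), gene_symbols = rownames(counts),
    cell_meta = meta
  )
}

make_assignment <- function(barcodes, clusters) {
  structure(
    data.frame(barcode = barcodes, cluster = clusters,
               stringsAsFactors = FALSE),
    class = c("cluster_assignment", "data.frame")
  )
}

truth_assignment <- function(truth) {
  make_assignment(names(truth$cell_cluster), unname(truth$cell_cluster))
}

# Adjusted Rand index between two label vectors (mclust when present).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# Independent brute-force clone grouping: productive contigs -> per-barcode
# sorted chain-signature string.
brute_clone_signatures <- function(contigs) {
  prod <- contigs[contigs$productive, ]
  keys <- paste(prod$chain, prod$v_gene, prod$j_gene, prod$cdr3_nt, sep = "|")
  vapply(split(keys, prod$barcode),
         function(k) paste(sort(unique(k)), collapse = ";"), character(1))
}

# Hypergeometric upper-tail P[X >= shared] by direct enumeration of the pmf.
hyper_tail_oracle <- function(shared, a, b, universe) {
  ks <- shared:min(a, b)
  if (shared > min(a, b)) return(0)
  sum(choose(a, ks) * choose(universe - a, b - ks)) / choose(universe, b)
}

# Naive Benjamini-Hochberg step-up rule.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
ranksum_oracle <- function(x, y) {
  v <- c(x, y)
  r <- rank(v)
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  ew <- n1 * (length(v) + 1) / 2
  combs <- utils::combn(length(v), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  mean(abs(ws - ew) >= abs(w_obs - ew) - 1e-9)
}
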