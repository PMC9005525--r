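# Ligand-receptor interaction calling between clusters from a curated pair
# list, with a product-of-means interaction score and a differential
# interactome built from cluster DEGs.

#' Read a curated ligand-receptor pair list
#'
#' TSV with columns `ligand`, `receptor` and optional `category`. A minimal
#' chemokine demo list ships with the package
#' (`system.file("extdata", "lr_pairs_chemokine.tsv", package = "synoclone")`).
#'
#' @param path TSV file path.
#' @return data.frame with columns `ligand`, `receptor`, `category`.
#' @export
read_lr_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("ligand", "receptor"), names(df))
  if (length(miss)) stopf("LR pair list missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(df$category)) df$category <- NA_character_
  df <- df[, c("ligand", "receptor", "category")]
  if (anyDuplicated(df[, c("ligand", "receptor")])) {
    stopf("duplicate ligand-receptor pairs in list")
  }
  df
}

#' Per-cluster expressed-gene sets
#'
#' A gene is "expressed" in a cluster when the fraction of the cluster's
#' cells with `log2(normalized UMI + 1) > 0` strictly exceeds
#' `frac_threshold` (default 0.20). The per-gene mean log-normalized
#' expression over all the cluster's cells is recorded alongside.
#'
#' @param normalized log-normalized matrix from [normalize_log()].
#' @param assignment a `cluster_assignment`.
#' @param frac_threshold expressing-cell fraction cutoff (strict `>`).
#' @param clusters optional subset of cluster labels; an unknown label is an
#'   error.
#' @return data.frame with columns `cluster`, `gene`, `frac_pos`,
#'   `mean_expr`, `expressed`.
#' @export
expressed_genes <- function(normalized, assignment, frac_threshold = 0.2,
                            clusters = NULL) {
  cl <- setNames(assignment$cluster, assignment$barcode)[colnames(normalized)]
  levels <- sort(unique(cl[!is.na(cl)]))
  if (!is.null(clusters)) {
    unknown <- setdiff(clusters, levels)
    if (length(unknown)) stopf("unknown cluster(s): %s",
                               paste(unknown, collapse = ", "))
    levels <- clusters
  }
  out <- lapply(levels, function(cc) {
    idx <- which(cl == cc)
    sub <- normalized[, idx, drop = FALSE]
    frac <- Matrix::rowMeans(sub > 0)
    mean_expr <- Matrix::rowMeans(sub)
    data.frame(cluster = cc, gene = rownames(normalized),
               frac_pos = as.numeric(frac), mean_expr = as.numeric(mean_expr),
               expressed = as.numeric(frac) > frac_threshold,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match expressed genes against a ligand-receptor pair list
#'
#' Emits a call (ligand, receptor, sender -> receiver) for every pair in
#' `lr_list` and every ordered cluster pair (self-pairs allowed) where the
#' ligand is expressed in the sender and the receptor in the receiver. Pairs
#' whose ligand or receptor gene is absent from the matrix gene universe are
#' skipped with a warning.
#'
#' @param expressed output of [expressed_genes()].
#' @param lr_list data.frame from [read_lr_pairs()].
#' @param senders,receivers optional cluster-role restrictions.
#' @return `interaction_call` data.frame with columns `ligand`, `receptor`,
#'   `sender`, `receiver`, `frac_ligand`, `frac_receptor`, `mean_ligand`,
#'   `mean_receptor`.
#' @export
match_lr_pairs <- function(expressed, lr_list, senders = NULL,
                           receivers = NULL) {
  clusters <- sort(unique(expressed$cluster))
  senders <- senders %||% clusters
  receivers <- receivers %||% clusters
  genes <- unique(expressed$gene)
  absent <- setdiff(unique(c(lr_list$ligand, lr_list$receptor)), genes)
  if (length(absent)) {
    warnf("LR gene(s) absent from the gene universe skipped: %s",
          paste(absent, collapse = ", "))
  }
  key <- paste(expressed$cluster, expressed$gene)
  lookup <- expressed[, c("frac_pos", "mean_expr", "expressed")]
  rownames(lookup) <- key
  rows <- list()
  for (r in seq_len(nrow(lr_list))) {
    lg <- lr_list$ligand[r]; rc <- lr_list$receptor[r]
    if (lg %in% absent || rc %in% absent) next
    for (s in senders) {
      ls <- lookup[paste(s, lg), ]
      if (!isTRUE(ls$expressed)) next
      for (rcv in receivers) {
        rr <- lookup[paste(rcv, rc), ]
        if (!isTRUE(rr$expressed)) next
        rows[[length(rows) + 1L]] <- data.frame(
          ligand = lg, receptor = rc, sender = s, receiver = rcv,
          frac_ligand = ls$frac_pos, frac_receptor = rr$frac_pos,
          mean_ligand = ls$mean_expr, mean_receptor = rr$mean_expr,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    ligand = character(0), receptor = character(0), sender = character(0),
    receiver = character(0), frac_ligand = numeric(0),
    frac_receptor = numeric(0), mean_ligand = numeric(0),
    mean_receptor = numeric(0), stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  class(res) <- c("interaction_call", "data.frame")
  res
}

#' Score interaction calls
#'
#' Attaches `score = mean_ligand * mean_receptor` (product of mean
#' log-normalized expression in sender and receiver) and sorts calls by
#' decreasing score. The product form preserves the intended semantics --
#' stronger expression on both sides gives a larger score, and the score is
#' zero exactly when either side's mean is zero. This is a package-defined
#' surrogate score, not a reproduction of any published formula.
#'
#' @param calls an `interaction_call` data.frame.
#' @return the calls with a `score` column, sorted by decreasing score.
#' @export
score_interactions <- function(calls) {
  calls$score <- calls$mean_ligand * calls$mean_receptor
  calls <- calls[order(-calls$score, calls$ligand, calls$receptor,
                       calls$sender, calls$receiver), ]
  rownames(calls) <- NULL
  calls
}

#' Differential interactome from cluster DEGs
#'
#' Matches significant cluster markers (q < `q_cutoff`) against the curated
#' pair list: a pair is reported for a (sender, receiver) cluster combination
#' when its ligand is a significant DEG of the sender and/or its receptor a
#' significant DEG of the receiver, annotated with which side is differential
#' and the corresponding log2 fold changes.
#'
#' @param markers a `marker_result` from [find_markers()] (which applies the
#'   min-fraction 0.2 expression filter).
#' @param lr_list data.frame from [read_lr_pairs()].
#' @param q_cutoff DEG significance cutoff.
#' @return data.frame with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `differential` (`"ligand"`, `"receptor"` or `"both"`),
#'   `log2_fc_ligand`, `log2_fc_receptor`.
#' @export
differential_interactome <- function(markers, lr_list, q_cutoff = 0.05) {
  sig <- markers[markers$q_value < q_cutoff & markers$log2_fc > 0, ]
  clusters <- sort(unique(markers$cluster))
  rows <- list()
  for (r in seq_len(nrow(lr_list))) {
    lg <- lr_list$ligand[r]; rc <- lr_list$receptor[r]
    lg_cl <- sig$cluster[sig$gene == lg]
    rc_cl <- sig$cluster[sig$gene == rc]
    if (!length(lg_cl) && !length(rc_cl)) next
    for (s in if (length(lg_cl)) lg_cl else clusters) {
      for (rcv in if (length(rc_cl)) rc_cl else clusters) {
        lig_diff <- s %in% lg_cl
        rec_diff <- rcv %in% rc_cl
        if (!lig_diff && !rec_diff) next
        lfc_l <- if (lig_diff) sig$log2_fc[sig$gene == lg & sig$cluster == s] else NA_real_
        lfc_r <- if (rec_diff) sig$log2_fc[sig$gene == rc & sig$cluster == rcv] else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          ligand = lg, receptor = rc, sender = s, receiver = rcv,
          differential = if (lig_diff && rec_diff) "both" else if (lig_diff) "ligand" else "receptor",
          log2_fc_ligand = lfc_l, log2_fc_receptor = lfc_r,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else data.frame(
    ligand = character(0), receptor = character(0), sender = character(0),
    receiver = character(0), differential = character(0),
    log2_fc_ligand = numeric(0), log2_fc_receptor = numeric(0),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  res
}
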