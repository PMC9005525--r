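# Synthetic paired PB/SF single-cell data generator.
#
# Emulates the structure the downstream analysis assumes: per-patient paired
# peripheral-blood (PB) and synovial-fluid (SF) samples, negative-binomial
# cluster-structured UMI counts, clonally expanded TCRs with planted
# cross-cluster clone sharing, a nonproductive-contig fraction, doublets built
# as sums of two parent cells, and planted chemokine ligand/receptor
# expression. Every planted feature is recorded in a TruthSet so each pipeline
# stage can be tested against known ground truth.

#' Cluster specification for the synthetic generator
#'
#' Describes one planted cell cluster: its signature genes (overexpressed
#' relative to all other genes), its per-sample size, negative-binomial
#' dispersion, and how strongly its cells skew toward the synovial-fluid
#' compartment.
#'
#' @param cluster_id character label, unique across specs.
#' @param n_cells_per_sample cells contributed by each patient (split between
#'   PB and SF according to `compartment_bias`).
#' @param signature_genes character vector of genes upregulated in this
#'   cluster only; signature gene sets must be disjoint across clusters.
#' @param signature_mean expected UMI count of a signature gene (per cell).
#' @param background_mean expected UMI count of any non-signature gene.
#' @param dispersion negative-binomial size (inverse-dispersion) parameter.
#' @param compartment_bias probability a cell of this cluster is assigned to
#'   SF rather than PB.
#' @param lineage lineage tag; clusters with lineage `"T"` receive TCR
#'   contigs (see [generate_dataset()]).
#' @return a `cluster_spec` object.
#' @export
cluster_spec <- function(cluster_id, n_cells_per_sample, signature_genes,
                         signature_mean = 5, background_mean = 0.005,
                         dispersion = 2, compartment_bias = 0.5,
                         lineage = "T") {
  stopifnot(is.character(cluster_id), length(cluster_id) == 1)
  if (!is_count(n_cells_per_sample)) stopf("n_cells_per_sample must be a count")
  stopifnot(is.character(signature_genes), length(signature_genes) >= 1)
  if (anyDuplicated(signature_genes)) stopf("duplicate signature genes in cluster '%s'", cluster_id)
  if (!(signature_mean > background_mean)) {
    stopf("cluster '%s': signature_mean must exceed background_mean", cluster_id)
  }
  if (dispersion <= 0) stopf("dispersion must be positive")
  if (!is_fraction(compartment_bias)) stopf("compartment_bias must be in [0, 1]")
  structure(
    list(cluster_id = cluster_id, n_cells_per_sample = n_cells_per_sample,
         signature_genes = signature_genes, signature_mean = signature_mean,
         background_mean = background_mean, dispersion = dispersion,
         compartment_bias = compartment_bias, lineage = lineage),
    class = "cluster_spec"
  )
}

#' Clone-sharing specification
#'
#' Plants `n_shared_clones` TCR clonotypes whose member cells span both
#' clusters of `cluster_pair`, plus private (single-cluster) clones, with
#' geometric clonal expansion.
#'
#' @param cluster_pair character vector of two cluster ids.
#' @param n_shared_clones clones planted in both clusters.
#' @param n_private_clones_per_cluster clones private to each cluster.
#' @param expansion_geom_p geometric success parameter; a clone's cell count
#'   per cluster is `1 + rgeom(expansion_geom_p)`.
#' @param nonproductive_fraction probability a clone-bearing cell carries an
#'   extra nonproductive contig.
#' @param multi_chain_fraction probability a private clone carries a second
#'   TRB chain (multi-chain clonotype).
#' @return a `sharing_spec` object.
#' @export
sharing_spec <- function(cluster_pair, n_shared_clones,
                         n_private_clones_per_cluster,
                         expansion_geom_p = 0.5,
                         nonproductive_fraction = 0.1,
                         multi_chain_fraction = 0.027) {
  stopifnot(is.character(cluster_pair), length(cluster_pair) == 2)
  if (cluster_pair[1] == cluster_pair[2]) stopf("cluster_pair must name two distinct clusters")
  if (!is_count(n_shared_clones)) stopf("n_shared_clones must be a count")
  if (!is_count(n_private_clones_per_cluster)) stopf("n_private_clones_per_cluster must be a count")
  stopifnot(expansion_geom_p > 0, expansion_geom_p <= 1)
  if (!is_fraction(nonproductive_fraction)) stopf("nonproductive_fraction must be in [0, 1]")
  if (!is_fraction(multi_chain_fraction)) stopf("multi_chain_fraction must be in [0, 1]")
  structure(
    list(cluster_pair = cluster_pair, n_shared_clones = n_shared_clones,
         n_private_clones_per_cluster = n_private_clones_per_cluster,
         expansion_geom_p = expansion_geom_p,
         nonproductive_fraction = nonproductive_fraction,
         multi_chain_fraction = multi_chain_fraction),
    class = "sharing_spec"
  )
}

#' Ligand-receptor planting specification
#'
#' Plants expression of ligand and receptor genes in designated sender and
#' receiver clusters at controlled expressing-cell fractions, so that
#' interactome calls can be checked against exact ground truth. Rows with
#' `positive = TRUE` must have both fractions above the caller's threshold
#' (0.20); decoy rows (`positive = FALSE`) must have at least one fraction at
#' or below it.
#'
#' @param pairs data.frame with columns `ligand`, `receptor`, `sender`,
#'   `receiver`, `ligand_on_fraction`, `receptor_on_fraction`, `positive`.
#' @param frac_threshold the caller's expressing-fraction threshold used to
#'   validate planted truth labels.
#' @return an `lr_plant_spec` object.
#' @export
lr_plant_spec <- function(pairs, frac_threshold = 0.2) {
  need <- c("ligand", "receptor", "sender", "receiver",
            "ligand_on_fraction", "receptor_on_fraction", "positive")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stopf("lr_plant_spec pairs missing column(s): %s", paste(miss, collapse = ", "))
  pos <- pairs$positive
  bad_pos <- pos & !(pairs$ligand_on_fraction > frac_threshold &
                       pairs$receptor_on_fraction > frac_threshold)
  if (any(bad_pos)) stopf("planted-positive pairs must have both on-fractions > %.2f", frac_threshold)
  bad_neg <- !pos & !(pairs$ligand_on_fraction <= frac_threshold |
                        pairs$receptor_on_fraction <= frac_threshold)
  if (any(bad_neg)) stopf("decoy pairs must have at least one on-fraction <= %.2f", frac_threshold)
  structure(list(pairs = pairs, frac_threshold = frac_threshold),
            class = "lr_plant_spec")
}

rand_nt <- function(n_codons) {
  paste(sample(c("A", "C", "G", "T"), 3 * n_codons, replace = TRUE), collapse = "")
}

rand_aa <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

rand_chain <- function(chain) {
  n_codons <- sample(12:15, 1)
  list(chain = chain,
       v_gene = sprintf("%sV%d-%d", chain, sample(1:30, 1), sample(1:3, 1)),
       j_gene = sprintf("%sJ%d", chain, sample(1:50, 1)),
       cdr3_nt = rand_nt(n_codons),
       cdr3_aa = paste0("C", rand_aa(n_codons - 2), "F"))
}

chain_key <- function(ch) {
  paste(ch$chain, ch$v_gene, ch$j_gene, ch$cdr3_nt, sep = "|")
}

clone_signature_key <- function(chains) {
  paste(sort(vapply(chains, chain_key, character(1))), collapse = ";")
}

#' Generate a paired PB/SF synthetic dataset
#'
#' Draws a genes-by-cells UMI count matrix with planted cluster structure
#' (negative binomial per gene per cluster), paired PB/SF sample metadata per
#' patient, a V(D)J contig table with planted clonal structure, optional
#' doublets constructed as gene-wise sums of two parent cells from different
#' clusters, and optional planted ligand-receptor expression. All randomness
#' flows from `seed` through one local RNG; re-running with the same inputs
#' reproduces identical output.
#'
#' @param cluster_specs list of [cluster_spec()] objects.
#' @param sharing_specs list of [sharing_spec()] objects (may be empty).
#' @param lr_spec optional [lr_plant_spec()].
#' @param n_patients number of patients; each contributes a PB and an SF
#'   sample.
#' @param doublet_rate doublets added as this fraction of singlet count, in
#'   \[0, 0.2\].
#' @param seed integer seed.
#' @param tcr_coverage fraction of each T-lineage cluster's cells that carry
#'   at least one productive chain (default 0.69, the coverage reported for
#'   CD3+ T cells in the study design this generator emulates).
#' @param n_background_genes filler genes expressed at each cluster's
#'   `background_mean`.
#' @param lineage_marker_sets optional named list of lineage marker gene sets;
#'   every cluster expresses its own lineage's markers at `signature_mean`.
#'   Unlike signature genes these may be shared across clusters of a lineage.
#' @param mito_genes mitochondrial gene symbols included in the panel.
#' @param mito_mean expected UMI per mitochondrial gene.
#' @param default_expansion_p,default_nonproductive_fraction,default_multi_chain_fraction
#'   clonal parameters for T clusters not covered by any sharing spec.
#' @return list with elements `matrix` (a `cell_gene_matrix`), `contigs`
#'   (a `contig_table` data.frame), and `truth` (a `truth_set` list with
#'   `cell_cluster`, `doublet_barcodes`, `cell_clone`, `shared_clones`,
#'   `planted_lr`, `seed`).
#' @export
generate_dataset <- function(cluster_specs, sharing_specs = list(),
                             lr_spec = NULL, n_patients = 8,
                             doublet_rate = 0, seed = 1,
                             tcr_coverage = 0.69, n_background_genes = 150,
                             lineage_marker_sets = NULL,
                             mito_genes = c("MT-CO1", "MT-ND1", "MT-ATP6"),
                             mito_mean = 1,
                             default_expansion_p = 0.5,
                             default_nonproductive_fraction = 0.1,
                             default_multi_chain_fraction = 0.027) {
  if (!length(cluster_specs)) stopf("need at least one cluster_spec")
  if (!all(vapply(cluster_specs, inherits, logical(1), "cluster_spec"))) {
    stopf("cluster_specs must be a list of cluster_spec objects")
  }
  if (!(doublet_rate >= 0 && doublet_rate <= 0.2)) {
    stopf("doublet_rate must be in [0, 0.2]")
  }
  ids <- vapply(cluster_specs, `[[`, character(1), "cluster_id")
  if (anyDuplicated(ids)) stopf("duplicate cluster ids")
  names(cluster_specs) <- ids

  sig_list <- lapply(cluster_specs, `[[`, "signature_genes")
  all_sig <- unlist(sig_list, use.names = FALSE)
  if (anyDuplicated(all_sig)) {
    stopf("signature gene(s) shared across clusters: %s",
          paste(unique(all_sig[duplicated(all_sig)]), collapse = ", "))
  }
  lineage_genes <- unique(unlist(lineage_marker_sets, use.names = FALSE))
  if (length(intersect(all_sig, lineage_genes))) {
    stopf("lineage marker genes may not appear in signature sets")
  }

  for (ss in sharing_specs) {
    missing_cl <- setdiff(ss$cluster_pair, ids)
    if (length(missing_cl)) {
      stopf("sharing spec references unknown cluster(s): %s",
            paste(missing_cl, collapse = ", "))
    }
  }
  lr_genes <- character(0)
  if (!is.null(lr_spec)) {
    stopifnot(inherits(lr_spec, "lr_plant_spec"))
    missing_cl <- setdiff(unique(c(lr_spec$pairs$sender, lr_spec$pairs$receiver)), ids)
    if (length(missing_cl)) {
      stopf("lr spec references unknown cluster(s): %s",
            paste(missing_cl, collapse = ", "))
    }
    lr_genes <- unique(c(lr_spec$pairs$ligand, lr_spec$pairs$receptor))
    if (length(intersect(lr_genes, c(all_sig, lineage_genes)))) {
      stopf("planted LR genes may not overlap signature or lineage genes")
    }
  }

  bg_genes <- if (n_background_genes > 0) sprintf("BG%03d", seq_len(n_background_genes)) else character(0)
  genes <- c(lineage_genes, all_sig, lr_genes, mito_genes, bg_genes)
  if (anyDuplicated(genes)) stopf("gene panel contains duplicated symbols")
  n_genes <- length(genes)

  with_seed(seed, {
    ## --- cells, metadata, counts -------------------------------------------
    patient_ids <- sprintf("P%d", seq_len(n_patients))
    meta_list <- list()
    count_blocks <- list()
    cell_cluster <- character(0)
    counter <- 0L
    for (cl in cluster_specs) {
      mu <- rep(cl$background_mean, n_genes)
      names(mu) <- genes
      mu[cl$signature_genes] <- cl$signature_mean
      if (!is.null(lineage_marker_sets) && cl$lineage %in% names(lineage_marker_sets)) {
        mu[lineage_marker_sets[[cl$lineage]]] <- cl$signature_mean
      }
      mu[mito_genes] <- mito_mean
      for (p in patient_ids) {
        n <- cl$n_cells_per_sample
        if (n == 0) next
        sf <- rbinom(n, 1, cl$compartment_bias) == 1
        compartment <- ifelse(sf, "SF", "PB")
        bc <- sprintf("%s-%s-%06d", p, "C", counter + seq_len(n))
        counter <- counter + n
        block <- matrix(rnbinom(n_genes * n, size = cl$dispersion, mu = mu),
                        nrow = n_genes)
        colnames(block) <- bc
        count_blocks[[length(count_blocks) + 1L]] <- block
        meta_list[[length(meta_list) + 1L]] <- data.frame(
          barcode = bc, patient = p, compartment = compartment,
          sample_id = paste0(p, "_", compartment),
          stringsAsFactors = FALSE
        )
        cc <- rep(cl$cluster_id, n)
        names(cc) <- bc
        cell_cluster <- c(cell_cluster, cc)
      }
    }
    if (length(count_blocks)) {
      counts <- do.call(cbind, count_blocks)
      cell_meta <- do.call(rbind, meta_list)
    } else {
      counts <- matrix(0L, nrow = n_genes, ncol = 0,
                       dimnames = list(NULL, character(0)))
      cell_meta <- data.frame(barcode = character(0), patient = character(0),
                              compartment = character(0),
                              sample_id = character(0),
                              stringsAsFactors = FALSE)
    }
    rownames(counts) <- genes

    ## --- planted ligand/receptor expression --------------------------------
    planted_lr <- NULL
    if (!is.null(lr_spec)) {
      plant <- unique(rbind(
        data.frame(gene = lr_spec$pairs$ligand, cluster = lr_spec$pairs$sender,
                   frac = lr_spec$pairs$ligand_on_fraction, stringsAsFactors = FALSE),
        data.frame(gene = lr_spec$pairs$receptor, cluster = lr_spec$pairs$receiver,
                   frac = lr_spec$pairs$receptor_on_fraction, stringsAsFactors = FALSE)
      ))
      key <- paste(plant$gene, plant$cluster)
      if (anyDuplicated(key)) {
        stopf("conflicting on-fractions planted for the same gene/cluster combination")
      }
      for (r in seq_len(nrow(plant))) {
        cells <- names(cell_cluster)[cell_cluster == plant$cluster[r]]
        on <- rbinom(length(cells), 1, plant$frac[r])
        counts[plant$gene[r], cells] <- on * (1L + rpois(length(cells), 1))
      }
      planted_lr <- lr_spec$pairs[lr_spec$pairs$positive,
                                  c("ligand", "receptor", "sender", "receiver")]
      rownames(planted_lr) <- NULL
    }

    ## --- doublets: gene-wise sums of two parents from distinct clusters ----
    n_singlet <- ncol(counts)
    n_doublet <- round(doublet_rate * n_singlet)
    doublet_barcodes <- character(0)
    if (n_doublet > 0) {
      if (length(cluster_specs) < 2) stopf("doublets require at least two clusters")
      d_counts <- matrix(0L, nrow = n_genes, ncol = n_doublet)
      d_meta <- vector("list", n_doublet)
      d_bc <- sprintf("DBL-%06d", seq_len(n_doublet))
      d_cluster <- character(n_doublet)
      nonempty <- ids[vapply(ids, function(x) any(cell_cluster == x), logical(1))]
      if (length(nonempty) < 2) stopf("doublets require two clusters with cells")
      for (i in seq_len(n_doublet)) {
        cl_pair <- sample(nonempty, 2)
        pick <- function(cc) {
          x <- names(cell_cluster)[cell_cluster == cc]
          x[sample.int(length(x), 1)]
        }
        p1 <- pick(cl_pair[1])
        p2 <- pick(cl_pair[2])
        d_counts[, i] <- counts[, p1] + counts[, p2]
        d_meta[[i]] <- cell_meta[cell_meta$barcode == p1, ]
        d_cluster[i] <- cl_pair[1]
      }
      colnames(d_counts) <- d_bc
      d_meta <- do.call(rbind, d_meta)
      d_meta$barcode <- d_bc
      counts <- cbind(counts, d_counts)
      cell_meta <- rbind(cell_meta, d_meta)
      dc <- d_cluster
      names(dc) <- d_bc
      cell_cluster <- c(cell_cluster, dc)
      doublet_barcodes <- d_bc
    }
    rownames(cell_meta) <- NULL

    ## --- TCR contigs with planted clonal structure -------------------------
    t_clusters <- ids[vapply(cluster_specs, function(s) identical(s$lineage, "T"), logical(1))]
    contigs <- make_contigs(
      cell_cluster = cell_cluster[setdiff(names(cell_cluster), doublet_barcodes)],
      t_clusters = t_clusters, sharing_specs = sharing_specs,
      tcr_coverage = tcr_coverage,
      default_expansion_p = default_expansion_p,
      default_nonproductive_fraction = default_nonproductive_fraction,
      default_multi_chain_fraction = default_multi_chain_fraction
    )

    truth <- structure(
      list(cell_cluster = cell_cluster,
           doublet_barcodes = doublet_barcodes,
           cell_clone = contigs$cell_clone,
           shared_clones = contigs$shared_clones,
           planted_lr = planted_lr,
           seed = as.integer(seed)),
      class = "truth_set"
    )

    mat <- new_cell_gene_matrix(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      gene_ids = sprintf("SYN%04d", seq_len(n_genes)),
      gene_symbols = genes,
      cell_meta = cell_meta
    )
    list(matrix = mat, contigs = contigs$table, truth = truth)
  })
}

# Builds the contig table: shared clones planted first (guaranteed >= 1 cell
# on each side), then private clones with geometric expansion; remaining
# covered cells become auto private clones so realized TCR coverage matches
# the requested fraction.
make_contigs <- function(cell_cluster, t_clusters, sharing_specs,
                         tcr_coverage, default_expansion_p,
                         default_nonproductive_fraction,
                         default_multi_chain_fraction) {
  rows <- list()
  cell_clone <- character(0)
  shared_clones <- list()
  if (!length(t_clusters)) {
    tab <- empty_contig_table()
    return(list(table = tab, cell_clone = cell_clone, shared_clones = shared_clones))
  }

  params <- list()
  for (cl in t_clusters) {
    params[[cl]] <- list(p = default_expansion_p,
                         npf = default_nonproductive_fraction,
                         mcf = default_multi_chain_fraction,
                         n_private = NA_integer_)
  }
  for (ss in sharing_specs) {
    for (cl in ss$cluster_pair) {
      if (!cl %in% t_clusters) stopf("sharing spec cluster '%s' is not T-lineage", cl)
      params[[cl]] <- list(p = ss$expansion_geom_p,
                           npf = ss$nonproductive_fraction,
                           mcf = ss$multi_chain_fraction,
                           n_private = ss$n_private_clones_per_cluster)
    }
  }

  covered <- list()
  for (cl in t_clusters) {
    cells <- names(cell_cluster)[cell_cluster == cl]
    n_cov <- round(tcr_coverage * length(cells))
    covered[[cl]] <- if (n_cov > 0) sample(cells, n_cov) else character(0)
  }

  new_clone <- function(multi_chain = FALSE) {
    chains <- list(rand_chain("TRA"), rand_chain("TRB"))
    if (multi_chain) chains <- c(chains, list(rand_chain("TRB")))
    chains
  }

  # clone assignment: cluster -> list of (chains, n_cells)
  assign_clones <- list()
  for (cl in t_clusters) assign_clones[[cl]] <- list()

  for (ss in sharing_specs) {
    a <- ss$cluster_pair[1]; b <- ss$cluster_pair[2]
    keys <- character(ss$n_shared_clones)
    if (ss$n_shared_clones > 0) {
      if (length(covered[[a]]) < ss$n_shared_clones ||
          length(covered[[b]]) < ss$n_shared_clones) {
        stopf("not enough TCR-covered cells in pair (%s, %s) to plant %d shared clones",
              a, b, ss$n_shared_clones)
      }
      for (i in seq_len(ss$n_shared_clones)) {
        cn <- new_clone()
        keys[i] <- clone_signature_key(cn)
        for (cl in c(a, b)) {
          assign_clones[[cl]][[length(assign_clones[[cl]]) + 1L]] <-
            list(chains = cn, size = 1L + rgeom(1, ss$expansion_geom_p),
                 shared = TRUE)
        }
      }
    }
    shared_clones[[paste(a, b, sep = "|")]] <- keys
  }

  for (cl in t_clusters) {
    n_priv <- params[[cl]]$n_private
    if (!is.na(n_priv) && n_priv > 0) {
      for (i in seq_len(n_priv)) {
        mc <- runif(1) < params[[cl]]$mcf
        assign_clones[[cl]][[length(assign_clones[[cl]]) + 1L]] <-
          list(chains = new_clone(mc), size = 1L + rgeom(1, params[[cl]]$p),
               shared = FALSE)
      }
    }
  }

  for (cl in t_clusters) {
    pool <- covered[[cl]]
    clones <- assign_clones[[cl]]
    shared_idx <- which(vapply(clones, `[[`, logical(1), "shared"))
    if (length(shared_idx) > length(pool)) {
      stopf("not enough TCR-covered cells in cluster '%s' to plant %d shared clones",
            cl, length(shared_idx))
    }
    # pass 1: reserve one cell per shared clone; pass 2: expansion extras
    alloc <- rep(0L, length(clones))
    pos <- 0L
    alloc[shared_idx] <- 1L
    pos <- length(shared_idx)
    for (i in seq_along(clones)) {
      extra <- max(0L, clones[[i]]$size - alloc[i])
      take <- min(extra, length(pool) - pos)
      if (take < 1L) next
      alloc[i] <- alloc[i] + take
      pos <- pos + take
    }
    pos <- 0L
    for (i in seq_along(clones)) {
      if (alloc[i] < 1L) next
      cells <- pool[pos + seq_len(alloc[i])]
      pos <- pos + alloc[i]
      rows[[length(rows) + 1L]] <- contig_rows(cells, clones[[i]]$chains,
                                               params[[cl]]$npf)
      key <- clone_signature_key(clones[[i]]$chains)
      cc <- rep(key, length(cells))
      names(cc) <- cells
      cell_clone <- c(cell_clone, cc)
    }
    # fill remaining covered cells with auto private clones
    while (pos < length(pool)) {
      mc <- runif(1) < params[[cl]]$mcf
      cn <- new_clone(mc)
      size <- 1L + rgeom(1, params[[cl]]$p)
      take <- min(size, length(pool) - pos)
      cells <- pool[pos + seq_len(take)]
      pos <- pos + take
      rows[[length(rows) + 1L]] <- contig_rows(cells, cn, params[[cl]]$npf)
      key <- clone_signature_key(cn)
      cc <- rep(key, length(cells))
      names(cc) <- cells
      cell_clone <- c(cell_clone, cc)
    }
  }

  tab <- if (length(rows)) do.call(rbind, rows) else empty_contig_table()
  rownames(tab) <- NULL
  class(tab) <- c("contig_table", "data.frame")
  list(table = tab, cell_clone = cell_clone, shared_clones = shared_clones)
}

empty_contig_table <- function() {
  structure(
    data.frame(barcode = character(0), chain = character(0),
               v_gene = character(0), j_gene = character(0),
               cdr3_nt = character(0), cdr3_aa = character(0),
               productive = logical(0), umis = integer(0),
               stringsAsFactors = FALSE),
    class = c("contig_table", "data.frame")
  )
}

contig_rows <- function(cells, chains, nonproductive_fraction) {
  out <- list()
  for (bc in cells) {
    for (ch in chains) {
      out[[length(out) + 1L]] <- data.frame(
        barcode = bc, chain = ch$chain, v_gene = ch$v_gene, j_gene = ch$j_gene,
        cdr3_nt = ch$cdr3_nt, cdr3_aa = ch$cdr3_aa, productive = TRUE,
        umis = 1L + rpois(1, 2), stringsAsFactors = FALSE
      )
    }
    if (runif(1) < nonproductive_fraction) {
      ch <- rand_chain(sample(c("TRA", "TRB"), 1))
      out[[length(out) + 1L]] <- data.frame(
        barcode = bc, chain = ch$chain, v_gene = ch$v_gene, j_gene = ch$j_gene,
        cdr3_nt = ch$cdr3_nt, cdr3_aa = ch$cdr3_aa, productive = FALSE,
        umis = 1L + rpois(1, 0.5), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write a synthetic dataset to disk in 10x-style plain-text formats
#'
#' Emits `matrix.mtx` (MatrixMarket coordinate integer), `barcodes.tsv`,
#' `features.tsv` (gene id, gene symbol), `contigs.tsv`, `metadata.tsv`, and
#' `truth.json`. Files are written deterministically so identical datasets
#' serialize byte-identically.
#'
#' @param dataset list as returned by [generate_dataset()].
#' @param out_dir output directory (created if absent).
#' @param overwrite allow writing into a non-empty directory.
#' @return invisibly, a named character vector of file paths.
#' @export
write_fixture <- function(dataset, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir)) {
    if (length(list.files(out_dir)) && !overwrite) {
      stopf("output directory '%s' is not empty (use overwrite = TRUE)", out_dir)
    }
  } else {
    dir.create(out_dir, recursive = TRUE)
  }
  mat <- dataset$matrix
  paths <- c(
    matrix = file.path(out_dir, "matrix.mtx"),
    barcodes = file.path(out_dir, "barcodes.tsv"),
    features = file.path(out_dir, "features.tsv"),
    contigs = file.path(out_dir, "contigs.tsv"),
    metadata = file.path(out_dir, "metadata.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_mtx_integer(mat$counts, paths[["matrix"]])
  writeLines(colnames(mat$counts) %||% character(0), paths[["barcodes"]])
  writeLines(paste(mat$gene_ids, mat$gene_symbols, sep = "\t"), paths[["features"]])
  write_tsv(dataset$contigs, paths[["contigs"]])
  write_tsv(mat$cell_meta, paths[["metadata"]])
  write_truth(dataset$truth, paths[["truth"]])
  invisible(paths)
}

# MatrixMarket coordinate-integer writer (10x convention); Matrix::writeMM
# emits "real", so integer headers and stable formatting are done here.
write_mtx_integer <- function(m, path) {
  s <- Matrix::summary(m)
  lines <- c(
    "%%MatrixMarket matrix coordinate integer general",
    "%",
    sprintf("%d %d %d", nrow(m), ncol(m), nrow(s)),
    if (nrow(s)) sprintf("%d %d %d", s$i, s$j, as.integer(s$x))
  )
  writeLines(lines, path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_truth <- function(truth, path) {
  payload <- list(
    cell_cluster = as.list(truth$cell_cluster),
    doublet_barcodes = truth$doublet_barcodes,
    cell_clone = as.list(truth$cell_clone),
    shared_clones = truth$shared_clones,
    planted_lr = truth$planted_lr,
    seed = truth$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
}

#' Read a TruthSet back from truth.json
#'
#' @param path path to a `truth.json` written by [write_fixture()].
#' @return a `truth_set` list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path)
  as_chr_map <- function(l) {
    if (!length(l)) return(setNames(character(0), character(0)))
    setNames(vapply(l, as.character, character(1)), names(l))
  }
  planted <- NULL
  if (!is.null(x$planted_lr)) {
    planted <- do.call(rbind, lapply(x$planted_lr, function(r) {
      data.frame(ligand = r$ligand, receptor = r$receptor,
                 sender = r$sender, receiver = r$receiver,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(
    list(cell_cluster = as_chr_map(x$cell_cluster),
         doublet_barcodes = vapply(x$doublet_barcodes, as.character, character(1)),
         cell_clone = as_chr_map(x$cell_clone),
         shared_clones = lapply(x$shared_clones, function(v) {
           vapply(v, as.character, character(1))
         }),
         planted_lr = planted,
         seed = as.integer(x$seed)),
    class = "truth_set"
  )
}
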