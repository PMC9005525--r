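# End-to-end orchestration: a config-driven pipeline over the module
# functions, plus a demo fixture generator with planted ground truth.

#' Default demo specifications
#'
#' The default synthetic study: six clusters spanning myeloid, B, NK and
#' three T lineages, with the two effector CD8 clusters skewed to opposite
#' compartments (a blood-enriched CX3CR1-high-like cluster and a
#' synovial-enriched CXCR3-high-like cluster), 20 TCR clones planted as
#' shared between them, chemokine ligand/receptor expression planted from
#' myeloid senders to the synovial T receiver (CXCL9/10/11 to CXCR3, CXCL16
#' to CXCR6) with a CX3CL1/CX3CR1 decoy below threshold, and coarse plus
#' per-cluster marker sets for doublet flagging and annotation.
#'
#' @param n_cells_per_sample cells per cluster per patient.
#' @return list with `cluster_specs`, `sharing_specs`, `lr_spec`,
#'   `lineage_marker_sets` (coarse), `cluster_marker_sets` (per-cluster
#'   signatures, for doublet flagging), and `marker_rules`.
#' @export
demo_specs <- function(n_cells_per_sample = 40) {
  cluster_specs <- list(
    cluster_spec("Myeloid", n_cells_per_sample,
                 c("S100A8", "S100A9", "VCAN", "CST3", "AIF1", "SERPINA1"),
                 compartment_bias = 0.6, lineage = "myeloid"),
    cluster_spec("B", n_cells_per_sample,
                 c("MS4A1", "IGHM", "BANK1", "CD24", "TNFRSF13B"),
                 compartment_bias = 0.3, lineage = "B"),
    cluster_spec("NK", n_cells_per_sample,
                 c("PRF1", "KLRF1", "NCAM1", "FCER1G", "SPON2"),
                 compartment_bias = 0.4, lineage = "NK"),
    cluster_spec("T_CD4", n_cells_per_sample,
                 c("CD4", "IL7R", "TCF7", "LTB", "MAL"),
                 compartment_bias = 0.4, lineage = "T"),
    cluster_spec("T_CD8_CX3CR1", n_cells_per_sample,
                 c("CD8A", "KLRG1", "FGFBP2", "GZMH", "TBX21", "ADGRG1"),
                 compartment_bias = 0.15, lineage = "T"),
    cluster_spec("T_CD8_CXCR3", n_cells_per_sample,
                 c("CD8B", "GZMK", "CRTAM", "PDCD1", "CD69", "DUSP4"),
                 compartment_bias = 0.85, lineage = "T")
  )
  lineage_marker_sets <- list(
    T = c("CD3D", "CD3E", "CD2", "CD7"),
    B = c("CD19", "CD79A", "CD79B"),
    myeloid = c("LYZ", "CD14", "FCN1"),
    NK = c("NKG7", "GNLY", "KLRD1")
  )
  cluster_marker_sets <- c(
    lapply(cluster_specs, `[[`, "signature_genes"),
    list()
  )
  names(cluster_marker_sets) <-
    vapply(cluster_specs, `[[`, character(1), "cluster_id")
  sharing_specs <- list(
    sharing_spec(c("T_CD8_CX3CR1", "T_CD8_CXCR3"),
                 n_shared_clones = 20, n_private_clones_per_cluster = 60)
  )
  lr_spec <- lr_plant_spec(data.frame(
    ligand = c("CXCL9", "CXCL10", "CXCL11", "CXCL16", "CX3CL1"),
    receptor = c("CXCR3", "CXCR3", "CXCR3", "CXCR6", "CX3CR1"),
    sender = "Myeloid",
    receiver = c(rep("T_CD8_CXCR3", 4), "T_CD8_CX3CR1"),
    ligand_on_fraction = c(0.6, 0.6, 0.6, 0.5, 0.5),
    receptor_on_fraction = c(0.6, 0.6, 0.6, 0.4, 0.05),
    positive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE
  ))
  marker_rules <- list(
    marker_rule("Myeloid", c("LYZ", "CD14", "S100A8"), forbidden = "CD3D"),
    marker_rule("B cells", c("CD19", "MS4A1"), forbidden = "CD3D"),
    marker_rule("NK", c("NKG7", "GNLY"), forbidden = "CD3D"),
    marker_rule("CD4 T", c("CD3D", "CD4", "IL7R"),
                forbidden = c("CD8A", "CD8B")),
    marker_rule("CX3CR1hi effector CD8 T", c("CD3D", "CD8A", "KLRG1")),
    marker_rule("CXCR3hi effector CD8 T", c("CD3D", "CD8B", "GZMK"))
  )
  list(cluster_specs = cluster_specs, sharing_specs = sharing_specs,
       lr_spec = lr_spec, lineage_marker_sets = lineage_marker_sets,
       cluster_marker_sets = cluster_marker_sets,
       marker_rules = marker_rules)
}

#' Specifications for a repertoire-overlap benchmark dataset
#'
#' Ten T-lineage clusters with private clones and one cluster pair sharing
#' `n_shared` planted clones; the realized clone universe is about 500
#' clones over 8 patients. With `n_shared = 0` every clone is private, the
#' matched null for sharing-recovery checks.
#'
#' @param n_shared clones shared between the first two clusters.
#' @param n_clusters number of T clusters.
#' @param n_private private clones per cluster in the shared pair.
#' @param n_cells_per_sample cells per cluster per patient.
#' @return list of generator arguments for [generate_dataset()].
#' @export
sharing_benchmark_specs <- function(n_shared = 20, n_clusters = 10,
                                    n_private = 48, n_cells_per_sample = 18) {
  cluster_specs <- lapply(seq_len(n_clusters), function(i) {
    cluster_spec(sprintf("T%02d", i), n_cells_per_sample,
                 signature_genes = sprintf("SIG%02d_%d", i, 1:4),
                 lineage = "T")
  })
  sharing_specs <- list(
    sharing_spec(c("T01", "T02"), n_shared_clones = n_shared,
                 n_private_clones_per_cluster = n_private)
  )
  list(cluster_specs = cluster_specs, sharing_specs = sharing_specs)
}

#' Write the demo fixture and a ready-to-run pipeline config
#'
#' Generates the default synthetic dataset ([demo_specs()]; 6 clusters, 8
#' patients, 5 percent doublets), writes it in 10x-style plain-text formats
#' together with the bundled chemokine ligand-receptor list, the marker
#' rules as YAML, and a `config.yaml` that [run_pipeline()] accepts.
#'
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param n_cells_per_sample cells per cluster per patient (default 40, for
#'   about 2,000 cells).
#' @param doublet_rate planted doublet fraction.
#' @return invisibly, list with `config` (path), `fixture_dir`, and
#'   `dataset` (the in-memory dataset).
#' @export
make_demo <- function(out_dir, seed = 1, n_cells_per_sample = 40,
                      doublet_rate = 0.05) {
  spec <- demo_specs(n_cells_per_sample)
  ds <- generate_dataset(spec$cluster_specs, spec$sharing_specs,
                         spec$lr_spec, n_patients = 8,
                         doublet_rate = doublet_rate, seed = seed,
                         lineage_marker_sets = spec$lineage_marker_sets)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fixture_dir <- file.path(out_dir, "fixture")
  write_fixture(ds, fixture_dir, overwrite = TRUE)
  lr_src <- system.file("extdata", "lr_pairs_chemokine.tsv",
                        package = "synoclone")
  file.copy(lr_src, file.path(out_dir, "lr_pairs.tsv"), overwrite = TRUE)
  rules_path <- file.path(out_dir, "marker_rules.yaml")
  yaml::write_yaml(lapply(spec$marker_rules, unclass), rules_path)
  config <- list(
    seed = as.integer(seed),
    input = list(
      matrix_dir = fixture_dir,
      contigs = file.path(fixture_dir, "contigs.tsv"),
      lr_list = file.path(out_dir, "lr_pairs.tsv"),
      marker_rules = rules_path
    ),
    output_dir = file.path(out_dir, "results"),
    # gene-count bounds scaled to the synthetic marker panel (a few hundred
    # genes); the package defaults carry the full-transcriptome values
    qc = list(min_genes = 3, max_genes = 6500, max_pct_mito = 15),
    cluster = list(n_hvg = 2000, n_pcs = 40, k_neighbors = 30,
                   resolution = 0.6),
    doublets = list(marker_sets = spec$cluster_marker_sets, k_hybrid = 2),
    repertoire = list(top_n = 100, q_cutoff = 0.05),
    interactome = list(frac_threshold = 0.2)
  )
  config_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  invisible(list(config = config_path, fixture_dir = fixture_dir,
                 dataset = ds))
}

#' Run the full pipeline from a config
#'
#' Stages, in order: read inputs, per-cell QC and filtering, normalization,
#' clustering, doublet flagging and removal (when marker sets are
#' configured), cluster markers and rule-based annotation (when rules are
#' configured), clonotype calling with top-expanded clones and cluster-pair
#' overlap tests, and ligand-receptor interaction calling (when an LR list
#' is configured; otherwise the stage is skipped with a notice). Each stage
#' writes TSV outputs into the output directory; a `manifest.json` records
#' parameters, seed and input/output checksums. A stage failure leaves prior
#' outputs in place and writes a machine-readable `error.json`.
#'
#' @param config path to a YAML config (as written by [make_demo()]) or an
#'   equivalent named list.
#' @return invisibly, list of stage results (paths and key objects).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("seed", "input", "output_dir")) {
    if (is.null(config[[field]])) stopf("config missing required field '%s'", field)
  }
  if (is.null(config$input$matrix_dir)) stopf("config missing input$matrix_dir")
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  log_msg <- function(fmt, ...) message(sprintf(paste0("[synoclone] ", fmt), ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      jsonlite::write_json(list(stage = name, message = conditionMessage(e)),
                           file.path(out_dir, "error.json"), auto_unbox = TRUE)
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  results <- list()

  stage("read", {
    log_msg("reading matrix from %s", config$input$matrix_dir)
    results$matrix <- read_matrix(config$input$matrix_dir)
  })

  stage("qc", {
    qc_cfg <- config$qc %||% list()
    thr <- qc_thresholds(min_genes = qc_cfg$min_genes %||% 200,
                         max_genes = qc_cfg$max_genes %||% 6500,
                         max_pct_mito = qc_cfg$max_pct_mito %||% 15)
    qc <- compute_cell_qc(results$matrix, thr)
    filt <- apply_qc_filters(results$matrix, qc, thr)
    write_tsv(qc, file.path(out_dir, "qc_metrics.tsv"))
    rep <- filt$report
    write_tsv(data.frame(metric = c("n_input", "n_removed", "n_kept",
                                    names(rep$by_rule)),
                         value = c(rep$n_input, rep$n_removed, rep$n_kept,
                                   unname(rep$by_rule))),
              file.path(out_dir, "qc_report.tsv"))
    log_msg("QC: %d cells in, %d removed, %d kept",
            rep$n_input, rep$n_removed, rep$n_kept)
    results$matrix <- filt$matrix
    results$qc_report <- rep
  })

  stage("cluster", {
    cl_cfg <- config$cluster %||% list()
    params <- clustering_params(
      n_pcs = cl_cfg$n_pcs %||% 40,
      k_neighbors = cl_cfg$k_neighbors %||% 200,
      resolution = cl_cfg$resolution %||% 0.6,
      n_hvg = cl_cfg$n_hvg %||% 2000, seed = seed
    )
    results$normalized <- normalize_log(results$matrix)
    results$clusters <- cluster_cells(results$normalized, params)
    write_tsv(as.data.frame(results$clusters),
              file.path(out_dir, "clusters.tsv"))
    log_msg("clustering: %d clusters over %d cells",
            length(unique(results$clusters$cluster)),
            nrow(results$clusters))
  })

  if (!is.null(config$doublets$marker_sets)) {
    stage("doublets", {
      flags <- flag_doublets(
        results$matrix, results$clusters,
        lineage_marker_sets = lapply(config$doublets$marker_sets, unlist),
        k_hybrid = config$doublets$k_hybrid %||% 2,
        max_genes = config$qc$max_genes %||% 6500,
        unassigned_action = "flag"
      )
      write_tsv(flags, file.path(out_dir, "doublet_flags.tsv"))
      keep <- flags$barcode[!flags$is_doublet]
      log_msg("doublets: %d flagged, %d cells retained",
              sum(flags$is_doublet), length(keep))
      results$matrix <- subset_cells(results$matrix, keep)
      results$normalized <- results$normalized[, keep, drop = FALSE]
      cl <- results$clusters
      results$clusters <- structure(
        cl[cl$barcode %in% keep, ],
        class = class(cl), round = attr(cl, "round"),
        params = attr(cl, "params")
      )
    })
  } else {
    log_msg("doublets: no marker sets configured; stage skipped")
  }

  stage("markers", {
    results$markers <- find_markers(results$normalized, results$clusters)
    write_tsv(results$markers, file.path(out_dir, "markers.tsv"))
    if (!is.null(config$input$marker_rules)) {
      rules <- read_marker_rules(config$input$marker_rules)
      ann <- annotate_clusters(results$markers, rules)
      write_tsv(data.frame(cluster = names(ann), label = unname(ann)),
                file.path(out_dir, "annotations.tsv"))
      results$annotations <- ann
      log_msg("annotation: %s",
              paste(sprintf("%s=%s", names(ann), ann), collapse = ", "))
    }
  })

  if (!is.null(config$input$contigs) && file.exists(config$input$contigs)) {
    stage("repertoire", {
      rep_cfg <- config$repertoire %||% list()
      contigs <- read_contigs(config$input$contigs)
      contigs <- contigs[contigs$barcode %in% results$matrix$barcodes, ]
      clono <- call_clonotypes(contigs, results$matrix$cell_meta)
      write_tsv(clono$clones, file.path(out_dir, "clones.tsv"))
      top <- top_expanded(clono, results$clusters, results$matrix$cell_meta,
                          n = rep_cfg$top_n %||% 100)
      write_tsv(top$top, file.path(out_dir, "top_clones.tsv"))
      om <- overlap_matrix(clono, results$clusters)
      write_tsv(data.frame(cluster = rownames(om), as.data.frame(om),
                           check.names = FALSE),
                file.path(out_dir, "overlap_counts.tsv"))
      ot <- overlap_test(om, universe_size = nrow(clono$clones),
                         q_cutoff = rep_cfg$q_cutoff %||% 0.05)
      write_tsv(ot, file.path(out_dir, "overlap_tests.tsv"))
      log_msg("repertoire: %d clones, %d significant cluster pairs",
              nrow(clono$clones), sum(ot$significant))
      results$clonotypes <- clono
      results$overlap <- ot
    })
  } else {
    log_msg("repertoire: no contig table configured; stage skipped")
  }

  if (!is.null(config$input$lr_list) && file.exists(config$input$lr_list)) {
    stage("interactome", {
      ia_cfg <- config$interactome %||% list()
      lr <- read_lr_pairs(config$input$lr_list)
      expr <- expressed_genes(results$normalized, results$clusters,
                              frac_threshold = ia_cfg$frac_threshold %||% 0.2)
      calls <- score_interactions(
        match_lr_pairs(expr, lr,
                       senders = ia_cfg$senders, receivers = ia_cfg$receivers)
      )
      write_tsv(calls, file.path(out_dir, "interactions.tsv"))
      di <- differential_interactome(results$markers, lr)
      write_tsv(di, file.path(out_dir, "differential_interactome.tsv"))
      log_msg("interactome: %d calls", nrow(calls))
      results$interactions <- calls
    })
  } else {
    log_msg("interactome: no LR list configured; stage skipped")
  }

  stage("manifest", {
    outputs <- sort(setdiff(list.files(out_dir), c("manifest.json", "error.json")))
    inputs <- c(config$input$contigs, config$input$lr_list,
                config$input$marker_rules)
    inputs <- inputs[!vapply(inputs, is.null, logical(1))]
    inputs <- unlist(inputs)
    manifest <- list(
      package = "synoclone",
      version = as.character(utils::packageVersion("synoclone")),
      seed = seed,
      params = config[setdiff(names(config), c("input", "output_dir"))],
      input_md5 = as.list(tools::md5sum(inputs[file.exists(inputs)])),
      output_md5 = as.list(tools::md5sum(file.path(out_dir, outputs)))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  })
  invisible(results)
}
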