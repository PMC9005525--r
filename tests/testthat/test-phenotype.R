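test_that("log normalization matches direct arithmetic and a dense oracle", {
  counts <- cbind(a = c(100, 0, 0), b = c(2, 3, 0), c = c(0, 0, 0))
  rownames(counts) <- c("G1", "G2", "G3")
  cgm <- make_cgm(counts)
  norm <- normalize_log(cgm)
  expect_equal(norm["G1", "a"], log2(10001))
  expect_equal(unname(as.matrix(norm)[, "c"]), rep(0, 3)) # zero cell stays zero
  expect_equal(unname(as.matrix(norm)["G3", ]), rep(0, 3)) # all-zero gene

  specs <- list(cluster_spec("A", 30, c("GA1", "GA2")),
                cluster_spec("B", 30, c("GB1", "GB2")))
  ds <- generate_dataset(specs, n_patients = 2, seed = 8)
  norm <- as.matrix(normalize_log(ds$matrix))
  dense <- as.matrix(ds$matrix$counts)
  tot <- colSums(dense)
  oracle <- log2(sweep(dense, 2, ifelse(tot > 0, tot, 1), "/") * 1e4 *
                   rep(ifelse(tot > 0, 1, 0), each = nrow(dense)) + 1)
  expect_equal(norm, oracle, tolerance = 1e-12)
})

test_that("two separable blocks yield exactly two clusters matching blocks", {
  set.seed(1)
  block <- function(sig_rows, n) {
    m <- matrix(rpois(8 * n, 0.1), nrow = 8)
    m[sig_rows, ] <- matrix(rpois(length(sig_rows) * n, 8), nrow = length(sig_rows))
    m
  }
  counts <- cbind(block(1:3, 30), block(5:7, 30))
  rownames(counts) <- sprintf("G%d", 1:8)
  colnames(counts) <- sprintf("c%02d", 1:60)
  cgm <- make_cgm(counts)
  norm <- normalize_log(cgm)
  cl <- cluster_cells(norm, clustering_params(n_pcs = 4, k_neighbors = 10,
                                              resolution = 0.6, seed = 1))
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(ari(cl$cluster, rep(c("x", "y"), each = 30)), 1)
})

test_that("clustering is invariant to input cell order", {
  specs <- list(cluster_spec("A", 40, c("GA1", "GA2", "GA3")),
                cluster_spec("B", 40, c("GB1", "GB2", "GB3")),
                cluster_spec("C", 40, c("GC1", "GC2", "GC3")))
  ds <- generate_dataset(specs, n_patients = 2, seed = 17)
  norm <- normalize_log(ds$matrix)
  params <- clustering_params(n_pcs = 10, k_neighbors = 10, resolution = 0.6,
                              seed = 3)
  cl1 <- cluster_cells(norm, params)
  perm <- sample(ncol(norm))
  cl2 <- cluster_cells(norm[, perm, drop = FALSE], params)
  m1 <- setNames(cl1$cluster, cl1$barcode)
  m2 <- setNames(cl2$cluster, cl2$barcode)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("subcluster on all parents equals clustering the full data", {
  specs <- list(cluster_spec("A", 30, c("GA1", "GA2")),
                cluster_spec("B", 30, c("GB1", "GB2")))
  ds <- generate_dataset(specs, n_patients = 2, seed = 19)
  norm <- normalize_log(ds$matrix)
  params <- clustering_params(n_pcs = 8, k_neighbors = 8, resolution = 0.6,
                              seed = 2)
  full <- cluster_cells(norm, params)
  sub <- subcluster(norm, full, unique(full$cluster), params)
  m_full <- setNames(full$cluster, full$barcode)
  m_sub <- setNames(sub$cluster, sub$barcode)[names(m_full)]
  expect_equal(ari(m_full, m_sub), 1)
  expect_error(subcluster(norm, full, character(0), params), "nonempty")
  expect_error(subcluster(norm, full, "nope", params), "unknown parent")
})

test_that("subclustering separates planted subtypes within a parent", {
  specs <- list(
    cluster_spec("T_a", 30, c("TA1", "TA2", "TA3")),
    cluster_spec("T_b", 30, c("TB1", "TB2", "TB3")),
    cluster_spec("Mono", 60, c("M1", "M2", "M3"), lineage = "myeloid")
  )
  ds <- generate_dataset(specs, n_patients = 2,
                         lineage_marker_sets = list(
                           T = c("CD3D", "CD3E"), myeloid = c("LYZ", "CD14")
                         ), seed = 23)
  norm <- normalize_log(ds$matrix)
  truth <- ds$truth$cell_cluster
  t_cells <- names(truth)[truth %in% c("T_a", "T_b")]
  parent <- make_assignment(ds$matrix$barcodes,
                            ifelse(ds$matrix$barcodes %in% t_cells, "T", "M"))
  sub <- subcluster(norm, parent, "T",
                    clustering_params(round = "treg_sub", k_neighbors = 10,
                                      seed = 5))
  expect_true(all(startsWith(sub$cluster, "T.")))
  expect_equal(ari(sub$cluster, truth[sub$barcode]), 1)
})

test_that("a cluster-exclusive gene is its top marker with pct_out 0", {
  set.seed(2)
  counts <- matrix(rpois(5 * 100, 2), nrow = 5,
                   dimnames = list(sprintf("G%d", 1:5), sprintf("c%03d", 1:100)))
  counts["G5", ] <- 0
  counts["G5", 1:50] <- rpois(50, 5) + 1
  cgm <- make_cgm(counts)
  norm <- normalize_log(cgm)
  asn <- make_assignment(colnames(counts), rep(c("A", "B"), each = 50))
  mk <- find_markers(norm, asn)
  a <- mk[mk$cluster == "A", ]
  expect_equal(a$gene[1], "G5")
  expect_equal(a$pct_out[a$gene == "G5"], 0)
  expect_gt(a$log2_fc[a$gene == "G5"], 0.5)
})

test_that("rank-sum p equals exact enumeration on small groups", {
  set.seed(3)
  for (rep in 1:5) {
    x <- sample(0:4, 6, replace = TRUE) # ties included
    y <- sample(2:6, 6, replace = TRUE)
    counts <- rbind(G1 = c(x, y) + 1) # keep library sizes equal
    counts <- rbind(counts, LIB = 10 - counts[1, ])
    colnames(counts) <- sprintf("c%02d", 1:12)
    cgm <- make_cgm(counts)
    norm <- normalize_log(cgm)
    asn <- make_assignment(colnames(counts), rep(c("A", "B"), each = 6))
    mk <- suppressWarnings(find_markers(norm, asn, min_frac = 0))
    p_impl <- mk$p_value[mk$cluster == "A" & mk$gene == "G1"]
    v <- as.matrix(norm)["G1", ]
    expect_equal(p_impl, ranksum_oracle(v[1:6], v[7:12]), tolerance = 1e-12)
  }
})

test_that("marker q-values respect BH monotonicity and dominate p", {
  specs <- list(cluster_spec("A", 30, c("GA1", "GA2")),
                cluster_spec("B", 30, c("GB1", "GB2")))
  ds <- generate_dataset(specs, n_patients = 2, seed = 29)
  norm <- normalize_log(ds$matrix)
  asn <- truth_assignment(ds$truth)
  mk <- find_markers(norm, asn)
  expect_true(all(mk$q_value >= mk$p_value - 1e-15))
  o <- order(mk$p_value)
  expect_true(all(diff(mk$q_value[o]) >= -1e-12))
})

test_that("annotation assigns unique rules, ties are ambiguous", {
  mk <- data.frame(
    gene = c("CD3D", "CD8A", "CD4", "CD3D", "NKG7"),
    cluster = c("C1", "C1", "C2", "C2", "C3"),
    log2_fc = 2, pct_in = 0.9, pct_out = 0.1,
    p_value = 1e-20, q_value = 1e-18
  )
  rules <- list(
    marker_rule("CD8 T", c("CD3D", "CD8A")),
    marker_rule("T cell", "CD3D"),
    marker_rule("NK", "NKG7", forbidden = "CD3D")
  )
  ann <- annotate_clusters(mk, rules)
  expect_equal(unname(ann["C1"]), "ambiguous") # matches both T rules
  expect_equal(unname(ann["C2"]), "T cell")
  expect_equal(unname(ann["C3"]), "NK")
  mk2 <- mk
  mk2$q_value <- 0.5
  expect_equal(unname(annotate_clusters(mk2, rules)),
               rep("unassigned", 3))
  expect_error(annotate_clusters(mk, c(rules, rules[1])), "duplicate")
})

test_that("planted lineages annotate 1:1 on the demo fixture", {
  spec <- demo_specs(n_cells_per_sample = 25)
  ds <- generate_dataset(spec$cluster_specs, spec$sharing_specs, spec$lr_spec,
                         n_patients = 4, seed = 37,
                         lineage_marker_sets = spec$lineage_marker_sets)
  norm <- normalize_log(ds$matrix)
  asn <- truth_assignment(ds$truth)
  mk <- find_markers(norm, asn)
  ann <- annotate_clusters(mk, spec$marker_rules)
  expect_equal(
    unname(ann[c("Myeloid", "B", "NK", "T_CD4", "T_CD8_CX3CR1", "T_CD8_CXCR3")]),
    c("Myeloid", "B cells", "NK", "CD4 T",
      "CX3CR1hi effector CD8 T", "CXCR3hi effector CD8 T")
  )
})

test_that("compartment composition: null case, paired oracle, normalization", {
  # 4 patients x 2 compartments, 2 clusters; identical fractions -> t=0, p=1
  pats <- sprintf("P%d", 1:4)
  meta <- expand.grid(patient = pats, compartment = c("PB", "SF"),
                      cell = 1:10, stringsAsFactors = FALSE)
  meta$sample_id <- paste0(meta$patient, "_", meta$compartment)
  meta$barcode <- sprintf("b%03d", seq_len(nrow(meta)))
  asn <- make_assignment(meta$barcode, rep(c("X", "Y"), length.out = nrow(meta)))
  cc <- compartment_composition(asn, meta, paired = TRUE)
  expect_true(all(abs(rowSums(cc$fractions) - 1) < 1e-12))
  expect_equal(cc$tests$p_value, c(1, 1))
  expect_equal(cc$tests$statistic, c(0, 0))

  # constructed paired fractions: p equals the closed-form paired t
  frac_pb <- c(0.2, 0.3, 0.25, 0.4)
  frac_sf <- c(0.5, 0.6, 0.45, 0.7)
  rows <- list()
  for (i in 1:4) {
    n <- 20
    n_x_pb <- round(frac_pb[i] * n); n_x_sf <- round(frac_sf[i] * n)
    rows[[i]] <- data.frame(
      patient = pats[i],
      compartment = rep(c("PB", "SF"), each = n),
      cluster = c(rep("X", n_x_pb), rep("Y", n - n_x_pb),
                  rep("X", n_x_sf), rep("Y", n - n_x_sf))
    )
  }
  df <- do.call(rbind, rows)
  df$sample_id <- paste0(df$patient, "_", df$compartment)
  df$barcode <- sprintf("q%03d", seq_len(nrow(df)))
  asn2 <- make_assignment(df$barcode, df$cluster)
  cc2 <- compartment_composition(asn2, df, paired = TRUE)
  d <- round(frac_pb * 20) / 20 - round(frac_sf * 20) / 20
  t_exp <- mean(d) / (sd(d) / sqrt(4))
  p_exp <- 2 * pt(-abs(t_exp), df = 3)
  x_row <- cc2$tests[cc2$tests$cluster == "X", ]
  expect_equal(x_row$statistic, t_exp, tolerance = 1e-12)
  expect_equal(x_row$p_value, p_exp, tolerance = 1e-12)

  # unmatched patients are reported
  df_bad <- df[!(df$patient == "P4" & df$compartment == "SF"), ]
  asn_bad <- make_assignment(df_bad$barcode, df_bad$cluster)
  expect_error(compartment_composition(asn_bad, df_bad, paired = TRUE), "P4")
})

test_that("three groups go through ANOVA with Bonferroni pairwise tests", {
  meta <- data.frame(
    patient = rep(sprintf("P%d", 1:9), each = 20),
    compartment = rep(c("g1", "g2", "g3"), each = 60)
  )
  meta$sample_id <- meta$patient
  meta$barcode <- sprintf("a%03d", seq_len(nrow(meta)))
  set.seed(4)
  cl <- ifelse(runif(nrow(meta)) <
                 rep(c(0.2, 0.5, 0.8), each = 60), "X", "Y")
  asn <- make_assignment(meta$barcode, cl)
  cc <- compartment_composition(asn, meta, paired = FALSE)
  expect_equal(nrow(cc$tests), 2)
  expect_true("pairwise" %in% names(cc))
  expect_lt(cc$tests$p_value[cc$tests$cluster == "X"], 0.05)
})
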