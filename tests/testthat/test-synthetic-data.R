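test_that("zero-doublet, zero-sharing generation gives the expected barcodes", {
  specs <- list(
    cluster_spec("A", 100, c("GA1", "GA2"), lineage = "none"),
    cluster_spec("B", 100, c("GB1", "GB2"), lineage = "none")
  )
  ds <- generate_dataset(specs, n_patients = 1, doublet_rate = 0, seed = 5)
  expect_equal(ncol(ds$matrix$counts), 200)
  expect_length(ds$truth$doublet_barcodes, 0)
  expect_equal(nrow(ds$contigs), 0)
  expect_setequal(names(ds$truth$cell_cluster), ds$matrix$barcodes)
})

test_that("planted shared clones are exactly recoverable by set intersection", {
  specs <- list(
    cluster_spec("A", 30, c("GA1", "GA2")),
    cluster_spec("B", 30, c("GB1", "GB2"))
  )
  sh <- list(sharing_spec(c("A", "B"), n_shared_clones = 5,
                          n_private_clones_per_cluster = 10))
  ds <- generate_dataset(specs, sh, n_patients = 2, seed = 11)
  sigs <- brute_clone_signatures(ds$contigs)
  cl <- ds$truth$cell_cluster[names(sigs)]
  in_a <- unique(sigs[cl == "A"])
  in_b <- unique(sigs[cl == "B"])
  shared <- intersect(in_a, in_b)
  expect_length(shared, 5)
  expect_setequal(shared, ds$truth$shared_clones[["A|B"]])
})

test_that("same seed reproduces byte-identical fixtures", {
  specs <- list(cluster_spec("A", 20, "GA1"), cluster_spec("B", 20, "GB1"))
  sh <- list(sharing_spec(c("A", "B"), 3, 5))
  d1 <- file.path(tempfile(), "f1")
  d2 <- file.path(tempfile(), "f2")
  write_fixture(generate_dataset(specs, sh, n_patients = 2, seed = 9,
                                 doublet_rate = 0.05), d1)
  write_fixture(generate_dataset(specs, sh, n_patients = 2, seed = 9,
                                 doublet_rate = 0.05), d2)
  for (f in c("matrix.mtx", "barcodes.tsv", "features.tsv", "contigs.tsv",
              "metadata.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("invalid specifications are rejected", {
  expect_error(cluster_spec("A", 10, "G1", signature_mean = 1,
                            background_mean = 2),
               "signature_mean")
  expect_error(cluster_spec("A", 10, "G1", compartment_bias = 1.2),
               "compartment_bias")
  overlapping <- list(cluster_spec("A", 10, c("G1", "G2")),
                      cluster_spec("B", 10, c("G2", "G3")))
  expect_error(generate_dataset(overlapping, n_patients = 1, seed = 1),
               "shared across clusters")
  specs <- list(cluster_spec("A", 10, "G1"), cluster_spec("B", 10, "G2"))
  expect_error(
    generate_dataset(specs, list(sharing_spec(c("A", "Z"), 1, 1)),
                     n_patients = 1, seed = 1),
    "unknown cluster"
  )
  expect_error(generate_dataset(specs, n_patients = 1, doublet_rate = 0.5,
                                seed = 1),
               "doublet_rate")
})

test_that("compartment bias is recovered within binomial bounds", {
  n <- 60 # cells per seed for the biased cluster
  lo <- qbinom(0.005, n, 0.9)
  hi <- qbinom(0.995, n, 0.9)
  for (s in 1:20) {
    specs <- list(cluster_spec("SFC", 30, "G1", compartment_bias = 0.9),
                  cluster_spec("Oth", 10, "G2", compartment_bias = 0.5))
    ds <- generate_dataset(specs, n_patients = 2, seed = 4000 + s)
    meta <- ds$matrix$cell_meta
    cl <- ds$truth$cell_cluster[meta$barcode]
    n_sf <- sum(meta$compartment[cl == "SFC"] == "SF")
    expect_gte(n_sf, lo)
    expect_lte(n_sf, hi)
  }
})

test_that("doublet library sizes stochastically dominate singlets", {
  specs <- list(cluster_spec("A", 50, c("GA1", "GA2", "GA3")),
                cluster_spec("B", 50, c("GB1", "GB2", "GB3")))
  ds <- generate_dataset(specs, n_patients = 4, doublet_rate = 0.1, seed = 21)
  libs <- Matrix::colSums(ds$matrix$counts)
  dbl <- libs[ds$truth$doublet_barcodes]
  sgl <- libs[setdiff(names(libs), ds$truth$doublet_barcodes)]
  # sum construction: doublet library quartiles sit above singlet quartiles
  expect_gt(median(dbl), median(sgl))
  expect_gt(quantile(dbl, 0.25), quantile(sgl, 0.25))
  expect_gt(mean(dbl), 1.7 * mean(sgl))
})

test_that("clone sizes follow the specified geometric expansion", {
  # single-cluster dataset with enough cells for >= 1000 geometric clones
  specs <- list(cluster_spec("T1", 420, "G1"))
  ds <- generate_dataset(specs, n_patients = 8, seed = 31,
                         default_expansion_p = 0.5)
  sizes <- as.integer(table(ds$truth$cell_clone))
  expect_gte(length(sizes), 1000)
  bins <- pmin(sizes, 5)
  obs <- tabulate(bins, 5)
  p_geom <- dgeom(0:3, 0.5)
  probs <- c(p_geom, 1 - sum(p_geom))
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("fixtures round-trip through write_fixture/read_matrix/read_contigs", {
  specs <- list(cluster_spec("A", 15, c("GA1", "GA2")),
                cluster_spec("B", 15, c("GB1", "GB2")))
  sh <- list(sharing_spec(c("A", "B"), 2, 4))
  ds <- generate_dataset(specs, sh, n_patients = 2, seed = 13)
  dir <- tempfile()
  paths <- write_fixture(ds, dir)
  m2 <- read_matrix(dir)
  expect_equal(as.matrix(m2$counts), as.matrix(ds$matrix$counts))
  expect_identical(m2$cell_meta, ds$matrix$cell_meta)
  expect_identical(m2$gene_symbols, ds$matrix$gene_symbols)
  c2 <- read_contigs(paths[["contigs"]])
  expect_equal(c2$barcode, ds$contigs$barcode)
  expect_equal(c2$productive, ds$contigs$productive)
  expect_equal(c2$cdr3_nt, ds$contigs$cdr3_nt)
  # matrix.mtx header declares (genes, cells)
  hdr <- readLines(paths[["matrix"]], n = 3)[3]
  dims <- as.integer(strsplit(hdr, " ")[[1]][1:2])
  expect_equal(dims, c(nrow(ds$matrix$counts), 30 * 2))
  # truth round-trips, including the seed
  tr <- read_truth(paths[["truth"]])
  expect_equal(tr$seed, 13L)
  expect_equal(tr$cell_cluster, ds$truth$cell_cluster)
  expect_equal(tr$shared_clones, ds$truth$shared_clones)
})

test_that("an empty dataset writes valid header-only files", {
  specs <- list(cluster_spec("A", 0, "GA1", lineage = "none"))
  ds <- generate_dataset(specs, n_patients = 1, seed = 1)
  dir <- tempfile()
  write_fixture(ds, dir)
  m <- read_matrix(dir)
  expect_equal(ncol(m$counts), 0)
  expect_gt(nrow(m$counts), 0)
})

test_that("write_fixture refuses a non-empty directory without overwrite", {
  specs <- list(cluster_spec("A", 5, "GA1", lineage = "none"))
  ds <- generate_dataset(specs, n_patients = 1, seed = 2)
  dir <- tempfile()
  write_fixture(ds, dir)
  expect_error(write_fixture(ds, dir), "not empty")
  expect_silent(write_fixture(ds, dir, overwrite = TRUE))
})
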