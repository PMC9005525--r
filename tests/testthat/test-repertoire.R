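contig_row <- function(barcode, chain, cdr3, productive = TRUE, v = "V1",
                       j = "J1") {
  data.frame(barcode = barcode, chain = chain, v_gene = v, j_gene = j,
             cdr3_nt = cdr3, cdr3_aa = "CASF", productive = productive,
             umis = 2L, stringsAsFactors = FALSE)
}

test_that("clonotype calling groups by productive chain signature", {
  # one cell, productive TRA+TRB -> one clone with one cell
  ct <- rbind(contig_row("b1", "TRA", "TGTGCA"), contig_row("b1", "TRB", "TGTGGG"))
  cl <- call_clonotypes(ct)
  expect_equal(nrow(cl$clones), 1)
  expect_equal(cl$clones$n_cells, 1L)
  expect_equal(cl$clones$n_chains, 2L)

  # identical signatures merge; extra nonproductive chain is ignored
  ct2 <- rbind(
    contig_row("b1", "TRA", "TGTGCA"), contig_row("b1", "TRB", "TGTGGG"),
    contig_row("b2", "TRA", "TGTGCA"), contig_row("b2", "TRB", "TGTGGG"),
    contig_row("b2", "TRB", "TGTAAA", productive = FALSE)
  )
  cl2 <- call_clonotypes(ct2)
  expect_equal(nrow(cl2$clones), 1)
  expect_equal(cl2$clones$n_cells, 2L)

  # an extra *productive* chain makes a distinct multi-chain clone
  ct3 <- rbind(ct2[1:4, ], contig_row("b2", "TRB", "TGTAAA"))
  cl3 <- call_clonotypes(ct3)
  expect_equal(nrow(cl3$clones), 2)
  expect_equal(sort(cl3$clones$n_chains), c(2L, 3L))

  # cells with no productive chain are absent
  ct4 <- contig_row("b9", "TRA", "TGTCCC", productive = FALSE)
  expect_equal(nrow(call_clonotypes(ct4)$cells), 0)
})

test_that("clonotype calling equals brute-force grouping on a fixture", {
  specs <- list(cluster_spec("A", 30, "GA1"), cluster_spec("B", 30, "GB1"))
  sh <- list(sharing_spec(c("A", "B"), 4, 8))
  ds <- generate_dataset(specs, sh, n_patients = 2, seed = 41)
  cl <- call_clonotypes(ds$contigs)
  oracle <- brute_clone_signatures(ds$contigs)
  expect_equal(nrow(cl$clones), length(unique(oracle)))
  expect_equal(setNames(cl$cells$signature, cl$cells$barcode),
               oracle[cl$cells$barcode])
  # generator truth agrees with called signatures
  expect_equal(ds$truth$cell_clone[cl$cells$barcode],
               setNames(cl$cells$signature, cl$cells$barcode))
})

test_that("clonal fractions are cellcounts over clone-bearing cells", {
  ct <- do.call(rbind, c(
    lapply(sprintf("b%02d", 1:5), contig_row, chain = "TRA", cdr3 = "AAA"),
    lapply(sprintf("b%02d", 6:50), function(b) {
      contig_row(b, "TRA", paste0("C", b))
    })
  ))
  meta <- data.frame(barcode = sprintf("b%02d", 1:50), sample_id = "S1")
  cl <- call_clonotypes(ct, meta)
  cf <- clonal_fraction(cl, "S1")
  expect_equal(sum(cf), 1)
  clone_a <- cl$cells$clone_id[cl$cells$barcode == "b01"]
  expect_equal(unname(cf[clone_a]), 0.1) # 5 of 50 clone-bearing cells
  expect_error(clonal_fraction(cl, "nope"), "unknown sample")

  ct_one <- contig_row("b1", "TRA", "AAA")
  cl_one <- call_clonotypes(ct_one, data.frame(barcode = "b1", sample_id = "S1"))
  expect_equal(unname(clonal_fraction(cl_one, "S1")), 1)
})

test_that("top_expanded ranks by count with total-count tie-break", {
  mk <- function(clone, n, compartment) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      contig_row(sprintf("%s_%s_%02d", clone, compartment, i), "TRA",
                 paste0("CDR", clone))
    }))
  }
  # PB: clone X 7 cells, clone Y 7 cells; totals differ via SF cells
  ct <- rbind(mk("X", 7, "PB"), mk("Y", 7, "PB"), mk("Y", 3, "SF"),
              mk("Z", 2, "PB"))
  meta <- data.frame(barcode = unique(ct$barcode))
  meta$compartment <- sub(".*_(PB|SF)_.*", "\\1", meta$barcode)
  meta$sample_id <- paste0("P1_", meta$compartment)
  cl <- call_clonotypes(ct, meta)
  asn <- make_assignment(meta$barcode, "T")
  top <- top_expanded(cl, asn, meta, n = 100)
  pb <- top$top[top$top$scope == "PB", ]
  expect_equal(nrow(pb), 3) # n exceeds the population: all clones returned
  y_id <- cl$cells$clone_id[grepl("^Y", cl$cells$barcode)][1]
  x_id <- cl$cells$clone_id[grepl("^X", cl$cells$barcode)][1]
  expect_equal(pb$clone_id[1], y_id) # tied at 7, Y has larger total
  expect_equal(pb$clone_id[2], x_id)
  expect_error(top_expanded(cl, asn, meta, n = 0), "positive")
})

test_that("overlap matrix counts shared clones exactly", {
  # disjoint clone sets -> zero off-diagonal
  ct <- rbind(contig_row("a1", "TRA", "AAA"), contig_row("a2", "TRA", "CCC"),
              contig_row("b1", "TRA", "GGG"), contig_row("b2", "TRA", "TTT"))
  cl <- call_clonotypes(ct)
  asn <- make_assignment(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  om <- overlap_matrix(cl, asn)
  expect_equal(om["A", "B"], 0L)
  expect_equal(om["A", "A"], 2L)

  # identical clone sets of size s -> entry s
  ct2 <- rbind(contig_row("a1", "TRA", "AAA"), contig_row("a2", "TRA", "CCC"),
               contig_row("b1", "TRA", "AAA"), contig_row("b2", "TRA", "CCC"))
  om2 <- overlap_matrix(call_clonotypes(ct2), asn)
  expect_equal(om2["A", "B"], 2L)

  # generator fixture: entry equals brute-force set intersection
  specs <- list(cluster_spec("A", 30, "GA1"), cluster_spec("B", 30, "GB1"))
  sh <- list(sharing_spec(c("A", "B"), 5, 10))
  ds <- generate_dataset(specs, sh, n_patients = 2, seed = 43)
  clono <- call_clonotypes(ds$contigs)
  asn3 <- truth_assignment(ds$truth)
  om3 <- overlap_matrix(clono, asn3)
  sigs <- brute_clone_signatures(ds$contigs)
  cc <- ds$truth$cell_cluster[names(sigs)]
  brute <- length(intersect(unique(sigs[cc == "A"]), unique(sigs[cc == "B"])))
  expect_gte(om3["A", "B"], 5)
  expect_equal(om3["A", "B"], brute)
})

test_that("overlap test matches the hypergeometric tail and BH step-up", {
  om <- matrix(c(10L, 5L, 5L, 8L), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  res <- overlap_test(om, universe_size = 20)
  expect_equal(res$p_one_sided, hyper_tail_oracle(5, 10, 8, 20),
               tolerance = 1e-14)

  # zero overlap -> p = 1
  om0 <- matrix(c(4L, 0L, 0L, 6L), 2, 2,
                dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(overlap_test(om0, 30)$p_one_sided, 1)

  # impossible table is rejected
  om_bad <- matrix(c(3L, 5L, 5L, 8L), 2, 2,
                   dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(overlap_test(om_bad, 30), "exceeds")

  # BH on a constructed p-vector: (0.01, 0.02, 0.03) -> all 0.03
  om3 <- diag(c(40L, 40L, 40L, 40L))
  dimnames(om3) <- list(LETTERS[1:4], LETTERS[1:4])
  # choose shared counts giving three distinct small p-values
  res3 <- local({
    m <- om3
    m[1, 2] <- m[2, 1] <- 20L
    m[1, 3] <- m[3, 1] <- 18L
    m[2, 3] <- m[3, 2] <- 16L
    overlap_test(m, universe_size = 400)
  })
  expect_equal(res3$q_bh, bh_oracle(res3$p_one_sided), tolerance = 1e-14)
})

test_that("overlap p-values equal enumeration for all universes up to 12", {
  for (U in 2:12) {
    for (a in 1:U) {
      for (b in 1:a) {
        for (s in max(0, a + b - U):min(a, b)) {
          om <- matrix(c(a, s, s, b), 2, 2,
                       dimnames = list(c("A", "B"), c("A", "B")))
          storage.mode(om) <- "integer"
          p <- overlap_test(om, U)$p_one_sided
          expect_equal(p, hyper_tail_oracle(s, a, b, U), tolerance = 1e-12)
        }
      }
    }
  }
})
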