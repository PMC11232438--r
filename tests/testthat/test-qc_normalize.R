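test_that("isoform collapsing sums contig rows per gene", {
  m <- Matrix::Matrix(matrix(c(2, 3, 0,
                               3, 0, 1,
                               1, 1, 1), 3, 3, byrow = TRUE,
                             dimnames = list(c("a1", "a2", "b1"),
                                             paste0("c", 1:3))),
                      sparse = TRUE)
  map <- data.frame(contig_id = c("a1", "a2", "b1"),
                    gene_id = c("A", "A", "B"))
  out <- collapse_isoforms(m, map)
  expect_equal(as.numeric(out["A", ]), c(5, 3, 1))
  expect_equal(as.numeric(out["B", ]), c(1, 1, 1))
  expect_error(collapse_isoforms(m, map[-1, ]), "a1")
  # single-contig genes unchanged up to naming
  solo <- collapse_isoforms(m, data.frame(contig_id = rownames(m),
                                          gene_id = rownames(m)))
  expect_identical(as.matrix(solo), as.matrix(m))
})

test_that("UMI-bound filter keeps boundary totals and recomputes after gene removal", {
  totals <- c(499, 500, 10000, 18000, 18001)
  m <- Matrix::Matrix(rbind(totals - 10, rep(10, 5)), sparse = TRUE,
                      dimnames = list(c("g1", "rrna"), paste0("c", 1:5)))
  f <- filter_cells_genes(m, qc_params())
  expect_equal(colnames(f$counts), c("c2", "c3", "c4"))
  expect_equal(f$report$n_cells_removed, 2)
  # removing a contaminant drops cells whose remaining total falls below 500
  f2 <- filter_cells_genes(m, qc_params(contaminant_genes = "rrna"))
  expect_equal(f2$report$n_genes_removed, 1)
  expect_false("c2" %in% colnames(f2$counts))  # 500 - 10 = 490 < 500
  # idempotence
  f3 <- filter_cells_genes(f$counts, qc_params())
  expect_identical(as.matrix(f3$counts), as.matrix(f$counts))
  # all-removed warns explicitly
  tiny <- Matrix::Matrix(matrix(1, 1, 2,
                                dimnames = list("g", c("a", "b"))),
                         sparse = TRUE)
  expect_warning(filter_cells_genes(tiny, qc_params()), "all cells removed")
})

test_that("filter removes exactly the planted out-of-bounds cells", {
  sim <- simulate_atlas(sim_config(n_cells_x1 = 300, n_cells_g0 = 300,
                                   libsize_logsd = 1.1, seed = 13))
  tot <- Matrix::colSums(sim$counts)
  planted_out <- sum(tot < 500 | tot > 18000)
  f <- filter_cells_genes(sim$counts, qc_params())
  expect_equal(f$report$n_cells_removed, planted_out)
})

test_that("lognormalize matches the stated formula and inverts exactly", {
  m <- Matrix::Matrix(matrix(c(5, 2495, 0, 100), 2, 2,
                             dimnames = list(c("g1", "g2"),
                                             c("c1", "c2"))), sparse = TRUE)
  nm <- lognormalize(m, scale_factor = 10000)
  expect_equal(nm$mat["g1", "c1"], log(21), tolerance = 1e-12)
  expect_equal(nm$mat["g1", "c2"], 0)
  set.seed(42)
  r <- Matrix::Matrix(matrix(rpois(200, 4) + 1, 20, 10), sparse = TRUE)
  dimnames(r) <- list(paste0("g", 1:20), paste0("c", 1:10))
  back <- denormalize(lognormalize(r))
  expect_lt(max(abs(as.matrix(back) - as.matrix(r))), 1e-9)
  zero <- Matrix::Matrix(matrix(c(1, 0), 1, 2,
                                dimnames = list("g", c("a", "b"))),
                         sparse = TRUE)
  expect_error(lognormalize(zero), "zero-total")
})

test_that("gating applies strict inequalities and the rule conjunction", {
  vals <- rbind("smedwi" = c(0.51, 0.50, 3.4, 3.6, 3.4),
                "p4hb"   = c(0.00, 0.00, 1.6, 1.6, 1.5))
  nm <- structure(list(mat = Matrix::Matrix(vals, sparse = TRUE,
                                            dimnames = list(rownames(vals),
                                                            paste0("c", 1:5))),
                       totals = rep(1, 5), scale_factor = 1e4),
                  class = "normalized_matrix")
  gx <- gate_cells(nm, x1_gate("smedwi"))
  expect_true("c1" %in% gx$barcodes)
  expect_false("c2" %in% gx$barcodes)   # 0.50 is not > 0.5
  gg <- gate_cells(nm, g0_gate("smedwi", "p4hb"))
  expect_equal(gg$barcodes, "c3")       # 3.6 fails <3.5; 1.5 fails >1.5
  expect_error(gate_cells(nm, x1_gate("absent-gene")), "absent-gene")
})

test_that("gates recover planted stage labels on synthetic data", {
  sim <- simulate_atlas(sim_config(n_cells_x1 = 400, n_cells_g0 = 400,
                                   seed = 21))
  f <- filter_cells_genes(sim$counts, qc_params())
  nm <- lognormalize(f$counts)
  truth <- sim$truth$cells
  x1_true <- truth$barcode[truth$stage == "X1"]
  kept_x1 <- intersect(colnames(nm$mat), x1_true)
  kept_g0 <- setdiff(colnames(nm$mat), x1_true)
  gx <- gate_cells(nm, x1_gate("smedwi1-like"))
  gg <- gate_cells(nm, g0_gate("smedwi1-like", "p4hb-like"))
  expect_gt(mean(kept_x1 %in% gx$barcodes), 0.95)
  expect_gt(mean(kept_g0 %in% gg$barcodes), 0.9)
  expect_lt(mean(kept_x1 %in% gg$barcodes), 0.05)
})

test_that("scale_center gives mean 0 / unit sd with n-1 denominator", {
  m <- matrix(c(1, 3, 2, 2), 2, 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("c1", "c2")))
  s <- scale_center(m)
  expect_equal(as.numeric(s["g1", ]), c(-0.7071, 0.7071), tolerance = 1e-4)
  expect_equal(as.numeric(s["g2", ]), c(0, 0))
  set.seed(31)
  big <- matrix(rnorm(10000, mean = 5, sd = 3), 1, 10000)
  rownames(big) <- "g"
  sb <- scale_center(big)
  expect_lt(abs(mean(sb)), 0.05)
  expect_true(var(as.numeric(sb)) > 0.95 && var(as.numeric(sb)) < 1.05)
})

test_that("PCA is variance-ordered, sign-fixed, and separates planted blobs", {
  line <- rbind(seq(-5, 5, length.out = 50),
                2 * seq(-5, 5, length.out = 50))
  dimnames(line) <- list(c("g1", "g2"), paste0("c", 1:50))
  p <- pca_embed(scale_center(line), 2)
  expect_gt(p$var_explained[1], 0.999)
  blobs <- make_blobs(3, 60, p = 8, sep = 3, sd = 0.3, seed = 41)
  pb <- pca_embed(t(blobs$x), 2)
  expect_gt(mean_silhouette(pb$coords, blobs$labels), 0.5)
  pb2 <- pca_embed(t(blobs$x), 2)
  expect_identical(pb$coords, pb2$coords)
  expect_error(pca_embed(line, 10), "n_components")
})

test_that("elbow rule picks the first small variance drop", {
  ev <- c(0.4, 0.2, 0.1, 0.099, 0.098, 0.097)
  # drops: .2 .1 .001 .001 .001 ; first below 5% of 0.2 (=0.01) is index 3
  expect_equal(choose_pcs_elbow(ev), 3)
})

test_that("graph clustering recovers separated blobs deterministically", {
  blobs <- make_blobs(2, 50, p = 5, sep = 4, sd = 0.2, seed = 51)
  for (res in c(0.5, 1)) {
    cl <- cluster_graph(blobs$x, resolution = res, seed = 1)
    expect_equal(adjusted_rand_index(cl$labels, blobs$labels), 1)
  }
  cl_leiden <- cluster_graph(blobs$x, method = "leiden", seed = 1)
  expect_equal(adjusted_rand_index(cl_leiden$labels, blobs$labels), 1)
  cl2 <- cluster_graph(blobs$x, seed = 1)
  expect_identical(cluster_graph(blobs$x, seed = 1)$labels, cl2$labels)
  expect_equal(sort(unique(cl2$labels)), 0:1)
  one <- cluster_graph(blobs$x[1, , drop = FALSE])
  expect_equal(unname(one$labels), 0L)
  expect_warning(cluster_graph(blobs$x[1:5, ], k = 20), "reduced")
})

test_that("2D embedding keeps planted subtypes closer than others", {
  tri <- matrix(c(0, 0, 1, 0, 2, 0), 3, 2, byrow = TRUE,
                dimnames = list(paste0("c", 1:3), NULL))
  e <- embed_2d(tri, method = "pca2")
  expect_equal(order(e[, 1]), order(tri[, 1]))
  blobs <- make_blobs(4, 40, p = 6, sep = 4, sd = 0.2, seed = 61)
  for (method in c("pca2", "graph_fr")) {
    em <- embed_2d(blobs$x, method = method, seed = 3)
    d <- as.matrix(dist(em))
    same <- outer(blobs$labels, blobs$labels, `==`) & upper.tri(d)
    diff_ <- outer(blobs$labels, blobs$labels, `!=`) & upper.tri(d)
    expect_lt(mean(d[same]), mean(d[diff_]))
    expect_identical(em, embed_2d(blobs$x, method = method, seed = 3))
  }
})
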