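test_that("marker enrichment handles the forced all-vs-none gene", {
  n <- 100
  vals <- matrix(0, 3, n, dimnames = list(paste0("g", 1:3),
                                          sprintf("c%03d", 1:n)))
  labs <- rep(c("t", "rest"), c(20, 80))
  vals["g1", labs == "t"] <- 2.0
  set.seed(3)
  vals["g2", ] <- runif(n)           # same distribution in and out
  vals["g3", labs == "t"] <- 1.0
  vals["g3", labs != "t"] <- 0.9     # enriched but below screen
  m <- enriched_markers(vals, labs, "t", min_lnfc = 0.5)
  g1 <- m[m$gene == "g1", ]
  expect_equal(g1$pct_in, 1)
  expect_equal(g1$pct_out, 0)
  expect_equal(g1$log2_fc, 12)       # out-mean 0 -> sentinel cap
  expect_lt(g1$adj_p, 1e-10)
  expect_false("g2" %in% m$gene)     # lnFC ~ 0, screened out
  expect_false("g3" %in% m$gene)     # lnFC < 0.5, screened out
})

test_that("the ln fold-change screen is >= at the 0.5 boundary", {
  n <- 40
  labs <- rep(c("t", "rest"), each = n / 2)
  mk <- function(fold) {
    v <- matrix(0, 1, n, dimnames = list("g", sprintf("c%03d", 1:n)))
    base <- 0.8
    v["g", labs != "t"] <- log1p(base)
    v["g", labs == "t"] <- log1p(base * fold)
    v
  }
  at <- enriched_markers(mk(exp(0.5)), labs, "t", min_lnfc = 0.5)
  below <- enriched_markers(mk(exp(0.49)), labs, "t", min_lnfc = 0.5)
  expect_true("g" %in% at$gene)      # exactly 0.5 retained (>=)
  expect_false("g" %in% below$gene)  # 0.49 excluded
})

test_that("rank-sum p-values match the exact enumeration oracle on small groups", {
  set.seed(19)
  for (i in 1:3) {
    a <- round(runif(5, 1, 9), 3)     # tie-free continuous values
    b <- round(runif(5, 2, 10), 3)
    vals <- matrix(c(a, b), 1, 10,
                   dimnames = list("g", sprintf("c%02d", 1:10)))
    labs <- rep(c("in", "out"), each = 5)
    m <- enriched_markers(vals, labs, "in", min_lnfc = -20)
    expect_equal(m$p[m$gene == "g"], oracle_ranksum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("identical in/out distributions give flat fold change and p near 1", {
  set.seed(23)
  v <- matrix(rep(runif(30), 2), 1, 60,
              dimnames = list("g", sprintf("c%02d", 1:60)))
  labs <- rep(c("a", "b"), each = 30)
  m <- enriched_markers(v, labs, "a", min_lnfc = -1)
  expect_lt(abs(m$ln_fc), 1e-12)
  expect_gt(m$adj_p, 0.9)
})

test_that("atlas filters keep the 8 smallest adjusted p of 12 passing TFs", {
  set.seed(29)
  markers <- data.frame(
    cluster = "c0",
    gene = paste0("tf", 1:20),
    ln_fc = 1.5, log2_fc = c(rep(2, 12), rep(2, 4), rep(1.4, 4)),
    p = seq(1e-10, 1e-5, length.out = 20),
    adj_p = c(seq(1e-8, 1e-4, length.out = 12),   # 12 passing
              rep(0.002, 4),                       # fail adj_p
              rep(1e-6, 4)),                       # fail log2fc
    pct_in = c(rep(0.5, 12), rep(0.5, 4), rep(0.5, 4)),
    pct_out = 0.05)
  out <- tf_atlas_table(markers, paste0("tf", 1:20))
  expect_equal(nrow(out$atlas), 8)
  expect_setequal(out$atlas$gene, paste0("tf", 1:8))
  expect_equal(out$atlas$gene[out$atlas$rank == 1], "tf1")
  expect_equal(names(out$pvalues), c("cluster", "gene", "p", "adj_p"))
})

test_that("atlas gates act exactly at 1.5 / 0.001 / 20% with documented ties", {
  markers <- data.frame(
    cluster = "c0", gene = paste0("g", 1:6),
    ln_fc = 1, log2_fc = c(1.5, 1.499, 2, 2, 3, 2),
    p = 1e-6, adj_p = c(1e-4, 1e-4, 0.001, 0.0011, 1e-4, 1e-4),
    pct_in = c(0.20, 0.20, 0.20, 0.20, 0.199, 0.20), pct_out = 0)
  out <- tf_atlas_table(markers, paste0("g", 1:6), top_n = 2)
  # g2 fails log2fc, g4 fails adj_p, g5 fails pct; g1, g3, g6 pass
  expect_setequal(
    tf_atlas_table(markers, paste0("g", 1:6), top_n = 8)$atlas$gene,
    c("g1", "g3", "g6"))
  # tie at adj_p = 1e-4 between g1 (log2fc 1.5) and g6 (2): larger log2fc first
  expect_equal(out$atlas$gene[out$atlas$rank == 1], "g6")
  # re-running is byte-identical (pure function of the marker table)
  expect_identical(tf_atlas_table(markers, paste0("g", 1:6), top_n = 2),
                   out)
})

test_that("profile matching recovers identity and planted permutations", {
  set.seed(31)
  a <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(paste0("g", 1:50), paste0("A", 1:10)))
  self <- match_zprofiles(a, a)
  expect_equal(self$matches$b_cluster, self$matches$a_cluster)
  expect_equal(self$matches$distance, rep(0, 10))
  perm <- sample(10)
  b <- a[, perm]
  colnames(b) <- paste0("B", 1:10)
  got <- match_zprofiles(a, b)$matches
  expect_equal(got$b_cluster, paste0("B", order(perm)))
  # distance matrix is equivariant to cluster relabeling
  d1 <- match_zprofiles(a, b)$distance
  d2 <- match_zprofiles(a, a)$distance
  expect_equal(unname(d1), unname(d2[, perm]), tolerance = 1e-12)
})

test_that("matching tolerates noise on z-profiles at the stated rate", {
  correct <- 0; total <- 0
  for (seed in 1:20) {
    set.seed(seed + 900)
    a <- matrix(rnorm(50 * 10), 50, 10,
                dimnames = list(paste0("g", 1:50), paste0("A", 1:10)))
    perm <- sample(10)
    b <- a[, perm] + matrix(rnorm(500, sd = 0.5), 50, 10)
    colnames(b) <- paste0("B", 1:10)
    got <- match_zprofiles(a, b)$matches
    correct <- correct + sum(got$b_cluster == paste0("B", order(perm)))
    total <- total + 10
  }
  expect_gte(correct / total, 0.9)
})

test_that("end-to-end cluster matching works on mutually-enriched genes", {
  sim <- simulate_atlas(sim_config(n_tissues = 3, subtypes_per_tissue = 1,
                                   n_cells_x1 = 200, n_cells_g0 = 200,
                                   n_background_genes = 30, seed = 9))
  cells <- sim$truth$cells
  split_a <- cells$barcode[cells$stage == "X1"]
  split_b <- cells$barcode[cells$stage == "G0"]
  na <- lognormalize(sim$counts[, split_a])
  nb <- lognormalize(sim$counts[, split_b])
  la <- setNames(cells$tissue, cells$barcode)[split_a]
  lb <- setNames(cells$tissue, cells$barcode)[split_b]
  res <- match_clusters(na, la, nb, lb)
  expect_equal(res$matches$b_cluster, res$matches$a_cluster)
  expect_gt(length(res$shared_genes), 0)
})

test_that("correlation shift is zero on identical cell sets and signed on planted data", {
  set.seed(37)
  m <- matrix(rexp(4 * 100), 4, 100,
              dimnames = list(paste0("tf", 1:4), sprintf("c%03d", 1:100)))
  pairs <- data.frame(gene1 = c("tf1", "tf2"), gene2 = c("tf3", "tf4"))
  cs <- correlation_shift(m, m, pairs)
  expect_equal(cs$delta, c(0, 0))
  flat <- rbind(m, flat = 1)
  csf <- correlation_shift(flat, flat,
                           data.frame(gene1 = "flat", gene2 = "tf1"))
  expect_true(is.na(csf$r_x1))
  expect_match(csf$flag, "constant")
  expect_error(correlation_shift(m, m,
                                 data.frame(gene1 = "zz", gene2 = "tf1")),
               "zz")
})

test_that("tissue TF enrichment finds planted TFs and normalizes ratios", {
  sim <- simulate_atlas(sim_config(n_tissues = 3, subtypes_per_tissue = 1,
                                   module_size = 2, n_cells_x1 = 300,
                                   n_cells_g0 = 1, coupling_x1 = 0.95,
                                   n_background_genes = 20, seed = 43))
  cells <- sim$truth$cells
  x1 <- cells$barcode[cells$stage == "X1"]
  nm <- lognormalize(sim$counts[, x1])
  tissues <- setNames(cells$tissue, cells$barcode)[x1]
  gtab <- sim$truth$genes[sim$truth$genes$role == "module-TF", ]
  catalog <- data.frame(gene = gtab$gene_id,
                        families = rep(c("Homeodomain", "zf-C2H2"), 3),
                        stringsAsFactors = FALSE)
  res <- tissue_tf_enrichment(nm, tissues, catalog)
  for (i in seq_len(nrow(gtab))) {
    hit <- res$enriched[res$enriched$gene == gtab$gene_id[i], ]
    expect_true(gtab$tissue[i] %in% hit$tissue)
  }
  # ratio rows: 1 in the owning tissue, ~0 elsewhere; row max is 1
  hd <- res$homeodomain_ratio
  expect_true(all(abs(apply(hd, 1, max) - 1) < 1e-12))
  # a TF uniform across tissues has an all-1 ratio row
  flatnorm <- matrix(1, 2, 9, dimnames = list(c("u1", "u2"),
                                              sprintf("c%02d", 1:9)))
  res2 <- tissue_tf_enrichment(
    flatnorm, rep(c("T1", "T2", "T3"), each = 3),
    data.frame(gene = c("u1", "u2"), families = "Homeodomain"))
  expect_true(all(res2$homeodomain_ratio == 1))
})
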