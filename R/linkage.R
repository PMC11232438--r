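#' One-vs-rest marker enrichment for a cluster
#'
#' Screens genes whose natural-log fold change (on means of `expm1`
#' normalized expression, pseudocount 0) is at least `min_lnfc`, then tests
#' each with a two-sided Wilcoxon rank-sum test (one cluster vs the rest)
#' and Benjamini-Hochberg adjusts across the tested genes. With
#' pseudocount 0 an in-cluster mean over a zero out-mean gives an infinite
#' fold change; it is reported at the sentinel cap (`log2FC = fc_cap_log2`)
#' so sorting and threshold gates behave.
#'
#' @param norm A `normalized_matrix`.
#' @param labels Per-cell cluster labels (named by barcode or in column
#'   order).
#' @param target The cluster to contrast against all others.
#' @param min_lnfc Screen threshold on the ln fold change, applied as `>=`
#'   (default 0.5).
#' @param genes Optional gene subset to test.
#' @param fc_cap_log2 Sentinel cap for infinite fold changes (default 12).
#' @return Data frame `gene`, `ln_fc`, `log2_fc`, `p`, `adj_p`, `pct_in`,
#'   `pct_out`, sorted by increasing p.
#' @export
enriched_markers <- function(norm, labels, target, min_lnfc = 0.5,
                             genes = NULL, fc_cap_log2 = 12) {
  x <- if (inherits(norm, "normalized_matrix")) norm$mat else norm
  labs <- if (!is.null(names(labels))) labels[colnames(x)] else labels
  stopifnot(length(labs) == ncol(x))
  if (length(unique(labs)) < 2L) stop("need at least 2 clusters")
  sel_in <- labs == target
  if (!any(sel_in)) stop("target cluster is empty")
  if (sum(sel_in) == 1L)
    warning("target cluster has a single cell; test power is minimal")
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  x <- as.matrix(x)
  e <- expm1(x)
  mi <- rowMeans(e[, sel_in, drop = FALSE])
  mo <- rowMeans(e[, !sel_in, drop = FALSE])
  cap_ln <- fc_cap_log2 * log(2)
  ln_fc <- ifelse(mi == 0 & mo == 0, 0,
           ifelse(mo == 0, cap_ln,
           ifelse(mi == 0, -cap_ln, log(mi / mo))))
  ln_fc <- pmin(pmax(ln_fc, -cap_ln), cap_ln)
  keep <- which(ln_fc >= min_lnfc)
  if (length(keep) == 0L)
    return(data.frame(gene = character(), ln_fc = numeric(),
                      log2_fc = numeric(), p = numeric(), adj_p = numeric(),
                      pct_in = numeric(), pct_out = numeric()))
  p <- vapply(keep, function(i) suppressWarnings(
    wilcox.test(x[i, sel_in], x[i, !sel_in])$p.value), numeric(1))
  out <- data.frame(
    gene = rownames(x)[keep],
    ln_fc = ln_fc[keep],
    log2_fc = ln_fc[keep] / log(2),
    p = p,
    adj_p = p.adjust(p, method = "BH"),
    pct_in = rowMeans(x[keep, sel_in, drop = FALSE] > 0),
    pct_out = rowMeans(x[keep, !sel_in, drop = FALSE] > 0),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker enrichment for every cluster
#'
#' Runs [enriched_markers()] once per cluster and stacks the results with a
#' `cluster` column.
#'
#' @inheritParams enriched_markers
#' @return Data frame with a leading `cluster` column.
#' @export
find_all_markers <- function(norm, labels, min_lnfc = 0.5, genes = NULL,
                             fc_cap_log2 = 12) {
  x <- if (inherits(norm, "normalized_matrix")) norm$mat else norm
  labs <- if (!is.null(names(labels))) labels[colnames(x)] else labels
  out <- lapply(sort(unique(as.character(labs))), function(cl) {
    m <- enriched_markers(norm, labels, cl, min_lnfc = min_lnfc,
                          genes = genes, fc_cap_log2 = fc_cap_log2)
    if (nrow(m) == 0L) return(NULL)
    cbind(cluster = cl, m, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(cluster = character(), gene = character(),
                      ln_fc = numeric(), log2_fc = numeric(), p = numeric(),
                      adj_p = numeric(), pct_in = numeric(),
                      pct_out = numeric())
  rownames(out) <- NULL
  out
}

#' Filter marker tables into a TF atlas
#'
#' Per subcluster, keeps catalog TFs with `log2FC >= min_log2fc`,
#' `adj_p <= max_adj_p` and `pct_in >= min_pct`, sorts by increasing
#' adjusted p (ties broken by larger log2FC, then gene ID) and truncates to
#' the top `top_n`. Defaults are the published atlas gates: 1.5 / 0.001 /
#' 20% / top 8. A companion p-value sheet is returned alongside.
#'
#' @param markers Marker table from [find_all_markers()] (needs columns
#'   `cluster`, `gene`, `log2_fc`, `adj_p`, `pct_in`).
#' @param tf_genes Catalog TF gene IDs (e.g. `catalog$gene`).
#' @param min_log2fc,max_adj_p,min_pct,top_n Atlas gates.
#' @return A list: `atlas` (with per-cluster `rank`), `pvalues` (cluster,
#'   gene, p, adj_p).
#' @export
tf_atlas_table <- function(markers, tf_genes, min_log2fc = 1.5,
                           max_adj_p = 0.001, min_pct = 0.20, top_n = 8) {
  m <- markers[markers$gene %in% tf_genes &
                 markers$log2_fc >= min_log2fc &
                 markers$adj_p <= max_adj_p &
                 markers$pct_in >= min_pct, , drop = FALSE]
  out <- lapply(split(m, m$cluster), function(mm) {
    mm <- mm[order(mm$adj_p, -mm$log2_fc, mm$gene), , drop = FALSE]
    mm <- head(mm, top_n)
    mm$rank <- seq_len(nrow(mm))
    mm
  })
  atlas <- do.call(rbind, out)
  if (is.null(atlas)) atlas <- cbind(m, rank = integer(0))
  rownames(atlas) <- NULL
  list(atlas = atlas,
       pvalues = atlas[, c("cluster", "gene", "p", "adj_p")])
}

#' Per-cluster mean expression profiles
#'
#' @param norm A `normalized_matrix`.
#' @param labels Per-cell cluster labels (named by barcode or in column
#'   order).
#' @param genes Optional gene subset.
#' @return Genes-by-cluster matrix of mean normalized expression.
#' @export
cluster_mean_profiles <- function(norm, labels, genes = NULL) {
  x <- if (inherits(norm, "normalized_matrix")) norm$mat else norm
  labs <- if (!is.null(names(labels))) labels[colnames(x)] else labels
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  cls <- sort(unique(as.character(labs)))
  out <- vapply(cls, function(cl)
    Matrix::rowMeans(x[, labs == cl, drop = FALSE]), numeric(nrow(x)))
  rownames(out) <- rownames(x)
  out
}

zscore_profiles <- function(means) {
  # per gene across that dataset's clusters, population (n denominator) sd
  mu <- rowMeans(means)
  s <- sqrt(rowMeans((means - mu)^2))
  z <- (means - mu) / ifelse(s == 0, 1, s)
  z[s == 0, ] <- 0
  z
}

#' Match cluster profiles across datasets by z-scored distance
#'
#' Z-scores each gene across each dataset's cluster means (population sd)
#' and computes the Euclidean distance between every pair of cluster
#' z-profiles over the shared genes. The nearest B-cluster per A-cluster is
#' reported with its rank-1 distance; the full matrix supports inspecting
#' runner-up candidates for low-distance ambiguity.
#'
#' @param profile_a,profile_b Genes-by-cluster mean-expression matrices
#'   sharing a gene namespace (rows are intersected).
#' @return A list: `matches` (a_cluster, b_cluster, distance), `distance`
#'   (full A x B matrix), `shared_genes`.
#' @export
match_zprofiles <- function(profile_a, profile_b) {
  shared <- intersect(rownames(profile_a), rownames(profile_b))
  if (length(shared) == 0L)
    stop("no shared genes between the two profile sets")
  za <- zscore_profiles(profile_a[shared, , drop = FALSE])
  zb <- zscore_profiles(profile_b[shared, , drop = FALSE])
  d <- matrix(0, ncol(za), ncol(zb),
              dimnames = list(colnames(za), colnames(zb)))
  for (i in seq_len(ncol(za)))
    d[i, ] <- sqrt(colSums((zb - za[, i])^2))
  best <- apply(d, 1, which.min)
  matches <- data.frame(a_cluster = rownames(d),
                        b_cluster = colnames(d)[best],
                        distance = d[cbind(seq_len(nrow(d)), best)],
                        stringsAsFactors = FALSE)
  rownames(matches) <- NULL
  list(matches = matches, distance = d, shared_genes = shared)
}

#' Match subclusters between two datasets by mutually-enriched genes
#'
#' Finds genes enriched (marker screen passed and `adj_p <= max_adj_p`) in
#' at least one subcluster of each dataset, takes the intersection, and
#' matches clusters by Euclidean distance between per-dataset z-scored
#' average expression of just those mutually-enriched genes -- the
#' procedure used to relate G0 progenitor subclusters to differentiated
#' cell subclusters.
#'
#' @param norm_a,norm_b `normalized_matrix` objects sharing a gene
#'   namespace.
#' @param labels_a,labels_b Per-cell subcluster labels.
#' @param min_lnfc Marker screen threshold (default 0.5).
#' @param max_adj_p Adjusted-p gate defining "enriched" (default 0.05).
#' @return As [match_zprofiles()], plus `markers_a`, `markers_b`.
#' @export
match_clusters <- function(norm_a, labels_a, norm_b, labels_b,
                           min_lnfc = 0.5, max_adj_p = 0.05) {
  ma <- find_all_markers(norm_a, labels_a, min_lnfc = min_lnfc)
  mb <- find_all_markers(norm_b, labels_b, min_lnfc = min_lnfc)
  ga <- unique(ma$gene[ma$adj_p <= max_adj_p])
  gb <- unique(mb$gene[mb$adj_p <= max_adj_p])
  shared <- intersect(ga, gb)
  if (length(shared) == 0L)
    stop("no mutually-enriched genes; consider relaxing min_lnfc/max_adj_p")
  pa <- cluster_mean_profiles(norm_a, labels_a, genes = shared)
  pb <- cluster_mean_profiles(norm_b, labels_b, genes = shared)
  out <- match_zprofiles(pa, pb)
  out$markers_a <- ma
  out$markers_b <- mb
  out
}

#' TF-pair correlation shift between stages
#'
#' Computes the Pearson correlation of each TF pair separately across the
#' X1 (neoblast) and G0 (progenitor) cell sets, on normalized expression
#' with zeros included, and reports the per-pair shift. A constant gene in
#' a stage yields an undefined correlation for that stage, flagged rather
#' than dropped.
#'
#' @param norm_x1,norm_g0 `normalized_matrix` objects for the two stages.
#' @param pairs Data frame with columns `gene1`, `gene2` (or a 2-column
#'   matrix).
#' @return Data frame `gene1`, `gene2`, `r_x1`, `r_g0`, `delta`, `n_x1`,
#'   `n_g0`, `flag`.
#' @export
correlation_shift <- function(norm_x1, norm_g0, pairs) {
  if (is.matrix(pairs))
    pairs <- data.frame(gene1 = pairs[, 1], gene2 = pairs[, 2],
                        stringsAsFactors = FALSE)
  x1 <- if (inherits(norm_x1, "normalized_matrix")) norm_x1$mat else norm_x1
  g0 <- if (inherits(norm_g0, "normalized_matrix")) norm_g0$mat else norm_g0
  need <- unique(c(pairs$gene1, pairs$gene2))
  for (nm in list(c("X1", "x1"), c("G0", "g0"))) {
    m <- if (nm[2] == "x1") x1 else g0
    missing <- setdiff(need, rownames(m))
    if (length(missing) > 0)
      stop("gene(s) absent from ", nm[1], " matrix: ",
           paste(missing, collapse = ", "))
  }
  stage_r <- function(m, g1, g2) {
    a <- as.numeric(m[g1, ]); b <- as.numeric(m[g2, ])
    if (var(a) == 0 || var(b) == 0) NA_real_ else cor(a, b)
  }
  r1 <- vapply(seq_len(nrow(pairs)), function(i)
    stage_r(x1, pairs$gene1[i], pairs$gene2[i]), numeric(1))
  r2 <- vapply(seq_len(nrow(pairs)), function(i)
    stage_r(g0, pairs$gene1[i], pairs$gene2[i]), numeric(1))
  data.frame(gene1 = pairs$gene1, gene2 = pairs$gene2,
             r_x1 = r1, r_g0 = r2, delta = r2 - r1,
             n_x1 = ncol(x1), n_g0 = ncol(g0),
             flag = ifelse(is.na(r1) | is.na(r2),
                           "constant gene in a stage", ""),
             stringsAsFactors = FALSE)
}

#' Per-tissue TF enrichment and homeodomain expression ratios
#'
#' For each tissue, lists catalog TFs with enriched expression (unadjusted
#' p < 0.05, pseudocount-0 fold change) binned by DBD family. For
#' homeodomain TFs, builds the ratio matrix of per-tissue mean expression
#' divided by the maximum tissue mean, rows ordered by average-linkage
#' hierarchical clustering.
#'
#' @param norm A `normalized_matrix`.
#' @param tissues Per-cell tissue labels.
#' @param catalog Catalog entries ([categorize_tf_genes()] output) with
#'   `gene` and `families`.
#' @param p_max Unadjusted p gate (default 0.05).
#' @param homeo_pattern Regex identifying homeodomain families (default
#'   `"Homeo"`, case-insensitive).
#' @return A list: `enriched` (tissue, gene, family, log2_fc, p),
#'   `homeodomain_ratio` (TF-by-tissue matrix in clustered row order).
#' @export
tissue_tf_enrichment <- function(norm, tissues, catalog, p_max = 0.05,
                                 homeo_pattern = "Homeo") {
  x <- if (inherits(norm, "normalized_matrix")) norm$mat else norm
  if (length(unique(tissues)) < 2L) stop("need at least 2 tissues")
  tf_genes <- intersect(catalog$gene, rownames(x))
  fam_of <- stats::setNames(catalog$families, catalog$gene)
  markers <- find_all_markers(norm, tissues, min_lnfc = 0,
                              genes = tf_genes)
  enr <- markers[markers$p < p_max & markers$ln_fc > 0, , drop = FALSE]
  enriched <- data.frame(tissue = enr$cluster, gene = enr$gene,
                         family = unname(fam_of[enr$gene]),
                         log2_fc = enr$log2_fc, p = enr$p,
                         stringsAsFactors = FALSE)
  homeo <- tf_genes[grepl(homeo_pattern, fam_of[tf_genes],
                          ignore.case = TRUE)]
  ratio <- NULL
  if (length(homeo) > 0) {
    means <- cluster_mean_profiles(norm, tissues, genes = homeo)
    mx <- apply(means, 1, max)
    ratio <- means / ifelse(mx == 0, 1, mx)
    ratio[mx == 0, ] <- 0
    if (nrow(ratio) > 2) {
      hc <- hclust(dist(ratio), method = "average")
      ratio <- ratio[hc$order, , drop = FALSE]
    }
  }
  list(enriched = enriched, homeodomain_ratio = ratio)
}
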