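#' QC parameters
#'
#' Cell/gene filter and normalization settings. Defaults follow the study's
#' published thresholds: cells with fewer than 500 or more than 18,000 total
#' UMIs are removed (totals of exactly 500 or 18,000 are kept — the rule
#' removes strictly "fewer"/"greater"), ribosomal/mitochondrial transcripts
#' are dropped before totals are computed, and expression is log-normalized
#' to ln(UMI-per-10,000 + 1).
#'
#' @param min_umi,max_umi Inclusive retention bounds on per-cell total UMIs.
#' @param contaminant_genes Gene/contig IDs to remove before filtering.
#' @param scale_factor Normalization scale factor.
#' @return A `qc_params` list.
#' @export
qc_params <- function(min_umi = 500, max_umi = 18000,
                      contaminant_genes = character(), scale_factor = 10000) {
  stopifnot(min_umi < max_umi, min_umi >= 0, scale_factor > 0)
  structure(list(min_umi = min_umi, max_umi = max_umi,
                 contaminant_genes = contaminant_genes,
                 scale_factor = scale_factor), class = "qc_params")
}

#' Collapse isoform contigs to gene-level counts
#'
#' Merges contig rows by summing counts over each gene's isoforms, the first
#' preprocessing step of the pipeline.
#'
#' @param counts Sparse contig-by-cell count matrix.
#' @param map Either a data frame with columns `contig_id` and `gene_id`, or
#'   a named character vector `contig -> gene`. Every matrix row must be
#'   covered.
#' @return Sparse gene-by-cell matrix, genes in order of first appearance.
#' @export
collapse_isoforms <- function(counts, map) {
  if (is.data.frame(map)) map <- stats::setNames(map$gene_id, map$contig_id)
  missing <- setdiff(rownames(counts), names(map))
  if (length(missing) > 0)
    stop("unmapped contigs: ", paste(missing, collapse = ", "))
  gene <- unname(map[rownames(counts)])
  fac <- factor(gene, levels = unique(gene))
  ind <- Matrix::fac2sparse(fac)   # levels x contigs indicator
  out <- ind %*% counts
  rownames(out) <- levels(fac)
  methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
}

#' Remove contaminant genes and out-of-bounds cells
#'
#' Drops contaminant (ribosomal/mitochondrial) gene rows first, then removes
#' cells whose recomputed total UMI count is strictly below `min_umi` or
#' strictly above `max_umi`.
#'
#' @param counts Sparse gene-by-cell count matrix.
#' @param params A [qc_params()] object.
#' @return A list: `counts` (filtered matrix) and `report` with
#'   `n_genes_removed`, `n_cells_removed`, `removed_barcodes`.
#' @export
filter_cells_genes <- function(counts, params = qc_params()) {
  keep_genes <- !(rownames(counts) %in% params$contaminant_genes)
  m <- counts[keep_genes, , drop = FALSE]
  totals <- Matrix::colSums(m)
  keep_cells <- totals >= params$min_umi & totals <= params$max_umi
  removed <- colnames(m)[!keep_cells]
  m <- m[, keep_cells, drop = FALSE]
  if (ncol(m) == 0L)
    warning("all cells removed by UMI-bound filter; result is empty")
  list(counts = m,
       report = list(n_genes_removed = sum(!keep_genes),
                     n_cells_removed = length(removed),
                     removed_barcodes = removed))
}

#' Log-normalize UMI counts
#'
#' Transforms counts to `ln(count / cell_total * scale_factor + 1)`
#' ("LogNormalize"), the expression space every downstream threshold in the
#' pipeline is stated in. The per-cell raw totals are carried so the
#' transform is exactly invertible.
#'
#' @param counts Sparse gene-by-cell count matrix; every cell total must be
#'   positive (zero-total cells should have been filtered).
#' @param scale_factor Scale factor (default 10,000).
#' @return A `normalized_matrix` list: `mat` (sparse, same dimnames),
#'   `totals`, `scale_factor`.
#' @export
lognormalize <- function(counts, scale_factor = 10000) {
  totals <- Matrix::colSums(counts)
  if (any(totals <= 0))
    stop("zero-total cell(s): ",
         paste(head(colnames(counts)[totals <= 0], 5), collapse = ", "),
         " (filter cells before normalizing)")
  m <- methods::as(counts %*% Matrix::Diagonal(x = scale_factor / totals),
                   "CsparseMatrix")
  m@x <- log1p(m@x)
  dimnames(m) <- dimnames(counts)
  structure(list(mat = methods::as(m, "generalMatrix"),
                 totals = totals, scale_factor = scale_factor),
            class = "normalized_matrix")
}

#' Invert [lognormalize()]
#'
#' @param norm A `normalized_matrix`.
#' @return The raw count matrix, reconstructed from the stored totals.
#' @export
denormalize <- function(norm) {
  m <- norm$mat
  m@x <- expm1(m@x)
  out <- m %*% Matrix::Diagonal(x = norm$totals / norm$scale_factor)
  dimnames(out) <- dimnames(norm$mat)
  methods::as(methods::as(out, "CsparseMatrix"), "generalMatrix")
}

#' Gate rules for marker-based stage selection
#'
#' `x1_gate()` retains cycling neoblasts: smedwi-1-like expression strictly
#' above 0.5 ln-units. `g0_gate()` retains post-mitotic progenitors:
#' smedwi-1-like strictly below 3.5 and p4hb-like strictly above 1.5
#' ln-units.
#'
#' @param smedwi_gene,p4hb_gene Gate marker gene IDs as present in the
#'   matrix.
#' @param threshold,smedwi_threshold,p4hb_threshold Thresholds in
#'   ln(UMI-per-scale + 1) units.
#' @return A list of gate rules for [gate_cells()].
#' @export
x1_gate <- function(smedwi_gene, threshold = 0.5) {
  list(list(gene = smedwi_gene, threshold = threshold, direction = "greater"))
}

#' @rdname x1_gate
#' @export
g0_gate <- function(smedwi_gene, p4hb_gene,
                    smedwi_threshold = 3.5, p4hb_threshold = 1.5) {
  list(list(gene = smedwi_gene, threshold = smedwi_threshold,
            direction = "less"),
       list(gene = p4hb_gene, threshold = p4hb_threshold,
            direction = "greater"))
}

#' Gate cells on normalized marker expression
#'
#' Applies the conjunction of gate rules with strict inequalities and
#' returns the retained barcodes.
#'
#' @param norm A `normalized_matrix`.
#' @param rules A list of rules, each `list(gene, threshold, direction)`
#'   with direction `"greater"` or `"less"`; see [x1_gate()], [g0_gate()].
#' @return A list: `barcodes` (retained), `pass_counts` (per-rule pass
#'   count, named by gene), `n_total`.
#' @export
gate_cells <- function(norm, rules) {
  genes <- vapply(rules, `[[`, character(1), "gene")
  missing <- setdiff(genes, rownames(norm$mat))
  if (length(missing) > 0)
    stop("gate gene(s) not in matrix: ", paste(missing, collapse = ", "))
  keep <- rep(TRUE, ncol(norm$mat))
  pass_counts <- integer(length(rules))
  for (ri in seq_along(rules)) {
    r <- rules[[ri]]
    v <- norm$mat[r$gene, ]
    ok <- if (r$direction == "greater") v > r$threshold else v < r$threshold
    pass_counts[ri] <- sum(ok)
    keep <- keep & ok
  }
  names(pass_counts) <- genes
  list(barcodes = colnames(norm$mat)[keep], pass_counts = pass_counts,
       n_total = ncol(norm$mat))
}

#' Per-gene scaling and centering
#'
#' Z-scores each gene across cells (mean 0, unit variance with the n-1
#' denominator); constant genes become all-zero rows. Optional symmetric
#' clipping of extreme values.
#'
#' @param norm A `normalized_matrix` (or a plain matrix of normalized
#'   values).
#' @param genes Optional gene subset (e.g. variable genes).
#' @param clip Optional absolute clip bound.
#' @return Dense genes-by-cells matrix of scaled values.
#' @export
scale_center <- function(norm, genes = NULL, clip = NULL) {
  x <- if (inherits(norm, "normalized_matrix")) norm$mat else norm
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("scaling requires at least 2 cells")
  mu <- rowMeans(x)
  s <- apply(x, 1, sd)
  out <- (x - mu) / ifelse(s == 0, 1, s)
  out[s == 0, ] <- 0
  if (!is.null(clip)) out <- pmin(pmax(out, -clip), clip)
  out
}

#' Rank variable genes by standardized variance
#'
#' Ranks genes by observed variance relative to the variance expected from a
#' quadratic mean-variance trend fitted on the log-log scale, a
#' loess-free analogue of vst selection.
#'
#' @param norm A `normalized_matrix`.
#' @param n Number of genes to return (default 2,000).
#' @return Character vector of gene IDs, most variable first.
#' @export
variable_genes <- function(norm, n = 2000) {
  x <- norm$mat
  mu <- Matrix::rowMeans(x)
  ex2 <- Matrix::rowMeans(x^2)
  v <- (ex2 - mu^2) * ncol(x) / max(1, ncol(x) - 1)
  ok <- mu > 0 & v > 0
  std_var <- rep(0, nrow(x))
  if (sum(ok) >= 3) {
    fit <- lm(log10(v[ok]) ~ poly(log10(mu[ok]), min(2, sum(ok) - 1)))
    std_var[ok] <- v[ok] / 10^predict(fit)
  } else {
    std_var[ok] <- v[ok]
  }
  names(std_var) <- rownames(x)
  head(names(sort(std_var, decreasing = TRUE)), n)
}

#' Principal component embedding
#'
#' PCA of cells on scaled expression, with a deterministic sign convention:
#' each component is flipped so its largest-magnitude gene loading is
#' positive, making repeated runs byte-identical.
#'
#' @param scaled Dense genes-by-cells matrix from [scale_center()].
#' @param n_components Number of components (<= min(genes, cells)).
#' @return A `pca_embedding` list: `coords` (cells x PCs), `var_explained`
#'   (fraction per retained PC), `rotation` (gene loadings).
#' @export
pca_embed <- function(scaled, n_components) {
  if (n_components > min(dim(scaled)))
    stop("n_components (", n_components, ") exceeds min(genes, cells) = ",
         min(dim(scaled)))
  p <- prcomp(t(scaled), center = FALSE, scale. = FALSE, rank. = n_components)
  for (j in seq_len(ncol(p$rotation))) {
    i <- which.max(abs(p$rotation[, j]))
    if (p$rotation[i, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  structure(list(coords = p$x,
                 var_explained = (p$sdev^2 / sum(p$sdev^2))[
                   seq_len(n_components)],
                 rotation = p$rotation),
            class = "pca_embedding")
}

#' Choose the number of PCs by the elbow rule
#'
#' Returns the smallest component count c at which the drop in explained
#' variance between successive components falls below `frac` of the first
#' drop. The published per-tissue presets (Neural 40, Muscle 20,
#' Cathepsin 20) can be passed directly to downstream functions instead.
#'
#' @param var_explained Per-component explained-variance fractions.
#' @param frac Fraction of the first drop (default 0.05).
#' @return Integer component count.
#' @export
choose_pcs_elbow <- function(var_explained, frac = 0.05) {
  if (length(var_explained) < 3L) return(length(var_explained))
  drops <- -diff(var_explained)
  ref <- drops[1]
  if (ref <= 0) return(1L)
  below <- which(drops < frac * ref)
  if (length(below) == 0L) length(var_explained) else below[1]
}

knn_graph <- function(coords, k) {
  n <- nrow(coords)
  if (n == 2L) return(igraph::make_graph(c(1, 2), directed = FALSE))
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  nb <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  el <- cbind(rep(seq_len(n), each = k), as.vector(t(nb)))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g)
}

#' Graph-based community clustering of cells
#'
#' Builds a k-nearest-neighbor graph on PC coordinates and partitions it by
#' modularity community detection (Louvain or Leiden). Deterministic given
#' `seed`.
#'
#' @param pcs A `pca_embedding` or a cells-by-PC matrix.
#' @param resolution Resolution parameter.
#' @param method `"louvain"` or `"leiden"`.
#' @param k Neighbors per cell (default 20; reduced with a warning when
#'   there are fewer cells).
#' @param seed Integer seed.
#' @return A `cluster_assignment` list: `labels` (integer, contiguous from
#'   0, named by barcode), `method`, `resolution`, `k`, `n_pcs`.
#' @export
cluster_graph <- function(pcs, resolution = 1,
                          method = c("louvain", "leiden"), k = 20, seed = 1) {
  method <- match.arg(method)
  coords <- if (inherits(pcs, "pca_embedding")) pcs$coords else as.matrix(pcs)
  n <- nrow(coords)
  if (n == 1L) {
    return(structure(list(labels = stats::setNames(0L, rownames(coords)),
                          method = method, resolution = resolution, k = 0L,
                          n_pcs = ncol(coords)),
                     class = "cluster_assignment"))
  }
  if (k >= n) {
    warning("k (", k, ") >= number of cells (", n, "); reduced to ", n - 1)
    k <- n - 1L
  }
  g <- knn_graph(coords, k)
  set.seed(seed)
  cl <- if (method == "louvain") {
    igraph::cluster_louvain(g, resolution = resolution)
  } else {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = resolution, n_iterations = 10)
  }
  memb <- as.integer(igraph::membership(cl))
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  structure(list(labels = stats::setNames(labels, rownames(coords)),
                 method = method, resolution = resolution, k = k,
                 n_pcs = ncol(coords)),
            class = "cluster_assignment")
}

#' Two-dimensional embedding of cells
#'
#' Either the first two principal components (`"pca2"`) or a seeded
#' force-directed (Fruchterman-Reingold) layout of the k-nearest-neighbor
#' graph (`"graph_fr"`), a neighborhood-preserving layout in the spirit of
#' UMAP-style plots. The only contract downstream code relies on is that
#' cells of the same planted subtype are closer on average than cells of
#' different subtypes.
#'
#' @param pcs A `pca_embedding` or a cells-by-PC matrix.
#' @param method `"graph_fr"` or `"pca2"`.
#' @param k Neighbors for the graph layout.
#' @param seed Integer seed (graph layout only).
#' @return Cells-by-2 coordinate matrix with barcode rownames.
#' @export
embed_2d <- function(pcs, method = c("graph_fr", "pca2"), k = 20, seed = 1) {
  method <- match.arg(method)
  coords <- if (inherits(pcs, "pca_embedding")) pcs$coords else as.matrix(pcs)
  if (nrow(coords) < 3L) stop("embedding requires at least 3 cells")
  if (method == "pca2") {
    out <- coords[, 1:2, drop = FALSE]
  } else {
    kk <- min(k, nrow(coords) - 1L)
    g <- knn_graph(coords, kk)
    set.seed(seed)
    out <- igraph::layout_with_fr(g)
    rownames(out) <- rownames(coords)
  }
  colnames(out) <- c("dim1", "dim2")
  out
}
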