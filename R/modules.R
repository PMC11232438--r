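#' Pairwise Pearson correlation of TFs across a cell subset
#'
#' Computes the TF-by-TF Pearson correlation matrix on log-normalized
#' expression with zeros included (no subsetting to expressing cells),
#' across all cells of a stage or an explicit subset. Constant (zero
#' variance) genes are excluded with a warning and listed, never returned as
#' NaN rows.
#'
#' @param norm A `normalized_matrix` (isoforms collapsed beforehand).
#' @param tf_genes Gene IDs to correlate (>= 2 present and non-constant).
#' @param cells Optional barcode subset (>= 3 cells).
#' @return A `tf_correlation` list: `r` (symmetric matrix, unit diagonal),
#'   `excluded` (constant genes), `n_cells`.
#' @export
pairwise_tf_correlation <- function(norm, tf_genes, cells = NULL) {
  x <- if (inherits(norm, "normalized_matrix")) norm$mat else norm
  missing <- setdiff(tf_genes, rownames(x))
  if (length(missing) > 0)
    stop("TF gene(s) not in matrix: ", paste(missing, collapse = ", "))
  x <- x[tf_genes, , drop = FALSE]
  if (!is.null(cells)) x <- x[, cells, drop = FALSE]
  if (ncol(x) < 3L) stop("correlation requires at least 3 cells")
  x <- as.matrix(x)
  v <- apply(x, 1, var)
  excluded <- rownames(x)[v == 0]
  if (length(excluded) > 0)
    warning("constant gene(s) excluded from correlation: ",
            paste(excluded, collapse = ", "))
  keep <- v > 0
  if (sum(keep) < 2L) stop("fewer than 2 non-constant TFs")
  r <- cor(t(x[keep, , drop = FALSE]))
  structure(list(r = r, excluded = excluded, n_cells = ncol(x)),
            class = "tf_correlation")
}

#' UPGMA ordering of a correlation matrix
#'
#' Reclusters a correlation matrix by average-linkage (UPGMA) hierarchical
#' clustering of the Euclidean distances between correlation rows, the
#' ordering used for module heatmaps. Deterministic: equal-height merges
#' follow the smallest-index pair, as in [stats::hclust()].
#'
#' @param corr A `tf_correlation` or a plain correlation matrix.
#' @return A list: `order` (gene IDs in leaf order), `hclust` (the tree).
#' @export
cluster_correlation_matrix <- function(corr) {
  r <- if (inherits(corr, "tf_correlation")) corr$r else corr
  if (is.null(dim(r)) || nrow(r) == 1L)
    return(list(order = rownames(r), hclust = NULL))
  hc <- hclust(dist(r), method = "average")
  list(order = rownames(r)[hc$order], hclust = hc)
}

#' Extract TF modules from a correlation matrix
#'
#' Identifies candidate fate-TF genes -- those correlated (strictly above
#' `candidate_threshold`, default r > 0.14) with a known FSTF or, through a
#' chain of such links, with another candidate -- then groups them by
#' cutting the UPGMA dendrogram at the largest height at which every
#' resulting multi-member group keeps all pairwise correlations above the
#' threshold, so module members are mutually correlated rather than merely
#' correlated on average. The automated cut is the reproducible surrogate
#' for the manual inspection step on real data; curated member lists can
#' be used downstream instead.
#'
#' @param corr A `tf_correlation` or correlation matrix.
#' @param known_fstfs Optional known FSTF gene IDs used as seeds; when
#'   `NULL`, every TF with at least one supra-threshold link is a candidate.
#' @param candidate_threshold Strict correlation threshold (default 0.14).
#' @param min_size Minimum module size (default 2).
#' @return A list of `tf_module` lists (`members`, `mean_r`, `height`,
#'   `label`); empty (with a warning) when there are no candidates.
#' @export
extract_modules <- function(corr, known_fstfs = NULL,
                            candidate_threshold = 0.14, min_size = 2) {
  r <- if (inherits(corr, "tf_correlation")) corr$r else corr
  adj <- r > candidate_threshold
  diag(adj) <- FALSE
  genes <- rownames(r)
  if (is.null(known_fstfs)) {
    cand <- genes[rowSums(adj) > 0]
  } else {
    seeds <- intersect(known_fstfs, genes)
    cand <- unique(c(seeds, genes[rowSums(adj[, seeds, drop = FALSE]) > 0]))
    repeat {
      grown <- unique(c(cand,
                        genes[rowSums(adj[, cand, drop = FALSE]) > 0]))
      if (length(grown) == length(cand)) break
      cand <- grown
    }
    cand <- genes[genes %in% cand]
  }
  if (length(cand) < min_size) {
    warning("no candidate TFs above the correlation threshold")
    return(list())
  }
  sub <- r[cand, cand, drop = FALSE]
  hc <- hclust(dist(sub), method = "average")
  mean_intra <- function(members) {
    m <- sub[members, members]
    mean(m[upper.tri(m)])
  }
  min_intra <- function(members) {
    m <- sub[members, members]
    min(m[upper.tri(m)])
  }
  cut_ok <- function(labs) {
    for (g in split(cand, labs)) {
      if (length(g) >= 2 && min_intra(g) <= candidate_threshold) return(FALSE)
    }
    TRUE
  }
  heights <- sort(unique(hc$height), decreasing = TRUE)
  labs <- NULL
  for (h in heights) {
    cand_labs <- cutree(hc, h = h)
    if (cut_ok(cand_labs)) { labs <- cand_labs; break }
  }
  if (is.null(labs)) labs <- seq_along(cand)  # all singletons: no modules
  groups <- split(cand, labs)
  groups <- groups[lengths(groups) >= min_size]
  if (length(groups) == 0L) {
    warning("no modules at the requested threshold")
    return(list())
  }
  h_used <- if (identical(labs, seq_along(cand))) 0 else h
  out <- lapply(seq_along(groups), function(i) {
    structure(list(members = unname(groups[[i]]),
                   mean_r = mean_intra(groups[[i]]),
                   height = h_used,
                   label = paste0("M", i)),
              class = "tf_module")
  })
  out[order(vapply(out, function(m) m$members[1], character(1)))]
}

#' Classify cells by full-module TF coexpression
#'
#' Selects the cells expressing EVERY member of a TF module above the
#' expression threshold (default 0.5 ln-units), the ensemble rule that
#' sharpens fate classification relative to single TFs. With fate labels,
#' reports the precision of the ensemble selection and of each single-TF
#' selection for comparison.
#'
#' @param norm A `normalized_matrix`.
#' @param module A `tf_module` or a character vector of member gene IDs.
#' @param expression_threshold Strict ln-unit threshold (default 0.5).
#' @param fate_labels Optional per-cell fate labels named by barcode (or in
#'   matrix column order).
#' @param target_fate The module's target fate; default: the modal label of
#'   the selected cells.
#' @return A list: `cells` (selected barcodes), `precision` (`NA` with a
#'   message when the selection is empty), `single_precision` (named, per
#'   member), `target_fate`, `n_selected`.
#' @export
classify_by_ensemble <- function(norm, module, expression_threshold = 0.5,
                                 fate_labels = NULL, target_fate = NULL) {
  members <- if (inherits(module, "tf_module")) module$members else module
  if (length(members) == 0L) stop("empty module")
  x <- if (inherits(norm, "normalized_matrix")) norm$mat else norm
  missing <- setdiff(members, rownames(x))
  if (length(missing) > 0)
    stop("module member(s) not in matrix: ", paste(missing, collapse = ", "))
  expr <- as.matrix(x[members, , drop = FALSE]) > expression_threshold
  sel <- colSums(expr) == length(members)
  cells <- colnames(x)[sel]
  precision <- NA_real_
  single_precision <- NULL
  if (!is.null(fate_labels)) {
    labs <- if (!is.null(names(fate_labels)))
      fate_labels[colnames(x)] else fate_labels
    if (is.null(target_fate)) {
      if (any(sel)) {
        tab <- table(labs[sel])
        target_fate <- names(tab)[which.max(tab)]
      }
    }
    if (!any(sel)) {
      message("empty ensemble selection: precision undefined")
    } else {
      precision <- mean(labs[sel] == target_fate)
    }
    single_precision <- vapply(members, function(g) {
      s <- expr[g, ]
      if (!any(s)) NA_real_ else mean(labs[s] == target_fate)
    }, numeric(1))
  }
  list(cells = cells, precision = precision,
       single_precision = single_precision, target_fate = target_fate,
       n_selected = length(cells))
}

gaussian_smooth_grid <- function(d, sigma_x, sigma_y) {
  # column-normalized truncated kernels: each source bin redistributes its
  # mass within the grid, so the total is conserved exactly
  norm_kernel <- function(n, sigma) {
    if (sigma <= 0) return(diag(n))
    k <- outer(seq_len(n), seq_len(n), function(i, j) dnorm(i - j, sd = sigma))
    sweep(k, 2, colSums(k), `/`)
  }
  kx <- norm_kernel(nrow(d), sigma_x)
  ky <- norm_kernel(ncol(d), sigma_y)
  kx %*% d %*% t(ky)
}

label_components <- function(region) {
  # 8-connectivity flood fill on a logical grid
  lab <- matrix(0L, nrow(region), ncol(region))
  nxt <- 0L
  nr <- nrow(region); nc <- ncol(region)
  for (start in which(region & lab == 0L)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      ci <- (cur - 1L) %% nr + 1L
      cj <- (cur - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ni <- ci + di; nj <- cj + dj
        if (ni >= 1 && ni <= nr && nj >= 1 && nj <= nc &&
            region[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          stack <- c(stack, (nj - 1L) * nr + ni)
        }
      }
    }
  }
  lab
}

#' Density contour of a module-positive cell set on a 2D embedding
#'
#' Bins the positions of module-positive cells into a 2D histogram over the
#' full embedding extent, smooths with a Gaussian kernel whose standard
#' deviation is `kernel_sigma_frac` of the smaller embedding extent
#' (kernels are truncated and renormalized at grid edges, so total mass is
#' conserved), and thresholds at `contour_frac` of the maximum density. The
#' published figures threshold at 0.5-0.7 of the maximum; other fractions in
#' (0, 1] are accepted with a warning.
#'
#' @param embedding Cells-by-2 coordinate matrix with barcode rownames.
#' @param positive Barcodes (or a logical vector over rows) of the
#'   module-positive cells.
#' @param bins Histogram resolution per axis (default 100).
#' @param kernel_sigma_frac Kernel sd as a fraction of the minimum embedding
#'   extent (default 0.02).
#' @param contour_frac Fraction of the maximum density (default 0.6).
#' @return A list: `density` (smoothed grid), `region` (logical grid),
#'   `components` (integer-labeled grid), `n_components`, `polygons`
#'   (closed contour polygons from [grDevices::contourLines()]), `x`, `y`
#'   (bin midpoints).
#' @export
module_domain_contour <- function(embedding, positive, bins = 100,
                                  kernel_sigma_frac = 0.02,
                                  contour_frac = 0.6) {
  stopifnot(ncol(embedding) == 2)
  if (contour_frac <= 0 || contour_frac > 1)
    stop("contour_frac must be in (0, 1]")
  if (contour_frac < 0.5 || contour_frac > 0.7)
    warning("contour_frac outside the published 0.5-0.7 range")
  pos <- if (is.logical(positive)) embedding[positive, , drop = FALSE] else
    embedding[rownames(embedding) %in% positive, , drop = FALSE]
  rx <- range(embedding[, 1]); ry <- range(embedding[, 2])
  if (diff(rx) == 0) rx <- rx + c(-0.5, 0.5)
  if (diff(ry) == 0) ry <- ry + c(-0.5, 0.5)
  bx <- seq(rx[1], rx[2], length.out = bins + 1)
  by <- seq(ry[1], ry[2], length.out = bins + 1)
  midx <- (bx[-1] + bx[-length(bx)]) / 2
  midy <- (by[-1] + by[-length(by)]) / 2
  d <- matrix(0, bins, bins)
  if (nrow(pos) > 0) {
    ix <- pmin(pmax(findInterval(pos[, 1], bx, all.inside = TRUE), 1), bins)
    iy <- pmin(pmax(findInterval(pos[, 2], by, all.inside = TRUE), 1), bins)
    tab <- tabulate(ix + (iy - 1L) * bins, nbins = bins * bins)
    d <- matrix(tab, bins, bins)
  }
  sigma_data <- kernel_sigma_frac * min(diff(rx), diff(ry))
  s <- gaussian_smooth_grid(d, sigma_data / (diff(rx) / bins),
                            sigma_data / (diff(ry) / bins))
  if (max(s) == 0) {
    region <- matrix(FALSE, bins, bins)
    comps <- matrix(0L, bins, bins)
    polys <- list()
  } else {
    thr <- contour_frac * max(s)
    region <- s >= thr
    comps <- label_components(region)
    polys <- grDevices::contourLines(x = midx, y = midy, z = s, levels = thr)
  }
  list(density = s, region = region, components = comps,
       n_components = max(comps), polygons = polys, x = midx, y = midy)
}
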