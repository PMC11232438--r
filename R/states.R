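#' Ratkowsky-Lance cluster-validity index
#'
#' For each variable j, `c_j = sqrt(BGSS_j / TSS_j)` where
#' `BGSS_j = sum_g n_g (mean_gj - mean_j)^2` (between-group sum of squares)
#' and `TSS_j = sum_i (x_ij - mean_j)^2` (total sum of squares); the index
#' is `mean_j(c_j) / sqrt(k)` for k groups. Each `c_j` lies in `[0, 1]`, so
#' the index lies in `(0, 1/sqrt(k)]`; its maximum over k indicates the
#' best-supported number of cell states.
#'
#' @param x Cells-by-variable (e.g. PC) matrix.
#' @param labels Group labels, one per row; >= 2 nonempty groups.
#' @return The index value.
#' @export
ratkowsky_index <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  groups <- unique(labels)
  k <- length(groups)
  if (k < 2) stop("ratkowsky_index requires at least 2 groups")
  mu <- colMeans(x)
  tss <- colSums(sweep(x, 2, mu)^2)
  bgss <- numeric(ncol(x))
  for (g in groups) {
    rows <- labels == g
    n_g <- sum(rows)
    mg <- colMeans(x[rows, , drop = FALSE])
    bgss <- bgss + n_g * (mg - mu)^2
  }
  ok <- tss > 0
  if (!any(ok)) stop("all variables have zero total sum of squares")
  if (any(!ok))
    warning(sum(!ok), " variable(s) with zero total sum of squares excluded")
  mean(sqrt(bgss[ok] / tss[ok])) / sqrt(k)
}

scan_seed <- function(base_seed, k, r) {
  ((as.integer(base_seed) %% 10000L) * 100003L + k * 1009L + r) %% 2147483647L
}

#' Scan candidate state numbers by repeated seeded k-means
#'
#' For each k in `k_range`, runs k-means (`nstart` random restarts,
#' Euclidean distance) `n_repeats` times with per-repeat derived seeds and
#' computes the Ratkowsky-Lance index of each partition. Reports per-k
#' means with percentile confidence intervals and the arg-max k. An
#' empty-cluster k-means failure is retried with a fresh derived seed,
#' never silently dropped.
#'
#' @param x Cells-by-PC matrix (rows >= max(k_range)).
#' @param k_range Integer candidate ks (default 2:15, min >= 2).
#' @param n_repeats Repeats per k (default 100; the study used 1,000).
#' @param nstart,iter_max k-means restarts per repeat and iteration cap.
#' @param ci_level Confidence level.
#' @param ci_method `"bootstrap"` (percentile bootstrap of the mean over
#'   repeats, 200 resamples) or `"normal"` (normal approximation).
#' @param seed Base seed driving every repeat.
#' @return A `state_scan` list: `table` (data frame k, mean, lo, hi),
#'   `per_repeat` (repeats x k matrix), `optimal_k`, `params`.
#' @export
kmeans_state_scan <- function(x, k_range = 2:15, n_repeats = 100,
                              nstart = 10, iter_max = 300,
                              ci_level = 0.95,
                              ci_method = c("bootstrap", "normal"),
                              seed = 1) {
  ci_method <- match.arg(ci_method)
  x <- as.matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  stopifnot(min(k_range) >= 2, n_repeats >= 2)
  if (nrow(x) < max(k_range))
    stop("fewer cells than max(k_range)")
  per <- matrix(NA_real_, n_repeats, length(k_range),
                dimnames = list(NULL, paste0("k", k_range)))
  for (ki in seq_along(k_range)) {
    k <- k_range[ki]
    for (r in seq_len(n_repeats)) {
      s <- scan_seed(seed, k, r)
      km <- NULL
      for (attempt in 0:5) {
        set.seed((s + attempt * 7919L) %% 2147483647L)
        km <- tryCatch(
          kmeans(x, centers = k, nstart = nstart, iter.max = iter_max),
          error = function(e) NULL)
        if (!is.null(km)) break
      }
      if (is.null(km)) stop("k-means failed repeatedly at k = ", k)
      per[r, ki] <- suppressWarnings(ratkowsky_index(x, km$cluster))
    }
  }
  alpha <- (1 - ci_level) / 2
  ci <- apply(per, 2, function(v) {
    if (ci_method == "normal") {
      se <- sd(v) / sqrt(length(v))
      mean(v) + stats::qnorm(c(alpha, 1 - alpha)) * se
    } else {
      set.seed(scan_seed(seed, 0L, 0L))
      boots <- replicate(200, mean(sample(v, replace = TRUE)))
      quantile(boots, probs = c(alpha, 1 - alpha), names = FALSE)
    }
  })
  tab <- data.frame(
    k = k_range,
    mean = colMeans(per),
    lo = pmin(ci[1, ], colMeans(per)),
    hi = pmax(ci[2, ], colMeans(per))
  )
  rownames(tab) <- NULL
  structure(list(table = tab, per_repeat = per,
                 optimal_k = k_range[which.max(tab$mean)],
                 params = list(k_range = k_range, n_repeats = n_repeats,
                               nstart = nstart, iter_max = iter_max,
                               ci_level = ci_level, seed = seed)),
            class = "state_scan")
}

#' @export
print.state_scan <- function(x, ...) {
  cat("Ratkowsky-Lance state scan (", x$params$n_repeats,
      " repeats per k)\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("optimal_k:", x$optimal_k, "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement from the pair-counting contingency table.
#' When both labelings are trivial (each a single cluster) the partitions
#' are identical and 1 is returned by convention.
#'
#' @param labels_a,labels_b Label vectors over the same cells, same order.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors differ in length")
  if (length(unique(labels_a)) == 1L && length(unique(labels_b)) == 1L)
    return(1)
  mclust::adjustedRandIndex(labels_a, labels_b)
}
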