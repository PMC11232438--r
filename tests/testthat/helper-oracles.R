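# Independent brute-force oracles and small fixture builders.
# These deliberately avoid the package's own code paths.

# two-pass Pearson correlation, elementwise loops
oracle_pearson <- function(x) {
  n <- nrow(x)
  out <- matrix(NA_real_, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- x[i, ]; b <- x[j, ]
      ma <- sum(a) / length(a); mb <- sum(b) / length(b)
      num <- sum((a - ma) * (b - mb))
      den <- sqrt(sum((a - ma)^2)) * sqrt(sum((b - mb)^2))
      out[i, j] <- num / den
    }
  }
  out
}

# naive O(n^3) UPGMA on a distance matrix; returns merge heights in order
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  diag(d) <- Inf
  sizes <- rep(1, nrow(d))
  heights <- numeric(0)
  while (nrow(d) > 1) {
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    heights <- c(heights, d[i, j])
    ni <- sizes[i]; nj <- sizes[j]
    newrow <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    d <- d[-j, -j, drop = FALSE]
    sizes <- sizes[-j]
    newrow <- newrow[-j]
    d[i, ] <- newrow
    d[, i] <- newrow
    d[i, i] <- Inf
    sizes[i] <- ni + nj
  }
  heights
}

# per-variable loop Ratkowsky-Lance index
oracle_ratkowsky <- function(x, labels) {
  x <- as.matrix(x)
  k <- length(unique(labels))
  cs <- numeric(0)
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    mu <- mean(v)
    tss <- sum((v - mu)^2)
    if (tss == 0) next
    bgss <- 0
    for (g in unique(labels)) {
      vg <- v[labels == g]
      bgss <- bgss + length(vg) * (mean(vg) - mu)^2
    }
    cs <- c(cs, sqrt(bgss / tss))
  }
  mean(cs) / sqrt(k)
}

# ARI by explicit enumeration of all cell pairs
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  np <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / np
  maxi <- ((n11 + n10) + (n11 + n01)) / 2
  if (maxi == expected) return(1)
  (n11 - expected) / (maxi - expected)
}

# exact two-sided rank-sum p by enumeration of group assignments
oracle_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  stats <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

make_norm <- function(m) {
  lognormalize(methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"))
}

mean_silhouette <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  s <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

# gaussian blob data: k blobs of n points in p dims; centers are a randomly
# rotated orthogonal frame at distance sep from the origin, so every pair of
# centers is sep*sqrt(2) apart and between-blob signal spans all p dims
# (as in the top PCs of structured data)
make_blobs <- function(k, n_per, p = 10, sep = 1, sd = 0.1, seed = 1) {
  stopifnot(k <= p)
  set.seed(seed)
  q <- qr.Q(qr(matrix(rnorm(p * p), p, p)))
  centers <- t(q[, seq_len(k), drop = FALSE]) * sep
  x <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * p, sd = sd), n_per, p) +
      matrix(centers[i, ], n_per, p, byrow = TRUE)))
  rownames(x) <- sprintf("c%04d", seq_len(k * n_per))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# HMMER tblout fixture writer: 18 fixed fields + description
write_tblout <- function(path, target, query, accession, evalue) {
  hdr <- c("#                       --- full sequence ---- (fixture)",
           "# target name p2 query name p4 ...",
           "#---------------")
  rows <- sprintf(
    "%s - %s %s %.3g 55.1 0.1 %.3g 54.0 0.1 1.1 1 1 1 1 1 1 1 fixture protein",
    target, query, accession, evalue, evalue)
  writeLines(c(hdr, rows), path)
  path
}

write_blast6 <- function(path, qseqid, sseqid, pident, evalue, bitscore) {
  rows <- sprintf("%s\t%s\t%.1f\t100\t5\t0\t1\t100\t1\t100\t%.3g\t%.1f",
                  qseqid, sseqid, pident, evalue, bitscore)
  writeLines(rows, path)
  path
}
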