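#' Configuration for the synthetic neoblast/progenitor atlas
#'
#' Describes a planted two-stage design: X1 (S/G2/M neoblast) and G0
#' (post-mitotic progenitor) cells distributed over tissues and subtypes,
#' each subtype carrying a module of fate-specific transcription factors
#' (TFs). Module TFs switch on per cell with stage-specific coupling:
#' independently per TF in neoblasts (weak coexpression) or through a
#' shared per-module gate in G0 cells (strong coexpression), mirroring the
#' observation that fate TFs are individually expressed but not coexpressed
#' in cycling neoblasts. Counts are negative binomial (gamma-Poisson), the
#' standard surrogate for 10X UMI data.
#'
#' @param n_tissues Number of tissues.
#' @param subtypes_per_tissue Subtypes (fate classes) per tissue.
#' @param module_size TFs per subtype module.
#' @param n_cells_x1,n_cells_g0 Cells per stage.
#' @param coupling_x1,coupling_g0 Probability in `[0,1]` that a module TF is
#'   active in a cell of the owning subtype, per stage.
#' @param gating_x1,gating_g0 `"per_tf"` (independent Bernoulli per TF) or
#'   `"per_module"` (one shared Bernoulli gate for the whole module).
#' @param offtarget_rate Probability that a module TF is active in a cell of
#'   a different subtype (single-TF leak).
#' @param baseline_rate Mean background UMI per background gene per cell.
#' @param on_rate Mean UMI for active marker/TF genes.
#' @param marker_off_rate Mean UMI of marker/TF genes in cells where they
#'   are inactive (dropout-style leak).
#' @param gate_on_rate,gate_off_rate Mean UMI of the stage gate markers
#'   (smedwi-1-like, p4hb-like) in their high and low stages.
#' @param contaminant_rate Mean UMI of ribosomal/mitochondrial-like genes.
#' @param dispersion Negative-binomial overdispersion (`size = 1/dispersion`).
#' @param libsize_logmean,libsize_logsd Log-normal library-size factor
#'   parameters.
#' @param n_background_genes Unstructured background genes.
#' @param markers_per_tissue Tissue-marker genes per tissue.
#' @param n_contaminant_genes Ribosomal/mitochondrial-like genes.
#' @param isoforms_per_gene Contigs per gene (>= 1); see [inject_isoforms()].
#' @param seed Integer seed fixing every downstream draw.
#' @return A `sim_config` list.
#' @seealso [simulate_atlas()]
#' @export
sim_config <- function(n_tissues = 4, subtypes_per_tissue = 2, module_size = 3,
                       n_cells_x1 = 1000, n_cells_g0 = 1000,
                       coupling_x1 = 0.3, coupling_g0 = 0.9,
                       gating_x1 = "per_tf", gating_g0 = "per_module",
                       offtarget_rate = 0,
                       baseline_rate = 1.2, on_rate = 40,
                       marker_off_rate = 0.02,
                       gate_on_rate = 60, gate_off_rate = 0.1,
                       contaminant_rate = 40,
                       dispersion = 0.3,
                       libsize_logmean = 0, libsize_logsd = 0.45,
                       n_background_genes = 500, markers_per_tissue = 5,
                       n_contaminant_genes = 10, isoforms_per_gene = 1,
                       seed = 1) {
  cfg <- list(
    n_tissues = n_tissues, subtypes_per_tissue = subtypes_per_tissue,
    module_size = module_size, n_cells_x1 = n_cells_x1,
    n_cells_g0 = n_cells_g0, coupling_x1 = coupling_x1,
    coupling_g0 = coupling_g0, gating_x1 = gating_x1, gating_g0 = gating_g0,
    offtarget_rate = offtarget_rate, baseline_rate = baseline_rate,
    on_rate = on_rate, marker_off_rate = marker_off_rate,
    gate_on_rate = gate_on_rate,
    gate_off_rate = gate_off_rate, contaminant_rate = contaminant_rate,
    dispersion = dispersion, libsize_logmean = libsize_logmean,
    libsize_logsd = libsize_logsd, n_background_genes = n_background_genes,
    markers_per_tissue = markers_per_tissue,
    n_contaminant_genes = n_contaminant_genes,
    isoforms_per_gene = isoforms_per_gene, seed = seed
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  count_fields <- c("n_tissues", "subtypes_per_tissue", "module_size",
                    "n_cells_x1", "n_cells_g0", "markers_per_tissue",
                    "isoforms_per_gene")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 1 || v != round(v))
      stop("invalid sim_config field '", f, "': must be an integer >= 1",
           call. = FALSE)
  }
  for (f in c("n_background_genes", "n_contaminant_genes")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("invalid sim_config field '", f, "': must be an integer >= 0",
           call. = FALSE)
  }
  for (f in c("coupling_x1", "coupling_g0", "offtarget_rate")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("invalid sim_config field '", f, "': must be a probability in [0,1]",
           call. = FALSE)
  }
  for (f in c("baseline_rate", "on_rate", "marker_off_rate", "gate_on_rate",
              "gate_off_rate", "contaminant_rate", "libsize_logsd")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("invalid sim_config field '", f, "': must be >= 0", call. = FALSE)
  }
  if (!is.numeric(cfg$dispersion) || length(cfg$dispersion) != 1L ||
      is.na(cfg$dispersion) || cfg$dispersion <= 0)
    stop("invalid sim_config field 'dispersion': must be > 0", call. = FALSE)
  for (f in c("gating_x1", "gating_g0")) {
    if (!cfg[[f]] %in% c("per_tf", "per_module"))
      stop("invalid sim_config field '", f,
           "': must be \"per_tf\" or \"per_module\"", call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("invalid sim_config field 'seed': must be a single integer",
         call. = FALSE)
  invisible(cfg)
}

#' Simulate a synthetic two-stage single-cell UMI atlas
#'
#' Draws a gene-by-cell UMI count matrix plus a ground-truth table under the
#' planted design described in [sim_config()]. Gene roles: two gate markers
#' (`smedwi1-like`, high in X1 and low in G0; `p4hb-like`, the converse),
#' tissue markers active in all cells of their tissue, subtype module TFs
#' active with stage-dependent coupling, ribosomal/mitochondrial-like
#' contaminants, and unstructured background genes. Counts are negative
#' binomial with mean = role rate x cell library factor. Deterministic
#' given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `counts` (sparse `dgCMatrix`, genes x cells) and
#'   `truth`, a `truth_table` list with data frames `cells` (barcode, stage,
#'   tissue, subtype, libsize_factor), `genes` (gene_id, role, tissue,
#'   subtype) and `contigs` (contig_id, gene_id).
#' @export
simulate_atlas <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)

  tissues <- paste0("T", seq_len(config$n_tissues))
  subtypes <- as.vector(outer(tissues, seq_len(config$subtypes_per_tissue),
                              function(t, s) paste0(t, ".S", s)))
  subtype_tissue <- rep(tissues, times = config$subtypes_per_tissue)
  names(subtype_tissue) <- subtypes

  genes <- data.frame(
    gene_id = c("smedwi1-like", "p4hb-like"),
    role = "gate-marker", tissue = NA_character_, subtype = NA_character_,
    stringsAsFactors = FALSE
  )
  for (t in tissues) {
    genes <- rbind(genes, data.frame(
      gene_id = paste0("mk.", t, ".", seq_len(config$markers_per_tissue)),
      role = "tissue-marker", tissue = t, subtype = NA_character_
    ))
  }
  for (s in subtypes) {
    genes <- rbind(genes, data.frame(
      gene_id = paste0("tf.", s, ".", seq_len(config$module_size)),
      role = "module-TF", tissue = subtype_tissue[[s]], subtype = s
    ))
  }
  if (config$n_contaminant_genes > 0) {
    n_rib <- ceiling(config$n_contaminant_genes / 2)
    n_mt <- config$n_contaminant_genes - n_rib
    ids <- c(paste0("rrna.", seq_len(n_rib)),
             if (n_mt > 0) paste0("mt.", seq_len(n_mt)))
    genes <- rbind(genes, data.frame(
      gene_id = ids, role = "contaminant",
      tissue = NA_character_, subtype = NA_character_
    ))
  }
  if (config$n_background_genes > 0) {
    genes <- rbind(genes, data.frame(
      gene_id = sprintf("bg.%04d", seq_len(config$n_background_genes)),
      role = "background", tissue = NA_character_, subtype = NA_character_
    ))
  }
  n_genes <- nrow(genes)

  n_cells <- config$n_cells_x1 + config$n_cells_g0
  stage <- c(rep("X1", config$n_cells_x1), rep("G0", config$n_cells_g0))
  barcode <- c(sprintf("bcX1_%05d", seq_len(config$n_cells_x1)),
               sprintf("bcG0_%05d", seq_len(config$n_cells_g0)))
  cell_subtype <- sample(subtypes, n_cells, replace = TRUE)
  cell_tissue <- unname(subtype_tissue[cell_subtype])
  libf <- rlnorm(n_cells, meanlog = config$libsize_logmean,
                 sdlog = config$libsize_logsd)

  mu <- matrix(config$baseline_rate, n_genes, n_cells,
               dimnames = list(genes$gene_id, barcode))
  mu[genes$role %in% c("tissue-marker", "module-TF"), ] <-
    config$marker_off_rate
  mu["smedwi1-like", ] <- ifelse(stage == "X1",
                                 config$gate_on_rate, config$gate_off_rate)
  mu["p4hb-like", ] <- ifelse(stage == "G0",
                              config$gate_on_rate, config$gate_off_rate)
  for (t in tissues) {
    rows <- genes$role == "tissue-marker" & genes$tissue == t
    mu[rows, cell_tissue == t] <- config$on_rate
  }
  mu[genes$role == "contaminant", ] <- config$contaminant_rate

  # stage-dependent module activation; draw order fixed by subtype then stage
  for (s in subtypes) {
    rows <- which(genes$role == "module-TF" & genes$subtype == s)
    m <- length(rows)
    own <- cell_subtype == s
    for (st in c("X1", "G0")) {
      sel <- which(own & stage == st)
      if (length(sel) == 0L) next
      p <- if (st == "X1") config$coupling_x1 else config$coupling_g0
      mode <- if (st == "X1") config$gating_x1 else config$gating_g0
      act <- if (mode == "per_module") {
        matrix(rep(runif(length(sel)) < p, each = m), m, length(sel))
      } else {
        matrix(runif(m * length(sel)) < p, m, length(sel))
      }
      blk <- mu[rows, sel, drop = FALSE]
      blk[act] <- config$on_rate
      mu[rows, sel] <- blk
    }
    if (config$offtarget_rate > 0) {
      sel <- which(!own)
      leak <- matrix(runif(m * length(sel)) < config$offtarget_rate,
                     m, length(sel))
      blk <- mu[rows, sel, drop = FALSE]
      blk[leak] <- config$on_rate
      mu[rows, sel] <- blk
    }
  }

  mu <- sweep(mu, 2, libf, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                   n_genes, n_cells, dimnames = dimnames(mu))
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "CsparseMatrix"), "generalMatrix")

  contigs <- if (config$isoforms_per_gene > 1) {
    data.frame(
      contig_id = as.vector(t(outer(genes$gene_id,
                                    seq_len(config$isoforms_per_gene),
                                    function(g, i) paste0(g, ".i", i)))),
      gene_id = rep(genes$gene_id, each = config$isoforms_per_gene),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(contig_id = genes$gene_id, gene_id = genes$gene_id,
               stringsAsFactors = FALSE)
  }

  truth <- structure(list(
    cells = data.frame(barcode = barcode, stage = stage, tissue = cell_tissue,
                       subtype = cell_subtype, libsize_factor = libf,
                       stringsAsFactors = FALSE),
    genes = genes,
    contigs = contigs
  ), class = "truth_table")

  list(counts = counts, truth = truth)
}

#' Split gene-level counts across isoform contigs
#'
#' Randomly partitions each gene's per-cell counts over its contigs
#' (multinomial with equal odds), producing the isoform-redundant matrix
#' that [collapse_isoforms()] undoes. Per-gene, per-cell totals are
#' conserved exactly; with one contig per gene the matrix is returned
#' unchanged (up to row naming by contig).
#'
#' @param counts Gene-level sparse count matrix (genes x cells).
#' @param truth A `truth_table` whose `contigs` map covers every matrix row.
#' @return Sparse contig-by-cell count matrix.
#' @export
inject_isoforms <- function(counts, truth) {
  map <- truth$contigs
  if (!all(rownames(counts) %in% map$gene_id))
    stop("contig map inconsistent with matrix: missing genes ",
         paste(setdiff(rownames(counts), map$gene_id), collapse = ", "))
  map <- map[map$gene_id %in% rownames(counts), , drop = FALSE]
  i <- integer(0); j <- integer(0); x <- integer(0)
  row_of <- stats::setNames(seq_len(nrow(map)), map$contig_id)
  for (g in rownames(counts)) {
    ctg <- map$contig_id[map$gene_id == g]
    k <- length(ctg)
    v <- counts[g, ]
    nz <- which(v > 0)
    if (length(nz) == 0L) next
    if (k == 1L) {
      i <- c(i, rep(row_of[[ctg]], length(nz)))
      j <- c(j, nz)
      x <- c(x, as.integer(v[nz]))
    } else {
      part <- vapply(v[nz], function(n) rmultinom(1, n, rep(1, k))[, 1],
                     integer(k))
      nzp <- which(part > 0, arr.ind = TRUE)
      i <- c(i, row_of[ctg][nzp[, 1]])
      j <- c(j, nz[nzp[, 2]])
      x <- c(x, part[nzp])
    }
  }
  Matrix::sparseMatrix(i = i, j = j, x = x,
                       dims = c(nrow(map), ncol(counts)),
                       dimnames = list(map$contig_id, colnames(counts)))
}

#' Write a simulated bundle to disk
#'
#' Writes the MatrixMarket coordinate matrix plus features, barcodes and
#' truth tables as plain TSV, the on-disk interchange format of the
#' pipeline. [read_bundle()] reproduces the matrix exactly.
#'
#' @param counts Sparse count matrix (contigs or genes x cells).
#' @param truth A `truth_table`.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(counts, truth, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  ok <- try(Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                            file.path(path, "matrix.mtx")), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write matrix to ", file.path(path, "matrix.mtx"))
  feat <- merge(data.frame(contig_id = rownames(counts),
                           ord = seq_len(nrow(counts))),
                truth$contigs, by = "contig_id", all.x = TRUE)
  feat$gene_id[is.na(feat$gene_id)] <- feat$contig_id[is.na(feat$gene_id)]
  feat <- feat[order(feat$ord), c("contig_id", "gene_id")]
  feat$role <- truth$genes$role[match(feat$gene_id, truth$genes$gene_id)]
  write.table(feat, file.path(path, "features.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bc <- colnames(counts)
  writeLines(if (is.null(bc)) character(0) else bc,
             file.path(path, "barcodes.tsv"))
  write.table(truth$cells, file.path(path, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(truth$genes, file.path(path, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bundle written by [write_bundle()]
#'
#' @param path Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `cells.tsv`, `genes.tsv`.
#' @return A list with `counts` and `truth` as in [simulate_atlas()].
#' @export
read_bundle <- function(path) {
  m <- methods::as(methods::as(Matrix::readMM(file.path(path, "matrix.mtx")),
                               "CsparseMatrix"), "generalMatrix")
  feat <- read.delim(file.path(path, "features.tsv"), stringsAsFactors = FALSE)
  bc <- readLines(file.path(path, "barcodes.tsv"))
  dimnames(m) <- list(feat$contig_id, bc)
  cells <- read.delim(file.path(path, "cells.tsv"), stringsAsFactors = FALSE)
  genes <- read.delim(file.path(path, "genes.tsv"), stringsAsFactors = FALSE)
  truth <- structure(list(
    cells = cells, genes = genes,
    contigs = feat[, c("contig_id", "gene_id")]
  ), class = "truth_table")
  list(counts = m, truth = truth)
}
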