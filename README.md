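# fatlas

Planarian neoblasts are adult pluripotent stem cells; their commitment
toward a tissue is marked by fate-specific transcription factors (FSTFs).
A central question in the field is **when cell-fate diversity emerges**:
already in cycling S/G2/M neoblasts (FACS gate X1), or later, in
post-mitotic G0 progenitors. `fatlas` is an R package for analysts working
with droplet scRNA-seq UMI matrices of such two-stage designs. It
implements the full computational pipeline:

* **QC and gating** — isoform collapsing, removal of
  ribosomal/mitochondrial transcripts, the 500–18,000 total-UMI cell
  filter, `ln(UMI-per-10,000 + 1)` normalization, and marker-gene stage
  gates (smedwi-1-like > 0.5 ln-units for X1; smedwi-1-like < 3.5 and
  p4hb-like > 1.5 for G0), plus scaling, PCA, Louvain/Leiden graph
  clustering and 2D embedding.
* **TF modules** — pairwise Pearson correlation across all cells of a
  stage (zeros included), UPGMA ordering, and module extraction above the
  r > 0.14 candidate threshold; density contours of module-positive cells
  on an embedding.
* **Ensemble classification** — cells expressing *every* member of a TF
  module above 0.5 ln-units, with precision against fate labels compared
  to single-TF precision.
* **State counting** — the Ratkowsky–Lance index
  `C(k) = mean_j sqrt(BGSS_j/TSS_j) / sqrt(k)` over repeated seeded
  k-means, with confidence intervals and the arg-max k; adjusted Rand
  index for robustness comparisons.
* **Stage linkage** — one-vs-rest marker enrichment (pseudocount-0 fold
  changes, rank-sum test, BH adjustment), the TF-atlas filters
  (log2FC ≥ 1.5, adjusted p ≤ 0.001, ≥ 20% expressing, top 8),
  cross-dataset cluster matching on z-scored profiles, and per-pair
  correlation shifts between stages.
* **TF catalog** — parsing HMMER tblout/domtblout and BLAST outfmt-6
  tables, longest-DBD-transcript selection, strict e-value (< 1e-5) and
  identity (> 90%) gates, and priority categorization (known FSTF >
  known planarian TF > human-TF hit > excluded non-TF > no hit,
  retained).
* **Synthetic data** — a seeded negative-binomial generator that plants
  tissues, fate subtypes, TF modules with stage-dependent coupling (per-TF
  in neoblasts, per-module in G0), gate markers, contaminants and library
  size variation, so the whole pipeline is testable offline.

See the methods vignette (`vignettes/fate-diversity-pipeline.Rmd`) for the
model, parameter meanings, numerical conventions and known limitations.

## Worked example

Simulate a two-stage atlas with weak per-TF coupling in neoblasts and
strong per-module coupling in G0 progenitors, run QC and gating, extract
TF modules, classify cells by full-ensemble coexpression, and measure the
stage shift of a planted TF pair:

```r
library(fatlas)

cfg <- sim_config(n_tissues = 3, subtypes_per_tissue = 1, module_size = 3,
                  coupling_x1 = 0.3, coupling_g0 = 0.9,
                  n_cells_x1 = 1500, n_cells_g0 = 1500, seed = 1)
sim <- simulate_atlas(cfg)

contam <- sim$truth$genes$gene_id[sim$truth$genes$role == "contaminant"]
qc <- filter_cells_genes(sim$counts, qc_params(contaminant_genes = contam))
cat("cells removed by UMI filter:", qc$report$n_cells_removed, "\n")
norm <- lognormalize(qc$counts)
g0 <- gate_cells(norm, g0_gate("smedwi1-like", "p4hb-like"))
cat("cells retained by G0 gate:", length(g0$barcodes), "\n")

tfs <- sim$truth$genes$gene_id[sim$truth$genes$role == "module-TF"]
norm_g0 <- lognormalize(qc$counts[, g0$barcodes])
mods <- extract_modules(pairwise_tf_correlation(norm_g0, tfs))
cat("modules found:", length(mods), "\n")
for (m in mods)
  cat(sprintf("  %s: %s (mean r = %.2f)\n", m$label,
              paste(m$members, collapse = " "), m$mean_r))

labs <- setNames(sim$truth$cells$subtype, sim$truth$cells$barcode)
res <- classify_by_ensemble(norm_g0, mods[[1]], fate_labels = labs[g0$barcodes])
cat(sprintf("ensemble precision %.2f vs single-TF %s\n", res$precision,
            paste(sprintf("%.2f", res$single_precision), collapse = "/")))

x1bc <- intersect(colnames(qc$counts),
                  sim$truth$cells$barcode[sim$truth$cells$stage == "X1"])
norm_x1 <- lognormalize(qc$counts[, x1bc])
pair <- matrix(mods[[1]]$members[1:2], 1)
print(correlation_shift(norm_x1, norm_g0, pair)[
  , c("gene1", "gene2", "r_x1", "r_g0", "delta")])
```

Output:

```
cells removed by UMI filter: 248
cells retained by G0 gate: 1383
modules found: 3
  M1: tf.T1.S1.1 tf.T1.S1.2 tf.T1.S1.3 (mean r = 0.97)
  M2: tf.T2.S1.1 tf.T2.S1.2 tf.T2.S1.3 (mean r = 0.97)
  M3: tf.T3.S1.1 tf.T3.S1.2 tf.T3.S1.3 (mean r = 0.97)
ensemble precision 1.00 vs single-TF 0.94/0.95/0.97
       gene1      gene2      r_x1      r_g0     delta
1 tf.T1.S1.1 tf.T1.S1.2 0.1987143 0.9700751 0.7713608
```

Reading the numbers: the UMI filter removed the 248 cells whose totals
fell outside 500–18,000; the G0 gate recovered the post-mitotic cells;
the three planted TF modules were recovered exactly with mean
within-module r = 0.97; requiring the full ensemble classified fate with
precision 1.00 against 0.94–0.97 for individual TFs; and the planted
pair's correlation rose from r = 0.20 across neoblasts to r = 0.97 across
G0 progenitors — the stage-dependent coexpression shift the pipeline is
built to detect.

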