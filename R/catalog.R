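#' Default contig-to-gene mapping
#'
#' Strips a trailing transcript-variant suffix of the form `_<n>_<n>`
#' (Dresden-assembly style) or `.i<n>` (synthetic bundles) from a contig ID.
#'
#' @param x Character vector of contig IDs.
#' @return Gene IDs.
#' @export
contig_gene <- function(x) sub("(_[0-9]+_[0-9]+|\\.i[0-9]+)$", "", x)

#' Parse an HMMER tabular DNA-binding-domain search
#'
#' Reads `hmmsearch --tblout` or `--domtblout` output (auto-detected) into
#' one row per (contig, domain family) pair, keeping the smallest e-value
#' for duplicated pairs. Comment lines are skipped; an e-value threshold can
#' be applied (default: keep all).
#'
#' @param file Path to the HMMER tabular file.
#' @param evalue_max Keep hits with e-value strictly below this (default
#'   `Inf`, keep all).
#' @param gene_from_contig Function or named character vector mapping contig
#'   IDs to gene IDs; default [contig_gene()].
#' @return Data frame: `contig`, `gene`, `family`, `accession`, `evalue`,
#'   `target_len` (`NA` for tblout input).
#' @export
parse_domain_table <- function(file, evalue_max = Inf,
                               gene_from_contig = contig_gene) {
  lines <- readLines(file)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    return(data.frame(contig = character(), gene = character(),
                      family = character(), accession = character(),
                      evalue = numeric(), target_len = numeric()))
  rows <- strsplit(trimws(lines[idx]), "[[:space:]]+")
  nf <- lengths(rows)
  # tblout has 18 fixed fields + description; domtblout has 22 + description
  is_dom <- all(nf >= 22) && !anyNA(suppressWarnings(
    as.numeric(vapply(rows, `[`, character(1), 3))))
  min_fields <- if (is_dom) 22L else 18L
  bad <- which(nf < min_fields)
  if (length(bad) > 0)
    stop("malformed HMMER row at line ", idx[bad[1]], ": expected at least ",
         min_fields, " fields, found ", nf[bad[1]])
  get <- function(p) vapply(rows, `[`, character(1), p)
  contig <- get(1)
  if (is_dom) {
    family <- get(4); acc <- get(5)
    evalue <- as.numeric(get(7)); tlen <- as.numeric(get(3))
  } else {
    family <- get(3); acc <- get(4)
    evalue <- as.numeric(get(5)); tlen <- rep(NA_real_, length(contig))
  }
  if (anyNA(evalue))
    stop("malformed HMMER row at line ", idx[which(is.na(evalue))[1]],
         ": non-numeric e-value")
  gene <- if (is.function(gene_from_contig)) gene_from_contig(contig) else
    unname(gene_from_contig[contig])
  hits <- data.frame(contig = contig, gene = gene, family = family,
                     accession = acc, evalue = evalue, target_len = tlen,
                     stringsAsFactors = FALSE)
  hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  # one row per (contig, family): keep the best-scoring occurrence
  hits <- hits[order(hits$contig, hits$family, hits$evalue), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("contig", "family")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Pick the longest DBD-containing transcript per gene
#'
#' Of transcripts representing isoforms of the same gene, only the longest
#' transcript that contains a DNA-binding domain is recorded; length ties
#' are broken by the lexicographically smaller transcript ID, so the choice
#' is deterministic.
#'
#' @param hits Domain hits from [parse_domain_table()].
#' @param lengths Named numeric vector (or data frame with columns
#'   `transcript`, `length`) of transcript lengths; must cover every hit
#'   transcript.
#' @return Data frame: `gene`, `transcript`, `length`, `families`
#'   (";"-joined DBD families found on the chosen transcript).
#' @export
select_longest_per_gene <- function(hits, lengths) {
  if (is.data.frame(lengths))
    lengths <- stats::setNames(lengths$length, lengths$transcript)
  missing <- setdiff(unique(hits$contig), names(lengths))
  if (length(missing) > 0)
    stop("missing transcript length(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(hits, hits$gene), function(h) {
    ctg <- sort(unique(h$contig))
    len <- lengths[ctg]
    best <- ctg[which.max(len)]   # which.max takes the first (smallest ID) tie
    data.frame(gene = h$gene[1], transcript = best,
               length = unname(len[[best]]),
               families = paste(sort(unique(h$family[h$contig == best])),
                                collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}

#' Parse a 12-column tabular BLAST file
#'
#' Reads BLAST `-outfmt 6` output and applies the catalog thresholds: hits
#' are kept when e-value is strictly below `evalue_max` (default 1e-5) and,
#' if `min_identity` is given (the known-planarian search uses 90), percent
#' identity is strictly above it.
#'
#' @param file Path to the tabular BLAST file.
#' @param evalue_max Strict e-value cutoff.
#' @param min_identity Optional strict percent-identity floor.
#' @return Data frame with the standard 12 columns (`qseqid`, `sseqid`,
#'   `pident`, `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`,
#'   `send`, `evalue`, `bitscore`).
#' @export
parse_blast_table <- function(file, evalue_max = 1e-5, min_identity = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- readLines(file)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), 12), cols))
    return(out)
  }
  fields <- strsplit(raw, "\t")
  bad <- which(lengths(fields) != 12L)
  if (length(bad) > 0)
    stop("malformed BLAST row at line ", bad[1], ": expected 12 columns, ",
         "found ", lengths(fields)[bad[1]])
  df <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(df) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  df[num] <- lapply(df[num], as.numeric)
  df <- df[df$evalue < evalue_max, , drop = FALSE]
  if (!is.null(min_identity))
    df <- df[df$pident > min_identity, , drop = FALSE]
  rownames(df) <- NULL
  df
}

best_hit_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$qseqid, hits$evalue, -hits$bitscore, -hits$pident,
             hits$sseqid)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$qseqid), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Categorize candidate TF genes
#'
#' Assigns each DBD-containing gene to one category by priority:
#' known FSTF > known planarian TF > human-TF hit > excluded (best human hit
#' is a non-TF protein) > no blast hit (retained). A passing hit in the
#' known-planarian BLAST search also qualifies a gene as a known planarian
#' TF. Genes whose best human hit is a non-TF are flagged excluded with the
#' reason recorded; excluded genes never appear in the final catalog
#' (`entries[!entries$excluded, ]`).
#'
#' @param chosen Output of [select_longest_per_gene()].
#' @param human_hits BLAST hits of chosen transcripts against the human
#'   proteome (already thresholded by [parse_blast_table()]); query IDs are
#'   matched against both transcript and gene IDs.
#' @param human_tf_ids Subject IDs in `human_hits` annotated as human TFs.
#' @param planarian_hits Optional BLAST hits against known planarian
#'   genes (thresholded with identity > 90).
#' @param known_fstf,known_planarian Gene IDs on the curated lists. A gene
#'   on both lists is categorized known FSTF and a message is logged.
#' @return Data frame of catalog entries: `gene`, `transcript`, `families`,
#'   `category`, `excluded`, `rule`.
#' @export
categorize_tf_genes <- function(chosen, human_hits, human_tf_ids = character(),
                                planarian_hits = NULL,
                                known_fstf = character(),
                                known_planarian = character()) {
  best <- best_hit_per_query(human_hits)
  planarian_queries <- if (!is.null(planarian_hits)) unique(
    planarian_hits$qseqid) else character()
  both <- intersect(known_fstf, known_planarian)
  both <- intersect(both, chosen$gene)
  if (length(both) > 0)
    message("gene(s) on both known lists categorized as known FSTF: ",
            paste(both, collapse = ", "))
  n <- nrow(chosen)
  category <- character(n); excluded <- logical(n); rule <- character(n)
  for (i in seq_len(n)) {
    g <- chosen$gene[i]; tx <- chosen$transcript[i]
    b <- best[best$qseqid %in% c(tx, g), , drop = FALSE]
    if (g %in% known_fstf) {
      category[i] <- "known FSTF"
      rule[i] <- "on curated FSTF list"
    } else if (g %in% known_planarian ||
               any(c(tx, g) %in% planarian_queries)) {
      category[i] <- "known planarian TF"
      rule[i] <- if (g %in% known_planarian) "on curated planarian list" else
        "passing hit in known-planarian BLAST"
    } else if (nrow(b) == 0L) {
      category[i] <- "no blast hit"
      rule[i] <- "no human hit below e-value threshold; retained"
    } else if (b$sseqid[1] %in% human_tf_ids) {
      category[i] <- "human-TF hit"
      rule[i] <- paste0("best human hit ", b$sseqid[1], " is a TF")
    } else {
      category[i] <- "excluded non-TF"
      excluded[i] <- TRUE
      rule[i] <- paste0("best human hit ", b$sseqid[1],
                        " is a non-TF protein")
    }
  }
  data.frame(gene = chosen$gene, transcript = chosen$transcript,
             families = chosen$families, category = category,
             excluded = excluded, rule = rule, stringsAsFactors = FALSE)
}

#' DBD family composition of a catalog subset
#'
#' Counts genes per DNA-binding-domain family over a subset of catalog
#' entries. Multi-family genes are counted once in each of their families,
#' so fractions (over the number of genes in the subset) can sum above 1.
#'
#' @param entries Catalog entries from [categorize_tf_genes()].
#' @param subset Optional gene IDs; default: all non-excluded entries.
#' @return Data frame `family`, `count`, `fraction`, sorted by decreasing
#'   count.
#' @export
family_composition <- function(entries, subset = NULL) {
  if (is.null(subset)) subset <- entries$gene[!entries$excluded]
  e <- entries[entries$gene %in% subset, , drop = FALSE]
  if (nrow(e) == 0L) stop("empty subset: no catalog entries to summarize")
  fams <- lapply(strsplit(e$families, ";"), unique)
  tab <- table(unlist(fams))
  out <- data.frame(family = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / nrow(e),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a TF catalog from search outputs
#'
#' Convenience orchestrator: parse the HMMER domain table, choose the
#' longest DBD-containing transcript per gene, parse the BLAST tables, and
#' categorize. The final catalog is the non-excluded entries.
#'
#' @param domain_file HMMER tblout/domtblout path.
#' @param lengths Transcript lengths (named vector or data frame).
#' @param human_blast_file BLAST outfmt-6 path (vs human proteome); `NULL`
#'   for none.
#' @param planarian_blast_file Optional BLAST outfmt-6 path (vs known
#'   planarian genes; identity > 90 applied).
#' @param human_tf_ids,known_fstf,known_planarian See
#'   [categorize_tf_genes()].
#' @param gene_from_contig See [parse_domain_table()].
#' @return A list: `entries` (all, with exclusion flags), `catalog`
#'   (retained entries), `hits` (parsed domain hits).
#' @export
build_catalog <- function(domain_file, lengths, human_blast_file = NULL,
                          planarian_blast_file = NULL,
                          human_tf_ids = character(),
                          known_fstf = character(),
                          known_planarian = character(),
                          gene_from_contig = contig_gene) {
  hits <- parse_domain_table(domain_file, gene_from_contig = gene_from_contig)
  chosen <- select_longest_per_gene(hits, lengths)
  human <- if (is.null(human_blast_file)) {
    parse_blast_table(textConnection(character(0)))
  } else parse_blast_table(human_blast_file, evalue_max = 1e-5)
  planarian <- if (is.null(planarian_blast_file)) NULL else
    parse_blast_table(planarian_blast_file, evalue_max = 1e-5,
                      min_identity = 90)
  entries <- categorize_tf_genes(chosen, human, human_tf_ids, planarian,
                                 known_fstf, known_planarian)
  list(entries = entries, catalog = entries[!entries$excluded, , drop = FALSE],
       hits = hits)
}
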