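#' Median-of-ratios library size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' all-positive counts, of the ratio of the sample's count to the gene's
#' geometric mean across samples.
#'
#' @param counts Genes-by-samples count matrix.
#' @return Named numeric vector of positive size factors (one per sample).
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) == 1) return(setNames(1, colnames(counts)))
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) {
    abort(paste("no gene has positive counts in every sample;",
                "consider a pseudo-reference fallback"))
  }
  lg <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(lg - geo), 2, median)
}

#' Convert counts to TPM
#'
#' Counts are optionally divided by per-sample size factors, converted to
#' per-bp rates using gene lengths, and scaled so every column sums to one
#' million.
#'
#' @param counts Genes-by-samples count matrix.
#' @param lengths Named numeric vector of gene lengths (bp), covering all
#'   rows of `counts`.
#' @param factors Optional per-sample size factors (see [size_factors()]).
#' @return A TPM matrix of the same dimensions; columns sum to 1e6.
#' @export
tpm_normalize <- function(counts, lengths, factors = NULL) {
  counts <- as.matrix(counts)
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    abort("every gene needs a positive length")
  }
  if (!is.null(factors)) counts <- sweep(counts, 2, factors, "/")
  rate <- counts / lengths
  totals <- colSums(rate)
  if (any(totals == 0)) abort("column with zero total rate")
  sweep(rate, 2, totals, "/") * 1e6
}

#' Differential expression between two cell populations
#'
#' A transparent stand-in engine for count-model differential testing:
#' Welch's t-test on log2(TPM + 1) per gene, Benjamini-Hochberg correction,
#' and the atlas thresholds (significant iff |log2FC| >= `lfc_threshold`
#' and q < `q_threshold`). log2FC is the mean log2(TPM + 1) of group B
#' minus group A. Externally computed tables (e.g. from a
#' negative-binomial GLM) can be injected anywhere a `lnc_de` tibble is
#' consumed, since only the thresholded columns are used downstream.
#'
#' @param tpm Genes-by-samples TPM matrix.
#' @param samples Sample map tibble (`sample`, `cell_type`).
#' @param group_a,group_b Cell-type labels to contrast (B over A).
#' @param lfc_threshold Absolute log2 fold-change threshold (default 1.5).
#' @param q_threshold BH-adjusted q-value threshold (default 0.01).
#' @return A tibble of class `lnc_de` with columns `gene`, `log2FC`, `p`,
#'   `q`, `significant` and attributes `contrast`, `thresholds`.
#' @export
differential_expression <- function(tpm, samples, group_a, group_b,
                                    lfc_threshold = 1.5, q_threshold = 0.01) {
  a <- samples$sample[samples$cell_type == group_a]
  b <- samples$sample[samples$cell_type == group_b]
  if (length(a) < 2 || length(b) < 2) {
    abort("each group needs at least 2 samples")
  }
  la <- log2(tpm[, a, drop = FALSE] + 1)
  lb <- log2(tpm[, b, drop = FALSE] + 1)
  lfc <- rowMeans(lb) - rowMeans(la)
  p <- vapply(seq_len(nrow(tpm)), function(i) {
    tryCatch(stats::t.test(lb[i, ], la[i, ])$p.value,
             error = function(e) if (abs(lfc[i]) < 1e-12) 1 else 0)
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  out <- tibble(gene = rownames(tpm), log2FC = unname(lfc), p = p, q = q,
                significant = abs(lfc) >= lfc_threshold & q < q_threshold)
  attr(out, "contrast") <- c(group_a, group_b)
  attr(out, "thresholds") <- c(lfc = lfc_threshold, q = q_threshold)
  class(out) <- c("lnc_de", class(out))
  out
}

#' Tissue (cell-type) specificity index tau
#'
#' For each gene, per-cell-type median TPM values x_i are scaled by their
#' maximum and tau = sum(1 - x_i/max) / (N - 1), giving 0 for uniformly
#' expressed genes and 1 for single-cell-type expression. Genes with zero
#' median everywhere are undefined and reported as `NA`.
#'
#' @param tpm Genes-by-samples TPM matrix (linear scale).
#' @param samples Sample map tibble (`sample`, `cell_type`).
#' @return A tibble of class `lnc_tau` with `gene`, `tau`, and one
#'   `median_<cell_type>` column per population.
#' @export
tau_index <- function(tpm, samples) {
  med <- cell_type_medians(tpm, samples)
  if (ncol(med) < 2) abort("tau needs at least 2 cell types")
  mx <- apply(med, 1, max)
  tau <- ifelse(mx == 0, NA_real_,
                rowSums(1 - med / ifelse(mx == 0, 1, mx)) / (ncol(med) - 1))
  out <- bind_cols(tibble(gene = rownames(med), tau = unname(tau)),
                   as_tibble(med, .name_repair = ~ paste0("median_", .x)))
  class(out) <- c("lnc_tau", class(out))
  out
}

# genes x cell-types matrix of per-cell-type median expression
cell_type_medians <- function(tpm, samples) {
  types <- unique(samples$cell_type)
  med <- vapply(types, function(ct) {
    cols <- samples$sample[samples$cell_type == ct]
    apply(tpm[, cols, drop = FALSE], 1, median)
  }, numeric(nrow(tpm)))
  rownames(med) <- rownames(tpm)
  med
}

#' Expression-trajectory clustering of genes across cell types
#'
#' Genes are summarised by per-cell-type median TPM, max-normalized per
#' gene, and clustered by k-means (k = 8 by default, matching the eight
#' trajectory archetypes across the six B cell stages) with a fixed seed
#' and 50 restarts. Genes with zero expression everywhere are dropped.
#'
#' @param tpm Genes-by-samples TPM matrix.
#' @param samples Sample map tibble (`sample`, `cell_type`).
#' @param k Number of clusters (default 8).
#' @param seed Integer seed (clustering is deterministic given the seed).
#' @return A list of class `lnc_traj`: `clusters` (tibble `gene`,
#'   `cluster`), `centers` (k x cell-type matrix), `k`.
#' @export
trajectory_clusters <- function(tpm, samples, k = 8, seed = 1) {
  med <- cell_type_medians(tpm, samples)
  med <- med[apply(med, 1, max) > 0, , drop = FALSE]
  norm <- med / apply(med, 1, max)
  if (k > nrow(unique(as.data.frame(norm)))) {
    abort("k exceeds the number of distinct expression profiles")
  }
  km <- withr::with_seed(seed, kmeans(norm, centers = k, nstart = 50,
                                      iter.max = 100))
  structure(list(clusters = tibble(gene = rownames(norm),
                                   cluster = unname(km$cluster)),
                 centers = km$centers, k = k),
            class = "lnc_traj")
}

#' PCA of samples on the most variable genes
#'
#' Genes are ranked by standard deviation of TPM across samples; the top
#' fraction (default 10%) is retained, centred per gene, and samples are
#' projected onto the principal axes.
#'
#' @param tpm Genes-by-samples TPM matrix.
#' @param samples Optional sample map; cell types are attached to scores.
#' @param top_fraction Fraction of genes to keep (default 0.10; ceiling).
#' @return A list of class `lnc_pca`: `scores` (tibble `sample`, `PC1`, ...,
#'   optional `cell_type`), `var_explained` (fractions), `n_genes`.
#' @export
pca_embedding <- function(tpm, samples = NULL, top_fraction = 0.10) {
  if (ncol(tpm) < 2) abort("PCA needs at least 2 samples")
  sds <- apply(tpm, 1, sd)
  n_keep <- ceiling(top_fraction * nrow(tpm))
  if (n_keep < 2) abort("fewer than 2 genes retained")
  keep <- names(sort(sds, decreasing = TRUE))[seq_len(n_keep)]
  pc <- prcomp(t(tpm[keep, , drop = FALSE]), center = TRUE, scale. = FALSE)
  scores <- as_tibble(pc$x, rownames = "sample")
  if (!is.null(samples)) scores <- left_join(scores, samples, by = "sample")
  structure(list(scores = scores,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2),
                 n_genes = n_keep),
            class = "lnc_pca")
}

#' Bootstrapped neighbor-joining phylogeny of cell types
#'
#' TPM values are log2(x + 1)-transformed; the distance between two cell
#' types is the median of all cross-group sample-pair distances (Euclidean
#' by default, or Pearson 1 - r); neighbor-joining is run on the resulting
#' matrix, and split supports come from gene-resampled bootstrap
#' replicates. Negative NJ branch lengths are clamped to 0 and flagged.
#'
#' @param tpm Genes-by-samples TPM matrix.
#' @param samples Sample map tibble (`sample`, `cell_type`).
#' @param metric `"euclidean"` or `"pearson"`.
#' @param n_boot Number of bootstrap replicates (default 100).
#' @param seed Integer seed for the bootstrap resampling.
#' @return A list of class `lnc_phylo`: `tree` (an [ape::phylo] with
#'   bootstrap percentages as `node.label`), `dist` (cell-type distance
#'   matrix), `support` (numeric per internal node), `negative_branches`
#'   (count clamped), `metric`, `n_boot`.
#' @export
group_phylogeny <- function(tpm, samples, metric = c("euclidean", "pearson"),
                            n_boot = 100, seed = 1) {
  metric <- match.arg(metric)
  types <- unique(samples$cell_type)
  if (length(types) < 3) abort("need at least 3 cell types")
  lt <- log2(tpm + 1)

  group_dist <- function(mat) {
    d <- switch(metric,
      euclidean = as.matrix(dist(t(mat))),
      pearson = 1 - stats::cor(mat))
    out <- matrix(0, length(types), length(types),
                  dimnames = list(types, types))
    for (i in seq_along(types)) for (j in seq_along(types)) {
      if (i < j) {
        si <- samples$sample[samples$cell_type == types[i]]
        sj <- samples$sample[samples$cell_type == types[j]]
        out[i, j] <- out[j, i] <- median(d[si, sj])
      }
    }
    out
  }

  build <- function(mat) nj_tree(group_dist(mat))
  tree0 <- ape::nj(as.dist(group_dist(lt)))
  n_neg <- sum(tree0$edge.length < 0)
  tree <- nj_tree(group_dist(lt))

  boots <- withr::with_seed(seed, lapply(seq_len(n_boot), function(b) {
    build(lt[sample(nrow(lt), replace = TRUE), , drop = FALSE])
  }))
  support <- ape::prop.clades(tree, boots, rooted = FALSE)
  support[is.na(support)] <- 0
  support_pct <- round(100 * support / n_boot, 1)
  tree$node.label <- as.character(support_pct)
  structure(list(tree = tree, dist = group_dist(lt), support = support_pct,
                 negative_branches = n_neg, metric = metric, n_boot = n_boot),
            class = "lnc_phylo")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin wrapper around [ape::nj()] that clamps the occasional negative
#' branch length to 0 (recorded in the `negative_branches` attribute).
#' On an additive distance matrix the tree's path distances reproduce the
#' input exactly.
#'
#' @param d A symmetric distance matrix (or `dist`) over >= 3 taxa.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  tr <- ape::nj(as.dist(d))
  neg <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "negative_branches") <- neg
  tr
}

#' Fraction of reads in the Ig locus, per sample
#'
#' For a gene class (coding or lncRNA), the per-sample fraction of that
#' class's reads assigned to genes overlapping the immunoglobulin loci.
#'
#' @param counts Genes-by-samples count matrix.
#' @param catalog A [transcript_catalog()] (gene spans are used; `gene_id`
#'   must match `counts` rownames).
#' @param ig_loci Ig-locus intervals (`chrom`, `start`, `end`).
#' @param biotypes Character vector of biotypes defining the class (e.g.
#'   `"coding"` or `c("novel_lncRNA", "annotated_lncRNA")`).
#' @return A tibble with `sample` and `ig_fraction` in \[0, 1\].
#' @export
ig_read_fraction <- function(counts, catalog, ig_loci, biotypes = "coding") {
  sub <- filter(catalog, .data$biotype %in% biotypes)
  if (nrow(sub) == 0) abort("no genes of the requested class in the counts")
  spans <- sub |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], start = min(.data$start),
              end = max(.data$end), .groups = "drop")
  spans <- spans[spans$gene_id %in% rownames(counts), ]
  if (nrow(spans) == 0) abort("no genes of the requested class in the counts")
  in_ig <- spans$gene_id[overlaps_any(spans, ig_loci)]
  cls <- counts[spans$gene_id, , drop = FALSE]
  total <- colSums(cls)
  igsum <- if (length(in_ig)) colSums(cls[in_ig, , drop = FALSE]) else 0 * total
  tibble(sample = colnames(counts),
         ig_fraction = unname(ifelse(total > 0, igsum / total, 0)))
}
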