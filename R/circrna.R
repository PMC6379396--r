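#' Filter circRNA back-splice junctions by read support
#'
#' Junctions are kept when they have at least `min_reads` junction reads in
#' at least `min_samples` samples (both bounds inclusive).
#'
#' @param junctions Tibble with `junction_id`, `chrom`, `donor`, `acceptor`
#'   and one integer count column per sample.
#' @param samples Sample map tibble (`sample`, `cell_type`); its `sample`
#'   values name the count columns.
#' @param min_reads Minimum junction reads per qualifying sample (default 5).
#' @param min_samples Minimum number of qualifying samples (default 3).
#' @return The filtered junction tibble (same columns).
#' @export
filter_circrnas <- function(junctions, samples, min_reads = 5,
                            min_samples = 3) {
  junctions <- as_tibble(junctions)
  if (nrow(junctions) == 0) return(junctions)
  cnt <- as.matrix(junctions[samples$sample])
  if (any(cnt < 0)) abort("junction counts must be non-negative")
  keep <- rowSums(cnt >= min_reads) >= min_samples
  junctions[keep, ]
}

#' Partition circRNAs into Ig and non-Ig groups
#'
#' A junction belongs to the Ig group when its genomic span
#' (`[donor, acceptor)`, half-open) intersects an immunoglobulin locus.
#' Per cell type and group, the mean per-sample total junction reads is
#' reported.
#'
#' @param junctions Filtered junction tibble (see [filter_circrnas()]).
#' @param ig_loci Ig-locus intervals (`chrom`, `start`, `end`).
#' @param samples Sample map tibble (`sample`, `cell_type`).
#' @return A list of class `lnc_circ`: `junctions` (input plus `ig`
#'   logical), `by_cell_type` (tibble `cell_type`, `group`,
#'   `mean_reads_per_sample`, `n_junctions`).
#' @export
partition_ig <- function(junctions, ig_loci, samples) {
  junctions <- as_tibble(junctions)
  stopifnot(all(junctions$donor < junctions$acceptor))
  spans <- tibble(chrom = junctions$chrom, start = junctions$donor,
                  end = junctions$acceptor)
  junctions$ig <- overlaps_any(spans, ig_loci)
  per_type <- samples |>
    group_by(.data$cell_type) |>
    group_modify(function(g, key) {
      if (nrow(g) == 0) abort(paste("no samples for cell type", key$cell_type))
      cnt <- as.matrix(junctions[g$sample])
      list_rbind(map(c(ig = TRUE, non_ig = FALSE), function(flag) {
        rows <- junctions$ig == flag
        tibble(group = if (flag) "ig" else "non_ig",
               mean_reads_per_sample = mean(colSums(cnt[rows, , drop = FALSE])),
               n_junctions = sum(rows))
      }))
    }) |>
    ungroup()
  structure(list(junctions = junctions, by_cell_type = per_type),
            class = "lnc_circ")
}

#' @export
print.lnc_circ <- function(x, ...) {
  cat("<lnc_circ> ", nrow(x$junctions), " junctions (",
      sum(x$junctions$ig), " Ig)\n", sep = "")
  print(x$by_cell_type)
  invisible(x)
}

#' Correlate total circRNA expression with selected genes
#'
#' Rank (Spearman) correlation between per-sample total junction reads and
#' each gene's TPM, with per-gene p-values. Descriptive (no multiplicity
#' adjustment); typical query genes are proliferation markers (MKI67,
#' PCNA) and RNA-binding circRNA regulators (ADAR1, DHX9, HNRNPL).
#'
#' @param junctions Filtered junction tibble.
#' @param tpm Genes-by-samples TPM matrix.
#' @param genes Character vector of gene IDs to test.
#' @param samples Sample map tibble (`sample`, `cell_type`).
#' @param method Correlation method (default `"spearman"`).
#' @return A tibble with `gene`, `rho`, `p`, `status`
#'   (`"ok"`, `"missing"`, or `"constant"`).
#' @export
circ_gene_correlation <- function(junctions, tpm, genes, samples,
                                  method = "spearman") {
  totals <- colSums(as.matrix(as_tibble(junctions)[samples$sample]))
  if (length(totals) < 4) abort("need at least 4 samples")
  rows <- map(genes, function(g) {
    if (!g %in% rownames(tpm)) {
      return(tibble(gene = g, rho = NA_real_, p = NA_real_,
                    status = "missing"))
    }
    v <- tpm[g, samples$sample]
    if (sd(v) == 0) {
      return(tibble(gene = g, rho = NA_real_, p = NA_real_,
                    status = "constant"))
    }
    ct <- suppressWarnings(cor.test(totals, v, method = method))
    tibble(gene = g, rho = unname(ct$estimate), p = ct$p.value, status = "ok")
  })
  list_rbind(rows)
}
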