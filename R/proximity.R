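#' GREAT-style basal-plus-extension regulatory domains
#'
#' Each coding gene gets a strand-oriented basal region (default 5 kb
#' upstream to 1 kb downstream of the TSS). Each side is then extended to
#' the nearest of: the maximum extension beyond the basal edge, the
#' chromosome edge, or the nearest other gene's basal-region boundary.
#' Extensions never truncate any basal region: when basal regions overlap,
#' the extension on that side is empty.
#'
#' @param coding Coding-gene [transcript_catalog()] (one TSS per gene; if a
#'   gene has several transcripts the span-level TSS is used).
#' @param genome A [genome_model()].
#' @param basal_up,basal_down Basal extent upstream/downstream of the TSS
#'   (bp; defaults 5000 and 1000).
#' @param max_extension Maximum extension beyond each basal edge (bp,
#'   default 1e6).
#' @return A tibble of regulatory domains: `gene_id`, `chrom`, `strand`,
#'   `tss`, `basal_start`, `basal_end`, `start`, `end`.
#' @export
regulatory_domains <- function(coding, genome, basal_up = 5000,
                               basal_down = 1000, max_extension = 1e6) {
  genes <- coding |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end),
           basal_start = pmax(0, ifelse(.data$strand == "+",
                                        .data$tss - basal_up,
                                        .data$tss - basal_down)),
           basal_end = ifelse(.data$strand == "+", .data$tss + basal_down,
                              .data$tss + basal_up))
  len <- setNames(genome$chrom_sizes$length, genome$chrom_sizes$chrom)
  genes$basal_end <- pmin(genes$basal_end, len[genes$chrom])

  out <- genes |>
    group_by(.data$chrom) |>
    group_modify(function(g, key) {
      L <- len[[key$chrom]]
      g$start <- NA_real_
      g$end <- NA_real_
      for (i in seq_len(nrow(g))) {
        others <- g[-i, ]
        left_caps <- others$basal_end[others$basal_start < g$basal_start[i]]
        cap_l <- if (length(left_caps)) min(g$basal_start[i], max(left_caps)) else 0
        g$start[i] <- max(0, g$basal_start[i] - max_extension, cap_l)
        right_caps <- others$basal_start[others$basal_start > g$basal_start[i] |
                                         (others$basal_start == g$basal_start[i] &
                                          others$gene_id > g$gene_id[i])]
        cap_r <- if (length(right_caps)) max(g$basal_end[i], min(right_caps)) else L
        g$end[i] <- min(L, g$basal_end[i] + max_extension, cap_r)
      }
      g
    }) |>
    ungroup() |>
    select("gene_id", "chrom", "strand", "tss", "basal_start", "basal_end",
           "start", "end")
  out
}

#' Associate lncRNAs with coding genes through regulatory domains
#'
#' Emits a (lncRNA, gene) pair whenever the lncRNA's genomic span
#' intersects the gene's regulatory domain: a many-to-many association.
#'
#' @param lncrnas A [transcript_catalog()] of lncRNAs.
#' @param domains Output of [regulatory_domains()].
#' @return A tibble with `transcript_id` (lncRNA) and `gene_id`.
#' @export
associate_lncrna_genes <- function(lncrnas, domains) {
  hits <- overlap_pairs(lncrnas[c("chrom", "start", "end")],
                        domains[c("chrom", "start", "end")])
  tibble(transcript_id = lncrnas$transcript_id[hits$i],
         gene_id = domains$gene_id[hits$j]) |>
    distinct() |>
    arrange(.data$transcript_id, .data$gene_id)
}

#' Distance-binned lncRNA fold-change profile around DE coding genes
#'
#' For every differentially expressed coding gene (the anchors, split into
#' up- and down-regulated), every lncRNA whose TSS lies within the window
#' of the gene's TSS contributes its own log2FC from the same contrast to
#' a signed-distance bin. Distances are TSS-to-TSS and oriented by the
#' anchor gene's strand (positive = downstream).
#'
#' @param coding_de A `lnc_de` table for the coding genes (see
#'   [differential_expression()]).
#' @param lnc_de A `lnc_de` table for the lncRNAs, same contrast.
#' @param coding,lncrnas The corresponding [transcript_catalog()]s
#'   (`gene_id` of `coding` must match `coding_de$gene`; `transcript_id`
#'   of `lncrnas` must match `lnc_de$gene`).
#' @param window Half-window around the anchor TSS (bp, default 250000).
#' @param bin_width Bin width (bp, default 25000); must divide `window`.
#' @return A tibble of class `lnc_distance_profile`: `direction`
#'   (`up`/`down`), `bin_lo`, `bin_hi`, `bin_mid`, `n`, `mean_lfc`
#'   (`NA` where `n` is 0). Bins partition \[-window, window\].
#' @export
distance_fc_profile <- function(coding_de, lnc_de, coding, lncrnas,
                                window = 250000, bin_width = 25000) {
  anchors <- coding |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              tss = ifelse(.data$strand[1] == "+", min(.data$start),
                           max(.data$end)), .groups = "drop") |>
    inner_join(filter(coding_de, .data$significant), by = c(gene_id = "gene")) |>
    mutate(direction = ifelse(.data$log2FC > 0, "up", "down"))
  if (nrow(anchors) == 0) abort("no significant anchor genes")

  lnc <- lncrnas |>
    select("transcript_id", "chrom", lnc_tss = "tss") |>
    inner_join(lnc_de, by = c(transcript_id = "gene"))

  pairs <- inner_join(anchors, lnc, by = "chrom",
                      relationship = "many-to-many") |>
    mutate(distance = ifelse(.data$strand == "+", 1, -1) *
             (.data$lnc_tss - .data$tss)) |>
    filter(abs(.data$distance) <= window)

  breaks <- seq(-window, window, by = bin_width)
  grid <- tidyr::expand_grid(direction = c("up", "down"),
                             bin_lo = head(breaks, -1)) |>
    mutate(bin_hi = .data$bin_lo + bin_width)
  binned <- pairs |>
    mutate(bin_lo = breaks[pmin(findInterval(.data$distance, breaks,
                                             rightmost.closed = TRUE),
                                length(breaks) - 1)]) |>
    group_by(.data$direction, .data$bin_lo) |>
    summarise(n = dplyr::n(), mean_lfc = mean(.data$log2FC.y),
              .groups = "drop")
  out <- grid |>
    left_join(binned, by = c("direction", "bin_lo")) |>
    mutate(n = coalesce(.data$n, 0L),
           bin_mid = (.data$bin_lo + .data$bin_hi) / 2) |>
    select("direction", "bin_lo", "bin_hi", "bin_mid", "n", "mean_lfc")
  class(out) <- c("lnc_distance_profile", class(out))
  out
}

#' Over-representation enrichment of gene sets
#'
#' One-sided hypergeometric test of query/set overlap against a universe,
#' Benjamini-Hochberg corrected across the collection; sets are flagged
#' enriched at q below the cutoff and ranked by -log10(q).
#'
#' @param query Character vector of genes of interest (must be a subset of
#'   `universe`).
#' @param universe Character vector: the gene universe.
#' @param collection Named list of character vectors (the gene sets).
#' @param q_max Enrichment cutoff on BH q (default 0.001).
#' @return A tibble with `set`, `set_size`, `overlap`, `p`, `q`,
#'   `neg_log10_q`, `enriched`, sorted by `q`.
#' @export
ora_enrichment <- function(query, universe, collection, q_max = 0.001) {
  query <- unique(query)
  universe <- unique(universe)
  extra <- setdiff(query, universe)
  if (length(extra)) {
    abort(paste("query genes missing from the universe:",
                paste(head(extra, 5), collapse = ", ")))
  }
  if (length(collection) == 0) abort("empty gene-set collection")
  N <- length(universe)
  n <- length(query)
  rows <- imap(collection, function(set, name) {
    K <- length(intersect(set, universe))
    k <- length(intersect(set, query))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set = name, set_size = K, overlap = k, p = p)
  })
  out <- list_rbind(rows) |>
    mutate(q = p.adjust(.data$p, method = "BH"),
           neg_log10_q = -log10(.data$q),
           enriched = .data$q < q_max) |>
    arrange(.data$q)
  out
}
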