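#' Percentile summary of a signal track around a TSS
#'
#' The summary value of a track at a TSS is a high percentile (default the
#' 90th) of the per-base signal in a window of +/- `half_width` bp around
#' the TSS (2 * half_width + 1 bases, clipped at chromosome edges). The
#' percentile removes outliers and normalizes for peak length; percentiles
#' use linear interpolation between order statistics (type 7). Uncovered
#' windows summarise to 0.
#'
#' @param track A [signal_track()].
#' @param chrom Chromosome of the TSS.
#' @param tss TSS position (0-based).
#' @param half_width Window half-width in bp (default 1000).
#' @param percentile Percentile in (0, 100\] (default 90).
#' @param chrom_length Optional chromosome length for edge clipping.
#' @return The summary value (numeric scalar >= 0).
#' @export
tss_signal_summary <- function(track, chrom, tss, half_width = 1000,
                               percentile = 90, chrom_length = NULL) {
  if (percentile <= 0 || percentile > 100) {
    abort("percentile must be in (0, 100]")
  }
  lo <- max(0, tss - half_width)
  hi <- tss + half_width + 1  # window is closed: [tss-hw, tss+hw]
  if (!is.null(chrom_length)) hi <- min(hi, chrom_length)
  if (hi <= lo) return(0)
  vals <- track_values(track, chrom, lo, hi)
  unname(quantile(vals, percentile / 100, type = 7))
}

#' Chromatin feature matrix at lncRNA TSSs
#'
#' One row per lncRNA, one column per mark/factor track, each entry the
#' [tss_signal_summary()] of that track at the lncRNA's TSS.
#'
#' @param catalog A [transcript_catalog()] of lncRNAs.
#' @param tracks A *named* list of [signal_track()]s (names become feature
#'   columns; duplicates are an error).
#' @param genome Optional [genome_model()] for edge clipping.
#' @param half_width,percentile Passed to [tss_signal_summary()].
#' @return A tibble with `transcript_id` plus one numeric column per track,
#'   rows in catalog order.
#' @export
feature_matrix <- function(catalog, tracks, genome = NULL, half_width = 1000,
                           percentile = 90) {
  if (length(tracks) == 0) abort("need at least one track")
  nm <- names(tracks)
  if (is.null(nm) || anyDuplicated(nm)) abort("tracks must have unique names")
  lens <- if (!is.null(genome)) {
    setNames(genome$chrom_sizes$length, genome$chrom_sizes$chrom)
  }
  cols <- map(tracks, function(tr) {
    # index segments by chromosome once per track for fast lookup
    by_chrom <- split(as.data.frame(tr)[c("start", "end", "value")], tr$chrom)
    map_dbl(seq_len(nrow(catalog)), function(i) {
      chrom <- catalog$chrom[i]
      seg <- by_chrom[[chrom]]
      sub <- if (is.null(seg)) tr[0, ] else {
        tibble(chrom = chrom, start = seg$start, end = seg$end,
               value = seg$value)
      }
      tss_signal_summary(sub, chrom, catalog$tss[i], half_width, percentile,
                         chrom_length = if (!is.null(lens)) lens[[chrom]])
    })
  })
  bind_cols(tibble(transcript_id = catalog$transcript_id), as_tibble(cols))
}

#' Winsorize and min-max scale features to \[0, 1\]
#'
#' Per feature: values are clipped at the given lower/upper percentiles
#' (removing the top and bottom 1% by default) and mapped linearly to
#' \[0, 1\]. Constant features map to all 0 by convention.
#'
#' @param features A numeric matrix or a tibble (an id column named
#'   `transcript_id` is carried through unscaled).
#' @param low,high Clip probabilities (defaults 0.01 and 0.99).
#' @return Object of the same shape with features in \[0, 1\].
#' @export
clip_scale <- function(features, low = 0.01, high = 0.99) {
  id <- NULL
  if (is.data.frame(features)) {
    if ("transcript_id" %in% names(features)) {
      id <- features$transcript_id
      features <- select(features, -"transcript_id")
    }
    mat <- as.matrix(features)
  } else {
    mat <- features
  }
  if (length(mat) == 0) abort("empty feature matrix")
  scaled <- apply(mat, 2, function(v) {
    q <- quantile(v, c(low, high), type = 7)
    v <- pmin(pmax(v, q[1]), q[2])
    if (q[2] == q[1]) return(rep(0, length(v)))
    (v - q[1]) / (q[2] - q[1])
  })
  scaled <- matrix(scaled, nrow = nrow(mat), dimnames = dimnames(mat))
  if (!is.null(id)) bind_cols(tibble(transcript_id = id), as_tibble(scaled))
  else scaled
}

#' Spectral clustering of lncRNAs by chromatin features
#'
#' lncRNAs are partitioned into functional classes (default k = 10) by
#' normalized spectral clustering on the clip-scaled feature matrix:
#' Gaussian-kernel affinity with bandwidth set to the median pairwise
#' distance, symmetric normalized graph Laplacian, k-means (fixed seed) on
#' the row-normalized leading eigenvectors. Per-cluster medians are
#' reported on the raw (unscaled) summaries for heatmap reporting, and a
#' 2-D embedding (PCA of the scaled features) is computed independently
#' for plotting.
#'
#' @param features Output of [feature_matrix()] (tibble with
#'   `transcript_id`).
#' @param k Number of clusters (default 10).
#' @param seed Integer seed.
#' @return A list of class `lnc_chromatin_clusters`: `clusters` (tibble
#'   `transcript_id`, `cluster`), `medians` (tibble, per-cluster raw
#'   feature medians), `embedding` (tibble `transcript_id`, `dim1`,
#'   `dim2`, `cluster`), `k`.
#' @export
functional_clusters <- function(features, k = 10, seed = 1) {
  ids <- features$transcript_id
  raw <- as.matrix(select(features, -"transcript_id"))
  if (nrow(raw) < k) abort("k exceeds the number of lncRNAs")
  scaled <- clip_scale(raw)

  d <- as.matrix(dist(scaled))
  sigma <- median(d[upper.tri(d)])
  if (sigma == 0) sigma <- 1
  A <- exp(-d^2 / (2 * sigma^2))
  diag(A) <- 0
  dg <- rowSums(A)
  dg[dg == 0] <- 1e-12
  L <- t(A / sqrt(dg)) / sqrt(dg)  # D^{-1/2} A D^{-1/2}
  ev <- eigen(L, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  km <- withr::with_seed(seed, kmeans(U, centers = k, nstart = 20,
                                      iter.max = 100))
  clusters <- tibble(transcript_id = ids, cluster = unname(km$cluster))

  medians <- bind_cols(clusters["cluster"],
                       as_tibble(raw)) |>
    group_by(.data$cluster) |>
    summarise(across(everything(), median), n = dplyr::n(), .groups = "drop")

  pc <- prcomp(scaled, center = TRUE, scale. = FALSE)
  emb <- tibble(transcript_id = ids,
                dim1 = pc$x[, 1],
                dim2 = if (ncol(pc$x) > 1) pc$x[, 2] else 0,
                cluster = clusters$cluster)
  structure(list(clusters = clusters, medians = medians, embedding = emb,
                 k = k),
            class = "lnc_chromatin_clusters")
}
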