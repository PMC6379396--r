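#' Call active and poised enhancers
#'
#' Enhancers are H3K4me1 peaks whose nearest coding-gene TSS is at least
#' `min_tss_distance` bp away from the peak's nearest edge (distance 0 if
#' the TSS falls inside the peak). Peaks that also contain/overlap an
#' H3K27ac peak are active enhancers; the rest are poised.
#'
#' @param k4me1 H3K4me1 peak tibble (`chrom`, `start`, `end`).
#' @param k27ac H3K27ac peak tibble.
#' @param coding_tss Tibble of coding TSSs (`chrom`, `tss`).
#' @param min_tss_distance Minimum edge-to-TSS distance (bp, default 2500;
#'   `>=` passes).
#' @param cell_type Optional label carried through.
#' @return A tibble of enhancer calls: `chrom`, `start`, `end`, `class`
#'   (`active`/`poised`), `tss_distance`, and `cell_type` if given.
#' @export
call_enhancers <- function(k4me1, k27ac, coding_tss, min_tss_distance = 2500,
                           cell_type = NULL) {
  k4me1 <- as_tibble(k4me1)
  if (nrow(k4me1) == 0) return(mutate(empty_intervals(), class = character()))
  dist_to_tss <- map_dbl(seq_len(nrow(k4me1)), function(i) {
    t <- coding_tss$tss[coding_tss$chrom == k4me1$chrom[i]]
    if (length(t) == 0) return(Inf)
    # distance from point to [start, end): 0 inside, else gap to nearest edge
    min(pmax(0, pmax(k4me1$start[i] - t, t - (k4me1$end[i] - 1))))
  })
  out <- k4me1 |>
    mutate(tss_distance = dist_to_tss) |>
    filter(.data$tss_distance >= min_tss_distance) |>
    mutate(class = ifelse(overlaps_any(pick("chrom", "start", "end"),
                                       k27ac[c("chrom", "start", "end")]),
                          "active", "poised"))
  if (!is.null(cell_type)) out$cell_type <- cell_type
  out
}

#' Call super-enhancers by stitching and rank-signal cutoff
#'
#' H3K27ac peaks within the stitch distance are merged into regions; each
#' region's signal is the sum of its constituent peak signals. Regions are
#' ranked ascending by signal; both rank and signal are scaled to \[0, 1\]
#' and the cutoff is the signal at the first rank where the scaled curve's
#' slope exceeds 1. Regions at or above the cutoff are super-enhancers;
#' their member peaks are the constituents.
#'
#' @param k27ac Peak tibble with `chrom`, `start`, `end` and a `signal`
#'   column (aggregate per-peak signal, e.g. mean fold-change x width).
#' @param stitch_distance Maximum gap for stitching (bp, default 12500;
#'   gaps `<=` this merge).
#' @return A list of class `lnc_se`: `regions` (tibble with `region_id`,
#'   `chrom`, `start`, `end`, `n_constituents`, `total_signal`, `rank`,
#'   `is_se`), `constituents` (peaks with `region_id`), `cutoff`.
#' @export
call_super_enhancers <- function(k27ac, stitch_distance = 12500) {
  peaks <- arrange(as_tibble(k27ac), .data$chrom, .data$start)
  if (!"signal" %in% names(peaks)) abort("peaks need a `signal` column")
  # stitch: walk sorted peaks per chromosome, merging gaps <= stitch_distance
  peaks <- peaks |>
    group_by(.data$chrom) |>
    mutate(new_region = c(TRUE, .data$start[-1] - cummax(.data$end)[-dplyr::n()] >
                            stitch_distance)) |>
    mutate(region_idx = cumsum(.data$new_region)) |>
    ungroup() |>
    mutate(region_id = paste0("region_", .data$chrom, "_", .data$region_idx))

  regions <- peaks |>
    group_by(.data$region_id, .data$chrom) |>
    summarise(start = min(.data$start), end = max(.data$end),
              n_constituents = dplyr::n(), total_signal = sum(.data$signal),
              .groups = "drop")
  if (nrow(regions) < 3) abort("fewer than 3 stitched regions: cutoff undefined")
  regions <- regions |>
    arrange(.data$total_signal) |>
    mutate(rank = dplyr::row_number())
  n <- nrow(regions)
  y <- regions$total_signal
  rngy <- diff(range(y))
  ys <- if (rngy == 0) rep(0, n) else (y - min(y)) / rngy
  xs <- (regions$rank - 1) / (n - 1)
  slope <- diff(ys) / diff(xs)
  idx <- which(slope > 1)
  if (length(idx) == 0) {
    cutoff <- Inf
    regions$is_se <- FALSE
  } else {
    cutoff <- y[idx[1] + 1]  # signal at the first rank the slope exceeds 1
    regions$is_se <- regions$total_signal >= cutoff
  }
  constituents <- select(peaks, "chrom", "start", "end", "signal", "region_id")
  structure(list(regions = regions, constituents = constituents,
                 cutoff = cutoff),
            class = "lnc_se")
}

#' @export
print.lnc_se <- function(x, ...) {
  cat("<lnc_se> ", nrow(x$regions), " stitched regions, ",
      sum(x$regions$is_se), " super-enhancers (signal cutoff ",
      format(x$cutoff, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' Identify eRNAs and per-class enhancer transcription fractions
#'
#' eRNA-eligible lncRNAs are single-exon and intergenic. An eligible
#' lncRNA is an eRNA when its TSS +/- `window` intersects an enhancer peak
#' and its TSS is at least `tss_exclusion` bp from every coding TSS
#' (TSS-to-TSS). Each enhancer class is also scored for transcription: a
#' region is transcribed when it intersects at least one eligible window.
#'
#' @param lncrnas Novel-lncRNA [transcript_catalog()] with a
#'   `position_class` column.
#' @param enhancers Output of [call_enhancers()].
#' @param coding_tss Tibble of coding TSSs (`chrom`, `tss`).
#' @param se Optional [call_super_enhancers()] result; adds SE-constituent
#'   and SE-region classes.
#' @param window eRNA window half-width (bp, default 1000).
#' @param tss_exclusion Minimum TSS-to-coding-TSS distance (bp, default
#'   2500).
#' @return A list of class `lnc_ernas`: `ernas` (tibble `transcript_id`,
#'   `chrom`, `tss`, `enhancer_class`), `eligible` (ids), `fractions`
#'   (tibble `class`, `n`, `n_transcribed`, `fraction`).
#' @export
call_ernas <- function(lncrnas, enhancers, coding_tss, se = NULL,
                       window = 1000, tss_exclusion = 2500) {
  if (!"position_class" %in% names(lncrnas)) {
    abort("lncrnas need a `position_class` column (run filter_novel_lncrnas)")
  }
  eligible <- lncrnas |>
    filter(.data$n_exons == 1, .data$position_class == "intergenic")
  far <- map_lgl(seq_len(nrow(eligible)), function(i) {
    t <- coding_tss$tss[coding_tss$chrom == eligible$chrom[i]]
    length(t) == 0 || min(abs(t - eligible$tss[i])) >= tss_exclusion
  })
  eligible <- eligible[far, ]
  windows <- tibble(transcript_id = eligible$transcript_id,
                    chrom = eligible$chrom,
                    start = pmax(0, eligible$tss - window),
                    end = eligible$tss + window + 1L)

  enh <- as_tibble(enhancers)
  hits <- overlap_pairs(windows, enh[c("chrom", "start", "end")])
  ernas <- tibble(transcript_id = windows$transcript_id[hits$i],
                  enhancer_class = enh$class[hits$j]) |>
    group_by(.data$transcript_id) |>
    summarise(enhancer_class = if (any(.data$enhancer_class == "active"))
      "active" else "poised", .groups = "drop")
  if (!is.null(se)) {
    se_hit <- windows$transcript_id[
      overlaps_any(windows, se$regions[se$regions$is_se,
                                       c("chrom", "start", "end")])]
    ernas <- ernas |>
      mutate(enhancer_class = ifelse(.data$transcript_id %in% se_hit,
                                     "super_enhancer", .data$enhancer_class))
  }
  ernas <- ernas |>
    left_join(select(eligible, "transcript_id", "chrom", "tss"),
              by = "transcript_id")

  transcribed_fraction <- function(ivs, class) {
    n <- nrow(ivs)
    nt <- if (n == 0) 0L else sum(overlaps_any(ivs, windows))
    tibble(class = class, n = n, n_transcribed = nt,
           fraction = if (n == 0) NA_real_ else nt / n)
  }
  fr <- bind_rows(
    transcribed_fraction(enh[enh$class == "poised", ], "poised"),
    transcribed_fraction(enh[enh$class == "active", ], "active"))
  if (!is.null(se)) {
    se_regions <- se$regions[se$regions$is_se, ]
    se_constituents <- se$constituents[
      se$constituents$region_id %in% se_regions$region_id, ]
    fr <- bind_rows(fr,
      transcribed_fraction(se_constituents, "se_constituent"),
      transcribed_fraction(se_regions, "se_region"))
  }
  structure(list(ernas = ernas, eligible = windows$transcript_id,
                 fractions = fr),
            class = "lnc_ernas")
}

#' @export
print.lnc_ernas <- function(x, ...) {
  cat("<lnc_ernas> ", nrow(x$ernas), " eRNAs from ", length(x$eligible),
      " eligible lncRNAs\n", sep = "")
  print(x$fractions)
  invisible(x)
}

#' Bidirectionality score at a genomic position
#'
#' For a position G, two flanking windows exclude the central +/- w bp:
#' G_left = \[G - w*l, G - w) and G_right = \[G + w, G + w*l). Read starts
#' falling in each window are summed per strand into F_left, F_right
#' (forward) and R_left, R_right (reverse), a dummy count epsilon guards
#' the ratios, and
#'
#' B = log10( (R_right + e)/(R_left + e) * (F_left + e)/(F_right + e) )
#'     - | log10( (R_right + e)/(F_left + e) ) |
#'
#' The first term peaks when reverse-strand signal sits right of G and
#' forward-strand signal left of G; the penalty term shrinks B when the
#' two strands are unbalanced. Positions with B above the threshold are
#' annotated bidirectional. `flip = TRUE` swaps the left/right roles for
#' the mirrored divergent-transcription convention.
#'
#' @param coverage A [stranded_coverage()] of read-start counts.
#' @param chrom Chromosome name (scalar) or vector along `G`.
#' @param G Position(s) scored (e.g. intergenic lncRNA TSSs).
#' @param w Window size in bp (default 100).
#' @param l Window count (default 7), so each flank spans w*(l-1) bp.
#' @param epsilon Dummy count (default 1).
#' @param threshold Bidirectional annotation threshold on B (default 0.5).
#' @param flip Swap left/right window roles.
#' @return A tibble with one row per position: `chrom`, `G`, `F_left`,
#'   `F_right`, `R_left`, `R_right`, `B`, `bidirectional`.
#' @export
bidirectionality_score <- function(coverage, chrom, G, w = 100, l = 7,
                                   epsilon = 1, threshold = 0.5,
                                   flip = FALSE) {
  stopifnot(w >= 1, l >= 2, epsilon > 0)
  chrom <- rep_len(chrom, length(G))
  rows <- map(seq_along(G), function(i) {
    g <- G[i]
    lw <- c(g - w * l, g - w)
    rw <- c(g + w, g + w * l)
    cnt <- function(win, strand) {
      count_read_starts(coverage, chrom[i], win[1], win[2], strand)
    }
    wc <- tibble(F_left = cnt(lw, "+"), F_right = cnt(rw, "+"),
                 R_left = cnt(lw, "-"), R_right = cnt(rw, "-"))
    if (flip) {
      wc <- tibble(F_left = wc$F_right, F_right = wc$F_left,
                   R_left = wc$R_right, R_right = wc$R_left)
    }
    mutate(wc, chrom = chrom[i], G = g, .before = 1)
  })
  out <- list_rbind(rows) |>
    mutate(B = log10((.data$R_right + epsilon) / (.data$R_left + epsilon) *
                     (.data$F_left + epsilon) / (.data$F_right + epsilon)) -
             abs(log10((.data$R_right + epsilon) / (.data$F_left + epsilon))),
           bidirectional = .data$B > threshold)
  out
}

#' Permutation null for peak/window overlap enrichment
#'
#' The observed statistic is the fraction of peaks overlapping any target
#' window. Each of `n_perm` permutations redraws, per chromosome, the same
#' number of intervals with the same lengths at uniformly random starts,
#' and recomputes the same fraction; the empirical p-value is
#' (1 + #\{null >= observed\}) / (n_perm + 1).
#'
#' @param peaks Observed peak tibble (`chrom`, `start`, `end`).
#' @param windows Target window tibble (`chrom`, `start`, `end`).
#' @param genome A [genome_model()].
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (identical seeds give identical null vectors).
#' @return A list of class `lnc_perm`: `observed`, `null` (numeric vector
#'   length `n_perm`), `p`, `n_perm`, `n_peaks`.
#' @export
permutation_overlap_test <- function(peaks, windows, genome, n_perm = 1000,
                                     seed = 1) {
  peaks <- as_tibble(peaks)
  len <- setNames(genome$chrom_sizes$length, genome$chrom_sizes$chrom)
  widths <- peaks$end - peaks$start
  if (any(widths > len[peaks$chrom])) {
    abort("peak longer than its chromosome")
  }
  win_gr <- GenomicRanges::reduce(as_granges(windows[c("chrom", "start", "end")]))
  frac_overlap <- function(p) {
    mean(suppressWarnings(IRanges::overlapsAny(as_granges(p), win_gr)))
  }
  observed <- frac_overlap(peaks)
  max_start <- len[peaks$chrom] - widths
  null <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b) {
    starts <- as.integer(floor(runif(nrow(peaks)) * (max_start + 1)))
    frac_overlap(tibble(chrom = peaks$chrom, start = starts,
                        end = starts + widths))
  }, numeric(1)))
  p <- (1 + sum(null >= observed)) / (n_perm + 1)
  structure(list(observed = observed, null = null, p = p, n_perm = n_perm,
                 n_peaks = nrow(peaks)),
            class = "lnc_perm")
}

#' @export
print.lnc_perm <- function(x, ...) {
  cat("<lnc_perm> observed overlap fraction ", format(x$observed, digits = 4),
      "; null median ", format(median(x$null), digits = 4),
      "; p = ", format(x$p, digits = 4), " (", x$n_perm, " permutations)\n",
      sep = "")
  invisible(x)
}

#' Folded empirical CDFs and rank-sum comparison of two samples
#'
#' Each sample's empirical CDF F is folded around the median as
#' min(F, 1 - F), which peaks at 0.5 at the median and eases visual
#' comparison of spread/location; the two samples are compared with a
#' two-sided Wilcoxon rank-sum test (mid-ranks for ties).
#'
#' @param values_a,values_b Numeric vectors (non-empty).
#' @param labels Length-2 character labels for the two samples.
#' @return A list of class `lnc_folded`: `curves` (tibble `group`, `x`,
#'   `F`, `folded`) and `p` (rank-sum p-value).
#' @export
folded_cdf <- function(values_a, values_b, labels = c("a", "b")) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    abort("both samples must be non-empty")
  }
  fold <- function(v, lab) {
    x <- sort(v)
    Fx <- ecdf(v)(x)
    tibble(group = lab, x = x, F = Fx, folded = pmin(Fx, 1 - Fx))
  }
  p <- suppressWarnings(wilcox.test(values_a, values_b, exact = FALSE,
                                    correct = TRUE)$p.value)
  structure(list(curves = bind_rows(fold(values_a, labels[1]),
                                    fold(values_b, labels[2])),
                 p = p),
            class = "lnc_folded")
}
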