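# shared fixtures, memoised so expensive synthetic runs happen once per
# test session

.fixtures <- new.env(parent = emptyenv())

small_config <- function(seed = 11) {
  synthetic_config(n_chroms = 2, chrom_length = 3e6, n_coding_genes = 40,
                   n_lncrna_candidates = 400, n_ernas = 8, n_enhancers = 25,
                   n_super_enhancers = 3, n_high_tau = 20, n_circ_ig = 15,
                   n_circ_other = 12, n_circ_subthreshold = 5, seed = seed)
}

get_small_atlas <- function() {
  if (is.null(.fixtures$atlas)) .fixtures$atlas <- simulate_atlas(small_config())
  .fixtures$atlas
}

# small atlas pushed through normalization + the discovery cascade
get_small_discovery <- function() {
  if (is.null(.fixtures$disc)) {
    atlas <- get_small_atlas()
    sf <- size_factors(atlas$counts)
    tpm <- tpm_normalize(atlas$counts, atlas$lengths, sf)
    scores <- summarise_coding_scores(atlas$orf_scores)
    flt <- filter_novel_lncrnas(atlas$candidates, tpm, atlas$genome$repeats,
                                scores, atlas$coding)
    .fixtures$disc <- list(atlas = atlas, tpm = tpm, filter = flt)
  }
  .fixtures$disc
}

# one full default-scale pipeline run shared by the acceptance checks
get_default_run <- function() {
  if (is.null(.fixtures$run)) {
    .fixtures$run <- run_atlas(synthetic_config(seed = 101),
                               out_dir = file.path(tempdir(), "lncatlas_acc"))
  }
  .fixtures$run
}

# ---------------------------------------------------------------------------
# independent oracles

# per-base repeat-overlap fraction (brute force over every exon base)
brute_repeat_fraction <- function(catalog, repeats) {
  vapply(seq_len(nrow(catalog)), function(i) {
    ex <- catalog$exons[[i]]
    bases <- unlist(lapply(seq_len(nrow(ex)), function(k) {
      seq(ex[k, "start"], ex[k, "end"] - 1L)
    }))
    rep_i <- repeats[repeats$chrom == catalog$chrom[i], ]
    hit <- vapply(bases, function(b) {
      any(b >= rep_i$start & b < rep_i$end)
    }, logical(1))
    mean(hit)
  }, numeric(1))
}

# per-base transcribed-fraction accounting with category precedence
brute_transcribed <- function(catalogs, genome) {
  sizes <- genome$chrom_sizes
  assign_chrom <- lapply(seq_len(nrow(sizes)), function(i) {
    character(sizes$length[i])
  })
  names(assign_chrom) <- sizes$chrom
  for (name in names(catalogs)) {
    ex <- catalog_exons(catalogs[[name]])
    for (k in seq_len(nrow(ex))) {
      idx <- (ex$start[k] + 1L):ex$end[k]
      cur <- assign_chrom[[ex$chrom[k]]][idx]
      assign_chrom[[ex$chrom[k]]][idx] <- ifelse(cur == "", name, cur)
    }
  }
  all_bases <- unlist(assign_chrom)
  total <- length(all_bases)
  out <- vapply(names(catalogs), function(n) sum(all_bases == n), numeric(1))
  c(out, total = sum(out)) / total
}

# per-base GREAT regulatory-domain construction: walk outward from each
# basal region until another basal, the extension cap, or the chrom edge
brute_domains <- function(genes, chrom_len, basal_up = 5000,
                          basal_down = 1000, max_extension = 1e6) {
  basal <- t(vapply(seq_len(nrow(genes)), function(i) {
    tss <- genes$tss[i]
    if (genes$strand[i] == "+") {
      c(max(0, tss - basal_up), min(chrom_len, tss + basal_down))
    } else {
      c(max(0, tss - basal_down), min(chrom_len, tss + basal_up))
    }
  }, numeric(2)))
  in_other_basal <- function(pos, i) {
    any(pos >= basal[-i, 1] & pos < basal[-i, 2])
  }
  t(vapply(seq_len(nrow(genes)), function(i) {
    lo <- basal[i, 1]
    while (lo - 1 >= 0 && lo - 1 >= basal[i, 1] - max_extension &&
           !in_other_basal(lo - 1, i)) {
      lo <- lo - 1
    }
    hi <- basal[i, 2]
    while (hi < chrom_len && hi < basal[i, 2] + max_extension &&
           !in_other_basal(hi, i)) {
      hi <- hi + 1
    }
    c(start = lo, end = hi)
  }, numeric(2)))
}

# exact hypergeometric upper-tail by term-wise summation
brute_hyper_tail <- function(k, K, N, n) {
  sum(vapply(k:min(K, n), function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1)))
}

# least-squares branch lengths for each of the 3 unrooted 4-leaf topologies;
# returns the best topology as the pair grouped with leaf 1
brute_nj4 <- function(d) {
  stopifnot(nrow(d) == 4)
  topos <- list(c(1, 2), c(1, 3), c(1, 4))
  fit <- lapply(topos, function(pair) {
    others <- setdiff(1:4, pair)
    ord <- c(pair, others)   # leaves a,b | c,d
    dd <- d[ord, ord]
    # distances: ab=a+b, cd=c+d, ac=a+i+c, ad=a+i+d, bc=b+i+c, bd=b+i+d
    A <- rbind(c(1, 1, 0, 0, 0),
               c(0, 0, 1, 1, 0),
               c(1, 0, 1, 0, 1),
               c(1, 0, 0, 1, 1),
               c(0, 1, 1, 0, 1),
               c(0, 1, 0, 1, 1))
    y <- c(dd[1, 2], dd[3, 4], dd[1, 3], dd[1, 4], dd[2, 3], dd[2, 4])
    beta <- qr.solve(A, y)
    rss <- sum((A %*% beta - y)^2)
    list(pair = pair, beta = beta, rss = rss)
  })
  fit[[which.min(vapply(fit, function(f) f$rss, numeric(1)))]]
}

# a stranded-coverage object realising given window counts around G with
# the default bidirectionality geometry (w = 100, l = 7)
coverage_from_counts <- function(G, F_left, F_right, R_left, R_right,
                                 chrom = "chrT") {
  seg <- function(pos, value) {
    tibble::tibble(chrom = chrom, start = pos, end = pos + 1L, value = value)
  }
  mk <- function(left, right) {
    rows <- dplyr::bind_rows(
      if (left > 0) seg(G - 400L, left),
      if (right > 0) seg(G + 400L, right))
    if (nrow(rows) == 0) {
      rows <- tibble::tibble(chrom = character(), start = integer(),
                             end = integer(), value = numeric())
    }
    signal_track(rows)
  }
  stranded_coverage(mk(F_left, F_right), mk(R_left, R_right))
}

# adjusted Rand index oracle (mclust's reference implementation)
ari_oracle <- function(a, b) mclust::adjustedRandIndex(a, b)
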