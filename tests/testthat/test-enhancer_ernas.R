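test_that("enhancer calls apply the TSS-distance and H3K27ac rules", {
  tss <- tibble::tibble(chrom = "chr1", tss = 30000)
  k4 <- tibble::tibble(chrom = "chr1", start = 10000L, end = 11000L)
  k27 <- tibble::tibble(chrom = "chr1", start = 10200L, end = 10300L)
  expect_equal(call_enhancers(k4, k27, tss)$class, "active")
  none <- k27[0, ]
  expect_equal(call_enhancers(k4, none, tss)$class, "poised")
  # peak edge 2400 bp from a TSS is excluded; exactly 2500 is kept
  near <- tibble::tibble(chrom = "chr1", start = 25000L, end = 27600L)
  expect_equal(nrow(call_enhancers(near, none, tss)), 0)
  edge <- tibble::tibble(chrom = "chr1", start = 25000L, end = 27500L)
  expect_equal(nrow(call_enhancers(edge, none, tss)), 1)
  # active + poised partition the retained peaks
  atlas <- get_small_atlas()
  coding_tss <- dplyr::distinct(atlas$coding, chrom, tss)
  calls <- call_enhancers(atlas$peaks$H3K4me1, atlas$peaks$H3K27ac,
                          coding_tss)
  expect_equal(sum(calls$class == "active") + sum(calls$class == "poised"),
               nrow(calls))
})

test_that("super-enhancer cutoff follows the scaled rank-signal slope rule", {
  # ten isolated regions with the derived toy signals: SEs are 20 and 50
  pk <- tibble::tibble(chrom = "chr1",
                       start = seq(0L, by = 100000L, length.out = 10),
                       end = seq(1000L, by = 100000L, length.out = 10),
                       signal = c(1, 1, 1, 1, 1, 1, 2, 5, 20, 50))
  se <- call_super_enhancers(pk)
  expect_equal(sort(se$regions$total_signal[se$regions$is_se]), c(20, 50))
  expect_equal(se$cutoff, 20)

  flat <- dplyr::mutate(pk, signal = 3)
  expect_equal(sum(call_super_enhancers(flat)$regions$is_se), 0)

  # stitching boundary: 12,400 bp gap merges, 12,600 bp gap does not
  two <- tibble::tibble(chrom = "chr1", start = c(0L, 13400L),
                        end = c(1000L, 14400L), signal = c(5, 5))
  pad <- tibble::tibble(chrom = "chr2",
                        start = c(0L, 100000L), end = c(1000L, 101000L),
                        signal = c(1, 2))
  expect_equal(nrow(call_super_enhancers(
    dplyr::bind_rows(two, pad))$regions), 3)
  two$start[2] <- 13600L; two$end[2] <- 14600L
  expect_equal(nrow(call_super_enhancers(
    dplyr::bind_rows(two, pad))$regions), 4)
  expect_error(call_super_enhancers(pk[1:2, ]), "fewer than 3")
})

test_that("slope-1 scan matches the analytic tangent on convex curves", {
  withr::with_seed(10, {
    for (i in 1:10) {
      n <- sample(30:80, 1)
      b <- runif(1, 3, 6)
      y <- exp(b * (seq_len(n) - 1) / (n - 1))   # strictly convex
      pk <- tibble::tibble(chrom = "chr1",
                           start = seq(0L, by = 100000L, length.out = n),
                           end = seq(1000L, by = 100000L, length.out = n),
                           signal = sample(y))
      se <- call_super_enhancers(pk)
      found_rank <- min(se$regions$rank[se$regions$is_se])
      # analytic x* where d(ys)/d(xs) = 1 for ys = (e^{bx} - 1)/(e^b - 1)
      x_star <- log((exp(b) - 1) / b) / b
      expect_lte(abs((found_rank - 1) / (n - 1) - x_star), 2 / (n - 1))
    }
  })
})

test_that("eRNA calls require single-exon intergenic lncRNAs near enhancers", {
  ids <- c("e1", "two_exon", "two_exon", "near_tss", "far")
  lnc <- transcript_catalog(tibble::tibble(
    transcript_id = ids, gene_id = ids, chrom = "chr1", strand = "+",
    start = c(5000, 5000, 5400, 31800, 200000),
    end = c(5600, 5200, 5600, 32400, 200600)))
  lnc$position_class <- "intergenic"
  enh <- tibble::tibble(chrom = "chr1", start = c(4500L, 31000L),
                        end = c(4800L, 33000L), class = c("active", "poised"))
  tss <- tibble::tibble(chrom = "chr1", tss = 30000)
  out <- call_ernas(lnc, enh, tss)
  expect_equal(out$ernas$transcript_id, "e1")   # window [4000,6001) hits peak
  expect_false("two_exon" %in% out$eligible)    # multi-exon ineligible
  expect_false("near_tss" %in% out$eligible)    # 1800 bp from coding TSS
  expect_true("far" %in% out$eligible)          # eligible but no enhancer
  fr <- out$fractions
  expect_equal(fr$fraction[fr$class == "active"], 1)
  expect_equal(fr$fraction[fr$class == "poised"], 0)
  expect_error(call_ernas(dplyr::select(lnc, -position_class), enh, tss),
               "position_class")
})

test_that("bidirectionality score reproduces the worked arithmetic", {
  g <- 10000L
  sym <- coverage_from_counts(g, 50, 50, 50, 50)
  expect_equal(bidirectionality_score(sym, "chrT", g)$B, 0)
  expect_false(bidirectionality_score(sym, "chrT", g)$bidirectional)

  perfect <- coverage_from_counts(g, 100, 0, 0, 100)
  b1 <- bidirectionality_score(perfect, "chrT", g)
  expect_equal(b1$B, 2 * log10(101), tolerance = 1e-12)
  expect_true(b1$bidirectional)
  expect_equal(unlist(b1[c("F_left", "F_right", "R_left", "R_right")]),
               c(F_left = 100, F_right = 0, R_left = 0, R_right = 100))

  uneven <- coverage_from_counts(g, 100, 0, 0, 10)
  b2 <- bidirectionality_score(uneven, "chrT", g)
  expect_equal(b2$B, log10(11 * 101) - abs(log10(11 / 101)),
               tolerance = 1e-12)
  expect_equal(b2$B, 2.082785, tolerance = 1e-5)
})

test_that("window geometry is [G-700,G-100) and [G+100,G+700) at defaults", {
  g <- 10000L
  seg <- function(pos) tibble::tibble(chrom = "chrT", start = pos,
                                      end = pos + 1L, value = 1)
  plus <- signal_track(dplyr::bind_rows(seg(g - 700L), seg(g - 101L),
                                        seg(g - 100L), seg(g - 701L)))
  minus <- signal_track(dplyr::bind_rows(seg(g + 100L), seg(g + 699L),
                                         seg(g + 700L), seg(g + 99L)))
  sc <- bidirectionality_score(stranded_coverage(plus, minus), "chrT", g)
  expect_equal(sc$F_left, 2)    # G-700 and G-101 in; G-701, G-100 out
  expect_equal(sc$R_right, 2)   # G+100 and G+699 in; G+99, G+700 out
})

test_that("B is antisymmetric in its first term and penalty-bounded", {
  withr::with_seed(11, {
    g <- 10000L
    first_term <- function(fl, fr, rl, rr, e = 1) {
      log10((rr + e) / (rl + e) * (fl + e) / (fr + e))
    }
    for (i in 1:20) {
      cnt <- sample(0:200, 4)
      b <- bidirectionality_score(
        coverage_from_counts(g, cnt[1], cnt[2], cnt[3], cnt[4]), "chrT", g)$B
      ft <- first_term(cnt[1], cnt[2], cnt[3], cnt[4])
      ft_swap <- first_term(cnt[2], cnt[1], cnt[4], cnt[3])
      expect_equal(ft_swap, -ft)
      expect_lte(b, ft + 1e-12)
      # scaling all counts by 10 with epsilon fixed approaches the
      # epsilon-free limit monotonically
      pos <- cnt + 1
      b_inf <- log10(pos[4] / pos[3] * pos[1] / pos[2]) -
        abs(log10(pos[4] / pos[1]))
      devs <- vapply(c(1, 10, 100), function(k) {
        abs(bidirectionality_score(
          coverage_from_counts(g, pos[1] * k, pos[2] * k, pos[3] * k,
                               pos[4] * k), "chrT", g)$B - b_inf)
      }, numeric(1))
      expect_true(all(diff(devs) <= 1e-9))
    }
  })
})

test_that("orientation flip swaps the window roles", {
  g <- 10000L
  cov <- coverage_from_counts(g, 0, 100, 100, 0)  # mirrored configuration
  expect_lte(bidirectionality_score(cov, "chrT", g)$B, 0)
  expect_equal(bidirectionality_score(cov, "chrT", g, flip = TRUE)$B,
               2 * log10(101), tolerance = 1e-12)
})

test_that("permutation nulls are seeded, calibrated, and floored", {
  gm <- genome_model(c(chr1 = 1e6L))
  win <- tibble::tibble(chrom = "chr1", start = 200000L, end = 400000L)
  withr::with_seed(13, {
    starts <- sample(0:999000, 150) * 1L
  })
  peaks <- tibble::tibble(chrom = "chr1", start = starts, end = starts + 1000L)
  p1 <- permutation_overlap_test(peaks, win, gm, n_perm = 400, seed = 9)
  p2 <- permutation_overlap_test(peaks, win, gm, n_perm = 400, seed = 9)
  expect_identical(p1$null, p2$null)

  # analytic overlap probability for width-1000 peaks vs one window
  expected <- (min(1e6 - 1000, 400000 - 1) - max(0, 200000 - 1000 + 1) + 1) /
    (1e6 - 1000 + 1)
  se <- sd(p1$null) / sqrt(p1$n_perm)
  expect_lt(abs(mean(p1$null) - expected), 3 * se + 1e-3)

  # windows tiling the genome: every null fraction 1, p = 1
  tile <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000000L)
  pt <- permutation_overlap_test(peaks, tile, gm, n_perm = 100, seed = 1)
  expect_true(all(pt$null == 1))
  expect_equal(pt$p, 1)

  # observed above every null: p at the 1/(n+1) floor
  clust <- tibble::tibble(chrom = "chr1",
                          start = seq(200000L, 399000L, by = 2000L))
  clust$end <- clust$start + 500L
  pf <- permutation_overlap_test(clust, win, gm, n_perm = 200, seed = 2)
  expect_equal(pf$p, 1 / 201)
  expect_error(permutation_overlap_test(
    tibble::tibble(chrom = "chr1", start = 0L, end = 2e6L), win, gm),
    "longer than")
})

test_that("folded CDFs peak at the median and rank-sum flags shifts", {
  withr::with_seed(14, {
    a <- rnorm(100)
    f <- folded_cdf(a, a + 50)
  })
  expect_equal(max(f$curves$folded), 0.5)
  med_x <- f$curves$x[which.max(f$curves$folded)]
  expect_lt(abs(med_x - median(a)), 0.5)
  expect_lt(f$p, 1e-6)

  same <- folded_cdf(rep(1:10, 4), rep(1:10, 4))
  expect_gte(same$p, 0.99)
  expect_error(folded_cdf(numeric(), 1:3), "non-empty")
})

test_that("planted enhancers, eRNAs and bidirectional loci are recovered", {
  atlas <- get_small_atlas()
  disc <- get_small_discovery()
  coding_tss <- dplyr::distinct(atlas$coding, chrom, tss)
  calls <- call_enhancers(atlas$peaks$H3K4me1, atlas$peaks$H3K27ac,
                          coding_tss)
  truth_enh <- atlas$truth$chromatin$enhancers
  expect_equal(nrow(calls), nrow(truth_enh))
  j <- dplyr::inner_join(calls, truth_enh, by = c("chrom", "start", "end"))
  expect_equal(nrow(j), nrow(truth_enh))
  expect_true(all(j$class.x == j$class.y))

  se <- call_super_enhancers(atlas$peaks$H3K27ac)
  expect_equal(sum(se$regions$is_se), atlas$config$n_super_enhancers)

  ernas <- call_ernas(disc$filter$catalog, calls, coding_tss, se = se)
  truth_ids <- atlas$truth$transcripts$transcript_id[
    atlas$truth$transcripts$erna]
  called_ids <- ernas$ernas$transcript_id
  expect_gte(mean(called_ids %in% truth_ids), 0.95)  # precision
  expect_gte(mean(truth_ids %in% called_ids), 0.95)  # recall
  # super-enhancer transcription matches the planted with/without split
  fr <- ernas$fractions
  se_truth <- atlas$truth$chromatin$se_areas
  expect_equal(fr$n_transcribed[fr$class == "se_region"],
               sum(se_truth$with_erna))
})
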