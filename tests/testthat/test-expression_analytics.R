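test_that("median-of-ratios size factors match the worked cases", {
  m <- matrix(c(5, 9, 13, 5, 9, 13), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- matrix(c(2, 2, 8, 8), ncol = 2,
               dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_equal(unname(size_factors(m2)), c(0.5, 2))

  single <- matrix(1:3, ncol = 1, dimnames = list(letters[1:3], "s1"))
  expect_equal(unname(size_factors(single)), 1)

  zero <- matrix(c(0, 1, 1, 0), 2)
  expect_error(size_factors(zero), "positive counts")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  withr::with_seed(9, {
    # odd gene count: the reference's exp-median-log equals median-of-ratios
    m <- matrix(rnbinom(606, mu = 100, size = 5) + 1, nrow = 101)
    dimnames(m) <- list(sprintf("g%03d", 1:101), paste0("s", 1:6))
    expect_equal(unname(size_factors(m)),
                 unname(DESeq2::estimateSizeFactorsForMatrix(m)),
                 tolerance = 1e-10)
  })
})

test_that("TPM conversion conserves column totals of one million", {
  one <- matrix(7, 1, 1, dimnames = list("g", "s"))
  expect_equal(unname(tpm_normalize(one, c(g = 500))[1, 1]), 1e6)

  m <- matrix(c(10, 40), 2, 1, dimnames = list(c("a", "b"), "s"))
  got <- tpm_normalize(m, c(a = 1000, b = 2000))
  expect_equal(unname(got[, 1]), c(1e6 / 3, 2e6 / 3), tolerance = 1e-9)
  # scale invariance
  expect_equal(tpm_normalize(m * 2, c(a = 1000, b = 2000)), got)

  withr::with_seed(2, {
    counts <- matrix(rpois(500, 40), 50,
                     dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:10)))
    lens <- stats::setNames(sample(200:3000, 50), rownames(counts))
    tpm <- tpm_normalize(counts, lens, size_factors(counts))
    expect_true(all(abs(colSums(tpm) - 1e6) / 1e6 < 1e-6))
  })
  expect_error(tpm_normalize(m, c(a = 1000, b = 0)), "positive length")
})

test_that("differential expression applies the atlas thresholds", {
  de <- generate_de_counts(n_genes = 300, de_fraction = 0.2, seed = 4)
  tpm <- tpm_normalize(de$counts, de$lengths)
  res <- differential_expression(tpm, de$samples, "A", "B")
  expect_s3_class(res, "lnc_de")
  expect_true(all(res$significant ==
                  (abs(res$log2FC) >= 1.5 & res$q < 0.01)))
  # q monotone in p
  ord <- order(res$p)
  expect_true(all(diff(res$q[ord]) >= -1e-12))
  # constant gene: log2FC 0, not significant
  tpm2 <- tpm
  tpm2[1, ] <- 100
  res2 <- differential_expression(tpm2, de$samples, "A", "B")
  expect_equal(res2$log2FC[1], 0)
  expect_false(res2$significant[1])

  bad <- de$samples[de$samples$sample != "A_1", ]
  expect_error(differential_expression(tpm[, bad$sample], bad, "A", "B"),
               NA)
  one <- de$samples[de$samples$sample %in% c("A_1", "B_1", "B_2"), ]
  expect_error(differential_expression(tpm[, one$sample], one, "A", "B"),
               "at least 2 samples")
})

test_that("tau matches the analytic cases and is monotone under sharpening", {
  smp <- tibble::tibble(sample = paste0("s", 1:6),
                        cell_type = paste0("ct", 1:6))
  m <- rbind(flat = c(5, 5, 5, 5, 5, 5),
             solo = c(10, 0, 0, 0, 0, 0),
             mixed = c(10, 5, 0, 0, 0, 0),
             zero = rep(0, 6))
  colnames(m) <- smp$sample
  tau <- tau_index(m, smp)
  expect_equal(tau$tau[match(c("flat", "solo", "mixed"), tau$gene)],
               c(0, 1, 0.9))
  expect_true(is.na(tau$tau[tau$gene == "zero"]))
  expect_error(tau_index(m, dplyr::mutate(smp, cell_type = "one")),
               "at least 2")

  # moving mass toward the max cell type never decreases tau
  withr::with_seed(3, {
    for (i in 1:20) {
      v <- sort(runif(6, 0, 10), decreasing = TRUE)
      sharpen <- v
      take <- sharpen[4] * 0.5
      sharpen[4] <- sharpen[4] - take
      sharpen[1] <- sharpen[1] + take
      mm <- rbind(a = v, b = sharpen)
      colnames(mm) <- smp$sample
      tt <- tau_index(mm, smp)
      expect_gte(tt$tau[tt$gene == "b"], tt$tau[tt$gene == "a"])
    }
  })
})

test_that("trajectory k-means recovers planted archetypes and is seeded", {
  types <- c("NB", "CB", "CC", "MEM", "TPC", "BMPC")
  smp <- tidyr::expand_grid(cell_type = types, rep = 1:3) |>
    dplyr::mutate(sample = paste0(cell_type, "_", rep))
  arch <- trajectory_archetypes(types)[c(1, 4, 6), ]
  withr::with_seed(8, {
    genes <- 60
    truth <- rep(1:3, each = genes / 3)
    base <- runif(genes, 50, 150)
    mu <- base * arch[truth, ]
    tpm <- mu[, smp$cell_type] * matrix(runif(genes * nrow(smp), 0.95, 1.05),
                                        genes)
    colnames(tpm) <- smp$sample
    rownames(tpm) <- sprintf("g%02d", 1:genes)
  })
  tc <- trajectory_clusters(tpm, smp, k = 3, seed = 2)
  expect_equal(ari_oracle(tc$clusters$cluster, truth), 1)
  tc2 <- trajectory_clusters(tpm, smp, k = 3, seed = 2)
  expect_identical(tc$clusters, tc2$clusters)
  # duplicated rows land in one cluster
  dup <- tpm
  dup[2, ] <- dup[1, ]
  td <- trajectory_clusters(dup, smp, k = 3, seed = 2)
  expect_equal(td$clusters$cluster[1], td$clusters$cluster[2])
  expect_error(trajectory_clusters(tpm[1:2, ], smp, k = 5, seed = 1), "k ")
})

test_that("PCA selects the top variable genes and separates planted groups", {
  withr::with_seed(5, {
    n <- 1000
    smp <- tibble::tibble(sample = paste0("s", 1:8),
                          cell_type = rep(c("X", "Y"), each = 4))
    mu <- matrix(100, n, 8, dimnames = list(sprintf("g%04d", 1:n),
                                            smp$sample))
    mu[1:50, smp$cell_type == "Y"] <- 400
    tpm <- mu * matrix(runif(n * 8, 0.9, 1.1), n)
  })
  pc <- pca_embedding(tpm, smp)
  expect_equal(pc$n_genes, 100)  # exactly 10% of 1000
  s1 <- pc$scores$PC1[pc$scores$cell_type == "X"]
  s2 <- pc$scores$PC1[pc$scores$cell_type == "Y"]
  expect_true(all(sign(s1) == sign(s1[1])) && all(sign(s2) == -sign(s1[1])))
  expect_lte(sum(pc$var_explained), 1 + 1e-9)
  expect_error(pca_embedding(tpm[, 1, drop = FALSE]), "2 samples")
})

test_that("neighbor joining recovers the 4-leaf additive worked example", {
  d <- matrix(c(0, 5, 4, 5,
                5, 0, 7, 8,
                4, 7, 0, 5,
                5, 8, 5, 0), 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  # the least-squares enumeration oracle picks the same split
  oracle <- brute_nj4(d)
  expect_equal(sort(LETTERS[oracle$pair]), c("A", "B"))
  split_ab <- ape::prop.part(tr)
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  # branch lengths: A=1, B=4, C=2, D=3, internal=1
  cp <- cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(cp, d, tolerance = 1e-12)
  tip_edge <- tr$edge.length[match(match(LETTERS[1:4], tr$tip.label),
                                   tr$edge[, 2])]
  expect_equal(tip_edge, c(1, 4, 2, 3))
  expect_equal(oracle$beta, c(1, 4, 2, 3, 1), tolerance = 1e-12)
})

test_that("NJ reconstructs additive distances from random trees", {
  withr::with_seed(77, {
    for (i in 1:100) {
      n <- sample(4:6, 1)
      true_tree <- ape::rtree(n, br = function(k) runif(k, 0.5, 3))
      d <- cophenetic(true_tree)
      tr <- nj_tree(d)
      cp <- cophenetic(tr)[rownames(d), colnames(d)]
      expect_lt(max(abs(cp - d)), 1e-9)
    }
  })
})

test_that("group phylogeny uses median cross-group distances and bootstraps", {
  disc <- get_small_discovery()
  atlas <- disc$atlas
  ph <- group_phylogeny(disc$tpm, atlas$samples, n_boot = 50, seed = 3)
  expect_setequal(ph$tree$tip.label, atlas$config$cell_types)
  expect_true(all(ph$support >= 0 & ph$support <= 100))
  expect_true(all(ph$tree$edge.length >= 0))
  # plasma-cell populations are planted as sisters
  expect_true(ape::is.monophyletic(ape::root(ph$tree, "NB"),
                                   c("TPC", "BMPC")))
  pc_node <- ape::getMRCA(ape::root(ph$tree, "NB"), c("TPC", "BMPC"))
  expect_error(group_phylogeny(disc$tpm, atlas$samples, metric = "cosine"),
               "arg")

  # three cell types: unique topology, full support
  smp3 <- atlas$samples[atlas$samples$cell_type %in% c("NB", "CB", "TPC"), ]
  ph3 <- group_phylogeny(disc$tpm[, smp3$sample], smp3, n_boot = 20, seed = 1)
  expect_equal(unname(ph3$support), 100)
})

test_that("pearson and euclidean metrics give trees over the same leaves", {
  disc <- get_small_discovery()
  ph <- group_phylogeny(disc$tpm, disc$atlas$samples,
                        metric = "pearson", n_boot = 10, seed = 5)
  expect_setequal(ph$tree$tip.label, disc$atlas$config$cell_types)
})

test_that("Ig read fractions are computed per sample and class", {
  cat_toy <- transcript_catalog(tibble::tibble(
    transcript_id = c("ig.t1", "x.t1"), gene_id = c("ig", "x"),
    chrom = "chr1", strand = "+", start = c(100, 5000), end = c(400, 5400),
    biotype = "coding"))
  ig_loci <- tibble::tibble(chrom = "chr1", start = 0L, end = 1000L)
  counts <- matrix(c(90, 10), 2, 1, dimnames = list(c("ig", "x"), "s1"))
  got <- ig_read_fraction(counts, cat_toy, ig_loci)
  expect_equal(got$ig_fraction, 0.9)
  far <- tibble::tibble(chrom = "chr1", start = 9000L, end = 9500L)
  expect_equal(ig_read_fraction(counts, cat_toy, far)$ig_fraction, 0)
  expect_error(ig_read_fraction(counts, cat_toy, ig_loci, biotypes = "nope"),
               "no genes")

  atlas <- get_small_atlas()
  igf <- ig_read_fraction(atlas$counts, atlas$coding, atlas$genome$ig_loci) |>
    dplyr::left_join(atlas$samples, by = "sample")
  pc <- igf$ig_fraction[igf$cell_type %in% c("TPC", "BMPC")]
  nb <- igf$ig_fraction[igf$cell_type == "NB"]
  expect_gt(min(pc), max(nb))
})
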