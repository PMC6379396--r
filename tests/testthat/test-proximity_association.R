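mk_genes <- function(gene_id, chrom, strand, tss) {
  # one-exon genes whose TSS sits at the requested position
  strand <- rep(strand, length.out = length(tss))
  start <- ifelse(strand == "+", tss, tss - 500)
  transcript_catalog(tibble::tibble(
    transcript_id = paste0(gene_id, ".t1"), gene_id = gene_id,
    chrom = chrom, strand = strand, start = start, end = start + 500,
    biotype = "coding"))
}

test_that("regulatory domains follow the basal-plus-extension rule", {
  gm <- genome_model(c(chr1 = 2e6L))
  genes <- mk_genes(c("g1", "g2"), "chr1", "+", c(10000, 50000))
  dom <- regulatory_domains(genes, gm)
  d1 <- dom[dom$gene_id == "g1", ]
  d2 <- dom[dom$gene_id == "g2", ]
  expect_equal(c(d1$basal_start, d1$basal_end), c(5000, 11000))
  expect_equal(c(d1$start, d1$end), c(0, 45000))
  expect_equal(c(d2$start, d2$end), c(11000, 1051000))

  # single gene mid-chromosome: basal +- max extension, clipped
  solo <- regulatory_domains(mk_genes("g", "chr1", "+", 1e6), gm)
  expect_equal(c(solo$start, solo$end), c(0, 2e6))
  big <- genome_model(c(chr1 = 5e6L))
  solo2 <- regulatory_domains(mk_genes("g", "chr1", "+", 2.5e6), big)
  expect_equal(c(solo2$start, solo2$end),
               c(2.5e6 - 5000 - 1e6, 2.5e6 + 1000 + 1e6))

  # overlapping basal regions stay intact; extensions meet at basal edges
  near <- regulatory_domains(mk_genes(c("a", "b"), "chr1", "+",
                                      c(10000, 13000)), gm)
  da <- near[near$gene_id == "a", ]
  db <- near[near$gene_id == "b", ]
  expect_equal(c(da$basal_start, da$basal_end), c(5000, 11000))
  expect_equal(c(db$basal_start, db$basal_end), c(8000, 14000))
  expect_equal(da$end, da$basal_end)   # no right extension into b's basal
  expect_equal(db$start, db$basal_start)
})

test_that("domain construction equals the per-base brute force", {
  for (s in 1:3) {
    withr::with_seed(s, {
      gm <- genome_model(c(chr1 = 100000L))
      tss <- sort(sample(seq(8000, 92000, by = 500), 6))
      strand <- sample(c("+", "-"), 6, replace = TRUE)
      genes <- mk_genes(sprintf("g%d", 1:6), "chr1", strand, tss)
      dom <- regulatory_domains(genes, gm, max_extension = 20000)
      spans <- genes |>
        dplyr::group_by(gene_id) |>
        dplyr::summarise(chrom = chrom[1], strand = strand[1],
                         tss = ifelse(strand[1] == "+", min(start), max(end)))
      oracle <- brute_domains(spans[match(dom$gene_id, spans$gene_id), ],
                              100000, max_extension = 20000)
      expect_equal(dom$start, unname(oracle[, "start"]))
      expect_equal(dom$end, unname(oracle[, "end"]))
    })
  }
})

test_that("lncRNA-gene association is many-to-many by domain intersection", {
  gm <- genome_model(c(chr1 = 2e6L))
  genes <- mk_genes(c("g1", "g2"), "chr1", "+", c(10000, 50000))
  dom <- regulatory_domains(genes, gm)
  lnc <- transcript_catalog(tibble::tibble(
    transcript_id = c("l_in", "l_straddle", "l_desert"),
    gene_id = c("l_in", "l_straddle", "l_desert"),
    chrom = "chr1", strand = "+",
    start = c(2000, 44000, 1500000), end = c(3000, 46000, 1501000)))
  pairs <- associate_lncrna_genes(lnc, dom)
  # [2000,3000) precedes g2's extension, which stops at g1's basal edge
  expect_equal(pairs$gene_id[pairs$transcript_id == "l_in"], "g1")
  expect_setequal(pairs$gene_id[pairs$transcript_id == "l_straddle"],
                  c("g1", "g2"))
  expect_false("l_desert" %in% pairs$transcript_id)

  # naive O(n*m) re-check of every emitted/omitted pair
  naive <- tidyr::expand_grid(i = seq_len(nrow(lnc)), j = seq_len(nrow(dom)))
  naive$hit <- lnc$start[naive$i] < dom$end[naive$j] &
    lnc$end[naive$i] > dom$start[naive$j]
  naive_pairs <- tibble::tibble(
    transcript_id = lnc$transcript_id[naive$i[naive$hit]],
    gene_id = dom$gene_id[naive$j[naive$hit]])
  expect_setequal(paste(pairs$transcript_id, pairs$gene_id),
                  paste(naive_pairs$transcript_id, naive_pairs$gene_id))
})

test_that("distance profiles bin signed TSS distances around DE anchors", {
  run <- get_small_discovery()
  atlas <- run$atlas
  # anchors injected from planted truth through the external-table
  # interface; lncRNA fold changes are the computed estimates
  coding_de <- tibble::tibble(gene = atlas$truth$de$gene,
                              log2FC = atlas$truth$de$planted_log2fc,
                              p = 0, q = 0, significant = TRUE)
  de <- differential_expression(run$tpm, atlas$samples, "NB", "CB")
  lnc_ids <- run$filter$catalog$transcript_id
  lnc_de <- de[de$gene %in% lnc_ids, ]
  prof <- distance_fc_profile(coding_de, lnc_de, atlas$coding,
                              run$filter$catalog)
  expect_s3_class(prof, "lnc_distance_profile")
  # bins partition [-250k, +250k] for both anchor directions
  expect_equal(nrow(prof), 2 * 20)
  for (dir in c("up", "down")) {
    b <- prof[prof$direction == dir, ]
    expect_equal(min(b$bin_lo), -250000)
    expect_equal(max(b$bin_hi), 250000)
    expect_true(all(diff(sort(b$bin_lo)) == 25000))
  }
  expect_true(all(is.na(prof$mean_lfc[prof$n == 0])))
  # planted co-directional coupling: near-anchor lncRNAs move with the
  # anchor, so near bins are positive for up-anchors, negative for down
  near <- prof[abs(prof$bin_mid) < 75000 & prof$n > 0, ]
  near_mean <- tapply(near$mean_lfc * near$n, near$direction, sum) /
    tapply(near$n, near$direction, sum)
  expect_gt(near_mean[["up"]], 0)
  expect_lt(near_mean[["down"]], 0)
})

test_that("ORA matches the exact hypergeometric tail", {
  universe <- sprintf("g%03d", 1:100)
  query <- universe[1:10]
  sets <- list(hit = c(universe[1:6], universe[50:63]),   # overlap 6, size 20
               miss = universe[80:84])
  out <- ora_enrichment(query, universe, sets, q_max = 0.01)
  p_hit <- out$p[out$set == "hit"]
  expect_equal(p_hit, 0.003933076, tolerance = 1e-6)
  expect_equal(p_hit, brute_hyper_tail(6, 20, 100, 10), tolerance = 1e-12)
  expect_equal(out$overlap[out$set == "miss"], 0)
  expect_gt(out$p[out$set == "miss"], 0.4)
  expect_false(out$enriched[out$set == "miss"])

  # degenerate: query = set = universe
  deg <- ora_enrichment(universe, universe, list(all = universe))
  expect_equal(deg$p, 1)
  expect_error(ora_enrichment(c(query, "zzz"), universe, sets), "missing")
})
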