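toy_catalog <- function(...) {
  transcript_catalog(tibble::tibble(...))
}

test_that("coding potential is the maximum over all codons of all ORFs", {
  expect_equal(coding_potential_max(list(c(-2, -1), c(-5, -3), c(-4))), -1)
  expect_equal(coding_potential_max(list(c(-2, 0.5, -1), c(-5), c(-4))), 0.5)
  expect_equal(coding_potential_max(list(0)), 0)
  expect_error(coding_potential_max(list(numeric(), numeric())), "empty")
})

test_that("positional classification follows span/exon overlap rules", {
  coding <- toy_catalog(
    transcript_id = "c1.t1", gene_id = "c1", chrom = "chr1", strand = "-",
    start = c(0, 4500), end = c(500, 5000))  # gene span [0, 5000)
  cands <- toy_catalog(
    transcript_id = c("antisense", "intergenic", "sense", "intronic"),
    gene_id = c("antisense", "intergenic", "sense", "intronic"),
    chrom = "chr1",
    strand = c("+", "+", "-", "-"),
    start = c(1000, 10000, 400, 1000),
    end = c(2000, 11000, 700, 2000))
  got <- classify_position(cands, coding)
  expect_equal(got$position_class[match(
    c("antisense", "intergenic", "sense", "intronic"), got$transcript_id)],
    c("antisense", "intergenic", "sense_overlap", "intronic"))
})

test_that("repeat overlap fraction merges repeats and is per mature length", {
  one <- toy_catalog(transcript_id = "t", gene_id = "t", chrom = "chr1",
                     strand = "+", start = 0, end = 100)
  expect_equal(
    repeat_overlap_fraction(one, tibble::tibble(chrom = "chr1", start = 0L,
                                                end = 100L))$repeat_fraction,
    1)
  two <- toy_catalog(transcript_id = "t", gene_id = "t", chrom = "chr1",
                     strand = "+", start = c(0, 200), end = c(100, 300))
  reps <- tibble::tibble(chrom = "chr1", start = c(50L, 200L),
                         end = c(100L, 250L))
  expect_equal(repeat_overlap_fraction(two, reps)$repeat_fraction, 0.5)
  # duplicated repeat records: identical answer (merge idempotence)
  expect_equal(repeat_overlap_fraction(two, dplyr::bind_rows(reps, reps)),
               repeat_overlap_fraction(two, reps))
})

test_that("interval repeat fraction equals per-base brute force", {
  for (s in 1:4) {
    withr::with_seed(s, {
      starts <- sort(sample(0:9500, 15)) * 1L
      cat_r <- toy_catalog(
        transcript_id = sprintf("t%02d", 1:15), gene_id = sprintf("t%02d", 1:15),
        chrom = "chr1", strand = "+",
        start = starts, end = starts + sample(50:400, 15, replace = TRUE))
      rs <- sort(sample(0:9500, 10)) * 1L
      reps <- tibble::tibble(chrom = "chr1", start = rs,
                             end = rs + sample(50:500, 10, replace = TRUE))
      got <- repeat_overlap_fraction(cat_r, reps)$repeat_fraction
      expect_equal(got, brute_repeat_fraction(cat_r, reps))
    })
  }
})

test_that("expressed_set applies thresholds, scopes and both comparators", {
  tpm <- rbind(a = c(1.2, 1.1, 0.9, 3.0, 0, 0),
               b = rep(0, 6),
               c = rep(1, 6))
  colnames(tpm) <- paste0("s", 1:6)
  expect_true("a" %in% expressed_set(tpm, 1, 3, comparator = ">="))
  expect_false("b" %in% expressed_set(tpm, 1, 3))
  expect_equal(expressed_set(tpm, 1, 7), character())
  # boundary: exactly 1 TPM counts under >=, not under >
  expect_true("c" %in% expressed_set(tpm, 1, 3, comparator = ">="))
  expect_false("c" %in% expressed_set(tpm, 1, 3, comparator = ">"))
  smp <- tibble::tibble(sample = paste0("s", 1:6),
                        cell_type = rep(c("NB", "CB"), each = 3))
  expect_error(expressed_set(tpm, samples = smp, cell_type = "XX"),
               "no samples")
  # monotonicity: raising min_tpm never grows the set
  withr::with_seed(1, {
    m <- matrix(rexp(300, 1 / 2), 50, dimnames = list(sprintf("g%02d", 1:50),
                                                      paste0("s", 1:6)))
    sets <- lapply(c(0.5, 1, 2, 4), function(th) expressed_set(m, th, 3))
    for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  })
})

test_that("the discovery cascade records the first failing rule", {
  coding <- toy_catalog(transcript_id = "c1.t1", gene_id = "c1",
                        chrom = "chr1", strand = "+",
                        start = c(50000, 54000), end = c(50500, 54500))
  starts <- c(1000, 5000, 9000, 13000, 17000, 50200)
  cands <- toy_catalog(
    transcript_id = sprintf("t%d", 1:6), gene_id = sprintf("t%d", 1:6),
    chrom = "chr1", strand = "+",
    start = starts,
    end = starts + c(150, 400, 400, 1000, 400, 400))
  # t1 too short (150 nt) even though its coding score is positive;
  # t2 expressed in only 2 samples; t3 repeat 80%; t4 repeat 74% but
  # coding score > 0; t5 passes; t6 sense-overlaps the coding gene
  tpm <- matrix(10, nrow = 6, ncol = 6,
                dimnames = list(sprintf("t%d", 1:6), paste0("s", 1:6)))
  tpm["t2", ] <- c(5, 5, 0, 0, 0, 0)
  reps <- tibble::tibble(chrom = "chr1",
                         start = c(9000L, 13000L), end = c(9320L, 13740L))
  scores <- tibble::tibble(transcript_id = sprintf("t%d", 1:6),
                           max_coding_score = c(2, -1, -1, 3, 0, -1))
  out <- filter_novel_lncrnas(cands, tpm, reps, scores, coding)
  v <- out$verdicts
  expect_equal(v$reason[match(sprintf("t%d", 1:6), v$transcript_id)],
               c("too_short", "low_expression", "repeat_overlap",
                 "coding_potential", "", "sense_overlap"))
  expect_true(v$pass[v$transcript_id == "t5"])  # score 0: bound is exclusive
  expect_equal(v$repeat_fraction[v$transcript_id == "t4"], 0.74)
  # verdict partition: pass + all reason buckets = candidates
  expect_equal(sum(v$pass) + sum(v$reason != ""), nrow(cands))
  expect_equal(out$catalog$position_class, "intergenic")
})

test_that("candidates missing from inputs get error verdicts, run continues", {
  coding <- toy_catalog(transcript_id = "c1.t1", gene_id = "c1",
                        chrom = "chr1", strand = "+", start = 50000,
                        end = 54500)
  cands <- toy_catalog(transcript_id = c("t1", "t2"), gene_id = c("t1", "t2"),
                       chrom = "chr1", strand = "+", start = c(1000, 5000),
                       end = c(1400, 5400))
  tpm <- matrix(10, 1, 6, dimnames = list("t1", paste0("s", 1:6)))
  scores <- tibble::tibble(transcript_id = "t1", max_coding_score = -1)
  v <- filter_novel_lncrnas(cands, tpm, empty_repeats <- tibble::tibble(
    chrom = character(), start = integer(), end = integer()),
    scores, coding)$verdicts
  expect_equal(v$reason[v$transcript_id == "t2"], "missing_data")
  expect_true(v$pass[v$transcript_id == "t1"])
})

test_that("synthetic filter verdicts reproduce planted fates exactly", {
  disc <- get_small_discovery()
  tr <- disc$atlas$truth$transcripts
  j <- dplyr::inner_join(disc$filter$verdicts, tr, by = "transcript_id")
  called <- ifelse(j$pass, "pass", j$reason)
  expect_equal(mean(called == j$true_fate), 1)
  expect_equal(j$position_class[j$pass], j$true_class[j$pass])
  v <- disc$filter$verdicts
  expect_equal(sum(v$pass) + sum(v$reason != ""), nrow(v))
})

test_that("transcribed-base accounting uses precedence and exon unions", {
  gm <- genome_model(c(chr1 = 10000L))
  lnc <- toy_catalog(transcript_id = c("l1", "l2"), gene_id = c("l1", "l2"),
                     chrom = "chr1", strand = "+",
                     start = c(0, 500), end = c(1000, 2000))
  out <- classify_transcribed_bases(list(lncRNA = lnc), gm)
  expect_equal(out$fraction[out$category == "lncRNA"], 0.2)  # merged union

  coding <- toy_catalog(transcript_id = "c1", gene_id = "c1", chrom = "chr1",
                        strand = "+", start = 800, end = 1200)
  both <- classify_transcribed_bases(list(coding = coding, lncRNA = lnc), gm)
  expect_equal(both$bp[both$category == "coding"], 400)
  expect_equal(both$bp[both$category == "lncRNA"], 1600)  # overlap went coding
  expect_equal(both$fraction[both$category == "total"], 0.2)

  none <- classify_transcribed_bases(
    list(coding = coding[0, ]), gm)
  expect_equal(none$fraction, c(0, 0))
})

test_that("transcribed fractions equal the per-base oracle on toy genomes", {
  for (s in 1:3) {
    withr::with_seed(s, {
      gm <- genome_model(c(chr1 = 8000L))
      mk <- function(prefix, n) {
        starts <- sample(0:7000, n) * 1L
        toy_catalog(transcript_id = paste0(prefix, 1:n),
                    gene_id = paste0(prefix, 1:n), chrom = "chr1",
                    strand = "+", start = starts,
                    end = starts + sample(100:900, n, replace = TRUE))
      }
      cats <- list(coding = mk("c", 5), lncRNA = mk("l", 8))
      got <- classify_transcribed_bases(cats, gm)
      oracle <- brute_transcribed(cats, gm)
      expect_equal(got$fraction, unname(oracle[got$category]))
    })
  }
})
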