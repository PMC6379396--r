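# Adjusted Rand index between two labelings (used for truth-aware run
# summaries; tests cross-check against mclust's implementation)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(as.vector(tab))
  si <- comb2(rowSums(tab))
  sj <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

#' Run the full atlas pipeline on synthetic data
#'
#' Orchestrates every stage end-to-end: simulate, discover (filter
#' cascade + genome transcription accounting), expression analytics (DE,
#' tau, trajectories, PCA, phylogeny, Ig read fraction), proximity
#' association, chromatin-state clustering, enhancer/eRNA calling with
#' bidirectionality and the permutation overlap test, and circRNA
#' filtering/partitioning. Writes per-stage outputs under `out_dir` and a
#' run manifest (resolved config, seed, per-stage wall time, file
#' digests, summary metrics including truth-recovery scores).
#'
#' @param config A [synthetic_config()].
#' @param seed Overrides `config$seed` when given.
#' @param out_dir Output directory.
#' @param n_perm Permutations for the overlap test (default 1000).
#' @return A list of class `lnc_manifest` (also written as
#'   `manifest.json`): `config`, `seed`, `stages` (tibble of wall times),
#'   `files`, `summary`, plus all in-memory stage results in `$results`.
#' @export
run_atlas <- function(config = synthetic_config(), seed = NULL,
                      out_dir = tempfile("lncatlas_run_"), n_perm = 1000) {
  if (!is.null(seed)) config$seed <- seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  timed <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    value <- force(expr)
    stages[[name]] <<- proc.time()[["elapsed"]] - t0
    value
  }
  p <- function(...) file.path(out_dir, ...)

  atlas <- timed("simulate", simulate_atlas(config, out_dir = p("sim")))
  truth <- atlas$truth

  # -- discover ------------------------------------------------------------
  disc <- timed("discover", {
    sf <- size_factors(atlas$counts)
    tpm <- tpm_normalize(atlas$counts, atlas$lengths, sf)
    scores <- summarise_coding_scores(atlas$orf_scores)
    flt <- filter_novel_lncrnas(atlas$candidates, tpm, atlas$genome$repeats,
                                scores, atlas$coding)
    expressed <- expressed_set(tpm, comparator = ">=")
    frac <- classify_transcribed_bases(
      list(coding = filter(atlas$coding, .data$gene_id %in% expressed),
           lncRNA = filter(flt$catalog,
                           .data$transcript_id %in% expressed)),
      atlas$genome)
    write_annotation(flt$catalog, p("novel_lncrnas.gtf"))
    readr::write_tsv(flt$verdicts, p("verdicts.tsv"))
    readr::write_tsv(frac, p("genome_fraction.tsv"))
    list(tpm = tpm, filter = flt, genome_fraction = frac)
  })

  # -- expression analytics -----------------------------------------------
  contrast <- truth$contrast
  expr <- timed("express", {
    de <- differential_expression(disc$tpm, atlas$samples,
                                  contrast[1], contrast[2])
    tau <- tau_index(disc$tpm, atlas$samples)
    lnc_ids <- disc$filter$catalog$transcript_id
    traj <- trajectory_clusters(disc$tpm[lnc_ids, , drop = FALSE],
                                atlas$samples,
                                k = config$n_trajectory_clusters,
                                seed = config$seed)
    pca <- pca_embedding(disc$tpm, atlas$samples)
    phylo <- group_phylogeny(disc$tpm, atlas$samples, seed = config$seed)
    igf <- ig_read_fraction(atlas$counts, atlas$coding, atlas$genome$ig_loci,
                            biotypes = "coding")
    readr::write_tsv(as_tibble(de), p("differential_expression.tsv"))
    readr::write_tsv(as_tibble(tau), p("tau.tsv"))
    readr::write_tsv(traj$clusters, p("trajectory_clusters.tsv"))
    readr::write_tsv(pca$scores, p("pca.tsv"))
    ape::write.tree(phylo$tree, p("cell_type_tree.nwk"))
    readr::write_tsv(igf, p("ig_read_fraction.tsv"))
    list(de = de, tau = tau, traj = traj, pca = pca, phylo = phylo,
         ig_fraction = igf)
  })

  # -- proximity association ----------------------------------------------
  assoc <- timed("associate", {
    domains <- regulatory_domains(atlas$coding, atlas$genome)
    pairs <- associate_lncrna_genes(disc$filter$catalog, domains)
    lnc_de <- expr$de[expr$de$gene %in% disc$filter$catalog$transcript_id, ]
    coding_de <- expr$de[expr$de$gene %in% atlas$coding$gene_id, ]
    profile <- tryCatch(
      distance_fc_profile(coding_de, lnc_de, atlas$coding,
                          disc$filter$catalog),
      error = function(e) NULL)
    readr::write_tsv(domains, p("regulatory_domains.tsv"))
    readr::write_tsv(pairs, p("lncrna_gene_pairs.tsv"))
    if (!is.null(profile)) readr::write_tsv(profile, p("distance_profile.tsv"))
    list(domains = domains, pairs = pairs, profile = profile)
  })

  # -- chromatin state -----------------------------------------------------
  chrom <- timed("chromstate", {
    fm <- feature_matrix(disc$filter$catalog, atlas$tracks, atlas$genome)
    fc <- functional_clusters(fm, k = 10, seed = config$seed)
    readr::write_tsv(fm, p("feature_matrix.tsv"))
    readr::write_tsv(fc$clusters, p("chromatin_clusters.tsv"))
    readr::write_tsv(fc$medians, p("cluster_medians.tsv"))
    readr::write_tsv(fc$embedding, p("embedding.tsv"))
    list(features = fm, clusters = fc)
  })

  # -- enhancers / eRNAs ---------------------------------------------------
  enh <- timed("enhancers", {
    coding_tss <- distinct(atlas$coding, .data$chrom, .data$tss) |>
      rename(tss = "tss")
    calls <- call_enhancers(atlas$peaks$H3K4me1, atlas$peaks$H3K27ac,
                            coding_tss)
    se <- call_super_enhancers(atlas$peaks$H3K27ac)
    ernas <- call_ernas(disc$filter$catalog, calls, coding_tss, se = se)
    lnc_ig <- filter(disc$filter$catalog, .data$position_class == "intergenic")
    bid <- bidirectionality_score(atlas$coverage, lnc_ig$chrom, lnc_ig$tss) |>
      mutate(transcript_id = lnc_ig$transcript_id, .before = 1)
    eligible_windows <- disc$filter$catalog |>
      filter(.data$transcript_id %in% ernas$eligible) |>
      transmute(chrom = .data$chrom, start = pmax(0, .data$tss - 1000L),
                end = .data$tss + 1001L)
    perm <- permutation_overlap_test(calls[c("chrom", "start", "end")],
                                     eligible_windows, atlas$genome,
                                     n_perm = n_perm, seed = config$seed)
    write_bed(mutate(calls, name = .data$class), p("enhancers.bed"))
    write_bed(mutate(se$regions[se$regions$is_se, ],
                     name = .data$region_id), p("superenhancers.bed"))
    write_bed(mutate(se$constituents, name = .data$region_id),
              p("constituents.bed"))
    readr::write_tsv(ernas$ernas, p("ernas.tsv"))
    readr::write_tsv(ernas$fractions, p("erna_fractions.tsv"))
    readr::write_tsv(bid, p("bidirectionality.tsv"))
    readr::write_tsv(tibble(null_fraction = perm$null), p("permutation.tsv"))
    list(calls = calls, se = se, ernas = ernas, bidirectionality = bid,
         permutation = perm)
  })

  # -- circRNA -------------------------------------------------------------
  circ <- timed("circ", {
    kept <- filter_circrnas(atlas$junctions, atlas$samples)
    part <- partition_ig(kept, atlas$genome$ig_loci, atlas$samples)
    corr <- circ_gene_correlation(kept, disc$tpm,
                                  head(sort(unique(atlas$coding$gene_id)), 5),
                                  atlas$samples)
    readr::write_tsv(kept, p("circ_filtered.tsv"))
    readr::write_tsv(part$by_cell_type, p("circ_ig_partition.tsv"))
    readr::write_tsv(corr, p("circ_correlations.tsv"))
    list(filtered = kept, partition = part, correlations = corr)
  })

  summary <- atlas_summary(atlas, disc, expr, chrom, enh, circ)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  digests <- tools::md5sum(files)
  manifest <- structure(
    list(version = as.character(utils::packageVersion("lncatlas")),
         seed = config$seed,
         config = unclass(config),
         stages = tibble(stage = names(stages),
                         seconds = round(unlist(stages), 2)),
         files = tibble(path = sub(paste0("^", out_dir, "/?"), "", files),
                        md5 = unname(digests)),
         summary = summary,
         out_dir = out_dir,
         results = list(atlas = atlas, discover = disc, express = expr,
                        associate = assoc, chromstate = chrom,
                        enhancers = enh, circ = circ)),
    class = "lnc_manifest")
  writeable <- manifest[c("version", "seed", "config", "stages", "files",
                          "summary")]
  jsonlite::write_json(writeable, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  manifest
}

# truth-aware summary metrics; truth fields are present for synthetic runs
atlas_summary <- function(atlas, disc, expr, chrom, enh, circ) {
  truth <- atlas$truth
  v <- disc$filter$verdicts
  tr <- truth$transcripts
  joined <- inner_join(v, tr, by = "transcript_id")
  fate_called <- ifelse(joined$pass, "pass", joined$reason)
  erna_truth <- tr$transcript_id[tr$erna]
  erna_called <- enh$ernas$ernas$transcript_id
  bid <- inner_join(enh$bidirectionality, truth$bidirectional,
                    by = "transcript_id")
  class_join <- inner_join(chrom$clusters$clusters, truth$chromatin$classes,
                           by = "transcript_id")
  circ_called <- circ$filtered$junction_id
  circ_truth <- truth$circ$junction_id[truth$circ$fate == "kept"]
  pc <- expr$ig_fraction |>
    left_join(atlas$samples, by = "sample") |>
    group_by(is_pc = .data$cell_type %in% c("TPC", "BMPC")) |>
    summarise(m = mean(.data$ig_fraction), .groups = "drop")
  list(
    n_candidates = nrow(v),
    n_novel_lncrnas = sum(v$pass),
    verdict_reason_counts = as.list(table(fate_called)),
    verdict_truth_agreement = mean(fate_called == joined$true_fate),
    n_enhancers_active = sum(enh$calls$class == "active"),
    n_enhancers_poised = sum(enh$calls$class == "poised"),
    n_super_enhancers = sum(enh$se$regions$is_se),
    erna_precision = if (length(erna_called))
      mean(erna_called %in% erna_truth) else NA,
    erna_recall = if (length(erna_truth))
      mean(erna_truth %in% erna_called) else NA,
    erna_fractions = enh$ernas$fractions,
    bidirectional_accuracy = mean(bid$bidirectional.x == bid$bidirectional.y),
    permutation_p = enh$permutation$p,
    permutation_null_median = median(enh$permutation$null),
    chromatin_ari = ari(class_join$cluster, class_join$chromatin_class),
    circ_filter_agreement = mean(
      (truth$circ$junction_id %in% circ_called) ==
        (truth$circ$junction_id %in% circ_truth)),
    ig_fraction_pc = pc$m[pc$is_pc],
    ig_fraction_other = pc$m[!pc$is_pc],
    tau_range = range(expr$tau$tau, na.rm = TRUE))
}

#' @export
print.lnc_manifest <- function(x, ...) {
  cat("<lnc_manifest> seed ", x$seed, "; stages:\n", sep = "")
  print(x$stages)
  cat("novel lncRNAs: ", x$summary$n_novel_lncrnas, " / ",
      x$summary$n_candidates, " candidates (truth agreement ",
      format(x$summary$verdict_truth_agreement, digits = 4), ")\n", sep = "")
  invisible(x)
}
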