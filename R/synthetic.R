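#' Generate the miniature genome and coding-gene catalog
#'
#' Places `n_coding_genes` three-exon coding genes across the chromosomes
#' with pairwise gaps of at least 10 kb, scatters repeats to the requested
#' density in intergenic space, and reserves one Ig-like locus (carrying
#' three dedicated Ig coding genes) at the end of the first chromosome.
#'
#' @param config A [synthetic_config()].
#' @return A list with `genome` (a [genome_model()]) and `coding` (a
#'   [transcript_catalog()]; Ig genes have `gene_id` prefix `"IGH"`).
#' @export
generate_genome <- function(config) {
  withr::with_seed(config$seed + 101L, {
    L <- config$chrom_length
    chroms <- paste0("chr", seq_len(config$n_chroms))
    gene_span <- 10500L   # 3 x 500 bp exons with 4.5 kb introns
    min_gap <- 10000L
    margin <- 50000L

    ig_start <- L - margin - config$ig_locus_span
    if (ig_start <= margin) abort("ig_locus_span too large for chrom_length")
    ig_loci <- tibble(chrom = chroms[1], start = as.integer(ig_start),
                      end = as.integer(ig_start + config$ig_locus_span))

    n_per <- rep(config$n_coding_genes %/% config$n_chroms, config$n_chroms)
    extra <- config$n_coding_genes %% config$n_chroms
    if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1L

    place_genes <- function(chrom, n, lo, hi) {
      slot <- (hi - lo) %/% n
      if (slot < gene_span + min_gap) {
        abort(sprintf(
          "genes do not fit at >= %d bp spacing; chromosomes must be at least %d bp",
          min_gap, n * (gene_span + min_gap) + 2 * margin +
            if (chrom == chroms[1]) config$ig_locus_span + margin else 0))
      }
      jitter <- floor(runif(n) * (slot - gene_span - min_gap + 1))
      tibble(chrom = chrom,
             start = as.integer(lo + (seq_len(n) - 1) * slot + jitter),
             strand = sample(c("+", "-"), n, replace = TRUE))
    }
    placed <- list_rbind(map(seq_along(chroms), function(ci) {
      hi <- if (ci == 1) ig_start - 20000 else L - margin
      place_genes(chroms[ci], n_per[ci], margin, hi)
    }))
    placed$gene_id <- sprintf("gene_%03d", seq_len(nrow(placed)))

    # three Ig coding genes inside the Ig locus
    ig_genes <- tibble(chrom = chroms[1],
                       start = as.integer(ig_start +
                                          c(20000, 120000, 220000)),
                       strand = c("+", "+", "-"),
                       gene_id = paste0("IGH", 1:3))
    placed <- bind_rows(placed, ig_genes)

    exon_offsets <- cbind(start = c(0L, 5000L, 10000L),
                          end = c(500L, 5500L, 10500L))
    exons <- placed |>
      mutate(transcript_id = paste0(.data$gene_id, ".t1"),
             biotype = "coding") |>
      tidyr::expand_grid(k = 1:3) |>
      mutate(exon_start = .data$start + exon_offsets[.data$k, "start"],
             exon_end = .data$start + exon_offsets[.data$k, "end"]) |>
      select("transcript_id", "gene_id", "chrom", "strand", "biotype",
             start = "exon_start", end = "exon_end")
    coding <- transcript_catalog(exons)

    # random repeats confined to intergenic space so planted candidate
    # fates stay deterministic; repeat-overlap fates get dedicated repeats
    spans <- coding |>
      group_by(.data$gene_id) |>
      summarise(chrom = .data$chrom[1], start = min(.data$start) - 3000L,
                end = max(.data$end) + 3000L, .groups = "drop")
    target_bp <- config$repeat_density * config$n_chroms * L
    reps <- list()
    total <- 0
    guard <- 0
    blocked <- bind_rows(spans[c("chrom", "start", "end")], ig_loci)
    while (total < target_bp && guard < 40) {
      guard <- guard + 1
      n_prop <- 1000L
      w <- as.integer(300 + floor(runif(n_prop) * 1200))
      ch <- sample(chroms, n_prop, replace = TRUE)
      s <- as.integer(floor(runif(n_prop) * (L - w)))
      prop <- tibble(chrom = ch, start = s, end = s + w)
      prop <- prop[!overlaps_any(prop, blocked), ]
      cum <- cumsum(prop$end - prop$start)
      keep <- which(total + cum <= target_bp + 1500)
      prop <- prop[keep, ]
      if (nrow(prop)) {
        reps[[length(reps) + 1]] <- prop
        total <- total + sum(prop$end - prop$start)
      }
    }
    repeats <- if (length(reps)) merge_intervals(list_rbind(reps)) else empty_intervals()

    genome <- genome_model(tibble(chrom = chroms, length = as.integer(L)),
                           repeats = repeats, ig_loci = ig_loci)
    list(genome = genome, coding = coding)
  })
}

# ---------------------------------------------------------------------------
# placement layout: carve exclusive areas out of clean intergenic space

# returns list(se_areas, erna_areas, enhancer_areas, slots)
build_layout <- function(genome, coding, config) {
  pad <- 3000L
  buffer <- 13000L   # keeps K27ac peaks in different areas un-stitchable
  spans <- coding |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], start = pmax(0L, min(.data$start) - pad),
              end = max(.data$end) + pad, .groups = "drop")
  blocked <- bind_rows(spans[c("chrom", "start", "end")],
                       genome$ig_loci,
                       tibble(chrom = genome$chrom_sizes$chrom, start = 0L,
                              end = 1000L),
                       tibble(chrom = genome$chrom_sizes$chrom,
                              start = genome$chrom_sizes$length - 1000L,
                              end = genome$chrom_sizes$length))
  chrom_gr <- as_granges(tibble(chrom = genome$chrom_sizes$chrom, start = 0L,
                                end = genome$chrom_sizes$length))
  # reserved areas are carved from whole intergenic gaps; random repeats
  # falling inside them are removed downstream so planted fates hold
  gaps <- as_interval_tbl(suppressWarnings(
    GenomicRanges::setdiff(chrom_gr, as_granges(merge_intervals(blocked)))))

  pool <- arrange(gaps, dplyr::desc(.data$end - .data$start))
  carve <- function(n, width) {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      pool <<- arrange(pool, dplyr::desc(.data$end - .data$start))
      seg <- pool[1, ]
      need <- width + 2 * buffer
      if (seg$end - seg$start < need) {
        abort("not enough clean intergenic space; enlarge the genome")
      }
      out[[i]] <- tibble(chrom = seg$chrom, start = seg$start + buffer,
                         end = seg$start + buffer + width)
      pool[1, "start"] <<- seg$start + need
    }
    list_rbind(out)
  }
  se_areas <- carve(config$n_super_enhancers, 30000L) |>
    mutate(se_id = sprintf("se_%02d", dplyr::row_number()))
  erna_areas <- carve(config$n_ernas, 2000L)
  enhancer_areas <- carve(config$n_enhancers, 2000L) |>
    mutate(center = as.integer((.data$start + .data$end) / 2))

  # ordinary candidate slots avoid repeats outright
  slot_space <- as_interval_tbl(suppressWarnings(GenomicRanges::setdiff(
    as_granges(pool), as_granges(merge_intervals(genome$repeats)))))
  slot_w <- 4000L
  slots <- slot_space |>
    filter(.data$end - .data$start >= slot_w) |>
    pmap(function(chrom, start, end) {
      k <- (end - start) %/% slot_w
      tibble(chrom = chrom,
             center = as.integer(start + (seq_len(k) - 1) * slot_w +
                                 slot_w / 2))
    }) |>
    list_rbind()
  slots <- slots[sample(nrow(slots)), ]
  list(se_areas = se_areas, erna_areas = erna_areas,
       enhancer_areas = enhancer_areas, slots = slots)
}

#' Generate lncRNA candidates, counts, and per-ORF coding scores
#'
#' Plants candidates in every discovery-filter fate (too short,
#' under-expressed, repeat-buried, positive coding score,
#' sense-overlapping, intronic) plus true novel lncRNAs (antisense and
#' intergenic), then draws negative-binomial counts whose cell-type means
#' encode planted differential expression, trajectory archetypes,
#' single-population (tau = 1) genes, and plasma-cell-biased Ig genes.
#' Counts in the designated population of each expressed candidate are
#' floored so planted expression fates are deterministic.
#'
#' @param gen Output of [generate_genome()].
#' @param config A [synthetic_config()].
#' @return A list: `candidates` ([transcript_catalog()]), `counts`
#'   (genes-by-samples integer matrix over coding genes and candidates),
#'   `lengths` (named mature lengths), `samples` (tibble `sample`,
#'   `cell_type`), `orf_scores` (tibble `transcript_id`, `orf`, `score`),
#'   `truth` (per-transcript ground truth + `layout`), `repeats` (full
#'   repeat set including planted ones).
#' @export
generate_candidates_and_expression <- function(gen, config) {
  if (config$replicates_per_type < 3) {
    abort("replicates_per_type must be >= 3 (the expression filter needs 3 samples)")
  }
  genome <- gen$genome
  coding <- gen$coding
  withr::with_seed(config$seed + 202L, {
    layout <- build_layout(genome, coding, config)
    mix <- config$candidate_mix
    n_cat <- round(mix * config$n_lncrna_candidates)
    n_cat[1] <- config$n_lncrna_candidates - sum(n_cat[-1])

    host_pool <- coding |>
      filter(!startsWith(.data$gene_id, "IGH")) |>
      group_by(.data$gene_id) |>
      summarise(chrom = .data$chrom[1], strand = .data$strand[1],
                start = min(.data$start), end = max(.data$end),
                .groups = "drop")

    slot_i <- 0L
    next_slot <- function() {
      slot_i <<- slot_i + 1L
      if (slot_i > nrow(layout$slots)) {
        abort("not enough placement slots; enlarge the genome")
      }
      layout$slots[slot_i, ]
    }
    opposite <- function(s) ifelse(s == "+", "-", "+")

    rows <- list()
    planted_repeats <- list()
    idx <- 0L
    add <- function(category, chrom, strand, exon_mat, extra = list()) {
      idx <<- idx + 1L
      id <- sprintf("cand_%04d", idx)
      rows[[idx]] <<- c(list(transcript_id = id, category = category,
                             chrom = chrom, strand = strand,
                             exons = list(exon_mat)), extra)
      id
    }

    # intergenic single/two-exon candidate centred in a 4 kb slot
    intergenic_exons <- function(center, total_len, n_exons) {
      if (n_exons == 1) {
        s <- as.integer(center - total_len %/% 2)
        cbind(start = s, end = s + as.integer(total_len))
      } else {
        half <- as.integer(total_len) %/% 2L
        s <- as.integer(center - (total_len + 600) %/% 2)
        cbind(start = c(s, s + half + 600L),
              end = c(s + half, s + 600L + as.integer(total_len)))
      }
    }

    n_se_erna <- ceiling(config$n_super_enhancers * 0.6)
    se_with_erna <- layout$se_areas$se_id[seq_len(n_se_erna)]
    # pass_intergenic: SE-resident eRNAs, standalone eRNAs, then ordinary
    n_pi <- n_cat[["pass_intergenic"]]
    if (n_pi < n_se_erna + config$n_ernas + 20) {
      abort("pass_intergenic quota too small for the planted eRNA loci")
    }
    for (i in seq_len(n_pi)) {
      if (i <= n_se_erna) {
        area <- layout$se_areas[i, ]
        center <- as.integer(area$start + 2000L)
        len <- 400L + as.integer(floor(runif(1) * 800))
        add("pass_intergenic", area$chrom, sample(c("+", "-"), 1),
            intergenic_exons(center, len, 1L),
            extra = list(erna = TRUE, se_area = area$se_id))
      } else if (i <= n_se_erna + config$n_ernas) {
        area <- layout$erna_areas[i - n_se_erna, ]
        center <- as.integer((area$start + area$end) / 2)
        len <- 400L + as.integer(floor(runif(1) * 800))
        add("pass_intergenic", area$chrom, sample(c("+", "-"), 1),
            intergenic_exons(center, len, 1L),
            extra = list(erna = TRUE, se_area = NA_character_))
      } else {
        sl <- next_slot()
        n_ex <- if (runif(1) < 0.6) 1L else 2L
        len <- 400L + as.integer(floor(runif(1) * 1100))
        add("pass_intergenic", sl$chrom, sample(c("+", "-"), 1),
            intergenic_exons(sl$center, len, n_ex),
            extra = list(erna = FALSE, se_area = NA_character_))
      }
    }
    for (i in seq_len(n_cat[["pass_antisense"]])) {
      host <- host_pool[(i - 1L) %% nrow(host_pool) + 1L, ]
      slot_k <- (i - 1L) %/% nrow(host_pool)
      if (slot_k > 2L) {
        abort("too many antisense candidates per host gene; add coding genes")
      }
      # fixed offsets keep antisense TSS windows from sharing chromatin
      # plateaus within one host
      s <- as.integer(host$start + 600L + 3900L * slot_k)
      add("pass_antisense", host$chrom, opposite(host$strand),
          cbind(start = s, end = s + 800L))
    }
    for (i in seq_len(n_cat[["too_short"]])) {
      sl <- next_slot()
      len <- 100L + as.integer(floor(runif(1) * 100))  # 100..199 nt
      add("too_short", sl$chrom, sample(c("+", "-"), 1),
          intergenic_exons(sl$center, len, 1L))
    }
    for (i in seq_len(n_cat[["low_expression"]])) {
      sl <- next_slot()
      len <- 400L + as.integer(floor(runif(1) * 600))
      add("low_expression", sl$chrom, sample(c("+", "-"), 1),
          intergenic_exons(sl$center, len, 1L))
    }
    for (i in seq_len(n_cat[["repeat_overlap"]])) {
      sl <- next_slot()
      len <- 400L + as.integer(floor(runif(1) * 600))
      ex <- intergenic_exons(sl$center, len, 1L)
      planted_repeats[[i]] <- tibble(chrom = sl$chrom,
                                     start = ex[1, "start"] - 50L,
                                     end = ex[1, "end"] + 50L)
      add("repeat_overlap", sl$chrom, sample(c("+", "-"), 1), ex)
    }
    for (i in seq_len(n_cat[["coding_potential"]])) {
      sl <- next_slot()
      len <- 400L + as.integer(floor(runif(1) * 1100))
      add("coding_potential", sl$chrom, sample(c("+", "-"), 1),
          intergenic_exons(sl$center, len, 1L))
    }
    for (i in seq_len(n_cat[["sense_overlap"]])) {
      host <- host_pool[(i + 7L) %% nrow(host_pool) + 1L, ]
      # overlap the host's middle exon ([start+5000, start+5500))
      s <- as.integer(host$start + 4800L)
      add("sense_overlap", host$chrom, host$strand,
          cbind(start = s, end = s + 500L))
    }
    for (i in seq_len(n_cat[["intronic"]])) {
      host <- host_pool[(i + 13L) %% nrow(host_pool) + 1L, ]
      # inside the host's first intron ([start+500, start+5000))
      off <- 700L + as.integer(floor(runif(1) * 3500))
      s <- as.integer(host$start + off)
      add("intronic", host$chrom, host$strand,
          cbind(start = s, end = s + 700L))
    }

    truth <- list_rbind(map(rows, function(r) {
      tibble(transcript_id = r$transcript_id, category = r$category,
             erna = r$erna %||% FALSE,
             se_area = r$se_area %||% NA_character_)
    }))
    exon_tbl <- list_rbind(map(rows, function(r) {
      ex <- r$exons[[1]]
      tibble(transcript_id = r$transcript_id, gene_id = r$transcript_id,
             chrom = r$chrom, strand = r$strand,
             start = as.integer(ex[, "start"]), end = as.integer(ex[, "end"]),
             biotype = "novel_candidate")
    }))
    candidates <- transcript_catalog(exon_tbl)
    truth <- truth |>
      left_join(select(candidates, "transcript_id", "n_exons", "chrom",
                       "tss", "strand", "mature_length"),
                by = "transcript_id") |>
      mutate(true_fate = dplyr::recode(.data$category,
               pass_intergenic = "pass", pass_antisense = "pass"),
             true_class = case_when(
               .data$category == "pass_intergenic" ~ "intergenic",
               .data$category == "pass_antisense" ~ "antisense",
               TRUE ~ NA_character_))

    # drop random repeats touching exons of candidates that must stay
    # repeat-clean, so planted repeat fates are deterministic
    clean_ex <- catalog_exons(candidates) |>
      filter(.data$transcript_id %in%
               truth$transcript_id[truth$category != "repeat_overlap"])
    keep_rep <- !overlaps_any(genome$repeats,
                              clean_ex[c("chrom", "start", "end")])
    repeats_all <- merge_intervals(bind_rows(genome$repeats[keep_rep, ],
                                             list_rbind(planted_repeats)))

    # ---- expression ------------------------------------------------------
    types <- config$cell_types
    samples <- tidyr::expand_grid(cell_type = types,
                                  rep = seq_len(config$replicates_per_type)) |>
      mutate(sample = paste0(.data$cell_type, "_", .data$rep)) |>
      select("sample", "cell_type")

    coding_genes <- unique(coding$gene_id)
    n_cod <- length(coding_genes)
    is_ig_gene <- startsWith(coding_genes, "IGH")

    arche <- trajectory_archetypes(types)
    mean_mat <- matrix(0, nrow = n_cod + nrow(candidates), ncol = length(types),
                       dimnames = list(c(coding_genes,
                                         candidates$transcript_id), types))

    cod_base <- exp(rnorm(n_cod, log(300), 0.5))
    mean_mat[coding_genes, ] <- cod_base
    mean_mat[coding_genes[is_ig_gene], ] <- cod_base[is_ig_gene] * 0.3
    pc_types <- intersect(c("TPC", "BMPC"), types) %||% tail(types, 2)
    mean_mat[coding_genes[is_ig_gene], pc_types] <- cod_base[is_ig_gene] * 30

    non_ig <- coding_genes[!is_ig_gene]
    n_de <- round(config$de_fraction * length(non_ig))
    de_genes <- sample(non_ig, n_de)
    de_sign <- rep(c(1, -1), length.out = n_de)
    contrast <- types[1:2]
    mean_mat[de_genes, contrast[2]] <-
      mean_mat[de_genes, contrast[2]] * 2^(de_sign * config$de_log2fc)
    de_truth <- tibble(gene = de_genes,
                       planted_log2fc = de_sign * config$de_log2fc)

    pass_ids <- truth$transcript_id[truth$true_fate == "pass"]
    other_ids <- setdiff(candidates$transcript_id, pass_ids)
    lnc_base <- setNames(exp(rnorm(length(pass_ids), log(80), 0.5)), pass_ids)

    n_tau <- min(config$n_high_tau, length(pass_ids))
    tau_ids <- sample(pass_ids, n_tau)
    tau_type <- setNames(rep(types, length.out = n_tau), tau_ids)
    arche_ids <- setdiff(pass_ids, tau_ids)
    k_arch <- config$n_trajectory_clusters
    arch_assign <- setNames(rep(seq_len(k_arch), length.out = length(arche_ids)),
                            arche_ids)
    arch_use <- arche[rep(seq_len(nrow(arche)),
                          length.out = k_arch)[seq_len(k_arch)], , drop = FALSE]

    for (id in arche_ids) {
      mean_mat[id, ] <- lnc_base[id] * arch_use[arch_assign[id], ]
    }
    for (id in tau_ids) {
      mean_mat[id, tau_type[id]] <- lnc_base[id]
    }
    # lncRNAs near planted DE coding genes co-vary with their anchor
    de_anchor <- coding |>
      filter(.data$gene_id %in% de_genes) |>
      distinct(.data$gene_id, .keep_all = TRUE) |>
      select("gene_id", "chrom", anchor_tss = "tss") |>
      left_join(de_truth, by = c(gene_id = "gene"))
    coupled <- candidates |>
      filter(.data$transcript_id %in% arche_ids) |>
      select("transcript_id", "chrom", "tss") |>
      inner_join(de_anchor, by = "chrom", relationship = "many-to-many") |>
      mutate(d = abs(.data$tss - .data$anchor_tss)) |>
      filter(.data$d < 75000) |>
      group_by(.data$transcript_id) |>
      slice_min(.data$d, n = 1, with_ties = FALSE) |>
      ungroup()
    for (i in seq_len(nrow(coupled))) {
      id <- coupled$transcript_id[i]
      mean_mat[id, ] <- lnc_base[id]
      mean_mat[id, contrast[2]] <-
        lnc_base[id] * 2^(sign(coupled$planted_log2fc[i]) * 2.5)
    }
    mean_mat[other_ids, ] <- 60
    low_ids <- truth$transcript_id[truth$category == "low_expression"]
    mean_mat[low_ids, ] <- 0

    mu <- mean_mat[, samples$cell_type, drop = FALSE]
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                     nrow = nrow(mu), dimnames = list(rownames(mean_mat),
                                                      samples$sample))
    # floor the designated population so expression fates are deterministic
    floor_type <- c(
      setNames(types[apply(mean_mat[arche_ids, , drop = FALSE], 1, which.max)],
               arche_ids),
      tau_type,
      setNames(rep(types[1], length(other_ids)), other_ids))
    floor_type <- floor_type[setdiff(names(floor_type), low_ids)]
    for (id in names(floor_type)) {
      cols <- samples$sample[samples$cell_type == floor_type[[id]]]
      counts[id, cols] <- pmax(counts[id, cols], 5L)
    }
    counts[low_ids, ] <- 0L
    counts[low_ids, samples$sample[1:2]] <- 50L

    cod_len <- coding |>
      group_by(.data$gene_id) |>
      summarise(len = sum(.data$mature_length), .groups = "drop")
    lengths <- c(setNames(cod_len$len, cod_len$gene_id),
                 setNames(candidates$mature_length,
                          candidates$transcript_id))
    lengths <- lengths[rownames(counts)]

    # ---- per-ORF coding-potential scores --------------------------------
    target_max <- ifelse(truth$category == "coding_potential",
                         runif(nrow(truth), 0.5, 4),
                         runif(nrow(truth), -5, -0.5))
    orf_scores <- tibble(transcript_id = rep(truth$transcript_id, each = 3),
                         orf = rep(1:3, nrow(truth)),
                         score = as.vector(vapply(target_max, function(m) {
                           s <- m - c(0, runif(2, 0.5, 3))
                           s[sample(3)]
                         }, numeric(3))))

    truth <- truth |>
      mutate(trajectory_cluster = unname(arch_assign[.data$transcript_id]),
             high_tau = .data$transcript_id %in% tau_ids,
             tau_type = unname(tau_type[.data$transcript_id]),
             coupled_anchor = NA_character_)
    truth$trajectory_cluster[truth$transcript_id %in% coupled$transcript_id] <- NA
    truth$coupled_anchor[match(coupled$transcript_id, truth$transcript_id)] <-
      coupled$gene_id

    list(candidates = candidates, counts = counts, lengths = lengths,
         samples = samples, orf_scores = orf_scores,
         truth = list(transcripts = truth, de = de_truth,
                      coupled = coupled[c("transcript_id", "gene_id",
                                          "planted_log2fc", "d")],
                      contrast = contrast, layout = layout,
                      se_with_erna = se_with_erna),
         repeats = repeats_all)
  })
}

#' Summarise per-ORF coding scores into per-transcript maxima
#'
#' @param orf_scores Tibble with `transcript_id`, `orf`, `score` (per-codon
#'   or per-ORF scores).
#' @return A tibble with `transcript_id`, `max_coding_score`.
#' @export
summarise_coding_scores <- function(orf_scores) {
  orf_scores |>
    group_by(.data$transcript_id) |>
    summarise(max_coding_score = coding_potential_max(
      split(.data$score, .data$orf)), .groups = "drop")
}

# max-resolved flattening of possibly overlapping constant segments
flatten_segments <- function(segs) {
  segs <- segs[segs$end > segs$start, ]
  if (nrow(segs) == 0) return(segs)
  gr <- as_granges(segs)
  dj <- GenomicRanges::disjoin(gr)
  hits <- GenomicRanges::findOverlaps(dj, gr)
  vals <- vapply(split(segs$value[S4Vectors::subjectHits(hits)],
                       S4Vectors::queryHits(hits)), max, numeric(1))
  out <- as_interval_tbl(dj)
  out$value <- unname(vals[as.character(seq_len(nrow(out)))])
  out
}

#' Generate chromatin peaks, signal tracks, and planted classes
#'
#' Assigns each novel lncRNA TSS a chromatin class (eRNA-planted loci are
#' enhancer-class), builds per-mark fold-change signal tracks with high
#' plateaus over the class-defining marks in the TSS window and low noise
#' elsewhere, and emits H3K4me1/H3K27ac peak sets realising the planted
#' enhancers (active and poised, all >= 2500 bp from coding TSSs) and
#' super-enhancer neighborhoods (clustered high-signal H3K27ac peaks).
#'
#' @param gen Output of [generate_genome()].
#' @param cand Output of [generate_candidates_and_expression()].
#' @param config A [synthetic_config()].
#' @return A list: `peaks` (named list of peak tibbles; `H3K27ac` carries
#'   `signal`), `tracks` (named list of [signal_track()]s), `truth`
#'   (`classes`, `enhancers`, `se_areas`).
#' @export
generate_chromatin <- function(gen, cand, config) {
  withr::with_seed(config$seed + 303L, {
    genome <- gen$genome
    tr_truth <- cand$truth$transcripts
    layout <- cand$truth$layout
    marks <- c("H3K4me1", "H3K4me2", "H3K4me3", "H3K27ac", "H3K27me3",
               "DNase", "CTCF", "EP300", "CREBBP", "MED1", "BRD4",
               "FOXO1", "FOXP1")
    class_marks <- list(
      enhancer = c("H3K4me1", "H3K27ac", "DNase", "EP300", "MED1", "BRD4",
                   "CREBBP", "FOXO1", "FOXP1"),
      promoter = c("H3K4me3", "H3K4me2", "H3K27ac", "DNase"),
      bivalent = c("H3K4me3", "H3K27me3"),
      ctcf = "CTCF",
      repressed = "H3K27me3",
      featureless = character())

    pass <- tr_truth[tr_truth$true_fate == "pass", ]
    props <- config$chromatin_proportions
    cls <- character(nrow(pass))
    cls[pass$erna] <- "enhancer"
    free <- which(!pass$erna)
    pool <- sample(rep(names(props), ceiling(props * length(free) + 1)))
    cls[free] <- pool[seq_along(free)]
    classes <- tibble(transcript_id = pass$transcript_id,
                      chrom = pass$chrom, tss = pass$tss,
                      chromatin_class = cls)

    # plateau segments per mark at each lncRNA TSS
    plateau <- map(set_names(marks), function(m) {
      sel <- classes[map_lgl(classes$chromatin_class,
                             function(cc) m %in% class_marks[[cc]]), ]
      if (nrow(sel) == 0) return(empty_intervals() |> mutate(value = numeric()))
      tibble(chrom = sel$chrom, start = pmax(0L, sel$tss - 1200L),
             end = sel$tss + 1201L, value = runif(nrow(sel), 7, 10))
    })

    # planted enhancers: at eRNA TSSs (all active), standalone areas;
    # SE-resident eRNAs are covered by the constituent peaks below
    erna_loci <- classes |>
      inner_join(select(pass, "transcript_id", "se_area"),
                 by = "transcript_id") |>
      filter(.data$transcript_id %in% pass$transcript_id[pass$erna],
             is.na(.data$se_area))
    k4_erna <- tibble(chrom = erna_loci$chrom,
                      start = erna_loci$tss - 400L, end = erna_loci$tss + 400L,
                      class = "active", has_erna = TRUE,
                      se_area = erna_loci$se_area)
    stand <- layout$enhancer_areas
    stand_active <- runif(nrow(stand)) < 0.6
    k4_stand <- tibble(chrom = stand$chrom, start = stand$center - 400L,
                       end = stand$center + 400L,
                       class = ifelse(stand_active, "active", "poised"),
                       has_erna = FALSE, se_area = NA_character_)

    # super-enhancer constituents: 4 high peaks per reserved area; the
    # first sits on the resident eRNA TSS when the area has one
    se_cons <- layout$se_areas |>
      pmap(function(chrom, start, end, se_id) {
        centers <- as.integer(start + 2000L + c(0L, 8000L, 16000L, 24000L))
        tibble(chrom = chrom, start = centers - 400L, end = centers + 400L,
               se_id = se_id)
      }) |>
      list_rbind()

    k4me1 <- bind_rows(k4_erna[c("chrom", "start", "end")],
                       k4_stand[c("chrom", "start", "end")],
                       se_cons[c("chrom", "start", "end")]) |>
      arrange(.data$chrom, .data$start)
    k27ac <- bind_rows(
      tibble(chrom = erna_loci$chrom, start = erna_loci$tss - 250L,
             end = erna_loci$tss + 250L,
             signal = runif(nrow(erna_loci), 10, 80)),
      tibble(chrom = stand$chrom[stand_active],
             start = stand$center[stand_active] - 250L,
             end = stand$center[stand_active] + 250L,
             signal = runif(sum(stand_active), 10, 80)),
      mutate(se_cons[c("chrom", "start", "end")],
             signal = runif(nrow(se_cons), 400, 600))) |>
      arrange(.data$chrom, .data$start)

    enhancer_truth <- bind_rows(
      k4_erna, k4_stand,
      mutate(se_cons[c("chrom", "start", "end")], class = "active",
             has_erna = FALSE, se_area = se_cons$se_id)) |>
      arrange(.data$chrom, .data$start)

    # signal plateaus over enhancer peaks too, then noise; resolve overlaps
    enh_sig <- function(p) mutate(p[c("chrom", "start", "end")],
                                  value = runif(nrow(p), 6, 12))
    noise <- function() {
      n <- 400L * config$n_chroms
      ch <- sample(genome$chrom_sizes$chrom, n, replace = TRUE)
      s <- as.integer(floor(runif(n) * (config$chrom_length - 500L)))
      tibble(chrom = ch, start = s, end = s + 500L,
             value = runif(n, 0.05, 0.4))
    }
    tracks <- imap(plateau, function(p, m) {
      extra <- switch(m,
        H3K4me1 = enh_sig(k4me1),
        H3K27ac = enh_sig(k27ac),
        NULL)
      signal_track(flatten_segments(bind_rows(p, extra, noise())), mark = m)
    })

    peaks <- list(H3K4me1 = k4me1, H3K27ac = k27ac)
    se_truth <- layout$se_areas |>
      mutate(with_erna = .data$se_id %in% cand$truth$se_with_erna)
    list(peaks = peaks, tracks = tracks,
         truth = list(classes = classes, enhancers = enhancer_truth,
                      se_areas = se_truth))
  })
}

#' Generate stranded read-start coverage with planted bidirectional loci
#'
#' Intergenic novel lncRNAs are split into bidirectional loci (a planted
#' fraction) and unidirectional loci. Bidirectional loci receive
#' forward-strand read starts in the left flanking window and
#' reverse-strand read starts in the right window (the configuration the
#' bidirectionality score rewards); unidirectional loci receive a single
#' strand on a single side. Sparse background read starts are scattered
#' genome-wide.
#'
#' @param gen Output of [generate_genome()].
#' @param cand Output of [generate_candidates_and_expression()].
#' @param config A [synthetic_config()]; `fraction_bidirectional` sets the
#'   planted fraction.
#' @param w,l Window geometry matching [bidirectionality_score()].
#' @return A list: `coverage` (a [stranded_coverage()]) and `truth`
#'   (tibble `transcript_id`, `tss`, `bidirectional`).
#' @export
generate_stranded_coverage <- function(gen, cand, config, w = 100, l = 7) {
  withr::with_seed(config$seed + 404L, {
    tr <- cand$truth$transcripts
    loci <- tr[tr$true_fate == "pass" & tr$true_class == "intergenic", ]
    n <- nrow(loci)
    bid <- runif(n) < config$fraction_bidirectional
    pos_counts <- list(plus = list(), minus = list())
    scatter <- function(lo, hi, total) {
      pos <- lo + sort(sample.int(hi - lo, 10)) - 1L
      cnt <- as.vector(stats::rmultinom(1, total, rep(1 / 10, 10)))
      tibble(start = pos, count = cnt)[cnt > 0, ]
    }
    add_reads <- function(strand, chrom, seg) {
      key <- if (strand == "+") "plus" else "minus"
      seg$chrom <- chrom
      pos_counts[[key]][[length(pos_counts[[key]]) + 1]] <<- seg
    }
    for (i in seq_len(n)) {
      g <- loci$tss[i]
      left <- c(g - w * l, g - w)
      right <- c(g + w, g + w * l)
      if (bid[i]) {
        add_reads("+", loci$chrom[i], scatter(left[1], left[2], 150L))
        add_reads("-", loci$chrom[i], scatter(right[1], right[2], 150L))
      } else if (loci$strand[i] == "+") {
        add_reads("+", loci$chrom[i], scatter(right[1], right[2], 150L))
      } else {
        add_reads("-", loci$chrom[i], scatter(left[1], left[2], 150L))
      }
    }
    # sparse background on both strands
    for (key in c("plus", "minus")) {
      nbg <- 750L
      pos_counts[[key]][[length(pos_counts[[key]]) + 1]] <-
        tibble(chrom = sample(gen$genome$chrom_sizes$chrom, nbg,
                              replace = TRUE),
               start = as.integer(floor(runif(nbg) *
                                        (config$chrom_length - 1))),
               count = 1L)
    }
    to_track <- function(lst, nm) {
      seg <- list_rbind(lst) |>
        group_by(.data$chrom, .data$start) |>
        summarise(value = sum(.data$count), .groups = "drop") |>
        mutate(end = .data$start + 1L) |>
        select("chrom", "start", "end", "value")
      signal_track(seg, mark = nm)
    }
    coverage <- stranded_coverage(to_track(pos_counts$plus, "plus"),
                                  to_track(pos_counts$minus, "minus"))
    list(coverage = coverage,
         truth = tibble(transcript_id = loci$transcript_id, chrom = loci$chrom,
                        tss = loci$tss, bidirectional = bid))
  })
}

#' Generate circRNA back-splice junction tables
#'
#' Ig-derived junctions (span inside the Ig locus) are expressed high only
#' in plasma-cell samples; non-Ig junctions are flat across populations;
#' a planted set sits below the read-support filter (4 reads in 5
#' samples).
#'
#' @param gen Output of [generate_genome()].
#' @param samples Sample map tibble (`sample`, `cell_type`).
#' @param config A [synthetic_config()].
#' @return A list: `junctions` (tibble `junction_id`, `chrom`, `donor`,
#'   `acceptor` + per-sample counts) and `truth` (tibble with `ig` and
#'   `fate`).
#' @export
generate_circ_junctions <- function(gen, samples, config) {
  withr::with_seed(config$seed + 505L, {
    ig <- gen$genome$ig_loci[1, ]
    pc_types <- intersect(c("TPC", "BMPC"), config$cell_types)
    n_ig <- config$n_circ_ig
    n_other <- config$n_circ_other
    n_sub <- config$n_circ_subthreshold

    mk_counts <- function(mu_by_type) {
      mu <- mu_by_type[samples$cell_type]
      rnbinom(nrow(samples), mu = mu, size = 1 / config$dispersion)
    }
    flat_mu <- function(v) setNames(rep(v, length(config$cell_types)),
                                    config$cell_types)
    rows <- list()
    for (i in seq_len(n_ig)) {
      d <- as.integer(ig$start + floor(runif(1) * (config$ig_locus_span - 25000)))
      mu <- flat_mu(2); mu[pc_types] <- 100
      rows[[length(rows) + 1]] <- c(list(junction_id = sprintf("circ_ig_%02d", i),
                                         chrom = ig$chrom, donor = d,
                                         acceptor = d + 2000L +
                                           as.integer(floor(runif(1) * 18000))),
                                    as.list(setNames(mk_counts(mu),
                                                     samples$sample)))
    }
    other_chroms <- setdiff(gen$genome$chrom_sizes$chrom, ig$chrom)
    for (i in seq_len(n_other)) {
      ch <- sample(other_chroms, 1)
      d <- as.integer(floor(runif(1) * (config$chrom_length - 30000)))
      rows[[length(rows) + 1]] <- c(list(junction_id = sprintf("circ_%02d", i),
                                         chrom = ch, donor = d,
                                         acceptor = d + 2000L +
                                           as.integer(floor(runif(1) * 18000))),
                                    as.list(setNames(mk_counts(flat_mu(20)),
                                                     samples$sample)))
    }
    for (i in seq_len(n_sub)) {
      ch <- sample(other_chroms, 1)
      d <- as.integer(floor(runif(1) * (config$chrom_length - 30000)))
      cnt <- setNames(rep(0L, nrow(samples)), samples$sample)
      cnt[seq_len(min(5, length(cnt)))] <- 4L
      rows[[length(rows) + 1]] <- c(list(junction_id = sprintf("circ_sub_%02d", i),
                                         chrom = ch, donor = d,
                                         acceptor = d + 3000L),
                                    as.list(cnt))
    }
    junctions <- list_rbind(map(rows, as_tibble))
    cnt <- as.matrix(junctions[samples$sample])
    truth <- tibble(
      junction_id = junctions$junction_id,
      ig = overlaps_any(tibble(chrom = junctions$chrom,
                               start = junctions$donor,
                               end = junctions$acceptor),
                        gen$genome$ig_loci),
      fate = ifelse(rowSums(cnt >= 5) >= 3, "kept", "filtered"))
    list(junctions = junctions, truth = truth)
  })
}

#' Run the full synthetic generator
#'
#' Generates the genome, candidates and expression, chromatin, stranded
#' coverage, and circRNA junctions from one seeded configuration, and
#' optionally writes every artifact in the formats the readers consume
#' (GTF, BED, bedGraph, chrom.sizes, TSV matrices, ground_truth.json).
#'
#' @param config A [synthetic_config()].
#' @param out_dir Optional output directory.
#' @return A list of class `synthetic_atlas` with elements `genome`,
#'   `coding`, `candidates`, `counts`, `lengths`, `samples`, `orf_scores`,
#'   `peaks`, `tracks`, `coverage`, `junctions`, `truth`, `config`.
#' @export
simulate_atlas <- function(config = synthetic_config(), out_dir = NULL) {
  gen <- generate_genome(config)
  cand <- generate_candidates_and_expression(gen, config)
  gen$genome$repeats <- cand$repeats
  chrom <- generate_chromatin(gen, cand, config)
  cov <- generate_stranded_coverage(gen, cand, config)
  circ <- generate_circ_junctions(gen, cand$samples, config)

  truth <- c(cand$truth,
             list(chromatin = chrom$truth, bidirectional = cov$truth,
                  circ = circ$truth))
  atlas <- structure(
    list(genome = gen$genome, coding = gen$coding,
         candidates = cand$candidates, counts = cand$counts,
         lengths = cand$lengths, samples = cand$samples,
         orf_scores = cand$orf_scores, peaks = chrom$peaks,
         tracks = chrom$tracks, coverage = cov$coverage,
         junctions = circ$junctions, truth = truth, config = config),
    class = "synthetic_atlas")
  if (!is.null(out_dir)) write_atlas(atlas, out_dir)
  atlas
}

#' @export
print.synthetic_atlas <- function(x, ...) {
  cat("<synthetic_atlas> ", nrow(x$candidates), " candidates, ",
      nrow(x$samples), " samples, ", length(x$tracks), " tracks, ",
      nrow(x$junctions), " circRNA junctions (seed ", x$config$seed, ")\n",
      sep = "")
  invisible(x)
}

#' Write a synthetic atlas to disk
#'
#' @param atlas A [simulate_atlas()] result.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_atlas <- function(atlas, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(atlas$genome$chrom_sizes, p("genome.chrom.sizes"),
                   col_names = FALSE)
  write_bed(atlas$genome$repeats, p("repeats.bed"))
  write_bed(atlas$genome$ig_loci, p("ig_loci.bed"))
  write_annotation(atlas$coding, p("coding.gtf"))
  write_annotation(atlas$candidates, p("candidates.gtf"))
  write_expression_tsv(atlas$counts, p("counts.tsv"))
  readr::write_tsv(atlas$samples, p("sample_map.tsv"))
  readr::write_tsv(atlas$orf_scores, p("coding_scores.tsv"))
  readr::write_tsv(tibble(gene = names(atlas$lengths),
                          length = unname(atlas$lengths)),
                   p("gene_lengths.tsv"))
  iwalk(atlas$peaks, function(pk, nm) {
    write_bed(pk, p(paste0("peaks_", nm, ".bed")))
  })
  dir.create(p("tracks"), showWarnings = FALSE)
  iwalk(atlas$tracks, function(tr, nm) {
    write_bedgraph(tr, p("tracks", paste0(nm, ".bedGraph")))
  })
  write_bedgraph(atlas$coverage$plus, p("coverage_plus.bedGraph"))
  write_bedgraph(atlas$coverage$minus, p("coverage_minus.bedGraph"))
  readr::write_tsv(atlas$junctions, p("circ_junctions.tsv"))
  truth_out <- atlas$truth
  truth_out$layout <- NULL
  jsonlite::write_json(truth_out, p("ground_truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(out_dir)
}

#' Generate a two-group count matrix with planted differential expression
#'
#' A focused generator for calibrating the differential-expression
#' stand-in: `n_genes` negative-binomial genes over two groups of
#' `n_per_group` samples, a planted fraction carrying |log2FC| =
#' `log2fc` (alternating sign), the rest null. The default dispersion is
#' the low-dispersion calibration setting under which an 8-fold planted
#' change is unambiguous at 3 replicates.
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_per_group Samples per group (default 5; the study's populations
#'   carry 3-5 donors, and Welch's small-sample degrees of freedom need
#'   replication for q < 0.01 calls to be reachable at all).
#' @param de_fraction Fraction of genes planted DE (default 0.05; 0 gives
#'   a pure null matrix).
#' @param log2fc Planted |log2FC| (default 3).
#' @param base_mean Mean count scale (default 200).
#' @param dispersion NB dispersion (default 0.01).
#' @param seed Integer seed.
#' @return A list: `counts` (matrix), `lengths` (all 1000 bp), `samples`
#'   (groups `A`/`B`), `truth` (tibble `gene`, `planted_log2fc`).
#' @export
generate_de_counts <- function(n_genes = 2000, n_per_group = 5,
                               de_fraction = 0.05, log2fc = 3,
                               base_mean = 200, dispersion = 0.01, seed = 1) {
  withr::with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(n_genes))
    samples <- tibble(sample = c(paste0("A_", seq_len(n_per_group)),
                                 paste0("B_", seq_len(n_per_group))),
                      cell_type = rep(c("A", "B"), each = n_per_group))
    base <- exp(rnorm(n_genes, log(base_mean), 0.4))
    n_de <- round(de_fraction * n_genes)
    de_idx <- if (n_de > 0) sample(n_genes, n_de) else integer()
    lfc <- numeric(n_genes)
    lfc[de_idx] <- rep(c(1, -1), length.out = n_de) * log2fc
    mu <- cbind(matrix(base, n_genes, n_per_group),
                matrix(base * 2^lfc, n_genes, n_per_group))
    counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = n_genes, dimnames = list(genes, samples$sample))
    list(counts = counts,
         lengths = setNames(rep(1000, n_genes), genes),
         samples = samples,
         truth = tibble(gene = genes, planted_log2fc = lfc))
  })
}
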