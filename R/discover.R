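#' Filter parameters for novel-lncRNA discovery
#'
#' Defaults follow the discovery cascade's published thresholds: transcripts
#' at least 200 nt long, expressed above 1 TPM in at least three samples,
#' overlapping repetitive elements over less than 75% of their mature
#' length, and with a maximum coding-potential score of at most 0 (scores
#' strictly above 0 are filtered out).
#'
#' @param min_length Minimum mature (summed exon) length in nt; `>=` passes.
#' @param min_tpm Expression threshold in TPM.
#' @param min_samples Minimum number of samples meeting `min_tpm`.
#' @param tpm_comparator `">"` (novel-discovery wording) or `">="` (expressed
#'   universe wording); both thresholds appear in the source methods.
#' @param max_repeat_fraction Repeat-overlap fraction bound; `<` passes.
#' @param max_coding_score Coding-potential bound; `<=` passes.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_length = 200, min_tpm = 1, min_samples = 3,
                          tpm_comparator = c(">", ">="),
                          max_repeat_fraction = 0.75, max_coding_score = 0) {
  tpm_comparator <- match.arg(tpm_comparator)
  stopifnot(min_length >= 0, min_tpm >= 0, min_samples >= 1,
            max_repeat_fraction >= 0)
  structure(list(min_length = min_length, min_tpm = min_tpm,
                 min_samples = min_samples, tpm_comparator = tpm_comparator,
                 max_repeat_fraction = max_repeat_fraction,
                 max_coding_score = max_coding_score),
            class = "filter_params")
}

#' Maximum coding potential across ORFs
#'
#' Per-codon coding-potential scores are computed for the three forward
#' ORFs of a transcript; the transcript's coding potential is the single
#' maximum score over all codons of all ORFs.
#'
#' @param orf_scores A list of numeric vectors (per-codon scores, one vector
#'   per ORF). Empty vectors are allowed as long as one ORF is non-empty.
#' @return The maximum score (numeric scalar).
#' @export
coding_potential_max <- function(orf_scores) {
  if (!is.list(orf_scores)) orf_scores <- list(orf_scores)
  values <- unlist(orf_scores, use.names = FALSE)
  if (length(values) == 0) abort("all ORF score sequences are empty")
  max(values)
}

#' Positional classification of a candidate against the coding catalog
#'
#' Novel transcripts are retained only when intergenic or antisense:
#' candidates whose exons overlap a same-strand coding exon are
#' sense-overlapping isoforms; candidates inside a same-strand gene span
#' without exon overlap are intronic; both are rejected as hard to separate
#' from transcriptional artifacts. Any overlap with an opposite-strand gene
#' span makes a candidate antisense; no overlap at all, intergenic.
#'
#' @param candidates A [transcript_catalog()] of candidates.
#' @param coding A [transcript_catalog()] of coding genes.
#' @return A tibble with `transcript_id` and `position_class` in
#'   `c("sense_overlap", "intronic", "antisense", "intergenic")`.
#' @export
classify_position <- function(candidates, coding) {
  spans <- coding |>
    group_by(.data$gene_id) |>
    summarise(chrom = .data$chrom[1], strand = .data$strand[1],
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  coding_ex <- catalog_exons(coding)

  cand_spans <- candidates |> select("transcript_id", "chrom", "strand", "start", "end")
  cand_ex <- catalog_exons(candidates)

  same_strand_pairs <- function(a, b) {
    hits <- overlap_pairs(a, b)
    hits[a$strand[hits$i] == b$strand[hits$j], , drop = FALSE]
  }
  # exon-level same-strand overlap -> sense_overlap
  so_hits <- same_strand_pairs(cand_ex, coding_ex)
  sense_ids <- unique(cand_ex$transcript_id[so_hits$i])
  # span-level same-strand overlap (without exon overlap) -> intronic
  sp_hits <- same_strand_pairs(cand_spans, spans)
  intronic_ids <- setdiff(unique(cand_spans$transcript_id[sp_hits$i]), sense_ids)
  # any opposite-strand span overlap -> antisense
  as_hits <- overlap_pairs(cand_spans, spans)
  as_hits <- as_hits[cand_spans$strand[as_hits$i] != spans$strand[as_hits$j], ,
                     drop = FALSE]
  antisense_ids <- setdiff(unique(cand_spans$transcript_id[as_hits$i]),
                           c(sense_ids, intronic_ids))

  tibble(transcript_id = candidates$transcript_id) |>
    mutate(position_class = case_when(
      .data$transcript_id %in% sense_ids ~ "sense_overlap",
      .data$transcript_id %in% intronic_ids ~ "intronic",
      .data$transcript_id %in% antisense_ids ~ "antisense",
      TRUE ~ "intergenic"))
}

#' Fraction of a transcript's mature length covered by repeats
#'
#' Repeats are merged first, so duplicated repeat records do not inflate the
#' fraction; the result is total exon-repeat intersection bp divided by the
#' mature (summed exon) length.
#'
#' @param catalog A [transcript_catalog()].
#' @param repeats Repeat intervals (`chrom`, `start`, `end`).
#' @return A tibble with `transcript_id` and `repeat_fraction` in \[0, 1\].
#' @export
repeat_overlap_fraction <- function(catalog, repeats) {
  merged <- merge_intervals(repeats[c("chrom", "start", "end")])
  ex <- catalog_exons(catalog)
  if (nrow(merged) == 0) {
    return(tibble(transcript_id = catalog$transcript_id, repeat_fraction = 0))
  }
  hits <- overlap_pairs(ex, merged)
  ov <- if (nrow(hits)) {
    tibble(transcript_id = ex$transcript_id[hits$i],
           bp = pmin(ex$end[hits$i], merged$end[hits$j]) -
                pmax(ex$start[hits$i], merged$start[hits$j])) |>
      group_by(.data$transcript_id) |>
      summarise(bp = sum(.data$bp), .groups = "drop")
  } else {
    tibble(transcript_id = character(), bp = integer())
  }
  catalog |>
    select("transcript_id", "mature_length") |>
    left_join(ov, by = "transcript_id") |>
    mutate(repeat_fraction = coalesce(.data$bp, 0L) / .data$mature_length) |>
    select("transcript_id", "repeat_fraction")
}

#' Transcripts expressed above a TPM threshold in enough samples
#'
#' @param tpm A genes-by-samples TPM matrix.
#' @param min_tpm TPM threshold (default 1).
#' @param min_samples Minimum number of qualifying samples (default 3).
#' @param comparator `">="` (at least `min_tpm`; expressed-universe rule) or
#'   `">"` (strictly above; novel-discovery rule).
#' @param samples Optional sample map (`sample`, `cell_type`) used with
#'   `cell_type` to restrict the scope to one population's samples.
#' @param cell_type Optional cell type defining the scope.
#' @return Character vector of expressed gene/transcript IDs.
#' @export
expressed_set <- function(tpm, min_tpm = 1, min_samples = 3,
                          comparator = c(">=", ">"),
                          samples = NULL, cell_type = NULL) {
  comparator <- match.arg(comparator)
  if (!is.null(cell_type)) {
    if (is.null(samples)) abort("supply `samples` to scope by cell type")
    keep <- samples$sample[samples$cell_type == cell_type]
    if (length(keep) == 0) abort(paste("no samples for cell type", cell_type))
    tpm <- tpm[, keep, drop = FALSE]
  }
  hits <- if (comparator == ">=") tpm >= min_tpm else tpm > min_tpm
  rownames(tpm)[rowSums(hits) >= min_samples]
}

#' Apply the novel-lncRNA discovery cascade
#'
#' Candidates are filtered, in order: mature length, expression, repeat
#' overlap, coding potential, then positional classification. Every
#' candidate receives exactly one verdict; the recorded reason is the first
#' failing rule, so reason bucket counts depend on this fixed order.
#' Survivors are labelled `antisense` or `intergenic`.
#'
#' @param candidates Candidate [transcript_catalog()].
#' @param tpm Genes-by-samples TPM matrix covering the candidates.
#' @param repeats Repeat intervals.
#' @param coding_scores Tibble with `transcript_id` and `max_coding_score`
#'   (see [coding_potential_max()]).
#' @param coding Coding-gene [transcript_catalog()].
#' @param params A [filter_params()].
#' @return A list of class `lnc_filter`: `catalog` (the passing novel
#'   lncRNAs, with `position_class`) and `verdicts` (one row per candidate:
#'   `transcript_id`, `pass`, `reason`, `position_class`, `mature_length`,
#'   `n_expressed_samples`, `repeat_fraction`, `max_coding_score`).
#' @export
filter_novel_lncrnas <- function(candidates, tpm, repeats, coding_scores,
                                 coding, params = filter_params()) {
  n_expr <- {
    present <- intersect(candidates$transcript_id, rownames(tpm))
    m <- tpm[present, , drop = FALSE]
    hits <- if (params$tpm_comparator == ">") m > params$min_tpm else m >= params$min_tpm
    setNames(rowSums(hits), present)
  }
  rf <- repeat_overlap_fraction(candidates, repeats)
  pos <- classify_position(candidates, coding)

  verdicts <- candidates |>
    select("transcript_id", "mature_length") |>
    left_join(rf, by = "transcript_id") |>
    left_join(pos, by = "transcript_id") |>
    left_join(coding_scores[c("transcript_id", "max_coding_score")],
              by = "transcript_id") |>
    mutate(n_expressed_samples = as.integer(n_expr[.data$transcript_id])) |>
    mutate(reason = case_when(
      is.na(.data$n_expressed_samples) | is.na(.data$max_coding_score) ~ "missing_data",
      .data$mature_length < params$min_length ~ "too_short",
      .data$n_expressed_samples < params$min_samples ~ "low_expression",
      .data$repeat_fraction >= params$max_repeat_fraction ~ "repeat_overlap",
      .data$max_coding_score > params$max_coding_score ~ "coding_potential",
      .data$position_class == "sense_overlap" ~ "sense_overlap",
      .data$position_class == "intronic" ~ "intronic",
      TRUE ~ ""),
      pass = .data$reason == "") |>
    mutate(position_class = ifelse(.data$pass, .data$position_class, NA_character_)) |>
    select("transcript_id", "pass", "reason", "position_class",
           "mature_length", "n_expressed_samples", "repeat_fraction",
           "max_coding_score")

  novel <- candidates |>
    filter(.data$transcript_id %in% verdicts$transcript_id[verdicts$pass]) |>
    mutate(biotype = "novel_lncRNA") |>
    left_join(verdicts[c("transcript_id", "position_class")],
              by = "transcript_id")
  class(novel) <- unique(c("transcript_catalog", class(novel)))
  structure(list(catalog = novel, verdicts = verdicts, params = params),
            class = "lnc_filter")
}

#' @export
print.lnc_filter <- function(x, ...) {
  cat("<lnc_filter> ", sum(x$verdicts$pass), " novel lncRNAs of ",
      nrow(x$verdicts), " candidates\n", sep = "")
  print(count(x$verdicts, .data$reason, .data$position_class))
  invisible(x)
}

#' Fraction of the genome transcribed, by element category
#'
#' Each genomic base covered by an expressed element is assigned to the
#' highest-precedence category covering it (by default coding > lncRNA >
#' other ncRNA > other), and fractions are reported against total genome
#' size. Only exonic unions are counted by default; `use_spans = TRUE`
#' counts full transcript extents (including introns) instead.
#'
#' @param catalogs A *named* list of [transcript_catalog()]s in decreasing
#'   precedence order (e.g. `list(coding = ..., lncRNA = ...)`), each
#'   already restricted to expressed elements.
#' @param genome A [genome_model()].
#' @param use_spans Count full transcript spans instead of exon unions.
#' @return A tibble with `category`, `bp`, `fraction`, plus a `total` row.
#' @export
classify_transcribed_bases <- function(catalogs, genome, use_spans = FALSE) {
  stopifnot(is.list(catalogs), !is.null(names(catalogs)))
  total_bp <- sum(as.numeric(genome$chrom_sizes$length))
  assigned <- GenomicRanges::GRanges()
  rows <- imap(catalogs, function(cat_i, name) {
    ivs <- if (use_spans) {
      cat_i[c("chrom", "start", "end")]
    } else {
      catalog_exons(cat_i)[c("chrom", "start", "end")]
    }
    u <- GenomicRanges::reduce(as_granges(ivs))
    new_bp <- suppressWarnings(
      sum(GenomicRanges::width(GenomicRanges::setdiff(u, assigned))))
    assigned <<- suppressWarnings(
      GenomicRanges::reduce(GenomicRanges::union(assigned, u)))
    tibble(category = name, bp = as.numeric(new_bp))
  })
  out <- list_rbind(rows)
  out <- bind_rows(out, tibble(category = "total", bp = sum(out$bp)))
  mutate(out, fraction = .data$bp / total_bp)
}
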