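#' Build a transcript catalog from exon records
#'
#' The transcript catalog is the package's central container for transcript
#' models: one row per transcript with an `exons` list-column. Coordinates
#' are 0-based half-open. The TSS is the leftmost coordinate on the `+`
#' strand and the half-open end coordinate (insertion point) on the `-`
#' strand, so TSS +/- w windows are symmetric in genome space on both
#' strands.
#'
#' @param exons A data frame with one row per exon and columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open) and optionally `biotype`.
#' @return A tibble of class `transcript_catalog` with columns
#'   `transcript_id`, `gene_id`, `chrom`, `strand`, `biotype`, `start`,
#'   `end` (transcript span), `tss`, `n_exons`, `mature_length`, and the
#'   `exons` list-column (two-column integer matrices).
#' @export
transcript_catalog <- function(exons) {
  exons <- as_tibble(exons)
  need <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(exons))) {
    abort(paste("exon table needs columns:", paste(need, collapse = ", ")))
  }
  if (!"biotype" %in% names(exons)) exons$biotype <- "novel_candidate"
  if (nrow(exons) == 0) abort("transcript with zero exons: empty exon table")
  if (!all(exons$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (any(exons$start >= exons$end)) abort("exon with start >= end")

  cat_tbl <- exons |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    summarise(
      gene_id = .data$gene_id[1], chrom = .data$chrom[1],
      strand = .data$strand[1], biotype = .data$biotype[1],
      n_exons = dplyr::n(),
      mature_length = sum(.data$end - .data$start),
      exons = list(cbind(start = .data$start, end = .data$end)),
      start = min(.data$start), end = max(.data$end),
      .groups = "drop") |>
    relocate("start", "end", .before = "n_exons") |>
    mutate(tss = ifelse(.data$strand == "+", .data$start, .data$end),
           .after = "end")

  bad <- map_lgl(cat_tbl$exons, function(e) {
    nrow(e) > 1 && any(e[-1, "start"] < e[-nrow(e), "end"])
  })
  if (any(bad)) {
    abort(paste("overlapping exons in transcript(s):",
                paste(cat_tbl$transcript_id[bad], collapse = ", ")))
  }
  class(cat_tbl) <- c("transcript_catalog", class(cat_tbl))
  cat_tbl
}

#' Flatten a transcript catalog to one row per exon
#'
#' @param catalog A [transcript_catalog()].
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `strand`, `biotype`, `start`, `end` (one row per exon).
#' @export
catalog_exons <- function(catalog) {
  if (nrow(catalog) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  biotype = character(), start = integer(), end = integer()))
  }
  catalog |>
    mutate(exons = map(.data$exons, as_tibble)) |>
    select("transcript_id", "gene_id", "chrom", "strand", "biotype", "exons") |>
    unnest("exons")
}

#' Read transcript models from a GTF/GFF file
#'
#' Exon features are grouped per transcript; GTF's 1-based closed coordinates
#' are converted to the package's 0-based half-open convention at this
#' boundary. The biotype is taken from the `gene_biotype` (or
#' `transcript_biotype`) attribute when present, else `novel_candidate`.
#'
#' @param path Path to a GTF/GFF file containing `exon` features with
#'   `transcript_id` and `gene_id` attributes.
#' @return A [transcript_catalog()].
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) abort(paste("no exon records in", path))
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id) || is.null(md$gene_id)) {
    abort("GTF exons must carry transcript_id and gene_id attributes")
  }
  biotype <- md$gene_biotype %||% md$transcript_biotype %||%
    rep("novel_candidate", length(gr))
  biotype[is.na(biotype)] <- "novel_candidate"
  transcript_catalog(tibble(
    transcript_id = md$transcript_id,
    gene_id = md$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    biotype = biotype))
}

#' Write a transcript catalog as GTF
#'
#' Emits one `exon` feature per exon, converting back to GTF's 1-based
#' closed coordinates. Output is sorted and byte-deterministic.
#'
#' @param catalog A [transcript_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(catalog, path) {
  ex <- catalog_exons(catalog) |> arrange(.data$chrom, .data$start, .data$transcript_id)
  lines <- sprintf(
    '%s\tlncatlas\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
    ex$chrom, ex$start + 1L, ex$end, ex$strand, ex$gene_id, ex$transcript_id,
    ex$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of peaks
#'
#' BED is natively 0-based half-open, matching the internal convention, so
#' coordinates pass through unchanged. A 5th column, when present, is kept
#' as `signal`.
#'
#' @param path Path to a BED3+ file. An empty file yields an empty peak set.
#' @param mark Name of the mark/factor the peaks belong to (kept as the
#'   `mark` attribute and column).
#' @param genome Optional [genome_model()]; peaks on chromosomes it does not
#'   know are dropped with a warning.
#' @return A tibble with columns `chrom`, `start`, `end`, `mark` and
#'   optionally `name`, `signal`, sorted per chromosome.
#' @export
read_peaks <- function(path, mark = "peak", genome = NULL) {
  if (file.size(path) == 0) {
    out <- empty_intervals()
    out$mark <- character()
    return(out)
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  out <- tibble(chrom = as.character(raw[[1]]),
                start = as.integer(raw[[2]]), end = as.integer(raw[[3]]))
  if (ncol(raw) >= 4) out$name <- as.character(raw[[4]])
  if (ncol(raw) >= 5) out$signal <- as.numeric(raw[[5]])
  if (any(out$start >= out$end)) abort(paste("BED interval with start >= end in", path))
  if (!is.null(genome)) {
    known <- out$chrom %in% genome$chrom_sizes$chrom
    if (!all(known)) {
      warn(sprintf("read_peaks: dropped %d record(s) on unknown chromosomes",
                   sum(!known)))
      out <- out[known, ]
    }
  }
  out$mark <- mark
  arrange(out, .data$chrom, .data$start, .data$end)
}

#' Write intervals as BED
#'
#' @param x A data frame with `chrom`, `start`, `end` and optionally `name`
#'   and `signal` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- arrange(as_tibble(x), .data$chrom, .data$start, .data$end)
  name <- if ("name" %in% names(x)) x$name else rep(".", nrow(x))
  cols <- sprintf("%s\t%d\t%d\t%s", x$chrom, x$start, x$end, name)
  if ("signal" %in% names(x)) cols <- sprintf("%s\t%g", cols, x$signal)
  writeLines(cols, path)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to a TSV with chromosome name and length columns.
#' @return A tibble with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  tibble(chrom = as.character(raw[[1]]), length = as.integer(raw[[2]]))
}

# ---------------------------------------------------------------------------
# signal tracks and stranded coverage

#' Construct a signal track
#'
#' A signal track is piecewise-constant non-negative coverage over 0-based
#' half-open segments; positions not covered by any segment read as 0.
#'
#' @param segments Data frame with `chrom`, `start`, `end`, `value`.
#' @param mark Track name.
#' @return A tibble of class `signal_track`, sorted, with attribute `mark`.
#' @export
signal_track <- function(segments, mark = "signal") {
  x <- as_tibble(segments)
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(x)))
  if (any(x$value < 0)) abort("signal track values must be non-negative")
  if (any(x$start >= x$end)) abort("signal segment with start >= end")
  x <- arrange(x, .data$chrom, .data$start)
  bad <- x |>
    group_by(.data$chrom) |>
    summarise(ov = any(.data$start[-1] < .data$end[-dplyr::n()]), .groups = "drop")
  if (any(bad$ov, na.rm = TRUE)) abort("signal track segments overlap")
  attr(x, "mark") <- mark
  class(x) <- c("signal_track", class(x))
  x
}

#' Read a bedGraph file as a signal track
#'
#' @param path Path to a bedGraph file (0-based half-open, 4 columns).
#' @param mark Track name.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, mark = "signal") {
  if (file.size(path) == 0) {
    return(signal_track(tibble(chrom = character(), start = integer(),
                               end = integer(), value = numeric()), mark))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  signal_track(tibble(chrom = as.character(raw[[1]]),
                      start = as.integer(raw[[2]]),
                      end = as.integer(raw[[3]]),
                      value = as.numeric(raw[[4]])), mark)
}

#' Write a signal track as bedGraph
#'
#' @param track A [signal_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  writeLines(sprintf("%s\t%d\t%d\t%g", track$chrom, track$start, track$end,
                     track$value), path)
  invisible(path)
}

# per-base values of a track over [start, end) on one chromosome
track_values <- function(track, chrom, start, end) {
  n <- end - start
  out <- numeric(n)
  seg <- track[track$chrom == chrom & track$end > start & track$start < end, ]
  if (nrow(seg)) {
    for (k in seq_len(nrow(seg))) {
      a <- max(seg$start[k], start) - start
      b <- min(seg$end[k], end) - start
      out[(a + 1L):b] <- seg$value[k]
    }
  }
  out
}

# total (sum over bases) of a track over [start, end)
track_sum <- function(track, chrom, start, end) {
  seg <- track[track$chrom == chrom & track$end > start & track$start < end, ]
  if (nrow(seg) == 0) return(0)
  sum(seg$value * (pmin(seg$end, end) - pmax(seg$start, start)))
}

#' Read stranded read-start coverage from a bedGraph pair
#'
#' The two tracks hold integer read-start (5' end) counts per position for
#' the forward and reverse strand respectively.
#'
#' @param plus_path,minus_path bedGraph paths for the `+` and `-` strand.
#' @return An object of class `stranded_coverage`: a list with `plus` and
#'   `minus` [signal_track()]s.
#' @export
read_stranded_coverage <- function(plus_path, minus_path) {
  stranded_coverage(read_bedgraph(plus_path, "plus"),
                    read_bedgraph(minus_path, "minus"))
}

#' @rdname read_stranded_coverage
#' @param plus,minus [signal_track()]s of per-position read-start counts.
#' @export
stranded_coverage <- function(plus, minus) {
  for (tr in list(plus, minus)) {
    if (any(tr$value < 0)) abort("stranded coverage counts must be non-negative")
  }
  structure(list(plus = plus, minus = minus), class = "stranded_coverage")
}

#' Count read starts on one strand over an interval
#'
#' @param coverage A [stranded_coverage()].
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param strand `"+"` or `"-"`.
#' @return Total read-start count (numeric scalar); 0 beyond covered regions.
#' @export
count_read_starts <- function(coverage, chrom, start, end, strand = "+") {
  track <- if (strand == "+") coverage$plus else coverage$minus
  track_sum(track, chrom, max(start, 0L), end)
}

#' Read a gene-by-sample count or TPM matrix from TSV
#'
#' @param path TSV with a header row of sample IDs and first column of gene
#'   IDs.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  as.matrix(raw)
}

#' Write a gene-by-sample matrix as TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
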