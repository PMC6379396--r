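#' Assemble a genome model
#'
#' A genome model bundles the reference facts every stage of the atlas
#' pipeline consults: chromosome lengths, the repeat annotation, and the
#' immunoglobulin (Ig) locus intervals. All intervals are 0-based half-open
#' (`[start, end)`), the convention used throughout the package; GTF input is
#' converted at the boundary by [read_annotation()].
#'
#' @param chrom_sizes A data frame with columns `chrom` and `length` (bp), or
#'   a named integer vector.
#' @param repeats,ig_loci Interval data frames with columns `chrom`, `start`,
#'   `end` (0-based half-open). Default: empty.
#' @return An object of class `genome_model`: a list with elements
#'   `chrom_sizes` (tibble), `repeats` and `ig_loci` (sorted interval
#'   tibbles).
#' @export
genome_model <- function(chrom_sizes, repeats = NULL, ig_loci = NULL) {
  if (!is.data.frame(chrom_sizes)) {
    chrom_sizes <- tibble(chrom = names(chrom_sizes),
                          length = as.integer(unname(chrom_sizes)))
  }
  chrom_sizes <- as_tibble(chrom_sizes)
  stopifnot(all(c("chrom", "length") %in% names(chrom_sizes)))
  if (any(chrom_sizes$length <= 0)) abort("all chromosome lengths must be > 0")
  if (anyDuplicated(chrom_sizes$chrom)) abort("duplicated chromosome names")
  gm <- structure(
    list(chrom_sizes = chrom_sizes,
         repeats = validate_intervals(repeats %||% empty_intervals(), chrom_sizes),
         ig_loci = validate_intervals(ig_loci %||% empty_intervals(), chrom_sizes)),
    class = "genome_model")
  gm
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chrom_sizes), " chromosomes, ",
      format(sum(x$chrom_sizes$length), big.mark = ","), " bp; ",
      nrow(x$repeats), " repeats; ", nrow(x$ig_loci), " Ig loci\n", sep = "")
  invisible(x)
}

empty_intervals <- function() {
  tibble(chrom = character(), start = integer(), end = integer())
}

validate_intervals <- function(x, chrom_sizes) {
  x <- as_tibble(x)
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) return(x)
  if (any(x$start >= x$end)) abort("interval with start >= end")
  if (any(x$start < 0)) abort("interval with negative start")
  len <- stats::setNames(chrom_sizes$length, chrom_sizes$chrom)
  unknown <- !x$chrom %in% names(len)
  if (any(unknown)) {
    warn(sprintf("dropping %d interval(s) on unknown chromosomes", sum(unknown)))
    x <- x[!unknown, ]
  }
  if (nrow(x) && any(x$end > len[x$chrom])) abort("interval beyond chromosome end")
  arrange(x, .data$chrom, .data$start, .data$end)
}

# -- interval algebra helpers (0-based half-open tibbles <-> GRanges) --------

as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end))
}

as_interval_tbl <- function(gr) {
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr))
}

# merge overlapping/adjacent-by-0 intervals
merge_intervals <- function(x) {
  if (nrow(x) == 0) return(x)
  as_interval_tbl(GenomicRanges::reduce(as_granges(x)))
}

# total bp of intersection between two interval sets (each merged first)
intersect_bp <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(0L)
  gr <- suppressWarnings(
    GenomicRanges::intersect(GenomicRanges::reduce(as_granges(x)),
                             GenomicRanges::reduce(as_granges(y))))
  sum(GenomicRanges::width(gr))
}

# logical: does row i of x overlap any interval of y (>= 1 bp)
overlaps_any <- function(x, y) {
  if (nrow(x) == 0) return(logical(0))
  if (nrow(y) == 0) return(rep(FALSE, nrow(x)))
  suppressWarnings(IRanges::overlapsAny(as_granges(x), as_granges(y)))
}

# overlap pairs between two interval tibbles; returns tibble(i, j)
overlap_pairs <- function(x, y) {
  if (nrow(x) == 0 || nrow(y) == 0) return(tibble(i = integer(), j = integer()))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(x), as_granges(y)))
  tibble(i = S4Vectors::queryHits(hits), j = S4Vectors::subjectHits(hits))
}
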