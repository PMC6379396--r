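#' Configuration for the synthetic atlas generator
#'
#' Defines the study conditions the generator emulates: six B cell
#' populations (naive B, centroblast, centrocyte, memory B, tonsillar and
#' bone-marrow plasma cells) with replicate RNA-seq samples, a miniature
#' multi-chromosome genome carrying coding genes, repeats and one Ig-like
#' locus, lncRNA candidates planted in every discovery-filter fate,
#' negative-binomial counts with planted differential expression
#' (|log2FC| = 3 by default, comfortably above the 1.5 analysis threshold),
#' trajectory archetypes, single-population (tau = 1) genes, chromatin
#' classes at lncRNA TSSs, enhancers and super-enhancers with and without
#' eRNA, bidirectional loci, and plasma-cell-restricted Ig circRNA
#' junctions.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_coding_genes Total coding genes (placed with >= 10 kb gaps).
#' @param n_lncrna_candidates Total lncRNA candidates.
#' @param cell_types Population labels (default the six B cell stages).
#' @param replicates_per_type Samples per population (>= 3; the expression
#'   filter needs three qualifying samples).
#' @param de_fraction Fraction of coding genes planted as differentially
#'   expressed between the first two populations.
#' @param de_log2fc Planted |log2FC| for those genes.
#' @param n_trajectory_clusters Number of trajectory archetypes planted
#'   (8 matches the atlas's expression-module analysis).
#' @param chromatin_proportions Named proportions (must sum to 1) over
#'   classes `enhancer`, `promoter`, `bivalent`, `ctcf`, `repressed`,
#'   `featureless`.
#' @param candidate_mix Named proportions (sum 1) over candidate fates:
#'   `pass_intergenic`, `pass_antisense`, `too_short`, `low_expression`,
#'   `repeat_overlap`, `coding_potential`, `sense_overlap`, `intronic`.
#' @param fraction_bidirectional Fraction of intergenic novel lncRNAs
#'   planted as bidirectional loci.
#' @param n_super_enhancers Super-enhancer neighborhoods (clustered
#'   high-signal H3K27ac peaks).
#' @param n_ernas Standalone planted eRNA loci (single-exon intergenic
#'   lncRNAs sitting in an enhancer, outside super-enhancers).
#' @param n_enhancers Planted enhancers without an eRNA.
#' @param repeat_density Fraction of the genome covered by random repeats.
#' @param ig_locus_span Width of the Ig-like locus (bp).
#' @param dispersion Negative-binomial dispersion for counts.
#' @param n_high_tau Genes planted as expressed in exactly one population.
#' @param n_circ_ig,n_circ_other,n_circ_subthreshold circRNA junction
#'   counts per planted group.
#' @param seed Integer seed; identical (config, seed) gives byte-identical
#'   outputs.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chroms = 4,
                             chrom_length = 4e6,
                             n_coding_genes = 120,
                             n_lncrna_candidates = 2000,
                             cell_types = c("NB", "CB", "CC", "MEM",
                                            "TPC", "BMPC"),
                             replicates_per_type = 3,
                             de_fraction = 0.05,
                             de_log2fc = 3,
                             n_trajectory_clusters = 8,
                             chromatin_proportions = c(
                               enhancer = 0.20, promoter = 0.20,
                               bivalent = 0.15, ctcf = 0.15,
                               repressed = 0.15, featureless = 0.15),
                             candidate_mix = c(
                               pass_intergenic = 0.30, pass_antisense = 0.12,
                               too_short = 0.10, low_expression = 0.12,
                               repeat_overlap = 0.10, coding_potential = 0.12,
                               sense_overlap = 0.07, intronic = 0.07),
                             fraction_bidirectional = 0.3,
                             n_super_enhancers = 5,
                             n_ernas = 25,
                             n_enhancers = 80,
                             repeat_density = 0.05,
                             ig_locus_span = 3e5,
                             dispersion = 0.05,
                             n_high_tau = 60,
                             n_circ_ig = 40,
                             n_circ_other = 30,
                             n_circ_subthreshold = 10,
                             seed = 1) {
  cfg <- as.list(environment())
  fracs <- c(cfg$de_fraction, cfg$fraction_bidirectional, cfg$repeat_density)
  if (any(fracs < 0 | fracs > 1)) abort("fractions must lie in [0, 1]")
  if (abs(sum(chromatin_proportions) - 1) > 1e-8) {
    abort("chromatin_proportions must sum to 1")
  }
  if (abs(sum(candidate_mix) - 1) > 1e-8) {
    abort("candidate_mix must sum to 1")
  }
  counts <- c(n_chroms, chrom_length, n_coding_genes, n_lncrna_candidates,
              replicates_per_type)
  if (any(counts <= 0)) abort("counts and sizes must be positive")
  if (dispersion <= 0) abort("dispersion must be positive")
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_chroms, " x ",
      format(x$chrom_length, big.mark = ","), " bp; ",
      x$n_coding_genes, " coding genes; ", x$n_lncrna_candidates,
      " lncRNA candidates; ", length(x$cell_types), " cell types x ",
      x$replicates_per_type, " replicates; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Trajectory archetypes across the six B cell stages
#'
#' Relative expression profiles (max-normalized) the generator plants:
#' stage-restricted patterns for each compartment, monotone up/down
#' trajectories, a transient germinal-center peak, and a flat profile.
#'
#' @param cell_types Population labels (length defines the profile width).
#' @return A matrix with one archetype per row.
#' @export
trajectory_archetypes <- function(cell_types = c("NB", "CB", "CC", "MEM",
                                                 "TPC", "BMPC")) {
  n <- length(cell_types)
  base <- rbind(
    nb_high   = c(1, .1, .1, .1, .1, .1),
    gc_high   = c(.1, 1, 1, .1, .1, .1),
    mem_high  = c(.1, .1, .1, 1, .1, .1),
    pc_high   = c(.1, .1, .1, .1, 1, 1),
    gradual_up   = c(.1, .25, .4, .6, .8, 1),
    gradual_down = c(1, .8, .6, .4, .25, .1),
    transient    = c(.2, .6, 1, .6, .3, .2),
    flat         = c(.6, .6, .6, .6, .6, .6))
  if (n != ncol(base)) {
    # interpolate archetype shapes onto a different stage count
    base <- t(apply(base, 1, function(v) {
      stats::approx(seq_along(v), v, n = n)$y
    }))
  }
  colnames(base) <- cell_types
  base
}
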