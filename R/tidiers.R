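# broom-style tidiers for the package's fitted/result objects

#' @export
tidy.lnc_filter <- function(x, ...) as_tibble(x$verdicts)

#' @export
glance.lnc_filter <- function(x, ...) {
  v <- x$verdicts
  bind_cols(tibble(n_candidates = nrow(v), n_pass = sum(v$pass)),
            pivot_wider(count(v[!v$pass, ], .data$reason),
                        names_from = "reason", values_from = "n"))
}

#' @export
tidy.lnc_de <- function(x, ...) as_tibble(unclass(x))

#' @export
glance.lnc_de <- function(x, ...) {
  th <- attr(x, "thresholds")
  ct <- attr(x, "contrast")
  tibble(contrast = paste(ct, collapse = " vs "), n_genes = nrow(x),
         n_significant = sum(x$significant),
         prop_significant = mean(x$significant),
         lfc_threshold = th[["lfc"]], q_threshold = th[["q"]])
}

#' @export
tidy.lnc_tau <- function(x, ...) as_tibble(unclass(x))

#' @export
tidy.lnc_traj <- function(x, ...) x$clusters

#' @export
glance.lnc_traj <- function(x, ...) {
  tibble(k = x$k, n_genes = nrow(x$clusters))
}

#' @export
tidy.lnc_pca <- function(x, ...) x$scores

#' @export
glance.lnc_pca <- function(x, ...) {
  tibble(n_genes = x$n_genes, pc1_var = x$var_explained[1],
         pc2_var = x$var_explained[2])
}

#' @export
tidy.lnc_phylo <- function(x, ...) {
  tr <- x$tree
  tibble(node = seq_along(x$support) + length(tr$tip.label),
         support = x$support)
}

#' @export
glance.lnc_phylo <- function(x, ...) {
  tibble(metric = x$metric, n_tips = length(x$tree$tip.label),
         n_boot = x$n_boot, min_support = min(x$support),
         negative_branches = x$negative_branches)
}

#' @export
tidy.lnc_se <- function(x, ...) x$regions

#' @export
glance.lnc_se <- function(x, ...) {
  tibble(n_regions = nrow(x$regions), n_super_enhancers = sum(x$regions$is_se),
         cutoff = x$cutoff)
}

#' @export
tidy.lnc_ernas <- function(x, ...) x$ernas

#' @export
glance.lnc_ernas <- function(x, ...) {
  pivot_wider(x$fractions[c("class", "fraction")], names_from = "class",
              values_from = "fraction", names_prefix = "frac_") |>
    mutate(n_ernas = nrow(x$ernas), n_eligible = length(x$eligible))
}

#' @export
tidy.lnc_perm <- function(x, ...) tibble(null_fraction = x$null)

#' @export
glance.lnc_perm <- function(x, ...) {
  tibble(observed = x$observed, null_median = median(x$null),
         null_max = max(x$null), p = x$p, n_perm = x$n_perm)
}

#' @export
tidy.lnc_chromatin_clusters <- function(x, ...) x$clusters

#' @export
glance.lnc_chromatin_clusters <- function(x, ...) {
  tibble(k = x$k, n_lncrnas = nrow(x$clusters))
}

#' @export
tidy.lnc_circ <- function(x, ...) x$by_cell_type

#' @export
tidy.lnc_folded <- function(x, ...) x$curves

#' @export
glance.lnc_folded <- function(x, ...) tibble(p = x$p)
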