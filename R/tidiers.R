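# broom-style tidiers for panstrep result objects.

#' Tidy a pan-genome result
#'
#' @param x A `pan_genome` object.
#' @param ... Unused.
#' @return Cluster membership tibble with one row per gene, carrying the
#'   cluster's partition class.
#' @export
tidy.pan_genome <- function(x, ...) {
  left_join(x$clusters,
            x$cluster_info[, c("cluster_id", "n_strains_present", "class")],
            by = "cluster_id")
}

#' Glance at a pan-genome result
#'
#' @param x A `pan_genome` object.
#' @param ... Unused.
#' @return One-row tibble with strain/gene/cluster counts, the partition,
#'   and the core fraction (percent).
#' @export
glance.pan_genome <- function(x, ...) {
  pc <- partition_counts(x)
  tibble(n_strains = x$n_strains, n_genes = nrow(x$clusters),
         n_clusters = pc$total, core = pc$core,
         dispensable = pc$dispensable, specific = pc$specific,
         core_pct = core_fraction(pc$core, pc$total))
}

#' Tidy a rarefaction curve
#'
#' @param x A `rarefaction_curve`.
#' @param ... Unused.
#' @return Per-n medians in long form: `n`, `genome` (pan/core), `size`.
#' @export
tidy.rarefaction_curve <- function(x, ...) {
  curve_medians(x) |>
    tidyr::pivot_longer(c("pan", "core"), names_to = "genome",
                        values_to = "size")
}

#' Glance at a rarefaction curve
#'
#' @param x A `rarefaction_curve`.
#' @param ... Unused.
#' @return One-row tibble: strain count, permutations, final median pan and
#'   core sizes.
#' @export
glance.rarefaction_curve <- function(x, ...) {
  med <- curve_medians(x)
  tibble(n_strains = attr(x, "n_strains"),
         permutations = attr(x, "permutations"),
         pan_final = med$pan[nrow(med)], core_final = med$core[nrow(med)])
}

#' Tidy a fitted rarefaction model
#'
#' @param x A `decay_fit` from [fit_core_decay()] or [fit_pan_growth()].
#' @param ... Unused.
#' @return Tibble of `term` / `estimate` pairs.
#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = names(x$parameters),
         estimate = unlist(x$parameters, use.names = FALSE))
}

#' Glance at a fitted rarefaction model
#'
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @return One-row tibble with the model name, RSS, convergence flag and,
#'   for the power-law model, the openness call.
#' @export
glance.decay_fit <- function(x, ...) {
  out <- tibble(model = x$model, rss = x$rss, converged = x$converged)
  if (!is.null(x$open)) {
    out$open <- x$open
    out$gamma_se <- x$gamma_se
  }
  out
}

predict_decay_fit <- function(x, n) {
  p <- x$parameters
  if (x$model == "core_exp_decay") {
    p$A * exp(-n / p$tau) + p$omega
  } else {
    p$K * n^p$gamma
  }
}
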