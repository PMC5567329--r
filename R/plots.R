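# ggplot2 visualisations for panstrep results.

#' Plot a rarefaction (dilution) curve
#'
#' Per-permutation pan and core trajectories (faint) with the per-n medians
#' overlaid — the usual dilution-curve figure of pan-genome papers.
#'
#' @param object A `rarefaction_curve` from [rarefy()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rarefaction_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("pan", "core"),
                              names_to = "genome", values_to = "size")
  med <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$size,
                                     colour = .data$genome)) +
    ggplot2::geom_line(ggplot2::aes(group = interaction(.data$perm,
                                                        .data$genome)),
                       alpha = 0.15) +
    ggplot2::geom_line(data = med, linewidth = 1) +
    ggplot2::geom_point(data = med, size = 2) +
    ggplot2::labs(x = "number of strains", y = "orthologue clusters",
                  colour = NULL, title = "Pan/core rarefaction") +
    ggplot2::theme_minimal()
}

#' Plot a fitted rarefaction model
#'
#' Medians with the fitted exponential-decay or power-law curve.
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.decay_fit <- function(object, ...) {
  med <- object$medians
  med$y <- if (object$model == "core_exp_decay") med$core else med$pan
  grid <- tibble(n = seq(min(med$n), max(med$n), length.out = 200))
  grid$y <- predict_decay_fit(object, grid$n)
  ggplot2::ggplot(med, ggplot2::aes(x = .data$n, y = .data$y)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "number of strains",
                  y = if (object$model == "core_exp_decay") {
                    "core clusters"
                  } else {
                    "pan clusters"
                  },
                  title = object$model) +
    ggplot2::theme_minimal()
}

#' Plot pan-genome partition counts
#'
#' Bar chart of core / dispensable / strain-specific cluster counts, with
#' per-strain specific counts shown alongside (the flower-plot numbers).
#'
#' @param object A `pan_genome` from [build_pan_pool()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pan_genome <- function(object, ...) {
  pc <- partition_counts(object)
  df <- tibble(class = factor(c("core", "dispensable", "specific"),
                              levels = c("core", "dispensable", "specific")),
               n = c(pc$core, pc$dispensable, pc$specific))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$n,
                                   fill = .data$class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "orthologue clusters",
                  title = "Pan-genome partition") +
    ggplot2::theme_minimal()
}

#' Plot per-strain specific gene counts (flower-plot numbers)
#'
#' @param result A `pan_genome`.
#' @return A ggplot object.
#' @export
plot_flower_counts <- function(result) {
  fc <- flower_counts(result)
  fc$strain_id <- factor(fc$strain_id, levels = fc$strain_id)
  ggplot2::ggplot(fc, ggplot2::aes(x = .data$strain_id, y = .data$n)) +
    ggplot2::geom_col(fill = "darkseagreen") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "clusters",
                  title = "Core (centre) and strain-specific counts") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
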