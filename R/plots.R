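#' Plot the energy landscape of a patient
#'
#' Ranked "waterfall" of per-node Gibbs energies, deepest wells first — the
#' one-dimensional view of the energy landscape that the filtration plane
#' sweeps through. A dashed line marks a capture threshold if given.
#'
#' @param object an `energy_map` from [gibbs_energy()].
#' @param threshold optional capture count to annotate.
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.energy_map <- function(object, threshold = NULL, ...) {
  df <- as_tibble(object) |>
    arrange(.data$gibbs) |>
    mutate(rank = dplyr::row_number())
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$gibbs)) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "node rank (deepest first)", y = "Gibbs free energy G_i",
      title = sprintf("Energy landscape: %s", attr(object, "patient_id") %||% "")
    ) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold + 0.5, linetype = "dashed")
  }
  p
}

#' @export
autoplot.knockout_records <- function(object, ...) {
  df <- as_tibble(object) |> arrange(.data$post_betti, .data$node)
  df$node <- factor(df$node, levels = df$node)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node, y = .data$post_betti)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(
      yintercept = attr(object, "nominal_betti"), linetype = "dashed"
    ) +
    ggplot2::labs(
      x = NULL, y = "Betti number after knockout",
      title = sprintf(
        "Knockout scan (nominal Betti %d)", attr(object, "nominal_betti")
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Pareto chart of cohort targets
#'
#' Descending-frequency bar chart of how many patients named each protein
#' among their equivalent best targets.
#'
#' @param summary a `cohort_summary` from [pareto_counts()].
#' @param top show at most this many targets.
#' @return A ggplot object.
#' @export
plot_pareto <- function(summary, top = 20) {
  stopifnot(inherits(summary, "cohort_summary"))
  df <- head(summary$pareto, top)
  df$target <- factor(df$target, levels = df$target)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = NULL, y = "patients with this best target",
      title = sprintf(
        "Pareto of equivalent targets (%d instances, %d patients)",
        summary$total_target_instances, summary$n_patients
      )
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @export
autoplot.cohort_summary <- function(object, top = 20, ...) plot_pareto(object, top)

#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$group_stats,
    ggplot2::aes(x = .data$group, y = .data$mean)
  ) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd
    )) +
    ggplot2::labs(
      x = NULL, y = "homology energy (mean ± SD)",
      title = "Homology energy by histology group"
    ) +
    ggplot2::theme_minimal()
}
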