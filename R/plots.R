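#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of the 16 stage-string bins
#'
#' @param object A [stage_calls()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stage_calls <- function(object, ...) {
  counts <- partition_report(object)
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$stage_string, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "four-bit stage string", y = "genes",
                  title = "Differential-expression pattern partition") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Group-mean trajectories of monotonic genes
#'
#' Draws per-gene mean log2 expression across control and stages I--IV for
#' the top-ranked monotonic genes, colored by direction.
#'
#' @param object A [monotonic_calls()] tibble (ranked or not).
#' @param n Number of genes to draw (by ascending adjusted p among
#'   non-`none` genes).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.monotonic_calls <- function(object, n = 12, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$direction != "none") |>
    dplyr::arrange(.data$adj_p) |>
    utils::head(n) |>
    tidyr::pivot_longer(dplyr::all_of(paste0("mean_", stage_levels())),
                        names_to = "group", values_to = "mean",
                        names_prefix = "mean_") |>
    dplyr::mutate(group = factor(.data$group, levels = stage_levels()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$mean,
                                   group = .data$gene,
                                   color = .data$direction)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "mean log2 expression",
                  title = "Monotonic expression trajectories") +
    ggplot2::theme_minimal()
}

#' Stagewise lfc profiles of stage-specific genes
#'
#' One line per stage-specific gene over its four stage-versus-control log
#' fold-changes, faceted by assigned stage; the assigned stage should carry
#' the extreme value.
#'
#' @param x A `stage_analysis` result (from [run_analysis()]).
#' @return A ggplot.
#' @export
plot_stage_profiles <- function(x) {
  stopifnot(inherits(x, "stage_analysis"))
  df <- x$stage_specific |>
    tidyr::pivot_longer(dplyr::all_of(paste0("lfc_", tumor_stages())),
                        names_to = "stage", values_to = "lfc",
                        names_prefix = "lfc_") |>
    dplyr::mutate(stage = factor(.data$stage, levels = tumor_stages()))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$lfc,
                                   group = .data$gene)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~assigned_stage, nrow = 1) +
    ggplot2::labs(x = "stage", y = "log2 fold-change vs control",
                  title = "Stage-specific gene profiles") +
    ggplot2::theme_minimal()
}
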