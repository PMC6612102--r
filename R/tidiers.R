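#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-gene fits into a long tibble
#'
#' @param x A `gene_fits` object.
#' @param ... Unused.
#' @return Tibble with columns `gene`, `term`, `estimate`.
#' @export
tidy.gene_fits <- function(x, ...) {
  tibble::as_tibble(x$coefficients, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "term", values_to = "estimate")
}

#' @export
glance.gene_fits <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$coefficients),
                 n_terms = ncol(x$coefficients),
                 df_residual = x$df_residual,
                 kind = x$kind %||% NA_character_,
                 weighted = x$weighted)
}

#' Tidy moderated statistics into a long tibble
#'
#' @param x A `moderated_stats` object.
#' @param ... Unused.
#' @return Tibble with `gene`, `term`, `estimate`, `statistic`, `p.value`,
#'   `adj.p.value`.
#' @export
tidy.moderated_stats <- function(x, ...) {
  long <- function(m, name) {
    tibble::as_tibble(m, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "term", values_to = name)
  }
  long(x$coefficients, "estimate") |>
    dplyr::left_join(long(x$t, "statistic"), by = c("gene", "term")) |>
    dplyr::left_join(long(x$p, "p.value"), by = c("gene", "term")) |>
    dplyr::left_join(long(x$adj_p, "adj.p.value"), by = c("gene", "term"))
}

#' @export
glance.moderated_stats <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes),
                 df_prior = x$df_prior, var_prior = x$var_prior,
                 df_residual = x$df_residual, df_total = x$df_total)
}

#' Tidy contrast results into a long tibble
#'
#' @param x A `contrast_fit` object.
#' @param ... Unused.
#' @return Tibble with `gene`, `contrast`, `estimate` (log2 lfc),
#'   `statistic`, `p.value`, `adj.p.value` -- the long-format shape of the
#'   per-contrast report.
#' @export
tidy.contrast_fit <- function(x, ...) {
  long <- function(m, name) {
    tibble::as_tibble(m, rownames = "gene") |>
      tidyr::pivot_longer(-"gene", names_to = "contrast", values_to = name)
  }
  long(x$estimate, "estimate") |>
    dplyr::left_join(long(x$t, "statistic"), by = c("gene", "contrast")) |>
    dplyr::left_join(long(x$p, "p.value"), by = c("gene", "contrast")) |>
    dplyr::left_join(long(x$adj_p, "adj.p.value"), by = c("gene", "contrast"))
}

#' @export
glance.contrast_fit <- function(x, ...) {
  tibble::tibble(n_genes = length(x$genes),
                 n_contrasts = ncol(x$estimate),
                 df_prior = x$df_prior, var_prior = x$var_prior)
}

#' @export
glance.stage_analysis <- function(x, ...) {
  n0 <- x$partition$n[x$partition$stage_string == "0000"]
  tibble::tibble(
    n_genes = nrow(x$linear_model),
    n_samples = x$n_samples,
    n_string_0000 = n0,
    n_stage_assigned = sum(x$partition$n) - n0,
    n_stage_specific = nrow(x$stage_specific),
    n_monotonic_strict = sum(x$monotonic$direction != "none"),
    n_monotonic_significant = nrow(x$monotonic_ranked))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
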