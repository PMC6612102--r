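#' Per-gene group means over control and stages
#'
#' @param dataset A [stage_dataset()]; every group must be non-empty.
#' @return Tibble with columns `gene`, `mean_control`, `mean_I`..`mean_IV`.
#' @export
group_means <- function(dataset) {
  stopifnot(inherits(dataset, "stage_dataset"))
  empty <- setdiff(stage_levels(), as.character(dataset$samples$group))
  if (length(empty) > 0) {
    stop("empty group(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  means <- vapply(stage_levels(), function(g) {
    rowMeans(dataset$exprs[, dataset$samples$group == g, drop = FALSE])
  }, numeric(nrow(dataset$exprs)))
  if (!is.matrix(means)) {
    means <- matrix(means, nrow = 1, dimnames = list(NULL, names(means)))
  }
  out <- tibble::as_tibble(means, .name_repair = ~ paste0("mean_", .x))
  dplyr::bind_cols(tibble::tibble(gene = rownames(dataset$exprs)), out)
}

#' Classify strictly monotonic group-mean trajectories
#'
#' `UP` when the means obey control < I < II < III < IV strictly, `DOWN`
#' when control > I > II > III > IV strictly, `none` otherwise (any tie or
#' reversal breaks monotonicity). Strict monotonicity implies the maximal
#' absolute deviation from control is reached in stage IV.
#'
#' @param means Numeric matrix (genes x 5, ordered control, I--IV), a
#'   5-vector, or the tibble returned by [group_means()].
#' @return Character scalar or vector in `UP`, `DOWN`, `none`.
#' @export
classify_monotonic <- function(means) {
  if (is.data.frame(means)) {
    means <- as.matrix(means[, paste0("mean_", stage_levels())])
  }
  m <- if (is.matrix(means)) means else matrix(means, nrow = 1)
  if (ncol(m) != 5) stop("expected five group means", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite group mean", call. = FALSE)
  d <- m[, -1, drop = FALSE] - m[, -5, drop = FALSE]
  out <- ifelse(rowSums(d > 0) == 4, "UP",
                ifelse(rowSums(d < 0) == 4, "DOWN", "none"))
  if (!is.matrix(means)) out[1] else unname(out)
}

#' Monotonic-trend calls with numeric-stage model inference
#'
#' Combines the strict group-mean monotonicity classification with the
#' moderated inference from the numeric-stage linear model
#' (`y = a X + b`, X = 0..4 over control, I--IV): each gene gets its group
#' means, direction, slope, intercept, and the slope's BH-adjusted p-value.
#'
#' @param dataset A [stage_dataset()].
#' @param numeric_stats A `moderated_stats` object from the numeric-stage
#'   design (built with `build_design(groups, "numeric")`), matching the
#'   dataset's genes. If `NULL`, it is fitted here (unweighted).
#' @return Tibble of class `monotonic_calls`: `gene`, the five group means,
#'   `direction`, `intercept`, `slope`, `p`, `adj_p`.
#' @export
monotonic_calls <- function(dataset, numeric_stats = NULL) {
  stopifnot(inherits(dataset, "stage_dataset"))
  if (is.null(numeric_stats)) {
    design <- build_design(dataset$samples$group, "numeric")
    numeric_stats <- ebayes_moderate(fit_gene_models(dataset, design))
  }
  stopifnot(inherits(numeric_stats, "moderated_stats"))
  if (!identical(numeric_stats$genes, rownames(dataset$exprs))) {
    stop("`numeric_stats` genes do not match the dataset", call. = FALSE)
  }
  gm <- group_means(dataset)
  out <- dplyr::mutate(gm,
    direction = classify_monotonic(gm),
    intercept = numeric_stats$coefficients[, "intercept"],
    slope = numeric_stats$coefficients[, "stage_num"],
    p = numeric_stats$p[, "stage_num"],
    adj_p = numeric_stats$adj_p[, "stage_num"])
  class(out) <- c("monotonic_calls", class(out))
  out
}

#' Rank significant monotonic genes
#'
#' The union of strictly monotonically up- and downregulated genes is
#' filtered to those whose numeric-stage slope is significant
#' (BH-adjusted p below `p_max`) and sorted by ascending adjusted p-value.
#'
#' @param calls A [monotonic_calls()] tibble.
#' @param p_max Adjusted-p threshold for the numeric-stage slope.
#' @return The filtered, ranked tibble; UP/DOWN counts are attached as
#'   attribute `direction_counts`.
#' @export
rank_monotonic <- function(calls, p_max = 0.05) {
  stopifnot(inherits(calls, "monotonic_calls"))
  out <- dplyr::filter(calls, .data$direction != "none",
                       .data$adj_p < p_max)
  out <- dplyr::arrange(out, .data$adj_p)
  attr(out, "direction_counts") <-
    c(UP = sum(out$direction == "UP"), DOWN = sum(out$direction == "DOWN"))
  class(out) <- unique(c("monotonic_calls", class(out)))
  out
}
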