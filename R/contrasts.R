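#' Stage-versus-control contrast matrix
#'
#' One contrast per stage: +1 on the stage, -1 on control, 0 elsewhere,
#' over the cell-means terms `(control, I, II, III, IV)`. The estimates are
#' the stagewise log fold-changes versus control.
#'
#' @return 5 x 4 numeric matrix; rows are cell-means terms, columns the
#'   four contrasts `I_vs_control`, ..., `IV_vs_control`.
#' @export
control_contrasts <- function() {
  C <- matrix(0, 5, 4,
              dimnames = list(stage_levels(),
                              paste0(tumor_stages(), "_vs_control")))
  C["control", ] <- -1
  for (k in seq_along(tumor_stages())) C[tumor_stages()[k], k] <- 1
  C
}

#' Inter-stage contrast matrix
#'
#' All six unordered stage pairs; the earlier stage gets +1, the later -1,
#' control 0. Orientation only affects the sign of the estimate, never |t|
#' or the p-value, and is fixed for reproducibility.
#'
#' @return 5 x 6 numeric matrix; columns `I_vs_II`, `I_vs_III`, `I_vs_IV`,
#'   `II_vs_III`, `II_vs_IV`, `III_vs_IV`.
#' @export
interstage_contrasts <- function() {
  pairs <- utils::combn(tumor_stages(), 2)
  C <- matrix(0, 5, ncol(pairs),
              dimnames = list(stage_levels(),
                              paste0(pairs[1, ], "_vs_", pairs[2, ])))
  for (j in seq_len(ncol(pairs))) {
    C[pairs[1, j], j] <- 1
    C[pairs[2, j], j] <- -1
  }
  C
}

#' Apply contrasts to per-gene fits with moderated inference
#'
#' Propagates cell-means fits through a contrast matrix: estimates
#' \eqn{c'\hat\beta}, unscaled standard deviations
#' \eqn{\sqrt{c'(X'WX)^{-1}c}}, then moderated t and p-values using the
#' empirical-Bayes posterior variances, with BH adjustment per contrast
#' across genes.
#'
#' @param fits A `gene_fits` object, normally from the cell-means design.
#' @param contrasts Contrast matrix with one row per model coefficient
#'   (e.g. [control_contrasts()], [interstage_contrasts()]).
#' @param prior_df,prior_var Optional fixed moderation hyperparameters
#'   passed to [ebayes_moderate()].
#' @return An object of class `contrast_fit` with genes x contrasts
#'   matrices `estimate` (log2), `t`, `p`, `adj_p`, plus the moderation
#'   hyperparameters.
#' @export
apply_contrasts <- function(fits, contrasts, prior_df = NULL,
                            prior_var = NULL) {
  stopifnot(inherits(fits, "gene_fits"))
  C <- as.matrix(contrasts)
  p <- ncol(fits$coefficients)
  if (nrow(C) != p) {
    stop("contrast matrix has ", nrow(C), " rows but the model has ", p,
         " coefficients", call. = FALSE)
  }
  if (!is.null(rownames(C)) && !is.null(colnames(fits$coefficients)) &&
      !identical(rownames(C), colnames(fits$coefficients))) {
    stop("contrast rows must match model coefficients: ",
         paste(colnames(fits$coefficients), collapse = ", "), call. = FALSE)
  }
  G <- nrow(fits$coefficients)
  est <- fits$coefficients %*% C

  if (is.array(fits$cov_unscaled) && length(dim(fits$cov_unscaled)) == 3) {
    sdu <- matrix(NA_real_, G, ncol(C))
    for (g in seq_len(G)) {
      sdu[g, ] <- sqrt(diag(t(C) %*% fits$cov_unscaled[, , g] %*% C))
    }
  } else {
    v <- diag(t(C) %*% fits$cov_unscaled %*% C)
    sdu <- matrix(sqrt(v), G, ncol(C), byrow = TRUE)
  }

  mod <- ebayes_moderate(fits, prior_df = prior_df, prior_var = prior_var)
  tt <- est / (sdu * sqrt(mod$var_post))
  pp <- 2 * stats::pt(-abs(tt), df = mod$df_total)
  adj <- pp
  for (j in seq_len(ncol(pp))) adj[, j] <- adjust_bh(pp[, j])
  dimnames(est) <- dimnames(tt) <- dimnames(pp) <- dimnames(adj) <-
    list(fits$genes, colnames(C))

  structure(list(estimate = est, t = tt, p = pp, adj_p = adj,
                 df_prior = mod$df_prior, var_prior = mod$var_prior,
                 df_total = mod$df_total, genes = fits$genes,
                 contrasts = C),
            class = "contrast_fit")
}

#' @export
print.contrast_fit <- function(x, ...) {
  cat("<contrast_fit> ", length(x$genes), " genes x ", ncol(x$estimate),
      " contrasts (", paste(colnames(x$estimate), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}
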