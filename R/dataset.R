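#' Staged expression dataset
#'
#' Container pairing a log2 expression matrix (genes in rows, samples in
#' columns) with a per-sample annotation table. The annotation carries the
#' parsed barcode fields and the collapsed pathologic stage; the `group`
#' column is the analysis grouping: `control` for normal-tissue samples and
#' `I`--`IV` for tumor samples with stage annotation.
#'
#' @param exprs Numeric matrix of log2 expression values, genes x samples,
#'   with row names (gene ids) and column names (sample barcodes).
#' @param samples Data frame with one row per column of `exprs`, containing
#'   at least `barcode` and `group`. `group` must be `NA` or one of
#'   `control`, `I`, `II`, `III`, `IV`.
#' @return An object of class `stage_dataset`.
#' @export
stage_dataset <- function(exprs, samples) {
  if (!is.matrix(exprs) || !is.numeric(exprs)) {
    stop("`exprs` must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) != ncol(exprs)) {
    stop("`samples` must have one row per column of `exprs` (",
         nrow(samples), " vs ", ncol(exprs), ")", call. = FALSE)
  }
  if (!"barcode" %in% names(samples)) {
    stop("`samples` must contain a `barcode` column", call. = FALSE)
  }
  if (!"group" %in% names(samples)) samples$group <- NA_character_
  bad <- setdiff(unique(as.character(samples$group)), c(stage_levels(), NA))
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  samples$group <- factor(as.character(samples$group), levels = stage_levels())
  if (is.null(rownames(exprs))) {
    rownames(exprs) <- paste0("gene_", seq_len(nrow(exprs)))
  }
  colnames(exprs) <- samples$barcode
  structure(list(exprs = exprs, samples = samples), class = "stage_dataset")
}

#' Group levels used throughout the pipeline
#'
#' @return Character vector `c("control", "I", "II", "III", "IV")`.
#' @export
stage_levels <- function() c("control", "I", "II", "III", "IV")

# Tumor stages only, in progression order.
tumor_stages <- function() c("I", "II", "III", "IV")

#' @export
print.stage_dataset <- function(x, ...) {
  cat("<stage_dataset> ", nrow(x$exprs), " genes x ", ncol(x$exprs),
      " samples\n", sep = "")
  tab <- table(x$samples$group, useNA = "ifany")
  cat("groups: ", paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.stage_dataset <- function(x) dim(x$exprs)

#' Subset a staged dataset
#'
#' @param x A [stage_dataset()].
#' @param genes,samples Index vectors (logical, integer or names) selecting
#'   rows and columns of the expression matrix; `NULL` keeps all.
#' @return A `stage_dataset` restricted to the selection.
#' @export
subset_dataset <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "stage_dataset"))
  if (is.null(genes)) genes <- seq_len(nrow(x$exprs))
  if (is.null(samples)) samples <- seq_len(ncol(x$exprs))
  stage_dataset(x$exprs[genes, samples, drop = FALSE],
                x$samples[samples, , drop = FALSE])
}
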