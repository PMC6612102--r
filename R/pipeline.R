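#' Pipeline configuration
#'
#' Collects every tunable threshold of the stage-specific analysis. The
#' defaults are the study's operating point: a 4-fold |lfc| cutoff for the
#' stage string, a stringent adjusted-p threshold for the control contrast,
#' a relaxed raw-p threshold for inter-stage contrasts, and a top-10 prune
#' of the low-powered stage-IV set.
#'
#' @param sigma_min Standard-deviation cutoff of the gene variance filter.
#' @param lfc_threshold |lfc| cutoff for the four-bit stage string.
#' @param p_control Adjusted-p threshold for the assigned stage's contrast
#'   versus control (cascade prong i).
#' @param p_inter Raw-p threshold for the inter-stage contrasts (prongs
#'   ii--iv).
#' @param p_monotonic Adjusted-p threshold for the numeric-stage slope.
#' @param stage4_top_n Number of stage-IV genes kept after the monotone
#'   prune.
#' @param use_meanvar_weights Named logical vector over the three fits
#'   (`eq_baseline`, `eq_numeric`, `eq_cellmeans`): whether to apply
#'   mean-variance precision weights. On by default only for the
#'   genome-wide baseline scan.
#' @param seed Integer seed used when the input is a simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sigma_min = 1, lfc_threshold = 2,
                            p_control = 0.001, p_inter = 0.05,
                            p_monotonic = 0.05, stage4_top_n = 10,
                            use_meanvar_weights = c(eq_baseline = TRUE,
                                                    eq_numeric = FALSE,
                                                    eq_cellmeans = FALSE),
                            seed = 1L) {
  stopifnot(sigma_min > 0, lfc_threshold > 0,
            p_control > 0, p_control < 1,
            p_inter > 0, p_inter < 1,
            p_monotonic > 0, p_monotonic < 1,
            stage4_top_n >= 1)
  w <- c(eq_baseline = TRUE, eq_numeric = FALSE, eq_cellmeans = FALSE)
  w[names(use_meanvar_weights)] <- use_meanvar_weights
  structure(list(sigma_min = sigma_min, lfc_threshold = lfc_threshold,
                 p_control = p_control, p_inter = p_inter,
                 p_monotonic = p_monotonic, stage4_top_n = stage4_top_n,
                 use_meanvar_weights = w, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the analysis core on a preprocessed dataset
#'
#' Executes the modelling stages in order: genome-wide baseline linear
#' model (optionally precision-weighted) with moderated F, numeric-stage
#' model, cell-means fit with stage-versus-control and inter-stage
#' contrasts, stage-string classification, significance cascade,
#' monotonic screen, and stage-IV pruning.
#'
#' @param dataset A preprocessed [stage_dataset()] with all five groups
#'   present.
#' @param config A [pipeline_config()].
#' @return A list of class `stage_analysis`: `linear_model` (tibble of the
#'   baseline scan), `baseline_stats`, `numeric_stats`, `control_fit`,
#'   `inter_fit`, `calls` (cascade-annotated [stage_calls()]),
#'   `stage_specific` (tibble), `partition` (16-bin counts), `monotonic`
#'   ([monotonic_calls()]), `monotonic_ranked`, `stage4_pruned`, `config`.
#' @export
run_analysis <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "stage_dataset"),
            inherits(config, "pipeline_config"))
  groups <- dataset$samples$group

  # genome-wide baseline scan (Fig. of merit: moderated F vs control)
  design_b <- build_design(groups, "baseline")
  w <- if (config$use_meanvar_weights[["eq_baseline"]]) {
    estimate_meanvar_weights(dataset, design_b)
  } else NULL
  baseline_stats <- ebayes_moderate(fit_gene_models(dataset, design_b, w))
  lfc_b <- baseline_stats$coefficients[, paste0("stage", tumor_stages()),
                                       drop = FALSE]
  linear_model <- tibble::tibble(
    gene = baseline_stats$genes,
    lfc_I = lfc_b[, 1], lfc_II = lfc_b[, 2], lfc_III = lfc_b[, 3],
    lfc_IV = lfc_b[, 4],
    F = baseline_stats$F, p = baseline_stats$F_p,
    adj_p = baseline_stats$F_adj_p,
    regulation = regulation_status(lfc_b))

  # numeric-stage trend model
  design_n <- build_design(groups, "numeric")
  wn <- if (config$use_meanvar_weights[["eq_numeric"]]) {
    estimate_meanvar_weights(dataset, design_n)
  } else NULL
  numeric_stats <- ebayes_moderate(fit_gene_models(dataset, design_n, wn))

  # cell-means fit + contrasts
  design_c <- build_design(groups, "cellmeans")
  wc <- if (config$use_meanvar_weights[["eq_cellmeans"]]) {
    estimate_meanvar_weights(dataset, design_c)
  } else NULL
  fits_c <- fit_gene_models(dataset, design_c, wc)
  control_fit <- apply_contrasts(fits_c, control_contrasts())
  inter_fit <- apply_contrasts(fits_c, interstage_contrasts())

  calls <- stage_calls(control_fit, threshold = config$lfc_threshold)
  calls <- significance_cascade(calls, control_fit, inter_fit,
                                p_control = config$p_control,
                                p_inter = config$p_inter)
  partition <- partition_report(calls)

  monotonic <- monotonic_calls(dataset, numeric_stats)
  monotonic_ranked <- rank_monotonic(monotonic, p_max = config$p_monotonic)

  stage_specific <- dplyr::filter(tibble::as_tibble(calls),
                                  .data$stage_specific)
  stage_specific$regulation <- regulation_status(
    as.matrix(stage_specific[, paste0("lfc_", tumor_stages())]))

  stage4_pruned <- prune_stage4(calls, monotonic,
                                dplyr::select(linear_model, "gene", "adj_p"),
                                top_n = config$stage4_top_n)

  structure(list(linear_model = linear_model,
                 baseline_stats = baseline_stats,
                 numeric_stats = numeric_stats,
                 control_fit = control_fit, inter_fit = inter_fit,
                 calls = calls, stage_specific = stage_specific,
                 partition = partition, monotonic = monotonic,
                 monotonic_ranked = monotonic_ranked,
                 stage4_pruned = stage4_pruned,
                 n_samples = ncol(dataset$exprs),
                 config = config),
            class = "stage_analysis")
}

#' @export
print.stage_analysis <- function(x, ...) {
  n0 <- x$partition$n[x$partition$stage_string == "0000"]
  cat("<stage_analysis> ", nrow(x$linear_model), " genes, ", x$n_samples,
      " samples\n", sep = "")
  cat("stage-assigned: ", sum(x$partition$n) - n0, " (", n0,
      " eliminated as '0000')\n", sep = "")
  cat("stage-specific: ", nrow(x$stage_specific), " (",
      paste(tumor_stages(),
            table(factor(x$stage_specific$assigned_stage,
                         levels = tumor_stages())), sep = "=",
            collapse = ", "), ")\n", sep = "")
  cat("significant monotonic: ", nrow(x$monotonic_ranked), "\n", sep = "")
  invisible(x)
}

#' Run the full pipeline end to end and write reports
#'
#' Ingests (or simulates) the data, applies the preprocessing filters in
#' study order (merge, variance filter, stage-missing removal), runs
#' [run_analysis()], and writes all TSV reports plus a JSON run manifest
#' recording the configuration, seed and survivor counts at every filter
#' step. With a fixed seed the outputs are byte-identical across runs.
#'
#' @param expression,clinical TSV paths (firebrowse-style layout), or
#'   `NULL` when `sim` is given.
#' @param sim A [sim_config()] to simulate input instead of reading files.
#'   Simulated data skip the variance filter: planted residual noise is on
#'   a much smaller scale than the real-data filter assumes.
#' @param out_dir Output directory for reports; `NULL` writes nothing.
#' @param config A [pipeline_config()].
#' @return A `stage_pipeline_run` list: the `stage_analysis` result plus
#'   `dataset`, `manifest`, and (if simulated) `truth`.
#' @export
run_pipeline <- function(expression = NULL, clinical = NULL, sim = NULL,
                         out_dir = NULL, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    s <- simulate_stage_expression(sim)
    dataset <- s$dataset
    truth <- s$truth
    n_genes_in <- nrow(dataset$exprs)
    n_samples_in <- ncol(dataset$exprs)
    merged <- dataset
  } else {
    if (is.null(expression) || is.null(clinical)) {
      stop("either `sim` or both `expression` and `clinical` must be given",
           call. = FALSE)
    }
    merged <- merge_clinical(expression, clinical)
    n_genes_in <- nrow(merged$exprs)
    n_samples_in <- ncol(merged$exprs)
    dataset <- merged |>
      filter_low_variance(sigma_min = config$sigma_min) |>
      drop_missing_stage()
  }

  analysis <- run_analysis(dataset, config)

  manifest <- list(
    package_version = as.character(utils::packageVersion("stagewise")),
    seed = config$seed,
    config = unclass(config),
    simulated = !is.null(sim),
    counts = list(
      genes_in = n_genes_in,
      genes_after_variance_filter = nrow(dataset$exprs),
      samples_in = n_samples_in,
      samples_after_stage_filter = ncol(dataset$exprs),
      genes_string_0000 =
        analysis$partition$n[analysis$partition$stage_string == "0000"],
      genes_stage_assigned = sum(!is.na(analysis$calls$assigned_stage)),
      cascade = attr(analysis$calls, "cascade_counts"),
      stage_specific = nrow(analysis$stage_specific),
      monotonic_strict = sum(analysis$monotonic$direction != "none"),
      monotonic_significant = nrow(analysis$monotonic_ranked),
      monotonic_up = unname(attr(analysis$monotonic_ranked,
                                 "direction_counts")["UP"]),
      monotonic_down = unname(attr(analysis$monotonic_ranked,
                                   "direction_counts")["DOWN"]),
      stage4_pruned = nrow(analysis$stage4_pruned)))

  if (!is.null(out_dir)) {
    write_reports(analysis, manifest, out_dir)
  }
  structure(list(analysis = analysis, dataset = dataset, truth = truth,
                 manifest = manifest),
            class = "stage_pipeline_run")
}

# Write the standard TSV reports and the JSON manifest.
write_reports <- function(analysis, manifest, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(analysis$linear_model,
                   file.path(out_dir, "results_linear_model.tsv"))
  readr::write_tsv(tibble::as_tibble(analysis$monotonic_ranked),
                   file.path(out_dir, "results_monotonic.tsv"))
  readr::write_tsv(tibble::as_tibble(analysis$calls),
                   file.path(out_dir, "stage_strings.tsv"))
  readr::write_tsv(analysis$stage_specific,
                   file.path(out_dir, "stage_specific.tsv"))
  readr::write_tsv(analysis$partition,
                   file.path(out_dir, "partition_counts.tsv"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
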