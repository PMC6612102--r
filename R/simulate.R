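#' Simulation configuration
#'
#' Defines the conditions for a synthetic staged expression study: group
#' sizes for controls and the four tumor stages, a scaled-inverse-chi-square
#' prior on gene-level residual variances (matching the hierarchical model
#' the moderation step assumes), and the mixture of planted gene classes.
#'
#' Gene classes:
#' \describe{
#'   \item{null}{all stage offsets zero.}
#'   \item{stage_I..stage_IV}{a single offset of magnitude `effect_lfc`
#'     (random sign) in the named stage, zero elsewhere, so the named stage
#'     carries the strictly largest |lfc|.}
#'   \item{monotonic_up / monotonic_down}{offsets `+-monotone_step * (1:4)`
#'     across stages I--IV, giving strictly ordered group means.}
#'   \item{global_de}{the same `effect_lfc` offset (random sign) in all four
#'     stages: differentially expressed everywhere but specific to no stage.}
#' }
#'
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector of sample counts for
#'   `(control, I, II, III, IV)`; all must be >= 2 except stage IV which may
#'   be small (but >= 2). Defaults mimic a staged tumor cohort with many
#'   early-stage samples and very few stage-IV samples.
#' @param baseline_mean_range Interval (log2 scale) from which per-gene
#'   baseline means are drawn uniformly.
#' @param prior_df,prior_var Degrees of freedom and scale of the
#'   scaled-inverse-chi-square prior from which gene residual variances are
#'   drawn: `var_g = prior_var * prior_df / rchisq(prior_df)`.
#' @param class_fractions Named proportions over the gene classes; must sum
#'   to 1.
#' @param effect_lfc Log2 fold-change magnitude of planted stage-specific and
#'   global effects.
#' @param monotone_step Per-stage log2 increment of planted monotonic genes.
#' @param seed Integer seed; identical configurations (including seed) give
#'   bit-identical datasets.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       group_sizes = c(control = 50, I = 170, II = 85,
                                       III = 85, IV = 6),
                       baseline_mean_range = c(4, 12),
                       prior_df = 4,
                       prior_var = 0.05,
                       class_fractions = c(null = 0.80,
                                           stage_I = 0.03, stage_II = 0.03,
                                           stage_III = 0.03, stage_IV = 0.03,
                                           monotonic_up = 0.03,
                                           monotonic_down = 0.02,
                                           global_de = 0.03),
                       effect_lfc = 3,
                       monotone_step = 1,
                       seed = 1L) {
  group_sizes <- as.integer(group_sizes)
  names(group_sizes) <- stage_levels()
  if (length(group_sizes) != 5 || any(group_sizes < 2)) {
    stop("`group_sizes` must give >= 2 samples for control and each stage",
         call. = FALSE)
  }
  classes <- c("null", "stage_I", "stage_II", "stage_III", "stage_IV",
               "monotonic_up", "monotonic_down", "global_de")
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% classes)) {
    stop("`class_fractions` must be named with gene classes: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  frac <- stats::setNames(numeric(length(classes)), classes)
  frac[names(class_fractions)] <- class_fractions
  if (abs(sum(frac) - 1) > 1e-8 || any(frac < 0)) {
    stop("`class_fractions` must be non-negative and sum to 1", call. = FALSE)
  }
  if (prior_df <= 0 || prior_var <= 0) {
    stop("`prior_df` and `prior_var` must be positive", call. = FALSE)
  }
  if (n_genes < 1) stop("`n_genes` must be positive", call. = FALSE)
  if (length(baseline_mean_range) != 2 ||
      baseline_mean_range[2] < baseline_mean_range[1]) {
    stop("`baseline_mean_range` must be an increasing interval", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), group_sizes = group_sizes,
                 baseline_mean_range = baseline_mean_range,
                 prior_df = prior_df, prior_var = prior_var,
                 class_fractions = frac, effect_lfc = effect_lfc,
                 monotone_step = monotone_step, seed = as.integer(seed)),
            class = "sim_config")
}

# Deterministic integer allocation of n genes over class fractions
# (largest-remainder method, ties to earlier classes).
allocate_classes <- function(n, frac) {
  raw <- n * frac
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Simulate a staged expression study with planted ground truth
#'
#' Draws gene-level residual variances from the configured
#' scaled-inverse-chi-square prior, plants class-specific stage offsets on
#' top of uniform baselines, and adds Gaussian noise, yielding a log2
#' expression matrix with the statistical structure the downstream linear
#' modelling assumes.
#'
#' @param config A [sim_config()].
#' @return A list of class `stage_sim` with elements `dataset`
#'   (a [stage_dataset()]) and `truth` (a tibble with per-gene class, true
#'   specific stage, true stage offsets and true residual variance).
#' @export
simulate_stage_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  sizes <- config$group_sizes
  N <- sum(sizes)
  group <- rep(stage_levels(), times = sizes)

  counts <- allocate_classes(G, config$class_fractions)
  class <- rep(names(config$class_fractions), times = counts)

  gene <- sprintf("GSIM%05d", seq_len(G))
  variance <- config$prior_var * config$prior_df /
    stats::rchisq(G, df = config$prior_df)
  baseline <- stats::runif(G, config$baseline_mean_range[1],
                           config$baseline_mean_range[2])

  offsets <- matrix(0, nrow = G, ncol = 4,
                    dimnames = list(gene, tumor_stages()))
  sign <- sample(c(-1, 1), G, replace = TRUE)
  for (k in 1:4) {
    offsets[class == paste0("stage_", tumor_stages()[k]), k] <-
      config$effect_lfc
  }
  offsets[class == "global_de", ] <- config$effect_lfc
  n_up <- sum(class == "monotonic_up")
  n_dn <- sum(class == "monotonic_down")
  if (n_up > 0) {
    offsets[class == "monotonic_up", ] <-
      matrix(config$monotone_step * (1:4), n_up, 4, byrow = TRUE)
  }
  if (n_dn > 0) {
    offsets[class == "monotonic_down", ] <-
      -matrix(config$monotone_step * (1:4), n_dn, 4, byrow = TRUE)
  }
  flip <- class %in% c("stage_I", "stage_II", "stage_III", "stage_IV",
                       "global_de") & sign < 0
  offsets[flip, ] <- -offsets[flip, , drop = FALSE]

  group_idx <- match(group, tumor_stages())  # NA for controls
  shift <- cbind(0, offsets)[, ifelse(is.na(group_idx), 1, group_idx + 1),
                             drop = FALSE]
  exprs <- baseline + shift +
    matrix(stats::rnorm(G * N, sd = rep(sqrt(variance), N)), G, N)
  rownames(exprs) <- gene

  samples <- simulate_sample_sheet(group)
  truth <- tibble::tibble(
    gene = gene, class = class,
    true_stage = dplyr::case_when(
      class == "stage_I" ~ "I", class == "stage_II" ~ "II",
      class == "stage_III" ~ "III", class == "stage_IV" ~ "IV",
      TRUE ~ NA_character_),
    offset_I = offsets[, 1], offset_II = offsets[, 2],
    offset_III = offsets[, 3], offset_IV = offsets[, 4],
    true_variance = variance)

  structure(list(dataset = stage_dataset(exprs, samples), truth = truth,
                 config = config),
            class = "stage_sim")
}

# Barcodes follow the hybridization-ref layout the parser assumes: after
# dropping separators the first 10 characters identify the patient and the
# next two are the sample-type code (01 tumor, 11 solid tissue normal).
simulate_sample_sheet <- function(group) {
  n <- length(group)
  patient <- sprintf("TCGA-AA-%04d", seq_len(n))
  type_code <- ifelse(group == "control", "11", "01")
  barcode <- paste0(patient, "-", type_code, "A-11R-A131-07")
  substage <- ifelse(group %in% c("I", "II"), "",
                     sample(c("", "A", "B", "C"), n, replace = TRUE))
  pathologic_stage <- ifelse(group == "control", NA_character_,
                             paste0("Stage ", group, substage))
  tibble::tibble(barcode = barcode,
                 patient_id = gsub("[-.]", "", patient),
                 sample_type = ifelse(group == "control", "normal", "tumor"),
                 pathologic_stage = pathologic_stage,
                 stage = ifelse(group == "control", NA_character_,
                                as.character(group)),
                 group = group)
}

#' @export
print.stage_sim <- function(x, ...) {
  cat("<stage_sim> seed", x$config$seed, "\n")
  print(x$dataset)
  print(table(x$truth$class))
  invisible(x)
}

#' Write a simulated study in firebrowse-style TSV layout
#'
#' Produces the two files the ingest step expects: an expression TSV whose
#' header row is `Hybridization REF` followed by sample barcodes (with a
#' second header row of data-type labels, as in firebrowse exports), and a
#' clinical TSV keyed by lowercase patient barcode carrying the raw
#' `pathologic_stage` strings (substages intact). A truth TSV is written
#' alongside when the input is a simulation.
#'
#' @param x A `stage_sim` or [stage_dataset()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, a named list of the written file paths.
#' @export
write_firebrowse_style <- function(x, dir, prefix = "synthetic") {
  dataset <- if (inherits(x, "stage_sim")) x$dataset else x
  stopifnot(inherits(dataset, "stage_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, paste0(prefix, "_expression.tsv"))
  clin_path <- file.path(dir, paste0(prefix, "_clinical.tsv"))

  con <- file(expr_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("Hybridization REF", dataset$samples$barcode),
                   collapse = "\t"), con)
  writeLines(paste(c("gene_id", rep("normalized_count",
                                    nrow(dataset$samples))),
                   collapse = "\t"), con)
  utils::write.table(
    data.frame(gene = rownames(dataset$exprs), dataset$exprs,
               check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  tumor <- dataset$samples[dataset$samples$sample_type == "tumor", ]
  clinical <- tibble::tibble(
    bcr_patient_barcode = tolower(substr(tumor$barcode, 1, 12)),
    `pathologic stage` = ifelse(is.na(tumor$pathologic_stage), "NA",
                                tolower(tumor$pathologic_stage)))
  readr::write_tsv(clinical, clin_path)

  paths <- list(expression = expr_path, clinical = clin_path)
  if (inherits(x, "stage_sim")) {
    truth_path <- file.path(dir, paste0(prefix, "_truth.tsv"))
    readr::write_tsv(x$truth, truth_path)
    paths$truth <- truth_path
  }
  invisible(paths)
}
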