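#' Parse TCGA-style hybridization-ref barcodes
#'
#' After dropping `-` and `.` separators, the first 10 characters of a
#' barcode identify the patient and the following two characters are the
#' sample-type code: 01--09 for tumor samples, 10--19 for normal tissue.
#'
#' @param barcode Character vector of sample barcodes.
#' @return A tibble with columns `barcode`, `patient_id` (10-character
#'   identifier) and `sample_type` (`"tumor"` or `"normal"`).
#' @export
#' @examples
#' parse_barcode("TCGA-AA-0001-01A-11R-A131-07")
parse_barcode <- function(barcode) {
  stripped <- gsub("[-.]", "", barcode)
  short <- nchar(stripped) < 12
  if (any(short)) {
    stop("malformed barcode (fewer than 12 informative characters): ",
         paste(utils::head(barcode[short], 3), collapse = ", "),
         call. = FALSE)
  }
  code <- suppressWarnings(as.integer(substr(stripped, 11, 12)))
  bad <- is.na(code) | code < 1 | code > 19
  if (any(bad)) {
    stop("unrecognized sample-type code in barcode: ",
         paste(utils::head(barcode[bad], 3), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(barcode = barcode,
                 patient_id = substr(stripped, 1, 10),
                 sample_type = ifelse(code <= 9, "tumor", "normal"))
}

#' Collapse pathologic-stage strings to parent stages
#'
#' Matches stage labels case-insensitively after stripping a `"stage"`
#' prefix; substages (A, B, C) are collapsed into the parent stage, e.g.
#' `"Stage IIIA"` becomes `"III"`. Missing or `"NA"` values stay missing;
#' unrecognized non-empty values become missing with a warning.
#'
#' @param x Character vector of raw stage annotations.
#' @return Character vector with values in `I`, `II`, `III`, `IV` or `NA`.
#' @export
collapse_stage <- function(x) {
  raw <- trimws(as.character(x))
  core <- toupper(sub("^\\s*stage\\s*", "", raw, ignore.case = TRUE))
  parent <- sub("^(IV|III|II|I)[ABC]?$", "\\1", core)
  out <- ifelse(parent %in% tumor_stages(), parent, NA_character_)
  missing_like <- is.na(raw) | raw == "" | toupper(raw) %in% c("NA", "[NOT AVAILABLE]")
  unrec <- is.na(out) & !missing_like
  if (any(unrec)) {
    warning("unrecognized stage value(s) treated as missing: ",
            paste(unique(utils::head(raw[unrec], 5)), collapse = ", "),
            call. = FALSE)
  }
  out
}

# Read a firebrowse-style expression TSV: header row "Hybridization REF"
# followed by barcodes; an optional second header row of data-type labels
# (e.g. "normalized_count") is detected and skipped; first column gene ids.
read_firebrowse_expression <- function(path) {
  header <- strsplit(readLines(path, n = 2), "\t")
  barcodes <- header[[1]][-1]
  second_is_types <- length(header) > 1 &&
    all(is.na(suppressWarnings(as.numeric(header[[2]][-1]))))
  body <- readr::read_tsv(path, skip = if (second_is_types) 2 else 1,
                          col_names = c("gene", barcodes),
                          col_types = readr::cols(
                            gene = readr::col_character(),
                            .default = readr::col_double()),
                          progress = FALSE)
  gene <- body$gene
  dup <- duplicated(gene) | duplicated(gene, fromLast = TRUE)
  gene[dup] <- paste0(gene[dup], "|", which(dup))  # composite key on clashes
  exprs <- as.matrix(body[, -1, drop = FALSE])
  rownames(exprs) <- gene
  exprs
}

# Read a clinical TSV, normalizing variable names (lowercase, spaces and
# dots to underscores) and locating the patient-barcode and pathologic-stage
# columns.
read_clinical <- function(path) {
  clin <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  names(clin) <- gsub("[. ]+", "_", tolower(names(clin)))
  stage_col <- grep("pathologic_stage$", names(clin), value = TRUE)
  key_col <- grep("patient_barcode$|^hybridization_ref$", names(clin),
                  value = TRUE)
  if (length(stage_col) == 0) {
    stop("clinical table has no pathologic stage column", call. = FALSE)
  }
  if (length(key_col) == 0) key_col <- names(clin)[1]
  tibble::tibble(
    patient_id = substr(toupper(gsub("[-.]", "", clin[[key_col[1]]])), 1, 10),
    pathologic_stage = clin[[stage_col[1]]])
}

#' Merge expression data with clinical stage annotation
#'
#' Parses the expression header barcodes, labels normal-coded samples as
#' controls, and joins tumor samples to the clinical table by patient
#' identifier to attach the collapsed pathologic stage. Tumor samples with
#' no clinical row (or an unusable stage value) are recorded as
#' stage-missing rather than dropped here; [drop_missing_stage()] removes
#' them.
#'
#' @param expression Path to a firebrowse-style expression TSV (header row
#'   `Hybridization REF` + barcodes, optional second header row of data-type
#'   labels), or a numeric matrix with barcode column names.
#' @param clinical Path to a clinical TSV keyed by patient barcode with a
#'   pathologic-stage column, or a data frame with columns `patient_id` and
#'   `pathologic_stage`.
#' @return A [stage_dataset()]; controls have `group = "control"`, tumor
#'   samples `group` equal to their collapsed stage (`NA` if missing).
#' @export
merge_clinical <- function(expression, clinical) {
  exprs <- if (is.character(expression)) {
    read_firebrowse_expression(expression)
  } else {
    as.matrix(expression)
  }
  clin <- if (is.character(clinical)) {
    read_clinical(clinical)
  } else {
    tibble::as_tibble(clinical)
  }
  clin <- dplyr::distinct(clin, .data$patient_id, .keep_all = TRUE)

  samples <- parse_barcode(colnames(exprs))
  samples <- dplyr::left_join(samples, clin, by = "patient_id")
  samples$stage <- collapse_stage(samples$pathologic_stage)
  samples$stage[samples$sample_type == "normal"] <- NA_character_
  samples$group <- dplyr::if_else(samples$sample_type == "normal", "control",
                                  samples$stage)
  stage_dataset(exprs, samples)
}

#' Remove genes with little expression change across all samples
#'
#' Drops genes whose sample standard deviation across all samples (controls
#' included, denominator n - 1, log2 scale) is strictly below `sigma_min`.
#' The order of surviving genes is preserved.
#'
#' @param dataset A [stage_dataset()] with at least 2 samples.
#' @param sigma_min Positive standard-deviation cutoff; genes with
#'   `sd < sigma_min` are removed (a gene at exactly `sigma_min` is kept).
#' @return The filtered `stage_dataset`.
#' @export
filter_low_variance <- function(dataset, sigma_min = 1) {
  stopifnot(inherits(dataset, "stage_dataset"))
  if (sigma_min <= 0) stop("`sigma_min` must be positive", call. = FALSE)
  if (ncol(dataset$exprs) < 2) {
    stop("variance filter needs at least 2 samples", call. = FALSE)
  }
  sds <- sqrt(row_vars(dataset$exprs))
  subset_dataset(dataset, genes = sds >= sigma_min)
}

# Row-wise sample variances (denominator n - 1), vectorized.
row_vars <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

#' Remove tumor samples lacking stage annotation
#'
#' Tumor samples whose collapsed stage is missing are removed; controls are
#' always retained (the rule applies to cancer samples only).
#'
#' @param dataset A [stage_dataset()].
#' @return The filtered `stage_dataset`.
#' @export
drop_missing_stage <- function(dataset) {
  stopifnot(inherits(dataset, "stage_dataset"))
  keep <- dataset$samples$group %in% "control" | !is.na(dataset$samples$group)
  subset_dataset(dataset, samples = keep)
}

#' Run the full preprocessing chain
#'
#' Merge, then variance-filter, then drop stage-missing tumor samples --
#' the order the analysis expects.
#'
#' @inheritParams merge_clinical
#' @inheritParams filter_low_variance
#' @return A fully preprocessed [stage_dataset()].
#' @export
preprocess_dataset <- function(expression, clinical, sigma_min = 1) {
  merge_clinical(expression, clinical) |>
    filter_low_variance(sigma_min = sigma_min) |>
    drop_missing_stage()
}
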