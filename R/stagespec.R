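#' Four-bit stage string of differential expression
#'
#' Character k of the string is `'1'` iff the absolute stage-k log
#' fold-change versus control strictly exceeds the threshold (absolute
#' value, since driver genes may be up- or downregulated). `'1100'` means
#' differential expression in stages I and II only.
#'
#' @param lfcs Numeric vector of four stage lfcs (I--IV vs control), or a
#'   genes x 4 matrix.
#' @param threshold Positive |lfc| cutoff; the default 2 corresponds to a
#'   4-fold change.
#' @return Character scalar or vector of 4-bit strings.
#' @export
stage_string <- function(lfcs, threshold = 2) {
  m <- if (is.matrix(lfcs)) lfcs else matrix(lfcs, nrow = 1)
  if (ncol(m) != 4) stop("expected four stage lfc values", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite lfc value", call. = FALSE)
  bits <- (abs(m) > threshold) + 0L
  out <- apply(bits, 1, paste, collapse = "")
  if (!is.matrix(lfcs)) out[1] else unname(out)
}

#' Assign each gene to its maximal-|lfc| stage
#'
#' Genes whose stage string is `'0000'` (no stage beyond the threshold) are
#' eliminated (`NA`); the rest are assigned to the stage with the highest
#' |lfc|. Ties are broken toward the earliest stage and flagged.
#'
#' @inheritParams stage_string
#' @return A tibble with columns `assigned_stage` (factor over I--IV, `NA`
#'   if eliminated) and `tie` (logical).
#' @export
assign_stage <- function(lfcs, threshold = 2) {
  m <- if (is.matrix(lfcs)) lfcs else matrix(lfcs, nrow = 1)
  string <- stage_string(m, threshold)
  a <- abs(m)
  idx <- apply(a, 1, which.max)  # which.max already ties to the first
  tie <- apply(a, 1, function(r) sum(r == max(r)) > 1)
  stage <- tumor_stages()[idx]
  stage[string == "0000"] <- NA_character_
  tie[string == "0000"] <- FALSE
  if (any(tie)) {
    message(sum(tie), " gene(s) had tied maximal |lfc|; ",
            "assigned to the earliest tied stage")
  }
  tibble::tibble(assigned_stage = factor(stage, levels = tumor_stages()),
                 tie = tie)
}

#' Build per-gene stage calls from stage-versus-control contrasts
#'
#' Combines the stagewise lfc estimates with the stage-string and
#' argmax-|lfc| assignment into one table, the unit record of the
#' stage-specificity analysis.
#'
#' @param control_fit A `contrast_fit` from [apply_contrasts()] with the
#'   four [control_contrasts()].
#' @param threshold |lfc| cutoff for the stage string.
#' @return A tibble of class `stage_calls`: `gene`, `lfc_I`..`lfc_IV`,
#'   `stage_string`, `assigned_stage`, `tie`, with the threshold stored as
#'   an attribute.
#' @export
stage_calls <- function(control_fit, threshold = 2) {
  stopifnot(inherits(control_fit, "contrast_fit"))
  lfc <- control_fit$estimate
  if (ncol(lfc) != 4) {
    stop("expected the four stage-vs-control contrasts", call. = FALSE)
  }
  asg <- assign_stage(lfc, threshold)
  out <- tibble::tibble(gene = control_fit$genes,
                        lfc_I = lfc[, 1], lfc_II = lfc[, 2],
                        lfc_III = lfc[, 3], lfc_IV = lfc[, 4],
                        stage_string = stage_string(lfc, threshold),
                        assigned_stage = asg$assigned_stage,
                        tie = asg$tie)
  attr(out, "threshold") <- threshold
  class(out) <- c("stage_calls", class(out))
  out
}

#' Four-pronged significance cascade for stage-specific genes
#'
#' For each stage-assigned gene, prong (i) requires the BH-adjusted p-value
#' of the assigned stage's contrast versus control below `p_control`
#' (stringent: a driver's profile must depart markedly from the controls);
#' prongs (ii)--(iv) require the raw p-value of each of the three
#' inter-stage contrasts involving the assigned stage below `p_inter`
#' (relaxed, to retain sensitivity). A gene is stage-specific iff all four
#' prongs pass.
#'
#' @param calls A [stage_calls()] tibble.
#' @param control_fit `contrast_fit` of the four [control_contrasts()].
#' @param inter_fit `contrast_fit` of the six [interstage_contrasts()].
#' @param p_control Adjusted-p threshold for the control contrast.
#' @param p_inter Raw-p threshold for each inter-stage contrast.
#' @return The input tibble with added columns `p_control_adj`,
#'   `p_inter_1`..`p_inter_3` (inter-stage p-values against the other
#'   stages in ascending stage order), prong flags `pass_control`,
#'   `pass_inter_1`..`pass_inter_3`, and `stage_specific`. Survivor counts
#'   per stage after each prong are attached as attribute
#'   `cascade_counts`.
#' @export
significance_cascade <- function(calls, control_fit, inter_fit,
                                 p_control = 0.001, p_inter = 0.05) {
  stopifnot(inherits(calls, "stage_calls"),
            inherits(control_fit, "contrast_fit"),
            inherits(inter_fit, "contrast_fit"))
  G <- nrow(calls)
  stage <- as.character(calls$assigned_stage)

  ctrl_cols <- paste0(tumor_stages(), "_vs_control")
  if (!all(ctrl_cols %in% colnames(control_fit$adj_p))) {
    stop("`control_fit` is missing stage-vs-control contrast results",
         call. = FALSE)
  }
  p_ctrl <- rep(NA_real_, G)
  pin <- matrix(NA_real_, G, 3)
  for (k in tumor_stages()) {
    rows <- which(stage == k)
    if (length(rows) == 0) next
    p_ctrl[rows] <- control_fit$adj_p[rows, paste0(k, "_vs_control")]
    others <- setdiff(tumor_stages(), k)
    for (j in 1:3) {
      nm <- c(paste0(k, "_vs_", others[j]), paste0(others[j], "_vs_", k))
      nm <- nm[nm %in% colnames(inter_fit$p)]
      if (length(nm) == 0) {
        stop("missing inter-stage contrast between ", k, " and ", others[j],
             call. = FALSE)
      }
      pin[rows, j] <- inter_fit$p[rows, nm[1]]
    }
  }

  assigned <- !is.na(calls$assigned_stage)
  pass_control <- assigned & !is.na(p_ctrl) & p_ctrl < p_control
  pass_inter <- !is.na(pin) & pin < p_inter
  pass_inter[!assigned, ] <- FALSE
  specific <- pass_control & pass_inter[, 1] & pass_inter[, 2] &
    pass_inter[, 3]

  out <- dplyr::mutate(calls,
    p_control_adj = p_ctrl,
    p_inter_1 = pin[, 1], p_inter_2 = pin[, 2], p_inter_3 = pin[, 3],
    pass_control = pass_control,
    pass_inter_1 = pass_inter[, 1], pass_inter_2 = pass_inter[, 2],
    pass_inter_3 = pass_inter[, 3],
    stage_specific = specific)

  surv <- function(flag) {
    tab <- table(factor(stage[flag], levels = tumor_stages()))
    as.integer(tab)
  }
  counts <- tibble::tibble(
    stage = tumor_stages(),
    assigned = surv(assigned),
    after_control = surv(pass_control),
    after_inter_1 = surv(pass_control & pass_inter[, 1]),
    after_inter_2 = surv(pass_control & pass_inter[, 1] & pass_inter[, 2]),
    stage_specific = surv(specific))
  attr(out, "cascade_counts") <- counts
  attr(out, "thresholds") <- c(p_control = p_control, p_inter = p_inter)
  class(out) <- unique(c("stage_calls", class(out)))
  out
}

#' Count genes in each of the 16 stage-string bins
#'
#' The \eqn{2^4 = 16} possible four-bit strings partition all genes; the
#' counts sum to the total gene count, and the complement of the `'0000'`
#' bin is the number of stage-assigned genes.
#'
#' @param calls A [stage_calls()] tibble.
#' @return Tibble with columns `stage_string` (all 16 strings) and `n`.
#' @export
partition_report <- function(calls) {
  stopifnot(inherits(calls, "stage_calls"))
  bins <- apply(expand.grid(rep(list(0:1), 4))[, 4:1], 1, paste,
                collapse = "")
  bins <- sort(bins)
  tibble::tibble(stage_string = bins,
                 n = as.integer(table(factor(calls$stage_string,
                                             levels = bins))))
}

#' Prune stage-IV calls to monotone, top-ranked genes
#'
#' The stage-IV group is typically tiny, giving low power to reject false
#' positives; stage-IV specific genes are therefore additionally required to
#' show a strictly monotone group-mean trajectory through cancer
#' progression (culminating in maximal differential expression in stage IV)
#' and are then ranked by the genome-wide linear-model adjusted p-value,
#' keeping the `top_n` most significant.
#'
#' @param calls A cascade-annotated [stage_calls()] tibble
#'   (from [significance_cascade()]).
#' @param monotonic_directions Tibble with columns `gene` and `direction`
#'   (`UP` / `DOWN` / `none`), e.g. from [classify_monotonic()] via
#'   [monotonic_calls()].
#' @param linmod_ranks Tibble with columns `gene` and `adj_p` carrying the
#'   baseline linear model's BH-adjusted F p-values.
#' @param top_n Number of stage-IV genes to keep (>= 1).
#' @return Tibble of the retained stage-IV genes, ranked by `adj_p`.
#' @export
prune_stage4 <- function(calls, monotonic_directions, linmod_ranks,
                         top_n = 10) {
  stopifnot(inherits(calls, "stage_calls"))
  if (top_n < 1) stop("`top_n` must be at least 1", call. = FALSE)
  s4 <- dplyr::filter(calls, .data$assigned_stage %in% "IV",
                      .data$stage_specific)
  s4 <- dplyr::inner_join(
    tibble::as_tibble(s4),
    dplyr::select(monotonic_directions, "gene", "direction"),
    by = "gene")
  s4 <- dplyr::filter(s4, .data$direction != "none")
  s4 <- dplyr::inner_join(s4, dplyr::select(linmod_ranks, "gene", "adj_p"),
                          by = "gene")
  s4 <- dplyr::arrange(s4, .data$adj_p)
  utils::head(s4, top_n)
}
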