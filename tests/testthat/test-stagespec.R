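test_that("stage strings follow the strict absolute-lfc rule", {
  expect_equal(stage_string(c(2.5, 2.1, 0.3, -0.5)), "1100")
  expect_equal(stage_string(c(0, 0, 0, 0)), "0000")
  expect_equal(stage_string(c(-3, 0, 0, 0)), "1000")  # absolute value governs
  expect_equal(stage_string(c(2, 2, 2, 2)), "0000")   # strictly greater than
  expect_equal(stage_string(c(2.0001, -2.0001, 0, 0)), "1100")
  expect_error(stage_string(c(1, 2, NA, 4)), "non-finite")
  expect_error(stage_string(c(1, 2, Inf, 4)), "non-finite")
  m <- rbind(c(2.5, 2.1, 0.3, -0.5), c(0, 0, 0, 0))
  expect_equal(stage_string(m), c("1100", "0000"))
})

test_that("stage assignment is argmax with earliest-stage tie-breaking", {
  a <- assign_stage(rbind(c(2.5, 2.1, 0.3, -0.5),
                          c(0, 0, 0, 0),
                          c(0, 0, 0.5, -3)))
  expect_equal(as.character(a$assigned_stage), c("I", NA, "IV"))
  expect_message(
    tie <- assign_stage(matrix(c(2.5, 2.5, 0, 0), 1)), "tied")
  expect_equal(as.character(tie$assigned_stage), "I")
  expect_true(tie$tie)
})

test_that("the partition report is an exhaustive disjoint 16-bin partition", {
  sim <- simulate_stage_expression(sim_config(n_genes = 300, seed = 19))
  fit <- fit_gene_models(sim$dataset,
                         build_design(sim$dataset$samples$group, "cellmeans"))
  calls <- stage_calls(apply_contrasts(fit, control_contrasts()))
  part <- partition_report(calls)
  expect_equal(nrow(part), 16)
  expect_equal(sum(part$n), nrow(calls))
  # complement identity: total - '0000' = stage-assigned
  expect_equal(sum(part$n) - part$n[part$stage_string == "0000"],
               sum(!is.na(calls$assigned_stage)))
  # all-null data put all mass in '0000'
  sim0 <- simulate_stage_expression(sim_config(
    n_genes = 200, class_fractions = c(null = 1), seed = 20))
  fit0 <- fit_gene_models(sim0$dataset,
                          build_design(sim0$dataset$samples$group,
                                       "cellmeans"))
  calls0 <- stage_calls(apply_contrasts(fit0, control_contrasts()))
  part0 <- partition_report(calls0)
  expect_equal(part0$n[part0$stage_string == "0000"], nrow(calls0))
})

test_that("the cascade enforces all four prongs for the assigned stage", {
  sim <- simulate_stage_expression(sim_config(n_genes = 800, seed = 29))
  fit <- fit_gene_models(sim$dataset,
                         build_design(sim$dataset$samples$group, "cellmeans"))
  ctrl <- apply_contrasts(fit, control_contrasts())
  inter <- apply_contrasts(fit, interstage_contrasts())
  calls <- significance_cascade(stage_calls(ctrl), ctrl, inter)

  spec <- dplyr::filter(calls, stage_specific)
  # every stage-specific gene passed every prong
  expect_true(all(spec$pass_control & spec$pass_inter_1 &
                    spec$pass_inter_2 & spec$pass_inter_3))
  expect_true(all(spec$p_control_adj < 0.001))
  expect_true(all(spec$p_inter_1 < 0.05 & spec$p_inter_2 < 0.05 &
                    spec$p_inter_3 < 0.05))
  # specificity is exclusive: one stage per gene
  expect_true(all(!is.na(spec$assigned_stage)))
  expect_lte(max(table(spec$gene)), 1)

  # a failed control prong vetoes regardless of inter-stage prongs
  fails <- dplyr::filter(calls, !is.na(assigned_stage),
                         p_control_adj >= 0.001)
  expect_true(all(!fails$stage_specific))

  # survivor counts shrink monotonically prong by prong
  counts <- attr(calls, "cascade_counts")
  expect_true(all(counts$after_control <= counts$assigned))
  expect_true(all(counts$after_inter_1 <= counts$after_control))
  expect_true(all(counts$after_inter_2 <= counts$after_inter_1))
  expect_true(all(counts$stage_specific <= counts$after_inter_2))

  # loosening p_inter can only grow the stage-specific set
  loose <- significance_cascade(stage_calls(ctrl), ctrl, inter,
                                p_inter = 0.5)
  expect_true(all(calls$gene[calls$stage_specific] %in%
                    loose$gene[loose$stage_specific]))
})

test_that("planted stage-specific genes pass the cascade at their stage", {
  sim <- simulate_stage_expression(sim_config(n_genes = 500, seed = 37))
  fit <- fit_gene_models(sim$dataset,
                         build_design(sim$dataset$samples$group, "cellmeans"))
  ctrl <- apply_contrasts(fit, control_contrasts())
  inter <- apply_contrasts(fit, interstage_contrasts())
  calls <- significance_cascade(stage_calls(ctrl), ctrl, inter)
  merged <- dplyr::inner_join(tibble::as_tibble(calls), sim$truth,
                              by = "gene")
  planted3 <- dplyr::filter(merged, class == "stage_III")
  expect_gt(mean(planted3$stage_specific &
                   planted3$assigned_stage == "III"), 0.9)
  # globally differentially expressed genes are never stage-specific
  global <- dplyr::filter(merged, class == "global_de")
  expect_true(all(!global$stage_specific))
})

test_that("stage-IV pruning keeps only monotone, top-ranked genes", {
  calls <- tibble::tibble(
    gene = paste0("g", 1:6),
    lfc_I = 0.1, lfc_II = 0.5, lfc_III = 1.5, lfc_IV = 3,
    stage_string = "0001",
    assigned_stage = factor("IV", levels = c("I", "II", "III", "IV")),
    tie = FALSE, stage_specific = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  class(calls) <- c("stage_calls", class(calls))
  dirs <- tibble::tibble(gene = paste0("g", 1:6),
                         direction = c("UP", "UP", "none", "DOWN", "UP",
                                       "UP"))
  ranks <- tibble::tibble(gene = paste0("g", 1:6),
                          adj_p = c(0.04, 0.001, 1e-6, 0.02, 0.3, 1e-9))
  pruned <- prune_stage4(calls, dirs, ranks, top_n = 3)
  # non-monotone g3 is excluded before ranking; non-specific g6 excluded
  expect_equal(pruned$gene, c("g2", "g4", "g1"))
  # fewer qualifying genes than top_n returns them all
  expect_equal(nrow(prune_stage4(calls, dirs, ranks, top_n = 10)), 4)
  expect_error(prune_stage4(calls, dirs, ranks, top_n = 0), "at least 1")
})
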