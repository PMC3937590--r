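test_that("best AUC table takes the maximum over methods per cell", {
  ev <- tibble::tibble(
    compound = rep(c("d1", "d2"), each = 4),
    data_type = rep(rep(c("rnaseq", "methylation"), each = 2), 2),
    method = rep(c("lssvm", "rf"), 4),
    auc = c(0.7, 0.8, 0.6, 0.65, 0.9, 0.85, 0.55, 0.5))
  tab <- best_auc_table(ev)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$best_auc[tab$compound == "d1" &
                              tab$data_type == "rnaseq"], 0.8)
  expect_error(best_auc_table(dplyr::select(ev, -"auc")), "auc")
})

test_that("data-type ranking detects a uniformly shifted platform", {
  withr::with_seed(61, {
    n_cmp <- 20
    base <- runif(n_cmp, 0.5, 0.8)
    grid <- dplyr::bind_rows(
      tibble::tibble(compound = sprintf("c%02d", 1:n_cmp),
                     data_type = "methylation", best_auc = base),
      tibble::tibble(compound = sprintf("c%02d", 1:n_cmp),
                     data_type = "rnaseq", best_auc = base + 0.1),
      tibble::tibble(compound = sprintf("c%02d", 1:n_cmp),
                     data_type = "copy_number",
                     best_auc = base + rnorm(n_cmp, sd = 0.02)))
    rk <- rank_data_types(grid)
    expect_equal(rk$ranking$data_type[1], "rnaseq")
    expect_equal(rk$ranking$wins[rk$ranking$data_type == "rnaseq"], 20L)
    pw <- rk$pairwise
    rn_me <- pw[pw$type1 == "methylation" & pw$type2 == "rnaseq" |
                  pw$type1 == "rnaseq" & pw$type2 == "methylation", ]
    # constant +0.1 difference: paired t is degenerate-perfect, adjusted
    # significance survives BH
    expect_lt(rn_me$p_adjusted, 0.05)
    expect_lt(rk$overall$p_value, 0.01)
    # adjusted p never below raw p
    expect_true(all(pw$p_adjusted >= pw$p_value - 1e-15, na.rm = TRUE))
    # invariant to compound ordering
    rk2 <- rank_data_types(grid[sample(nrow(grid)), ])
    expect_equal(rk$ranking, rk2$ranking)
    expect_equal(rk$overall, rk2$overall)
  })
})

test_that("identical AUC columns yield tied wins and a p of 1", {
  grid <- tibble::tibble(
    compound = rep(sprintf("c%d", 1:5), 2),
    data_type = rep(c("rnaseq", "methylation"), each = 5),
    best_auc = rep(c(0.6, 0.7, 0.8, 0.65, 0.75), 2))
  rk <- rank_data_types(grid)
  expect_equal(rk$ranking$wins, c(5L, 5L))
  expect_equal(rk$pairwise$p_value, 1)
  expect_equal(rk$pairwise$flag, "zero_variance")
  expect_error(rank_data_types(grid[grid$data_type == "rnaseq", ]), ">= 2")
})

test_that("a noise grid is usually non-significant overall", {
  withr::with_seed(67, {
    hits <- vapply(1:60, function(i) {
      grid <- tibble::tibble(
        compound = rep(sprintf("c%02d", 1:12), 3),
        data_type = rep(c("a", "b", "c"), each = 12),
        best_auc = runif(36, 0.4, 0.9))
      rank_data_types(grid)$overall$p_value > 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.9)
  })
})

test_that("subtype baseline is strong for subtype-driven response, null otherwise", {
  panel <- quick_panel(seed = 71, n_lines = 40, n_features = 50,
                       compounds = dplyr::bind_rows(
                         design_compound("dS", driver = "subtype",
                                         gi50_spread = 1.5,
                                         gi50_noise_sd = 0.3),
                         design_compound("dN", driver = "null")))
  labS <- dichotomize(panel$response, "dS")
  aucS <- subtype_baseline(labS, panel$annotation, n_splits = 10,
                           seed = 3)$mean_auc
  expect_gte(aucS, 0.8)

  labN <- dichotomize(panel$response, "dN")
  aucN <- subtype_baseline(labN, panel$annotation, n_splits = 20,
                           seed = 3)$mean_auc
  expect_lt(abs(aucN - 0.5), 0.2)
})

test_that("subtype sufficiency rule partitions with exact boundaries", {
  expect_equal(classify_subtype_sufficiency(0.80, 0.75), "subtype_sufficient")
  expect_equal(classify_subtype_sufficiency(0.72, 0.55), "omics_adds")
  expect_equal(classify_subtype_sufficiency(0.65, 0.60), "weak")
  # boundaries: delta exactly 0.1 counts as omics_adds; AUC exactly 0.7
  # does not pass the strict floor
  expect_equal(classify_subtype_sufficiency(0.85, 0.75), "omics_adds")
  expect_equal(classify_subtype_sufficiency(0.80, 0.70), "omics_adds")
  expect_equal(classify_subtype_sufficiency(0.70, 0.65), "weak")
  # vectorized and exhaustive over a lattice: every pair gets exactly one
  grid <- expand.grid(best = seq(0, 1, 0.05), sub = seq(0, 1, 0.05))
  cls <- classify_subtype_sufficiency(grid$best, grid$sub)
  expect_true(all(cls %in% c("subtype_sufficient", "omics_adds", "weak")))
})

test_that("splice deltas difference and flag per compound", {
  all_f <- c(d1 = 0.8, d2 = 0.75, d3 = 0.9)
  gene <- c(d1 = 0.8, d2 = 0.69, d3 = 0.7)
  sd_ <- splice_delta(all_f, gene)
  expect_equal(sd_$delta, c(0, 0.06, 0.2))
  expect_equal(sd_$splice_specific, c(FALSE, TRUE, TRUE))
  expect_equal(attr(sd_, "mean_delta"), mean(c(0, 0.06, 0.2)))
})

test_that("gene-only signal gives splice deltas centred at zero", {
  panel <- quick_panel(seed = 83, n_lines = 36, n_features = 60,
                       compounds = design_compound("dA", n_planted = 8,
                                                   effect_size = 2))
  # derive multi-level ids: copy the expression data, relabel half the
  # features as junction-level noise carriers
  vals <- panel$omics$expression_array$values
  ids <- colnames(vals)
  junk <- withr::with_seed(83, matrix(rnorm(nrow(vals) * 30), nrow(vals), 30,
                dimnames = list(rownames(vals),
                                sprintf("GEX%04d|junction|j", 1:30))))
  ds_all <- omic_dataset(cbind(vals, junk), "rnaseq")
  ds_gene <- omic_dataset(vals, "rnaseq")
  lab <- dichotomize(panel$response, "dA")
  a_all <- evaluate_multisplit(assemble_features(ds_all), lab, "lssvm",
                               n_splits = 10, seed = 5)$mean_auc
  a_gene <- evaluate_multisplit(assemble_features(ds_gene), lab, "lssvm",
                                n_splits = 10, seed = 5)$mean_auc
  expect_lt(abs(splice_delta(a_all, a_gene)$delta), 0.05)
})

test_that("labeling concordance is a symmetric percent agreement", {
  la <- setNames(rep(c("sensitive", "resistant"), c(3, 2)),
                 sprintf("L%d", 1:5))
  expect_equal(gi50_tgi_concordance(la, la), 100)
  lb <- setNames(ifelse(la == "sensitive", "resistant", "sensitive"),
                 names(la))
  expect_equal(gi50_tgi_concordance(la, lb), 0)
  lc <- la; lc[1] <- "resistant"
  expect_equal(gi50_tgi_concordance(la, lc), 80)
  expect_equal(gi50_tgi_concordance(lc, la), 80)
  # 34 of 51 agreeing
  big_a <- setNames(rep("sensitive", 51), sprintf("L%02d", 1:51))
  big_b <- big_a; big_b[1:17] <- "resistant"
  expect_equal(round(gi50_tgi_concordance(big_a, big_b), 1), 66.7)
})
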