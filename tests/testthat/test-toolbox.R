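make_cutoffs <- function(c1, c2) {
  structure(list(cutoff1 = c1, cutoff2 = c2, n_components = 3L,
                 loglik = NA_real_, flag = "ok"), class = "cutoff_pair")
}

test_that("status assignment resolves boundaries toward resistance", {
  cp <- make_cutoffs(0.3, 0.7)
  expect_equal(assign_status(c(0.3, 0.5, 0.7, 0.71, 1.0), cp),
               c("resistant", "intermediate", "intermediate",
                 "sensitive", "sensitive"))
  expect_equal(assign_status(0.0, cp), "resistant")
})

test_that("probability rescaling hits its anchors and stays monotone", {
  cp <- make_cutoffs(0.5, 0.75)
  expect_equal(rescale_probability(c(0, 0.5, 0.625, 0.75, 1), cp),
               c(0, 1 / 3, 0.5, 2 / 3, 1))
  p <- seq(0, 1, length.out = 101)
  r <- rescale_probability(p, cp)
  expect_true(all(diff(r) > 0))
  # status bands map exactly onto display thirds
  st <- assign_status(p, cp)
  expect_true(all(r[st == "resistant"] <= 1 / 3 + 1e-12))
  expect_true(all(r[st == "intermediate"] > 1 / 3 &
                    r[st == "intermediate"] <= 2 / 3 + 1e-12))
  expect_true(all(r[st == "sensitive"] > 2 / 3))
})

test_that("mixture cutoffs recover analytic intersections of a trimodal cohort", {
  # equal weights and sds: density intersections at the midpoints 0.35, 0.65
  hits <- vapply(1:20, function(s) {
    p <- withr::with_seed(300 + s,
      pmin(pmax(c(rnorm(100, 0.2, 0.05), rnorm(100, 0.5, 0.05),
                  rnorm(100, 0.8, 0.05)), 0), 1))
    cp <- select_cutoffs(p, seed = s)
    abs(cp$cutoff1 - 0.35) <= 0.05 && abs(cp$cutoff2 - 0.65) <= 0.05
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("bimodal and degenerate cohorts fall back sensibly", {
  p2 <- withr::with_seed(9, c(rnorm(150, 0.2, 0.05), rnorm(150, 0.8, 0.05)))
  cp2 <- select_cutoffs(p2, seed = 1)
  expect_equal(cp2$n_components, 2)
  expect_lt(abs(cp2$cutoff2 - 0.5), 0.05)
  expect_lt(cp2$cutoff1, cp2$cutoff2)

  cp3 <- select_cutoffs(rep(0.5, 50))
  expect_equal(cp3$flag, "fallback")
  expect_lt(cp3$cutoff1, cp3$cutoff2)

  expect_error(select_cutoffs(runif(10)), ">= 30")
})

test_that("compound ranking enforces floors and the dynamic-range tie-break", {
  preds <- tibble::tibble(
    patient = rep("P1", 4),
    compound = c("dA", "dB", "dC", "dD"),
    probability = c(0.8, 0.8, 0.9, 0.95),
    rescaled = c(0.7, 0.7, 0.8, 0.9),
    status = c("sensitive", "sensitive", "sensitive", "sensitive"),
    model_auc = c(0.85, 0.85, 0.9, 0.65),
    dynamic_range = c(1.0, 2.0, 0.5, 3.0))
  rep_ <- rank_compounds(preds)
  # dD excluded by the AUC floor; equal-probability dA/dB ordered by range
  expect_equal(rep_$ranking$compound, c("dC", "dB", "dA"))
  expect_equal(rep_$ranking$rank, 1:3)

  # prob floor: a compound nobody responds to disappears from the report
  preds2 <- preds
  preds2$probability <- c(0.5, 0.6, 0.9, 0.9)
  rep2 <- rank_compounds(preds2)
  expect_equal(unique(rep2$ranking$compound), "dC")

  # permutation invariance of input row order
  rep3 <- rank_compounds(preds[sample(4), ])
  expect_equal(rep3$ranking, rep_$ranking)

  # id tie-break after probability and range
  preds4 <- preds[1:2, ]
  preds4$dynamic_range <- c(1, 1)
  expect_equal(rank_compounds(preds4)$ranking$compound, c("dA", "dB"))
})

test_that("cohort summaries count sensitivity exactly", {
  preds <- tibble::tibble(
    patient = rep(c("P1", "P2", "P3", "P4"), each = 1),
    compound = "dA",
    probability = c(0.9, 0.8, 0.4, 0.2),
    rescaled = c(0.9, 0.8, 0.4, 0.2),
    status = c("sensitive", "sensitive", "intermediate", "resistant"),
    model_auc = 0.8, dynamic_range = 1)
  rep_ <- rank_compounds(preds)
  expect_equal(rep_$cohort$pct_sensitive, 50)
  expect_equal(rep_$patients$n_sensitive, c(1L, 1L, 0L, 0L))
})

test_that("signatures apply to tumor profiles with overlap guards and imputation", {
  panel <- quick_panel(seed = 91, n_lines = 36, n_features = 120,
                       compounds = design_compound("dA", n_planted = 10,
                                                   effect_size = 2))
  lab <- dichotomize(panel$response, "dA")
  asm <- assemble_features(panel$omics$expression_array)
  sig <- fit_signature(asm, lab, "lssvm", dynamic_range = 2, n_splits = 6,
                       seed = 7)

  # resubstitution: most training lines land on their own side of 0.5
  own <- apply_signature(sig, panel$omics$expression_array)
  y <- setNames(lab$labels$label == "sensitive", lab$labels$cell_line)
  expect_gte(mean((own$probability > 0.5) == y[own$patient]), 0.9)

  # all-mean profile scores between the class-mean profiles
  X <- asm$X
  mk <- function(m, id) {
    mm <- matrix(m, 1, length(m), dimnames = list(id, asm$meta$feature_id))
    omic_dataset(mm, "expression_array")
  }
  p_all <- apply_signature(sig, mk(colMeans(X), "Tmean"))$probability
  p_pos <- apply_signature(sig, mk(colMeans(X[y[rownames(X)], ]), "Tpos"))$probability
  p_neg <- apply_signature(sig, mk(colMeans(X[!y[rownames(X)], ]), "Tneg"))$probability
  expect_true(p_all >= min(p_pos, p_neg) && p_all <= max(p_pos, p_neg))

  # refusal below the overlap floor
  half <- panel$omics$expression_array
  keep <- half$features$feature_id[seq_len(60)]
  half <- omic_dataset(half$values[, keep], "expression_array")
  used <- sig$selected_features$feature_id
  if (mean(used %in% keep) < 0.8) {
    expect_error(apply_signature(sig, half), "overlap")
  }
  tiny <- omic_dataset(
    panel$omics$expression_array$values[, 1:2, drop = FALSE],
    "expression_array")
  expect_error(apply_signature(sig, tiny), "overlap")
})

test_that("end-to-end cohort prediction recovers the planted responder fraction", {
  panel <- quick_panel(seed = 95, n_lines = 40, n_features = 120,
                       compounds = design_compound("dA", n_planted = 12,
                                                   effect_size = 2))
  lab <- dichotomize(panel$response, "dA")
  asm <- assemble_features(panel$omics$expression_array)
  sig <- fit_signature(asm, lab, "lssvm", dynamic_range = 2, n_splits = 6,
                       seed = 7)
  tc <- simulate_tumor_cohort(panel, "dA", n_patients = 200,
                              responder_fraction = 0.3, seed = 12)
  expect_gte(auc(apply_signature(sig, tc$profiles)$probability,
                 tc$status$responder), 0.9)
  rep_ <- predict_cohort(list(sig), tc$profiles, seed = 3)
  expect_lte(abs(rep_$cohort$pct_sensitive / 100 - 0.3), 0.15)
  # percent sensitive equals the sensitive-status fraction exactly
  expect_equal(rep_$cohort$pct_sensitive,
               100 * mean(rep_$ranking$status == "sensitive"))
})

test_that("coherence is 1 on identical matrices and detects planted co-regulation", {
  withr::with_seed(101, {
    n <- 40; g <- 30
    ids <- sprintf("G%02d|gene", 1:g)
    base <- matrix(rnorm(n * g), n, g,
                   dimnames = list(sprintf("S%02d", 1:n), ids))
    base[, 1:5] <- base[, 1:5] * 0.4 + rnorm(n)  # co-regulated block
    ds <- omic_dataset(base, "expression_array")
    same <- signature_coherence(sprintf("G%02d", 1:10), ds, ds, n_perm = 50)
    expect_equal(same$jaccard, 1)

    # 10 signature genes share a latent factor in both cohorts; the other
    # 990 genes of the shared genome are independent noise, so random gene
    # sets almost never reproduce a co-regulation block
    G <- 1000
    big_ids <- sprintf("B%04d|gene", 1:G)
    mk_cohort <- function(seed) {
      withr::with_seed(seed, {
        m <- matrix(rnorm(n * G), n, G,
                    dimnames = list(sprintf("X%02d", 1:n), big_ids))
        f <- rnorm(n)
        m[, 1:10] <- m[, 1:10] * 0.4 + f
        omic_dataset(m, "expression_array")
      })
    }
    coh <- signature_coherence(sprintf("B%04d", 1:10), mk_cohort(1),
                               mk_cohort(2), n_perm = 999, seed = 5)
    expect_lte(coh$p_value, 0.01)

    # independently permuted tumors: coherence at the null level
    perm <- base
    for (j in 1:g) perm[, j] <- sample(perm[, j])
    nullr <- signature_coherence(sprintf("G%02d", 1:10), ds,
                                 omic_dataset(perm, "expression_array"),
                                 n_perm = 99, seed = 5)
    expect_gt(nullr$p_value, 0.05)
  })
})
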