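test_that("AUC matches pairwise enumeration and handles ties", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auc(c(0.9, 0.8, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 0.875)
  # enumeration oracle over random small score vectors on a coarse alphabet
  withr::with_seed(5, {
    for (rep in 1:200) {
      n <- sample(4:8, 1)
      s <- sample(c(0.1, 0.3, 0.5, 0.7, 0.9), n, replace = TRUE)
      pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (all(pos) || !any(pos)) next
      expect_equal(auc(s, pos), auc_enum(s, pos))
    }
  })
  expect_error(auc(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("AUC is antisymmetric under score reversal and invariant to monotone maps", {
  withr::with_seed(8, {
    s <- runif(20); pos <- rep(c(TRUE, FALSE), 10)
    a <- auc(s, pos)
    expect_equal(auc(-s, pos), 1 - a)
    expect_equal(auc(exp(3 * s), pos), a)
    expect_equal(auc(rank(s), pos), a)
  })
})

test_that("LS-SVM reproduces the hand-solved two-point system", {
  X <- matrix(c(-1, 1), 2, 1, dimnames = list(c("a", "b"), "f"))
  m <- train_weighted_lssvm(X, c(-1, 1), gamma = 1, standardize = FALSE)
  expect_equal(unname(m$b), 0, tolerance = 1e-12)
  expect_equal(unname(m$alpha), c(-1 / 3, 1 / 3), tolerance = 1e-12)
  # decision function f(x) = (2/3) x
  xs <- matrix(c(-2, 0.5, 3), 3, 1)
  expect_equal(predict(m, xs, type = "decision"), (2 / 3) * drop(xs),
               tolerance = 1e-12)
})

test_that("LS-SVM satisfies its KKT structure on random instances", {
  withr::with_seed(13, {
    for (rep in 1:30) {
      n <- sample(6:30, 1); p <- sample(2:10, 1)
      X <- matrix(rnorm(n * p), n, p)
      y <- sign(rnorm(n)); if (abs(sum(y)) == n) y[1] <- -y[1]
      gamma <- 10^runif(1, -2, 2)
      m <- train_weighted_lssvm(X, y, gamma = gamma)
      # first KKT row
      expect_lt(abs(sum(m$alpha)), 1e-8)
      # oracle: independently assembled dense system on the standardized data
      o <- lssvm_oracle(m$X_train, y, gamma)
      denom <- max(1, sqrt(sum(o$alpha^2)))
      expect_lt(sqrt(sum((m$alpha - o$alpha)^2)) / denom, 1e-8)
      expect_lt(abs(m$b - o$b) / max(1, abs(o$b)), 1e-8)
    }
  })
})

test_that("class weights balance class totals; duplication leaves predictions unchanged", {
  y <- c(1, 1, 1, -1)
  w <- lssvm_weights(y)
  expect_equal(w, c(4 / 6, 4 / 6, 4 / 6, 2))
  expect_equal(sum(w[y > 0]), sum(w[y < 0]))
  expect_equal(lssvm_weights(c(1, 1, -1, -1)), rep(1, 4))

  # duplicating every sample doubles the squared-error term of the LS-SVM
  # objective, so the duplicated panel at gamma reproduces the original at
  # 2*gamma exactly (class weights are unchanged: proportions persist)
  withr::with_seed(21, {
    X <- matrix(rnorm(16), 8, 2)
    y <- rep(c(1, -1), 4)
    m1 <- train_weighted_lssvm(X, y, gamma = 2, standardize = FALSE)
    m2 <- train_weighted_lssvm(rbind(X, X), c(y, y), gamma = 1,
                               standardize = FALSE)
    xs <- matrix(rnorm(10), 5, 2)
    expect_equal(predict(m1, xs, type = "decision"),
                 predict(m2, xs, type = "decision"), tolerance = 1e-8)
  })
})

test_that("grid search returns a single cell unchanged and prefers small k on ties", {
  withr::with_seed(3, {
    X <- matrix(rnorm(40 * 20), 40, 20)
    y <- rep(c(1, -1), 20)
    gs1 <- grid_search_lssvm(X, y, grid = lssvm_grid(k = 5, gamma = 1))
    expect_equal(gs1$k, 5)
    expect_equal(gs1$gamma, 1)
    # separable problem: every cell reaches AUC 1, ties resolve to the
    # smallest k then smallest gamma
    Xs <- X; Xs[, 1] <- y * 5
    gs2 <- grid_search_lssvm(Xs, y, grid = lssvm_grid(k = c(5, 10, 20),
                                                      gamma = c(0.1, 1)),
                             seed = 2)
    expect_equal(gs2$k, 5)
    expect_equal(gs2$gamma, 0.1)
  })
})

test_that("grid search recovers planted features and stays null under permuted labels", {
  withr::with_seed(31, {
    n <- 40; p <- 1000
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(1, -1), each = n / 2)
    planted <- sample(p, 10)
    X[y > 0, planted] <- X[y > 0, planted] + 1.5
    gs <- grid_search_lssvm(X, y, seed = 1)
    expect_lte(gs$k, 50)
    expect_gte(sum(planted %in% gs$ranked_features[1:50]), 8)

    # permutation null: mean inner AUC of the chosen cell hovers near 0.5
    nulls <- vapply(1:25, function(i) {
      grid_search_lssvm(X, sample(y), seed = i,
                        grid = lssvm_grid(k = c(10, 100), gamma = 1))$inner_auc
    }, numeric(1))
    expect_lt(abs(mean(nulls) - 0.5), 0.15)
  })
})

test_that("random forest is deterministic given a seed and separates trivially", {
  withr::with_seed(17, {
    X <- matrix(rnorm(40), 20, 2)
    y <- rep(c(1, -1), 10)
    X[, 1] <- y * 2 + rnorm(20, sd = 0.1)
    m1 <- train_rf(X, y, n_trees = 100, seed = 9)
    m2 <- train_rf(X, y, n_trees = 100, seed = 9)
    xs <- matrix(rnorm(20), 10, 2)
    expect_identical(predict_rf(m1, xs), predict_rf(m2, xs))
    # single tree on a cleanly separable cloud trains to accuracy 1
    X2 <- matrix(rep(c(-1, 1), each = 15), 30, 1)
    y2 <- rep(c(-1, 1), each = 15)
    mtiny <- train_rf(X2, y2, n_trees = 1, seed = 1, mtry = 1)
    p <- predict_rf(mtiny, matrix(c(-1, 1), 2, 1))
    expect_true(p[2] > 0.5 && p[1] < 0.5)
  })
})

test_that("random forest importances recover planted features", {
  withr::with_seed(23, {
    n <- 48; p <- 300
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, sprintf("f%03d", 1:p)))
    y <- rep(c(1, -1), each = n / 2)
    planted <- sprintf("f%03d", 1:15)
    X[y > 0, planted] <- X[y > 0, planted] + 1.5
    m <- train_rf(X, y, n_trees = 500, seed = 4)
    top20 <- names(sort(m$importance, decreasing = TRUE))[1:20]
    expect_gte(sum(top20 %in% planted), 10)
  })
})

test_that("multi-split evaluation scores planted signal high and stays honest on null", {
  panel <- quick_panel(seed = 41, n_lines = 30, n_features = 200,
                       compounds = design_compound("dA", n_planted = 10,
                                                   effect_size = 2))
  lab <- dichotomize(panel$response, "dA")
  asm <- assemble_features(panel$omics$expression_array)
  ev <- evaluate_multisplit(asm, lab, "lssvm", n_splits = 8, seed = 2)
  expect_gte(ev$mean_auc, 0.85)
  expect_equal(ev$mean_auc, mean(ev$per_split$auc), tolerance = 1e-12)
  expect_true(all(ev$per_split$auc >= 0 & ev$per_split$auc <= 1))
  # train fraction ~ 2/3 with stratification
  expect_true(all(abs(ev$per_split$n_train - 20) <= 1))

  # determinism under a fixed seed
  ev2 <- evaluate_multisplit(asm, lab, "lssvm", n_splits = 8, seed = 2)
  expect_identical(ev$per_split, ev2$per_split)
})

test_that("feature ranking never sees test labels (leakage canary)", {
  # a feature that perfectly encodes the labels on what will be test lines
  # (noise on training lines) must not be selected above chance
  withr::with_seed(53, {
    n <- 30; p <- 60
    X <- matrix(rnorm(n * p), n, p)
    y <- rep(c(1, -1), 15)
    freq <- numeric(2)
    for (s in 1:15) {
      split_seed <- 1000 + s
      tr <- withr::with_seed(split_seed, sample(n, 20))
      te <- setdiff(1:n, tr)
      Xc <- X
      Xc[te, 1] <- y[te] * 10          # test-only perfect canary feature
      gs <- grid_search_lssvm(Xc[tr, ], y[tr],
                              grid = lssvm_grid(k = 10, gamma = 1),
                              seed = split_seed)
      freq[1] <- freq[1] + (1 %in% gs$ranked_features[1:10])
      freq[2] <- freq[2] + (2 %in% gs$ranked_features[1:10])
    }
    # canary column behaves like any noise column (here column 2)
    expect_lte(abs(freq[1] - freq[2]), 6)
  })
})
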