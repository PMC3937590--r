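#' Area under the ROC curve (rank statistic)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, ties counted half: (concordant + 0.5 * tied) /
#' (n_pos * n_neg). Computed from midranks, so it is invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric prediction scores (larger = more positive).
#' @param labels Logical or two-valued vector; TRUE / larger value = positive.
#' @return AUC in \[0, 1\].
#' @export
#' @examples
#' auc(c(0.9, 0.8, 0.8, 0.1), c(TRUE, TRUE, FALSE, FALSE))
auc <- function(scores, labels) {
  pos <- as.logical(labels)
  if (!is.logical(labels)) {
    u <- sort(unique(labels))
    if (length(u) != 2) abort("AUC needs exactly two classes.")
    pos <- labels == u[2]
  }
  npos <- sum(pos); nneg <- sum(!pos)
  if (npos == 0 || nneg == 0) {
    abort("AUC undefined: both classes must be present.")
  }
  r <- rank(scores)
  (sum(r[pos]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Assemble omic datasets into one modeling matrix
#'
#' Binds one or more [omic_dataset()]s column-wise over their common samples
#' (or a requested line subset). Feature columns are tagged with their data
#' type; mutation columns are flagged to skip standardization. Features with
#' more than `max_missing` missing values among the retained samples are
#' dropped; remaining missing values are mean-imputed.
#'
#' @param datasets A single [omic_dataset()] or list of them.
#' @param lines Optional sample subset; default = samples common to all sets.
#' @param max_missing Maximum tolerated fraction of missing values per
#'   feature.
#' @return A `feature_assembly`: list with `X` (samples x features matrix),
#'   `meta` (tibble: `feature_id`, `column`, `gene`, `level`, `data_type`,
#'   `scale`), `samples`.
#' @export
assemble_features <- function(datasets, lines = NULL, max_missing = 0.2) {
  if (inherits(datasets, "omic_dataset")) datasets <- list(datasets)
  samp <- Reduce(intersect, lapply(datasets, function(d) d$samples))
  if (!is.null(lines)) samp <- intersect(samp, lines)
  if (length(samp) < 2) abort("Fewer than 2 samples common to all datasets.")
  samp <- sort(samp)

  blocks <- purrr::map(datasets, function(d) {
    X <- d$values[samp, , drop = FALSE]
    keep <- colMeans(is.na(X)) <= max_missing
    X <- X[, keep, drop = FALSE]
    if (anyNA(X)) {
      mu <- colMeans(X, na.rm = TRUE)
      idx <- which(is.na(X), arr.ind = TRUE)
      X[idx] <- mu[idx[, 2]]
    }
    meta <- d$features[keep, ] |>
      mutate(data_type = d$data_type,
             column = paste0(d$data_type, ":", .data$feature_id),
             scale = d$data_type != "mutation")
    colnames(X) <- meta$column
    list(X = X, meta = meta)
  })
  X <- do.call(cbind, purrr::map(blocks, "X"))
  meta <- bind_rows(purrr::map(blocks, "meta"))
  structure(list(X = X, meta = meta, samples = samp),
            class = "feature_assembly")
}

#' @export
print.feature_assembly <- function(x, ...) {
  cat(sprintf("<feature_assembly> %d samples x %d features (%s)\n",
              nrow(x$X), ncol(x$X),
              paste(unique(x$meta$data_type), collapse = ", ")))
  invisible(x)
}

#' Default LS-SVM search grid
#'
#' @param k Candidate signature sizes (number of top-ranked features).
#' @param gamma Candidate regularization values.
#' @param kernels List of [lssvm_kernel()] specs.
#' @return A grid list consumed by [grid_search_lssvm()].
#' @export
lssvm_grid <- function(k = c(5, 10, 25, 50, 100, 250, 500),
                       gamma = 10^seq(-2, 2),
                       kernels = list(lssvm_kernel("linear"))) {
  list(k = k, gamma = gamma, kernels = kernels)
}

rank_features <- function(X, y, statistic = c("t", "correlation")) {
  statistic <- match.arg(statistic)
  s <- if (statistic == "t") {
    feature_t_stats(X, y)
  } else {
    drop(stats::cor(as.numeric(y), X))
  }
  s[!is.finite(s)] <- 0
  order(-abs(s))
}

## Stratified split of indices into train/test at the given fraction.
stratified_split <- function(y, train_fraction) {
  idx <- seq_along(y)
  train <- integer(0)
  for (cls in unique(y)) {
    members <- idx[y == cls]
    n_tr <- max(1L, round(length(members) * train_fraction))
    n_tr <- min(n_tr, length(members) - 1L)
    train <- c(train, sample(members, n_tr))
  }
  sort(train)
}

#' Grid search for LS-SVM feature count and hyperparameters
#'
#' Inner cross-validation on the training lines: within each inner training
#' fold, features are ranked by absolute two-sample t statistic (or absolute
#' correlation) against the labels; every grid cell (feature count k, gamma,
#' kernel) is scored by mean inner-fold AUC. Ties prefer the smallest k, then
#' the smallest gamma. The returned feature ranking is recomputed on the full
#' training data.
#'
#' @param X Training matrix, samples x features.
#' @param y Labels in \{-1, +1\}.
#' @param grid An [lssvm_grid()].
#' @param inner_folds Number of inner CV folds.
#' @param seed Integer seed for fold assignment.
#' @param statistic Feature-ranking statistic.
#' @param scale_feature Per-column logical, passed to
#'   [train_weighted_lssvm()].
#' @return List: `k`, `gamma`, `kernel`, `ranked_features` (column indices,
#'   best first), `inner_auc` (mean inner AUC of the chosen cell), `table`
#'   (tibble of all cells).
#' @export
grid_search_lssvm <- function(X, y, grid = lssvm_grid(), inner_folds = 3,
                              seed = 1, statistic = c("t", "correlation"),
                              scale_feature = NULL) {
  statistic <- match.arg(statistic)
  ks <- sort(unique(pmin(grid$k, ncol(X))))
  cells <- tidyr::expand_grid(k = ks, gamma = sort(grid$gamma),
                              kernel = seq_along(grid$kernels))
  if (nrow(cells) == 1) {
    ranked <- rank_features(X, y, statistic)
    return(list(k = cells$k[1], gamma = cells$gamma[1],
                kernel = grid$kernels[[1]], ranked_features = ranked,
                inner_auc = NA_real_, table = cells))
  }
  if (is.null(scale_feature)) scale_feature <- rep(TRUE, ncol(X))
  all_linear <- all(purrr::map_chr(grid$kernels, "family") == "linear")
  withr::with_seed(seed, {
    folds <- make_folds(y, inner_folds)
    aucs <- matrix(NA_real_, nrow(cells), inner_folds)
    for (f in seq_len(inner_folds)) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[te])) < 2 || length(unique(y[tr])) < 2) next
      ranked <- rank_features(X[tr, , drop = FALSE], y[tr], statistic)
      if (all_linear) {
        # linear kernels over nested feature sets grow by rank-one blocks,
        # so build the train and test Gram matrices incrementally over k
        cs <- column_standardizer(X[tr, , drop = FALSE], scale_feature)
        Xtr <- standardize_columns(X[tr, , drop = FALSE], cs)
        Xte <- standardize_columns(X[te, , drop = FALSE], cs)
        w <- lssvm_weights(y[tr])
        Ktr <- matrix(0, sum(tr), sum(tr))
        Kte <- matrix(0, sum(te), sum(tr))
        prev <- 0L
        for (ki in seq_along(ks)) {
          block <- ranked[(prev + 1L):ks[ki]]
          Btr <- Xtr[, block, drop = FALSE]
          Ktr <- Ktr + tcrossprod(Btr)
          Kte <- Kte + Xte[, block, drop = FALSE] %*% t(Btr)
          prev <- ks[ki]
          for (gi in seq_along(sort(grid$gamma))) {
            gmm <- sort(grid$gamma)[gi]
            sol <- solve_lssvm_system(Ktr, y[tr], gmm, w)
            p <- drop(Kte %*% sol$alpha + sol$b)
            ci <- which(cells$k == ks[ki] & cells$gamma == gmm)
            aucs[ci, f] <- auc(p, y[te] > 0)
          }
        }
      } else {
        for (ci in seq_len(nrow(cells))) {
          feats <- ranked[seq_len(cells$k[ci])]
          m <- train_weighted_lssvm(
            X[tr, feats, drop = FALSE], y[tr], gamma = cells$gamma[ci],
            kernel = grid$kernels[[cells$kernel[ci]]],
            scale_feature = scale_feature[feats])
          p <- predict(m, X[te, feats, drop = FALSE], type = "decision")
          aucs[ci, f] <- auc(p, y[te] > 0)
        }
      }
    }
  })
  cells$mean_auc <- rowMeans(aucs, na.rm = TRUE)
  best <- cells |>
    arrange(desc(.data$mean_auc), .data$k, .data$gamma) |>
    slice(1)
  list(k = best$k, gamma = best$gamma, kernel = grid$kernels[[best$kernel]],
       ranked_features = rank_features(X, y, statistic),
       inner_auc = best$mean_auc, table = cells)
}

make_folds <- function(y, n_folds) {
  folds <- integer(length(y))
  for (cls in unique(y)) {
    members <- which(y == cls)
    folds[members] <- sample(rep_len(seq_len(n_folds), length(members)))
  }
  folds
}

#' Train a random-forest response classifier
#'
#' A probability forest (vote fraction = probability of sensitivity) with
#' permutation-free impurity importances, deterministic given the seed.
#'
#' @param X Samples x features matrix.
#' @param y Labels in \{-1, +1\} or logical.
#' @param n_trees Number of trees.
#' @param mtry Split-candidate count; default floor(sqrt(p)).
#' @param seed Integer seed.
#' @return List with `forest` (ranger object), `importance` (named vector),
#'   `feature_ids`.
#' @export
train_rf <- function(X, y, n_trees = 1000, mtry = NULL, seed = 1) {
  y <- factor(ifelse(as.numeric(y) > 0, "sensitive", "resistant"),
              levels = c("resistant", "sensitive"))
  if (nlevels(droplevels(y)) < 2) abort("Both classes must be present.")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  df <- as.data.frame(X)
  colnames(df) <- paste0("f", seq_len(ncol(X)))
  fit <- ranger::ranger(x = df, y = y, num.trees = n_trees, mtry = mtry,
                        probability = TRUE, importance = "impurity",
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  names(imp) <- colnames(X)
  list(forest = fit, importance = imp, feature_ids = colnames(X))
}

predict_rf <- function(model, X) {
  df <- as.data.frame(X)
  colnames(df) <- paste0("f", seq_len(ncol(X)))
  predict(model$forest, data = df, num.threads = 1)$predictions[, "sensitive"]
}

#' Multi-split evaluation of a response classifier
#'
#' Repeated stratified random division of the labeled lines into two-thirds
#' training and one-third test. The entire pipeline — standardization,
#' supervised per-gene reduction (optional), feature ranking and grid search
#' — is refit on each training set only; the AUC is computed on the held-out
#' test lines and averaged over splits. Splits whose test set degenerates to
#' one class are redrawn (bounded retries).
#'
#' @param assembly A [assemble_features()] result (or plain matrix).
#' @param labels A [response_labels()] object or named logical vector.
#' @param method `"lssvm"` or `"rf"`.
#' @param n_splits Number of random splits.
#' @param train_fraction Fraction of lines used for training.
#' @param seed Integer seed; split s uses a seed derived from it.
#' @param grid [lssvm_grid()] for the LS-SVM path.
#' @param inner_folds Inner CV folds for the grid search.
#' @param reduce_per_gene If TRUE, apply the supervised best-feature-per-gene
#'   reduction inside each training split (multi-level platforms).
#' @param n_trees,mtry Random-forest settings.
#' @return An `evaluation` object: list with `per_split` tibble, `mean_auc`,
#'   `method`, `seed`, `n_splits`.
#' @export
evaluate_multisplit <- function(assembly, labels, method = c("lssvm", "rf"),
                                n_splits = 100, train_fraction = 2 / 3,
                                seed = 1, grid = lssvm_grid(),
                                inner_folds = 3, reduce_per_gene = FALSE,
                                n_trees = 1000, mtry = NULL) {
  method <- match.arg(method)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0,1).")
  }
  dat <- align_labels(assembly, labels)
  X <- dat$X; y <- dat$y; meta <- dat$meta
  if (length(y) < 6 || min(table(y)) < 2) {
    abort("Need >= 6 labeled lines with >= 2 per class.")
  }
  per_split <- purrr::map_dfr(seq_len(n_splits), function(s) {
    split_seed <- as.integer((as.numeric(seed) * 10007 + s) %% 2147483647)
    withr::with_seed(split_seed, {
      for (try in 1:10) {
        tr <- stratified_split(y, train_fraction)
        te <- setdiff(seq_along(y), tr)
        if (length(unique(y[te])) == 2 && length(unique(y[tr])) == 2) break
      }
      cols <- seq_len(ncol(X))
      if (reduce_per_gene && !is.null(meta)) {
        cols <- reduce_columns_per_gene(X[tr, , drop = FALSE], y[tr], meta)
      }
      a <- fit_and_score(X[, cols, drop = FALSE], y, tr, te, method, grid,
                         inner_folds, split_seed, meta$scale[cols], n_trees,
                         mtry)
      tibble(split = s, auc = a, n_train = length(tr), n_test = length(te))
    })
  })
  structure(list(per_split = per_split, mean_auc = mean(per_split$auc),
                 method = method, seed = seed, n_splits = n_splits),
            class = "evaluation")
}

align_labels <- function(assembly, labels) {
  yv <- labels_as_logical(labels)
  if (inherits(assembly, "feature_assembly")) {
    samp <- intersect(assembly$samples, names(yv))
    X <- assembly$X[samp, , drop = FALSE]
    meta <- assembly$meta
  } else {
    X <- as.matrix(assembly)
    samp <- intersect(rownames(X), names(yv))
    X <- X[samp, , drop = FALSE]
    meta <- tibble(column = colnames(X) %||% as.character(seq_len(ncol(X))),
                   feature_id = colnames(X) %||% as.character(seq_len(ncol(X))),
                   gene = NA_character_, level = NA_character_,
                   data_type = NA_character_, scale = TRUE)
  }
  list(X = X, y = ifelse(yv[samp], 1, -1), meta = meta)
}

## Supervised per-gene reduction on training rows only: returns column indices.
reduce_columns_per_gene <- function(Xtr, ytr, meta) {
  multi <- !is.na(meta$gene) &
    meta$data_type %in% c("exon_array", "rnaseq")
  if (!any(multi)) return(seq_len(nrow(meta)))
  tt <- abs(feature_t_stats(Xtr[, multi, drop = FALSE], ytr > 0))
  sub <- meta[multi, ] |> mutate(stat = tt, idx = which(multi))
  chosen <- sub |>
    group_by(.data$data_type, .data$gene) |>
    summarise(idx = {
      if (all(.data$stat == 0)) {
        gl <- .data$idx[.data$level == "gene"]
        if (length(gl)) gl[1] else NA_integer_
      } else .data$idx[order(-.data$stat, .data$column)][1]
    }, .groups = "drop") |>
    filter(!is.na(.data$idx)) |>
    pull("idx")
  sort(c(which(!multi), chosen))
}

fit_and_score <- function(X, y, tr, te, method, grid, inner_folds, seed,
                          scale_feature, n_trees, mtry) {
  if (method == "lssvm") {
    gs <- grid_search_lssvm(X[tr, , drop = FALSE], y[tr], grid = grid,
                            inner_folds = inner_folds, seed = seed,
                            scale_feature = scale_feature)
    feats <- gs$ranked_features[seq_len(gs$k)]
    m <- train_weighted_lssvm(X[tr, feats, drop = FALSE], y[tr],
                              gamma = gs$gamma, kernel = gs$kernel,
                              scale_feature = scale_feature[feats])
    p <- predict(m, X[te, feats, drop = FALSE], type = "decision")
  } else {
    m <- train_rf(X[tr, , drop = FALSE], y[tr], n_trees = n_trees,
                  mtry = mtry, seed = seed)
    p <- predict_rf(m, X[te, , drop = FALSE])
  }
  auc(p, y[te] > 0)
}

#' @export
print.evaluation <- function(x, ...) {
  cat(sprintf("<evaluation> %s: mean AUC %.3f over %d splits\n",
              x$method, x$mean_auc, x$n_splits))
  invisible(x)
}

#' Per-split AUCs of a multi-split evaluation
#' @param x An `evaluation`.
#' @param ... Unused.
#' @return Tibble with one row per split.
#' @method tidy evaluation
#' @export
tidy.evaluation <- function(x, ...) x$per_split |> mutate(method = x$method)

#' One-row summary of a multi-split evaluation
#' @param x An `evaluation`.
#' @param ... Unused.
#' @return Tibble with `method`, `mean_auc`, `sd_auc`, `n_splits`, `seed`.
#' @method glance evaluation
#' @export
glance.evaluation <- function(x, ...) {
  tibble(method = x$method, mean_auc = x$mean_auc,
         sd_auc = sd(x$per_split$auc), n_splits = x$n_splits, seed = x$seed)
}
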