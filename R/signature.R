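#' Fit a response signature for one compound
#'
#' Trains the final model on all labeled lines (grid-search feature
#' optimization for the LS-SVM; impurity importances for the RF) and attaches
#' the multi-split evaluation, the dichotomization threshold and the
#' compound's GI50 dynamic range. The signature stores its training payload
#' so that reading a written signature reconstructs the identical model.
#'
#' @param assembly A [assemble_features()] result.
#' @param labels A [response_labels()] object.
#' @param method `"lssvm"` or `"rf"`.
#' @param dynamic_range The compound's GI50 dynamic range (from
#'   [compound_summary()]).
#' @param evaluation Optional precomputed [evaluate_multisplit()] result; if
#'   NULL one is run with `n_splits`.
#' @param n_splits Splits for the evaluation when not supplied.
#' @param grid [lssvm_grid()] for the LS-SVM path.
#' @param inner_folds Inner CV folds for the grid search.
#' @param n_trees,mtry Random-forest settings.
#' @param seed Integer seed.
#' @return An object of class `signature`.
#' @export
fit_signature <- function(assembly, labels, method = c("lssvm", "rf"),
                          dynamic_range = NA_real_, evaluation = NULL,
                          n_splits = 50, grid = lssvm_grid(),
                          inner_folds = 3, n_trees = 1000, mtry = NULL,
                          seed = 1) {
  method <- match.arg(method)
  if (is.null(evaluation)) {
    evaluation <- evaluate_multisplit(
      assembly, labels, method = method, n_splits = n_splits, seed = seed,
      grid = grid, inner_folds = inner_folds, n_trees = n_trees, mtry = mtry)
  }
  dat <- align_labels(assembly, labels)
  X <- dat$X; y <- dat$y; meta <- dat$meta

  if (method == "lssvm") {
    gs <- grid_search_lssvm(X, y, grid = grid, inner_folds = inner_folds,
                            seed = seed, scale_feature = meta$scale)
    sel <- gs$ranked_features[seq_len(gs$k)]
    hyper <- list(gamma = gs$gamma, kernel = gs$kernel,
                  feature_count = gs$k)
    ranked_idx <- gs$ranked_features[seq_len(min(100L, ncol(X)))]
    model <- train_weighted_lssvm(X[, sel, drop = FALSE], y,
                                  gamma = gs$gamma, kernel = gs$kernel,
                                  scale_feature = meta$scale[sel])
    weight <- if (gs$kernel$family == "linear") {
      drop(t(model$X_train) %*% model$alpha)
    } else {
      abs(feature_t_stats(X[, sel, drop = FALSE], y > 0))
    }
  } else {
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
    hyper <- list(n_trees = n_trees, mtry = mtry)
    model <- train_rf(X, y, n_trees = n_trees, mtry = mtry, seed = seed)
    sel <- seq_len(ncol(X))
    weight <- unname(model$importance)
    ranked_idx <- order(-model$importance)[seq_len(min(100L, ncol(X)))]
  }

  selected <- meta[sel, ] |>
    select("feature_id", "data_type") |>
    mutate(weight = unname(weight))
  # top-ranked features beyond the optimizer's cut, for signature reporting
  ranking <- meta[ranked_idx, ] |>
    select("feature_id", "data_type") |>
    mutate(rank = dplyr::row_number())

  structure(
    list(compound = labels$compound,
         method = method,
         data_types = unique(meta$data_type),
         selected_features = selected,
         ranking = ranking,
         hyperparameters = hyper,
         per_split_auc = evaluation$per_split$auc,
         mean_auc = evaluation$mean_auc,
         threshold = labels$threshold,
         dynamic_range = dynamic_range,
         seed = seed,
         training = list(X = X[, sel, drop = FALSE], y = unname(y),
                         sample_ids = rownames(X),
                         scale_feature = meta$scale[sel]),
         model = model),
    class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> %s [%s]: %d features (%s), mean AUC %.3f\n",
              x$compound, x$method, nrow(x$selected_features),
              paste(x$data_types, collapse = "+"), x$mean_auc))
  invisible(x)
}

#' Selected features of a signature
#' @param x A `signature`.
#' @param ... Unused.
#' @return Tibble of `feature_id`, `data_type`, `weight` (LS-SVM primal
#'   weight or RF importance).
#' @method tidy signature
#' @export
tidy.signature <- function(x, ...) {
  x$selected_features |> mutate(compound = x$compound, method = x$method)
}

#' One-row signature summary
#' @param x A `signature`.
#' @param ... Unused.
#' @return Tibble with compound, method, feature count, mean AUC, threshold
#'   and dynamic range.
#' @method glance signature
#' @export
glance.signature <- function(x, ...) {
  tibble(compound = x$compound, method = x$method,
         n_features = nrow(x$selected_features),
         mean_auc = x$mean_auc, threshold = x$threshold,
         dynamic_range = x$dynamic_range, seed = x$seed)
}

signature_format_version <- "1.0"

#' Write a signature to a JSON file
#'
#' All fields, including the training payload, are serialized at full
#' numeric precision; [read_signature()] reconstructs the fitted model
#' deterministically from them.
#'
#' @param signature A `signature`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature <- function(signature, path) {
  x <- unclass(signature)
  x$model <- NULL
  x$format_version <- signature_format_version
  x$training$X <- list(values = unname(x$training$X),
                       feature_ids = colnames(x$training$X),
                       sample_ids = rownames(x$training$X))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  invisible(path)
}

#' Read a signature written by [write_signature()]
#'
#' Checks the format version tag, restores every field and re-fits the
#' predictive model from the stored training payload (LS-SVM: direct
#' re-solve; RF: re-grown with the stored seed), so predictions are identical
#' to the original object's.
#'
#' @param path Path to a signature JSON file.
#' @return A `signature`.
#' @export
read_signature <- function(path) {
  x <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                error = function(e) {
    abort(sprintf("Cannot parse signature file %s: %s", path,
                  conditionMessage(e)))
  })
  if (is.null(x$format_version)) {
    abort(sprintf("File %s is not a signature file (no version tag).", path))
  }
  if (!identical(x$format_version, signature_format_version)) {
    abort(sprintf("Signature format version mismatch: file has '%s', expected '%s'.",
                  x$format_version, signature_format_version))
  }
  Xl <- x$training$X
  X <- matrix(as.numeric(Xl$values), nrow = length(Xl$sample_ids),
              dimnames = list(Xl$sample_ids, Xl$feature_ids))
  sig <- list(
    compound = x$compound, method = x$method, data_types = x$data_types,
    selected_features = as_tibble(x$selected_features),
    ranking = as_tibble(x$ranking),
    hyperparameters = x$hyperparameters,
    per_split_auc = as.numeric(x$per_split_auc),
    mean_auc = x$mean_auc, threshold = x$threshold,
    dynamic_range = if (is.null(x$dynamic_range)) NA_real_ else x$dynamic_range,
    seed = x$seed,
    training = list(X = X, y = as.numeric(x$training$y),
                    sample_ids = x$training$sample_ids,
                    scale_feature = as.logical(x$training$scale_feature)))
  sig$model <- rebuild_model(sig)
  structure(sig, class = "signature")
}

rebuild_model <- function(sig) {
  if (sig$method == "lssvm") {
    kern <- lssvm_kernel(sig$hyperparameters$kernel$family,
                         sig$hyperparameters$kernel$sigma %||% 1)
    train_weighted_lssvm(sig$training$X, sig$training$y,
                         gamma = sig$hyperparameters$gamma, kernel = kern,
                         scale_feature = sig$training$scale_feature)
  } else {
    train_rf(sig$training$X, sig$training$y,
             n_trees = sig$hyperparameters$n_trees,
             mtry = sig$hyperparameters$mtry, seed = sig$seed)
  }
}
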