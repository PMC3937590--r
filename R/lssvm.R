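## Weighted least-squares SVM.
##
## Training reduces to one (N+1) x (N+1) saddle-point linear system
##   [ 0   1^T            ] [ b     ]   [ 0 ]
##   [ 1   K + diag(1/(gamma*w)) ] [ alpha ] = [ y ]
## with per-sample weights w_i = N / (2 * N_class(i)) correcting class
## imbalance. The decision value is f(x) = sum_i alpha_i k(x, x_i) + b.

kernel_matrix <- function(kernel, X, Z = NULL) {
  if (is.null(Z)) Z <- X
  switch(kernel$family,
    linear = Z %*% t(X),
    radial = {
      d2 <- outer(rowSums(Z^2), rowSums(X^2), "+") - 2 * Z %*% t(X)
      d2[d2 < 0] <- 0
      exp(-d2 / (2 * kernel$sigma^2))
    },
    abort(sprintf("Unknown kernel family '%s'.", kernel$family)))
}

#' Kernel specification for the LS-SVM
#'
#' @param family `"linear"` or `"radial"` (Gaussian, bandwidth `sigma`).
#' @param sigma Radial-kernel bandwidth; ignored for the linear kernel.
#' @return A kernel spec list.
#' @export
lssvm_kernel <- function(family = c("linear", "radial"), sigma = 1) {
  family <- match.arg(family)
  list(family = family, sigma = sigma)
}

#' Class-balancing sample weights
#'
#' `w_i = N / (2 * N_class(i))`, so each class contributes equal total weight;
#' balanced classes give all weights 1.
#'
#' @param y Label vector in \{-1, +1\}.
#' @return Positive weight per sample.
#' @export
lssvm_weights <- function(y) {
  n <- length(y)
  npos <- sum(y > 0); nneg <- sum(y < 0)
  ifelse(y > 0, n / (2 * npos), n / (2 * nneg))
}

#' Train a weighted least-squares support vector machine
#'
#' Standardizes features on the training data (binary columns flagged in
#' `scale_feature` are passed through as 0/1), builds the weighted LS-SVM
#' saddle system and solves it directly. A Platt-style two-parameter sigmoid
#' is fitted on the training decision values so the model emits calibrated
#' probabilities of the positive (sensitive) class.
#'
#' @param X Numeric matrix, samples x features (training data).
#' @param y Labels in \{-1, +1\} (or logical, TRUE = positive class).
#' @param gamma Regularization parameter (> 0); larger fits the training data
#'   more closely.
#' @param kernel A [lssvm_kernel()] specification.
#' @param scale_feature Logical vector per column; FALSE columns (e.g. binary
#'   mutation indicators) are not standardized.
#' @param standardize If FALSE, use the features exactly as given (no
#'   centering or scaling at all).
#' @return An object of class `lssvm_model`.
#' @export
train_weighted_lssvm <- function(X, y, gamma = 1,
                                 kernel = lssvm_kernel("linear"),
                                 scale_feature = NULL, standardize = TRUE) {
  X <- as.matrix(X)
  if (is.logical(y) || all(y %in% c(0, 1))) y <- ifelse(y > 0, 1, -1)
  if (!all(y %in% c(-1, 1))) abort("Labels must be coercible to {-1,+1}.")
  if (length(unique(y)) < 2) abort("Both classes must be present.")
  if (gamma <= 0) abort("`gamma` must be positive.")
  n <- nrow(X)
  if (is.null(scale_feature)) scale_feature <- rep(TRUE, ncol(X))
  if (!standardize) scale_feature <- rep(FALSE, ncol(X))

  cs <- column_standardizer(X, scale_feature)
  Xs <- standardize_columns(X, cs)
  center <- cs$center; scl <- cs$scale

  w <- lssvm_weights(y)
  K <- kernel_matrix(kernel, Xs)
  sol <- solve_lssvm_system(K, y, gamma, w)
  b <- sol$b; alpha <- sol$alpha

  model <- structure(
    list(alpha = alpha, b = b, gamma = gamma, kernel = kernel,
         weights = w, y = y, X_train = Xs,
         center = center, scale = scl, scale_feature = scale_feature,
         feature_ids = colnames(X), sample_ids = rownames(X),
         calibration = NULL),
    class = "lssvm_model")
  f_train <- lssvm_decision(model, X)
  model$calibration <- fit_platt(f_train, y)
  model
}

## Vectorized training-column standardization: binary (scale_feature = FALSE)
## columns pass through untouched.
column_standardizer <- function(X, scale_feature) {
  center <- ifelse(scale_feature, colMeans(X), 0)
  scl <- rep(1, ncol(X))
  if (any(scale_feature)) {
    n <- nrow(X)
    mu <- colMeans(X[, scale_feature, drop = FALSE])
    s <- sqrt((colSums(X[, scale_feature, drop = FALSE]^2) - n * mu^2) /
                (n - 1))
    s[s < 1e-12 | is.na(s)] <- 1
    scl[scale_feature] <- s
  }
  list(center = center, scale = scl)
}

standardize_columns <- function(X, cs) {
  sweep(sweep(X, 2, cs$center), 2, cs$scale, "/")
}

## Solve the (N+1)x(N+1) saddle system for given kernel matrix and labels.
solve_lssvm_system <- function(K, y, gamma, w) {
  n <- length(y)
  A <- rbind(c(0, rep(1, n)),
             cbind(1, K + diag(1 / (gamma * w), n)))
  rhs <- c(0, y)
  sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
  if (is.null(sol)) {
    A2 <- A + diag(1e-8, n + 1)
    sol <- tryCatch(solve(A2, rhs), error = function(e) {
      abort("LS-SVM system is singular even after ridge jitter.")
    })
  }
  list(b = sol[1], alpha = sol[-1])
}

## Decision values on raw (unstandardized) inputs.
lssvm_decision <- function(model, X) {
  X <- as.matrix(X)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  Kx <- kernel_matrix(model$kernel, model$X_train, Xs)
  drop(Kx %*% model$alpha + model$b)
}

## Platt sigmoid p = 1/(1+exp(a*f + c)) fitted on the training decision
## values with Platt's smoothed targets (N+1)/(N+2) and 1/(N+2): the
## smoothing keeps the slope finite on separable training data, so
## probabilities never saturate to exactly 0/1 and remain rank-informative.
fit_platt <- function(f, y) {
  pos <- y > 0
  np <- sum(pos); nn <- sum(!pos)
  target <- ifelse(pos, (np + 1) / (np + 2), 1 / (nn + 2))
  obj <- function(par) {
    p <- 1 / (1 + exp(par[1] * f + par[2]))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(target * log(p) + (1 - target) * log(1 - p))
  }
  s <- max(sd(f), 1e-6)
  fit <- stats::optim(c(-3 / s, 0), obj, method = "BFGS")
  list(slope = fit$par[1], offset = fit$par[2])
}

#' Predict from a weighted LS-SVM
#'
#' @param object An `lssvm_model`.
#' @param newdata Matrix of samples x features on the training feature set.
#' @param type `"probability"` (calibrated, default), `"decision"` (raw
#'   decision value) or `"class"` (+1/-1 at probability 0.5).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.lssvm_model <- function(object, newdata,
                                type = c("probability", "decision", "class"),
                                ...) {
  type <- match.arg(type)
  f <- lssvm_decision(object, newdata)
  if (type == "decision") return(f)
  p <- 1 / (1 + exp(object$calibration$slope * f + object$calibration$offset))
  if (type == "probability") p else ifelse(p > 0.5, 1, -1)
}

#' @export
print.lssvm_model <- function(x, ...) {
  cat(sprintf("<lssvm_model> %s kernel, gamma=%g, n=%d, p=%d\n",
              x$kernel$family, x$gamma, length(x$alpha), length(x$center)))
  invisible(x)
}

#' Tidy LS-SVM dual solution
#' @param x An `lssvm_model`.
#' @param ... Unused.
#' @return Tibble with per-sample `alpha`, `weight`, `label`.
#' @method tidy lssvm_model
#' @export
tidy.lssvm_model <- function(x, ...) {
  tibble(sample_id = x$sample_ids %||% as.character(seq_along(x$alpha)),
         alpha = x$alpha, weight = x$weights, label = x$y)
}

#' One-row LS-SVM model summary
#' @param x An `lssvm_model`.
#' @param ... Unused.
#' @return Tibble with `gamma`, `kernel`, `bias`, `n`, `p`, `alpha_sum`.
#' @method glance lssvm_model
#' @export
glance.lssvm_model <- function(x, ...) {
  tibble(gamma = x$gamma, kernel = x$kernel$family, bias = x$b,
         n = length(x$alpha), p = length(x$center), alpha_sum = sum(x$alpha))
}
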