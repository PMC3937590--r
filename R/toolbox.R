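#' Apply a trained signature to tumor profiles
#'
#' Looks up the signature's features in the tumor datasets by data type.
#' Each data type must supply at least `min_overlap` of the signature's
#' features; otherwise the call refuses with the observed overlap fraction.
#' Features absent from the tumor data are imputed with their training-panel
#' mean (logged). Standardization uses the training-panel parameters stored
#' in the model.
#'
#' @param signature A [fit_signature()] / [read_signature()] object.
#' @param tumor_profiles A single [omic_dataset()] or list of them covering
#'   the signature's data types.
#' @param min_overlap Minimum per-data-type fraction of signature features
#'   that must be present.
#' @return Tibble with columns `patient`, `probability`.
#' @export
apply_signature <- function(signature, tumor_profiles, min_overlap = 0.8) {
  if (inherits(tumor_profiles, "omic_dataset")) {
    tumor_profiles <- list(tumor_profiles)
  }
  by_type <- split(seq_len(nrow(signature$selected_features)),
                   signature$selected_features$data_type)
  available <- purrr::map(tumor_profiles, "data_type")
  patients <- Reduce(intersect, purrr::map(tumor_profiles, "samples"))
  if (length(patients) == 0) abort("No samples common to all tumor profiles.")

  k <- nrow(signature$selected_features)
  train_mean <- colMeans(signature$training$X)
  Xnew <- matrix(rep(train_mean, each = length(patients)),
                 nrow = length(patients), ncol = k,
                 dimnames = list(patients, colnames(signature$training$X)))
  n_imputed <- 0L
  for (dt in names(by_type)) {
    idx <- by_type[[dt]]
    src <- which(unlist(available) == dt)
    if (length(src) == 0) {
      abort(sprintf("Tumor profiles lack data type '%s' required by the signature.", dt))
    }
    ds <- tumor_profiles[[src[1]]]
    want <- signature$selected_features$feature_id[idx]
    have <- want %in% ds$features$feature_id
    overlap <- mean(have)
    if (overlap < min_overlap) {
      abort(sprintf(
        "Refusing to predict: %s overlap %.0f%% of signature features (< %.0f%%).",
        dt, 100 * overlap, 100 * min_overlap))
    }
    vals <- ds$values[patients, want[have], drop = FALSE]
    if (anyNA(vals)) {
      mu <- train_mean[idx][have]
      nai <- which(is.na(vals), arr.ind = TRUE)
      vals[nai] <- mu[nai[, 2]]
    }
    Xnew[, idx[have]] <- vals
    n_imputed <- n_imputed + sum(!have)
  }
  if (n_imputed > 0) {
    message(sprintf("apply_signature: %d of %d signature features imputed with training means.",
                    n_imputed, k))
  }
  p <- if (signature$method == "lssvm") {
    predict(signature$model, Xnew, type = "probability")
  } else {
    predict_rf(signature$model, Xnew)
  }
  tibble(patient = patients, probability = unname(p))
}

#' Choose resistant/intermediate/sensitive probability cutoffs
#'
#' Fits one-, two- and three-component univariate normal mixtures to the
#' cohort's predicted probabilities (EM via mclust) and selects the component
#' count by BIC. Cutoffs are placed at the density-intersection points
#' between adjacent selected components. With two components the single
#' intersection becomes the intermediate|sensitive boundary and the
#' resistant|intermediate boundary falls at a configurable quantile of the
#' lower component; with one component (or EM failure) fixed data quantiles
#' (0.25, 0.75) are used and the result is flagged.
#'
#' @param probabilities Numeric vector in \[0,1\], length >= 30.
#' @param resistant_quantile Quantile of the lower mixture component used for
#'   cutoff 1 in the two-component case.
#' @param seed Integer seed (mixture initialization).
#' @return A `cutoff_pair`: list with `cutoff1 < cutoff2`, `n_components`,
#'   `loglik`, `flag` (`"ok"`, `"unimodal"` or `"fallback"`).
#' @export
select_cutoffs <- function(probabilities, resistant_quantile = 0.25,
                           seed = 1) {
  p <- probabilities[!is.na(probabilities)]
  if (length(p) < 30) abort("Need >= 30 probabilities to choose cutoffs.")
  fallback <- function(flag) {
    q <- quantile(p, c(0.25, 0.75), names = FALSE)
    if (q[1] >= q[2]) q <- c(max(q[1] - 0.05, 0), min(q[1] + 0.05, 1))
    new_cutoff_pair(q[1], q[2], 1L, NA_real_, flag)
  }
  if (sd(p) < 1e-9) return(fallback("fallback"))
  # Mclust resolves helpers in the calling frame, so it must run with the
  # mclust namespace attached; with_package keeps the attach scoped.
  em_fit <- function(model_names) {
    withr::with_seed(seed, tryCatch(
      withr::with_package("mclust", suppressMessages(
        Mclust(p, G = 1:3, modelNames = model_names, verbose = FALSE))),
      error = function(e) NULL))
  }
  fit <- em_fit("V")
  if (is.null(fit)) fit <- em_fit("E")
  if (is.null(fit)) return(fallback("fallback"))
  g <- fit$G
  mu <- fit$parameters$mean
  sig <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sig) == 1) sig <- rep(sig, g)
  pro <- fit$parameters$pro
  o <- order(mu)
  mu <- mu[o]; sig <- sig[o]; pro <- pro[o]
  if (g == 1) return(fallback("unimodal"))

  cuts <- purrr::map_dbl(seq_len(g - 1), function(i) {
    component_intersection(mu[i], sig[i], pro[i], mu[i + 1], sig[i + 1],
                           pro[i + 1])
  })
  if (anyNA(cuts)) return(fallback("fallback"))
  if (g == 2) {
    c1 <- qnorm(resistant_quantile, mu[1], sig[1])
    cuts <- c(c1, cuts)
  }
  c1 <- max(0, min(cuts)); c2 <- min(1, max(cuts))
  if (!(c1 < c2)) return(fallback("fallback"))
  new_cutoff_pair(c1, c2, g, fit$loglik, "ok")
}

new_cutoff_pair <- function(c1, c2, g, loglik, flag) {
  structure(list(cutoff1 = c1, cutoff2 = c2, n_components = g,
                 loglik = loglik, flag = flag),
            class = "cutoff_pair")
}

## Intersection of two weighted normal densities between their means.
component_intersection <- function(m1, s1, w1, m2, s2, w2) {
  f <- function(x) w1 * dnorm(x, m1, s1) - w2 * dnorm(x, m2, s2)
  lo <- m1; hi <- m2
  if (sign(f(lo)) == sign(f(hi))) return((m1 + m2) / 2)
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.cutoff_pair <- function(x, ...) {
  cat(sprintf("<cutoff_pair> c1=%.3f c2=%.3f (%d component%s, %s)\n",
              x$cutoff1, x$cutoff2, x$n_components,
              if (x$n_components > 1) "s" else "", x$flag))
  invisible(x)
}

#' @method tidy cutoff_pair
#' @export
tidy.cutoff_pair <- function(x, ...) {
  tibble(cutoff1 = x$cutoff1, cutoff2 = x$cutoff2,
         n_components = x$n_components, loglik = x$loglik, flag = x$flag)
}

#' Assign tri-level response status
#'
#' `p <= cutoff1` is resistant, `cutoff1 < p <= cutoff2` intermediate, and
#' `p > cutoff2` sensitive (boundaries resolve toward the less responsive
#' status).
#'
#' @param probability Numeric vector of predicted probabilities.
#' @param cutoffs A `cutoff_pair`.
#' @return Character vector of statuses.
#' @export
assign_status <- function(probability, cutoffs) {
  dplyr::case_when(
    probability <= cutoffs$cutoff1 ~ "resistant",
    probability <= cutoffs$cutoff2 ~ "intermediate",
    TRUE ~ "sensitive")
}

#' Rescale probabilities to the display scale
#'
#' Strictly increasing continuous piecewise-linear map sending
#' `[0, cutoff1]` to `[0, 1/3]`, `(cutoff1, cutoff2]` to `(1/3, 2/3]` and
#' `(cutoff2, 1]` to `(2/3, 1]`, so the three statuses occupy equal display
#' thirds.
#'
#' @param probability Numeric vector in \[0,1\].
#' @param cutoffs A `cutoff_pair`.
#' @return Rescaled values in \[0,1\].
#' @export
rescale_probability <- function(probability, cutoffs) {
  c1 <- cutoffs$cutoff1; c2 <- cutoffs$cutoff2
  dplyr::case_when(
    probability <= c1 ~ if (c1 > 0) probability / c1 / 3 else 0,
    probability <= c2 ~ 1 / 3 + (probability - c1) / (c2 - c1) / 3,
    TRUE ~ 2 / 3 + (probability - c2) / (1 - c2) / 3)
}

#' Rank compounds for each patient
#'
#' Filters to compounds whose model AUC exceeds `auc_floor`, drops compounds
#' for which no patient's probability exceeds `prob_floor`, and orders each
#' patient's remaining compounds by probability (descending), breaking ties
#' by the larger in-vitro GI50 dynamic range, then by compound id.
#'
#' @param predictions Tibble with columns `patient`, `compound`,
#'   `probability`, `status`, `rescaled`, `model_auc`, `dynamic_range` (as
#'   produced by [predict_cohort()]).
#' @param auc_floor Minimum model AUC (strict).
#' @param prob_floor Probability at least one patient must exceed (strict)
#'   for a compound to enter the report.
#' @return A `prediction_report`: list with `ranking` (per-patient ordered
#'   tibble with `rank`), `cohort` (per-compound `pct_sensitive`,
#'   `n_over_prob_floor`), `patients` (per-patient sensitive-compound
#'   counts).
#' @export
rank_compounds <- function(predictions, auc_floor = 0.7, prob_floor = 0.65) {
  kept <- predictions |>
    filter(.data$model_auc > auc_floor) |>
    group_by(.data$compound) |>
    filter(any(.data$probability > prob_floor)) |>
    ungroup()
  if (nrow(kept) == 0) {
    message(sprintf(
      "No compound passes model AUC > %.2f with any probability > %.2f.",
      auc_floor, prob_floor))
  }
  ranking <- kept |>
    arrange(.data$patient, desc(.data$probability),
            desc(.data$dynamic_range), .data$compound) |>
    group_by(.data$patient) |>
    mutate(rank = row_number()) |>
    ungroup()
  cohort <- kept |>
    group_by(.data$compound) |>
    summarise(pct_sensitive = 100 * mean(.data$status == "sensitive"),
              n_over_prob_floor = sum(.data$probability > prob_floor),
              model_auc = .data$model_auc[1],
              dynamic_range = .data$dynamic_range[1],
              .groups = "drop")
  patients <- kept |>
    group_by(.data$patient) |>
    summarise(n_sensitive = sum(.data$status == "sensitive"),
              .groups = "drop")
  structure(list(ranking = ranking, cohort = cohort, patients = patients,
                 auc_floor = auc_floor, prob_floor = prob_floor),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %d patients x %d compounds (AUC floor %.2f, prob floor %.2f)\n",
              nrow(x$patients), nrow(x$cohort), x$auc_floor, x$prob_floor))
  invisible(x)
}

#' Per-patient ranked compound table of a prediction report
#' @param x A `prediction_report`.
#' @param ... Unused.
#' @return The `ranking` tibble.
#' @method tidy prediction_report
#' @export
tidy.prediction_report <- function(x, ...) x$ranking

#' Cohort-level summary of a prediction report
#' @param x A `prediction_report`.
#' @param ... Unused.
#' @return The per-compound `cohort` tibble.
#' @method glance prediction_report
#' @export
glance.prediction_report <- function(x, ...) x$cohort

#' Predict, threshold and rank a tumor cohort
#'
#' End-to-end toolbox run: applies each signature to the cohort, chooses
#' per-compound probability cutoffs by mixture clustering, assigns statuses,
#' rescales probabilities and ranks compounds per patient.
#'
#' @param signatures List of `signature` objects.
#' @param tumor_profiles List of [omic_dataset()]s.
#' @param auc_floor,prob_floor Report filters, see [rank_compounds()].
#' @param resistant_quantile Passed to [select_cutoffs()].
#' @param seed Integer seed.
#' @param min_overlap Passed to [apply_signature()].
#' @return A `prediction_report` with an extra `cutoffs` tibble attached.
#' @export
predict_cohort <- function(signatures, tumor_profiles, auc_floor = 0.7,
                           prob_floor = 0.65, resistant_quantile = 0.25,
                           seed = 1, min_overlap = 0.8) {
  rows <- purrr::map(signatures, function(sig) {
    probs <- apply_signature(sig, tumor_profiles, min_overlap = min_overlap)
    # cohorts too small for mixture clustering fall back to data quantiles
    cuts <- tryCatch(
      select_cutoffs(probs$probability,
                     resistant_quantile = resistant_quantile, seed = seed),
      error = function(e) {
        q <- quantile(probs$probability, c(0.25, 0.75), names = FALSE)
        if (q[1] >= q[2]) q <- c(max(q[1] - 0.05, 0), min(q[1] + 0.05, 1))
        new_cutoff_pair(q[1], q[2], 1L, NA_real_, "fallback")
      })
    probs |>
      mutate(compound = sig$compound,
             status = assign_status(.data$probability, cuts),
             rescaled = rescale_probability(.data$probability, cuts),
             model_auc = sig$mean_auc,
             dynamic_range = sig$dynamic_range,
             cutoff1 = cuts$cutoff1, cutoff2 = cuts$cutoff2,
             cutoff_flag = cuts$flag)
  })
  predictions <- bind_rows(rows)
  report <- rank_compounds(predictions, auc_floor = auc_floor,
                           prob_floor = prob_floor)
  report$cutoffs <- predictions |>
    distinct(.data$compound, .data$cutoff1, .data$cutoff2, .data$cutoff_flag)
  report
}

#' Coherence of a signature's co-regulation structure across cohorts
#'
#' Builds, separately in the cell-line and tumor expression matrices, the set
#' of unordered signature-gene pairs whose absolute Pearson correlation
#' exceeds `r_threshold`, and reports the Jaccard coefficient of the two edge
#' sets. Significance comes from a permutation null: random gene sets of the
#' same size drawn from the genes shared by both matrices.
#'
#' @param genes Character vector of signature gene symbols (>= 5 present in
#'   both matrices).
#' @param cell_line_expr,tumor_expr [omic_dataset()]s or plain matrices
#'   (samples x genes, gene symbols as column names).
#' @param r_threshold Absolute-correlation threshold defining an edge.
#' @param n_perm Number of null gene sets.
#' @param seed Integer seed.
#' @return A `coherence_result`: list with `jaccard`, `p_value`, `n_perm`,
#'   `n_genes`, `null_mean`.
#' @export
signature_coherence <- function(genes, cell_line_expr, tumor_expr,
                                r_threshold = 0.5, n_perm = 999, seed = 1) {
  Xc <- gene_matrix(cell_line_expr)
  Xt <- gene_matrix(tumor_expr)
  shared <- intersect(colnames(Xc), colnames(Xt))
  genes <- intersect(genes, shared)
  if (length(genes) < 5) {
    abort("Need >= 5 signature genes present in both matrices.")
  }
  jac <- function(gs) {
    ec <- edge_set(Xc[, gs, drop = FALSE], r_threshold)
    et <- edge_set(Xt[, gs, drop = FALSE], r_threshold)
    un <- sum(ec | et)
    if (un == 0) return(NA_real_)
    sum(ec & et) / un
  }
  j <- jac(genes)
  if (is.na(j)) {
    warn("Empty edge union: Jaccard coefficient undefined.")
    return(structure(list(jaccard = NA_real_, p_value = NA_real_,
                          n_perm = n_perm, n_genes = length(genes),
                          null_mean = NA_real_),
                     class = "coherence_result"))
  }
  # a null gene set with no edges in either cohort shows zero reproducible
  # co-regulation: it counts as J = 0, not as a dropped draw
  null <- withr::with_seed(seed, purrr::map_dbl(seq_len(n_perm), function(i) {
    v <- jac(sample(shared, length(genes)))
    if (is.na(v)) 0 else v
  }))
  p <- (1 + sum(null >= j)) / (1 + length(null))
  structure(list(jaccard = j, p_value = p, n_perm = n_perm,
                 n_genes = length(genes), null_mean = mean(null)),
            class = "coherence_result")
}

gene_matrix <- function(x) {
  if (inherits(x, "omic_dataset")) {
    m <- x$values
    colnames(m) <- x$features$gene
    m[, !duplicated(colnames(m)), drop = FALSE]
  } else {
    as.matrix(x)
  }
}

edge_set <- function(X, r_threshold) {
  cc <- suppressWarnings(stats::cor(X))
  cc[is.na(cc)] <- 0
  abs(cc[upper.tri(cc)]) > r_threshold
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence_result> J = %.3f over %d genes (null mean %.3f, p = %.4g)\n",
              x$jaccard, x$n_genes, x$null_mean, x$p_value))
  invisible(x)
}

#' @method tidy coherence_result
#' @export
tidy.coherence_result <- function(x, ...) {
  tibble(jaccard = x$jaccard, p_value = x$p_value, n_perm = x$n_perm,
         n_genes = x$n_genes, null_mean = x$null_mean)
}
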