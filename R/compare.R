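#' Best AUC per compound and data type
#'
#' Collapses an evaluation table to the highest AUC obtained with either
#' classification method (and, for multi-level platforms, either feature
#' set) for each compound x data type cell.
#'
#' @param evaluations Tibble with columns `compound`, `data_type`, `auc` and
#'   optionally `method` / `feature_set` discriminators being maximized over.
#' @return Tibble with columns `compound`, `data_type`, `best_auc`.
#' @export
best_auc_table <- function(evaluations) {
  req <- c("compound", "data_type", "auc")
  miss <- setdiff(req, names(evaluations))
  if (length(miss)) abort(paste0("Missing column(s): ",
                                 paste(miss, collapse = ", ")))
  evaluations |>
    group_by(.data$compound, .data$data_type) |>
    summarise(best_auc = max(.data$auc, na.rm = TRUE), .groups = "drop")
}

#' Rank molecular data types by predictive performance
#'
#' Per-compound best AUCs are treated as repeated measures over compounds:
#' an overall one-way within-subject ANOVA (compounds as subjects) tests
#' whether data types differ at all, every pair of data types is compared by
#' a paired t-test with Benjamini-Hochberg adjustment, and types are ranked
#' by mean AUC. Win counts give, per data type, the number of compounds on
#' which it attains the (possibly tied) maximum. Only compounds with an AUC
#' in every data type enter the tests.
#'
#' @param grid A [best_auc_table()] result.
#' @return A `datatype_ranking`: list with `ranking` (tibble: `data_type`,
#'   `mean_auc`, `wins`, `n_compounds`), `pairwise` (tibble with raw and
#'   BH-adjusted p-values), `overall` (tibble: `statistic`, `df1`, `df2`,
#'   `p_value`).
#' @export
rank_data_types <- function(grid) {
  types <- unique(grid$data_type)
  if (length(types) < 2) abort("Ranking needs >= 2 data types.")
  wide <- grid |>
    tidyr::pivot_wider(names_from = "data_type", values_from = "best_auc") |>
    filter(complete.cases(across(dplyr::all_of(types))))
  if (nrow(wide) < 3) abort("Ranking needs >= 3 compounds with complete AUCs.")

  M <- as.matrix(wide[, types])
  wins <- colSums(M == apply(M, 1, max))
  ranking <- tibble(
    data_type = types,
    mean_auc = colMeans(M),
    wins = as.integer(wins),
    n_compounds = nrow(M)) |>
    arrange(desc(.data$mean_auc))

  pairs <- utils::combn(types, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    d <- M[, pr[1]] - M[, pr[2]]
    if (sd(d) == 0) {
      # constant differences: the paired t degenerates; its limit is p = 1
      # for identical columns and p = 0 for a constant nonzero shift
      tibble(type1 = pr[1], type2 = pr[2], mean_delta = mean(d),
             statistic = if (all(d == 0)) NA_real_ else Inf * sign(mean(d)),
             p_value = if (all(d == 0)) 1 else 0,
             flag = "zero_variance")
    } else {
      tt <- t.test(M[, pr[1]], M[, pr[2]], paired = TRUE)
      tibble(type1 = pr[1], type2 = pr[2], mean_delta = mean(d),
             statistic = unname(tt$statistic), p_value = tt$p.value,
             flag = "ok")
    }
  }) |>
    mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"))

  long <- grid |>
    filter(.data$compound %in% wide$compound) |>
    mutate(compound = factor(.data$compound),
           data_type = factor(.data$data_type))
  fit <- aov(best_auc ~ data_type + Error(compound), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  overall <- tibble(statistic = tab["data_type", "F value"],
                    df1 = tab["data_type", "Df"],
                    df2 = tab["Residuals", "Df"],
                    p_value = tab["data_type", "Pr(>F)"])
  structure(list(ranking = ranking, pairwise = pairwise, overall = overall),
            class = "datatype_ranking")
}

#' @export
print.datatype_ranking <- function(x, ...) {
  cat("<datatype_ranking>\n")
  print(x$ranking)
  cat(sprintf("overall repeated-measures F = %.3f, p = %.4g\n",
              x$overall$statistic, x$overall$p_value))
  invisible(x)
}

#' Pairwise data-type comparison table
#' @param x A `datatype_ranking`.
#' @param ... Unused.
#' @return The `pairwise` tibble.
#' @method tidy datatype_ranking
#' @export
tidy.datatype_ranking <- function(x, ...) x$pairwise

#' Overall repeated-measures test of a data-type ranking
#' @param x A `datatype_ranking`.
#' @param ... Unused.
#' @return The `overall` tibble.
#' @method glance datatype_ranking
#' @export
glance.datatype_ranking <- function(x, ...) x$overall

#' Transcriptional-subtype baseline classifier
#'
#' Evaluates how well subtype membership alone (one-hot subtype indicators
#' plus the ERBB2-amplification flag) predicts response, under the same
#' multi-split protocol as the omics models.
#'
#' @param labels A [response_labels()] object.
#' @param annotation A [subtype_annotation()] tibble.
#' @param include_erbb2 Include the ERBB2 amplification flag.
#' @param n_splits,seed,train_fraction Passed to [evaluate_multisplit()].
#' @return An `evaluation` object.
#' @export
subtype_baseline <- function(labels, annotation, include_erbb2 = TRUE,
                             n_splits = 50, seed = 1, train_fraction = 2 / 3) {
  y <- labels_as_logical(labels)
  ann <- annotation[annotation$sample_id %in% names(y), ]
  if (nrow(ann) < length(y)) {
    abort("Every labeled line needs a subtype annotation.")
  }
  if (dplyr::n_distinct(ann$subtype) < 2 &&
      (!include_erbb2 || dplyr::n_distinct(ann$erbb2_amplified) < 2)) {
    abort("Single subtype present: baseline AUC undefined.")
  }
  lv <- sort(unique(ann$subtype))
  X <- sapply(lv, function(s) as.numeric(ann$subtype == s))
  colnames(X) <- paste0("subtype_", lv)
  if (include_erbb2) X <- cbind(X, erbb2 = as.numeric(ann$erbb2_amplified))
  rownames(X) <- ann$sample_id
  evaluate_multisplit(X, y, method = "lssvm", n_splits = n_splits,
                      seed = seed, train_fraction = train_fraction,
                      grid = lssvm_grid(k = ncol(X), gamma = 10^(-2:2)),
                      inner_folds = 3)
}

#' Is transcriptional subtype alone a sufficient predictor?
#'
#' A compound is `subtype_sufficient` when the subtype-only model already
#' performs well (AUC > 0.7) and the best omics model adds less than 0.1
#' AUC; `omics_adds` when the best omics model exceeds 0.7 and improves on
#' subtype by at least 0.1; otherwise `weak`.
#'
#' @param best_omics_auc Best AUC over omics models (vectorized).
#' @param subtype_auc Subtype-baseline AUC.
#' @return Character vector: `"subtype_sufficient"`, `"omics_adds"` or
#'   `"weak"`.
#' @export
classify_subtype_sufficiency <- function(best_omics_auc, subtype_auc) {
  # small tolerance so a delta of exactly 0.1 in decimal counts as >= 0.1
  # despite binary floating point (e.g. 0.85 - 0.75 < 0.1 in doubles)
  delta <- best_omics_auc - subtype_auc
  at_least_01 <- delta >= 0.1 - 1e-9
  dplyr::case_when(
    subtype_auc > 0.7 & !at_least_01 ~ "subtype_sufficient",
    best_omics_auc > 0.7 & at_least_01 ~ "omics_adds",
    TRUE ~ "weak")
}

#' Splice-aware minus gene-level AUC differences
#'
#' Per-compound difference between models built on all transcript features
#' (exons, junctions, boundaries...) and on gene-level features alone, from
#' the same splits. Compounds whose difference exceeds `flag_threshold` are
#' flagged as splice-specific predictors.
#'
#' @param auc_all_features,auc_gene_level Named numeric vectors (names =
#'   compounds) or unnamed vectors of equal length.
#' @param flag_threshold Flagging threshold for the per-compound delta.
#' @return Tibble with `compound`, `delta`, `splice_specific`; the overall
#'   mean delta is in attribute `"mean_delta"` and in [glance][generics::glance]able form via
#'   `attr(x, "mean_delta")`.
#' @export
splice_delta <- function(auc_all_features, auc_gene_level,
                         flag_threshold = 0.05) {
  if (length(auc_all_features) != length(auc_gene_level)) {
    abort("AUC vectors must have equal length (same compounds, same splits).")
  }
  cmpd <- names(auc_all_features) %||% as.character(seq_along(auc_all_features))
  out <- tibble(compound = cmpd,
                delta = unname(auc_all_features - auc_gene_level)) |>
    mutate(splice_specific = .data$delta > flag_threshold)
  attr(out, "mean_delta") <- mean(out$delta)
  out
}

#' Concordance between two response labelings
#'
#' Percent of lines labeled identically under two dichotomizations (e.g.
#' GI50-based versus TGI-based).
#'
#' @param labels_a,labels_b [response_labels()] objects or named character
#'   vectors of labels.
#' @return Percent agreement over the common lines.
#' @export
gi50_tgi_concordance <- function(labels_a, labels_b) {
  la <- labels_as_vector(labels_a)
  lb <- labels_as_vector(labels_b)
  common <- intersect(names(la), names(lb))
  if (length(common) == 0) abort("No common lines between labelings.")
  100 * mean(la[common] == lb[common])
}

labels_as_vector <- function(labels) {
  if (inherits(labels, "response_labels")) {
    setNames(labels$labels$label, labels$labels$cell_line)
  } else if (!is.null(names(labels))) {
    labels
  } else {
    abort("Labelings must be response_labels objects or named vectors.")
  }
}
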