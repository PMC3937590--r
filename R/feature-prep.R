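#' Unsupervised variance and detection filtering
#'
#' Removes features whose variance falls below the given quantile of the
#' per-feature variance distribution and, optionally, features detected above
#' a signal floor in too few samples. The filter never sees response labels.
#'
#' @param dataset An [omic_dataset()] with continuous values.
#' @param variance_quantile Quantile of per-feature variances below which
#'   features are removed; 0 keeps everything with positive variance rank.
#' @param detection_floor Optional signal level; a feature must exceed it in
#'   at least `detection_fraction` of samples to be kept. Use for platforms
#'   with a detection-above-background notion (arrays) or as a minimum
#'   expression floor (RNAseq).
#' @param detection_fraction Minimum fraction of samples with signal above
#'   `detection_floor`.
#' @return Filtered [omic_dataset()].
#' @export
variance_detection_filter <- function(dataset, variance_quantile = 0.25,
                                      detection_floor = NULL,
                                      detection_fraction = 0.5) {
  if (dataset$data_type == "mutation") {
    abort("Variance/detection filtering applies to continuous data types.")
  }
  v <- apply(dataset$values, 2, var, na.rm = TRUE)
  # zero-variance features carry no information and are always removed
  keep <- !is.na(v) & v > 0
  if (variance_quantile > 0) {
    keep <- keep & v >= quantile(v, variance_quantile, na.rm = TRUE, names = FALSE)
  }
  if (!is.null(detection_floor)) {
    det <- colMeans(dataset$values > detection_floor, na.rm = TRUE)
    keep <- keep & det >= detection_fraction
  }
  if (!any(keep)) {
    abort("All features removed; relax variance_quantile or detection settings.")
  }
  omic_dataset(dataset$values[, keep, drop = FALSE], dataset$data_type)
}

#' Two-sample t statistics of features against binary labels
#'
#' Pooled-variance two-sample t per feature, vectorised; features constant in
#' both groups get a statistic of 0.
#' @noRd
feature_t_stats <- function(X, y) {
  # positive class: TRUE for logical input, > 0 for {-1,+1} or {0,1} labels
  y <- as.numeric(y) > 0
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 < 2 || n0 < 2) {
    m1 <- colMeans(X[y, , drop = FALSE], na.rm = TRUE)
    m0 <- colMeans(X[!y, , drop = FALSE], na.rm = TRUE)
    d <- m1 - m0
    d[!is.finite(d)] <- 0
    return(d)
  }
  X1 <- X[y, , drop = FALSE]; X0 <- X[!y, , drop = FALSE]
  m1 <- colMeans(X1, na.rm = TRUE); m0 <- colMeans(X0, na.rm = TRUE)
  # vectorized column variances (NA-free modeling matrices by construction)
  v1 <- (colSums(X1^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(X0^2) - n0 * m0^2) / (n0 - 1)
  sp <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  sp[sp < 0] <- 0
  d <- m1 - m0
  t <- d / sqrt(sp * (1 / n1 + 1 / n0))
  # zero within-class variance with a real mean shift separates perfectly:
  # rank above any finite t, ordered among themselves by effect size
  degen <- !is.finite(t)
  t[degen] <- ifelse(d[degen] == 0 | !is.finite(d[degen]), 0,
                     sign(d[degen]) * (1e9 + abs(d[degen])))
  t
}

#' Keep the most label-discriminative feature per gene
#'
#' For multi-level platforms (exon array, RNAseq) keeps, per gene, the single
#' feature with the largest absolute two-sample t statistic against the
#' response labels. This is a supervised reduction: apply it only to training
#' lines inside each evaluation split. Genes whose features are all constant
#' fall back to their gene-level feature when present, else are dropped.
#'
#' @param dataset An [omic_dataset()].
#' @param labels A [response_labels()] object (or a named logical vector of
#'   sensitivity, names = sample ids).
#' @return An [omic_dataset()] with at most one feature per gene.
#' @export
best_feature_per_gene <- function(dataset, labels) {
  y <- labels_as_logical(labels)
  common <- intersect(dataset$samples, names(y))
  if (length(common) < 4) abort("Too few labeled samples for per-gene reduction.")
  X <- dataset$values[common, , drop = FALSE]
  tt <- abs(feature_t_stats(X, y[common]))
  feats <- dataset$features |> mutate(stat = tt[.data$feature_id])
  chosen <- feats |>
    group_by(.data$gene) |>
    summarise(feature_id = {
      if (all(.data$stat == 0)) {
        gl <- .data$feature_id[.data$level == "gene"]
        if (length(gl)) gl[1] else NA_character_
      } else {
        .data$feature_id[order(-.data$stat, .data$feature_id)][1]
      }
    }, .groups = "drop") |>
    filter(!is.na(.data$feature_id)) |>
    pull("feature_id")
  omic_dataset(dataset$values[, chosen, drop = FALSE], dataset$data_type)
}

labels_as_logical <- function(labels) {
  if (inherits(labels, "response_labels")) {
    setNames(labels$labels$label == "sensitive", labels$labels$cell_line)
  } else if (is.logical(labels) && !is.null(names(labels))) {
    labels
  } else {
    abort("`labels` must be a response_labels object or named logical vector.")
  }
}

#' Dichotomize GI50 response at the core-line mean
#'
#' The threshold is the arithmetic mean -log10 GI50 of the compound over the
#' designated core cell lines (lines with response data and several molecular
#' data sets). Every line with a GI50 is then labeled: strictly above the
#' threshold is sensitive, at or below is resistant (ties do not recommend
#' treatment).
#'
#' @param response Tibble from [build_response_matrix()].
#' @param compound Compound identifier.
#' @param core_lines Character vector of core cell lines; default all lines
#'   with a GI50 for this compound.
#' @return A `response_labels` object: list with `compound`, `threshold`,
#'   `labels` (tibble `cell_line`, `gi50`, `label`), `core_lines`, `usable`.
#' @export
dichotomize <- function(response, compound, core_lines = NULL) {
  rows <- response[response$compound == compound & !is.na(response$gi50), ]
  if (is.null(core_lines)) core_lines <- rows$cell_line
  core <- rows[rows$cell_line %in% core_lines, ]
  if (nrow(core) < 2) abort("Need >= 2 core lines with GI50 to dichotomize.")
  threshold <- mean(core$gi50)
  labels <- rows |>
    mutate(label = ifelse(.data$gi50 > threshold, "sensitive", "resistant")) |>
    select("cell_line", "gi50", "label")
  usable <- dplyr::n_distinct(labels$label) == 2
  if (!usable) {
    warn(sprintf("Compound %s: single-class labels (all GI50 identical?); unusable for training.",
                 compound))
  }
  structure(list(compound = compound, threshold = threshold, labels = labels,
                 core_lines = core$cell_line, usable = usable),
            class = "response_labels")
}

#' @export
print.response_labels <- function(x, ...) {
  tab <- table(x$labels$label)
  cat(sprintf("<response_labels> %s: threshold %.3f (-log10 M), %s\n",
              x$compound, x$threshold,
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' @method tidy response_labels
#' @export
tidy.response_labels <- function(x, ...) {
  x$labels |> mutate(compound = x$compound, threshold = x$threshold)
}

#' Genes of the fixed recurrent-mutation panel
#' @return Character vector of the seven panel genes.
#' @export
mutation_panel_genes <- function() {
  c("TP53", "PIK3CA", "MLL3", "CDH1", "MAP2K4", "PTEN", "NCOR1")
}

#' Extract the fixed seven-gene mutation panel
#'
#' The panel of recurrently mutated breast-cancer genes (TP53, PIK3CA, MLL3,
#' CDH1, MAP2K4, PTEN, NCOR1) is fixed by design; an input missing any of
#' them is an error. Extra genes are ignored.
#'
#' @param dataset A binary mutation [omic_dataset()].
#' @return An [omic_dataset()] with exactly seven columns in panel order.
#' @export
build_mutation_panel <- function(dataset) {
  if (dataset$data_type != "mutation") abort("Expected a mutation dataset.")
  genes <- mutation_panel_genes()
  idx <- match(genes, dataset$features$gene)
  if (anyNA(idx)) {
    abort(paste0("Mutation panel gene(s) absent from input: ",
                 paste(genes[is.na(idx)], collapse = ", ")))
  }
  omic_dataset(dataset$values[, dataset$features$feature_id[idx],
                              drop = FALSE], "mutation")
}
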