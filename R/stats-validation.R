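#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood convention: the sum of
#' hypergeometric probabilities (margins fixed) of every table at most as
#' probable as the observed one. The conditional maximum-likelihood odds
#' ratio is reported. Rows are mutation present/absent, columns
#' sensitive/resistant.
#'
#' @param table 2x2 integer matrix, or a length-4 vector (a, b, c, d, filled
#'   by row).
#' @return Tibble with `p_value`, `odds_ratio`, `flag` (`"ok"` or
#'   `"zero_margin"`).
#' @export
#' @examples
#' fisher_exact_2x2(matrix(c(13, 12, 3, 16), 2, byrow = TRUE))
fisher_exact_2x2 <- function(table) {
  if (!is.matrix(table)) table <- matrix(table, 2, byrow = TRUE)
  if (any(table < 0) || any(table != round(table))) {
    abort("Counts must be non-negative integers.")
  }
  if (sum(table) == 0) abort("Empty table.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble(p_value = 1, odds_ratio = NA_real_, flag = "zero_margin"))
  }
  ft <- fisher.test(table)
  tibble(p_value = ft$p.value, odds_ratio = unname(ft$estimate), flag = "ok")
}

#' Welch t association of a feature with response
#'
#' Two-sample Welch t-test of a continuous feature (expression, copy number,
#' methylation...) between sensitive and resistant lines.
#'
#' @param values Numeric feature values.
#' @param labels Logical (TRUE = sensitive) or two-level vector aligned with
#'   `values`.
#' @return Tibble with `estimate` (sensitive minus resistant mean),
#'   `statistic`, `p_value`, `flag`.
#' @export
feature_response_ttest <- function(values, labels) {
  pos <- as.logical(labels)
  if (!is.logical(labels)) {
    u <- sort(unique(labels)); pos <- labels == u[length(u)]
  }
  x <- values[pos]; y <- values[!pos]
  if (length(x) < 2 || length(y) < 2) abort("Both classes need >= 2 values.")
  if (sd(x) == 0 && sd(y) == 0) {
    return(tibble(estimate = mean(x) - mean(y), statistic = NA_real_,
                  p_value = NA_real_, flag = "zero_variance"))
  }
  tt <- t.test(x, y)
  tibble(estimate = unname(diff(rev(tt$estimate))), statistic = unname(tt$statistic),
         p_value = tt$p.value, flag = "ok")
}

#' Association table of omic features with a response labeling
#'
#' Runs [feature_response_ttest()] (continuous types) or
#' [fisher_exact_2x2()] (mutation) per feature and adds
#' Benjamini-Hochberg-adjusted q-values.
#'
#' @param dataset An [omic_dataset()].
#' @param labels A [response_labels()] object or named logical vector.
#' @return Tibble with one row per feature: `feature_id`, `gene`, `test`,
#'   `estimate`, `statistic`, `p_value`, `q_value`.
#' @export
association_table <- function(dataset, labels) {
  y <- labels_as_logical(labels)
  common <- intersect(dataset$samples, names(y))
  X <- dataset$values[common, , drop = FALSE]
  yy <- y[common]
  rows <- purrr::map_dfr(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    ok <- !is.na(v)
    if (dataset$data_type == "mutation") {
      tab <- matrix(c(sum(v[ok] == 1 & yy[ok]), sum(v[ok] == 1 & !yy[ok]),
                      sum(v[ok] == 0 & yy[ok]), sum(v[ok] == 0 & !yy[ok])),
                    2, byrow = TRUE)
      res <- fisher_exact_2x2(tab)
      tibble(feature_id = colnames(X)[j], test = "fisher",
             estimate = res$odds_ratio, statistic = NA_real_,
             p_value = res$p_value)
    } else {
      res <- tryCatch(feature_response_ttest(v[ok], yy[ok]),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      tibble(feature_id = colnames(X)[j], test = "welch_t",
             estimate = res$estimate, statistic = res$statistic,
             p_value = res$p_value)
    }
  })
  rows |>
    left_join(dataset$features |> select("feature_id", "gene"),
              by = "feature_id") |>
    mutate(q_value = p.adjust(.data$p_value, method = "BH")) |>
    select("feature_id", "gene", "test", "estimate", "statistic",
           "p_value", "q_value") |>
    arrange(.data$p_value)
}

#' Kaplan-Meier curves and log-rank test for predicted response groups
#'
#' Product-limit survival estimates per predicted group and the standard
#' two-group log-rank chi-square test.
#'
#' @param cohort Tibble with columns `time` (>= 0), `event` (0/1) and
#'   `group` (two levels, e.g. predicted sensitive/resistant).
#' @return A `km_result`: list with `fit` (survfit), `chisq`, `p_value`,
#'   `observed`, `expected`, `flag`.
#' @export
km_logrank <- function(cohort) {
  req <- c("time", "event", "group")
  miss <- setdiff(req, names(cohort))
  if (length(miss)) abort(paste0("Missing column(s): ",
                                 paste(miss, collapse = ", ")))
  if (any(cohort$time < 0)) abort("Survival times must be non-negative.")
  if (dplyr::n_distinct(cohort$group) != 2) {
    abort("Exactly two predicted groups required.")
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = cohort)
  if (sum(cohort$event) == 0) {
    warn("No events: log-rank p undefined.")
    return(structure(list(fit = fit, chisq = NA_real_, p_value = NA_real_,
                          observed = NULL, expected = NULL,
                          flag = "no_events"),
                     class = "km_result"))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group,
                            data = cohort)
  p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  structure(list(fit = fit, chisq = unname(sd_$chisq), p_value = p,
                 observed = sd_$obs, expected = sd_$exp, flag = "ok"),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("<km_result> log-rank chisq = %.3f, p = %.4g\n",
              x$chisq, x$p_value))
  invisible(x)
}

#' @method glance km_result
#' @export
glance.km_result <- function(x, ...) {
  tibble(chisq = x$chisq, p_value = x$p_value, flag = x$flag)
}

#' Validate predicted probabilities against observed classes
#'
#' Dichotomizes predicted probabilities at `threshold` (a probability exactly
#' at the threshold classifies resistant, consistent with the response
#' tie rule) and reports per-class correct counts plus the threshold-free
#' AUC.
#'
#' @param probabilities Predicted probabilities of sensitivity.
#' @param observed Logical or two-level observed classes (TRUE/larger =
#'   sensitive).
#' @param threshold Classification threshold.
#' @return Tibble with `n_sensitive`, `correct_sensitive`, `n_resistant`,
#'   `correct_resistant`, `accuracy`, `auc`.
#' @export
dichotomous_validation <- function(probabilities, observed, threshold = 0.5) {
  pos <- as.logical(observed)
  if (!is.logical(observed)) {
    u <- sort(unique(observed)); pos <- observed == u[length(u)]
  }
  pred <- probabilities > threshold
  tibble(
    n_sensitive = sum(pos),
    correct_sensitive = sum(pred & pos),
    n_resistant = sum(!pos),
    correct_resistant = sum(!pred & !pos),
    accuracy = mean(pred == pos),
    auc = auc(probabilities, pos))
}
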