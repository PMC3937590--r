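#' Analysis configuration
#'
#' Bundles the tunable settings of the whole pipeline; every stochastic
#' operation receives the seed recorded here. Mirrored one-to-one by the
#' YAML config consumed by the command-line interface.
#'
#' @param n_splits Random training/test divisions per evaluation.
#' @param train_fraction Fraction of lines in each training set.
#' @param seed Integer seed.
#' @param grid [lssvm_grid()] search ranges.
#' @param sd_floor,offscale_max_fraction Low-variation compound filter, see
#'   [filter_low_variation()].
#' @param variance_quantile Unsupervised feature filter quantile.
#' @param max_missing Maximum missing fraction per feature before modeling.
#' @param resistant_quantile Cutoff-model setting, see [select_cutoffs()].
#' @param auc_floor,prob_floor Report thresholds, see [rank_compounds()].
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_splits = 100, train_fraction = 2 / 3, seed = 1,
                            grid = lssvm_grid(), sd_floor = 0.5,
                            offscale_max_fraction = 0.5,
                            variance_quantile = 0.25, max_missing = 0.2,
                            resistant_quantile = 0.25, auc_floor = 0.7,
                            prob_floor = 0.65) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0,1).")
  }
  if (n_splits < 1) abort("`n_splits` must be >= 1.")
  structure(list(n_splits = as.integer(n_splits),
                 train_fraction = train_fraction, seed = as.integer(seed),
                 grid = grid, sd_floor = sd_floor,
                 offscale_max_fraction = offscale_max_fraction,
                 variance_quantile = variance_quantile,
                 max_missing = max_missing,
                 resistant_quantile = resistant_quantile,
                 auc_floor = auc_floor, prob_floor = prob_floor),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML
#'
#' @param path Path to a YAML file whose keys mirror [analysis_config()]
#'   arguments (the grid as `grid: {k: [...], gamma: [...]}`).
#' @return An `analysis_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$grid)) {
    raw$grid <- lssvm_grid(
      k = raw$grid$k %||% lssvm_grid()$k,
      gamma = raw$grid$gamma %||% lssvm_grid()$gamma)
  }
  do.call(analysis_config, raw)
}

#' Write an analysis configuration to YAML
#'
#' @param config An [analysis_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$grid <- list(k = config$grid$k, gamma = config$grid$gamma)
  yaml::write_yaml(x, path)
  invisible(path)
}
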