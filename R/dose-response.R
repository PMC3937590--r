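#' Background-correct a plate record into a growth curve
#'
#' Subtracts the mean of the drug-plate background ODs from every OD on that
#' plate and the mean of the T0-plate backgrounds from the T0 median OD, then
#' summarises triplicates by their median (masked replicates excluded). A
#' concentration whose replicates are all masked is dropped with a warning;
#' a record whose corrected untreated control is non-positive is rejected.
#'
#' @param record A single-row tibble in the [read_plate_file()] schema.
#' @return A list with elements `cell_line`, `compound`, `t0` (corrected
#'   time-zero signal), `control` (corrected untreated signal), and a tibble
#'   `treated` with columns `concentration`, `signal`, `n_replicates`.
#' @export
correct_background <- function(record) {
  stopifnot(nrow(record) == 1)
  bg <- mean(c(record$background_od1, record$background_od2), na.rm = TRUE)
  if (is.nan(bg)) abort("Record has no usable drug-plate background OD.")
  t0_bg <- mean(c(record$T0_background_od1, record$T0_background_od2),
                na.rm = TRUE)
  if (is.nan(t0_bg)) abort("Record has no usable T0-plate background OD.")
  t0 <- record$T0_median_od - t0_bg

  od0 <- unlist(record[paste0("od0.", 1:3)], use.names = FALSE) - bg
  control <- median(od0, na.rm = TRUE)
  if (is.na(control) || control <= 0) {
    abort(sprintf("Record %s/%s rejected: untreated control <= 0 after background correction.",
                  record$cellline, record$compound))
  }

  treated <- purrr::map_dfr(1:9, function(j) {
    reps <- unlist(record[paste0("od", j, ".", 1:3)], use.names = FALSE) - bg
    tibble(concentration = record[[paste0("c", j)]],
           signal = median(reps, na.rm = TRUE),
           n_replicates = sum(!is.na(reps)))
  })
  dropped <- treated$n_replicates == 0
  if (any(dropped)) {
    warn(sprintf("%s/%s: %d concentration(s) excluded (all replicates masked).",
                 record$cellline, record$compound, sum(dropped)))
    treated <- treated[!dropped, , drop = FALSE]
  }
  list(cell_line = record$cellline, compound = record$compound,
       t0 = t0, control = control, treated = treated)
}

#' Percent growth (NCI two-branch convention)
#'
#' Growth relative to the time-zero cell number `t0` and untreated control
#' `control`: `100 * (t - t0) / (control - t0)` when `t >= t0` (net growth)
#' and `100 * (t - t0) / t0` when `t < t0` (net kill). Continuous at
#' `t == t0` and bounded below by -100 (complete kill).
#'
#' @param t Treated signal(s), background-corrected.
#' @param t0 Time-zero signal (scalar, > 0).
#' @param control Untreated control signal (scalar, must exceed `t0`).
#' @return Percent growth, same length as `t`.
#' @export
#' @examples
#' growth_percent(c(150, 100, 50, 0), t0 = 100, control = 150)
growth_percent <- function(t, t0, control) {
  if (t0 <= 0) abort("Time-zero signal must be positive.")
  if (control <= t0) {
    abort("Untreated control does not exceed time zero: growth undefined.")
  }
  ifelse(t >= t0, 100 * (t - t0) / (control - t0), 100 * (t - t0) / t0)
}

#' Locate where a growth curve crosses a given level
#'
#' Finds the first (lowest-concentration) pair of tested concentrations
#' bracketing `level` and interpolates linearly in log10(concentration)
#' against growth. If growth at the lowest tested concentration is already at
#' or below `level` the value clamps to that edge (`at_min`); if growth never
#' drops to `level` it clamps to the highest tested concentration (`at_max`).
#'
#' @param concentrations Strictly increasing positive molar concentrations.
#' @param growth Percent-growth values paired with `concentrations`.
#' @param level Growth level to cross (50 for GI50, 0 for TGI).
#' @return A list with `value` (-log10 molar) and `clamped` (one of
#'   `"none"`, `"at_min"`, `"at_max"`), or NULL value with fewer than 2
#'   usable points.
#' @export
interpolate_crossing <- function(concentrations, growth, level) {
  keep <- !is.na(concentrations) & !is.na(growth)
  conc <- concentrations[keep]
  g <- growth[keep]
  if (length(conc) < 2) {
    return(list(value = NA_real_, clamped = NA_character_))
  }
  o <- order(conc)
  conc <- conc[o]; g <- g[o]
  lc <- log10(conc)
  if (g[1] <= level) {
    return(list(value = -lc[1], clamped = "at_min"))
  }
  for (j in seq_len(length(conc) - 1L)) {
    if (g[j] > level && g[j + 1] <= level) {
      frac <- (g[j] - level) / (g[j] - g[j + 1])
      return(list(value = -(lc[j] + frac * (lc[j + 1] - lc[j])),
                  clamped = "none"))
    }
  }
  list(value = -lc[length(lc)], clamped = "at_max")
}

#' GI50 and TGI per plate record
#'
#' Runs background correction, percent growth and crossing interpolation for
#' each plate. GI50 is the 50%-growth crossing and TGI the zero-growth
#' crossing, both reported as -log10(molar) so that larger values mean more
#' sensitive. A TGI clamped at the top of the tested range (never reached) is
#' reported as missing.
#'
#' @param plates Tibble in the [read_plate_file()] schema.
#' @return Tibble with columns `cell_line`, `compound`, `drug_plate_id`,
#'   `gi50`, `clamped`, `tgi`, `n_concentrations`. Rejected records are
#'   dropped with a warning.
#' @export
plate_response <- function(plates) {
  out <- purrr::map(seq_len(nrow(plates)), function(i) {
    rec <- plates[i, , drop = FALSE]
    curve <- tryCatch(correct_background(rec), error = function(e) {
      warn(conditionMessage(e)); NULL
    })
    if (is.null(curve)) return(NULL)
    g <- tryCatch(
      growth_percent(curve$treated$signal, curve$t0, curve$control),
      error = function(e) { warn(conditionMessage(e)); NULL })
    if (is.null(g)) return(NULL)
    gi <- interpolate_crossing(curve$treated$concentration, g, 50)
    tg <- interpolate_crossing(curve$treated$concentration, g, 0)
    tibble(cell_line = curve$cell_line, compound = curve$compound,
           drug_plate_id = rec$drug_plate_id,
           gi50 = gi$value, clamped = gi$clamped,
           tgi = if (identical(tg$clamped, "at_max")) NA_real_ else tg$value,
           n_concentrations = nrow(curve$treated))
  })
  bind_rows(out)
}

#' Build the cell-line x compound response matrix
#'
#' Replicate plates for a (cell line, compound) pair are combined by the
#' median GI50 (and median TGI) across plates; the clamping flag is kept only
#' when all plates agree. Rows are ordered lexicographically by cell line
#' then compound so output is independent of input record order.
#'
#' @param plates Tibble in the [read_plate_file()] schema, or a per-plate
#'   response tibble from [plate_response()].
#' @return Tibble with columns `cell_line`, `compound`, `gi50`, `tgi`,
#'   `clamped`, `n_plates`.
#' @export
build_response_matrix <- function(plates) {
  per_plate <- if (all(c("gi50", "clamped") %in% names(plates))) {
    plates
  } else {
    plate_response(plates)
  }
  per_plate |>
    filter(!is.na(.data$gi50)) |>
    group_by(.data$cell_line, .data$compound) |>
    summarise(
      gi50 = median(.data$gi50),
      tgi = if (all(is.na(.data$tgi))) NA_real_ else
        median(.data$tgi, na.rm = TRUE),
      clamped = if (dplyr::n_distinct(.data$clamped) == 1)
        .data$clamped[1] else "none",
      n_plates = dplyr::n(),
      .groups = "drop") |>
    arrange(.data$cell_line, .data$compound)
}

#' Per-compound response summaries
#'
#' Dynamic range is max minus min of -log10 GI50 over lines with unclamped
#' values (0 when fewer than two such lines).
#'
#' @param response Tibble from [build_response_matrix()].
#' @return Tibble with columns `compound`, `n_lines`, `sd_gi50`,
#'   `dynamic_range`, `frac_clamped`.
#' @export
compound_summary <- function(response) {
  if (!"clamped" %in% names(response)) response$clamped <- "none"
  response |>
    group_by(.data$compound) |>
    summarise(
      n_lines = dplyr::n(),
      sd_gi50 = if (dplyr::n() >= 2) sd(.data$gi50) else NA_real_,
      dynamic_range = {
        un <- .data$gi50[.data$clamped == "none"]
        if (length(un) >= 2) max(un) - min(un) else 0
      },
      frac_clamped = mean(.data$clamped != "none"),
      .groups = "drop")
}

#' Eliminate compounds with low variation in response
#'
#' Retains compounds whose -log10 GI50 standard deviation across the panel
#' meets `sd_floor` and whose fraction of off-scale (clamped) measures does
#' not exceed `offscale_max_fraction`.
#'
#' @param response Tibble from [build_response_matrix()].
#' @param sd_floor Minimum GI50 standard deviation (log10 units).
#' @param offscale_max_fraction Maximum tolerated fraction of clamped values.
#' @return [compound_summary()] tibble with a logical `retained` column.
#' @export
filter_low_variation <- function(response, sd_floor = 0.5,
                                 offscale_max_fraction = 0.5) {
  compound_summary(response) |>
    mutate(retained = !is.na(.data$sd_gi50) &
             .data$sd_gi50 >= sd_floor &
             .data$frac_clamped <= offscale_max_fraction)
}
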