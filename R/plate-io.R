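## Raw growth-inhibition plate schema: one row per cell line x compound plate.
## Nine concentrations, treated in triplicate, untreated (od0) triplicate,
## two background wells per plate and a separate time-zero (T0) plate.

plate_od_columns <- function() {
  c(paste0("od0.", 1:3),
    as.vector(t(outer(1:9, 1:3, function(j, r) paste0("od", j, ".", r)))))
}

plate_columns <- function() {
  c("cellline", "compound", "drug_plate_id", "T0_plate_id",
    "background_od1", "background_od2",
    plate_od_columns(),
    "T0_background_od1", "T0_background_od2", "T0_median_od",
    paste0("c", 1:9), "units")
}

#' Read a raw drug-response plate file
#'
#' Parses the delimited dialect used for raw growth-inhibition data: per row
#' one cell line x compound plate with two background ODs, an untreated
#' triplicate (`od0.1`-`od0.3`), treated triplicates at nine concentrations
#' (`od1.1`-`od9.3`), the time-zero plate summary, the nine tested
#' concentrations `c1`-`c9` (molar) and their unit string. Empty OD cells are
#' read as masked (NA) replicates.
#'
#' @param path Path to a comma-delimited plate file.
#' @return A tibble with one row per plate and exactly the documented columns.
#' @export
read_plate_file <- function(path) {
  cols <- plate_columns()
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("Plate file %s is missing required column(s): %s",
                  path, paste(miss, collapse = ", ")))
  }
  df <- df[, cols]
  num_cols <- setdiff(cols, c("cellline", "compound", "drug_plate_id",
                              "T0_plate_id", "units"))
  for (cc in num_cols) {
    raw <- df[[cc]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad)) {
      abort(sprintf("Non-numeric value '%s' in column %s, row %d of %s.",
                    raw[bad[1]], cc, bad[1], path))
    }
    df[[cc]] <- val
  }
  conc <- as.matrix(df[, paste0("c", 1:9)])
  if (anyNA(conc)) {
    abort(sprintf("Missing concentration in row %d of %s.",
                  which(rowSums(is.na(conc)) > 0)[1], path))
  }
  if (any(conc <= 0) || any(t(apply(conc, 1, diff)) <= 0)) {
    abort("Concentrations c1-c9 must be positive and strictly increasing.")
  }
  as_tibble(df)
}

#' Write plate records in the raw plate dialect
#'
#' @param plates A tibble as returned by [read_plate_file()] or
#'   [simulate_plates()].
#' @param path Output path (comma-delimited).
#' @return `path`, invisibly.
#' @export
write_plate_file <- function(plates, path) {
  miss <- setdiff(plate_columns(), names(plates))
  if (length(miss)) abort(paste0("Missing plate column(s): ",
                                 paste(miss, collapse = ", ")))
  readr::write_csv(plates[, plate_columns()], path, na = "")
  invisible(path)
}
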