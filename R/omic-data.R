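#' Omic data types recognised by the package
#'
#' @return Character vector of valid `data_type` tags.
#' @export
omic_data_types <- function() {
  c("expression_array", "exon_array", "rnaseq", "copy_number",
    "methylation", "protein_array", "mutation")
}

#' Feature levels recognised in feature identifiers
#' @return Character vector of valid level tags.
#' @export
feature_levels <- function() {
  c("gene", "transcript", "exon", "junction", "boundary", "intron",
    "probe", "protein", "site")
}

#' Parse feature identifiers of the form "GENE|level|detail"
#'
#' Identifiers carry a gene symbol, a feature level (gene, transcript, exon,
#' junction, boundary, intron, probe, protein or site) and an optional detail
#' field, separated by `|`. A bare symbol is taken as a gene-level feature.
#'
#' @param ids Character vector of feature identifiers.
#' @return A tibble with columns `feature_id`, `gene`, `level`, `detail`.
#' @export
#' @examples
#' parse_feature_ids(c("ERBB2|gene", "TP53|exon|e4", "PTEN"))
parse_feature_ids <- function(ids) {
  parts <- stringr::str_split(ids, stringr::fixed("|"))
  gene <- purrr::map_chr(parts, 1)
  level <- purrr::map_chr(parts, ~ if (length(.x) >= 2) .x[[2]] else "gene")
  detail <- purrr::map_chr(parts, ~ if (length(.x) >= 3) .x[[3]] else NA_character_)
  bad <- !level %in% feature_levels()
  if (any(bad)) {
    abort(sprintf("Unknown feature level '%s' in id '%s'.",
                  level[bad][1], ids[bad][1]))
  }
  tibble(feature_id = ids, gene = gene, level = level, detail = detail)
}

#' Construct an omic dataset
#'
#' A typed samples-by-features matrix for one molecular platform. Mutation
#' datasets must be binary 0/1 (NA allowed for missing calls).
#'
#' @param values Numeric matrix, samples in rows, features in columns, with
#'   dimnames giving sample and feature identifiers.
#' @param data_type One of [omic_data_types()].
#' @return An object of class `omic_dataset`: a list with elements `values`,
#'   `data_type`, `features` (tibble from [parse_feature_ids()]) and `samples`.
#' @export
omic_dataset <- function(values, data_type) {
  data_type <- match.arg(data_type, omic_data_types())
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (samples x features).")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have sample rownames and feature colnames.")
  }
  if (anyDuplicated(rownames(values))) abort("Duplicate sample ids.")
  if (anyDuplicated(colnames(values))) abort("Duplicate feature ids.")
  if (data_type == "mutation") {
    v <- values[!is.na(values)]
    if (!all(v %in% c(0, 1))) {
      abort("Mutation datasets must contain only 0/1 values.")
    }
  }
  structure(
    list(values = values,
         data_type = data_type,
         features = parse_feature_ids(colnames(values)),
         samples = rownames(values)),
    class = "omic_dataset")
}

#' @export
print.omic_dataset <- function(x, ...) {
  cat(sprintf("<omic_dataset> %s: %d samples x %d features\n",
              x$data_type, nrow(x$values), ncol(x$values)))
  lv <- table(x$features$level)
  cat("  levels:", paste(names(lv), lv, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omic_dataset <- function(x) dim(x$values)

#' Read a delimited omic feature matrix
#'
#' Files follow the genomics convention: features in rows, samples in columns,
#' first column holding feature identifiers in the "GENE|level|detail" grammar.
#' The matrix is transposed to samples-by-features on read.
#'
#' @param path Path to a tab-delimited text file.
#' @param data_type One of [omic_data_types()].
#' @return An [omic_dataset()].
#' @export
read_omic_matrix <- function(path, data_type) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2) abort("Omic matrix needs a feature id column and >= 1 sample.")
  types <- paste0("c", strrep("d", length(header) - 1L))
  df <- suppressWarnings(
    readr::read_tsv(path, col_types = types, show_col_types = FALSE))
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed omic matrix %s: row %d (%s).",
                  path, probs$row[1], probs$expected[1]))
  }
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate feature id '%s' in %s.", ids[duplicated(ids)][1], path))
  }
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- ids
  omic_dataset(m, data_type)
}

#' Write an omic dataset to a tab-delimited file (features x samples)
#'
#' @param dataset An [omic_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_omic_matrix <- function(dataset, path) {
  m <- t(dataset$values)
  df <- tibble(feature_id = rownames(m))
  df <- bind_cols(df, as_tibble(m))
  readr::write_tsv(df, path)
  invisible(path)
}

#' Tidy an omic dataset into long form
#'
#' @param x An [omic_dataset()].
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `feature_id`, `gene`, `level`,
#'   `data_type`, `value`.
#' @method tidy omic_dataset
#' @export
tidy.omic_dataset <- function(x, ...) {
  long <- as_tibble(x$values, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "feature_id",
                        values_to = "value")
  long |>
    left_join(x$features, by = "feature_id") |>
    mutate(data_type = x$data_type) |>
    select("sample_id", "feature_id", "gene", "level", "data_type", "value")
}

#' Subtype annotation table
#'
#' Validates a sample annotation tibble: one row per sample, a transcriptional
#' subtype (luminal, basal, claudin_low, normal_like or unknown) and an ERBB2
#' amplification flag; optional estrogen-receptor status.
#'
#' @param data A data frame with columns `sample_id`, `subtype`,
#'   `erbb2_amplified` and optionally `er_status`.
#' @return A validated tibble.
#' @export
subtype_annotation <- function(data) {
  req <- c("sample_id", "subtype", "erbb2_amplified")
  miss <- setdiff(req, names(data))
  if (length(miss)) abort(paste0("Missing annotation column(s): ",
                                 paste(miss, collapse = ", ")))
  if (anyDuplicated(data$sample_id)) abort("Duplicate sample_id in annotation.")
  ok <- c("luminal", "basal", "claudin_low", "normal_like", "unknown")
  bad <- setdiff(unique(data$subtype), ok)
  if (length(bad)) abort(sprintf("Unknown subtype '%s'.", bad[1]))
  out <- as_tibble(data)
  if (!"er_status" %in% names(out)) out$er_status <- NA
  out
}
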