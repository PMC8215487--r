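.spot_cols <- c("slide_id", "channel", "antibody_id", "sample_id",
                "print_conc_mg_ml", "replicate_idx", "raw_intensity",
                "local_background")
.channels <- c("antibody", "total_protein", "negative_control")

#' Read a spot-level RPPA table
#'
#' Tab-delimited, one row per printed spot; columns `slide_id`, `channel`,
#' `antibody_id`, `sample_id`, `print_conc_mg_ml`, `replicate_idx`,
#' `raw_intensity`, `local_background`.
#'
#' @param path path to a TSV file.
#' @return a validated `spot_table` data.frame.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(.spot_cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("spot table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("empty spot table", call. = FALSE)
  }
  for (col in c("print_conc_mg_ml", "raw_intensity", "local_background")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("", "NA")))
    if (length(bad)) {
      stop(sprintf("non-numeric `%s` at row %d: '%s'", col, bad[1L],
                   df[[col]][bad[1L]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  df$replicate_idx <- as.integer(df$replicate_idx)
  df$antibody_id[df$antibody_id %in% c("", "NA")] <- NA_character_
  unknown <- setdiff(unique(df$channel), .channels)
  if (length(unknown)) {
    stop(sprintf("unknown channel value(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Write a spot table as TSV
#'
#' @param spots a `spot_table` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(spots, path) {
  utils::write.table(as.data.frame(spots)[.spot_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' CSV with columns `sample_id`, `group` and optionally `psa_ng_ml`,
#' `gleason`, `ptnm`, `recurrent` (0/1), `followup_years`. Gleason and
#' pTNM values are validated against the declared orderings
#' ([gleason_levels()], [ptnm_levels()]); missing recurrence is kept as
#' `NA` and only blocks prognostic stages.
#'
#' @param path path to a CSV file.
#' @param groups optional character vector of allowed group labels.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path, groups = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group")) {
    if (!col %in% names(df)) {
      stop(sprintf("annotation missing column `%s`", col), call. = FALSE)
    }
  }
  if (!is.null(groups)) {
    unknown <- setdiff(unique(df$group), groups)
    if (length(unknown)) {
      stop(sprintf("undeclared group label(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
  }
  if ("psa_ng_ml" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$psa_ng_ml))
    bad <- which(is.na(v) & !(df$psa_ng_ml %in% c("", "NA", NA)))
    if (length(bad)) {
      stop(sprintf("malformed PSA at row %d: '%s'", bad[1L], df$psa_ng_ml[bad[1L]]),
           call. = FALSE)
    }
    if (any(v < 0, na.rm = TRUE)) stop("PSA must be >= 0", call. = FALSE)
    df$psa_ng_ml <- v
  }
  for (spec in list(c("gleason", "gleason_levels"), c("ptnm", "ptnm_levels"))) {
    col <- spec[1L]
    if (col %in% names(df)) {
      lv <- if (col == "gleason") gleason_levels() else ptnm_levels()
      vals <- as.character(df[[col]])
      vals[vals %in% c("", "NA")] <- NA_character_
      bad <- which(!is.na(vals) & !vals %in% lv)
      if (length(bad)) {
        stop(sprintf("invalid %s value at row %d: '%s' (allowed: %s)", col,
                     bad[1L], vals[bad[1L]], paste(lv, collapse = ", ")),
             call. = FALSE)
      }
      df[[col]] <- vals
    }
  }
  if ("recurrent" %in% names(df)) {
    v <- suppressWarnings(as.integer(df$recurrent))
    if (any(!v %in% c(0L, 1L) & !is.na(v))) {
      stop("`recurrent` must be 0, 1 or missing", call. = FALSE)
    }
    df$recurrent <- v
  }
  df
}

#' Write / read a normalized matrix as TSV
#'
#' Samples as rows (first column `sample_id`), endpoints as columns.
#'
#' @param matrix samples-by-endpoints matrix with dimnames.
#' @param path file path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(matrix, path) {
  df <- data.frame(sample_id = rownames(matrix), as.data.frame(unclass(matrix)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  storage.mode(m) <- "double"
  m
}

#' Write a reference-curve fit (or any result list) as JSON
#'
#' @param x a list-like result (e.g. `ref_curve_fit`, `roc_result`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
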