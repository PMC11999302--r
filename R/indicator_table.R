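#' Construct an indicator table
#'
#' An indicator table is the area-by-indicator matrix of raw rates or
#' percentages, one row per small area (census tract), plus the area
#' identifiers. Missing values are `NA`.
#'
#' @param values numeric matrix or data frame, rows = areas, columns =
#'   indicators (column names are indicator ids).
#' @param area_ids character vector of unique area identifiers, one per row.
#' @return an object of class `indicator_table`.
#' @export
indicator_table <- function(values, area_ids) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  area_ids <- canon_id(area_ids)
  if (length(area_ids) != nrow(values))
    svi_stop("number of area ids must equal number of rows", "svi_data_error")
  if (anyDuplicated(area_ids))
    svi_stop(paste0("duplicate area id(s): ",
                    paste(unique(area_ids[duplicated(area_ids)]), collapse = ", ")),
             "svi_data_error")
  if (is.null(colnames(values)))
    svi_stop("indicator columns must be named", "svi_data_error")
  colnames(values) <- canon_id(colnames(values))
  rownames(values) <- area_ids
  # percentages above 100 usually signal a scale mix-up; warn, don't stop
  # (land-cover shares may legitimately be proportions in [0, 1])
  mx <- suppressWarnings(max(values, na.rm = TRUE))
  if (is.finite(mx) && mx > 100 + 1e-9)
    warning("indicator values above 100; check rate scales", call. = FALSE)
  structure(list(area_ids = area_ids, values = values),
            class = "indicator_table")
}

#' Read an indicator table from delimited text
#'
#' Expects UTF-8 delimited text (comma default, tab accepted), a header row
#' of indicator ids, and the area identifier in the first column (or the
#' column named by `id_field`). Empty fields and "NA" are read as missing.
#'
#' @param path file path.
#' @param sep field separator; `NULL` auto-detects comma vs tab from the
#'   header line.
#' @param id_field name of the area-id column; default: first column.
#' @return an `indicator_table`.
#' @export
read_indicator_table <- function(path, sep = NULL, id_field = NULL) {
  if (!file.exists(path))
    svi_stop(paste0("indicator table not found: ", path), "svi_data_error")
  if (is.null(sep)) {
    header <- readLines(path, n = 1L, encoding = "UTF-8")
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("", "NA"), check.names = FALSE,
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          comment.char = "")
  if (is.null(id_field)) id_field <- names(df)[1L]
  if (!id_field %in% names(df))
    svi_stop(paste0("id column '", id_field, "' not present"), "svi_data_error")
  ids <- df[[id_field]]
  df[[id_field]] <- NULL
  indicator_table(as.matrix(df), ids)
}

#' Write an indicator table as delimited text
#' @param table an `indicator_table`.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_indicator_table <- function(table, path, sep = ",") {
  stopifnot(inherits(table, "indicator_table"))
  df <- data.frame(area_id = table$area_ids, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Compute a per-area rate column from counts
#'
#' Turns numerator/denominator counts (e.g. persons without higher
#' education over total persons) into the percentage or proportion column
#' an indicator table stores. A zero denominator yields a missing rate with
#' a warning; negative counts are an error.
#'
#' @param numerators,denominators non-negative per-area counts.
#' @param scale `"percent"` (multiply by 100) or `"proportion"`.
#' @return numeric vector of rates, `NA` where the denominator is zero.
#' @export
compute_rate <- function(numerators, denominators,
                         scale = c("percent", "proportion")) {
  scale <- match.arg(scale)
  if (length(numerators) != length(denominators))
    svi_stop("numerators and denominators differ in length", "svi_data_error")
  if (any(numerators < 0, na.rm = TRUE) || any(denominators < 0, na.rm = TRUE))
    svi_stop("counts must be non-negative", "svi_data_error")
  zero <- !is.na(denominators) & denominators == 0 & !is.na(numerators)
  if (any(zero))
    warning(sprintf("%d rate(s) undefined (zero denominator); set to missing",
                    sum(zero)), call. = FALSE)
  rate <- numerators / denominators
  rate[zero] <- NA_real_
  rate * if (scale == "percent") 100 else 1
}

#' Apply a missing-data policy to an indicator table
#'
#' Three policies: `"error"` aborts on any missing cell, naming the first
#' offending area and indicator; `"median_impute"` fills each missing cell
#' with its column median (imputed cells are listed in the report);
#' `"renormalize_weights"` leaves values untouched and instructs the
#' weighting stage to redistribute within-domain weights over the
#' indicators observed for each area (the default downstream, since
#' imputation invents data).
#'
#' @param table an `indicator_table`.
#' @param policy one of `"error"`, `"median_impute"`, `"renormalize_weights"`.
#' @return list with `table` (possibly imputed) and `report` (class
#'   `svi_missing_report`): the policy, a data frame of imputed cells, and
#'   `renormalize` (logical flag for the weighting stage).
#' @export
handle_missing <- function(table,
                           policy = c("renormalize_weights", "median_impute", "error")) {
  stopifnot(inherits(table, "indicator_table"))
  if (!is_string(policy[1]) ||
      !policy[1] %in% c("renormalize_weights", "median_impute", "error"))
    svi_stop(paste0("unknown missing-data policy: ", policy[1]),
             "svi_policy_error")
  policy <- policy[1]
  miss <- which(is.na(table$values), arr.ind = TRUE)
  imputed <- data.frame(area_id = character(), indicator_id = character(),
                        value = numeric(), stringsAsFactors = FALSE)
  if (nrow(miss)) {
    if (policy == "error") {
      svi_stop(sprintf("missing value for area '%s', indicator '%s' (policy=error)",
                       table$area_ids[miss[1, 1]],
                       colnames(table$values)[miss[1, 2]]),
               "svi_data_error")
    }
    if (policy == "median_impute") {
      med <- apply(table$values, 2, stats::median, na.rm = TRUE)
      imputed <- data.frame(
        area_id = table$area_ids[miss[, 1]],
        indicator_id = colnames(table$values)[miss[, 2]],
        value = med[miss[, 2]], stringsAsFactors = FALSE
      )
      table$values[miss] <- med[miss[, 2]]
    }
  }
  report <- structure(
    list(policy = policy, n_missing = nrow(miss), imputed = imputed,
         renormalize = policy == "renormalize_weights" && nrow(miss) > 0),
    class = "svi_missing_report"
  )
  list(table = table, report = report)
}
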