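# Reading and writing datasets (CSV and ARFF) and mask files.
#
# CSV dialect: UTF-8, comma-separated, header row; an empty cell or "NA" is
# missing; a column is numeric when every non-missing token parses as a
# number. ARFF goes through the standard WEKA dialect ("?" = missing,
# @attribute numeric vs nominal), delegated to foreign::read.arff /
# foreign::write.arff.

#' Read a dataset from CSV or ARFF
#'
#' @param path file path
#' @param format `"csv"` or `"arff"`; default inferred from the extension
#' @param label_col label column name (default `"label"`); set `NULL` to read
#'   an unlabelled table
#' @return a `survey_dataset`
#' @export
read_table <- function(path, format = NULL, label_col = "label") {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  format <- format %||% (if (grepl("\\.arff$", path, ignore.case = TRUE))
    "arff" else "csv")
  df <- switch(format,
    csv = utils::read.csv(path, na.strings = c("", "NA"),
                          stringsAsFactors = FALSE, check.names = FALSE),
    arff = {
      out <- tryCatch(foreign::read.arff(path), error = function(e) {
        stop_invalid("ARFF parse error in %s: %s", path, conditionMessage(e))
      })
      out[] <- lapply(out, function(col) {
        if (is.factor(col)) as.character(col) else col
      })
      out
    },
    stop_invalid("unknown format '%s'", format)
  )
  labels <- NULL
  if (!is.null(label_col) && label_col %in% names(df)) {
    labels <- factor(df[[label_col]])
    df[[label_col]] <- NULL
  }
  survey_dataset(df, labels = labels)
}

#' Write a dataset to CSV or ARFF
#'
#' Round-trips with [read_table()]: values, kinds and missing cells are
#' preserved. Labels, when present, are written as the `label_col` column.
#'
#' @param ds a `survey_dataset`
#' @param path output path
#' @param format `"csv"` or `"arff"`; default inferred from the extension
#' @param label_col name for the label column
#' @export
write_table <- function(ds, path, format = NULL, label_col = "label") {
  format <- format %||% (if (grepl("\\.arff$", path, ignore.case = TRUE))
    "arff" else "csv")
  df <- ds$values
  if (!is.null(ds$labels)) df[[label_col]] <- as.character(ds$labels)
  if (format == "csv") {
    utils::write.csv(df, path, row.names = FALSE, na = "NA")
  } else if (format == "arff") {
    df[] <- lapply(df, function(col) {
      if (is.character(col)) factor(col) else col
    })
    foreign::write.arff(df, path)
  } else {
    stop_invalid("unknown format '%s'", format)
  }
  invisible(path)
}

#' Write a selected-feature mask file
#'
#' Plain text: line 1 is the bitstring, following lines list the selected
#' feature names in order.
#'
#' @param path output path
#' @param mask 0/1 vector
#' @param feature_names one name per mask bit
#' @export
write_mask <- function(path, mask, feature_names) {
  mask <- as.integer(mask)
  if (length(mask) != length(feature_names)) {
    stop_invalid("mask length != feature_names length")
  }
  writeLines(c(paste(mask, collapse = ""), feature_names[mask == 1L]), path)
  invisible(path)
}

#' Read a mask file written by [write_mask()]
#' @param path file path
#' @return list with `mask` (`feature_mask`) and `selected_names`
#' @export
read_mask <- function(path) {
  lines <- readLines(path)
  bits <- as.integer(strsplit(lines[[1L]], "")[[1L]])
  list(mask = feature_mask(bits),
       selected_names = if (length(lines) > 1L) lines[-1L] else character())
}
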