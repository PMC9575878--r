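#' Read and write feature-selection datasets as CSV
#'
#' `read_dataset()` loads a CSV with a header row in which every column except
#' the label is numeric and the label column is binary. `write_dataset()` is
#' its inverse; a write/read round trip reproduces the matrix, labels and
#' feature names.
#'
#' @param path Path to a CSV file.
#' @param label Name of the label column (default `"class"`). If absent from
#'   the header, the last column is used.
#' @return For `read_dataset()`, an [fs_data] object.
#' @export
read_dataset <- function(path, label = "class") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("file '", path, "' has no data rows or fewer than two columns")
  }
  if (!label %in% names(df)) label <- names(df)[ncol(df)]
  yraw <- df[[label]]
  feat <- df[setdiff(names(df), label)]
  for (nm in names(feat)) {
    if (!is.numeric(feat[[nm]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(feat[[nm]])))))[1]
      stop("non-numeric value in column '", nm, "', row ",
           ifelse(is.na(bad), 1L, bad))
    }
    if (anyNA(feat[[nm]])) {
      stop("missing value in column '", nm, "', row ", which(is.na(feat[[nm]]))[1])
    }
  }
  uy <- unique(yraw)
  if (length(uy) != 2L && !all(uy %in% c(0, 1))) {
    stop("label column '", label, "' is not binary (found ",
         length(uy), " distinct values)")
  }
  fs_data(as.matrix(feat), validate_labels(if (is.numeric(yraw)) yraw
                                           else factor(yraw)))
}

#' @rdname read_dataset
#' @param data An [fs_data] object to write.
#' @export
write_dataset <- function(data, path, label = "class") {
  stopifnot(inherits(data, "fs_data"))
  utils::write.csv(as.data.frame(data, label = label), path, row.names = FALSE)
  invisible(path)
}
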