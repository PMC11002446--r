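#' Column kinds of a dataset
#'
#' Datasets are plain data frames carrying a `kinds` attribute that labels
#' every column `continuous`, `binary` or `ordinal`. If the attribute is
#' missing, kinds are inferred: ordered factors are ordinal, 0/1 integer
#' columns binary, all other numeric columns continuous.
#'
#' @param data a data frame.
#' @return named character vector of kinds.
#' @export
dataset_kinds <- function(data) {
  k <- attr(data, "kinds")
  if (!is.null(k)) return(k[names(data)])
  vapply(data, function(col) {
    if (is.ordered(col)) "ordinal"
    else if (is.numeric(col) && all(col %in% c(0, 1))) "binary"
    else if (is.numeric(col)) "continuous"
    else stop("cannot infer kind for a non-numeric, non-ordered column")
  }, "")
}

#' Coerce a dataset to an all-numeric matrix
#'
#' Ordinal columns become their integer level codes; binary columns 0/1.
#' Quality grades are treated numerically throughout effect estimation, so
#' this coercion is the shared entry point for scoring and regression.
#'
#' @param data a data frame.
#' @return numeric matrix with the same column names.
#' @export
as_numeric_dataset <- function(data) {
  m <- vapply(data, function(col) {
    if (is.ordered(col) || is.factor(col)) as.numeric(as.integer(col)) else as.numeric(col)
  }, numeric(nrow(data)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(data), dimnames = list(NULL, names(data)))
  m
}

#' Write / read a dataset as CSV plus a sidecar JSON schema
#'
#' Ordinal levels are written as their labels; the sidecar
#' (`<file>.schema.json`) records each column's kind and, for ordinal
#' columns, the ordered levels, so `read_dataset()` restores types exactly.
#'
#' @param data a data frame with (or without) a `kinds` attribute.
#' @param file CSV path; the schema goes to `paste0(file, ".schema.json")`.
#' @export
write_dataset <- function(data, file) {
  kinds <- dataset_kinds(data)
  schema <- lapply(stats::setNames(names(data), names(data)), function(v) {
    s <- list(kind = unname(kinds[[v]]))
    if (kinds[[v]] == "ordinal") s$levels <- levels(data[[v]])
    s
  })
  utils::write.csv(data, file, row.names = FALSE)
  jsonlite::write_json(schema, paste0(file, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(file)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  schema_path <- paste0(file, ".schema.json")
  if (file.exists(schema_path)) {
    schema <- jsonlite::read_json(schema_path, simplifyVector = TRUE)
    for (v in names(schema)) {
      if (identical(schema[[v]]$kind, "ordinal")) {
        df[[v]] <- factor(df[[v]], levels = schema[[v]]$levels, ordered = TRUE)
      }
    }
    attr(df, "kinds") <- vapply(schema[names(df)], `[[`, "", "kind")
  }
  df
}
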