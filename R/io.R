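#' Read and write the pipeline's CSV interchange formats
#'
#' Thin wrappers around `utils::read.csv`/`write.csv` that enforce the column
#' schemas documented in `inst/extdata/file_schemas.csv` and write with fixed
#' column order and 6-decimal formatting so outputs are diff-stable.
#'
#' @param path File path.
#' @param x Object to write.
#' @name pipeline_io
NULL

.req_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L)
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  df
}

.write_csv6 <- function(x, path) {
  num <- vapply(x, is.numeric, logical(1))
  x[num] <- lapply(x[num], function(v) formatC(v, digits = 6, format = "f"))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
}

#' @rdname pipeline_io
#' @export
read_stations_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .req_cols(df, c("station_id", "lon", "lat", "pollutant", "week", "value"),
            "stations file")
}

#' @rdname pipeline_io
#' @export
read_residences_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- .req_cols(df, c("subject_id", "start_date", "end_date", "lon", "lat"),
                  "residences file")
  df$start_date <- as.Date(df$start_date)
  df$end_date <- as.Date(df$end_date)
  df
}

#' @rdname pipeline_io
#' @export
read_betas_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cpg <- df[[1]]
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- cpg
  m
}

#' @rdname pipeline_io
#' @export
write_betas_csv <- function(x, path) {
  df <- data.frame(cpg_id = colnames(x), t(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}
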