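#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for reported origin percentages so
#' that 55.15 prints as 55.2 rather than the IEEE banker's rounding of
#' [round()].
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## Polynomial rolling hash over the deparsed object; enough to fingerprint
## a config in the run manifest without a hashing dependency.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

## Write a CSV atomically: write to a temp file in the same directory, then
## rename over the destination so a failed stage never leaves a torn table.
write_csv_atomic <- function(df, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE, fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}

read_table_checked <- function(path, required_cols, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing input '%s': run stage '%s' first", path, producer),
         call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("table '%s' lacks column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}
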