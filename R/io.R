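# Tidy CSV writers/readers with JSON sidecars of generating parameters.
# Dialect: comma-separated, UTF-8, header row, '.' decimal.

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a simulated dataset with a parameter sidecar
#'
#' Writes the data.frame as tidy CSV (one row per trial / probe /
#' respondent-item) and, when generating parameters are supplied or attached
#' as attributes, a JSON sidecar next to it.
#'
#' @param data data.frame (or survey matrix) to write
#' @param path CSV path
#' @param params generating parameter list; defaults to the `"params"`
#'   attribute when present
#' @return `path`, invisibly
#' @export
write_dataset <- function(data, path, params = attr(data, "params")) {
  if (is.matrix(data)) {
    long <- data.frame(respondent = rep(seq_len(nrow(data)), ncol(data)),
                       item = rep(colnames(data), each = nrow(data)),
                       response = as.vector(data))
    write.csv(long, path, row.names = FALSE)
  } else {
    write.csv(data, path, row.names = FALSE)
  }
  if (!is.null(params)) {
    jsonlite::write_json(unclass(params), sidecar_path(path),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param path CSV path
#' @return the data.frame, with the JSON sidecar (if present) attached as
#'   attribute `"params"`
#' @export
read_dataset <- function(path) {
  out <- read.csv(path)
  sc <- sidecar_path(path)
  if (file.exists(sc)) attr(out, "params") <- jsonlite::read_json(sc)
  out
}
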