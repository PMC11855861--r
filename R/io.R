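# Plain-text I/O. TSV everywhere (UTF-8, '.' decimal, LF); '#' comment lines
# are ignored on input. CSV input is accepted for the long consumption format.

detect_sep <- function(path) {
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!startsWith(trimws(first), "#") & nzchar(first)][1L]
  if (grepl("\t", first)) "\t" else ","
}

#' Read a long-format consumption table
#'
#' Expected header: `subject_id, group, price, consumption` (TSV or CSV;
#' lines starting with `#` are ignored).
#'
#' @param path File path.
#' @return Data frame with the four columns, types coerced.
#' @export
read_consumption <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                         comment.char = "#", stringsAsFactors = FALSE)
  req <- c("subject_id", "group", "price", "consumption")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing columns in ", path, ": ",
                         paste(miss, collapse = ", "), call. = FALSE)
  d$price <- as.numeric(d$price)
  d$consumption <- as.numeric(d$consumption)
  d[req]
}

#' Write a data frame as TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Read a gene-by-sample expression matrix
#'
#' First column = gene id, header row = sample ids.
#'
#' @param path File path (TSV).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, header = TRUE, comment.char = "#",
                         check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- d[[1L]]
  mat
}

#' Read a sample metadata table
#'
#' @param path File path (TSV) with at least `sample_id`; typically also
#'   `subject_id`, `group`, `region`, `ev`.
#' @return Data frame.
#' @export
read_sample_meta <- function(path) {
  utils::read.delim(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read a simulation configuration file
#'
#' Flat YAML mapping of [simulation_config()] keys; unknown keys are an
#' error.
#'
#' @param path YAML file path.
#' @return A validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(simulation_config, vals)
}
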