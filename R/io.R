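# File formats: labelled CSV matrices (cells may be decimals or fractions
# "p/q"), respondent score CSVs, and JSON/YAML configs.

#' Read a labelled matrix from CSV
#'
#' First row and first column are labels; cells may be decimals or exact
#' fractions like `"1/3"`.
#'
#' @param path CSV file.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) ws_validation_error(paste("file not found:", path))
  raw <- utils::read.csv(path, header = TRUE, row.names = 1,
                         check.names = FALSE, colClasses = "character")
  x <- apply(as.matrix(raw), c(1, 2), parse_fraction)
  storage.mode(x) <- "double"
  x
}

#' Write a labelled matrix to CSV
#'
#' @param x matrix with dimnames.
#' @param path destination file.
#' @export
write_matrix_csv <- function(x, path) {
  utils::write.csv(as.data.frame(unclass(as.matrix(x))), path, row.names = TRUE)
  invisible(path)
}

#' Read a respondent score table from CSV
#'
#' Header row holds indicator labels; the first column holds respondent ids.
#'
#' @param path CSV file.
#' @return a [score_matrix()].
#' @export
read_scores_csv <- function(path) {
  if (!file.exists(path)) ws_validation_error(paste("file not found:", path))
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  ids <- as.character(raw[[1]])
  score_matrix(as.matrix(raw[, -1, drop = FALSE]), respondent_ids = ids)
}

#' Write a score matrix to CSV
#' @param scores a [score_matrix()].
#' @param path destination file.
#' @export
write_scores_csv <- function(scores, path) {
  df <- data.frame(respondent_id = rownames(scores),
                   unclass(as.matrix(scores)), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a JSON or YAML configuration file
#'
#' Format is chosen by extension (`.json` vs `.yaml`/`.yml`; YAML requires the
#' yaml package).
#'
#' @param path config file.
#' @return a list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ws_validation_error(paste("file not found:", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      ws_validation_error("YAML configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    ws_validation_error(sprintf("unsupported config extension '.%s' (use .json or .yaml)", ext))
  }
}

#' Load a hierarchy configuration
#'
#' Expects a list (or JSON/YAML file) with `criteria`, an ordered array of
#' `{name, children, local_weights | matrix_file}` entries, and optionally
#' `criteria_matrix`, a CSV path of criterion pairwise comparisons. Relative
#' paths resolve against the config file's directory.
#'
#' @param x path or list.
#' @return list with `hierarchy` (a [hierarchy_spec()]) and `criteria_matrix`
#'   (a [comparison_matrix()] or NULL).
#' @export
load_hierarchy_config <- function(x) {
  base <- "."
  if (is.character(x) && length(x) == 1L) {
    base <- dirname(x)
    x <- read_config(x)
  }
  if (is.null(x$criteria)) ws_validation_error("hierarchy config needs a 'criteria' array")
  entries <- x$criteria
  if (is.data.frame(entries)) entries <- split(entries, seq_len(nrow(entries)))
  children <- list()
  local <- list()
  for (e in entries) {
    e <- as.list(e)
    nm <- e$name[[1]]
    children[[nm]] <- unlist(e$children)
    if (!is.null(e$local_weights)) {
      local[[nm]] <- unlist(e$local_weights)
    } else if (!is.null(e$matrix_file)) {
      local[[nm]] <- comparison_matrix(read_matrix_csv(file.path(base, e$matrix_file[[1]])))
    } else {
      ws_validation_error(sprintf(
        "criterion '%s' needs local_weights or matrix_file", nm))
    }
  }
  cm <- NULL
  if (!is.null(x$criteria_matrix)) {
    p <- x$criteria_matrix
    if (!file.exists(p)) p <- file.path(base, p)
    cm <- comparison_matrix(read_matrix_csv(p))
  }
  list(hierarchy = hierarchy_spec(children, local), criteria_matrix = cm)
}
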