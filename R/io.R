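# All table formats are delimited UTF-8 text: comma by default, tab
# accepted; '.' decimal separator; health-state names quoted.

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

#' Read and write EQ-5D response tables
#'
#' Delimited text with header; required columns `respondent_id,
#' health_state_id, mo, sc, ua, pd, ad` (dimension columns are mapped to
#' D1..D5 by these explicit names, never by position). The separator
#' (comma or tab) is detected from the header line. Rows failing
#' validation are reported with their line number.
#'
#' @param path file path.
#' @param reference optional reference table for id validation.
#' @return [read_responses()]: a validated [as_responses()] table.
#' @export
read_responses <- function(path, reference = NULL) {
  if (!file.exists(path)) stop("responses file not found: ", path)
  df <- utils::read.csv(path, sep = detect_sep(path), stringsAsFactors = FALSE,
                        check.names = FALSE)
  if (nrow(df) == 0L) stop("no responses in ", path)
  tryCatch(as_responses(df, reference), error = function(e) {
    # row i of the data is physical line i + 1 (header)
    msg <- conditionMessage(e)
    m <- regmatches(msg, regexpr("at row [0-9]+", msg))
    if (length(m)) {
      row <- as.integer(sub("at row ", "", m))
      msg <- sub("at row [0-9]+", sprintf("at line %d of '%s'", row + 1L, path), msg)
    }
    stop(msg, call. = FALSE)
  })
}

#' @rdname read_responses
#' @param responses a response table.
#' @param sep `","` or `"\t"`.
#' @export
write_responses <- function(responses, path, sep = ",") {
  utils::write.table(as.data.frame(responses)[, c("respondent_id", "health_state_id",
                                                  eq5d_dimensions,
                                                  intersect("utility", names(responses)))],
                     path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read and write value-set files
#'
#' Value sets are YAML documents:
#' ```yaml
#' name: example
#' constant: 0.1
#' decrements:
#'   mo: {l2: 0.05, l3: 0.20}
#'   # ... sc, ua, pd, ad
#' indicators:
#'   any_level_3: 0.25
#' ```
#' Level-1 decrements are implicitly zero; `indicators` is optional.
#'
#' @param path file path.
#' @return [read_value_set()]: an [value_set()] object.
#' @export
read_value_set <- function(path) {
  if (!file.exists(path)) stop("value-set file not found: ", path)
  doc <- yaml::read_yaml(path)
  for (f in c("name", "constant", "decrements")) {
    if (is.null(doc[[f]])) stop("value-set file lacks field '", f, "'")
  }
  dec <- matrix(NA_real_, 5L, 2L)
  for (i in seq_along(eq5d_dimensions)) {
    d <- doc$decrements[[eq5d_dimensions[i]]]
    if (is.null(d) || is.null(d$l2) || is.null(d$l3)) {
      stop("value-set decrements need l2 and l3 for dimension '",
           eq5d_dimensions[i], "'")
    }
    dec[i, ] <- c(d$l2, d$l3)
  }
  ind <- if (!is.null(doc$indicators)) unlist(doc$indicators) else NULL
  value_set(doc$name, doc$constant, dec, ind)
}

#' @rdname read_value_set
#' @param vs a value set.
#' @export
write_value_set <- function(vs, path) {
  stopifnot(inherits(vs, "eq5d_value_set"))
  dec <- lapply(seq_len(5L), function(i) {
    list(l2 = unname(vs$decrements[i, 1L]), l3 = unname(vs$decrements[i, 2L]))
  })
  names(dec) <- eq5d_dimensions
  doc <- list(name = vs$name, constant = vs$constant, decrements = dec)
  if (length(vs$indicators)) doc$indicators <- as.list(vs$indicators)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' Read a probabilistic crosswalk matrix
#'
#' Delimited matrix whose first column (`profile5`) keys rows by 5L profile
#' string and whose remaining columns are named by 3L profile strings; rows
#' must be stochastic. Rows for 5L profiles never scored may be omitted.
#'
#' @param path file path.
#' @return An [crosswalk()] of kind `probability_matrix`.
#' @export
read_crosswalk <- function(path) {
  if (!file.exists(path)) stop("crosswalk file not found: ", path)
  df <- utils::read.csv(path, sep = detect_sep(path), check.names = FALSE,
                        colClasses = "character")
  if (names(df)[1L] != "profile5") stop("first crosswalk column must be 'profile5'")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$profile5
  crosswalk("probability_matrix", m)
}

#' Read a health-state summary table (per-state mean utilities)
#'
#' @param path delimited file with at least `health_state_id` and `mean`.
#' @return Data frame.
#' @export
read_state_summaries <- function(path) {
  if (!file.exists(path)) stop("summary file not found: ", path)
  df <- utils::read.csv(path, sep = detect_sep(path), stringsAsFactors = FALSE)
  if (!all(c("health_state_id", "mean") %in% names(df))) {
    stop("summary table needs columns health_state_id and mean")
  }
  df
}

write_table <- function(df, path, sep = ",") {
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}
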