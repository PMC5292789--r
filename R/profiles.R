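#' EQ-5D dimension names
#'
#' The five EQ-5D dimensions in their fixed positional order: mobility,
#' self-care, usual activities, pain/discomfort, anxiety/depression
#' (D1..D5). All functions in this package treat profile levels positionally
#' in this order; readers of named columns map them to D1..D5 explicitly.
#'
#' @format Character vector of length 5 (short column codes).
#' @export
eq5d_dimensions <- c("mo", "sc", "ua", "pd", "ad")

max_level <- function(version) if (version == "3L") 3L else 5L

#' Construct an EQ-5D profile
#'
#' An `eq5d_profile` is an ordered 5-tuple of integer severity levels, one
#' per dimension (D1 mobility, D2 self-care, D3 usual activities, D4
#' pain/discomfort, D5 anxiety/depression), under either the 3-level or the
#' 5-level instrument.
#'
#' @param levels integer vector of length 5; each level in 1..3 (`"3L"`) or
#'   1..5 (`"5L"`). Missing levels are rejected, not imputed.
#' @param version `"3L"` or `"5L"`.
#' @return An object of class `eq5d_profile`: the integer level vector with
#'   a `version` attribute.
#' @examples
#' eq5d_profile(c(1, 2, 3, 4, 5), "5L")
#' @export
eq5d_profile <- function(levels, version = c("5L", "3L")) {
  version <- match.arg(version)
  if (length(levels) != 5L) {
    stop("an EQ-5D profile needs exactly 5 levels, got ", length(levels))
  }
  if (anyNA(levels)) {
    stop("missing levels are not allowed in an EQ-5D profile")
  }
  lv <- as.integer(levels)
  if (any(lv != levels)) stop("levels must be whole numbers")
  hi <- max_level(version)
  bad <- which(lv < 1L | lv > hi)
  if (length(bad)) {
    stop(sprintf("level %d invalid for %s in dimension %s (allowed 1..%d)",
                 lv[bad[1L]], version, eq5d_dimensions[bad[1L]], hi))
  }
  structure(lv, version = version, class = "eq5d_profile")
}

#' Parse a 5-character digit string into an EQ-5D profile
#'
#' Digits map positionally to D1..D5, e.g. `"21345"` means mobility 2,
#' self-care 1, usual activities 3, pain/discomfort 4, anxiety/depression 5.
#'
#' @param text a single 5-character string of digits.
#' @inheritParams eq5d_profile
#' @return An [eq5d_profile()].
#' @examples
#' parse_profile("54321", "5L")
#' @seealso [format_profile()] for the inverse.
#' @export
parse_profile <- function(text, version = c("5L", "3L")) {
  version <- match.arg(version)
  if (length(text) != 1L || !is.character(text)) {
    stop("'text' must be a single character string")
  }
  if (nchar(text) != 5L) {
    stop("profile string must have exactly 5 characters, got '", text, "'")
  }
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% as.character(0:9))) {
    stop("profile string contains non-digit characters: '", text, "'")
  }
  eq5d_profile(as.integer(chars), version)
}

#' Format an EQ-5D profile as its 5-digit string
#'
#' @param profile an [eq5d_profile()].
#' @return A 5-character string, the inverse of [parse_profile()].
#' @export
format_profile <- function(profile) {
  stopifnot(inherits(profile, "eq5d_profile"))
  paste(unclass(profile), collapse = "")
}

#' @export
print.eq5d_profile <- function(x, ...) {
  cat(sprintf("<EQ-5D-%s profile %s>\n", attr(x, "version"), format_profile(x)))
  invisible(x)
}

profile_version <- function(profile) attr(profile, "version")

is_full_health <- function(profile) all(unclass(profile) == 1L)

#' Assemble respondent-level response records
#'
#' Validates a response table (one row per respondent x health state) against
#' a health-state reference table: every level must be a valid 5L level and
#' every `health_state_id` must exist in the reference.
#'
#' @param df data frame with columns `respondent_id`, `health_state_id` and
#'   the five dimension columns `mo, sc, ua, pd, ad`; any further columns
#'   are carried along as demographics.
#' @param reference a health-state reference table (see [gbd_reference()]),
#'   or `NULL` to skip the id check.
#' @return The validated data frame, dimension columns coerced to integer,
#'   with class `eq5d_responses` prepended.
#' @export
as_responses <- function(df, reference = NULL) {
  req <- c("respondent_id", "health_state_id", eq5d_dimensions)
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("response table lacks required column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("no responses: the table is empty")
  for (d in eq5d_dimensions) {
    v <- df[[d]]
    if (anyNA(v)) {
      stop("missing level in dimension '", d, "' at row ",
           which(is.na(v))[1L], "; complete answers are required")
    }
    vi <- as.integer(v)
    if (any(vi != v) || any(vi < 1L | vi > 5L)) {
      bad <- which(vi != v | vi < 1L | vi > 5L)[1L]
      stop(sprintf("invalid level '%s' in dimension '%s' at row %d (allowed 1..5)",
                   as.character(v[bad]), d, bad))
    }
    df[[d]] <- vi
  }
  df$health_state_id <- as.integer(df$health_state_id)
  if (!is.null(reference)) {
    unknown <- setdiff(df$health_state_id, reference$id)
    if (length(unknown)) {
      stop("health_state_id(s) absent from the reference table: ",
           paste(unknown, collapse = ", "))
    }
  }
  class(df) <- c("eq5d_responses", class(df))
  df
}

#' Extract one row of a response table as a 5L profile
#' @param responses an `eq5d_responses` table.
#' @param i row index.
#' @return An [eq5d_profile()] (5L).
#' @export
response_profile <- function(responses, i) {
  eq5d_profile(unlist(responses[i, eq5d_dimensions], use.names = FALSE), "5L")
}
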