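# Indicator terms a value-set file may reference. Each predicate takes the
# integer level vector of a 3L profile and says whether the decrement applies.
indicator_registry <- list(
  any_level_2 = function(lv) any(lv == 2L),
  any_level_3 = function(lv) any(lv == 3L),
  all_level_3 = function(lv) all(lv == 3L)
)

#' Construct an additive EQ-5D-3L value set (tariff)
#'
#' A value set turns a 3L profile into a utility by the additive tariff
#' \deqn{U = 1 - c\,[\mathrm{profile} \neq 11111] - \sum_d \delta_{d,\ell_d}
#'   - \sum_j \gamma_j\,[\mathrm{predicate}_j]}{
#'   U = 1 - c*[profile != 11111] - sum(level decrements) - sum(triggered
#'   indicator decrements)}
#' where `c` is a constant decrement applied to any profile other than full
#' health, the level decrements are indexed by (dimension, level 2..3), and
#' indicator terms are named predicates over the whole profile (e.g. "any
#' dimension at level 3"). Full health (11111) always scores exactly 1;
#' utilities of severe profiles may be negative ("worse than death") and are
#' never clipped.
#'
#' Country tariffs (such as the Belgian 3L set) are shipped as data files and
#' loaded with [read_value_set()]; nothing is hard-coded.
#'
#' @param name label for the value set.
#' @param constant the constant decrement `c` (applied iff profile != 11111).
#' @param decrements a 5 x 2 numeric matrix of level decrements, rows in
#'   dimension order D1..D5, columns for levels 2 and 3 (level 1 decrements
#'   are identically zero).
#' @param indicators named numeric vector of indicator decrements; names
#'   must be registered predicates: `r paste(names(indicator_registry),
#'   collapse = ", ")`.
#' @return An object of class `eq5d_value_set`.
#' @examples
#' toy <- value_set("toy", constant = 0.1,
#'                  decrements = matrix(c(rep(0.05, 5), rep(0.2, 5)), ncol = 2))
#' apply_value_set(parse_profile("21111", "3L"), toy)
#' @export
value_set <- function(name, constant, decrements, indicators = NULL) {
  decrements <- as.matrix(decrements)
  if (!all(dim(decrements) == c(5L, 2L))) {
    stop("'decrements' must be a 5 x 2 matrix (dimensions x levels 2:3)")
  }
  if (!all(is.finite(decrements)) || !is.finite(constant)) {
    stop("all tariff decrements must be finite")
  }
  dimnames(decrements) <- list(eq5d_dimensions, c("l2", "l3"))
  if (!is.null(indicators) && length(indicators)) {
    unknown <- setdiff(names(indicators), names(indicator_registry))
    if (length(unknown)) {
      stop("unknown indicator term(s): ", paste(unknown, collapse = ", "),
           " (known: ", paste(names(indicator_registry), collapse = ", "), ")")
    }
    if (!all(is.finite(indicators))) stop("indicator decrements must be finite")
  }
  structure(list(name = name, constant = constant,
                 decrements = decrements,
                 indicators = indicators %||% numeric(0)),
            class = "eq5d_value_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eq5d_value_set <- function(x, ...) {
  cat(sprintf("<EQ-5D-3L value set '%s'>\n", x$name))
  cat(sprintf("  constant decrement: %g\n", x$constant))
  print(x$decrements)
  if (length(x$indicators)) {
    cat("  indicator terms:\n")
    for (nm in names(x$indicators)) cat(sprintf("    %s: %g\n", nm, x$indicators[[nm]]))
  }
  invisible(x)
}

#' Score a 3L profile with a value set
#'
#' @param profile an [eq5d_profile()] with version `"3L"`. A 5L profile is an
#'   error: crosswalk it first (see [utility_5l()]).
#' @param vs an [value_set()].
#' @return The utility, a single number `<= 1`; may be negative.
#' @export
apply_value_set <- function(profile, vs) {
  stopifnot(inherits(profile, "eq5d_profile"), inherits(vs, "eq5d_value_set"))
  if (profile_version(profile) != "3L") {
    stop("apply_value_set() scores 3L profiles; crosswalk 5L responses first")
  }
  lv <- unclass(profile)
  if (all(lv == 1L)) return(1)
  u <- 1 - vs$constant
  for (d in 1:5) if (lv[d] > 1L) u <- u - vs$decrements[d, lv[d] - 1L]
  for (nm in names(vs$indicators)) {
    if (indicator_registry[[nm]](lv)) u <- u - vs$indicators[[nm]]
  }
  u
}

#' Enumerate all profile strings of a version
#'
#' All 243 3L (or 3125 5L) profiles as 5-digit strings in lexicographic
#' order; the column/row space of crosswalk matrices.
#' @inheritParams eq5d_profile
#' @return Character vector of profile strings.
#' @export
all_profiles <- function(version = c("3L", "5L")) {
  version <- match.arg(version)
  hi <- max_level(version)
  g <- expand.grid(d5 = 1:hi, d4 = 1:hi, d3 = 1:hi, d2 = 1:hi, d1 = 1:hi)
  apply(g[, 5:1], 1L, paste, collapse = "")
}

#' Construct a 5L-to-3L crosswalk
#'
#' Two kinds are supported. `deterministic_collapse` is the fixed level map
#' 1 -> 1, \{2,3\} -> 2, \{4,5\} -> 3 applied dimension-wise; it is an
#' explicitly labelled stand-in for a published crosswalk and warns on first
#' use. `probability_matrix` carries a row-stochastic matrix giving, for each
#' 5L profile, a weight distribution over 3L profiles; utilities are then
#' weight-averaged expected utilities.
#'
#' @param kind `"deterministic_collapse"` or `"probability_matrix"`.
#' @param matrix for `probability_matrix`: a numeric matrix with rownames =
#'   5L profile strings and colnames = 3L profile strings; every row must
#'   sum to 1 within 1e-9. Rows for unused 5L profiles may be omitted.
#' @return An object of class `eq5d_crosswalk`.
#' @export
crosswalk <- function(kind = c("deterministic_collapse", "probability_matrix"),
                      matrix = NULL) {
  kind <- match.arg(kind)
  if (kind == "probability_matrix") {
    if (is.null(matrix)) stop("probability_matrix crosswalk needs a matrix")
    matrix <- as.matrix(matrix)
    if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
      stop("crosswalk matrix needs 5L profile rownames and 3L profile colnames")
    }
    rs <- rowSums(matrix)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("crosswalk matrix rows must sum to 1 (worst deviation ",
           format(max(abs(rs - 1))), ")")
    }
    if (any(matrix < 0)) stop("crosswalk weights must be non-negative")
  }
  structure(list(kind = kind, matrix = matrix), class = "eq5d_crosswalk")
}

collapse_levels <- function(lv) c(1L, 2L, 2L, 3L, 3L)[lv]

.collapse_warned <- new.env(parent = emptyenv())

#' Map a 5L profile into 3L valuation space
#'
#' @param profile an [eq5d_profile()] with version `"5L"`.
#' @param cw an [crosswalk()]; defaults to the deterministic level collapse.
#' @return For `deterministic_collapse`, a single 3L [eq5d_profile()]. For
#'   `probability_matrix`, the named weight vector over 3L profile strings
#'   (the matrix row), for downstream expected-utility computation.
#' @export
crosswalk_5to3 <- function(profile, cw = crosswalk("deterministic_collapse")) {
  stopifnot(inherits(profile, "eq5d_profile"), inherits(cw, "eq5d_crosswalk"))
  if (profile_version(profile) != "5L") stop("crosswalk_5to3() expects a 5L profile")
  if (cw$kind == "deterministic_collapse") {
    if (is.null(.collapse_warned$done)) {
      warning("deterministic_collapse is a fixed-level-map stand-in, not a ",
              "published EuroQol crosswalk; supply a probability_matrix ",
              "crosswalk for production scoring", call. = FALSE)
      .collapse_warned$done <- TRUE
    }
    eq5d_profile(collapse_levels(unclass(profile)), "3L")
  } else {
    key <- format_profile(profile)
    if (!key %in% rownames(cw$matrix)) {
      stop("crosswalk matrix has no row for 5L profile ", key)
    }
    cw$matrix[key, ]
  }
}

#' Utility of a 5L profile: crosswalk then tariff
#'
#' The two-step scoring recommended for 5L data valued with a 3L tariff:
#' translate the 5L profile into 3L space, then apply the additive value
#' set. With a probabilistic crosswalk the result is the expected utility,
#' i.e. the dot product of the weight row with the 3L utility vector.
#'
#' @inheritParams crosswalk_5to3
#' @param vs an [value_set()].
#' @return The utility (single number).
#' @export
utility_5l <- function(profile, cw = crosswalk("deterministic_collapse"), vs) {
  if (cw$kind == "deterministic_collapse") {
    apply_value_set(crosswalk_5to3(profile, cw), vs)
  } else {
    w <- crosswalk_5to3(profile, cw)
    w <- w[w != 0]
    sum(w * vapply(names(w),
                   function(s) apply_value_set(parse_profile(s, "3L"), vs),
                   numeric(1)))
  }
}

#' Score a response table into utilities
#'
#' @param responses an [as_responses()] table of 5L responses.
#' @param cw crosswalk, see [crosswalk()].
#' @param vs value set, see [value_set()].
#' @return The input data frame with a `utility` column appended.
#' @export
score_responses <- function(responses, cw = crosswalk("deterministic_collapse"), vs) {
  stopifnot(inherits(responses, "eq5d_responses"))
  responses$utility <- vapply(seq_len(nrow(responses)), function(i) {
    utility_5l(response_profile(responses, i), cw, vs)
  }, numeric(1))
  responses
}
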