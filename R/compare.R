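#' Summary statistics for a set of utilities
#'
#' Textbook descriptives: mean, sample standard deviation (n - 1), median,
#' range, plus the fraction of negative ("worse than death") utilities and
#' the fraction exactly equal to 1 (full health).
#'
#' @param values non-empty numeric vector of utilities.
#' @return A one-row data frame with columns `n, mean, sd, median, min,
#'   max, fraction_negative, fraction_equal_one`.
#' @export
summarize_utilities <- function(values) {
  if (length(values) == 0L) stop("empty utility vector")
  if (anyNA(values)) stop("utilities contain NA")
  data.frame(n = length(values),
             mean = mean(values),
             sd = if (length(values) > 1L) stats::sd(values) else NA_real_,
             median = stats::median(values),
             min = min(values), max = max(values),
             fraction_negative = mean(values < 0),
             fraction_equal_one = mean(values == 1))
}

#' Per-state utility summaries of a scored response table
#'
#' @param scored a response table with a `utility` column (see
#'   [score_responses()]).
#' @return Data frame, one row per `health_state_id`, columns as in
#'   [summarize_utilities()].
#' @export
utilities_by_state <- function(scored) {
  if (!"utility" %in% names(scored)) stop("table has no 'utility' column")
  ids <- sort(unique(scored$health_state_id))
  out <- do.call(rbind, lapply(ids, function(i) {
    summarize_utilities(scored$utility[scored$health_state_id == i])
  }))
  cbind(health_state_id = ids, out)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average (mid) ranks; ties get the average of the
#' tied ranks.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' lengths differ")
  if (length(x) < 2L) stop("need at least 2 observations")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("zero rank variance: all values tied")
  }
  stats::cor(x, y, method = "spearman")
}

# All permutations of 1..n as a matrix (n! rows); n is capped upstream.
permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' P-value for a Spearman correlation
#'
#' Two methods. `exact_permutation` enumerates all `n!` pairings of the two
#' rank vectors (hence requires `n <= 8`) and reports the two-sided tail
#' fraction of permutations whose `|rho|` is at least the observed one —
#' valid with or without ties. `t_approx` is the usual large-sample
#' transform `t = rho * sqrt((n-2)/(1-rho^2))` referred to a t distribution
#' on `n - 2` degrees of freedom.
#'
#' @inheritParams spearman_rho
#' @param method `"exact_permutation"` or `"t_approx"`.
#' @return Two-sided p-value.
#' @examples
#' # 4 states in perfect anticorrelation: p = 2/24
#' spearman_p(1:4, 4:1, "exact_permutation")
#' @export
spearman_p <- function(x, y, method = c("exact_permutation", "t_approx")) {
  method <- match.arg(method)
  rho <- spearman_rho(x, y)
  n <- length(x)
  if (method == "exact_permutation") {
    if (n > 8L) stop("exact permutation enumeration supported for n <= 8 only")
    rx <- rank(x)
    ry <- rank(y)
    perm <- permutations(n)
    rhos <- apply(perm, 1L, function(p) stats::cor(rx, ry[p]))
    mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) return(0)
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
}

#' Paired t-test wrapper tolerating degenerate differences
#'
#' Classic paired t on `a - b` with `n - 1` degrees of freedom. When the
#' differences have zero variance the test statistic is undefined; the
#' result is then flagged `degenerate` and carries no p-value rather than
#' erroring, so batch pipelines can proceed.
#'
#' @param a,b numeric vectors of equal length `>= 2`.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) stop("'a' and 'b' lengths differ")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                mean_diff = mean(d), degenerate = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = unname(tt$estimate), degenerate = FALSE)
}

match_states <- function(state_means, ref) {
  if (is.null(state_means$health_state_id)) stop("'state_means' needs a health_state_id column")
  idx <- match(state_means$health_state_id, ref$id)
  if (anyNA(idx)) {
    stop("state(s) missing from the reference table: ",
         paste(state_means$health_state_id[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Differences between utility complements and disability weights
#'
#' For each state, `d = (1 - mean utility) - DW`: how much more severe (or
#' milder, if negative) the valuation-study respondents judged the state
#' than the GBD study did, under the naive complement translation of
#' utilities into DWs.
#'
#' @param state_means data frame with columns `health_state_id` and `mean`
#'   (per-state mean utility), e.g. from [utilities_by_state()].
#' @param ref health-state reference table (see [gbd_reference()]).
#' @param dw_column `"dw2010"` or `"dw2013"`.
#' @return List: `table` (per-state id, name, mean utility, DW, diff),
#'   `mean`, `sd`, `min`, `max`, and the state names attaining the
#'   extremes (`min_state`, `max_state`).
#' @export
complement_difference_table <- function(state_means, ref,
                                        dw_column = c("dw2010", "dw2013")) {
  dw_column <- match.arg(dw_column)
  idx <- match_states(state_means, ref)
  dw <- ref[[dw_column]][idx]
  diff <- (1 - state_means$mean) - dw
  tab <- data.frame(health_state_id = state_means$health_state_id,
                    name = ref$name[idx],
                    u_mean = state_means$mean, dw = dw, diff = diff)
  list(table = tab,
       mean = mean(diff), sd = stats::sd(diff),
       min = min(diff), max = max(diff),
       min_state = tab$name[which.min(diff)],
       max_state = tab$name[which.max(diff)])
}

#' Severity rank table
#'
#' Ranks every state by each DW column (ascending: rank 1 = lowest DW =
#' least severe) and by mean utility (descending: rank 1 = highest utility =
#' least severe). Ties receive average ranks. Each ranking also flags the
#' state's position relative to that ranking's own median value.
#'
#' @inheritParams complement_difference_table
#' @return Data frame with the id, name, the three rank columns
#'   (`rank_utility`, `rank_dw2010`, `rank_dw2013`) and matching
#'   `"below_median"` / `"at_median"` / `"above_median"` severity flags
#'   (below = less severe than the study-specific median).
#' @export
rank_table <- function(state_means, ref) {
  if (nrow(state_means) < 2L) stop("ranking needs at least 2 states")
  idx <- match_states(state_means, ref)
  u <- state_means$mean
  d10 <- ref$dw2010[idx]
  d13 <- ref$dw2013[idx]
  flag <- function(severity) {
    m <- stats::median(severity)
    ifelse(severity < m, "below_median",
           ifelse(severity > m, "above_median", "at_median"))
  }
  data.frame(health_state_id = state_means$health_state_id,
             name = ref$name[idx],
             rank_utility = rank(-u), # high utility = least severe
             rank_dw2010 = rank(d10),
             rank_dw2013 = rank(d13),
             flag_utility = flag(-u),
             flag_dw2010 = flag(d10),
             flag_dw2013 = flag(d13))
}

#' Dimension-by-level frequency table
#'
#' For every health state and EQ-5D dimension, the percentage of responses
#' at each level 1..5 plus the mean and sample SD of the integer levels —
#' the standard descriptive table of ordinal EQ-5D data.
#'
#' @param responses an [as_responses()] table.
#' @return Data frame, one row per (state, dimension): `health_state_id`,
#'   `dimension`, `pct_l1` .. `pct_l5` (percentages summing to 100 per
#'   row), `mean`, `sd`, `n`.
#' @export
dimension_level_frequencies <- function(responses) {
  stopifnot(inherits(responses, "eq5d_responses"))
  ids <- sort(unique(responses$health_state_id))
  rows <- list()
  for (i in ids) {
    grp <- responses[responses$health_state_id == i, , drop = FALSE]
    if (nrow(grp) == 0L) stop("empty response group for state ", i)
    for (d in eq5d_dimensions) {
      lv <- grp[[d]]
      pct <- 100 * tabulate(lv, nbins = 5L) / length(lv)
      rows[[length(rows) + 1L]] <- data.frame(
        health_state_id = i, dimension = d,
        pct_l1 = pct[1], pct_l2 = pct[2], pct_l3 = pct[3],
        pct_l4 = pct[4], pct_l5 = pct[5],
        mean = mean(lv),
        sd = if (length(lv) > 1L) stats::sd(lv) else 0,
        n = length(lv))
    }
  }
  do.call(rbind, rows)
}

#' Full utility-versus-DW comparison report
#'
#' Bundles the inferential comparisons for one DW column: Spearman rank
#' correlation between per-state mean utilities and DWs (with p-value),
#' paired t-test of the utility complements `1 - u` against the DWs, the
#' complement-difference table and the severity rank table.
#'
#' @inheritParams complement_difference_table
#' @param p_method p-value method for the correlation: `"auto"` (exact
#'   permutation enumeration when `n <= 8`, t approximation otherwise) or
#'   any [spearman_p()] method.
#' @return Object of class `dw_comparison`.
#' @export
compare_report <- function(state_means, ref, dw_column = c("dw2010", "dw2013"),
                           p_method = c("auto", "exact_permutation", "t_approx")) {
  dw_column <- match.arg(dw_column)
  p_method <- match.arg(p_method)
  if (nrow(state_means) < 2L) stop("comparison needs at least 2 states")
  idx <- match_states(state_means, ref)
  u <- state_means$mean
  dw <- ref[[dw_column]][idx]
  if (p_method == "auto") {
    p_method <- if (length(u) <= 8L) "exact_permutation" else "t_approx"
  }
  tt <- paired_t(1 - u, dw)
  structure(list(dw_column = dw_column, n = length(u),
                 rho = spearman_rho(u, dw),
                 rho_p = spearman_p(u, dw, p_method),
                 rho_p_method = p_method,
                 t_test = tt,
                 diffs = complement_difference_table(state_means, ref, dw_column),
                 ranks = rank_table(state_means, ref)),
            class = "dw_comparison")
}

#' @export
print.dw_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("<utility vs %s comparison, %d states>\n",
              toupper(x$dw_column), x$n))
  cat(sprintf("  Spearman rho = %.*f (p = %.3g, %s)\n", digits, x$rho,
              x$rho_p, x$rho_p_method))
  if (x$t_test$degenerate) {
    cat("  paired t of (1 - u) vs DW: degenerate (zero-variance differences)\n")
  } else {
    cat(sprintf("  paired t of (1 - u) vs DW: t = %.*f, df = %d, p = %.3g\n",
                digits, x$t_test$t, as.integer(x$t_test$df), x$t_test$p))
  }
  cat(sprintf("  complement differences: mean %.*f (sd %.*f), range [%.*f '%s', %.*f '%s']\n",
              digits, x$diffs$mean, digits, x$diffs$sd,
              digits, x$diffs$min, x$diffs$min_state,
              digits, x$diffs$max, x$diffs$max_state))
  invisible(x)
}
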