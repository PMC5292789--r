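#' Packaged GBD 2010/2013 health-state reference table
#'
#' The 27 GBD health states used in the valuation pilot studies, with their
#' GBD 2010 and GBD 2013 disability weights and the per-study mean (SD)
#' utilities: four states carry study-1 values, all 27 carry study-2
#' values. The table ships as a plain CSV under `inst/extdata/`.
#'
#' @param path optional path to an alternative reference CSV with at least
#'   the columns `id, name, dw2010, dw2013`.
#' @return Data frame with columns `id, name, u1_mean, u1_sd, u2_mean,
#'   u2_sd, dw2010, dw2013`.
#' @examples
#' ref <- gbd_reference()
#' ref[ref$id == 220, c("name", "dw2010", "dw2013")]
#' @export
gbd_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "gbd_dw_reference.csv", package = "eq5dmap",
                        mustWork = TRUE)
  }
  if (!file.exists(path)) stop("reference table not found: ", path)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("id", "name", "dw2010", "dw2013")
  miss <- setdiff(req, names(ref))
  if (length(miss)) stop("reference table lacks column(s): ", paste(miss, collapse = ", "))
  for (col in c("dw2010", "dw2013")) {
    if (any(ref[[col]] < 0 | ref[[col]] > 1, na.rm = TRUE)) {
      stop("disability weights in '", col, "' must lie in [0, 1]")
    }
  }
  ref
}

#' Configuration for the synthetic response generator
#'
#' The generator emulates a valuation survey: respondents rate health states
#' whose latent severity is the (clamped) logit of a true disability weight,
#' and report an ordinal level per EQ-5D dimension. Defaults reproduce the
#' second pilot survey's conditions: the 27 packaged reference states (true
#' DW = GBD 2010 column) and 58 respondents per state (393 respondents
#' rating 4 states each spread over 27 states).
#'
#' @param states data frame with columns `id` and `true_dw` (in (0, 1)), or
#'   `NULL` for the packaged reference states with `true_dw = dw2010`.
#' @param n_respondents_per_state ratings per state, `>= 1`.
#' @param dimension_loadings 5 positive reals: how strongly each dimension's
#'   latent response tracks severity.
#' @param cutpoints 4 strictly increasing thresholds on the latent
#'   (logit-DW) scale separating levels 1..5. The defaults are calibrated so
#'   that simulated per-state mean utilities and their spread track the
#'   observed study-2 utility distribution of the packaged reference table.
#' @param noise_sd SD of the Gaussian noise added per respondent x state x
#'   dimension on the latent scale (default calibrated jointly with the
#'   cutpoints).
#' @param seed root seed; per-state streams are derived from it
#'   deterministically, so adding states never reshuffles existing ones.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(states = NULL, n_respondents_per_state = 58L,
                       dimension_loadings = rep(1, 5),
                       cutpoints = c(-3, -0.5, 2, 4.5),
                       noise_sd = 3, seed = 1L) {
  if (is.null(states)) {
    ref <- gbd_reference()
    states <- data.frame(id = ref$id, true_dw = ref$dw2010)
  }
  if (!all(c("id", "true_dw") %in% names(states))) {
    stop("'states' needs columns id and true_dw")
  }
  if (nrow(states) == 0L) stop("'states' is empty")
  if (any(states$true_dw <= 0 | states$true_dw >= 1)) {
    stop("true_dw values must lie strictly in (0, 1)")
  }
  if (anyDuplicated(states$id)) stop("duplicate state ids")
  if (n_respondents_per_state < 1L) stop("n_respondents_per_state must be >= 1")
  if (length(dimension_loadings) != 5L || any(dimension_loadings <= 0)) {
    stop("'dimension_loadings' must be 5 positive numbers")
  }
  if (length(cutpoints) != 4L || any(diff(cutpoints) <= 0)) {
    stop("'cutpoints' must be 4 strictly increasing numbers")
  }
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  structure(list(states = states,
                 n_respondents_per_state = as.integer(n_respondents_per_state),
                 dimension_loadings = dimension_loadings,
                 cutpoints = cutpoints, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

state_seed <- function(root, id) {
  as.integer((as.numeric(root) * 7919 + as.numeric(id) * 104729) %% 2147483647)
}

#' Simulate respondent-level EQ-5D-5L responses
#'
#' Latent-variable ordinal model: for each respondent x state x dimension,
#' `latent = loading_d * logit_clamped(true_dw, 1e-3) + N(0, noise_sd)`, and
#' the observed level is `1 +` the number of cutpoints below the latent
#' value (so levels lie in 1..5). Expected severity — and hence expected
#' derived utility — is therefore monotone in the state's true DW.
#'
#' @param cfg a [sim_config()].
#' @return An [as_responses()] table (columns `respondent_id,
#'   health_state_id, mo, sc, ua, pd, ad`), reproducible given the seed.
#' @export
simulate_responses <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_respondents_per_state
  sev <- logit_clamped(cfg$states$true_dw, 1e-3)
  per_state <- lapply(seq_len(nrow(cfg$states)), function(s) {
    id <- cfg$states$id[s]
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(state_seed(cfg$seed, id))
    latent <- outer(rep(sev[s], n), cfg$dimension_loadings) +
      matrix(stats::rnorm(n * 5L, 0, cfg$noise_sd), n, 5L)
    lev <- matrix(1L + findInterval(latent, cfg$cutpoints), n, 5L)
    df <- as.data.frame(lev)
    names(df) <- eq5d_dimensions
    cbind(respondent_id = sprintf("sim_%d_%03d", id, seq_len(n)),
          health_state_id = id, df)
  })
  as_responses(do.call(rbind, per_state))
}
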