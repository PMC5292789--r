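#' Clamped logit transform
#'
#' `logit_clamped(p, eps)` returns `log(q/(1-q))` with
#' `q = min(max(p, eps), 1 - eps)`. Disability weights of exactly 0 or 1
#' (notably the anchor pseudo-observations) would have an infinite logit;
#' clamping by `epsilon` keeps every transformed response finite.
#'
#' @param p numeric vector in `[0, 1]`.
#' @param epsilon clamp bound, a single number in `(0, 0.5)`.
#' @return `log(q/(1-q))`, same length as `p`.
#' @examples
#' logit_clamped(0.5, 1e-3)      # 0
#' logit_clamped(1, 1e-3)        # log(0.999/0.001)
#' @export
logit_clamped <- function(p, epsilon = 1e-3) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L ||
      epsilon <= 0 || epsilon >= 0.5) {
    stop("'epsilon' must be a single number in (0, 0.5)")
  }
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("'p' must lie in [0, 1]")
  }
  q <- pmin(pmax(p, epsilon), 1 - epsilon)
  log(q / (1 - q))
}

#' Inverse logit
#'
#' @param x finite numeric vector.
#' @return `1/(1 + exp(-x))`, strictly inside `(0, 1)` for finite `x`.
#' @export
inv_logit <- function(x) stats::plogis(x)

#' Map utilities to disability weights by anchored local regression
#'
#' Fits the mapping between EQ-5D utilities and Global Burden of Disease
#' disability weights (DWs): the DWs are logit-transformed (after clamping by
#' `epsilon`) and a locally weighted polynomial regression (loess-type) of
#' logit(DW) on utility is set up. Predictions are back-transformed with the
#' inverse logit, so predicted DWs always lie strictly in (0, 1).
#'
#' With `anchors = TRUE` (default) two pseudo-observations pin the scale
#' ends: utility 0 corresponds to DW 1 and utility 1 to DW 0. They enter the
#' training set as ordinary points (one each), their DWs clamped by
#' `epsilon` before the logit like any other response.
#'
#' Fitting is lazy: the model object stores the training pairs and
#' hyperparameters, and each call to [predict.dw_map()] solves a weighted
#' polynomial least-squares problem in the neighbourhood of every query
#' point. At a query `x0`, the `ceiling(span * n)` nearest training
#' utilities form the neighbourhood (distance ties at the boundary are all
#' included), tricube weights `(1 - (d/d_max)^3)^3` are applied, and a
#' degree-`degree` polynomial is fit by weighted least squares and evaluated
#' at `x0`.
#'
#' @param utility numeric vector of utilities (the predictor). Values
#'   outside `[0, 1]` — e.g. "worse than death" utilities — are accepted
#'   unchanged; only DWs are logit-transformed.
#' @param dw numeric vector of disability weights in `[0, 1]`, same length.
#' @param span fraction of points in each local neighbourhood, in `(0, 1]`.
#' @param degree local polynomial degree: 0, 1 or 2.
#' @param epsilon clamp bound for the logit, see [logit_clamped()].
#' @param anchors add the (utility 0, DW 1) and (utility 1, DW 0) anchor
#'   pseudo-observations?
#' @param weights `"tricube"` (default) or `"uniform"` neighbourhood
#'   weights. With `weights = "uniform"`, `span = 1` and `degree = 0` the
#'   fit reduces to the global mean of the transformed responses.
#' @return An object of class `dw_map` with components `u`, `dw`, `y`
#'   (clamped logit of `dw`), `anchor` (logical, per training point), and
#'   the hyperparameters.
#' @examples
#' ref <- gbd_reference()
#' m <- dw_map(ref$u2_mean, ref$dw2010)
#' predict(m, c(0.9, 0.5, 0.2))
#' @seealso [predict.dw_map()], [logit_linear_fit()], [write_dw_map()]
#' @export
dw_map <- function(utility, dw, span = 0.75, degree = 2L, epsilon = 1e-3,
                   anchors = TRUE, weights = c("tricube", "uniform")) {
  weights <- match.arg(weights)
  if (length(utility) != length(dw)) stop("'utility' and 'dw' lengths differ")
  if (anyNA(utility) || any(!is.finite(utility))) stop("utilities must be finite")
  if (anyNA(dw) || any(dw < 0 | dw > 1)) stop("DWs must lie in [0, 1]")
  if (!degree %in% 0:2) stop("'degree' must be 0, 1 or 2")
  if (span <= 0 || span > 1) stop("'span' must be in (0, 1]")
  u <- as.numeric(utility)
  d <- as.numeric(dw)
  anchor <- rep(FALSE, length(u))
  if (anchors) {
    u <- c(u, 0, 1)
    d <- c(d, 1, 0)
    anchor <- c(anchor, TRUE, TRUE)
  }
  n <- length(u)
  if (n < degree + 2L) {
    stop("insufficient points: need at least degree + 2 = ", degree + 2L,
         " training pairs, got ", n)
  }
  q <- ceiling(span * n)
  if (q < degree + 1L) {
    stop("span ", span, " gives local neighbourhoods of ", q,
         " point(s); a degree-", degree, " fit needs at least ", degree + 1L)
  }
  structure(list(u = u, dw = d, y = logit_clamped(d, epsilon),
                 anchor = anchor, span = span, degree = as.integer(degree),
                 epsilon = epsilon, anchors = anchors, weights = weights),
            class = "dw_map")
}

# Weighted polynomial fit in the neighbourhood of one query point.
local_fit <- function(model, x0) {
  if (is.na(x0)) stop("query utility is NA")
  u <- model$u
  n <- length(u)
  q <- ceiling(model$span * n)
  dist <- abs(u - x0)
  dmax <- sort(dist)[q]
  keep <- which(dist <= dmax)
  w <- if (model$weights == "uniform" || dmax == 0) {
    rep(1, length(keep))
  } else {
    (1 - (dist[keep] / dmax)^3)^3
  }
  pos <- w > 0
  if (sum(pos) < model$degree + 1L) {
    stop("local neighbourhood at u = ", x0, " has ", sum(pos),
         " point(s) with positive weight; degree-", model$degree,
         " fit needs ", model$degree + 1L)
  }
  x <- u[keep] - x0
  X <- outer(x, 0:model$degree, `^`)
  fit <- stats::lm.wfit(X, model$y[keep], w)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  beta[1L]  # polynomial evaluated at x = 0
}

#' Predict disability weights from a fitted mapping
#'
#' @param object a [dw_map()] model.
#' @param newdata numeric vector of query utilities. Defaults to the
#'   training utilities.
#' @param scale `"dw"` (inverse-logit back-transform, default) or
#'   `"logit"` (the raw local-regression response).
#' @param ... unused.
#' @return Numeric vector of predictions; on the `"dw"` scale strictly
#'   inside (0, 1). Queries outside the training utility range are permitted
#'   but flagged: the result carries a logical attribute `extrapolated` and
#'   a warning is issued.
#' @export
predict.dw_map <- function(object, newdata = NULL, scale = c("dw", "logit"), ...) {
  scale <- match.arg(scale)
  x <- if (is.null(newdata)) object$u else as.numeric(newdata)
  if (anyNA(x)) stop("query utilities contain NA")
  yhat <- vapply(x, function(x0) local_fit(object, x0), numeric(1))
  out <- if (scale == "dw") inv_logit(yhat) else yhat
  extra <- x < min(object$u) | x > max(object$u)
  if (any(extra)) {
    warning(sum(extra), " query point(s) outside the training utility range [",
            format(min(object$u)), ", ", format(max(object$u)),
            "]; predictions are extrapolations", call. = FALSE)
  }
  attr(out, "extrapolated") <- extra
  out
}

#' @export
fitted.dw_map <- function(object, ...) {
  f <- suppressWarnings(predict(object))
  attr(f, "extrapolated") <- NULL
  f
}

#' @rdname predict.dw_map
#' @details `residuals()` returns observed minus fitted DWs on the response
#'   (DW) scale, anchor pseudo-observations included.
#' @export
residuals.dw_map <- function(object, ...) object$dw - fitted(object)

#' @export
print.dw_map <- function(x, ...) {
  cat("<dw_map: anchored local regression of logit(DW) on utility>\n")
  cat(sprintf("  training points: %d (%d anchor%s)\n", length(x$u),
              sum(x$anchor), if (sum(x$anchor) == 1L) "" else "s"))
  cat(sprintf("  span %.3g, degree %d, epsilon %g, %s weights\n",
              x$span, x$degree, x$epsilon, x$weights))
  cat(sprintf("  utility range [%.3f, %.3f], DW range [%.3f, %.3f]\n",
              min(x$u), max(x$u), min(x$dw), max(x$dw)))
  invisible(x)
}

#' @export
summary.dw_map <- function(object, ...) {
  res <- residuals.dw_map(object)
  lin <- logit_linear_fit(object$u, object$dw, epsilon = object$epsilon)
  structure(list(model = object, residuals = res, linear = lin),
            class = "summary.dw_map")
}

#' @export
print.summary.dw_map <- function(x, ...) {
  print(x$model)
  cat("  residuals (DW scale):\n")
  print(summary(x$residuals))
  cat(sprintf("  linear comparator (logit scale): intercept %.4f, slope %.4f\n",
              x$linear$intercept, x$linear$slope))
  invisible(x)
}

#' Plot a utility-to-DW mapping
#'
#' Scatter of training DWs against utilities, the local-regression curve on
#' a utility grid, and (optionally) the inverse-logit of the global linear
#' comparator, mirroring the conventional presentation of such mappings.
#'
#' @param x a [dw_map()] model.
#' @param grid_n number of grid points for the curves.
#' @param linear draw the linear-comparator curve?
#' @param ... passed to [plot()].
#' @export
plot.dw_map <- function(x, grid_n = 101L, linear = TRUE, ...) {
  g <- seq(min(x$u), max(x$u), length.out = grid_n)
  pred <- suppressWarnings(predict(x, g))
  graphics::plot(x$u, x$dw, pch = ifelse(x$anchor, 17, 19),
                 col = ifelse(x$anchor, "red", "grey30"),
                 xlab = "utility", ylab = "disability weight", ...)
  graphics::lines(g, pred, lwd = 2)
  if (linear) {
    lin <- logit_linear_fit(x$u, x$dw, epsilon = x$epsilon)
    graphics::lines(g, inv_logit(lin$intercept + lin$slope * g),
                    col = "grey60", lty = 2)
  }
  invisible(x)
}

#' Global linear comparator on the logit scale
#'
#' Ordinary least squares of the clamped-logit DWs on utilities — the
#' straight reference line conventionally drawn next to the local fit.
#'
#' @inheritParams dw_map
#' @param y optional pre-transformed responses (logit DWs); if supplied,
#'   `dw` and `epsilon` are ignored.
#' @return List with `intercept` and `slope`.
#' @export
logit_linear_fit <- function(utility, dw = NULL, epsilon = 1e-3, y = NULL) {
  if (is.null(y)) y <- logit_clamped(dw, epsilon)
  if (length(utility) != length(y)) stop("predictor/response lengths differ")
  if (length(utility) < 2L) stop("need at least 2 points")
  if (length(unique(utility)) < 2L) stop("degenerate: all utilities equal")
  co <- stats::lm.fit(cbind(1, utility), y)$coefficients
  list(intercept = unname(co[1L]), slope = unname(co[2L]))
}

#' Serialize / restore a fitted mapping
#'
#' The model is written as a JSON document holding the training pairs and
#' hyperparameters at full floating-point precision, so a restored model
#' reproduces predictions bit for bit.
#'
#' @param model a [dw_map()] object.
#' @param path file path.
#' @return `write_dw_map()` returns `path` invisibly; `read_dw_map()`
#'   returns the restored `dw_map` object.
#' @export
write_dw_map <- function(model, path) {
  stopifnot(inherits(model, "dw_map"))
  doc <- list(type = "dw_map",
              u = model$u, dw = model$dw, anchor = model$anchor,
              span = model$span, degree = model$degree,
              epsilon = model$epsilon, anchors = model$anchors,
              weights = model$weights)
  writeLines(jsonlite::toJSON(doc, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname write_dw_map
#' @export
read_dw_map <- function(path) {
  doc <- jsonlite::fromJSON(path)
  if (!identical(doc$type, "dw_map")) stop("not a serialized dw_map document")
  structure(list(u = doc$u, dw = doc$dw,
                 y = logit_clamped(doc$dw, doc$epsilon),
                 anchor = doc$anchor, span = doc$span,
                 degree = as.integer(doc$degree), epsilon = doc$epsilon,
                 anchors = doc$anchors, weights = doc$weights),
            class = "dw_map")
}
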