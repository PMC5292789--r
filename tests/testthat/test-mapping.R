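test_that("clamped logit matches direct evaluation of the formula", {
  expect_equal(logit_clamped(0.5, 1e-3), 0)
  expect_equal(logit_clamped(0.756, 1e-3), log(0.756 / 0.244))
  expect_equal(logit_clamped(0.756, 1e-3), 1.130873, tolerance = 1e-6)
  expect_equal(logit_clamped(1, 1e-3), log(0.999 / 0.001))
  expect_equal(logit_clamped(1, 1e-3), 6.906755, tolerance = 1e-6)
  expect_error(logit_clamped(-0.1), "\\[0, 1\\]")
  expect_error(logit_clamped(1.1), "\\[0, 1\\]")
  expect_error(logit_clamped(0.5, 0.7), "epsilon")
})

test_that("inverse logit round-trips the clamped logit inside the clamp", {
  expect_equal(inv_logit(0), 0.5)
  p <- seq(0.001, 0.999, length.out = 41)
  expect_equal(inv_logit(logit_clamped(p, 1e-3)), p, tolerance = 1e-12)
  expect_true(all(diff(inv_logit(seq(-30, 30, 0.5))) > 0))
  expect_lt(inv_logit(-40), 1e-15)
})

test_that("exactly logit-linear data is reproduced at any span and degree", {
  set.seed(41)
  u <- sort(runif(20))
  a <- -1.2; b <- 2.1
  dw <- inv_logit(a + b * u)
  for (span in c(0.4, 0.75, 1)) {
    for (degree in 1:2) {
      m <- dw_map(u, dw, span = span, degree = degree, anchors = FALSE)
      expect_equal(as.numeric(fitted(m)), dw, tolerance = 1e-8)
      grid <- seq(min(u), max(u), length.out = 23)
      expect_equal(as.numeric(suppressWarnings(predict(m, grid))),
                   inv_logit(a + b * grid), tolerance = 1e-8)
    }
  }
})

test_that("predictions equal the brute-force weighted least-squares oracle", {
  ref <- gbd_reference()
  set.seed(42)
  cases <- list(
    list(u = ref$u2_mean, dw = ref$dw2010, anchors = TRUE),
    list(u = runif(40), dw = runif(40, 0.01, 0.99), anchors = FALSE),
    list(u = runif(15, -0.2, 1), dw = runif(15, 0.05, 0.95), anchors = TRUE)
  )
  for (cs in cases) {
    for (degree in 0:2) {
      m <- dw_map(cs$u, cs$dw, span = 0.75, degree = degree, anchors = cs$anchors)
      queries <- c(runif(10, min(m$u), max(m$u)), m$u[1:3])
      pred <- suppressWarnings(predict(m, queries, scale = "logit"))
      orc <- vapply(queries, function(x0) {
        oracle_local_fit(m$u, m$y, x0, 0.75, degree)
      }, numeric(1))
      expect_equal(as.numeric(pred), orc, tolerance = 1e-8)
    }
  }
})

test_that("all predictions lie strictly inside (0, 1)", {
  ref <- gbd_reference()
  m <- dw_map(ref$u2_mean, ref$dw2010)
  p <- suppressWarnings(predict(m, seq(-0.3, 1.3, length.out = 60)))
  expect_true(all(p > 0 & p < 1))
})

test_that("anchors pull the predicted DW at full health towards zero", {
  ref <- gbd_reference()
  m <- dw_map(ref$u2_mean, ref$dw2010) # defaults: anchors on
  at_full_health <- as.numeric(predict(m, 1))
  expect_lte(at_full_health, 0.05)
  # and the oracle agrees at the same point
  expect_equal(at_full_health,
               inv_logit(oracle_local_fit(m$u, m$y, 1, m$span, m$degree)),
               tolerance = 1e-8)
})

test_that("degree-0 span-1 uniform-weight fit is the global transformed mean", {
  set.seed(43)
  u <- runif(12)
  dw <- runif(12, 0.05, 0.95)
  m <- dw_map(u, dw, span = 1, degree = 0, anchors = FALSE, weights = "uniform")
  p <- suppressWarnings(predict(m, c(0.2, 0.9), scale = "logit"))
  expect_equal(as.numeric(p), rep(mean(logit_clamped(dw, 1e-3)), 2),
               tolerance = 1e-12)
})

test_that("insufficient points or too-small spans are errors", {
  expect_error(dw_map(c(0.1, 0.5, 0.9), c(0.9, 0.5, 0.1), degree = 2,
                      anchors = FALSE), "insufficient points")
  expect_error(dw_map(runif(20), runif(20), span = 0.05, degree = 2,
                      anchors = FALSE), "neighbourhoods")
  expect_error(dw_map(c(0.1, 0.2), c(0.5, 1.2), anchors = FALSE), "\\[0, 1\\]")
})

test_that("extrapolation is allowed but flagged", {
  set.seed(44)
  m <- dw_map(runif(20, 0.2, 0.8), runif(20, 0.1, 0.9), anchors = FALSE)
  expect_warning(p <- predict(m, c(0.5, 1.5)), "extrapolation")
  expect_identical(attr(p, "extrapolated"), c(FALSE, TRUE))
  expect_error(suppressWarnings(predict(m, c(0.5, NA))), "NA")
})

test_that("serialized models reproduce predictions bit for bit", {
  ref <- gbd_reference()
  m <- dw_map(ref$u2_mean, ref$dw2013, span = 0.6, degree = 1)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  write_dw_map(m, path)
  m2 <- read_dw_map(path)
  q <- seq(0.05, 0.95, length.out = 31)
  expect_identical(as.numeric(predict(m, q)), as.numeric(predict(m2, q)))
})

test_that("linear comparator matches the closed-form normal equations", {
  # two points: interpolating line
  lin <- logit_linear_fit(c(0, 1), y = c(3, -3))
  expect_equal(lin$intercept, 3)
  expect_equal(lin$slope, -6)
  # exact recovery from noiseless linear data
  u <- seq(0, 1, 0.1)
  lin2 <- logit_linear_fit(u, y = 1.5 - 2 * u)
  expect_equal(lin2$slope, -2)
  expect_equal(lin2$intercept, 1.5)
  # random data: closed-form OLS oracle
  set.seed(45)
  for (i in 1:10) {
    x <- runif(9); yy <- rnorm(9)
    lin3 <- logit_linear_fit(x, y = yy)
    orc <- oracle_ols(x, yy)
    expect_equal(c(lin3$intercept, lin3$slope), unname(orc), tolerance = 1e-10)
  }
  expect_error(logit_linear_fit(rep(0.5, 4), y = rnorm(4)), "degenerate")
})
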