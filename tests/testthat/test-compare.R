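test_that("utility summaries are textbook statistics", {
  s <- summarize_utilities(c(0.2, 0.4, 0.6))
  expect_equal(s$mean, 0.4)
  expect_equal(s$median, 0.4)
  expect_equal(s$sd, 0.2)
  expect_equal(c(s$min, s$max), c(0.2, 0.6))
  one <- summarize_utilities(1)
  expect_equal(one$mean, 1)
  expect_equal(one$fraction_equal_one, 1)
  neg <- summarize_utilities(c(-0.158, 0.5, 1, 1))
  expect_equal(neg$fraction_negative, 0.25)
  expect_equal(neg$fraction_equal_one, 0.5)
  expect_error(summarize_utilities(numeric(0)), "empty")
})

test_that("spearman rho equals the definitional rank-then-Pearson oracle", {
  expect_equal(spearman_rho(1:7, 1:7), 1)
  set.seed(51)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (i %% 2 == 0) { # inject ties
      x <- round(x, 1); y <- round(y, 1)
      if (sd(rank(x)) == 0 || sd(rank(y)) == 0) next
    }
    expect_equal(spearman_rho(x, y), oracle_spearman(x, y), tolerance = 1e-12)
  }
  expect_error(spearman_rho(1:3, 1:4), "lengths differ")
  expect_error(spearman_rho(rep(1, 5), 1:5), "zero rank variance")
})

test_that("exact permutation p-values match enumeration", {
  # perfect anticorrelation of 4 states: 2 of the 24 permutations attain |rho| = 1
  expect_equal(spearman_p(c(0.667, 0.530, 0.474, 0.289),
                          c(0.003, 0.040, 0.127, 0.756),
                          "exact_permutation"), 2 / 24)
  expect_equal(spearman_p(1:3, c(2, 5, 9), "exact_permutation"), 2 / 6)
  expect_equal(spearman_p(1:2, c(4, 1), "exact_permutation"), 1)
  expect_error(spearman_p(1:9, 9:1, "exact_permutation"), "n <= 8")
  # agreement with cor.test's exact null distribution (tie-free case)
  set.seed(52)
  x <- rnorm(7); y <- rnorm(7)
  expect_equal(spearman_p(x, y, "exact_permutation"),
               cor.test(x, y, method = "spearman", exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("exact and t-approximate p-values agree loosely at n = 8", {
  set.seed(53)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8)
    expect_lt(abs(spearman_p(x, y, "exact_permutation") -
                  spearman_p(x, y, "t_approx")), 0.05)
  }
})

test_that("paired t-test reproduces the four-state pilot comparison", {
  u1 <- c(0.667, 0.530, 0.474, 0.289)
  tt <- paired_t(1 - u1, c(0.003, 0.040, 0.127, 0.756))
  expect_false(tt$degenerate)
  expect_equal(tt$df, 3)
  expect_equal(tt$p, 0.085, tolerance = 0.005)
  tt13 <- paired_t(1 - u1, c(0.005, 0.037, 0.128, 0.778))
  expect_equal(tt13$p, 0.099, tolerance = 0.005)
  # degenerate cases are flagged, not errors
  expect_true(paired_t(c(1, 2, 3), c(1, 2, 3))$degenerate)
  expect_true(paired_t(c(2, 3, 4, 5), c(1, 2, 3, 4))$degenerate)
  expect_error(paired_t(1:3, 1:4), "lengths differ")
})

test_that("complement differences match hand computation and name extremes", {
  ref <- gbd_reference()
  d <- complement_difference_table(study2_means(ref), ref, "dw2010")
  tab <- d$table
  expect_equal(tab$diff[tab$health_state_id == 193], 0.019) # migraine
  expect_equal(tab$diff[tab$health_state_id == 220], -0.097) # schizophrenia
  expect_equal(d$min_state, "Schizophrenia, acute")
  expect_equal(d$max_state, "Amputation of both legs (long-term with treatment)")
  expect_equal(d$mean, mean(tab$diff))
  # u = 1, dw = 0 -> difference 0
  ref1 <- data.frame(id = 1L, name = "x", dw2010 = 0, dw2013 = 0)
  d0 <- complement_difference_table(data.frame(health_state_id = 1L, mean = 1),
                                    ref1, "dw2010")
  expect_equal(d0$table$diff, 0)
  expect_error(complement_difference_table(
    data.frame(health_state_id = 999L, mean = 0.5), ref), "missing")
})

test_that("rank tables use rank 1 = least severe and midrank ties", {
  ref <- gbd_reference()
  rt <- rank_table(study2_means(ref), ref)
  expect_equal(rt$rank_dw2010[rt$health_state_id == 1], 1) # lowest DW2010
  expect_equal(rt$rank_utility[rt$health_state_id == 60], 23) # both legs
  expect_equal(rt$rank_utility[rt$health_state_id == 193], 11) # migraine
  expect_equal(rt$rank_utility[rt$health_state_id == 200], 15) # fistula
  # permutations of 1..n in the tie-free fixture
  expect_setequal(rt$rank_utility, 1:27)
  expect_setequal(rt$rank_dw2010, 1:27)
  expect_setequal(rt$rank_dw2013, 1:27)
  # median flags partition severity
  expect_equal(rt$flag_dw2010[rt$rank_dw2010 == 14], "at_median")
  expect_equal(sum(rt$flag_dw2010 == "below_median"), 13)
  expect_error(rank_table(study2_means(ref)[1, , drop = FALSE], ref),
               "at least 2")
})

test_that("dimension-level frequencies sum to 100 and average the levels", {
  all1 <- as_responses(data.frame(respondent_id = c("a", "b"),
                                  health_state_id = 1L,
                                  mo = 1L, sc = 1L, ua = 1L, pd = 1L, ad = 1L))
  f <- dimension_level_frequencies(all1)
  expect_true(all(f$pct_l1 == 100))
  expect_true(all(f$mean == 1) && all(f$sd == 0))
  mixed <- as_responses(data.frame(respondent_id = c("a", "b"),
                                   health_state_id = 1L,
                                   mo = c(1L, 3L), sc = 1:2, ua = c(5L, 5L),
                                   pd = c(2L, 4L), ad = c(1L, 1L)))
  fm <- dimension_level_frequencies(mixed)
  mo <- fm[fm$dimension == "mo", ]
  expect_equal(unlist(mo[, paste0("pct_l", 1:5)], use.names = FALSE),
               c(50, 0, 50, 0, 0))
  expect_equal(mo$mean, 2)
  rs <- rowSums(fm[, paste0("pct_l", 1:5)])
  expect_equal(rs, rep(100, nrow(fm)), ignore_attr = TRUE)
})

test_that("compare_report bundles rho, t-test, differences and ranks", {
  ref <- gbd_reference()
  rep2 <- compare_report(study2_means(ref), ref, "dw2010")
  expect_s3_class(rep2, "dw_comparison")
  expect_equal(rep2$rho_p_method, "t_approx")
  expect_lt(rep2$rho_p, 0.001)
  expect_output(print(rep2), "Spearman rho = -0.808")
  rep1 <- compare_report(study1_means(ref), ref, "dw2010")
  expect_equal(rep1$rho, -1)
  expect_equal(rep1$rho_p_method, "exact_permutation")
  expect_equal(rep1$rho_p, 2 / 24)
  expect_error(compare_report(study2_means(ref)[1, , drop = FALSE], ref),
               "at least 2")
})
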