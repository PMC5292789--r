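# Toy value set from first principles: constant 0.1 off full health, every
# level-2 decrement 0.05, every level-3 decrement 0.2, no indicator terms.
toy_vs <- function() {
  value_set("toy", constant = 0.1,
            decrements = cbind(l2 = rep(0.05, 5), l3 = rep(0.2, 5)))
}

# Row-stochastic crosswalk matrix equivalent to the deterministic level
# collapse (a 1 in the collapsed column of each requested 5L profile).
collapse_matrix <- function(profiles5) {
  cols <- all_profiles("3L")
  m <- matrix(0, length(profiles5), length(cols),
              dimnames = list(profiles5, cols))
  for (p in profiles5) {
    lv <- as.integer(strsplit(p, "")[[1L]])
    m[p, paste(c(1L, 2L, 2L, 3L, 3L)[lv], collapse = "")] <- 1
  }
  m
}

# Small respondent table used by IO and frequency tests.
tiny_responses <- function() {
  as_responses(data.frame(
    respondent_id = c("r1", "r2", "r3", "r4"),
    health_state_id = c(1L, 1L, 220L, 220L),
    mo = c(1L, 3L, 5L, 4L), sc = c(1L, 1L, 4L, 4L),
    ua = c(1L, 2L, 5L, 5L), pd = c(2L, 2L, 3L, 4L),
    ad = c(1L, 1L, 5L, 5L)))
}

# Per-state mean-utility table for the second pilot study, straight from the
# packaged reference fixture.
study2_means <- function(ref = gbd_reference()) {
  data.frame(health_state_id = ref$id, mean = ref$u2_mean)
}

study1_means <- function(ref = gbd_reference()) {
  s1 <- ref[!is.na(ref$u1_mean), ]
  data.frame(health_state_id = s1$id, mean = s1$u1_mean)
}
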