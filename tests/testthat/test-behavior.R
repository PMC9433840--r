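toy_dataset <- function() {
  # two subjects, hand-built histories with known preceding-outflow classes
  rbind(
    toy_subject("s1", "social",
                sessions = list(
                  data.frame(own = c(2, 3, 1, 2), out = c(6, 4, 5, 3)),
                  data.frame(own = c(1, 2), out = c(6, 2)))),
    toy_subject("s2", "social",
                sessions = list(
                  data.frame(own = c(3, 3, 3), out = c(4, 6, 4)))))
}

toy_subject <- function(id, condition, sessions) {
  rows <- lapply(seq_along(sessions), function(ss) {
    s <- sessions[[ss]]
    o1 <- pmin(pmax(s$out - 3L, 1L), 3L)
    data.frame(subject_id = id, condition = condition, session = ss,
               trial = seq_len(nrow(s)), stock_pre = 16L,
               own_choice = s$own, own_payoff = s$own,
               other1_catch = o1, other2_catch = s$out - o1,
               outflow = s$out, stock_post_catch = 8L, stock_next = 12L,
               terminal = seq_len(nrow(s)) == nrow(s))
  })
  do.call(rbind, rows)
}

test_that("session length summaries aggregate per-subject means", {
  d <- toy_dataset()
  s <- session_length_summary(d)
  # s1: sessions of 4 and 2 trials -> mean 3; s2: one session of 3
  expect_equal(s$mean_trials[s$condition == "social"], mean(c(3, 3)))
  d2 <- cohort("null", list(), n = 2, seed = 3)
  s2 <- session_length_summary(d2)
  expect_true(all(s2$mean_trials >= 1 & s2$mean_trials <= 8))
  # all-cap sessions: total extraction 3 never depletes
  cap <- toy_subject("s9", "nonsocial",
                     list(data.frame(own = rep(1, 8), out = rep(2, 8)),
                          data.frame(own = rep(1, 8), out = rep(2, 8))))
  sc <- session_length_summary(cap)
  expect_equal(sc$mean_trials, 8)
  expect_equal(sc$sd_trials, NA_real_)  # single subject, sd undefined
})

test_that("choice frequencies normalize and hit degenerate anchors", {
  d <- toy_dataset()
  f <- choice_frequency_summary(d)
  expect_equal(sum(f$frequency), 1)
  always3 <- toy_subject("s3", "nonsocial",
                         list(data.frame(own = rep(3, 5), out = rep(3, 5))))
  f3 <- choice_frequency_summary(always3)
  expect_equal(f3$frequency, c(0, 0, 1))
  d0 <- cohort("null", list(), n = 4, seed = 8)
  f0 <- choice_frequency_summary(d0)
  expect_true(all(abs(f0$frequency - 1 / 3) < 0.06))
})

test_that("depletion reactions condition on the preceding decrease class", {
  d <- toy_dataset()
  dr <- depletion_reaction(d)
  # s1: after large (out=6): trials s1/1/2 (own 3) and s1/2/2 (own 2);
  #     after moderate (out 4 or 3): s1/1/3 (own 1); out=5 excluded
  expect_equal(dr$mean_after_large[dr$subject_id == "s1"], 2.5)
  expect_equal(dr$mean_after_moderate[dr$subject_id == "s1"], 1)
  expect_equal(dr$difference[dr$subject_id == "s1"], 1.5)
  # s2: after large: own 3; after moderate: own 3
  expect_equal(dr$difference[dr$subject_id == "s2"], 0)
  expect_true(all(dr$mean_after_large >= 1 & dr$mean_after_large <= 3,
                  na.rm = TRUE))
})

test_that("history-insensitive agents show no systematic escalation", {
  d <- cohort("null", list(), n = 12, seed = 19)
  dr <- depletion_reaction(d)
  expect_lt(abs(mean(dr$difference, na.rm = TRUE)), 0.25)
})

test_that("escalation correlation handles degenerate inputs", {
  d <- toy_dataset()
  fits <- data.frame(subject_id = c("s1", "s2"), theta_s = c(0.5, 0.5))
  r <- social_weight_escalation_correlation(fits, d)
  expect_true(is.na(r$r))
  fits2 <- data.frame(subject_id = c("s1", "s2"), theta_s = c(0.2, 0.8))
  r2 <- social_weight_escalation_correlation(fits2, d)
  expect_true(is.na(r2$r))  # still < 3 subjects
  expect_equal(r2$n, 2L)
})

test_that("posterior predictive cells normalize and match the null anchor", {
  d <- cohort("null", list(), n = 3, seed = 27)
  fits <- fit_population(model_spec("null"), d, seed = 1)
  ppc <- posterior_predictive_check(fits, d)
  expect_true(all(abs(tapply(ppc$predicted,
                             paste(ppc$condition, ppc$preceding), sum) - 1)
                  < 1e-9))
  expect_true(all(abs(tapply(ppc$observed,
                             paste(ppc$condition, ppc$preceding), sum) - 1)
                  < 1e-9))
  expect_true(all(ppc$predicted == 1 / 3))  # uniform model
  expect_error(posterior_predictive_check(fits[-1, ], d), "do not cover")
})

test_that("exported RPE regressors follow the frozen-value identity at alpha 0", {
  d <- cohort("nonsocial", list(alpha = 0.5, beta = 1.5, theta_n = 0.5),
              n = 1, condition = "nonsocial", seed = 31)
  fits <- data.frame(subject_id = unique(d$subject_id),
                     condition = "nonsocial", model = "nonsocial", k = 3,
                     alpha = 0, beta = 1.2, theta_s = NA, theta_n = 0.7,
                     theta = NA, delta_adv = NA, delta_dis = NA, xi = NA,
                     loglik = NA, n_obs = nrow(d), bic = NA,
                     converged = TRUE)
  reg <- export_rpe_regressors(fits, d)
  expect_identical(nrow(reg), nrow(d))
  # with alpha = 0, Q stays at Q0, so each RPE is R_chosen - Q0(chosen)
  counts <- sapply(1:3, function(i) sum(d$own_choice[d$trial == 1] == i))
  Q0 <- 4 * counts / length(unique(d$session))
  Rch <- (1 - 0.7) * d$own_choice +
    0.7 * (-abs(6 - d$own_choice - d$outflow))
  expect_equal(reg$rpe_chosen, Rch - Q0[d$own_choice], tolerance = 1e-12)
})
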