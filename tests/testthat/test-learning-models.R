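test_that("softmax policy normalizes, is symmetric, and sharpens with beta", {
  expect_equal(softmax_policy(c(2, 2, 2), 3.7), rep(1 / 3, 3))
  expect_equal(softmax_policy(c(-1, 0, 5), 0), rep(1 / 3, 3))
  expect_equal(softmax_policy(c(1, 2, 3), 1),
               c(0.0900305732, 0.2447284711, 0.6652409558),
               tolerance = 1e-9)
  # numerically stable at large beta
  p <- softmax_policy(c(1, 2, 3), 50)
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # argmax probability weakly increases with beta
  Q <- c(0.2, 1.1, 0.7)
  betas <- seq(0, 20, by = 0.5)
  pmaxs <- vapply(betas, function(b) softmax_policy(Q, b)[2], numeric(1))
  expect_true(all(diff(pmaxs) >= -1e-12))
})

test_that("initial expectations are scaled first-trial frequencies summing to 4", {
  expect_equal(initial_values(c(4, 8, 4), 16), c(1, 2, 1))
  expect_equal(initial_values(c(0, 16, 0), 16), c(0, 4, 0))
  set.seed(31)
  for (r in 1:25) {
    n <- sample(1:40, 1)
    counts <- as.vector(stats::rmultinom(1, n, runif(3)))
    expect_equal(sum(initial_values(counts, n)), 4)
  }
  expect_error(initial_values(c(0, 0, 0), 0))
  expect_error(initial_values(c(1, 1, 1), 16))
})

test_that("reinforcement components match their defining arithmetic", {
  expect_equal(social_comparison(3, 2), 1)
  expect_equal(social_comparison(2, 2), 0)
  expect_equal(social_comparison(1, 3), -2)
  expect_equal(reinforcement_social(2, social_comparison(2, 3), 0), 2)
  expect_equal(reinforcement_social(2, social_comparison(2, 3), 1), -1)
  expect_equal(reinforcement_social(2, social_comparison(2, 3), 0.5), 0.5)
  expect_equal(sustainability_component(2, 4), 0)
  expect_equal(sustainability_component(3, 6), -3)
  expect_equal(sustainability_component(1, 2), -3)
  expect_true(all(sapply(1:3, function(i)
    sapply(2:6, function(o) sustainability_component(i, o)) <= 0)))
  expect_equal(reinforcement_sustain(2, sustainability_component(2, 4), 1), 0)
  expect_equal(reinforcement_sustain(3, sustainability_component(3, 6), 0.5), 0)
  expect_equal(fs_comparison(2, c(2, 2), 0.7, 0.9), 2)
  expect_equal(fs_comparison(3, c(1, 2), 0.5, 0), 1.5)
  expect_equal(fs_comparison(1, c(3, 2), 0, 0.5), 1 - 0.5 * 3)
  expect_equal(fs_comparison(2, c(1, 3), 0, 0), 2)
  expect_equal(hybrid_reinforcement(5, 1, -3, 1, 0.5), -1)
  expect_equal(update_values(c(1, 2, 3), c(9, 9, 9), 0), c(1, 2, 3))
  expect_equal(update_values(c(1, 2, 3), c(9, 9, 9), 1), c(9, 9, 9))
  expect_equal(update_values(c(1, 2, 3), c(3, 3, 3), 0.5), c(2, 2.5, 3))
  expect_equal(counterfactual_payoffs(), c(1, 2, 3))
})

test_that("model replay matches the scalar trial-by-trial oracle for all kinds", {
  d <- cohort("fs", list(alpha = 0.45, beta = 1.8, theta_s = 0.55,
                         delta_adv = 0.3, delta_dis = 0.6),
              n = 1, seed = 17)
  cases <- list(
    list("rw", list(alpha = 0.3, beta = 1.2)),
    list("social", list(alpha = 0.3, beta = 1.2, theta_s = 0.7)),
    list("nonsocial", list(alpha = 0.6, beta = 2.5, theta_n = 0.4)),
    list("fs", list(alpha = 0.5, beta = 0.8, theta_s = 0.5,
                    delta_adv = 0.2, delta_dis = 0.9)),
    list("hybrid", list(alpha = 0.25, beta = 3, theta = 0.8, xi = 0.35)),
    list("null", list()))
  for (cs in cases) {
    got <- run_model(d, model_spec(cs[[1]]), cs[[2]])$loglik
    want <- oracle_loglik(d, cs[[1]], cs[[2]])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("a three-trial hand-worked sequence reproduces the frozen trace", {
  d <- toy_trials(own = c(2, 3, 1), o1 = c(2, 3, 1), o2 = c(2, 3, 2))
  soc <- run_model(d, model_spec("social"),
                   list(alpha = 0.5, beta = 1, theta_s = 0.6))$loglik
  expect_equal(soc, -4.221493073780968, tolerance = 1e-10)
  expect_equal(soc, oracle_loglik(d, "social",
                                  list(alpha = 0.5, beta = 1,
                                       theta_s = 0.6)),
               tolerance = 1e-10)
  nso <- run_model(d, model_spec("nonsocial"),
                   list(alpha = 0.5, beta = 1, theta_n = 0.6))$loglik
  expect_equal(nso, -3.962661542506350, tolerance = 1e-10)
})

test_that("nested parameterizations give exact likelihood identities", {
  d <- cohort("social", list(alpha = 0.4, beta = 2, theta_s = 0.6),
              n = 1, seed = 23)
  ab <- list(alpha = 0.37, beta = 1.4)
  ll_rw <- run_model(d, model_spec("rw"), ab)$loglik
  expect_equal(run_model(d, model_spec("social"),
                         c(ab, theta_s = 0))$loglik, ll_rw)
  expect_equal(run_model(d, model_spec("nonsocial"),
                         c(ab, theta_n = 0))$loglik, ll_rw)
  ll_soc <- run_model(d, model_spec("social"),
                      c(ab, theta_s = 0.53))$loglik
  expect_equal(run_model(d, model_spec("fs"),
                         c(ab, theta_s = 0.53, delta_adv = 0,
                           delta_dis = 0))$loglik, ll_soc)
  expect_equal(run_model(d, model_spec("hybrid"),
                         c(ab, theta = 0.53, xi = 0))$loglik, ll_soc)
  ll_nso <- run_model(d, model_spec("nonsocial"),
                      c(ab, theta_n = 0.53))$loglik
  expect_equal(run_model(d, model_spec("hybrid"),
                         c(ab, theta = 0.53, xi = 1))$loglik, ll_nso)
})

test_that("trial traces normalize, bound values, and reset each session", {
  d <- cohort("nonsocial", list(alpha = 0.5, beta = 1.5, theta_n = 0.7),
              n = 1, condition = "nonsocial", seed = 41)
  res <- run_model(d, model_spec("nonsocial"),
                   list(alpha = 0.5, beta = 1.5, theta_n = 0.7),
                   trace = TRUE)
  tr <- res$trials
  expect_equal(tr$p1 + tr$p2 + tr$p3, rep(1, nrow(tr)), tolerance = 1e-12)
  expect_identical(nrow(tr), nrow(d))
  expect_identical(res$n_obs, nrow(d))
  # delta rule keeps Q inside the hull of Q0 and reinforcements, so the
  # chosen-option RPE is bounded by the attainable reinforcement span
  rmin <- min(tr[, c("r1", "r2", "r3")]); rmax <- max(tr[, c("r1", "r2", "r3")])
  expect_true(all(tr$rpe_chosen >= rmin - 4 - 1e-9))
  expect_true(all(tr$rpe_chosen <= rmax + 4 + 1e-9))
  # null model trace: uniform probabilities, likelihood -n log 3
  res0 <- run_model(d, model_spec("null"), trace = TRUE)
  expect_equal(res0$loglik, -nrow(d) * log(3))
  expect_true(all(res0$trials$p1 == 1 / 3))
})

test_that("dropping last trials removes one likelihood term per session", {
  d <- cohort("rw", list(alpha = 0.3, beta = 1), n = 1, seed = 50)
  full <- run_model(d, model_spec("rw"), list(alpha = 0.3, beta = 1))
  dropped <- run_model(d, model_spec("rw"), list(alpha = 0.3, beta = 1),
                       drop_last_trial = TRUE)
  n_sessions <- length(unique(d$session))
  expect_identical(dropped$n_obs, full$n_obs - n_sessions)
  expect_true(dropped$loglik > full$loglik)  # fewer negative terms
  expect_error(run_model(transform(d, own_choice = 4), model_spec("rw"),
                         list(alpha = 0.3, beta = 1)),
               "invalid choice")
})
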