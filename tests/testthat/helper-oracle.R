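# Independent reference implementations used as oracles. Deliberately
# scalar, loop-based and separate from the package's vectorized code
# paths.

# Naive trial-by-trial log-likelihood for every model family.
oracle_loglik <- function(d, kind, params, Q0 = NULL, sustainable = 6) {
  d <- d[order(d$session, d$trial), ]
  sessions <- unique(d$session)
  if (is.null(Q0)) {
    counts <- sapply(1:3, function(i)
      sum(d$own_choice[d$trial == 1] == i))
    Q0 <- 4 * counts / length(sessions)
  }
  if (kind == "null") return(-nrow(d) * log(3))
  ll <- 0
  for (ss in sessions) {
    Q <- Q0
    dd <- d[d$session == ss, ]
    for (t in seq_len(nrow(dd))) {
      p <- exp(params$beta * Q) / sum(exp(params$beta * Q))
      ll <- ll + log(p[dd$own_choice[t]])
      o1 <- dd$other1_catch[t]; o2 <- dd$other2_catch[t]
      m <- (o1 + o2) / 2
      R <- sapply(1:3, function(i) {
        switch(kind,
          rw = i,
          social = (1 - params$theta_s) * i +
            params$theta_s * (i - m),
          nonsocial = (1 - params$theta_n) * i +
            params$theta_n * (-abs(sustainable - i - (o1 + o2))),
          fs = {
            cc <- i - params$delta_dis * (max(o1 - i, 0) + max(o2 - i, 0)) -
              params$delta_adv * (max(i - o1, 0) + max(i - o2, 0))
            (1 - params$theta_s) * i + params$theta_s * cc
          },
          hybrid = (1 - params$theta) * i + params$theta *
            ((1 - params$xi) * (i - m) +
               params$xi * (-abs(sustainable - i - (o1 + o2)))))
      })
      Q <- Q + params$alpha * (R - Q)
    }
  }
  ll
}

# Hand-assembled trial log (no engine involved) for oracle comparisons.
toy_trials <- function(own, o1, o2, session = NULL) {
  n <- length(own)
  if (is.null(session)) session <- rep(1L, n)
  trial <- stats::ave(seq_len(n), session, FUN = seq_along)
  data.frame(subject_id = "toy", condition = "social",
             session = session, trial = trial,
             stock_pre = 16L, own_choice = own, own_payoff = own,
             other1_catch = o1, other2_catch = o2, outflow = o1 + o2,
             stock_post_catch = 0L, stock_next = 0L, terminal = FALSE)
}

# Small simulated cohort shared by several tests.
cohort <- function(kind, params, n = 2, condition = "social", seed = 7,
                   ...) {
  simulate_agents(model_spec(kind), params, n_subjects = n,
                  condition = condition, seed = seed, ...)
}
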