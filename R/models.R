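#' Model specification
#'
#' The model family shares a delta-rule value update and a softmax policy
#' over the three net sizes; members differ in how the trial reinforcement
#' is constructed:
#'
#' * `null` — uniform choice (probability 1/3), no learning; one counted
#'   parameter per subject for information criteria.
#' * `rw` — Rescorla-Wagner: reinforcement is the own payoff only
#'   (parameters `alpha`, `beta`).
#' * `social` — weighted blend of own payoff and a social-comparison
#'   component, own payoff minus the opponents' mean payoff
#'   (`alpha`, `beta`, `theta_s`).
#' * `nonsocial` — weighted blend of own payoff and a sustainability
#'   component, minus the absolute deviation of total extraction from the
#'   sustainable catch (`alpha`, `beta`, `theta_n`).
#' * `fs` — like `social` but with a Fehr-Schmidt inequity-averse
#'   comparison term (`alpha`, `beta`, `theta_s`, `delta_adv`,
#'   `delta_dis`).
#' * `hybrid` — comparison term interpolates between the social and
#'   sustainability components with weight `xi` (`alpha`, `beta`, `theta`,
#'   `xi`); `xi = 0` degenerates into `social`, `xi = 1` into `nonsocial`.
#'
#' @param kind One of `"null"`, `"rw"`, `"social"`, `"nonsocial"`, `"fs"`,
#'   `"hybrid"`.
#' @return An object of class `model_spec` with fields `kind`,
#'   `free_parameter_names`, `k` (free-parameter count per subject),
#'   `lower` and `upper` bounds.
#' @export
#' @examples
#' model_spec("social")$free_parameter_names
model_spec <- function(kind = c("null", "rw", "social", "nonsocial",
                                "fs", "hybrid")) {
  kind <- match.arg(kind)
  pars <- switch(kind,
    null      = character(0),
    rw        = c("alpha", "beta"),
    social    = c("alpha", "beta", "theta_s"),
    nonsocial = c("alpha", "beta", "theta_n"),
    fs        = c("alpha", "beta", "theta_s", "delta_adv", "delta_dis"),
    hybrid    = c("alpha", "beta", "theta", "xi"))
  lower <- stats::setNames(rep(0, length(pars)), pars)
  upper <- stats::setNames(rep(1, length(pars)), pars)
  if ("beta" %in% pars) upper["beta"] <- 50
  # the null baseline is counted as one parameter per subject in BIC
  k <- if (kind == "null") 1L else length(pars)
  structure(list(kind = kind, free_parameter_names = pars, k = k,
                 lower = lower, upper = upper),
            class = "model_spec")
}

#' Softmax choice probabilities
#'
#' `p(i)` proportional to `exp(beta * Q(i))`, computed with a max shift for
#' numerical stability. `beta = 0` yields uniform probabilities.
#'
#' @param Q Numeric vector (or matrix, rows = independent states) of
#'   option values.
#' @param beta Inverse temperature, `>= 0`.
#' @return Probabilities with the same shape as `Q`, rows summing to 1.
#' @export
softmax_policy <- function(Q, beta) {
  stopifnot(beta >= 0)
  if (is.matrix(Q)) {
    z <- beta * Q
    z <- z - apply(z, 1L, max)
    e <- exp(z)
    e / rowSums(e)
  } else {
    z <- beta * Q
    e <- exp(z - max(z))
    e / sum(e)
  }
}

#' Initial option values from first-trial choice frequencies
#'
#' The a-priori expectation of each net size is its relative frequency
#' among the first trials of all sessions, scaled by four to span the range
#' of obtainable payoffs. The components therefore always sum to exactly 4.
#'
#' @param first_trial_choice_counts Integer triple of first-trial counts
#'   per net size.
#' @param n_sessions Total number of sessions (must equal the sum of the
#'   counts).
#' @return Numeric triple `Q0`.
#' @export
initial_values <- function(first_trial_choice_counts, n_sessions) {
  stopifnot(n_sessions > 0,
            length(first_trial_choice_counts) == 3L,
            all(first_trial_choice_counts >= 0),
            sum(first_trial_choice_counts) == n_sessions)
  4 * first_trial_choice_counts / n_sessions
}

#' Social comparison component
#'
#' Own payoff minus the opponents' mean payoff, per option.
#'
#' @param own_payoff Own payoff(s) per option.
#' @param others_mean_payoff Mean payoff of the two others.
#' @return Numeric, same shape as `own_payoff`.
#' @export
social_comparison <- function(own_payoff, others_mean_payoff) {
  own_payoff - others_mean_payoff
}

#' Social reinforcement
#'
#' Weighted sum of the direct payoff and the social-comparison component.
#'
#' @param own Own payoff per option.
#' @param soc_comp Social-comparison component per option.
#' @param theta_s Social-comparison weight in `[0, 1]`.
#' @return Reinforcement per option.
#' @export
reinforcement_social <- function(own, soc_comp, theta_s) {
  stopifnot(theta_s >= 0, theta_s <= 1)
  (1 - theta_s) * own + theta_s * soc_comp
}

#' Sustainability component
#'
#' Negative absolute deviation of the trial's total extraction (own payoff
#' plus outflow) from the sustainable catch: zero when the total equals the
#' sustainable level, negative when too many *or* too few fish are taken.
#'
#' @param own Own payoff per option.
#' @param outflow Total fish removed by the others / migration this trial.
#' @param sustainable_catch Sustainable total (default 6).
#' @return Non-positive value per option.
#' @export
sustainability_component <- function(own, outflow, sustainable_catch = 6) {
  -abs(sustainable_catch - own - outflow)
}

#' Sustainable reinforcement
#'
#' Weighted sum of the direct payoff and the sustainability component.
#'
#' @param own Own payoff per option.
#' @param sust_comp Sustainability component per option.
#' @param theta_n Sustainability weight in `[0, 1]`.
#' @return Reinforcement per option.
#' @export
reinforcement_sustain <- function(own, sust_comp, theta_n) {
  stopifnot(theta_n >= 0, theta_n <= 1)
  (1 - theta_n) * own + theta_n * sust_comp
}

#' Fehr-Schmidt inequity-averse comparison
#'
#' Own payoff penalized by disadvantageous inequality (each opponent ahead
#' of the subject, weighted by `delta_dis`) and by advantageous inequality
#' (the subject ahead of each opponent, weighted by `delta_adv`).
#'
#' @param own Own payoff per option.
#' @param others_payoffs Numeric pair of the two opponents' payoffs.
#' @param delta_adv Advantageous-inequality coefficient in `[0, 1]`.
#' @param delta_dis Disadvantageous-inequality coefficient in `[0, 1]`.
#' @return Comparison value per option.
#' @export
fs_comparison <- function(own, others_payoffs, delta_adv, delta_dis) {
  stopifnot(delta_adv >= 0, delta_adv <= 1, delta_dis >= 0, delta_dis <= 1)
  dis <- pmax(others_payoffs[1L] - own, 0) + pmax(others_payoffs[2L] - own, 0)
  adv <- pmax(own - others_payoffs[1L], 0) + pmax(own - others_payoffs[2L], 0)
  own - delta_dis * dis - delta_adv * adv
}

#' Hybrid reinforcement
#'
#' The comparison term interpolates between the social and sustainability
#' components: `(1 - xi) * soc_comp + xi * sust_comp`, then blends with the
#' own payoff by weight `theta`.
#'
#' @param own Own payoff per option.
#' @param soc_comp Social-comparison component per option.
#' @param sust_comp Sustainability component per option.
#' @param theta Comparison weight in `[0, 1]`.
#' @param xi Interpolation weight in `[0, 1]`.
#' @return Reinforcement per option.
#' @export
hybrid_reinforcement <- function(own, soc_comp, sust_comp, theta, xi) {
  stopifnot(xi >= 0, xi <= 1, theta >= 0, theta <= 1)
  (1 - theta) * own + theta * ((1 - xi) * soc_comp + xi * sust_comp)
}

#' Delta-rule value update with fictive (counterfactual) updating
#'
#' All three options are updated toward their (counterfactual)
#' reinforcements: `Q <- Q + alpha * (R - Q)`.
#'
#' @param Q Current option values (vector or matrix).
#' @param reinforcements Reinforcements, same shape as `Q`.
#' @param alpha Learning rate in `[0, 1]`.
#' @return Updated values.
#' @export
update_values <- function(Q, reinforcements, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  Q + alpha * (reinforcements - Q)
}

#' Counterfactual own payoffs per option
#'
#' The payoff a hypothetical choice of net size `i` would have yielded,
#' holding the trial's others/migration fixed: simply `i` itself (stock
#' truncation is ignored; scarcity can only bite on terminal trials).
#'
#' @param net_sizes Integer vector of options (default 1:3).
#' @return Numeric vector of per-option payoffs.
#' @export
counterfactual_payoffs <- function(net_sizes = 1:3) {
  as.numeric(net_sizes)
}

# Per-trial reinforcement matrix (rows = sessions/states, cols = options)
# given the trial's realized others' payoffs. `o1`, `o2` are vectors over
# rows; options are the net sizes 1..3.
reinforcement_matrix <- function(kind, params, o1, o2,
                                 sustainable_catch = 6) {
  n <- length(o1)
  own <- matrix(rep(1:3, each = n), nrow = n)  # counterfactual payoffs
  outflow <- o1 + o2
  switch(kind,
    rw = own,
    social = {
      sc <- own - (outflow / 2)
      (1 - params[["theta_s"]]) * own + params[["theta_s"]] * sc
    },
    nonsocial = {
      su <- -abs(sustainable_catch - own - outflow)
      (1 - params[["theta_n"]]) * own + params[["theta_n"]] * su
    },
    fs = {
      dis <- pmax(o1 - own, 0) + pmax(o2 - own, 0)
      adv <- pmax(own - o1, 0) + pmax(own - o2, 0)
      cc <- own - params[["delta_dis"]] * dis - params[["delta_adv"]] * adv
      (1 - params[["theta_s"]]) * own + params[["theta_s"]] * cc
    },
    hybrid = {
      sc <- own - (outflow / 2)
      su <- -abs(sustainable_catch - own - outflow)
      comp <- (1 - params[["xi"]]) * sc + params[["xi"]] * su
      (1 - params[["theta"]]) * own + params[["theta"]] * comp
    },
    stop("unknown model kind: ", kind))
}

#' Run a learning model over one subject's data
#'
#' Replays the model trial by trial: at every trial the softmax choice
#' probabilities are computed from the current values *before* the choice
#' is observed, the log-likelihood accumulates `log p(chosen)`, and all
#' three option values are then updated toward their counterfactual
#' reinforcements (fictive updating). Values are re-initialized to `Q0` at
#' the start of every session; `Q0` is computed from the subject's own
#' first-trial choice frequencies via [initial_values()] unless supplied.
#'
#' In the nonsocial condition the per-opponent payoff entering the social
#' and inequity-averse comparisons is `outflow / 2`, so every model is
#' computable in both conditions (cross-fitting).
#'
#' @param subject_data Data frame for one subject with columns `session`,
#'   `trial`, `own_choice`, `other1_catch`, `other2_catch`, `outflow`.
#' @param spec A [model_spec()].
#' @param params Named list/vector of parameter values for `spec`.
#' @param config A [cpr_config()].
#' @param Q0 Optional initial values (numeric triple); default computed
#'   from the data.
#' @param drop_last_trial Exclude each session's final trial from the
#'   log-likelihood (the update still never affects excluded trials'
#'   probabilities, which are emitted before feedback).
#' @param trace If `TRUE`, return the per-trial computations.
#' @return A list with `loglik`, `n_obs` and, if `trace`, a data frame
#'   `trials` with columns `session`, `trial`, `own_choice`, `p1`, `p2`,
#'   `p3`, `r1`, `r2`, `r3`, `rpe_chosen`, `in_likelihood`.
#' @export
run_model <- function(subject_data, spec, params = list(),
                      config = cpr_config(), Q0 = NULL,
                      drop_last_trial = FALSE, trace = FALSE) {
  d <- subject_data[order(subject_data$session, subject_data$trial), ,
                    drop = FALSE]
  if (!all(d$own_choice %in% config$net_sizes))
    stop("invalid choice code in subject data")
  sessions <- unique(d$session)
  S <- length(sessions)
  sid <- match(d$session, sessions)
  tno <- stats::ave(seq_len(nrow(d)), sid, FUN = seq_along)
  Tmax <- max(tno)
  idx <- cbind(sid, tno)
  put <- function(x, fill = NA_real_) {
    m <- matrix(fill, S, Tmax); m[idx] <- x; m
  }
  choice <- put(d$own_choice)
  o1 <- put(d$other1_catch)
  o2 <- put(d$other2_catch)
  last_t <- tapply(tno, sid, max)

  if (is.null(Q0)) {
    counts <- tabulate(choice[, 1L], nbins = 3L)
    Q0 <- initial_values(counts, S)
  }

  n_obs <- if (drop_last_trial) sum(tno < last_t[sid]) else nrow(d)

  if (spec$kind == "null") {
    ll <- -n_obs * log(3)
    out <- list(loglik = ll, n_obs = n_obs)
    if (trace) {
      out$trials <- data.frame(
        session = d$session, trial = d$trial, own_choice = d$own_choice,
        p1 = 1 / 3, p2 = 1 / 3, p3 = 1 / 3,
        r1 = NA_real_, r2 = NA_real_, r3 = NA_real_,
        rpe_chosen = NA_real_,
        in_likelihood = if (drop_last_trial) tno < last_t[sid] else
          rep(TRUE, nrow(d)))
    }
    return(out)
  }

  alpha <- params[["alpha"]]
  beta <- params[["beta"]]
  Q <- matrix(Q0, S, 3L, byrow = TRUE)
  ll <- 0
  if (trace) {
    P_tr <- matrix(NA_real_, S * Tmax, 3L)
    R_tr <- matrix(NA_real_, S * Tmax, 3L)
    rpe_tr <- rep(NA_real_, S * Tmax)
  }
  for (t in seq_len(Tmax)) {
    act <- which(!is.na(choice[, t]))
    P <- softmax_policy(Q[act, , drop = FALSE], beta)
    R <- reinforcement_matrix(spec$kind, params, o1[act, t], o2[act, t],
                              config$sustainable_catch)
    ch <- choice[act, t]
    pick <- cbind(seq_along(act), ch)
    keep <- if (drop_last_trial) t < last_t[act] else rep(TRUE, length(act))
    ll <- ll + sum(log(P[pick])[keep])
    rpe <- R[pick] - Q[cbind(act, ch)]
    if (trace) {
      pos <- (act - 1L) * Tmax + t
      P_tr[pos, ] <- P
      R_tr[pos, ] <- R
      rpe_tr[pos] <- rpe
    }
    Q[act, ] <- Q[act, , drop = FALSE] +
      alpha * (R - Q[act, , drop = FALSE])
  }
  out <- list(loglik = ll, n_obs = n_obs)
  if (trace) {
    pos <- (sid - 1L) * Tmax + tno
    out$trials <- data.frame(
      session = d$session, trial = d$trial, own_choice = d$own_choice,
      p1 = P_tr[pos, 1L], p2 = P_tr[pos, 2L], p3 = P_tr[pos, 3L],
      r1 = R_tr[pos, 1L], r2 = R_tr[pos, 2L], r3 = R_tr[pos, 3L],
      rpe_chosen = rpe_tr[pos],
      in_likelihood = if (drop_last_trial) tno < last_t[sid] else
        rep(TRUE, nrow(d)))
  }
  out
}
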