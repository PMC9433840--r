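#' Simulate a cohort of learning agents playing the CPR task
#'
#' Each synthetic subject plays `sessions_per_subject` sessions against
#' freshly sampled surrogate streams, choosing net sizes via the softmax
#' policy over values learned exactly as [run_model()] replays them (same
#' counterfactual reinforcements, fictive updating and session-wise value
#' reset). The stream semantics are identical in the social condition
#' (two opponents' catches) and the nonsocial condition (migration
#' outflow, recorded as the same two-way split).
#'
#' Simulated agents start every session from `Q0_agent`, by default the
#' uniform expectation `(4/3, 4/3, 4/3)` (first-trial frequencies scaled
#' to sum 4 are only defined once data exist; fitting recomputes `Q0` from
#' the generated data itself).
#'
#' @param spec A [model_spec()]; `null` agents choose uniformly.
#' @param params Named parameter values for `spec`.
#' @param n_subjects Number of agents.
#' @param condition `"social"` or `"nonsocial"` label written to the data.
#' @param config A [cpr_config()].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param dist An [others_distribution()] for the surrogate totals.
#' @param stock_conditional Use the conserving surrogate policy hook of
#'   [surrogate_stream()].
#' @param conserve_strength Strength of the conserving policy.
#' @param Q0_agent Initial option values used by the simulated agents.
#' @param subject_prefix Prefix for generated subject ids.
#' @return A behavioral dataset: one data frame row per trial with columns
#'   `subject_id`, `condition`, `session`, `trial`, `stock_pre`,
#'   `own_choice`, `own_payoff`, `other1_catch`, `other2_catch`,
#'   `outflow`, `stock_post_catch`, `stock_next`, `terminal`.
#' @export
#' @examples
#' d <- simulate_agents(model_spec("rw"), list(alpha = 0.3, beta = 1.5),
#'                      n_subjects = 2, seed = 1)
#' head(d)
simulate_agents <- function(spec, params = list(), n_subjects = 1L,
                            condition = c("social", "nonsocial"),
                            config = cpr_config(), seed = 1L,
                            dist = others_distribution(),
                            stock_conditional = FALSE,
                            conserve_strength = 2.7,
                            Q0_agent = rep(4 / 3, 3),
                            subject_prefix = NULL) {
  condition <- match.arg(condition)
  if (is.null(subject_prefix))
    subject_prefix <- paste0(substr(condition, 1, 1), "ag")
  check_params(spec, params)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    stream <- surrogate_stream(dist, stock_conditional, conserve_strength,
                               config)
    sess <- vector("list", config$sessions_per_subject)
    for (ss in seq_len(config$sessions_per_subject)) {
      Q <- Q0_agent  # new environment each session
      stock <- config$capacity
      rows <- vector("list", config$max_trials_per_session)
      for (t in seq_len(config$max_trials_per_session)) {
        p <- if (spec$kind == "null") rep(1 / 3, 3) else
          drop(softmax_policy(Q, params[["beta"]]))
        own <- sample(config$net_sizes, 1L, prob = p)
        others <- stream(stock, t)
        alloc <- allocate_catch(stock, c(own, others))
        stock_next <- replenish(alloc$stock_post_catch, config)
        terminal <- stock_next == 0L || t == config$max_trials_per_session
        rows[[t]] <- data.frame(
          session = ss, trial = t, stock_pre = stock,
          own_choice = own, own_payoff = alloc$payoffs[1L],
          other1_catch = alloc$payoffs[2L],
          other2_catch = alloc$payoffs[3L],
          outflow = alloc$payoffs[2L] + alloc$payoffs[3L],
          stock_post_catch = alloc$stock_post_catch,
          stock_next = stock_next, terminal = terminal)
        if (spec$kind != "null") {
          R <- reinforcement_matrix(spec$kind, params,
                                    alloc$payoffs[2L], alloc$payoffs[3L],
                                    config$sustainable_catch)
          Q <- update_values(Q, drop(R), params[["alpha"]])
        }
        stock <- stock_next
        if (terminal) break
      }
      sess[[ss]] <- do.call(rbind,
                            rows[!vapply(rows, is.null, logical(1))])
    }
    d <- do.call(rbind, sess)
    d$subject_id <- sprintf("%s%03d", subject_prefix, s)
    d$condition <- condition
    out[[s]] <- d
  }
  d <- do.call(rbind, out)
  d[, c("subject_id", "condition", "session", "trial", "stock_pre",
        "own_choice", "own_payoff", "other1_catch", "other2_catch",
        "outflow", "stock_post_catch", "stock_next", "terminal")]
}

# Validate that `params` covers the spec's free parameters within bounds.
check_params <- function(spec, params) {
  for (p in spec$free_parameter_names) {
    if (is.null(params[[p]]))
      stop("missing parameter '", p, "' for model '", spec$kind, "'")
    if (params[[p]] < spec$lower[[p]] || params[[p]] > spec$upper[[p]])
      stop("parameter '", p, "' out of bounds for model '", spec$kind, "'")
  }
  invisible(TRUE)
}
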