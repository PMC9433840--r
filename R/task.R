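#' Task configuration for the CPR fishing game
#'
#' Bundles the fixed parameters of the common-pool resource task: three
#' players repeatedly harvest fish from a lake that replenishes by a growth
#' factor (rounded down) at the end of every trial, up to a hard capacity.
#' A session ends when the lake is fished out or after
#' `max_trials_per_session` trials.
#'
#' @param capacity Maximum number of fish the lake can hold.
#' @param growth_factor Multiplicative replenishment applied to the
#'   post-catch stock at the end of each trial (result rounded down).
#' @param sustainable_catch Total per-trial extraction that keeps the stock
#'   approximately constant; equals the group catch when all three players
#'   choose the middle net size.
#' @param max_trials_per_session Trial cap per session.
#' @param sessions_per_subject Number of sessions each subject plays.
#' @param net_sizes Ordered set of choosable net sizes.
#' @param payoff_per_fish Monetary payoff per fish (Swiss francs).
#'
#' @return An object of class `cpr_config` (a named list).
#' @export
#' @examples
#' cfg <- cpr_config()
#' replenish(10, cfg)
cpr_config <- function(capacity = 16L,
                       growth_factor = 1.5,
                       sustainable_catch = 6L,
                       max_trials_per_session = 8L,
                       sessions_per_subject = 16L,
                       net_sizes = 1:3,
                       payoff_per_fish = 0.25) {
  stopifnot(capacity > 0, growth_factor > 1,
            max_trials_per_session >= 1, sessions_per_subject >= 1,
            all(net_sizes == seq(min(net_sizes), by = 1,
                                 length.out = length(net_sizes))),
            all(net_sizes > 0))
  if (sustainable_catch != 3 * stats::median(net_sizes))
    stop("sustainable_catch must equal the group catch at the middle net size")
  structure(list(capacity = as.integer(capacity),
                 growth_factor = growth_factor,
                 sustainable_catch = as.integer(sustainable_catch),
                 max_trials_per_session = as.integer(max_trials_per_session),
                 sessions_per_subject = as.integer(sessions_per_subject),
                 net_sizes = as.integer(net_sizes),
                 payoff_per_fish = payoff_per_fish),
            class = "cpr_config")
}

#' Replenish the fish stock at the end of a trial
#'
#' The post-catch stock is multiplied by the growth factor, rounded down,
#' and capped at the lake capacity. An empty lake stays empty.
#'
#' @param stock_post_catch Fish count after this trial's catch, in
#'   `[0, capacity]`.
#' @param config A [cpr_config()].
#' @return Integer stock carried into the next trial.
#' @export
replenish <- function(stock_post_catch, config = cpr_config()) {
  if (any(stock_post_catch < 0)) stop("stock cannot be negative")
  if (any(stock_post_catch > config$capacity)) stop("stock exceeds capacity")
  pmin(as.integer(floor(config$growth_factor * stock_post_catch)),
       config$capacity)
}

#' Allocate the trial's catch under possible scarcity
#'
#' When the stock covers all demands, everyone receives what they asked
#' for. When it does not, demands are granted in a seeded random player
#' order, each player taking the minimum of their demand and what remains,
#' so that the full remaining stock is distributed.
#'
#' @param stock Pre-catch fish stock.
#' @param demands Integer vector of demands, one per player (the first
#'   entry is conventionally the modeled subject).
#' @param rng_order Optional permutation of `seq_along(demands)` fixing the
#'   scarcity order; by default a random permutation is drawn from the
#'   current RNG stream.
#' @return A list with `payoffs` (integer vector, same order as `demands`)
#'   and `stock_post_catch`.
#' @export
allocate_catch <- function(stock, demands, rng_order = NULL) {
  stopifnot(stock >= 0, all(demands >= 0))
  demands <- as.integer(demands)
  if (stock >= sum(demands)) {
    return(list(payoffs = demands,
                stock_post_catch = as.integer(stock - sum(demands))))
  }
  ord <- if (is.null(rng_order)) sample.int(length(demands)) else rng_order
  payoffs <- integer(length(demands))
  remaining <- as.integer(stock)
  for (p in ord) {
    take <- min(demands[p], remaining)
    payoffs[p] <- take
    remaining <- remaining - take
  }
  list(payoffs = payoffs, stock_post_catch = remaining)
}

#' Run a single session of the CPR task
#'
#' The session starts with a full lake. Each trial the subject's policy and
#' the surrogate stream produce demands, the catch is allocated, and the
#' stock replenishes. The session terminates when the replenished stock is
#' zero or the trial cap is reached.
#'
#' @param policy_own Function `(stock, trial) -> net size` giving the
#'   subject's demand.
#' @param others_stream Function `(stock, trial) -> integer pair` giving
#'   the two others' (or the migration split's) demands.
#' @param config A [cpr_config()].
#' @return A data frame with one row per trial: `trial`, `stock_pre`,
#'   `own_choice`, `own_payoff`, `other1_catch`, `other2_catch`, `outflow`,
#'   `stock_post_catch`, `stock_next`, `terminal`.
#' @export
run_session <- function(policy_own, others_stream, config = cpr_config()) {
  n_max <- config$max_trials_per_session
  rec <- vector("list", n_max)
  stock <- config$capacity
  for (t in seq_len(n_max)) {
    own <- as.integer(policy_own(stock, t))
    stopifnot(own %in% config$net_sizes)
    others <- as.integer(others_stream(stock, t))
    stopifnot(length(others) == 2L)
    alloc <- allocate_catch(stock, c(own, others))
    stock_next <- replenish(alloc$stock_post_catch, config)
    terminal <- stock_next == 0L || t == n_max
    rec[[t]] <- data.frame(trial = t,
                           stock_pre = stock,
                           own_choice = own,
                           own_payoff = alloc$payoffs[1L],
                           other1_catch = alloc$payoffs[2L],
                           other2_catch = alloc$payoffs[3L],
                           outflow = alloc$payoffs[2L] + alloc$payoffs[3L],
                           stock_post_catch = alloc$stock_post_catch,
                           stock_next = stock_next,
                           terminal = terminal)
    stock <- stock_next
    if (terminal) break
  }
  do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
}
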