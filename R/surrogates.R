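#' Distribution of the two others' total extraction
#'
#' Marginal distribution of the per-trial total number of fish removed by
#' the two pre-recorded opponents (social condition) or migrating out
#' (nonsocial condition). Defaults reproduce the task's pre-recorded
#' streams: totals 2..6 with frequencies 3.4, 2.7, 34.9, 25.3 and 33.7
#' percent.
#'
#' @param support Integer totals, each expressible as a sum of two net
#'   sizes in 1..3.
#' @param probabilities Probabilities, summing to 1.
#' @return An object of class `others_distribution`.
#' @export
others_distribution <- function(support = 2:6,
                                probabilities = c(0.034, 0.027, 0.349,
                                                  0.253, 0.337)) {
  stopifnot(length(support) == length(probabilities),
            all(probabilities >= 0),
            abs(sum(probabilities) - 1) < 1e-12,
            all(support >= 2), all(support <= 6))
  structure(list(support = as.integer(support),
                 probabilities = probabilities),
            class = "others_distribution")
}

#' Sample per-trial totals from the surrogate distribution
#'
#' @param n Number of i.i.d. draws.
#' @param dist An [others_distribution()].
#' @return Integer vector of totals.
#' @export
sample_others_total <- function(n, dist = others_distribution()) {
  dist$support[sample.int(length(dist$support), n, replace = TRUE,
                          prob = dist$probabilities)]
}

#' Split a total extraction into two opponent catches
#'
#' Uniformly over the compositions of `total` into two parts, each a valid
#' net size (1..3).
#'
#' @param total Integer total in 2..6 (vectorized).
#' @return A matrix with columns `other1`, `other2`.
#' @export
split_total <- function(total) {
  stopifnot(all(total >= 2), all(total <= 6))
  o1 <- integer(length(total))
  for (k in seq_along(total)) {
    lo <- max(1L, total[k] - 3L)
    hi <- min(3L, total[k] - 1L)
    parts <- lo:hi
    o1[k] <- if (length(parts) == 1L) parts else
      parts[sample.int(length(parts), 1L)]
  }
  cbind(other1 = o1, other2 = as.integer(total) - o1)
}

#' Surrogate stream factory
#'
#' Returns a stream function usable by [run_session()]. By default the
#' totals are i.i.d. draws from `dist`. With `stock_conditional = TRUE`
#' the stream emulates the conserving behavior of the pre-recorded human
#' opponents: with probability `min(1, conserve_strength * (capacity -
#' stock) / capacity)` the pair takes the sustainable total of 2 fish
#' (one each) instead of an i.i.d. draw. The default strength 2.7 is
#' calibrated so that simulated cohorts reproduce the original design's
#' mean session length of about 6.5 trials.
#'
#' @param dist An [others_distribution()].
#' @param stock_conditional Enable the conserving policy hook.
#' @param conserve_strength Strength of the conserving tendency.
#' @param config A [cpr_config()] (for the capacity).
#' @return A function `(stock, trial) -> c(other1, other2)`.
#' @export
surrogate_stream <- function(dist = others_distribution(),
                             stock_conditional = FALSE,
                             conserve_strength = 2.7,
                             config = cpr_config()) {
  force(dist); force(stock_conditional); force(conserve_strength)
  capacity <- config$capacity
  function(stock, trial) {
    if (stock_conditional &&
        stats::runif(1) < min(1, conserve_strength *
                                   (capacity - stock) / capacity)) {
      return(c(1L, 1L))
    }
    total <- sample_others_total(1L, dist)
    split <- split_total(total)
    c(split[1, 1L], split[1, 2L])
  }
}
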