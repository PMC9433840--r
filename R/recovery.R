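#' Model recovery confusion matrix
#'
#' For each generating model, simulates `n_runs` agents against fresh
#' surrogate streams, fits every candidate model to each run, identifies
#' the winner by lowest BIC (ties broken toward the smaller parameter
#' count, then alphabetically), and tabulates the identification
#' fractions. Rows sum to 1 over the runs that yielded converged fits for
#' every candidate; excluded runs are counted in `n_excluded`.
#'
#' @param candidate_specs List of [model_spec()]s to fit.
#' @param generating Named list: one entry per generating model kind, each
#'   a named parameter list for [simulate_agents()].
#' @param n_runs Simulated agents per generating model.
#' @param config A [cpr_config()].
#' @param seed Integer seed.
#' @param condition Condition label for the simulated data.
#' @param n_starts Starts per fit.
#' @param ... Passed to [simulate_agents()] (e.g. `dist`,
#'   `stock_conditional`).
#' @return A list of class `confusion_matrix`: `fractions` (generating x
#'   identified), `counts`, `n_runs`, `n_excluded`, `seed`.
#' @export
model_recovery <- function(candidate_specs, generating, n_runs = 50L,
                           config = cpr_config(), seed = 1L,
                           condition = "social", n_starts = 10L, ...) {
  stopifnot(n_runs >= 1, length(candidate_specs) >= 1)
  cand_kinds <- vapply(candidate_specs, `[[`, character(1), "kind")
  gen_kinds <- names(generating)
  counts <- matrix(0L, length(gen_kinds), length(cand_kinds),
                   dimnames = list(gen_kinds, cand_kinds))
  excluded <- stats::setNames(integer(length(gen_kinds)), gen_kinds)
  k_of <- vapply(candidate_specs, `[[`, integer(1), "k")
  for (g in gen_kinds) {
    gspec <- model_spec(g)
    for (r in seq_len(n_runs)) {
      run_seed <- derive_seed(seed, paste0("recover-", g, "-", r))
      d <- simulate_agents(gspec, generating[[g]], n_subjects = 1L,
                           condition = condition, config = config,
                           seed = run_seed, ...)
      bics <- rep(NA_real_, length(candidate_specs))
      ok <- TRUE
      for (j in seq_along(candidate_specs)) {
        f <- fit_subject(candidate_specs[[j]], d, n_starts = n_starts,
                         seed = derive_seed(run_seed, cand_kinds[j]),
                         config = config)
        if (!f$converged) { ok <- FALSE; break }
        bics[j] <- bic(f$loglik, candidate_specs[[j]]$k, f$n_obs)
      }
      if (!ok) {
        excluded[g] <- excluded[g] + 1L
        next
      }
      # lowest BIC; ties toward the simpler model, then alphabetically
      o <- order(bics, k_of, cand_kinds)
      counts[g, o[1L]] <- counts[g, o[1L]] + 1L
    }
  }
  fr <- counts / pmax(rowSums(counts), 1L)
  structure(list(fractions = fr, counts = counts,
                 n_runs = as.integer(n_runs), n_excluded = excluded,
                 seed = as.integer(seed)),
            class = "confusion_matrix")
}

#' Parameter recovery sweep
#'
#' Simulate-then-refit at each grid point: `n_reps` agents are generated
#' from the model at the grid point's parameters and refitted with the
#' same model; the sweep reports the mean bias and RMSE per free
#' parameter.
#'
#' @param spec A [model_spec()].
#' @param param_grid Data frame, one row per grid point, columns named
#'   after the spec's free parameters.
#' @param n_reps Agents per grid point.
#' @param config A [cpr_config()].
#' @param seed Integer seed.
#' @param n_starts Starts per fit.
#' @param ... Passed to [simulate_agents()].
#' @return Data frame: grid point columns, then `<par>_bias`,
#'   `<par>_rmse` and `<par>_median` for each free parameter, plus
#'   `n_reps` and `n_excluded`.
#' @export
parameter_recovery <- function(spec, param_grid, n_reps = 10L,
                               config = cpr_config(), seed = 1L,
                               n_starts = 10L, ...) {
  nm <- spec$free_parameter_names
  stopifnot(all(nm %in% names(param_grid)))
  out <- vector("list", nrow(param_grid))
  for (gp in seq_len(nrow(param_grid))) {
    truth <- as.list(param_grid[gp, nm, drop = FALSE])
    est <- matrix(NA_real_, n_reps, length(nm),
                  dimnames = list(NULL, nm))
    excl <- 0L
    for (r in seq_len(n_reps)) {
      rs <- derive_seed(seed, paste0("prec-", gp, "-", r))
      d <- simulate_agents(spec, truth, n_subjects = 1L, config = config,
                           seed = rs, ...)
      f <- fit_subject(spec, d, n_starts = n_starts,
                       seed = derive_seed(rs, "fit"), config = config)
      if (!f$converged) { excl <- excl + 1L; next }
      est[r, ] <- f$estimates[nm]
    }
    row <- param_grid[gp, nm, drop = FALSE]
    for (p in nm) {
      err <- est[, p] - truth[[p]]
      row[[paste0(p, "_bias")]] <- mean(err, na.rm = TRUE)
      row[[paste0(p, "_rmse")]] <- sqrt(mean(err^2, na.rm = TRUE))
      row[[paste0(p, "_median")]] <- stats::median(est[, p], na.rm = TRUE)
    }
    row$n_reps <- n_reps
    row$n_excluded <- excl
    out[[gp]] <- row
  }
  do.call(rbind, out)
}
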