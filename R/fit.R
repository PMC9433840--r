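#' Negative log-likelihood of a model on one subject's data
#'
#' @param spec A [model_spec()].
#' @param params Named parameter values within the spec's bounds.
#' @param subject_data One subject's trials (see [run_model()]).
#' @param ... Passed to [run_model()] (`config`, `Q0`, `drop_last_trial`).
#' @return Scalar negative log-likelihood.
#' @export
negloglik <- function(spec, params, subject_data, ...) {
  -run_model(subject_data, spec, params, ...)$loglik
}

# Deterministic sub-seed from a base seed and a string key, < 2^31.
derive_seed <- function(seed, key) {
  h <- sum(utf8ToInt(as.character(key)) *
             (seq_along(utf8ToInt(as.character(key))) %% 31 + 1))
  as.integer((as.numeric(seed) %% 65011 + 1) * 26041 + h %% 1e6) %% 2147483629L
}

#' Fit one subject by maximum likelihood
#'
#' Bounded multi-start optimization of the model's likelihood: `n_starts`
#' seeded uniform-random initial points (inverse temperature starts drawn
#' on `[0, 5]`, where fitted values concentrate), each refined by
#' `L-BFGS-B` within the parameter bounds. The best start wins; ties are
#' broken by the earliest start index. The null baseline has a closed-form
#' likelihood and skips optimization.
#'
#' @param spec A [model_spec()].
#' @param subject_data One subject's trials.
#' @param n_starts Number of random starts (>= 1).
#' @param seed Integer seed for the starts.
#' @param config A [cpr_config()].
#' @param drop_last_trial Exclude each session's last trial from the
#'   likelihood.
#' @return A list of class `cpr_fit`: `spec`, `estimates` (named numeric),
#'   `loglik`, `n_obs`, `n_starts`, `converged`, `seed`.
#' @export
fit_subject <- function(spec, subject_data, n_starts = 20L, seed = 1L,
                        config = cpr_config(), drop_last_trial = FALSE) {
  stopifnot(n_starts >= 1)
  nm <- spec$free_parameter_names
  base <- run_model(subject_data, spec,
                    params = stats::setNames(as.list(rep(0, length(nm))), nm),
                    config = config, drop_last_trial = drop_last_trial)
  if (spec$kind == "null") {
    return(structure(list(spec = spec, estimates = stats::setNames(
      numeric(0), character(0)), loglik = base$loglik, n_obs = base$n_obs,
      n_starts = 0L, converged = TRUE, seed = as.integer(seed)),
      class = "cpr_fit"))
  }
  lower <- spec$lower
  upper <- spec$upper
  start_upper <- upper
  if ("beta" %in% nm) start_upper["beta"] <- 5
  set.seed(derive_seed(seed, "starts"))
  starts <- matrix(stats::runif(n_starts * length(nm), lower,
                                start_upper),
                   nrow = n_starts, byrow = TRUE,
                   dimnames = list(NULL, nm))
  obj <- function(x) {
    -run_model(subject_data, spec, as.list(stats::setNames(x, nm)),
               config = config, drop_last_trial = drop_last_trial)$loglik
  }
  best <- NULL
  any_ok <- FALSE
  for (i in seq_len(n_starts)) {
    res <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) {
      # keep the raw start as a fallback candidate
      res <- list(par = starts[i, ], value = obj(starts[i, ]),
                  convergence = 99L)
    } else {
      any_ok <- any_ok || res$convergence == 0L
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  structure(list(spec = spec,
                 estimates = stats::setNames(as.numeric(best$par), nm),
                 loglik = -best$value, n_obs = base$n_obs,
                 n_starts = as.integer(n_starts),
                 converged = any_ok, seed = as.integer(seed)),
            class = "cpr_fit")
}

#' @export
print.cpr_fit <- function(x, ...) {
  cat("CPR model fit:", x$spec$kind, "\n")
  cat("  loglik:", format(x$loglik, digits = 6),
      " n_obs:", x$n_obs,
      " BIC:", format(bic(x$loglik, x$spec$k, x$n_obs), digits = 6), "\n")
  if (length(x$estimates))
    print(round(x$estimates, 4))
  invisible(x)
}

#' Fit every subject in a dataset
#'
#' Independent per-subject maximum-likelihood fits. Start points are
#' seeded from the subject id, so results do not depend on subject order.
#' Subjects with no usable trials are skipped with a message.
#'
#' @param spec A [model_spec()].
#' @param dataset Behavioral dataset covering one or more subjects.
#' @param n_starts,seed,config,drop_last_trial As in [fit_subject()].
#' @param verbose Log per-subject progress.
#' @return A data frame with one row per subject: `subject_id`,
#'   `condition`, `model`, `k`, one column per free parameter (NA where a
#'   parameter does not belong to the model), `loglik`, `n_obs`, `bic`,
#'   `converged`.
#' @export
fit_population <- function(spec, dataset, n_starts = 20L, seed = 1L,
                           config = cpr_config(), drop_last_trial = FALSE,
                           verbose = FALSE) {
  subjects <- sort(unique(dataset$subject_id))
  stopifnot(length(subjects) >= 1)
  all_pars <- c("alpha", "beta", "theta_s", "theta_n", "theta",
                "delta_adv", "delta_dis", "xi")
  rows <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sd <- dataset[dataset$subject_id == subjects[i], , drop = FALSE]
    if (nrow(sd) == 0L) {
      message("subject ", subjects[i], " has no usable trials; skipped")
      next
    }
    fit <- fit_subject(spec, sd, n_starts = n_starts,
                       seed = derive_seed(seed, subjects[i]),
                       config = config, drop_last_trial = drop_last_trial)
    pars <- stats::setNames(rep(NA_real_, length(all_pars)), all_pars)
    pars[names(fit$estimates)] <- fit$estimates
    rows[[i]] <- data.frame(subject_id = subjects[i],
                            condition = sd$condition[1L],
                            model = spec$kind, k = spec$k,
                            as.list(pars),
                            loglik = fit$loglik, n_obs = fit$n_obs,
                            bic = bic(fit$loglik, spec$k, fit$n_obs),
                            converged = fit$converged)
    if (verbose)
      message("fit ", spec$kind, " to ", subjects[i], ": loglik ",
              format(fit$loglik, digits = 6))
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
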