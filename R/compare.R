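#' Bayesian Information Criterion
#'
#' `-2 * loglik + k * log(n_obs)`; lower is better. `-BIC/2` approximates
#' the log model evidence.
#'
#' @param loglik Maximized log-likelihood.
#' @param k Number of free parameters counted for the subject.
#' @param n_obs Number of observations entering the likelihood.
#' @param per_observation Divide the score by `n_obs`.
#' @return Numeric score (vectorized over its arguments).
#' @export
bic <- function(loglik, k, n_obs, per_observation = FALSE) {
  stopifnot(all(n_obs >= 1), all(k >= 0))
  score <- -2 * loglik + k * log(n_obs)
  if (per_observation) score / n_obs else score
}

#' Categorize a BIC difference as Bayes-factor evidence
#'
#' Absolute differences of at most 2 are inconclusive, more than 2 count
#' as positive evidence and more than 10 as very strong evidence. The sign
#' of the difference gives the direction.
#'
#' @param delta_bic BIC difference (model A minus model B).
#' @return Character vector with levels `"inconclusive"`, `"positive"`,
#'   `"very strong"`, with attribute `direction` (-1, 0, 1 = sign).
#' @export
bayes_factor_category <- function(delta_bic) {
  a <- abs(delta_bic)
  lab <- ifelse(a > 10, "very strong",
                ifelse(a > 2, "positive", "inconclusive"))
  structure(lab, direction = sign(delta_bic))
}

#' McFadden pseudo-R-squared
#'
#' `1 - loglik_model / loglik_null`; 0 for the null model itself, 1 in the
#' limit of a perfect model.
#'
#' @param loglik_model Log-likelihood of the model of interest.
#' @param loglik_null Log-likelihood of the uniform baseline (must be
#'   negative).
#' @return Fraction.
#' @export
mcfadden_r2 <- function(loglik_model, loglik_null) {
  if (any(loglik_null >= 0)) stop("null log-likelihood must be negative")
  1 - loglik_model / loglik_null
}

#' Evidence matrix from per-model population fits
#'
#' Combines the outputs of [fit_population()] for several models into a
#' subjects-by-models grid of BIC scores and log-evidence approximations
#' (`-BIC/2`).
#'
#' @param fits List of [fit_population()] data frames (one per model).
#' @return A list of class `evidence_matrix`: `bic` and `log_evidence`
#'   matrices (rows = subjects, columns = models), `loglik`, `n_obs`, `k`
#'   matrices, `subjects`, `models`, `conditions`.
#' @export
evidence_matrix <- function(fits) {
  stopifnot(length(fits) >= 1)
  models <- vapply(fits, function(f) f$model[1L], character(1))
  subjects <- sort(unique(unlist(lapply(fits, `[[`, "subject_id"))))
  grab <- function(col) {
    m <- matrix(NA_real_, length(subjects), length(models),
                dimnames = list(subjects, models))
    for (j in seq_along(fits))
      m[fits[[j]]$subject_id, j] <- fits[[j]][[col]]
    m
  }
  bicm <- grab("bic")
  if (anyNA(bicm)) stop("every model must be fitted to every subject")
  cond <- rep(NA_character_, length(subjects))
  names(cond) <- subjects
  for (f in fits) cond[f$subject_id] <- as.character(f$condition)
  structure(list(bic = bicm, log_evidence = -bicm / 2,
                 loglik = grab("loglik"), n_obs = grab("n_obs"),
                 k = grab("k"), subjects = subjects, models = models,
                 conditions = cond),
            class = "evidence_matrix")
}

#' Balanced accuracy of condition classification from model fit
#'
#' Each model is assigned a class (`social` or `nonsocial`) and paired
#' with its opposite-class counterpart (`social` with `nonsocial`, `fs`
#' with `rw`). A model of class `c` predicts that a subject belongs to
#' condition `c` iff its BIC beats the counterpart's. Balanced accuracy is
#' the mean of the two per-condition correct-classification rates.
#'
#' @param evidence An [evidence_matrix()].
#' @param model_class_map Named character vector mapping each model to
#'   `"social"` or `"nonsocial"`.
#' @param pairs Named character vector mapping each model to its
#'   counterpart.
#' @return Named numeric vector of balanced accuracies, one per mapped
#'   model present in the evidence.
#' @export
balanced_accuracy <- function(evidence,
                              model_class_map = c(social = "social",
                                                  nonsocial = "nonsocial",
                                                  fs = "social",
                                                  rw = "nonsocial"),
                              pairs = c(social = "nonsocial",
                                        nonsocial = "social",
                                        fs = "rw", rw = "fs")) {
  out <- c()
  for (m in intersect(names(model_class_map), evidence$models)) {
    cp <- pairs[[m]]
    if (is.na(cp) || !(cp %in% evidence$models))
      stop("counterpart model '", cp, "' missing from evidence for '",
           m, "'")
    cls <- model_class_map[[m]]
    predicted_in_class <- evidence$bic[, m] < evidence$bic[, cp]
    truth_in_class <- evidence$conditions == cls
    rate <- function(mask, correct)
      if (!any(mask)) NA_real_ else mean(correct[mask])
    acc_in <- rate(truth_in_class, predicted_in_class)
    acc_out <- rate(!truth_in_class, !predicted_in_class)
    out[m] <- mean(c(acc_in, acc_out))
  }
  out
}

#' Random-effects Bayesian model selection
#'
#' Variational treatment of model identity as a random effect across
#' subjects: a Dirichlet prior (concentration 1 per model) over group
#' model frequencies is updated by iterating posterior subject-wise
#' assignment weights `u[n, k] = exp(log_evidence[n, k] +
#' digamma(alpha[k]) - digamma(sum(alpha)))`, row-normalized, with
#' concentrations updated to the prior plus summed weights, to a
#' fixed-point tolerance of 1e-8. Exceedance probabilities (the
#' probability that each model is the most frequent) are estimated by
#' seeded Monte-Carlo draws from the fitted Dirichlet.
#'
#' @param evidence An [evidence_matrix()], or a numeric matrix of
#'   log-evidence values (rows = subjects, columns = models).
#' @param n_mc_samples Monte-Carlo draws for the exceedance estimate.
#' @param seed Integer seed for the draws.
#' @param prior_alpha Prior Dirichlet concentration per model.
#' @param max_iter Iteration cap; non-convergence is flagged, not fatal.
#' @return A list of class `bms_result`: `model_frequencies`,
#'   `exceedance_probabilities`, `dirichlet_concentrations`,
#'   `n_mc_samples`, `seed`, `converged`, `n_iter`.
#' @export
bms_random_effects <- function(evidence, n_mc_samples = 1e6, seed = 1L,
                               prior_alpha = 1, max_iter = 10000L) {
  L <- if (inherits(evidence, "evidence_matrix")) evidence$log_evidence
       else as.matrix(evidence)
  stopifnot(ncol(L) >= 2, nrow(L) >= 1, all(is.finite(L)))
  K <- ncol(L)
  alpha <- rep(prior_alpha, K)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    lw <- sweep(L, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    lw <- lw - apply(lw, 1L, max)
    w <- exp(lw)
    w <- w / rowSums(w)
    alpha_new <- prior_alpha + colSums(w)
    if (max(abs(alpha_new - alpha)) < 1e-8) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  freq <- alpha / sum(alpha)
  set.seed(derive_seed(seed, "bms-xp"))
  draws <- matrix(stats::rgamma(n_mc_samples * K,
                                shape = rep(alpha, each = n_mc_samples)),
                  nrow = n_mc_samples)
  xp <- tabulate(max.col(draws, ties.method = "first"), nbins = K) /
    n_mc_samples
  names(freq) <- names(xp) <- colnames(L)
  structure(list(model_frequencies = freq,
                 exceedance_probabilities = xp,
                 dirichlet_concentrations = stats::setNames(alpha,
                                                            colnames(L)),
                 n_mc_samples = as.integer(n_mc_samples),
                 seed = as.integer(seed),
                 converged = converged, n_iter = it),
            class = "bms_result")
}
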