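#' Session length summary per condition
#'
#' Per-subject mean session lengths, aggregated per condition (mean and
#' s.d. of the per-subject means).
#'
#' @param dataset Behavioral dataset.
#' @return Data frame with columns `condition`, `n_subjects`,
#'   `mean_trials`, `sd_trials`.
#' @export
session_length_summary <- function(dataset) {
  per_subj <- stats::aggregate(
    trial ~ subject_id + condition,
    data = stats::aggregate(trial ~ subject_id + condition + session,
                            data = dataset, FUN = max),
    FUN = mean)
  agg <- stats::aggregate(trial ~ condition, data = per_subj,
                          FUN = function(x) c(n = length(x),
                                              mean = mean(x),
                                              sd = stats::sd(x)))
  out <- data.frame(condition = agg$condition,
                    n_subjects = as.integer(agg$trial[, "n"]),
                    mean_trials = agg$trial[, "mean"],
                    sd_trials = agg$trial[, "sd"])
  rownames(out) <- NULL
  out
}

#' Net-size choice frequencies per condition
#'
#' @param dataset Behavioral dataset.
#' @param net_sizes Option set (default 1:3).
#' @return Data frame with columns `condition`, `net_size`, `frequency`;
#'   frequencies sum to 1 within each condition.
#' @export
choice_frequency_summary <- function(dataset, net_sizes = 1:3) {
  out <- lapply(split(dataset, dataset$condition), function(d) {
    f <- tabulate(match(d$own_choice, net_sizes),
                  nbins = length(net_sizes)) / nrow(d)
    data.frame(condition = d$condition[1L], net_size = net_sizes,
               frequency = f)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Classify each trial by the preceding trial's others/migration outflow:
# "large" = 6 fish, "moderate" = 2-4 fish, NA otherwise (5 excluded, and
# first trials have no preceding trial). Returns a character vector
# aligned with `dataset` rows.
classify_preceding_outflow <- function(dataset) {
  d <- dataset
  key <- paste(d$subject_id, d$session)
  ord <- order(key, d$trial)
  cls <- rep(NA_character_, nrow(d))
  prev_out <- c(NA, d$outflow[ord][-length(ord)])
  same_sess <- c(FALSE, key[ord][-1] == key[ord][-length(ord)])
  prev_out[!same_sess] <- NA
  cls_ord <- ifelse(is.na(prev_out), NA_character_,
                    ifelse(prev_out == 6, "large",
                           ifelse(prev_out >= 2 & prev_out <= 4,
                                  "moderate", NA_character_)))
  cls[ord] <- cls_ord
  cls
}

#' Reaction to resource depletion
#'
#' Per-subject mean chosen net size in trials following a large decrease
#' by others/migration (6 fish) *vs* following a moderate decrease (2-4
#' fish; 5 excluded), and their difference (large minus moderate). A
#' positive difference indicates escalation after depletion.
#'
#' @param dataset Behavioral dataset.
#' @return Data frame with columns `subject_id`, `condition`,
#'   `mean_after_large`, `mean_after_moderate`, `difference` (NA where a
#'   subject has no trials in a class).
#' @export
depletion_reaction <- function(dataset) {
  cls <- classify_preceding_outflow(dataset)
  subjects <- unique(dataset$subject_id)
  rows <- lapply(subjects, function(s) {
    m <- dataset$subject_id == s
    lg <- dataset$own_choice[m & !is.na(cls) & cls == "large"]
    md <- dataset$own_choice[m & !is.na(cls) & cls == "moderate"]
    ml <- if (length(lg)) mean(lg) else NA_real_
    mm <- if (length(md)) mean(md) else NA_real_
    data.frame(subject_id = s,
               condition = dataset$condition[m][1L],
               mean_after_large = ml, mean_after_moderate = mm,
               difference = ml - mm)
  })
  do.call(rbind, rows)
}

#' Correlation between social-comparison weight and harvesting escalation
#'
#' Product-moment correlation between per-subject `theta_s` estimates and
#' the depletion-reaction difference score.
#'
#' @param fits A [fit_population()] data frame containing a `theta_s`
#'   column.
#' @param dataset Behavioral dataset for the same subjects.
#' @return A list: `r` (NA when undefined), `n`, and `message` when the
#'   correlation is undefined.
#' @export
social_weight_escalation_correlation <- function(fits, dataset) {
  dr <- depletion_reaction(dataset)
  m <- merge(fits[, c("subject_id", "theta_s")], dr, by = "subject_id")
  m <- m[stats::complete.cases(m[, c("theta_s", "difference")]), ]
  if (nrow(m) < 3)
    return(list(r = NA_real_, n = nrow(m),
                message = "fewer than 3 complete subjects"))
  if (stats::sd(m$theta_s) == 0 || stats::sd(m$difference) == 0)
    return(list(r = NA_real_, n = nrow(m),
                message = "zero variance; correlation undefined"))
  list(r = stats::cor(m$theta_s, m$difference), n = nrow(m),
       message = NULL)
}

# Re-run each subject's fitted model over the observed history and return
# the trial-level trace merged with the dataset rows.
fitted_trace <- function(fits, dataset, config = cpr_config()) {
  rows <- vector("list", nrow(fits))
  for (i in seq_len(nrow(fits))) {
    s <- fits$subject_id[i]
    spec <- model_spec(fits$model[i])
    params <- as.list(fits[i, spec$free_parameter_names, drop = FALSE])
    sd <- dataset[dataset$subject_id == s, , drop = FALSE]
    if (nrow(sd) == 0L) stop("no data for fitted subject ", s)
    tr <- run_model(sd, spec, params, config = config, trace = TRUE)$trials
    tr$subject_id <- s
    tr$condition <- sd$condition[1L]
    rows[[i]] <- tr
  }
  do.call(rbind, rows)
}

#' Posterior predictive check of conditional choice probabilities
#'
#' For every trial, records the fitted model's one-step-ahead (pre-choice)
#' probabilities conditioned on the observed history, aggregates them by
#' the preceding-decrease class (large = 6 fish, moderate = 2-4), and
#' pairs them with the observed conditional choice frequencies.
#'
#' @param fits A [fit_population()] data frame (one model per subject).
#' @param dataset Behavioral dataset covering every fitted subject.
#' @param config A [cpr_config()].
#' @return Data frame with columns `condition`, `preceding`, `net_size`,
#'   `predicted` (mean model probability) and `observed` (choice
#'   frequency); `predicted` and `observed` each sum to 1 within a
#'   (`condition`, `preceding`) cell.
#' @export
posterior_predictive_check <- function(fits, dataset,
                                       config = cpr_config()) {
  missing <- setdiff(unique(dataset$subject_id), fits$subject_id)
  if (length(missing))
    stop("fits do not cover subjects: ", paste(missing, collapse = ", "))
  tr <- fitted_trace(fits, dataset, config)
  ds <- dataset[order(dataset$subject_id, dataset$session,
                      dataset$trial), ]
  tr <- tr[order(tr$subject_id, tr$session, tr$trial), ]
  cls <- classify_preceding_outflow(ds)
  keep <- !is.na(cls)
  cells <- expand.grid(condition = unique(ds$condition),
                       preceding = c("moderate", "large"),
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  pm <- as.matrix(tr[, c("p1", "p2", "p3")])
  for (i in seq_len(nrow(cells))) {
    m <- keep & ds$condition == cells$condition[i] &
      cls == cells$preceding[i]
    if (!any(m)) next
    pred <- colMeans(pm[m, , drop = FALSE])
    obs <- tabulate(ds$own_choice[m], nbins = 3L) / sum(m)
    out[[i]] <- data.frame(condition = cells$condition[i],
                           preceding = cells$preceding[i],
                           net_size = 1:3,
                           predicted = as.numeric(pred),
                           observed = obs)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Export trial-wise reward prediction errors of the chosen option
#'
#' One row per trial with the chosen-option RPE under each subject's
#' fitted model (social RPE or sustainability RPE depending on the fitted
#' model), suitable as a parametric-modulator column. The first trial of
#' every session uses the initial values `Q0` as the expectation.
#'
#' @param fits A [fit_population()] data frame.
#' @param dataset Behavioral dataset.
#' @param config A [cpr_config()].
#' @return Data frame with columns `subject_id`, `condition`, `session`,
#'   `trial`, `model`, `rpe_chosen`.
#' @export
export_rpe_regressors <- function(fits, dataset, config = cpr_config()) {
  tr <- fitted_trace(fits, dataset, config)
  model_of <- stats::setNames(fits$model, fits$subject_id)
  data.frame(subject_id = tr$subject_id, condition = tr$condition,
             session = tr$session, trial = tr$trial,
             model = unname(model_of[tr$subject_id]),
             rpe_chosen = tr$rpe_chosen)
}
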