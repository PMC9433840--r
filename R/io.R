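dataset_columns <- c("subject_id", "condition", "session", "trial",
                     "stock_pre", "own_choice", "own_payoff",
                     "other1_catch", "other2_catch", "outflow",
                     "stock_post_catch", "stock_next", "terminal")

# Short config hash for output provenance headers.
config_hash <- function(config) {
  s <- paste(vapply(config, function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = ";")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

#' Write a behavioral dataset as CSV
#'
#' The file starts with a `#`-prefixed provenance line recording the seed
#' and task-configuration hash, followed by the standard trial-log schema.
#'
#' @param dataset Behavioral dataset.
#' @param path Output path.
#' @param seed Seed used to generate the data (recorded in the header).
#' @param config A [cpr_config()].
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, seed = NA, config = cpr_config()) {
  stopifnot(all(dataset_columns %in% names(dataset)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cprlearn trial log; seed=%s; config=%s",
                     as.character(seed), config_hash(config)), con)
  utils::write.csv(dataset[, dataset_columns], con, row.names = FALSE)
  invisible(path)
}

#' Read and validate a behavioral dataset
#'
#' Checks the header schema, the choice codes, integer-valued catches and
#' the stock-consistency invariant `stock_next ==
#' replenish(stock_post_catch)`; malformed rows are reported with their
#' line numbers.
#'
#' @param path CSV file written by [write_dataset()] (or following the
#'   same schema; `#` lines are ignored).
#' @param config A [cpr_config()].
#' @return A validated behavioral dataset.
#' @export
read_dataset <- function(path, config = cpr_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, comment.char = "#",
                       stringsAsFactors = FALSE)
  missing <- setdiff(dataset_columns, names(d))
  if (length(missing))
    stop("schema mismatch; missing columns: ",
         paste(missing, collapse = ", "))
  # line numbers for diagnostics: header + comment offset
  n_comment <- 0L
  first <- readLines(path, n = 20L)
  n_comment <- sum(startsWith(first, "#"))
  lineno <- seq_len(nrow(d)) + n_comment + 1L
  problems <- character(0)
  int_cols <- c("session", "trial", "stock_pre", "own_choice",
                "own_payoff", "other1_catch", "other2_catch", "outflow",
                "stock_post_catch", "stock_next")
  for (col in int_cols) {
    bad <- which(!is.finite(d[[col]]) | d[[col]] != round(d[[col]]))
    if (length(bad))
      problems <- c(problems, sprintf("line %d: non-integer %s",
                                      lineno[bad], col))
  }
  if (!length(problems)) {
    bad <- which(!(d$own_choice %in% config$net_sizes))
    if (length(bad))
      problems <- c(problems,
                    sprintf("line %d: own_choice=%s outside net sizes",
                            lineno[bad], d$own_choice[bad]))
    bad <- which(d$stock_next !=
                   replenish(pmin(pmax(d$stock_post_catch, 0),
                                  config$capacity), config) |
                   d$stock_post_catch < 0 |
                   d$stock_post_catch > config$capacity)
    if (length(bad))
      problems <- c(problems,
                    sprintf("line %d: stock inconsistency (subject %s session %d trial %d)",
                            lineno[bad], d$subject_id[bad],
                            d$session[bad], d$trial[bad]))
    bad <- which(!(d$condition %in% c("social", "nonsocial")))
    if (length(bad))
      problems <- c(problems, sprintf("line %d: unknown condition",
                                      lineno[bad]))
  }
  if (length(problems))
    stop("invalid dataset:\n  ",
         paste(utils::head(problems, 10L), collapse = "\n  "))
  d$terminal <- as.logical(d$terminal)
  d
}

#' Read a run configuration from YAML
#'
#' Recognized top-level keys: `task` (fields of [cpr_config()]),
#' `distribution` (`support`, `probabilities`), `fitting` (`n_starts`,
#' `drop_last_trial`), `seed`.
#'
#' @param path YAML file.
#' @return A list with elements `config`, `dist`, `n_starts`,
#'   `drop_last_trial`, `seed`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  config <- do.call(cpr_config, y$task %||% list())
  dist <- if (!is.null(y$distribution))
    others_distribution(y$distribution$support,
                        y$distribution$probabilities)
  else others_distribution()
  list(config = config, dist = dist,
       n_starts = y$fitting$n_starts %||% 20L,
       drop_last_trial = isTRUE(y$fitting$drop_last_trial),
       seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
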