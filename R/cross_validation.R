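## The four prediction scenarios. Folds are hybrid-level: a hybrid is
## "tested" (its records enter training) or "untested" (all its records
## are withheld) consistently across environments within a repeat.
## CV2/CV1: train on tested hybrids in all environments, score tested
## (CV2) and untested (CV1) hybrids per environment. CV0/CV00: hold one
## environment out entirely, train on tested hybrids in the remaining
## environments, score tested (CV0) and untested (CV00) hybrids in the
## held-out environment. Prediction ability is the Pearson correlation
## between predicted and observed BLUEs.

#' Hybrid-level cross-validation fold plan
#'
#' Partitions the hybrid set into `k` folds, `repeats` times; fold sizes
#' differ by at most one. The same plan drives all four scenarios, so a
#' hybrid's tested/untested status is common to CV2/CV1/CV0/CV00.
#'
#' @param hybrids Character vector of hybrid identifiers.
#' @param k Number of folds (default 5).
#' @param repeats Number of repeats (default 20).
#' @param seed Integer seed.
#' @return An object of class `fold_plan`: `assignment` is a hybrids x
#'   repeats integer matrix of fold indices.
#' @export
make_folds <- function(hybrids, k = 5L, repeats = 20L, seed = 1L) {
  n <- length(hybrids)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("need at least k hybrids")
  set.seed(seed)
  assignment <- vapply(seq_len(repeats), function(r)
    sample(rep_len(seq_len(k), n)), integer(n))
  rownames(assignment) <- hybrids
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seed = as.integer(seed), assignment = assignment),
            class = "fold_plan")
}

#' Pearson prediction ability
#'
#' @param predicted,observed Numeric vectors of equal length (>= 3),
#'   finite, each with positive variance.
#' @return Pearson correlation in \[-1, 1\].
#' @export
prediction_ability <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 3L)
    stop("need >= 3 paired values")
  if (!all(is.finite(predicted)) || !all(is.finite(observed)))
    stop("inputs must be finite")
  if (stats::sd(predicted) < 1e-12 || stats::sd(observed) < 1e-12)
    stop("prediction ability undefined for zero-variance input")
  stats::cor(predicted, observed)
}

#' Bundle responses and kernel sets for cross-validation
#'
#' @param blues BLUE table covering all environments of the population
#'   (one trait).
#' @param kernel_sets Named list of `kernel_set` objects (names are model
#'   ids), all sharing one record ordering.
#' @param secondary Optional named vector (by `hybrid@environment` id) of
#'   the complete secondary trait for M6.
#' @return An object of class `cv_data`.
#' @export
build_cv_data <- function(blues, kernel_sets, secondary = NULL) {
  if (!length(kernel_sets)) stop("no kernel sets supplied")
  records <- kernel_sets[[1]]$records
  ids <- .record_ids(records)
  for (ks in kernel_sets) {
    if (!identical(.record_ids(ks$records), ids))
      stop("kernel sets do not share a record ordering")
  }
  y <- stats::setNames(rep(NA_real_, length(ids)), ids)
  bid <- paste(blues$hybrid, blues$environment, sep = "@")
  y[intersect(bid, ids)] <- blues$blue[match(intersect(bid, ids), bid)]
  if (!is.null(secondary)) {
    if (!all(ids %in% names(secondary)))
      stop("secondary trait must cover every record")
    secondary <- secondary[ids]
  }
  structure(list(records = records, ids = ids, y = y,
                 secondary = secondary, kernel_sets = kernel_sets),
            class = "cv_data")
}

.fit_one <- function(data, model, y_train, config, seed_offset) {
  ks <- data$kernel_sets[[model]]
  cfg <- config
  cfg$seed <- config$seed + seed_offset
  if (ks$multitrait) {
    if (is.null(data$secondary))
      stop("model ", model, " needs a secondary trait in cv_data")
    fit_multitrait(cbind(y_train, data$secondary), ks, cfg)
  } else {
    fit_rkhs(y_train, ks, cfg)
  }
}

.score_env <- function(res, preds, data, hyb_sets, scenarios, model,
                       rp, fold, envs) {
  for (env in envs) {
    for (s in seq_along(scenarios)) {
      sel <- data$records$environment == env &
        data$records$hybrid %in% hyb_sets[[s]] & !is.na(data$y)
      if (sum(sel) < 3L) next
      r <- tryCatch(prediction_ability(preds[sel], data$y[sel]),
                    error = function(e) NA_real_)
      res[[length(res) + 1L]] <- data.frame(
        model_id = model, scenario = scenarios[s], environment = env,
        rep = rp, fold = fold, r = r, n = sum(sel),
        stringsAsFactors = FALSE)
    }
  }
  res
}

#' Within-environment prediction scenarios CV2 and CV1
#'
#' Per repeat and fold: the fold's hybrids are the untested set; their
#' responses are withheld in every environment and the models are trained
#' on the tested hybrids' records from all environments. Prediction
#' ability is computed per environment for tested hybrids (CV2) and
#' untested hybrids (CV1).
#'
#' @param data A [build_cv_data()] bundle.
#' @param models Character vector of model ids to run (must exist in
#'   `data$kernel_sets`).
#' @param foldplan A [make_folds()] plan.
#' @param config A [gibbs_config()]; each fit derives its own chain seed
#'   from it.
#' @param repeats Number of repeats actually run (default all in the
#'   plan).
#' @return Data frame (`model_id`, `scenario`, `environment`, `rep`,
#'   `fold`, `r`, `n`).
#' @export
run_within_env <- function(data, models, foldplan, config = gibbs_config(),
                           repeats = foldplan$repeats) {
  stopifnot(inherits(data, "cv_data"), inherits(foldplan, "fold_plan"))
  miss <- setdiff(models, names(data$kernel_sets))
  if (length(miss)) stop("no kernel set for model(s): ",
                         paste(miss, collapse = ", "))
  envs <- unique(data$records$environment)
  hybrids <- rownames(foldplan$assignment)
  res <- list()
  for (rp in seq_len(min(repeats, foldplan$repeats))) {
    for (fold in seq_len(foldplan$k)) {
      untested <- hybrids[foldplan$assignment[, rp] == fold]
      tested <- setdiff(hybrids, untested)
      y_train <- data$y
      y_train[data$records$hybrid %in% untested] <- NA
      for (model in models) {
        fit <- .fit_one(data, model, y_train, config,
                        seed_offset = 1000L * rp + 10L * fold +
                          match(model, models))
        preds <- fit$fitted
        res <- .score_env(res, preds, data, list(tested, untested),
                          c("CV2", "CV1"), model, rp, fold, envs)
      }
    }
  }
  do.call(rbind, res)
}

#' Leave-one-environment-out scenarios CV0 and CV00
#'
#' Each environment serves once as the held-out (untested) environment:
#' models are trained on tested hybrids' records from the remaining
#' environments only (untested hybrids are excluded everywhere, so no
#' genotype information leaks), then scored in the held-out environment
#' for tested hybrids (CV0) and untested hybrids (CV00).
#'
#' @inheritParams run_within_env
#' @return Data frame as in [run_within_env()], `environment` being the
#'   held-out environment.
#' @export
run_leave_one_env <- function(data, models, foldplan,
                              config = gibbs_config(),
                              repeats = foldplan$repeats) {
  stopifnot(inherits(data, "cv_data"), inherits(foldplan, "fold_plan"))
  envs <- unique(data$records$environment)
  if (length(envs) < 2L) stop("leave-one-environment-out needs >= 2 environments")
  miss <- setdiff(models, names(data$kernel_sets))
  if (length(miss)) stop("no kernel set for model(s): ",
                         paste(miss, collapse = ", "))
  hybrids <- rownames(foldplan$assignment)
  res <- list()
  for (held in envs) {
    for (rp in seq_len(min(repeats, foldplan$repeats))) {
      for (fold in seq_len(foldplan$k)) {
        untested <- hybrids[foldplan$assignment[, rp] == fold]
        tested <- setdiff(hybrids, untested)
        y_train <- data$y
        y_train[data$records$environment == held |
                  data$records$hybrid %in% untested] <- NA
        for (model in models) {
          fit <- .fit_one(data, model, y_train, config,
                          seed_offset = 100000L * match(held, envs) +
                            1000L * rp + 10L * fold + match(model, models))
          res <- .score_env(res, fit$fitted, data, list(tested, untested),
                            c("CV0", "CV00"), model, rp, fold, held)
        }
      }
    }
  }
  do.call(rbind, res)
}

#' Summarize prediction abilities
#'
#' Mean and standard deviation of prediction ability per model and
#' scenario, pooled over environments, repeats and folds.
#'
#' @param results Data frame from [run_within_env()] /
#'   [run_leave_one_env()] (rows may be concatenated).
#' @param by Grouping columns (default model and scenario).
#' @return Data frame with `mean_r`, `sd_r` and `n_cells`.
#' @export
summarize_cv <- function(results, by = c("model_id", "scenario")) {
  ok <- !is.na(results$r)
  agg <- stats::aggregate(results$r[ok], results[ok, by, drop = FALSE],
                          function(v) c(mean = mean(v), sd = stats::sd(v),
                                        n = length(v)))
  out <- cbind(agg[by], as.data.frame(agg$x))
  names(out)[names(out) %in% c("mean", "sd", "n")] <-
    c("mean_r", "sd_r", "n_cells")
  out[do.call(order, out[by]), , drop = FALSE]
}
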