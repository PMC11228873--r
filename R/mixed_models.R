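## Stage-1 mixed models: hybrid BLUEs, entry-mean heritability, and
## hybrid-by-flight temporal BLUPs. Variance components are estimated by
## REML (lme4); BLUEs/BLUPs are the GLS / Henderson mixed-model-equation
## solutions at the converged variances, which is what lme4 returns.

.as_factor_cols <- function(data, cols) {
  for (cl in cols) data[[cl]] <- factor(data[[cl]])
  data
}

# random-intercept terms with >= 2 levels only; lme4 cannot fit the rest
.usable_random <- function(data, terms) {
  keep <- vapply(terms, function(tm) {
    v <- interaction(data[strsplit(tm, ":", fixed = TRUE)[[1]]], drop = TRUE)
    nlevels(v) >= 2L
  }, logical(1))
  terms[keep]
}

.fit_lmm <- function(formula, data, max_iter = 500L) {
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = "ignore",
    optCtrl = list(maxfun = max(1000L, 50L * max_iter)))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(formula, data = data, REML = TRUE, control = ctrl)))
  conv <- length(fit@optinfo$conv$lme4) == 0L &&
    (is.null(fit@optinfo$conv$opt) || fit@optinfo$conv$opt == 0L)
  list(fit = fit, converged = conv,
       iterations = as.integer(fit@optinfo$feval %||% NA_integer_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.varcomp <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  out <- stats::setNames(vc$vcov, vc$grp)
  names(out)[names(out) == "Residual"] <- "residual"
  out
}

#' REML mixed-model solver
#'
#' Fits a Gaussian linear mixed model with simple random-intercept terms by
#' REML and returns variance components, fixed-effect (GLS) solutions and
#' random-effect (BLUP) predictions at the converged variances. This is the
#' engine behind the per-environment trait and temporal vegetation-index
#' models.
#'
#' @param response Numeric response vector (length `nrow(data)`); missing
#'   values are dropped row-wise.
#' @param data Data frame holding the design columns.
#' @param fixed Character vector of fixed-term column names (coerced to
#'   factors unless numeric), or `NULL` for intercept-only.
#' @param random Character vector of random-intercept terms; interactions
#'   written `"a:b"`. Terms with fewer than 2 observed levels are dropped
#'   (their variance is not identifiable) with a message.
#' @param tol Convergence tolerance forwarded to the optimizer.
#' @param max_iter Maximum optimizer evaluations (scaled internally).
#' @param constrain_zero If `TRUE`, all random variances are fixed at 0 and
#'   the fixed effects are the ordinary least-squares solutions.
#' @return List with `varcomp` (named variances incl. `residual`),
#'   `fixef`, `ranef` (named list of named vectors), `fitted`, `converged`,
#'   `iterations`, and the underlying `fit` object (or `NULL`).
#' @export
solve_reml <- function(response, data, fixed = NULL, random = character(),
                       tol = 1e-6, max_iter = 500L, constrain_zero = FALSE) {
  stopifnot(length(response) == nrow(data))
  keep <- !is.na(response)
  if (!any(keep)) stop("response is entirely missing")
  data <- data[keep, , drop = FALSE]
  data$.y <- response[keep]
  fchar <- Filter(function(cl) !is.numeric(data[[cl]]), fixed)
  data <- .as_factor_cols(data, unique(c(
    fchar, unlist(strsplit(random, ":", fixed = TRUE)))))

  fixed_part <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  Xf <- stats::model.matrix(stats::as.formula(paste("~", fixed_part)), data)
  if (qr(Xf)$rank < ncol(Xf))
    stop("fixed design is rank deficient after coding")

  # degenerate input: constant response needs no variance estimation
  if (stats::sd(data$.y) < 1e-12) {
    vc <- stats::setNames(rep(0, length(random) + 1L),
                          c(random, "residual"))
    re <- lapply(stats::setNames(random, random), function(tm) {
      lv <- levels(interaction(data[strsplit(tm, ":", fixed = TRUE)[[1]]],
                               drop = TRUE, sep = ":"))
      stats::setNames(rep(0, length(lv)), lv)
    })
    beta <- stats::setNames(rep(0, ncol(Xf)), colnames(Xf))
    beta[1] <- data$.y[1]
    return(list(varcomp = vc, fixef = beta, ranef = re,
                fitted = rep(data$.y[1], nrow(data)),
                converged = TRUE, iterations = 0L, fit = NULL))
  }

  random <- .usable_random(data, random)
  if (constrain_zero || !length(random)) {
    fit <- stats::lm(stats::as.formula(paste(".y ~", fixed_part)), data = data)
    vc <- stats::setNames(rep(0, length(random)), random)
    vc["residual"] <- summary(fit)$sigma^2
    return(list(varcomp = vc, fixef = stats::coef(fit),
                ranef = lapply(stats::setNames(random, random),
                               function(tm) numeric(0)),
                fitted = stats::fitted(fit), converged = TRUE,
                iterations = 0L, fit = fit))
  }

  fml <- stats::as.formula(paste(
    ".y ~", fixed_part, "+",
    paste(sprintf("(1 | %s)", random), collapse = " + ")))
  res <- .fit_lmm(fml, data, max_iter)
  fit <- res$fit
  re <- lapply(lme4::ranef(fit), function(df)
    stats::setNames(df[["(Intercept)"]], rownames(df)))
  list(varcomp = .varcomp(fit), fixef = lme4::fixef(fit), ranef = re,
       fitted = stats::fitted(fit), converged = res$converged,
       iterations = res$iterations, fit = fit)
}

.check_plots <- function(plots) {
  need <- c("hybrid", "environment", "range", "row", "rep")
  miss <- setdiff(need, names(plots))
  if (length(miss)) stop("plot table lacks columns: ",
                         paste(miss, collapse = ", "))
  invisible(plots)
}

#' Hybrid BLUEs for one trait and environment
#'
#' Fits, per environment, the trial model
#' `y = mu + Hybrid + Range + Row + Rep + error` with hybrid fixed and the
#' design terms (range, row, replication) random, and returns one best
#' linear unbiased estimate per hybrid on the trait scale (grand mean plus
#' hybrid effect).
#'
#' @param plots Plot table (data frame with `hybrid`, `environment`,
#'   `range`, `row`, `rep` and the trait column).
#' @param trait `"gy"` (grain yield, t/ha) or `"pht"` (plant height, cm).
#' @param environment Environment label to fit.
#' @return Data frame (`hybrid`, `environment`, `trait`, `blue`), one row
#'   per hybrid with a non-missing trait observation.
#' @export
fit_blues <- function(plots, trait = c("gy", "pht"), environment) {
  trait <- match.arg(trait)
  .check_plots(plots)
  d <- plots[plots$environment == environment & !is.na(plots[[trait]]), ]
  if (!nrow(d)) stop("no non-missing '", trait, "' observations in ",
                     environment)
  if (length(unique(d$hybrid)) < 2L) stop("need >= 2 hybrids with data")
  d <- .as_factor_cols(d, c("hybrid", "range", "row", "rep"))
  d$.y <- d[[trait]]

  hyb_means <- tapply(d$.y, d$hybrid, mean)
  within_dev <- d$.y - hyb_means[as.character(d$hybrid)]
  if (max(abs(within_dev)) < 1e-10) {
    blue <- hyb_means            # noise-free: BLUE is the replicate mean
  } else {
    rnd <- .usable_random(d, c("range", "row", "rep"))
    fml <- stats::as.formula(paste(
      ".y ~ 0 + hybrid",
      if (length(rnd)) paste("+", paste(sprintf("(1 | %s)", rnd),
                                        collapse = " + ")) else ""))
    fit <- .fit_lmm(fml, d)$fit
    beta <- lme4::fixef(fit)
    names(beta) <- sub("^hybrid", "", names(beta))
    blue <- beta[levels(d$hybrid)]
  }
  data.frame(hybrid = names(blue), environment = environment,
             trait = trait, blue = as.numeric(blue),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Entry-mean heritability from a fully random trial model
#'
#' Refits the trial model with every term (including hybrid) random and
#' returns `sigma2_H / (sigma2_H + sigma2_e / r)` with `r` the number of
#' replications — the entry-mean heritability of the trait in that
#' environment. Range/row/rep variances do not enter the denominator.
#'
#' @inheritParams fit_blues
#' @return Heritability in \[0, 1\].
#' @export
estimate_heritability <- function(plots, trait = c("gy", "pht"), environment) {
  trait <- match.arg(trait)
  .check_plots(plots)
  d <- plots[plots$environment == environment & !is.na(plots[[trait]]), ]
  if (!nrow(d)) stop("no non-missing '", trait, "' observations in ",
                     environment)
  n_reps <- length(unique(d$rep))
  if (n_reps < 2L) stop("heritability needs >= 2 replications")
  d <- .as_factor_cols(d, c("hybrid", "range", "row", "rep"))
  d$.y <- d[[trait]]

  hyb_means <- tapply(d$.y, d$hybrid, mean)
  within_dev <- d$.y - hyb_means[as.character(d$hybrid)]
  if (max(abs(within_dev)) < 1e-10) {
    # zero residual variance: heritability is 1 when hybrids differ at all
    return(if (stats::sd(d$.y) < 1e-12) NA_real_ else 1)
  }
  rnd <- .usable_random(d, c("hybrid", "range", "row", "rep"))
  fml <- stats::as.formula(paste(
    ".y ~ 1 +", paste(sprintf("(1 | %s)", rnd), collapse = " + ")))
  vc <- .varcomp(.fit_lmm(fml, d)$fit)
  s2h <- vc["hybrid"] %||% 0
  if (is.na(s2h)) s2h <- 0
  unname(s2h / (s2h + vc["residual"] / n_reps))
}

#' Temporal hybrid-by-flight BLUPs for vegetation indices
#'
#' Fits, per vegetation index and environment, the fully random model
#' `V = mu + Hybrid + Flight + Hybrid:Flight + Range + Row + Rep + error`
#' and returns the BLUPs of the hybrid-by-flight interaction — the
#' "temporal value" of each hybrid at each flight, shrunk toward zero.
#' The output grid is complete (every hybrid at every flight) even when a
#' plot observation is missing.
#'
#' All indices share one model structure within an environment, so after
#' the first REML fit the remaining indices are refit on the same design
#' (a fresh fit is used automatically if missingness patterns differ).
#'
#' @param vi_obs Temporal VI table (data frame with `hybrid`,
#'   `environment`, `flight_dap`, `vi_name`, `range`, `row`, `rep`,
#'   `value`).
#' @param vi_names Indices to fit; default all present in `environment`.
#' @param environment Environment label.
#' @return Data frame (`hybrid`, `environment`, `vi_name`, `flight_dap`,
#'   `blup`) covering the full hybrid-by-flight grid per index, plus a
#'   `blup_hybrid` column carrying the hybrid main-effect BLUP (constant
#'   across flights); `blup + blup_hybrid` is the hybrid's full temporal
#'   deviation at a flight, used by [temporal_correlation()].
#' @export
fit_temporal_blups <- function(vi_obs, vi_names = NULL, environment) {
  need <- c("hybrid", "environment", "flight_dap", "vi_name", "value")
  miss <- setdiff(need, names(vi_obs))
  if (length(miss)) stop("VI table lacks columns: ",
                         paste(miss, collapse = ", "))
  d_env <- vi_obs[vi_obs$environment == environment, ]
  if (!nrow(d_env)) stop("no VI observations in environment ", environment)
  present <- unique(d_env$vi_name)
  if (is.null(vi_names)) vi_names <- sort(present)
  unknown <- setdiff(vi_names, present)
  if (length(unknown)) stop("unknown VI(s) in ", environment, ": ",
                            paste(unknown, collapse = ", "))

  hybrids <- sort(unique(d_env$hybrid))
  daps <- sort(unique(d_env$flight_dap))
  if (length(hybrids) < 2L || length(daps) < 2L)
    stop("need >= 2 hybrids and >= 2 flights")

  base_fit <- NULL
  base_key <- NULL
  out <- vector("list", length(vi_names))
  for (vi in seq_along(vi_names)) {
    d <- d_env[d_env$vi_name == vi_names[vi] & !is.na(d_env$value), ]
    d <- d[order(d$hybrid, d$flight_dap, d$rep, d$range, d$row), ]
    d <- .as_factor_cols(d, c("hybrid", "range", "row", "rep"))
    d$flight <- factor(d$flight_dap, levels = daps)
    d$hf <- interaction(d$hybrid, d$flight, sep = ":", drop = FALSE)
    key <- paste(d$hybrid, d$flight_dap, d$rep, sep = "/")

    if (!is.null(base_fit) && identical(key, base_key)) {
      fit <- suppressMessages(suppressWarnings(lme4::refit(base_fit, d$value)))
    } else {
      rnd <- .usable_random(d, c("hybrid", "flight", "hf",
                                 "range", "row", "rep"))
      fml <- stats::as.formula(paste(
        "value ~ 1 +", paste(sprintf("(1 | %s)", rnd), collapse = " + ")))
      fit <- .fit_lmm(fml, d)$fit
      base_fit <- fit
      base_key <- key
    }
    re <- lme4::ranef(fit)
    blup <- stats::setNames(re$hf[["(Intercept)"]], rownames(re$hf))
    blup_h <- stats::setNames(re$hybrid[["(Intercept)"]],
                              rownames(re$hybrid))
    grid_keys <- as.vector(outer(hybrids, daps, paste, sep = ":"))
    vals <- blup[grid_keys]
    vals[is.na(vals)] <- 0        # unobserved cells shrink fully to zero
    vals_h <- blup_h[rep(hybrids, times = length(daps))]
    vals_h[is.na(vals_h)] <- 0
    out[[vi]] <- data.frame(
      hybrid = rep(hybrids, times = length(daps)),
      environment = environment, vi_name = vi_names[vi],
      flight_dap = rep(daps, each = length(hybrids)),
      blup = as.numeric(vals), blup_hybrid = as.numeric(vals_h),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
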