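## Functional PCA of temporal BLUP curves. Curves live on a common,
## environment-specific flight grid (days after planting), so the
## Karhunen-Loeve decomposition V(t) = mu(t) + sum_k xi_k phi_k(t) is
## computed exactly at the observed design: eigendecomposition of the
## trapezoid-quadrature-weighted sample covariance. Eigenfunctions are
## orthonormal in the weighted inner product; scores are weighted inner
## products of the centered curves with the eigenfunctions.

.trapezoid_weights <- function(grid) {
  m <- length(grid)
  if (m < 2L) stop("need >= 2 grid points")
  w <- numeric(m)
  w[1] <- (grid[2] - grid[1]) / 2
  w[m] <- (grid[m] - grid[m - 1]) / 2
  if (m > 2L) w[2:(m - 1)] <- (grid[3:m] - grid[1:(m - 2)]) / 2
  w
}

#' Functional principal component analysis of temporal curves
#'
#' Decomposes hybrid-level temporal curves (one value per flight DAP) into
#' a mean curve, orthonormal eigenfunctions and per-hybrid scores. All
#' components are retained; downstream phenomic analyses use the first
#' two scores per vegetation index.
#'
#' @param curves Numeric matrix, hybrids (rows, named) by grid points.
#' @param dap_grid Ascending numeric vector of flight DAPs, one per column.
#' @param window_daps Optional subset of `dap_grid` to restrict to (e.g.
#'   flights until flowering); default all flights. At least 2 in-window
#'   grid points are required.
#' @param vi_name,environment,window Optional labels stored in the model.
#' @return An object of class `fpca_model`: `dap_grid`, `weights`
#'   (trapezoid quadrature), `mean_curve`, `eigenfunctions` (columns
#'   `phi_k`, sign-fixed so each function's largest-magnitude value is
#'   positive), `eigenvalues` (non-increasing, >= 0), `scores` (hybrids by
#'   components), `explained_fractions`, plus the labels.
#' @export
fit_fpca <- function(curves, dap_grid, window_daps = NULL,
                     vi_name = NA_character_, environment = NA_character_,
                     window = "full") {
  stopifnot(is.matrix(curves), ncol(curves) == length(dap_grid))
  if (nrow(curves) < 2L) stop("need >= 2 hybrids")
  if (is.unsorted(dap_grid, strictly = TRUE))
    stop("dap_grid must be strictly increasing")
  if (!is.null(window_daps)) {
    keep <- dap_grid %in% window_daps
    if (sum(keep) < 2L) stop("fewer than 2 flights inside the window")
    curves <- curves[, keep, drop = FALSE]
    dap_grid <- dap_grid[keep]
  }
  m <- ncol(curves)
  n <- nrow(curves)
  w <- .trapezoid_weights(dap_grid)
  mu <- colMeans(curves)
  C <- sweep(curves, 2L, mu)
  S <- crossprod(C) / (n - 1)
  sw <- sqrt(w)
  K <- S * tcrossprod(sw)                    # W^(1/2) S W^(1/2)
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  lambda <- pmax(eg$values, 0)
  phi <- eg$vectors / sw                     # rows scaled by W^(-1/2)
  # sign convention: largest-magnitude grid value of each phi_k positive
  for (k in seq_len(m)) {
    j <- which.max(abs(phi[, k]))
    if (phi[j, k] < 0) phi[, k] <- -phi[, k]
  }
  scores <- C %*% (w * phi)
  tot <- sum(lambda)
  dimnames(phi) <- list(paste0("t", dap_grid), paste0("phi", seq_len(m)))
  dimnames(scores) <- list(rownames(curves), paste0("FPCA", seq_len(m)))
  structure(list(vi_name = vi_name, environment = environment,
                 window = window, dap_grid = dap_grid, weights = w,
                 mean_curve = mu, eigenfunctions = phi,
                 eigenvalues = lambda, scores = scores,
                 explained_fractions =
                   if (tot > 0) lambda / tot else rep(0, m)),
            class = "fpca_model")
}

#' @export
print.fpca_model <- function(x, ...) {
  cat(sprintf("FPCA model%s%s: %d hybrids, %d flights (%s window)\n",
              if (is.na(x$vi_name)) "" else paste0(" for ", x$vi_name),
              if (is.na(x$environment)) "" else paste0(" in ", x$environment),
              nrow(x$scores), length(x$dap_grid), x$window))
  cat("  explained by first 2 components:",
      sprintf("%.1f%%", 100 * sum(x$explained_fractions[1:min(2, length(x$explained_fractions))])),
      "\n")
  invisible(x)
}

#' Reshape a temporal BLUP table into a curve matrix
#'
#' @param blups Table from [fit_temporal_blups()].
#' @param vi_name,environment Which index/environment to extract.
#' @return List with `curves` (hybrids by flights matrix) and `dap_grid`.
#' @export
blups_to_curves <- function(blups, vi_name, environment) {
  b <- blups[blups$vi_name == vi_name & blups$environment == environment, ]
  if (!nrow(b)) stop("no BLUPs for ", vi_name, " in ", environment)
  hybrids <- sort(unique(b$hybrid))
  daps <- sort(unique(b$flight_dap))
  M <- matrix(NA_real_, length(hybrids), length(daps),
              dimnames = list(hybrids, daps))
  M[cbind(match(b$hybrid, hybrids), match(b$flight_dap, daps))] <- b$blup
  if (anyNA(M)) stop("incomplete hybrid x flight grid for ", vi_name)
  list(curves = M, dap_grid = daps)
}

#' Fit FPCA for every vegetation index in one environment and window
#'
#' @param blups Temporal BLUP table.
#' @param environment Environment label.
#' @param window `"full"` (all flights) or `"until_flowering"` (flights
#'   with DAP at or before `flowering_start_dap`).
#' @param flowering_start_dap Required for the until-flowering window.
#' @param vi_names Indices to fit; default all in the table.
#' @return Named list of `fpca_model` objects.
#' @export
fit_fpca_env <- function(blups, environment,
                         window = c("full", "until_flowering"),
                         flowering_start_dap = NULL, vi_names = NULL) {
  window <- match.arg(window)
  b <- blups[blups$environment == environment, ]
  if (!nrow(b)) stop("no BLUPs in environment ", environment)
  if (is.null(vi_names)) vi_names <- sort(unique(b$vi_name))
  daps <- sort(unique(b$flight_dap))
  wdaps <- if (window == "until_flowering") {
    if (is.null(flowering_start_dap))
      stop("flowering_start_dap required for the until-flowering window")
    daps[daps <= flowering_start_dap]
  } else daps
  models <- lapply(vi_names, function(vn) {
    cv <- blups_to_curves(b, vn, environment)
    fit_fpca(cv$curves, cv$dap_grid, window_daps = wdaps,
             vi_name = vn, environment = environment, window = window)
  })
  stats::setNames(models, vi_names)
}

#' Cumulative explained-variance summary over FPCA models
#'
#' @param models List of `fpca_model` objects (e.g. all VIs of an
#'   environment).
#' @param k Number of leading components to accumulate (default 2).
#' @return List with `per_model` (data frame: vi_name, environment,
#'   window, fraction) and the grand `mean` and `sd` of the fractions.
#' @export
explained_variance_summary <- function(models, k = 2L) {
  if (k < 1L) stop("k must be >= 1")
  per <- do.call(rbind, lapply(models, function(m) {
    data.frame(vi_name = m$vi_name, environment = m$environment,
               window = m$window,
               fraction = sum(m$explained_fractions[
                 seq_len(min(k, length(m$explained_fractions)))]),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_model = per, mean = mean(per$fraction),
       sd = if (nrow(per) > 1L) stats::sd(per$fraction) else 0)
}

#' Assemble the per-environment FPCA score matrix
#'
#' Binds the first two FPCA scores of every vegetation index into one
#' table: one row per hybrid, two columns per index (`<VI>.FPCA1`,
#' `<VI>.FPCA2`), columns in canonical (alphabetical) VI order. Identical
#' column names across environments are what make score matrices from
#' environments with different flight schedules mergeable.
#'
#' @param models Named list of `fpca_model` objects, one per VI, fitted on
#'   the same hybrid set.
#' @return An object of class `score_matrix`: data frame with `hybrid`,
#'   `environment`, then the score columns.
#' @export
build_score_matrix <- function(models) {
  if (!length(models)) stop("no FPCA models supplied")
  vis <- sort(vapply(models, `[[`, character(1), "vi_name"))
  models <- models[order(vapply(models, `[[`, character(1), "vi_name"))]
  hybrids <- rownames(models[[1]]$scores)
  env <- models[[1]]$environment
  for (m in models) {
    if (!identical(rownames(m$scores), hybrids))
      stop("hybrid sets differ across VI models; cannot align scores")
  }
  cols <- lapply(models, function(m) m$scores[, 1:2, drop = FALSE])
  M <- do.call(cbind, cols)
  colnames(M) <- as.vector(t(outer(vis, c("FPCA1", "FPCA2"), paste, sep = ".")))
  out <- data.frame(hybrid = hybrids, environment = env, M,
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_matrix", "data.frame")
  out
}

.score_cols <- function(sm) setdiff(names(sm), c("hybrid", "environment"))

#' Merge per-environment score matrices row-wise
#'
#' Score matrices share column names regardless of each environment's
#' flight schedule, so they concatenate row-wise into one multi-year,
#' multi-trial phenomic data set keyed by (hybrid, environment).
#'
#' @param matrices List of [build_score_matrix()] results.
#' @return A `score_matrix` with `sum(nrow)` rows, columns in canonical
#'   order.
#' @export
merge_environments <- function(matrices) {
  if (!length(matrices)) stop("nothing to merge")
  canon <- sort(.score_cols(matrices[[1]]))
  for (sm in matrices) {
    if (!setequal(.score_cols(sm), canon))
      stop("score column labels differ across environments")
  }
  out <- do.call(rbind, lapply(matrices, function(sm)
    sm[, c("hybrid", "environment", canon), drop = FALSE]))
  rownames(out) <- NULL
  class(out) <- c("score_matrix", "data.frame")
  out
}
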