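## Relationship kernels at the hybrid-by-environment record level.
## Genomic: G = Xc Xc' / p with columns centered and standardized
## (population denominator), so trace(G)/n = 1. Phenomic: the same
## construction on FPCA score columns, divisor 2 x 36 when all indices are
## present. Environment: scaled block indicator. Interactions: Hadamard
## products of the environment indicator with the (record-expanded)
## genomic or phenomic kernel, per the reaction-norm construction.

.standardize_cols <- function(M, label = "column") {
  mu <- colMeans(M)
  Mc <- sweep(M, 2L, mu)
  sdp <- sqrt(colMeans(Mc^2))               # population denominator
  keep <- sdp > 1e-12
  if (!any(keep)) stop("all ", label, "s are constant")
  if (!all(keep))
    warning(sum(!keep), " constant ", label, "(s) dropped; divisor reduced")
  sweep(Mc[, keep, drop = FALSE], 2L, sdp[keep], `/`)
}

#' Genomic relationship matrix
#'
#' `G = Xc Xc' / p` from the 0/1/2 marker matrix with columns centered and
#' standardized (population variance); monomorphic markers are dropped.
#' `trace(G)/n = 1` exactly, which puts genomic and phenomic variance
#' components on a comparable scale.
#'
#' @param markers Hybrids x markers matrix, entries 0/1/2, hybrid row
#'   names.
#' @return Symmetric hybrid-level kernel with dimnames.
#' @export
genomic_relationship <- function(markers) {
  if (nrow(markers) < 2L) stop("need >= 2 hybrids")
  if (!all(markers %in% c(0, 1, 2)))
    stop("marker codes must be 0/1/2")
  Xs <- tryCatch(.standardize_cols(markers, "marker"),
                 error = function(e) stop("no polymorphic markers"))
  G <- tcrossprod(Xs) / ncol(Xs)
  dimnames(G) <- list(rownames(markers), rownames(markers))
  (G + t(G)) / 2
}

#' Phenomic relationship matrix from FPCA scores
#'
#' `P = Rc Rc' / (2 x 36)` on the centered, standardized score columns
#' (two FPCA scores for each of the 36 vegetation indices); constant
#' columns are dropped with a warning and the divisor reduced to the
#' number of columns actually used. Rows are hybrid-by-environment
#' records, so a merged multi-environment score matrix yields the
#' record-level phenomic kernel directly.
#'
#' @param scores A [build_score_matrix()] / [merge_environments()] result,
#'   or a plain numeric matrix of score columns.
#' @return Symmetric record-level kernel; record labels
#'   `hybrid@environment` when available.
#' @export
phenomic_relationship <- function(scores) {
  if (inherits(scores, "score_matrix") ||
      (is.data.frame(scores) && all(c("hybrid", "environment") %in% names(scores)))) {
    lab <- paste(scores$hybrid, scores$environment, sep = "@")
    M <- as.matrix(scores[, .score_cols(scores), drop = FALSE])
  } else {
    M <- as.matrix(scores)
    lab <- rownames(M)
  }
  if (nrow(M) < 2L) stop("need >= 2 rows")
  Rs <- .standardize_cols(M, "score column")
  P <- tcrossprod(Rs) / ncol(Rs)
  dimnames(P) <- list(lab, lab)
  (P + t(P)) / 2
}

#' Environment kernel
#'
#' Scaled block indicator `Z_E Z_E' / n_env`: records in the same
#' environment covary at `1/n_env`, records in different environments at
#' 0.
#'
#' @param records Data frame with `hybrid` and `environment` columns
#'   defining the record order.
#' @param scaled If `FALSE`, returns the raw 0/1 same-environment
#'   indicator (the Hadamard factor for interaction kernels).
#' @return Symmetric record-level kernel.
#' @export
environment_kernel <- function(records, scaled = TRUE) {
  env <- as.character(records$environment)
  n_env <- length(unique(env))
  ind <- outer(env, env, `==`) * 1
  lab <- paste(records$hybrid, env, sep = "@")
  dimnames(ind) <- list(lab, lab)
  if (scaled) ind / n_env else ind
}

#' Hadamard interaction kernel
#'
#' Elementwise product of a main-effect kernel with the same-environment
#' indicator, divided by `divisor` (`n_env` for genomic-by-environment,
#' `n_env x 36 x 2` for phenomic-by-environment when the main kernel is
#' the unscaled `R R'`).
#'
#' @param main Record-level main-effect kernel.
#' @param env_indicator Unscaled 0/1 same-environment indicator
#'   ([environment_kernel()] with `scaled = FALSE`).
#' @param divisor Positive scaling count.
#' @return Symmetric record-level kernel.
#' @export
interaction_kernel <- function(main, env_indicator, divisor) {
  if (!all(dim(main) == dim(env_indicator)))
    stop("main kernel and environment indicator are not conformable")
  if (divisor <= 0) stop("divisor must be positive")
  K <- main * env_indicator / divisor
  (K + t(K)) / 2
}

# expand a hybrid-level kernel to hybrid-by-environment records
.expand_to_records <- function(G, records) {
  idx <- match(records$hybrid, rownames(G))
  if (anyNA(idx)) stop("records contain hybrids absent from the kernel")
  K <- G[idx, idx, drop = FALSE]
  lab <- paste(records$hybrid, records$environment, sep = "@")
  dimnames(K) <- list(lab, lab)
  K
}

#' Assemble the kernel set for one prediction model
#'
#' Builds the named covariance kernels entering each of the six
#' prediction models: M1 genomic (`E`, `g`, `gxE`); M2 early phenomic
#' (`E`, `P1`, `P1xE`); M3 all-flight phenomic (`E`, `P2`, `P2xE`); M4 =
#' M1 + M2's phenomic kernels; M5 = M1 + M3's; M6 uses M1's kernels with
#' a bivariate (multitrait) response. The hybrid-level genomic matrix is
#' expanded to records before the Hadamard interaction is formed.
#'
#' @param model_id One of `"M1"`..`"M6"`.
#' @param records Data frame (`hybrid`, `environment`) fixing record
#'   order.
#' @param G Hybrid-level genomic kernel (models M1, M4, M5, M6).
#' @param P1,P2 Record-level phenomic kernels, until-flowering and
#'   all-flight windows (models M2/M4 and M3/M5), aligned with `records`.
#'   Their own divisor (2 x number of VIs) is set by
#'   [phenomic_relationship()]; the interaction divides additionally by
#'   the number of environments.
#' @return An object of class `kernel_set`: list with `model_id`,
#'   `records`, `kernels` (named list), `multitrait` flag.
#' @export
assemble_model <- function(model_id = c("M1", "M2", "M3", "M4", "M5", "M6"),
                           records, G = NULL, P1 = NULL, P2 = NULL) {
  model_id <- match.arg(model_id)
  needs <- list(M1 = "G", M2 = "P1", M3 = "P2", M4 = c("G", "P1"),
                M5 = c("G", "P2"), M6 = "G")[[model_id]]
  have <- c(G = !is.null(G), P1 = !is.null(P1), P2 = !is.null(P2))
  if (!all(have[needs]))
    stop("model ", model_id, " requires kernel(s): ",
         paste(needs[!have[needs]], collapse = ", "))
  n_env <- length(unique(records$environment))
  ind <- environment_kernel(records, scaled = FALSE)
  ker <- list(E = ind / n_env)
  if ("G" %in% needs) {
    g_rec <- .expand_to_records(G, records)
    ker$g <- g_rec
    ker$gxE <- interaction_kernel(g_rec, ind, n_env)
  }
  for (pk in intersect(needs, c("P1", "P2"))) {
    P <- if (pk == "P1") P1 else P2
    if (!all(dim(P) == nrow(records)))
      stop(pk, " must be a record-level kernel aligned with records")
    ker[[pk]] <- P
    # P is already R R' / (2 n_vi); dividing by n_env completes
    # R R' / (n_env * n_vi * 2)
    ker[[paste0(pk, "xE")]] <- interaction_kernel(P, ind, n_env)
  }
  structure(list(model_id = model_id,
                 records = records[, c("hybrid", "environment")],
                 kernels = ker, multitrait = model_id == "M6"),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf("Kernel set %s (%s): %d records, kernels: %s\n",
              x$model_id, if (x$multitrait) "multitrait" else "univariate",
              nrow(x$records), paste(names(x$kernels), collapse = ", ")))
  invisible(x)
}
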