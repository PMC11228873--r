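## Bayesian kernel (RKHS) regression by Gibbs sampling. Each random
## effect u ~ N(0, K sigma2) is reparameterized through the kernel's
## eigendecomposition K = V D V' as u = B alpha with B = V D^(1/2) and
## alpha ~ N(0, I sigma2); because B'B = D is diagonal, each term's
## coefficient block has an independent conditional posterior and is
## sampled jointly in closed form. Variances carry scaled-inverse-chi2
## priors; missing responses are sampled by data augmentation, which is
## how unobserved records acquire predictions.

#' Gibbs sampler settings
#'
#' @param n_iter Total iterations (default 12000).
#' @param burn_in Burn-in iterations discarded (default 2000).
#' @param thin Keep every `thin`-th post-burn-in sample (default 5).
#' @param df0 Prior degrees of freedom per variance term (default 5).
#' @param R2 Prior proportion of response variance attributed to the
#'   non-residual terms jointly (default 0.5); prior scales are derived
#'   from it.
#' @param seed Integer seed; chains are reproducible from it.
#' @return An object of class `gibbs_config`.
#' @export
gibbs_config <- function(n_iter = 12000L, burn_in = 2000L, thin = 5L,
                         df0 = 5, R2 = 0.5, seed = 1L) {
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), df0 = df0, R2 = R2,
                 seed = as.integer(seed)), class = "gibbs_config")
}

# eigendecompose kernels, truncating at eigenvalue > 1e-8 * max
.kernel_bases <- function(kernels) {
  lapply(kernels, function(K) {
    eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
    mx <- max(eg$values)
    if (mx <= 0) stop("kernel has no positive eigenvalue")
    if (min(eg$values) < -1e-6 * mx)
      stop("kernel is not positive semi-definite")
    keep <- eg$values > 1e-8 * mx
    d <- eg$values[keep]
    list(B = eg$vectors[, keep, drop = FALSE] *
           rep(sqrt(d), each = nrow(K)), d = d, q = sum(keep))
  })
}

# effective sample size via the initial positive-autocorrelation estimator
.ess <- function(x) {
  n <- length(x)
  if (n < 10L || stats::sd(x) < 1e-12) return(n)
  rho <- stats::acf(x, lag.max = min(n - 1L, 100L), plot = FALSE)$acf[-1]
  neg <- which(rho < 0)
  if (length(neg)) rho <- rho[seq_len(neg[1] - 1L)]
  max(1, n / (1 + 2 * sum(rho)))
}

.record_ids <- function(records) paste(records$hybrid, records$environment,
                                       sep = "@")

#' Fit a univariate Bayesian kernel regression (models M1-M5)
#'
#' Gibbs sampler for `y = mu + sum_k u_k + e` with `u_k ~ N(0, K_k
#' sigma2_k)` over the kernels of a [assemble_model()] kernel set.
#' Records with missing `y` are predicted through data augmentation, so
#' the fit directly yields predictions for untested hybrids or
#' environments.
#'
#' @param y Numeric response, one entry per record in `kernels$records`;
#'   `NA` marks records to predict.
#' @param kernels A `kernel_set`.
#' @param config A [gibbs_config()].
#' @return An object of class `posterior_fit`: posterior-mean variance
#'   components (`varcomp`), intercept `mu`, per-kernel record effects
#'   `u`, posterior-mean `fitted` values (named by record), the response,
#'   `ess` diagnostics and the configuration.
#' @export
fit_rkhs <- function(y, kernels, config = gibbs_config()) {
  stopifnot(inherits(kernels, "kernel_set"), inherits(config, "gibbs_config"))
  n <- nrow(kernels$records)
  if (length(y) != n) stop("response length does not match record count")
  obs <- !is.na(y)
  if (sum(obs) < 10L) stop("need >= 10 non-missing responses")
  set.seed(config$seed)

  bases <- .kernel_bases(kernels$kernels)
  m <- length(bases)
  df0 <- config$df0
  vy <- stats::var(y[obs])
  S_k <- vapply(seq_len(m), function(k)
    vy * config$R2 / m * (df0 + 2) /
      mean(diag(kernels$kernels[[k]])), numeric(1))
  S_e <- vy * (1 - config$R2) * (df0 + 2)

  mu <- mean(y[obs])
  yf <- ifelse(obs, y, mu)
  alpha <- lapply(bases, function(b) numeric(b$q))
  u <- lapply(bases, function(b) numeric(n))
  sig2 <- S_k / (df0 + 2)
  sig2e <- S_e / (df0 + 2)
  e <- yf - mu

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  vs <- matrix(NA_real_, n_keep, m + 1L)
  mu_s <- numeric(n_keep)
  fit_acc <- numeric(n)
  u_acc <- lapply(seq_len(m), function(k) numeric(n))
  kept <- 0L

  for (it in seq_len(config$n_iter)) {
    # intercept (flat prior)
    e <- e + mu
    mu <- mean(e) + stats::rnorm(1L, 0, sqrt(sig2e / n))
    e <- e - mu
    # kernel terms
    for (k in seq_len(m)) {
      b <- bases[[k]]
      ep <- e + u[[k]]
      prec <- b$d / sig2e + 1 / sig2[k]
      mn <- (crossprod(b$B, ep) / sig2e) / prec
      a <- drop(mn) + stats::rnorm(b$q) / sqrt(prec)
      alpha[[k]] <- a
      u[[k]] <- drop(b$B %*% a)
      e <- ep - u[[k]]
      sig2[k] <- (sum(a^2) + S_k[k]) / stats::rchisq(1L, df0 + b$q)
    }
    # data augmentation for unobserved records
    if (any(!obs)) {
      e[!obs] <- stats::rnorm(sum(!obs), 0, sqrt(sig2e))
      yf[!obs] <- e[!obs] + mu + Reduce(`+`, lapply(u, `[`, !obs))
    }
    sig2e <- (sum(e^2) + S_e) / stats::rchisq(1L, df0 + n)

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      vs[kept, ] <- c(sig2, sig2e)
      mu_s[kept] <- mu
      fitted_now <- mu + Reduce(`+`, u)
      fit_acc <- fit_acc + fitted_now
      for (k in seq_len(m)) u_acc[[k]] <- u_acc[[k]] + u[[k]]
    }
  }

  ids <- .record_ids(kernels$records)
  vc <- colMeans(vs[seq_len(kept), , drop = FALSE])
  names(vc) <- c(paste0("sigma2_", names(kernels$kernels)), "sigma2_e")
  structure(list(
    model_id = kernels$model_id, records = kernels$records,
    varcomp = vc, mu = mean(mu_s[seq_len(kept)]),
    u = stats::setNames(lapply(u_acc, function(x)
      stats::setNames(x / kept, ids)), names(kernels$kernels)),
    fitted = stats::setNames(fit_acc / kept, ids),
    y = stats::setNames(y, ids), observed = stats::setNames(obs, ids),
    ess = stats::setNames(apply(vs[seq_len(kept), , drop = FALSE], 2, .ess),
                          names(vc)),
    n_samples = kept, multitrait = FALSE, config = config),
    class = "posterior_fit")
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("Posterior fit %s (%s), %d records, %d kept samples\n",
              x$model_id, if (x$multitrait) "multitrait" else "univariate",
              nrow(x$records), x$n_samples))
  if (x$multitrait) {
    cat(sprintf("  genetic correlation: %.3f\n", x$genetic_correlation))
  } else {
    cat("  variance components:\n")
    print(round(x$varcomp, 4))
  }
  invisible(x)
}

## ---- bivariate multitrait sampler (model M6) -------------------------

.rinvwishart <- function(nu, S) {
  solve(stats::rWishart(1L, nu, solve(S))[, , 1])
}

# vectorized sampler for all rows of a q x 2 coefficient block whose
# conditional precisions are d_j * Se_inv + Sk_inv (2x2 each)
.sample_block2 <- function(M, d, Se_inv, Sk_inv) {
  a <- Se_inv[1, 1]; b <- Se_inv[1, 2]; cc <- Se_inv[2, 2]
  P11 <- d * a + Sk_inv[1, 1]
  P12 <- d * b + Sk_inv[1, 2]
  P22 <- d * cc + Sk_inv[2, 2]
  rhs1 <- a * M[, 1] + b * M[, 2]
  rhs2 <- b * M[, 1] + cc * M[, 2]
  det <- P11 * P22 - P12^2
  m1 <- (P22 * rhs1 - P12 * rhs2) / det
  m2 <- (P11 * rhs2 - P12 * rhs1) / det
  l11 <- sqrt(P11); l21 <- P12 / l11; l22 <- sqrt(P22 - l21^2)
  z1 <- stats::rnorm(length(d)); z2 <- stats::rnorm(length(d))
  w2 <- z2 / l22
  w1 <- (z1 - l21 * w2) / l11
  cbind(m1 + w1, m2 + w2)
}

#' Fit the bivariate multitrait model (M6)
#'
#' Gibbs sampler for a two-trait model (primary trait plus the VARI FPCA1
#' secondary trait) over M6's kernels: unstructured 2x2 genetic
#' covariances on the genomic and genomic-by-environment terms
#' (inverse-Wishart priors), trait-specific independent environment
#' variances, and an unstructured 2x2 residual covariance. The secondary
#' trait must be observed for every record; missing primary values are
#' imputed within the chain from their conditional distribution, which is
#' how the secondary trait informs predictions for untested records.
#'
#' @param Y Numeric matrix, records x 2: column 1 the primary trait
#'   (`NA` allowed), column 2 the secondary trait (complete).
#' @param kernels A `kernel_set` built with `model_id = "M6"`.
#' @param config A [gibbs_config()].
#' @return A `posterior_fit` with posterior-mean 2x2 covariance matrices
#'   (`Sigma_g`, `Sigma_gxE`, `Sigma_e`), the posterior-mean genetic
#'   correlation, and `fitted` primary-trait values per record.
#' @export
fit_multitrait <- function(Y, kernels, config = gibbs_config()) {
  stopifnot(inherits(kernels, "kernel_set"))
  if (!kernels$multitrait)
    stop("multitrait fitting needs an M6 kernel set")
  Y <- as.matrix(Y)
  n <- nrow(kernels$records)
  if (nrow(Y) != n || ncol(Y) != 2L)
    stop("Y must be a records x 2 matrix")
  if (anyNA(Y[, 2])) stop("secondary trait must be observed for all records")
  obs1 <- !is.na(Y[, 1])
  if (sum(obs1) < 2L) stop("need >= 2 records with both traits")
  set.seed(config$seed)

  bases <- .kernel_bases(kernels$kernels)
  kn <- names(kernels$kernels)
  full_cov <- kn %in% c("g", "gxE")         # 2x2 unstructured terms
  m <- length(bases)
  df0 <- config$df0
  nu0 <- df0 + 2                            # IW df; mean exists for p = 2
  vys <- apply(Y, 2, function(v) stats::var(v, na.rm = TRUE))
  S0 <- lapply(seq_len(m), function(k)
    diag(vys * config$R2 / m / mean(diag(kernels$kernels[[k]])),
         2) * (nu0 - 3))
  S0e <- diag(vys * (1 - config$R2), 2) * (nu0 - 3)

  mu <- colMeans(Y, na.rm = TRUE)
  Yf <- Y
  Yf[!obs1, 1] <- mu[1]
  A <- lapply(bases, function(b) matrix(0, b$q, 2))
  U <- lapply(bases, function(b) matrix(0, n, 2))
  Sig_k <- lapply(S0, function(s) s / (nu0 - 3))
  sig2E <- lapply(seq_len(m), function(k) diag(Sig_k[[k]]))
  Se <- S0e / (nu0 - 3)
  E <- sweep(Yf, 2L, mu)

  n_keep <- (config$n_iter - config$burn_in) %/% config$thin
  kept <- 0L
  Sig_acc <- lapply(seq_len(m), function(k) matrix(0, 2, 2))
  Se_acc <- matrix(0, 2, 2)
  rho_s <- numeric(n_keep)
  fit_acc <- matrix(0, n, 2)

  for (it in seq_len(config$n_iter)) {
    Se_inv <- solve(Se)
    # intercepts (flat prior, joint bivariate draw)
    E <- sweep(E, 2L, mu, `+`)
    mu <- colMeans(E) + drop(stats::rnorm(2) %*% chol(Se / n))
    E <- sweep(E, 2L, mu)
    # kernel terms
    for (k in seq_len(m)) {
      b <- bases[[k]]
      Rp <- E + U[[k]]
      M <- crossprod(b$B, Rp)
      Sk_inv <- if (full_cov[k]) solve(Sig_k[[k]]) else
        diag(1 / sig2E[[k]], 2)
      A[[k]] <- .sample_block2(M, b$d, Se_inv, Sk_inv)
      U[[k]] <- b$B %*% A[[k]]
      E <- Rp - U[[k]]
      if (full_cov[k]) {
        Sig_k[[k]] <- .rinvwishart(nu0 + b$q, S0[[k]] + crossprod(A[[k]]))
      } else {
        for (j in 1:2)
          sig2E[[k]][j] <- (sum(A[[k]][, j]^2) +
                            (df0 + 2) * S0[[k]][j, j] / (nu0 - 3)) /
            stats::rchisq(1L, df0 + b$q)
      }
    }
    # impute missing primary values from their conditional distribution
    if (any(!obs1)) {
      fitted <- Yf - E
      cm <- fitted[!obs1, 1] +
        (Se[1, 2] / Se[2, 2]) * (Yf[!obs1, 2] - fitted[!obs1, 2])
      cv <- Se[1, 1] - Se[1, 2]^2 / Se[2, 2]
      ynew <- cm + stats::rnorm(sum(!obs1), 0, sqrt(max(cv, 1e-12)))
      E[!obs1, 1] <- ynew - fitted[!obs1, 1]
      Yf[!obs1, 1] <- ynew
    }
    Se <- .rinvwishart(nu0 + n, S0e + crossprod(E))

    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0L) {
      kept <- kept + 1L
      for (k in seq_len(m)) {
        Sk <- if (full_cov[k]) Sig_k[[k]] else diag(sig2E[[k]], 2)
        Sig_acc[[k]] <- Sig_acc[[k]] + Sk
      }
      Se_acc <- Se_acc + Se
      gk <- which(kn == "g")
      rho_s[kept] <- Sig_k[[gk]][1, 2] /
        sqrt(Sig_k[[gk]][1, 1] * Sig_k[[gk]][2, 2])
      fit_acc <- fit_acc +
        sweep(Reduce(`+`, U), 2L, mu, `+`)
    }
  }

  ids <- .record_ids(kernels$records)
  Sig_mean <- lapply(Sig_acc, function(s) s / kept)
  names(Sig_mean) <- paste0("Sigma_", kn)
  fitted_mean <- fit_acc / kept
  dimnames(fitted_mean) <- list(ids, c("primary", "secondary"))
  structure(list(
    model_id = kernels$model_id, records = kernels$records,
    covariances = c(Sig_mean, list(Sigma_e = Se_acc / kept)),
    genetic_correlation = mean(rho_s[seq_len(kept)]),
    fitted = stats::setNames(fitted_mean[, 1], ids),
    fitted_secondary = stats::setNames(fitted_mean[, 2], ids),
    y = stats::setNames(Y[, 1], ids), observed = stats::setNames(obs1, ids),
    n_samples = kept, multitrait = TRUE, config = config),
    class = "posterior_fit")
}

#' Posterior-mean predictions for a subset of records
#'
#' @param fit A `posterior_fit`.
#' @param target Records to predict: a data frame with `hybrid` and
#'   `environment`, a character vector of `hybrid@environment` ids, or an
#'   integer index into the fit's records.
#' @return Named numeric vector of posterior-mean fitted values, in the
#'   order of `target` (empty input gives an empty vector).
#' @export
predict_records <- function(fit, target) {
  stopifnot(inherits(fit, "posterior_fit"))
  ids <- if (is.data.frame(target)) .record_ids(target)
  else if (is.numeric(target)) names(fit$fitted)[target]
  else as.character(target)
  if (!length(ids)) return(stats::setNames(numeric(0), character(0)))
  if (anyNA(ids) || !all(ids %in% names(fit$fitted)))
    stop("unknown record(s) in prediction target")
  fit$fitted[ids]
}
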