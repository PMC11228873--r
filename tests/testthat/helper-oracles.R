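# Independent oracles for the mixed-model, kernel and FPCA stages.
# These are deliberately naive (dense algebra, explicit loops) and share
# no code with the package implementation.

# design matrices for a set of factor columns (full indicator coding)
oracle_Z <- function(data, term) {
  f <- interaction(data[strsplit(term, ":", fixed = TRUE)[[1]]],
                   drop = TRUE, sep = ":")
  stats::model.matrix(~ 0 + f)
}

# restricted log-likelihood of y = X beta + sum_k Z_k u_k + e at given
# variances (explicit V-based formula)
oracle_reml_loglik <- function(y, X, Zlist, sig2k, sig2e) {
  n <- length(y)
  V <- diag(sig2e, n)
  for (k in seq_along(Zlist)) V <- V + sig2k[k] * tcrossprod(Zlist[[k]])
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
            t(r) %*% Vi %*% r)[1]
}

# dense Henderson mixed-model equations at given variances
oracle_mme <- function(y, X, Zlist, sig2k, sig2e) {
  Z <- do.call(cbind, Zlist)
  q <- vapply(Zlist, ncol, integer(1))
  lambda <- rep(sig2e / sig2k, times = q)
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + diag(lambda)))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  p <- ncol(X)
  u <- split(sol[-seq_len(p)], rep(seq_along(Zlist), times = q))
  list(beta = sol[seq_len(p)], u = u)
}

# GLS fixed-effect solutions at given variances
oracle_gls <- function(y, X, Zlist, sig2k, sig2e) {
  n <- length(y)
  V <- diag(sig2e, n)
  for (k in seq_along(Zlist)) V <- V + sig2k[k] * tcrossprod(Zlist[[k]])
  Vi <- solve(V)
  drop(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# textbook Pearson correlation
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# elementwise brute-force kernels
oracle_cross_kernel <- function(M, divisor) {
  n <- nrow(M)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- sum(M[i, ] * M[j, ]) / divisor
  K
}

oracle_standardize <- function(M) {
  for (j in seq_len(ncol(M))) {
    x <- M[, j]
    M[, j] <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  }
  M
}

# small balanced two-environment plot data with known genetic values
make_tiny_plots <- function(n_hybrids = 12, n_reps = 2, sd_g = 1,
                            sd_e = 0.5, seed = 1, environment = "E1") {
  set.seed(seed)
  hybrids <- sprintf("H%03d", seq_len(n_hybrids))
  u <- stats::setNames(rnorm(n_hybrids, sd = sd_g), hybrids)
  d <- expand.grid(hybrid = hybrids, rep = seq_len(n_reps),
                   stringsAsFactors = FALSE)
  d$environment <- environment
  d$range <- ((seq_len(nrow(d)) - 1) %% 4) + 1
  d$row <- ((seq_len(nrow(d)) - 1) %/% 4) + 1
  d$gy <- 8 + u[d$hybrid] + rnorm(nrow(d), sd = sd_e)
  d$pht <- 210 + 8 * u[d$hybrid] + rnorm(nrow(d), sd = 4)
  attr(d, "u") <- u
  d
}

# small config for fast end-to-end trials
tiny_config <- function(n_hybrids = 60, vi_names = c("VARI", "RCC", "GCC"),
                        seed = 1, n_markers = 300, ...) {
  nrow_grid <- ceiling(2 * n_hybrids / 15)
  sim_config(
    n_hybrids = n_hybrids,
    environments = list(
      env_spec("E1", c(20, 30, 40, 50, 60, 75, 90), 55, 15, nrow_grid),
      env_spec("E2", c(18, 28, 38, 48, 58, 70, 85, 100), 52, 15, nrow_grid)),
    n_markers = n_markers, vi_names = vi_names, seed = seed, ...)
}
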