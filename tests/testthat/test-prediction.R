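# shared small kernel set builders
m1_kernels <- function(nh = 100, n_env = 2, n_markers = 300, seed = 1) {
  X <- simulate_markers(nh, n_markers, seed = seed)
  G <- genomic_relationship(X)
  records <- data.frame(hybrid = rep(rownames(X), n_env),
                        environment = rep(paste0("Env", seq_len(n_env)),
                                          each = nh))
  list(G = G, records = records,
       ks = assemble_model("M1", records, G = G))
}

kernel_sqrt <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

test_that("chains are seed-reproducible and noise shrinks toward zero", {
  mk <- m1_kernels(nh = 40, seed = 3)
  set.seed(99)
  y <- rnorm(80)
  cfg <- gibbs_config(n_iter = 600, burn_in = 100, thin = 2, seed = 11)
  f1 <- fit_rkhs(y, mk$ks, cfg)
  f2 <- fit_rkhs(y, mk$ks, cfg)
  expect_identical(f1$fitted, f2$fitted)
  expect_identical(f1$varcomp, f2$varcomp)

  # pure-noise response: genomic variance share stays small
  mk2 <- m1_kernels(nh = 100, seed = 3)
  shares <- vapply(1:5, function(s) {
    set.seed(200 + s)
    y <- rnorm(200)
    f <- fit_rkhs(y, mk2$ks, gibbs_config(n_iter = 2000, burn_in = 500,
                                          seed = s))
    unname(f$varcomp["sigma2_g"] /
             (f$varcomp["sigma2_g"] + f$varcomp["sigma2_e"]))
  }, numeric(1))
  expect_lt(mean(shares), 0.2)
})

test_that("posterior means match conjugate closed form with pinned variances", {
  # one identity kernel, variances pinned by an overwhelming prior: the
  # posterior mean of mu + u is the GLS/ridge solution
  set.seed(17)
  n <- 12
  records <- data.frame(hybrid = sprintf("H%02d", 1:n), environment = "A")
  K <- diag(n); dimnames(K) <- list(records$hybrid, records$hybrid)
  ks <- structure(list(model_id = "M1", records = records,
                       kernels = list(g = K), multitrait = FALSE),
                  class = "kernel_set")
  y <- rnorm(n, sd = 1.5)
  cfg <- gibbs_config(n_iter = 24000, burn_in = 4000, thin = 2,
                      df0 = 1e7, R2 = 0.5, seed = 5)
  fit <- fit_rkhs(y, ks, cfg)
  s2g <- var(y) * 0.5
  s2e <- var(y) * 0.5
  V <- K * s2g + diag(s2e, n)
  Vi <- solve(V)
  mu_gls <- drop(solve(t(rep(1, n)) %*% Vi %*% rep(1, n),
                       t(rep(1, n)) %*% Vi %*% y))
  u_blup <- drop(s2g * K %*% Vi %*% (y - mu_gls))
  expect_equal(unname(fit$fitted), unname(mu_gls + u_blup),
               tolerance = 0.05)
})

test_that("variance components recover generative truth on average", {
  vy <- numeric(10)
  vc <- sapply(1:10, function(s) {
    set.seed(300 + s)
    mk <- m1_kernels(nh = 150, n_markers = 400, seed = 400 + s)
    env <- mk$records$environment
    y <- drop(kernel_sqrt(mk$ks$kernels$E) %*% rnorm(300)) * sqrt(0.3) +
      drop(kernel_sqrt(mk$ks$kernels$g) %*% rnorm(300)) +
      drop(kernel_sqrt(mk$ks$kernels$gxE) %*% rnorm(300)) * sqrt(0.5) +
      rnorm(300)
    # within-environment sample variance (the E term only moves env means)
    vy[s] <<- mean(tapply(y, env, var))
    fit <- fit_rkhs(y, mk$ks, gibbs_config(n_iter = 3000, burn_in = 800,
                                           seed = s))
    fit$varcomp
  })
  means <- rowMeans(vc)
  expect_lt(abs(means["sigma2_g"] - 1), 0.3)
  expect_lt(abs(means["sigma2_e"] - 1), 0.3)
  # posterior-mean within-environment variance tracks the data variance
  tot <- means["sigma2_g"] + 0.5 * means["sigma2_gxE"] + means["sigma2_e"]
  expect_lt(abs(tot - mean(vy)) / mean(vy), 0.25)
})

test_that("prediction ability of the genomic model increases with h2", {
  ability_at_h2 <- function(h2, s) {
    cfg <- tiny_config(n_hybrids = 80, vi_names = character(0),
                       seed = 500 + s, heritability_gy = h2,
                       gxe_fraction = 0.1)
    tr <- simulate_trial(cfg)
    blues <- rbind(fit_blues(tr$plots, "gy", "E1"),
                   fit_blues(tr$plots, "gy", "E2"))
    G <- genomic_relationship(tr$markers)
    rec <- data.frame(hybrid = rep(rownames(G), 2),
                      environment = rep(c("E1", "E2"), each = 80))
    ks <- assemble_model("M1", rec, G = G)
    y <- blues$blue[match(paste(rec$hybrid, rec$environment),
                          paste(blues$hybrid, blues$environment))]
    mask <- rec$hybrid %in% rownames(G)[1:20]
    ym <- y; ym[mask] <- NA
    fit <- fit_rkhs(ym, ks, gibbs_config(n_iter = 1500, burn_in = 300,
                                         seed = s))
    cor(fit$fitted[mask], y[mask])
  }
  r <- vapply(c(0.2, 0.5, 0.8), function(h2)
    mean(vapply(1:3, function(s) ability_at_h2(h2, s), numeric(1))),
    numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("multitrait sampler recovers genetic correlation and degenerates", {
  mk <- m1_kernels(nh = 100, n_markers = 300, seed = 21)
  ks6 <- assemble_model("M6", mk$records, G = mk$G)

  rho <- vapply(1:4, function(s) {
    set.seed(600 + s)
    n <- 200
    Lg <- chol(matrix(c(1, .8, .8, 1), 2))
    Y <- kernel_sqrt(ks6$kernels$g) %*% matrix(rnorm(n * 2), n) %*% Lg +
      matrix(rnorm(n * 2, sd = sqrt(0.5)), n)
    fit <- fit_multitrait(Y, ks6, gibbs_config(n_iter = 2000, burn_in = 400,
                                               seed = s))
    fit$genetic_correlation
  }, numeric(1))
  expect_lt(abs(mean(rho) - 0.8), 0.15)

  # secondary an exact copy of the primary: correlation near 1
  set.seed(61)
  y <- drop(kernel_sqrt(ks6$kernels$g) %*% rnorm(200)) + rnorm(200, sd = .3)
  fit_dup <- fit_multitrait(cbind(y, y), ks6,
                            gibbs_config(n_iter = 1500, burn_in = 300,
                                         seed = 2))
  expect_gt(fit_dup$genetic_correlation, 0.95)

  Ybad <- cbind(y, y); Ybad[3, 2] <- NA
  expect_error(fit_multitrait(Ybad, ks6, gibbs_config(600, 100, seed = 1)),
               "secondary")
  expect_error(fit_multitrait(cbind(y, y), assemble_model("M1", mk$records,
                                                          G = mk$G)),
               "M6")
})

test_that("multitrait prediction beats univariate when traits share genetics", {
  diffs <- vapply(1:4, function(s) {
    set.seed(700 + s)
    mk <- m1_kernels(nh = 100, n_markers = 300, seed = 800 + s)
    ks6 <- assemble_model("M6", mk$records, G = mk$G)
    n <- 200
    Lg <- chol(matrix(c(1, .8, .8, 1), 2))
    Y <- kernel_sqrt(ks6$kernels$g) %*% matrix(rnorm(n * 2), n) %*% Lg +
      matrix(rnorm(n * 2, sd = sqrt(0.5)), n)
    mask <- mk$records$hybrid %in% rownames(mk$G)[1:20]
    Ym <- Y; Ym[mask, 1] <- NA
    cfg <- gibbs_config(n_iter = 2000, burn_in = 400, seed = s)
    f6 <- fit_multitrait(Ym, ks6, cfg)
    f1 <- fit_rkhs(Ym[, 1], mk$ks, cfg)
    cor(f6$fitted[mask], Y[mask, 1]) - cor(f1$fitted[mask], Y[mask, 1])
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("predict_records subsets correctly and validates targets", {
  mk <- m1_kernels(nh = 30, seed = 41)
  set.seed(42)
  y <- rnorm(60)
  fit <- fit_rkhs(y, mk$ks, gibbs_config(n_iter = 600, burn_in = 100,
                                         seed = 1))
  ids <- paste(mk$records$hybrid, mk$records$environment, sep = "@")
  expect_equal(predict_records(fit, mk$records), fit$fitted)
  expect_equal(predict_records(fit, ids[c(5, 2)]),
               fit$fitted[c(5, 2)])
  # invariant to target ordering
  expect_equal(unname(predict_records(fit, rev(ids))[60]),
               unname(fit$fitted[1]))
  expect_length(predict_records(fit, character(0)), 0L)
  expect_error(predict_records(fit, "nope@Env9"), "unknown record")
})
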