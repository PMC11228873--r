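# small two-environment data set with genetic + GxE + noise structure,
# built once for the scenario tests
make_cv_setup <- function(nh = 80, seed = 1, h2 = 0.7, gxe = 0.3,
                          models = c("M1", "M2")) {
  cfg <- tiny_config(n_hybrids = nh, vi_names = c("VARI", "RCC", "GCC"),
                     seed = seed, heritability_gy = h2, gxe_fraction = gxe)
  tr <- simulate_trial(cfg)
  blues <- rbind(fit_blues(tr$plots, "gy", "E1"),
                 fit_blues(tr$plots, "gy", "E2"))
  blups <- rbind(fit_temporal_blups(tr$vi_obs, environment = "E1"),
                 fit_temporal_blups(tr$vi_obs, environment = "E2"))
  flowering <- c(E1 = 55, E2 = 52)
  sms <- lapply(c("E1", "E2"), function(ev)
    build_score_matrix(fit_fpca_env(blups, ev, window = "until_flowering",
                                    flowering_start_dap = flowering[[ev]])))
  scores <- merge_environments(sms)
  records <- scores[, c("hybrid", "environment")]
  G <- genomic_relationship(tr$markers)
  P1 <- phenomic_relationship(scores)
  ksets <- lapply(stats::setNames(models, models), function(m)
    assemble_model(m, records, G = G, P1 = P1))
  secondary <- stats::setNames(scores[["VARI.FPCA1"]],
                               paste(records$hybrid, records$environment,
                                     sep = "@"))
  list(trial = tr, data = build_cv_data(blues, ksets, secondary))
}

test_that("fold plans partition hybrids with balanced sizes", {
  hy <- sprintf("H%04d", 1:415)
  fp <- make_folds(hy, k = 5, repeats = 3, seed = 2)
  for (r in 1:3) {
    sizes <- table(fp$assignment[, r])
    expect_equal(sum(sizes), 415)
    expect_equal(unname(sort(table(fp$assignment[, r]))[1]), 83)
    expect_lte(diff(range(sizes)), 1)
    # training/test split 332 / 83 for every fold
    for (f in 1:5) {
      expect_equal(sum(fp$assignment[, r] != f), 332)
      expect_equal(sum(fp$assignment[, r] == f), 83)
    }
  }
  fp2 <- make_folds(sprintf("H%03d", 1:220), k = 5, repeats = 2, seed = 3)
  expect_equal(unique(colSums(fp2$assignment == 1)), 44)
  expect_equal(unique(colSums(fp2$assignment != 1)), 176)

  expect_identical(make_folds(hy, 5, 2, seed = 9)$assignment,
                   make_folds(hy, 5, 2, seed = 9)$assignment)
  expect_error(make_folds(hy[1:3], k = 5), "at least k")
})

test_that("requesting a model without a kernel set is a configuration error", {
  blues <- data.frame(hybrid = sprintf("H%02d", 1:10), environment = "E1",
                      trait = "gy", blue = rnorm(10))
  G <- genomic_relationship(simulate_markers(10, 40, seed = 1))
  rec <- data.frame(hybrid = rownames(G), environment = "E1")
  cvd <- build_cv_data(blues, list(M1 = assemble_model("M1", rec, G = G)))
  plan <- make_folds(rownames(G), k = 5, repeats = 1, seed = 1)
  expect_error(run_within_env(cvd, "M9", plan), "no kernel set")
  expect_error(run_leave_one_env(cvd, "M1", plan), ">= 2 environments")
})

test_that("prediction ability equals the textbook Pearson formula", {
  x <- c(1.2, -0.4, 2.2, 0.3)
  y <- c(0.8, -0.9, 1.4, 0.1)
  expect_equal(prediction_ability(x, y), oracle_pearson(x, y),
               tolerance = 1e-12)
  expect_equal(prediction_ability(y, y), 1.0)
  expect_equal(prediction_ability(-y, y), -1.0)
  expect_error(prediction_ability(c(1, 1, 1), y[1:3]), "zero-variance")
  expect_error(prediction_ability(1:2, 1:2), "paired")
})

test_that("within-environment scenarios produce CV2 >= CV1 bookkeeping", {
  setup <- make_cv_setup(nh = 80, seed = 31)
  plan <- make_folds(sort(unique(setup$data$records$hybrid)), k = 5,
                     repeats = 2, seed = 5)
  res <- run_within_env(setup$data, c("M1", "M2"), plan,
                        gibbs_config(n_iter = 1200, burn_in = 300, seed = 1))
  # one row per model x scenario x environment x repeat x fold
  expect_equal(nrow(res), 2 * 2 * 2 * 2 * 5)
  expect_true(all(res$r >= -1 & res$r <= 1, na.rm = TRUE))

  sm <- summarize_cv(res)
  cv2 <- sm$mean_r[sm$model_id == "M1" & sm$scenario == "CV2"]
  cv1 <- sm$mean_r[sm$model_id == "M1" & sm$scenario == "CV1"]
  expect_gte(cv2, cv1)
})

test_that("leave-one-environment-out never trains on held-out information", {
  setup <- make_cv_setup(nh = 60, seed = 32, models = "M1")
  plan <- make_folds(sort(unique(setup$data$records$hybrid)), k = 5,
                     repeats = 1, seed = 6)
  res <- run_leave_one_env(setup$data, "M1", plan,
                           gibbs_config(n_iter = 1000, burn_in = 250,
                                        seed = 2))
  # both environments serve once as held-out, per fold
  expect_equal(sort(unique(res$environment)), c("E1", "E2"))
  expect_equal(nrow(res), 2 * 2 * 5)

  # leakage check on the constructed training response
  untested <- rownames(plan$assignment)[plan$assignment[, 1] == 1]
  y_train <- setup$data$y
  y_train[setup$data$records$environment == "E1" |
            setup$data$records$hybrid %in% untested] <- NA
  expect_true(all(is.na(
    y_train[setup$data$records$hybrid %in% untested])))
  expect_true(all(is.na(
    y_train[setup$data$records$environment == "E1"])))
})

test_that("noise-free genetic signal gives near-perfect CV1 ability", {
  # perfect-signal limit: noiseless marker-determined trait with a
  # low-dimensional genetic architecture (far fewer markers than training
  # hybrids), so the genomic kernel can represent untested hybrids exactly
  cfg <- tiny_config(n_hybrids = 150, vi_names = character(0), seed = 33,
                     n_markers = 10, heritability_gy = 1, gxe_fraction = 0,
                     spatial_sd = 0)
  tr <- simulate_trial(cfg)
  blues <- rbind(fit_blues(tr$plots, "gy", "E1"),
                 fit_blues(tr$plots, "gy", "E2"))
  G <- genomic_relationship(tr$markers)
  rec <- data.frame(hybrid = rep(rownames(G), 2),
                    environment = rep(c("E1", "E2"), each = 150))
  cvd <- build_cv_data(blues, list(M1 = assemble_model("M1", rec, G = G)))
  plan <- make_folds(rownames(G), k = 5, repeats = 1, seed = 7)
  res <- run_within_env(cvd, "M1", plan,
                        gibbs_config(n_iter = 1500, burn_in = 300, seed = 3))
  sm <- summarize_cv(res)
  expect_gt(sm$mean_r[sm$scenario == "CV1"], 0.95)
})

test_that("cv results pivot into a model-by-scenario summary", {
  res <- data.frame(model_id = rep(c("M1", "M2"), each = 4),
                    scenario = rep(c("CV2", "CV1"), 4),
                    environment = "E1", rep = 1, fold = rep(1:4, 2),
                    r = c(.6, .3, .65, .35, .55, .4, .6, .45), n = 10)
  sm <- summarize_cv(res)
  expect_equal(nrow(sm), 4L)
  expect_equal(sm$mean_r[sm$model_id == "M1" & sm$scenario == "CV2"],
               mean(c(.6, .65)))
  expect_equal(sm$n_cells, rep(2L, 4))
})
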