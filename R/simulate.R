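#' Default vegetation-index names
#'
#' The 36 per-plot features extracted from RGB drone orthomosaics: 33
#' visible-band vegetation indices plus the raw R, G and B band means.
#' VARI (visible atmospherically resistant index) and RCC (red chromatic
#' coordinate) are listed first; in synthetic trials they receive the
#' strongest positive and negative genetic correlation with grain yield,
#' mirroring their empirical behaviour.
#'
#' @return Character vector of length 36.
#' @export
default_vi_names <- function() {
  c("VARI", "RCC", "GCC", "BCC", "ExG", "ExR", "ExGR", "NGRDI", "MGRVI",
    "RGBVI", "GLI", "VEG", "CIVE", "COM1", "COM2", "TGI", "NDI", "BI",
    "SCI", "GLAI", "HI", "HUE", "SAT", "VAL", "SI", "BGI", "PSRI",
    "NGBDI", "NDRBI", "GRVI", "MExG", "IKAW", "WI", "R", "G", "B")
}

#' Specify one trial environment
#'
#' An environment is one year/trial combination: a range-by-row field grid
#' and a schedule of drone flights expressed in days after planting (DAP).
#'
#' @param name Environment label, e.g. `"2018"` or `"2020.drought"`.
#' @param flight_daps Strictly increasing integer vector of flight DAPs.
#' @param flowering_start_dap DAP at which flowering begins; flights at or
#'   before this date form the "until flowering" window. Must lie within
#'   the flight schedule's range.
#' @param n_ranges,n_rows Field grid dimensions.
#' @return An object of class `env_spec`.
#' @export
env_spec <- function(name, flight_daps, flowering_start_dap, n_ranges, n_rows) {
  flight_daps <- as.integer(flight_daps)
  if (any(diff(flight_daps) <= 0))
    stop("flight_daps must be strictly increasing")
  if (flowering_start_dap < min(flight_daps) ||
      flowering_start_dap > max(flight_daps))
    stop("flowering_start_dap must lie within the flight schedule")
  if (n_ranges < 1L || n_rows < 1L) stop("grid dimensions must be positive")
  structure(list(name = as.character(name), flight_daps = flight_daps,
                 flowering_start_dap = as.integer(flowering_start_dap),
                 n_ranges = as.integer(n_ranges), n_rows = as.integer(n_rows)),
            class = "env_spec")
}

#' Configure a synthetic multi-environment trial
#'
#' Collects the generative parameters for [simulate_trial()]. The defaults
#' describe a mid-sized maize hybrid trial: RCBD with 2 replications,
#' entry-mean heritabilities in the range observed for grain yield and
#' plant height in temperate hybrid trials, and a vegetation-index genetic
#' signal moderately correlated with yield.
#'
#' @param n_hybrids Number of hybrids.
#' @param environments List of [env_spec()] objects.
#' @param n_markers Number of biallelic markers (0/1/2 coding).
#' @param n_reps Replications per environment (RCBD blocks).
#' @param vi_names Vegetation indices to simulate; default the 36 standard
#'   names. May be a subset (or empty) for lighter simulations.
#' @param heritability_gy,heritability_pht Target per-environment entry-mean
#'   heritability of grain yield / plant height, in (0, 1].
#' @param vi_genetic_corr Target correlation between the strongest VI's
#'   trajectory genetic component and the true yield genetic value.
#' @param gxe_fraction Variance of per-environment genotype-by-environment
#'   deviations as a fraction of main-effect genetic variance.
#' @param trait_genetic_corr Genetic correlation between yield and height.
#' @param spatial_sd Multiplier on all range/row/rep spatial effect
#'   standard deviations (1 = default field heterogeneity, 0 = none).
#' @param maf_range Minor-allele-frequency interval for simulated markers.
#' @param seed Integer seed; the whole trial is reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_hybrids, environments, n_markers = 1000L,
                       n_reps = 2L, vi_names = default_vi_names(),
                       heritability_gy = 0.55, heritability_pht = 0.65,
                       vi_genetic_corr = 0.5, gxe_fraction = 0.3,
                       trait_genetic_corr = 0.5, spatial_sd = 1,
                       maf_range = c(0.05, 0.5), seed = 1L) {
  if (n_hybrids < 2L || n_markers < 2L) stop("counts must be >= 2")
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (heritability_gy < 0 || heritability_gy > 1 ||
      heritability_pht < 0 || heritability_pht > 1)
    stop("heritabilities must lie in [0, 1]")
  if (abs(vi_genetic_corr) > 1) stop("vi_genetic_corr must lie in [-1, 1]")
  if (!is.list(environments) || !length(environments) ||
      !all(vapply(environments, inherits, logical(1), "env_spec")))
    stop("environments must be a non-empty list of env_spec objects")
  for (e in environments) {
    if (e$n_ranges * e$n_rows < n_hybrids * n_reps)
      stop("grid too small for ", n_hybrids, " hybrids x ", n_reps,
           " reps in environment ", e$name)
  }
  structure(list(n_hybrids = as.integer(n_hybrids),
                 environments = environments,
                 n_markers = as.integer(n_markers), n_reps = as.integer(n_reps),
                 vi_names = as.character(vi_names),
                 heritability_gy = heritability_gy,
                 heritability_pht = heritability_pht,
                 vi_genetic_corr = vi_genetic_corr,
                 gxe_fraction = gxe_fraction,
                 trait_genetic_corr = trait_genetic_corr,
                 spatial_sd = spatial_sd,
                 maf_range = maf_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Preset trial configurations
#'
#' Two ready-made configurations shaped like the field study populations:
#' `"pop1"` has 415 hybrids in two environments with 7 and 14 flights;
#' `"pop2"` has 220 hybrids in three environments with 17, 17 and 20
#' flights (the two 2020 trials share a flight schedule). Flight DAP grids
#' differ across environments, so the cross-environment merging problem the
#' FPCA stage solves is present by construction.
#'
#' @param name `"pop1"` or `"pop2"`.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
preset_config <- function(name = c("pop1", "pop2"), seed = 1L, ...) {
  name <- match.arg(name)
  if (name == "pop1") {
    envs <- list(
      env_spec("2018", c(29L, 36L, 43L, 51L, 65L, 79L, 99L), 65L, 30L, 28L),
      env_spec("2019", seq(25L, 116L, by = 7L), 67L, 30L, 28L))
    args <- list(n_hybrids = 415L, environments = envs, seed = seed)
  } else {
    daps20 <- seq(20L, 116L, by = 6L)   # 17 flights, shared by both 2020 trials
    daps21 <- seq(18L, 132L, by = 6L)   # 20 flights
    envs <- list(
      env_spec("2020.drought", daps20, 68L, 22L, 20L),
      env_spec("2020.optimal", daps20, 68L, 22L, 20L),
      env_spec("2021.drought", daps21, 66L, 22L, 20L))
    args <- list(n_hybrids = 220L, environments = envs, seed = seed)
  }
  do.call(sim_config, utils::modifyList(args, list(...)))
}

#' Simulate a biallelic marker matrix
#'
#' Genotypes are drawn per marker as Binomial(2, f) with allele frequency f
#' uniform on `maf_range`; columns that come out monomorphic are redrawn so
#' the matrix is usable for a genomic relationship matrix.
#'
#' @param n_hybrids,n_markers Dimensions (both >= 2).
#' @param maf_range Allele-frequency interval, a subset of (0, 0.5].
#' @param seed Optional integer seed.
#' @return Integer matrix (hybrids x markers, entries 0/1/2) with hybrid
#'   row names and marker column names.
#' @export
simulate_markers <- function(n_hybrids, n_markers, maf_range = c(0.05, 0.5),
                             seed = NULL) {
  if (n_hybrids < 2L || n_markers < 2L) stop("counts must be >= 2")
  if (min(maf_range) <= 0 || max(maf_range) > 0.5)
    stop("maf_range must be a subset of (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  f <- stats::runif(n_markers, maf_range[1], maf_range[2])
  X <- matrix(stats::rbinom(n_hybrids * n_markers, 2L, rep(f, each = n_hybrids)),
              nrow = n_hybrids)
  # monomorphic columns defeat marker standardization; redraw them
  for (tries in seq_len(25L)) {
    mono <- which(apply(X, 2, function(x) length(unique(x)) == 1L))
    if (!length(mono)) break
    X[, mono] <- stats::rbinom(n_hybrids * length(mono), 2L,
                               rep(f[mono], each = n_hybrids))
  }
  dimnames(X) <- list(sprintf("H%04d", seq_len(n_hybrids)),
                      sprintf("M%05d", seq_len(n_markers)))
  X
}

#' Double-logistic vegetation-index trajectory
#'
#' Canopy reflectance indices over a maize season rise through vegetative
#' growth, plateau around flowering and decline during senescence. That
#' shape is generated as the difference of two logistic curves:
#' `baseline + amplitude * L(rate_green (t - t_green)) -
#'  senescence * L(rate_sen (t - t_sen))` with `L` the standard logistic.
#'
#' @param params Named list or vector with elements `baseline`, `amplitude`,
#'   `t_green` (green-up inflection DAP), `rate_green`, `senescence`
#'   (amplitude of the decline; 0 disables senescence), `t_sen`, `rate_sen`.
#' @param dap Numeric vector of days after planting (>= 0).
#' @return Numeric vector of trajectory values, finite and continuous.
#' @export
vi_trajectory <- function(params, dap) {
  p <- as.list(params)
  if (any(dap < 0)) stop("dap must be >= 0")
  p$baseline +
    p$amplitude * stats::plogis(p$rate_green * (dap - p$t_green)) -
    p$senescence * stats::plogis(p$rate_sen * (dap - p$t_sen))
}

# Trait plot values for one environment: mu + u + gxe + spatial + residual.
# Residual variance set so the per-environment entry-mean heritability
# sigma2_H / (sigma2_H + sigma2_e / n_reps) hits `h2`, where sigma2_H is the
# within-environment hybrid variance (main effect + GxE deviation).
.sim_trait_env <- function(plots, u, gxe, mu, h2, n_reps, spatial_sd) {
  nh <- length(u)
  sig2H <- stats::var(u + gxe)
  sig2e <- if (h2 >= 1) 0 else n_reps * sig2H * (1 - h2) / h2
  rng_eff <- stats::rnorm(max(plots$range), sd = spatial_sd)
  row_eff <- stats::rnorm(max(plots$row), sd = spatial_sd)
  rep_eff <- stats::rnorm(max(plots$rep), sd = spatial_sd / 2)
  hi <- match(plots$hybrid, names(u))
  mu + u[hi] + gxe[hi] +
    rng_eff[plots$range] + row_eff[plots$row] + rep_eff[plots$rep] +
    stats::rnorm(nrow(plots), sd = sqrt(sig2e))
}

#' Simulate a complete multi-environment phenotyping trial
#'
#' Generates markers, an RCBD field layout per environment, end-of-season
#' grain yield (t/ha) and plant height (cm) plot values, and plot-level
#' temporal vegetation-index observations at every flight, together with
#' the ground truth (true genetic values, GxE deviations, VI genetic
#' loadings) that parameter-recovery tests check against.
#'
#' Genetic values are marker-determined (`u = X beta`, rescaled), so
#' genomic kernels carry real signal. Each VI's hybrid-level trajectory
#' modifier is a loading times a shared marker-determined component `z`
#' (correlated with the yield genetic value at `vi_genetic_corr`) plus an
#' independent hybrid-specific part; VARI gets loading +1 and RCC -1, so
#' VARI attains the programmed correlation and RCC its negative.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_trial`: list with elements
#'   `markers`, `plots` (data frame: hybrid, environment, range, row, rep,
#'   gy, pht), `vi_obs` (data frame: hybrid, environment, flight_dap,
#'   vi_name, range, row, rep, value), `truth`, and `config`.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nh <- config$n_hybrids
  nv <- length(config$vi_names)

  X <- simulate_markers(nh, config$n_markers, config$maf_range)
  hybrids <- rownames(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)

  # marker-determined genetic values, rescaled to fixed genetic SDs
  mk_gv <- function(beta, sd_target) {
    u <- drop(Xc %*% beta)
    u <- u - mean(u)
    as.numeric(u * sd_target / stats::sd(u))
  }
  beta_gy <- stats::rnorm(config$n_markers)
  beta_pht <- config$trait_genetic_corr * beta_gy +
    sqrt(1 - config$trait_genetic_corr^2) * stats::rnorm(config$n_markers)
  beta_z <- stats::rnorm(config$n_markers)
  sd_g_gy <- 0.8   # t/ha
  sd_g_pht <- 10   # cm
  u_gy <- stats::setNames(mk_gv(beta_gy, sd_g_gy), hybrids)
  u_pht <- stats::setNames(mk_gv(beta_pht, sd_g_pht), hybrids)

  # shared VI genetic driver z: corr(z, u_gy) = vi_genetic_corr
  rho <- config$vi_genetic_corr
  u_std <- (u_gy - mean(u_gy)) / stats::sd(u_gy)
  w <- mk_gv(beta_z, 1)
  w <- stats::residuals(stats::lm(w ~ u_std))          # exactly orthogonal
  w <- w / stats::sd(w)
  z <- stats::setNames(rho * u_std + sqrt(1 - rho^2) * w, hybrids)

  # per-VI loadings on z and independent hybrid-level components
  loadings <- stats::runif(nv, -0.85, 0.85)
  names(loadings) <- config$vi_names
  if ("VARI" %in% config$vi_names) loadings["VARI"] <- 1
  if ("RCC" %in% config$vi_names) loadings["RCC"] <- -1
  g_vi <- matrix(0, nh, nv, dimnames = list(hybrids, config$vi_names))
  for (v in seq_len(nv)) {
    l <- loadings[v]
    g_vi[, v] <- l * z + sqrt(max(0, 1 - l^2)) * stats::rnorm(nh)
  }

  # per-VI base trajectory parameters (environment-independent part)
  vi_base <- stats::runif(nv, -0.1, 0.3)
  vi_amp <- stats::runif(nv, 0.25, 0.45)
  vi_sen <- stats::runif(nv, 0.1, 0.3)
  vi_rate_g <- stats::runif(nv, 0.15, 0.25)
  vi_rate_s <- stats::runif(nv, 0.1, 0.2)

  n_env <- length(config$environments)
  env_names <- vapply(config$environments, `[[`, character(1), "name")
  env_mu_gy <- stats::setNames(8 + stats::rnorm(n_env, sd = 0.8), env_names)
  env_mu_pht <- stats::setNames(210 + stats::rnorm(n_env, sd = 10), env_names)
  gxe_sd <- sqrt(config$gxe_fraction)
  gxe_gy <- matrix(stats::rnorm(nh * n_env, sd = gxe_sd * sd_g_gy), nh, n_env,
                   dimnames = list(hybrids, env_names))
  gxe_pht <- matrix(stats::rnorm(nh * n_env, sd = gxe_sd * sd_g_pht), nh, n_env,
                    dimnames = list(hybrids, env_names))
  # environment-specific trajectory shifts (same for all VIs)
  env_t_green <- stats::setNames(stats::runif(n_env, 42, 52), env_names)
  env_t_sen <- stats::setNames(stats::runif(n_env, 85, 100), env_names)
  env_amp_mult <- stats::setNames(stats::runif(n_env, 0.85, 1.15), env_names)
  # GxE on trajectories: per-env hybrid deviation added to the VI modifier
  gxe_vi <- array(stats::rnorm(nh * nv * n_env, sd = gxe_sd), c(nh, nv, n_env),
                  dimnames = list(hybrids, config$vi_names, env_names))

  plots_l <- vi_l <- vector("list", n_env)
  for (ei in seq_len(n_env)) {
    es <- config$environments[[ei]]
    np <- nh * config$n_reps
    # RCBD: reps occupy contiguous blocks of the range-by-row grid,
    # hybrids randomized within each rep block
    grid <- expand.grid(range = seq_len(es$n_ranges), row = seq_len(es$n_rows))
    grid <- grid[order(grid$range, grid$row), ][seq_len(np), ]
    pl <- data.frame(
      hybrid = unlist(lapply(seq_len(config$n_reps),
                             function(r) sample(hybrids))),
      environment = es$name,
      range = grid$range, row = grid$row,
      rep = rep(seq_len(config$n_reps), each = nh),
      stringsAsFactors = FALSE)
    pl$gy <- .sim_trait_env(pl, u_gy, gxe_gy[, ei], env_mu_gy[ei],
                            config$heritability_gy, config$n_reps,
                            0.3 * config$spatial_sd)
    pl$pht <- .sim_trait_env(pl, u_pht, gxe_pht[, ei], env_mu_pht[ei],
                             config$heritability_pht, config$n_reps,
                             4 * config$spatial_sd)
    plots_l[[ei]] <- pl

    if (nv > 0L) {
      daps <- es$flight_daps
      nf <- length(daps)
      rng_eff <- stats::rnorm(es$n_ranges, sd = 0.01 * config$spatial_sd)
      row_eff <- stats::rnorm(es$n_rows, sd = 0.01 * config$spatial_sd)
      rep_eff <- stats::rnorm(config$n_reps, sd = 0.005 * config$spatial_sd)
      spat <- rng_eff[pl$range] + row_eff[pl$row] + rep_eff[pl$rep]
      hi <- match(pl$hybrid, hybrids)
      per_vi <- vector("list", nv)
      for (v in seq_len(nv)) {
        gmod <- g_vi[, v] + gxe_vi[, v, ei]      # hybrid modifier, this env
        amp <- vi_amp[v] * env_amp_mult[ei] * (1 + 0.15 * gmod)
        tg <- env_t_green[ei] + 2 * gmod
        # hybrid x flight trajectory values
        sen_curve <- vi_sen[v] * env_amp_mult[ei] *
          stats::plogis(vi_rate_s[v] * (daps - env_t_sen[ei]))
        # genetics enter the whole-curve level (0.12 amp), the amplitude
        # (0.15) and the green-up timing (2 d per SD of the modifier)
        traj <- vi_base[v] + 0.12 * vi_amp[v] * gmod +
          amp * stats::plogis(vi_rate_g[v] * outer(-tg, daps, `+`)) -
          matrix(sen_curve, nh, nf, byrow = TRUE)
        vals <- traj[hi, , drop = FALSE] + spat +
          matrix(stats::rnorm(np * nf, sd = 0.02), np, nf)
        per_vi[[v]] <- data.frame(
          hybrid = rep(pl$hybrid, nf), environment = es$name,
          flight_dap = rep(daps, each = np),
          vi_name = config$vi_names[v],
          range = rep(pl$range, nf), row = rep(pl$row, nf),
          rep = rep(pl$rep, nf),
          value = as.vector(vals), stringsAsFactors = FALSE)
      }
      vi_l[[ei]] <- do.call(rbind, per_vi)
    }
  }

  structure(list(
    markers = X,
    plots = do.call(rbind, plots_l),
    vi_obs = if (nv > 0L) do.call(rbind, vi_l) else NULL,
    truth = list(u_gy = u_gy, u_pht = u_pht, z = z,
                 vi_loadings = loadings, g_vi = g_vi,
                 gxe_gy = gxe_gy, gxe_pht = gxe_pht,
                 env_mu_gy = env_mu_gy, env_mu_pht = env_mu_pht),
    config = config), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat("Synthetic multi-environment trial\n")
  cat("  hybrids:", x$config$n_hybrids,
      " markers:", x$config$n_markers,
      " reps:", x$config$n_reps, "\n")
  cat("  environments:",
      paste(vapply(x$config$environments, function(e)
        sprintf("%s (%d flights)", e$name, length(e$flight_daps)),
        character(1)), collapse = ", "), "\n")
  cat("  plot records:", nrow(x$plots),
      " VI records:", if (is.null(x$vi_obs)) 0L else nrow(x$vi_obs), "\n")
  invisible(x)
}
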