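#' Flight-wise correlation between a VI's temporal values and a trait
#'
#' For one vegetation index and environment, computes at every flight the
#' Pearson correlation over hybrids between the hybrid-by-flight BLUP and
#' the hybrid's trait BLUE, then summarizes the per-flight correlations by
#' their mean and standard deviation. These temporal correlations are how
#' the secondary trait for the multitrait model is chosen.
#'
#' The temporal value correlated at each flight is the hybrid's full
#' predicted deviation there — the hybrid main-effect BLUP plus the
#' hybrid-by-flight BLUP when the table carries both (the interaction
#' alone is mean-centered per hybrid, which would force the per-flight
#' correlations to change sign across the season and their mean toward
#' zero regardless of the underlying genetic association).
#'
#' Flights where either input has zero variance have no defined
#' correlation; they are excluded from the mean/sd with a warning.
#'
#' @param blups Temporal BLUP table from [fit_temporal_blups()].
#' @param blues BLUE table from [fit_blues()].
#' @param vi_name Vegetation index to correlate.
#' @param trait Trait label carried into the output (the `blues` table is
#'   assumed to already hold that trait).
#' @param environment Environment label.
#' @return An object of class `temporal_correlation`: list with `vi_name`,
#'   `environment`, `trait`, `r` (named by flight DAP), `mean`, `sd`,
#'   `n_hybrids`.
#' @export
temporal_correlation <- function(blups, blues, vi_name, trait, environment) {
  b <- blups[blups$vi_name == vi_name & blups$environment == environment, ]
  if (!nrow(b)) stop("no BLUPs for VI ", vi_name, " in ", environment)
  e <- blues[blues$environment == environment, ]
  common <- intersect(unique(b$hybrid), e$hybrid)
  if (length(common) < 3L) stop("need >= 3 hybrids common to both tables")
  y <- stats::setNames(e$blue, e$hybrid)[common]

  daps <- sort(unique(b$flight_dap))
  r <- vapply(daps, function(dp) {
    bi <- b[b$flight_dap == dp, ]
    tv <- if ("blup_hybrid" %in% names(bi)) bi$blup + bi$blup_hybrid
    else bi$blup
    x <- stats::setNames(tv, bi$hybrid)[common]
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
  names(r) <- daps
  if (anyNA(r))
    warning(sum(is.na(r)), " flight(s) with zero variance excluded for ",
            vi_name, " in ", environment)
  r_ok <- r[!is.na(r)]
  structure(list(vi_name = vi_name, environment = environment, trait = trait,
                 r = r, mean = mean(r_ok),
                 sd = if (length(r_ok) > 1L) stats::sd(r_ok) else 0,
                 n_hybrids = length(common)),
            class = "temporal_correlation")
}

#' @export
print.temporal_correlation <- function(x, ...) {
  cat(sprintf("Temporal correlation %s ~ %s in %s: %.3f +/- %.3f (%d flights)\n",
              x$vi_name, x$trait, x$environment, x$mean, x$sd,
              sum(!is.na(x$r))))
  invisible(x)
}

#' Rank vegetation indices by mean temporal correlation
#'
#' Orders `temporal_correlation` results by mean correlation, descending,
#' with ties broken by VI name so the ranking is deterministic. The top
#' entry is the natural choice of secondary trait for the multitrait
#' model.
#'
#' @param correlations List of [temporal_correlation()] results.
#' @return Data frame (`vi_name`, `environment`, `trait`, `mean_r`,
#'   `sd_r`), sorted.
#' @export
rank_vis <- function(correlations) {
  if (!length(correlations)) stop("no correlations to rank")
  df <- do.call(rbind, lapply(correlations, function(tc)
    data.frame(vi_name = tc$vi_name, environment = tc$environment,
               trait = tc$trait, mean_r = tc$mean, sd_r = tc$sd,
               stringsAsFactors = FALSE)))
  df[order(-df$mean_r, df$vi_name), , drop = FALSE]
}
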