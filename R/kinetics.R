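# kinetics: initial uptake rates from radiolabel counts, Michaelis-Menten
# parameter fitting, and specific growth rates from OD time courses.

#' Initial uptake rate from radiolabel counts
#'
#' `rate = ((activity - background) / specific_activity) / (time/60) /
#' dry_weight`, in nmol min^-1 mg DW^-1. A negative corrected activity
#' (background over-correction) yields a negative rate that is flagged, not
#' silently clamped.
#'
#' @param activity counted activity, Bq (vectorized).
#' @param background negative-control background, Bq.
#' @param specific_activity substrate specific activity, Bq nmol^-1 (> 0).
#' @param time incubation time, seconds (> 0; assays typically stop at 20 s).
#' @param dry_weight cell dry weight, mg (> 0).
#' @return Data frame with columns `rate` (nmol min^-1 mgDW^-1) and
#'   `flagged` (TRUE where the corrected activity was negative).
#' @export
rate_from_counts <- function(activity, background, specific_activity,
                             time, dry_weight) {
  if (any(specific_activity <= 0)) stop("specific_activity must be > 0")
  if (any(time <= 0)) stop("time must be > 0")
  if (any(dry_weight <= 0)) stop("dry_weight must be > 0")
  corrected <- activity - background
  rate <- (corrected / specific_activity) / (time / 60) / dry_weight
  data.frame(rate = rate, flagged = corrected < 0)
}

.as_uptake_df <- function(observations) {
  obs <- as.data.frame(observations)
  if (!"substrate_mM" %in% names(obs)) {
    if ("substrate_uM" %in% names(obs))
      obs$substrate_mM <- obs$substrate_uM / 1000
    else stop("observations need a substrate_mM (or substrate_uM) column")
  }
  if (!"rate" %in% names(obs)) {
    need <- c("activity_Bq", "background_Bq", "specific_activity_Bq_per_nmol",
              "time_s", "dry_weight_mg")
    if (!all(need %in% names(obs)))
      stop("observations need a rate column or raw count columns (",
           paste(need, collapse = ", "), ")")
    rc <- rate_from_counts(obs$activity_Bq, obs$background_Bq,
                           obs$specific_activity_Bq_per_nmol,
                           obs$time_s, obs$dry_weight_mg)
    obs$rate <- rc$rate
    obs$flagged <- rc$flagged
  }
  if (is.null(obs$flagged)) obs$flagged <- obs$rate < 0
  if (any(obs$substrate_mM <= 0)) stop("substrate concentrations must be > 0")
  obs
}

#' Fit Michaelis-Menten uptake kinetics
#'
#' Nonlinear least squares on `V = Vmax * S / (Km + S)` (pooled unweighted
#' observations), initialized at `Vmax0 = max(V)` and `Km0` = the
#' concentration whose rate is nearest `Vmax0/2`. Standard errors come from
#' the curvature of the objective at the optimum. Negative (flagged) rates
#' are excluded by default.
#'
#' @param observations data frame with columns `substrate_mM` (or
#'   `substrate_uM`, converted on ingest) and `rate`, or the raw count
#'   columns accepted by [rate_from_counts()]; optional `replicate`.
#' @param include_flagged keep negative-rate observations in the fit.
#' @return An object of class `mm_fit`: list with `Vmax`, `Km`, `se_Vmax`,
#'   `se_Km`, `rss`, `n`, and the underlying `nls` fit.
#' @export
fit_michaelis_menten <- function(observations, include_flagged = FALSE) {
  obs <- .as_uptake_df(observations)
  if (!include_flagged) obs <- obs[!obs$flagged, , drop = FALSE]
  if (length(unique(obs$substrate_mM)) < 3L)
    stop("need at least 3 distinct substrate concentrations")
  if (all(obs$rate == 0)) stop("all rates are zero; nothing to fit")
  vmax0 <- max(obs$rate)
  km0 <- obs$substrate_mM[which.min(abs(obs$rate - vmax0 / 2))]
  km0 <- max(km0, min(obs$substrate_mM) / 10)
  fit <- minpack.lm::nlsLM(
    rate ~ Vmax * substrate_mM / (Km + substrate_mM), data = obs,
    start = list(Vmax = vmax0, Km = km0),
    lower = c(Vmax = 1e-12, Km = 1e-12),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                         ptol = 1e-15))
  if (!fit$convInfo$isConv)
    stop("Michaelis-Menten fit did not converge after ",
         fit$convInfo$finIter, " iterations")
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  structure(list(Vmax = unname(est["Vmax"]), Km = unname(est["Km"]),
                 se_Vmax = unname(se["Vmax"]), se_Km = unname(se["Km"]),
                 rss = sum(residuals(fit)^2), n = nrow(obs), fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Michaelis-Menten fit (n = %d):\n", x$n))
  cat(sprintf("  Vmax = %.4g +/- %.2g nmol min^-1 mgDW^-1\n",
              x$Vmax, x$se_Vmax))
  cat(sprintf("  Km   = %.4g +/- %.2g mM\n", x$Km, x$se_Km))
  cat(sprintf("  RSS  = %.4g\n", x$rss))
  invisible(x)
}

#' Predicted Michaelis-Menten rate
#'
#' @param object an `mm_fit`.
#' @param substrate_mM concentrations, mM.
#' @param ... unused.
#' @return Predicted rates.
#' @export
predict.mm_fit <- function(object, substrate_mM, ...) {
  object$Vmax * substrate_mM / (object$Km + substrate_mM)
}

#' Specific growth rate from an OD time course
#'
#' The stationary-phase onset is the first time point whose OD reaches 95%
#' of the series maximum; the specific growth rate mu (h^-1) is the slope
#' of the least-squares line through ln(OD) versus time from T = 0 up to
#' (and including) that onset. If the onset leaves fewer than 3 points the
#' series has no resolvable exponential phase and the whole series is used
#' (a constant series therefore gives mu = 0).
#'
#' @param time time points, hours, strictly increasing.
#' @param od optical-density values, > 0; alternatively pass a data frame
#'   with columns `time_h` and `od` as `time`.
#' @return An object of class `growth_fit`: list with `mu` (h^-1),
#'   `intercept_ln_od`, `onset_time`, `n_used`.
#' @export
fit_growth_rate <- function(time, od) {
  if (is.data.frame(time)) {
    od <- time$od
    time <- time$time_h
  }
  stopifnot(length(time) == length(od))
  if (length(time) < 3L) stop("need at least 3 time points")
  if (any(diff(time) <= 0)) stop("time points must be strictly increasing")
  if (any(od <= 0)) stop("OD values must be positive")
  onset <- which(od >= 0.95 * max(od))[1L]
  use <- if (onset >= 3L) seq_len(onset) else seq_along(time)
  f <- lm(log(od[use]) ~ time[use])
  structure(list(mu = unname(coef(f)[2L]),
                 intercept_ln_od = unname(coef(f)[1L]),
                 onset_time = time[onset], n_used = length(use)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("growth fit: mu = %.4g h^-1 (%d points to onset t = %g h)\n",
              x$mu, x$n_used, x$onset_time))
  invisible(x)
}
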