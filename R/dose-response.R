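# Hill-curve fitting of velocity dose-response data and the speed map used by
# the predation simulator.

#' Construct a saturating response curve
#'
#' A four-parameter Hill description of chemokinetic speed versus inducer
#' concentration: `v(c) = v0 + (vmax - v0) c^h / (ec50^h + c^h)`.
#'
#' @param v0 baseline velocity at zero dose (um/min).
#' @param vmax saturating velocity (um/min), `>= v0`.
#' @param ec50 half-maximal concentration (must be positive).
#' @param hill Hill slope (positive).
#' @param dose_unit label for the concentration axis (e.g. `"mg/ml"`).
#' @return object of class `response_curve`.
#' @export
response_curve <- function(v0 = 1, vmax = 3, ec50 = 1, hill = 1,
                           dose_unit = "mg/ml") {
  .check_pos(ec50, "ec50")
  .check_pos(hill, "hill")
  if (!.is_num1(v0) || !.is_num1(vmax) || vmax < v0)
    stop("need finite `v0` and `vmax` with vmax >= v0", call. = FALSE)
  structure(list(v0 = v0, vmax = vmax, ec50 = ec50, hill = hill,
                 dose_unit = dose_unit, converged = TRUE,
                 residual_sd = NA_real_),
            class = "response_curve")
}

#' @export
print.response_curve <- function(x, ...) {
  cat(sprintf(
    "<response_curve> v0 = %.4g, vmax = %.4g um/min; EC50 = %.4g %s; hill = %.3g\n",
    x$v0, x$vmax, x$ec50, x$dose_unit, x$hill))
  if (!is.na(x$residual_sd))
    cat(sprintf("  residual SD %.4g, converged: %s\n", x$residual_sd,
                x$converged))
  if (!isTRUE(x$converged)) cat("  ** fit flagged as unreliable **\n")
  invisible(x)
}

#' Fit a Hill dose-response curve to velocity readings
#'
#' Least-squares fit of `v(c) = v0 + (vmax - v0) c^h / (ec50^h + c^h)` by
#' Levenberg-Marquardt with box constraints, started from several
#' data-quantile initializations (EC50 starts at the 25th, 50th and 75th dose
#' percentiles) and keeping the best-converged fit. Dose zero is evaluated
#' exactly; no pseudo-dose is substituted for log spacing.
#'
#' @param data data frame with columns `dose` and `velocity` (a `replicate`
#'   column is allowed and ignored by the fit).
#' @param fix_hill optional fixed Hill slope (e.g. `1`); `NULL` fits it.
#' @param dose_unit label carried into the result.
#' @return a `response_curve` with fitted parameters plus `residual_sd`,
#'   `converged`, and `fit` (the underlying `nls` object, or `NULL`). An
#'   unidentifiable or non-convergent fit is returned with
#'   `converged = FALSE`, never silently.
#' @export
fit_response_curve <- function(data, fix_hill = NULL, dose_unit = "mg/ml") {
  stopifnot(all(c("dose", "velocity") %in% names(data)))
  data <- data[is.finite(data$dose) & is.finite(data$velocity), ]
  doses <- sort(unique(data$dose))
  if (length(doses) < 4L)
    stop("need >= 4 distinct doses to fit a Hill curve", call. = FALSE)
  if (min(doses) > 0.05 * max(doses))
    warning("no zero or near-zero dose: baseline v0 is poorly constrained",
            call. = FALSE)

  mean_by_dose <- tapply(data$velocity, data$dose, mean)
  v0_init <- as.numeric(mean_by_dose[1])
  vmax_init <- as.numeric(mean_by_dose[length(mean_by_dose)])
  pos <- doses[doses > 0]
  ec50_starts <- unique(quantile(pos, c(0.25, 0.5, 0.75), names = FALSE))
  hill_starts <- if (is.null(fix_hill)) c(1, 2) else fix_hill

  # flat data: the curve is unidentifiable; flag rather than fit garbage
  if (stats::var(data$velocity) == 0 ||
      abs(vmax_init - v0_init) < 1e-12 * max(1, abs(v0_init))) {
    out <- response_curve(v0 = v0_init, vmax = v0_init + 1e-12,
                          ec50 = stats::median(pos),
                          hill = if (is.null(fix_hill)) 1 else fix_hill,
                          dose_unit = dose_unit)
    out$converged <- FALSE
    out$residual_sd <- sd(data$velocity)
    out$fit <- NULL
    return(out)
  }

  best <- NULL
  for (e0 in ec50_starts) for (h0 in hill_starts) {
    fit <- tryCatch({
      if (is.null(fix_hill)) {
        minpack.lm::nlsLM(
          velocity ~ v0 + (vmax - v0) * ifelse(dose > 0,
            dose^hill / (ec50^hill + dose^hill), 0),
          data = data,
          start = list(v0 = v0_init, vmax = vmax_init, ec50 = e0, hill = h0),
          lower = c(v0 = -Inf, vmax = -Inf, ec50 = 1e-12, hill = 0.05),
          upper = c(v0 = Inf, vmax = Inf, ec50 = Inf, hill = 20),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      } else {
        minpack.lm::nlsLM(
          velocity ~ v0 + (vmax - v0) * ifelse(dose > 0,
            dose^fix_hill / (ec50^fix_hill + dose^fix_hill), 0),
          data = data,
          start = list(v0 = v0_init, vmax = vmax_init, ec50 = e0),
          lower = c(v0 = -Inf, vmax = -Inf, ec50 = 1e-12),
          upper = c(v0 = Inf, vmax = Inf, ec50 = Inf),
          control = minpack.lm::nls.lm.control(maxiter = 200))
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(resid(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }

  if (is.null(best)) {
    out <- response_curve(v0 = v0_init, vmax = max(vmax_init, v0_init),
                          ec50 = stats::median(pos),
                          hill = if (is.null(fix_hill)) 1 else fix_hill,
                          dose_unit = dose_unit)
    out$converged <- FALSE
    out$residual_sd <- sd(data$velocity)
    out$fit <- NULL
    return(out)
  }

  p <- coef(best$fit)
  hill_hat <- if (is.null(fix_hill)) unname(p["hill"]) else fix_hill
  n <- nrow(data)
  k <- length(p)
  out <- structure(list(
    v0 = unname(p["v0"]), vmax = unname(p["vmax"]),
    ec50 = unname(p["ec50"]), hill = hill_hat, dose_unit = dose_unit,
    converged = TRUE,
    residual_sd = sqrt(best$ssr / max(1, n - k))
  ), class = "response_curve")
  # EC50 outside (or at the edge of) the tested dose range is extrapolation
  if (out$ec50 > 2 * max(pos) || out$ec50 < 1e-10) out$converged <- FALSE
  if (out$vmax < out$v0) {
    # decreasing response: keep estimates but flag, the model family assumes
    # a non-decreasing curve
    out$converged <- FALSE
  }
  out$fit <- best$fit
  out
}

#' Chemokinetic speed as a function of concentration
#'
#' Returns the monotone non-decreasing map from local chemo-effector
#' concentration to crawling speed implied by a response curve. The map
#' satisfies `f(0) = v0` and `f(c) -> vmax` as `c -> Inf`.
#'
#' @param curve a `response_curve`.
#' @return vectorized function `concentration -> speed (um/min)`.
#' @export
speed_function <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  v0 <- curve$v0; vmax <- curve$vmax; ec50 <- curve$ec50; h <- curve$hill
  function(conc) {
    conc <- pmax(conc, 0)
    hill_velocity(conc, v0, vmax, ec50, h)
  }
}

#' Implied albumin concentration at a serum EC50
#'
#' Given the albumin content of a serum (mg/ml) and the serum's EC50 expressed
#' as a volume fraction, returns the albumin concentration present at that
#' EC50 -- the arithmetic used to argue that serum albumin alone can account
#' for a serum's chemokinesis potency. For example, a serum containing
#' 25 mg/ml albumin with an EC50 of 1% v/v implies 0.25 mg/ml albumin at the
#' EC50, the same order as the EC50 of the pure protein (~1 mg/ml).
#'
#' @param bsa_content albumin content of the serum in mg/ml (positive).
#' @param fbs_ec50 serum EC50 as a volume fraction (e.g. `0.01` for 1% v/v).
#' @return implied albumin concentration in mg/ml.
#' @export
implied_bsa_at_fbs_ec50 <- function(bsa_content, fbs_ec50) {
  .check_pos(bsa_content, "bsa_content")
  .check_nonneg(fbs_ec50, "fbs_ec50")
  bsa_content * fbs_ec50
}
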