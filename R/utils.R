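# Internal numeric helpers shared across modules.

#' Draw from a truncated normal distribution
#'
#' Samples from N(mean, sd^2) truncated to `[mean - bound, mean + bound]` by
#' inverse-CDF transform. Used for turn angles of persistent random walks.
#'
#' @param n number of draws.
#' @param mean centre of the untruncated normal.
#' @param sd standard deviation of the untruncated normal; `sd = 0` returns
#'   `mean` exactly.
#' @param bound symmetric truncation half-width (same units as `sd`); must be
#'   positive.
#' @return numeric vector of length `n`.
#' @export
rtruncnorm_sym <- function(n, mean = 0, sd = 1, bound = pi) {
  stopifnot(n >= 0, sd >= 0, bound > 0)
  if (n == 0) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  lo <- pnorm(-bound / sd)
  hi <- pnorm(bound / sd)
  mean + sd * qnorm(runif(n, lo, hi))
}

#' Mean resultant cosine of a symmetric truncated-normal turn angle
#'
#' Computes `E[cos(theta)]` for `theta ~ N(0, sd^2)` truncated to
#' `[-bound, bound]`, the single number that sets the directional persistence
#' of a correlated random walk with that turn distribution.
#'
#' @inheritParams rtruncnorm_sym
#' @return scalar in `(-1, 1]`.
#' @export
truncnorm_mean_cos <- function(sd, bound = pi) {
  stopifnot(sd >= 0, bound > 0)
  if (sd == 0) return(1)
  z <- 2 * (pnorm(bound / sd) - 0.5)   # truncated mass
  f <- function(x) cos(x) * exp(-x^2 / (2 * sd^2))
  num <- integrate(f, -bound, bound, rel.tol = 1e-10)$value
  num / (sqrt(2 * pi) * sd * z)
}

#' Closed-form mean-squared displacement of a 2-D persistent random walk
#'
#' Exact discrete-step MSD of a correlated random walk with i.i.d. step
#' lengths and i.i.d. symmetric turn angles:
#' \deqn{E[R_n^2] = n m_2 + 2 \mu^2 \sum_{k=1}^{n-1} (n-k) c^k}
#' where \eqn{\mu} and \eqn{m_2} are the first and second moments of the step
#' length and \eqn{c = E[\cos\theta]}. In the continuum limit this reduces to
#' the Fuerth formula with persistence time \eqn{P = -\Delta t / \ln c} and
#' diffusivity \eqn{v^2 P / 2}.
#'
#' @param n_steps integer vector of lag lengths (in steps).
#' @param step_mean mean step length (micrometres).
#' @param turn_sd,turn_bound turn-angle distribution parameters (radians).
#' @param step_dist `"exponential"` (second moment `2 * step_mean^2`) or
#'   `"fixed"` (second moment `step_mean^2`).
#' @return numeric vector of MSD values (micrometres squared), one per lag.
#' @export
prw_msd_theory <- function(n_steps, step_mean, turn_sd, turn_bound = pi,
                           step_dist = c("exponential", "fixed")) {
  step_dist <- match.arg(step_dist)
  stopifnot(all(n_steps >= 1), step_mean > 0)
  m2 <- if (step_dist == "exponential") 2 * step_mean^2 else step_mean^2
  cc <- truncnorm_mean_cos(turn_sd, turn_bound)
  vapply(as.integer(n_steps), function(n) {
    if (n == 1 || cc == 0) return(n * m2)
    k <- seq_len(n - 1)
    n * m2 + 2 * step_mean^2 * sum((n - k) * cc^k)
  }, numeric(1))
}

#' Persistence time implied by a turn-angle distribution
#'
#' @inheritParams prw_msd_theory
#' @param dt time between steps (seconds).
#' @return persistence time in seconds (`Inf` for a zero-turn walk).
#' @export
prw_persistence_time <- function(turn_sd, turn_bound = pi, dt = 1) {
  cc <- truncnorm_mean_cos(turn_sd, turn_bound)
  if (cc >= 1) return(Inf)
  -dt / log(cc)
}

# Reflect coordinates into [0, w] by folding (triangle wave); handles
# excursions of arbitrary length.
fold_reflect <- function(x, w) {
  stopifnot(w > 0)
  y <- x %% (2 * w)
  ifelse(y > w, 2 * w - y, y)
}

# Euclidean distance helper for paired coordinate vectors.
.dist2d <- function(x1, y1, x2, y2) sqrt((x2 - x1)^2 + (y2 - y1)^2)

# Scalar finite positive check used by config validators.
.is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.check_pos <- function(x, name) {
  if (!.is_num1(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

.check_nonneg <- function(x, name) {
  if (!.is_num1(x) || x < 0)
    stop(sprintf("`%s` must be a single non-negative finite number", name),
         call. = FALSE)
  invisible(x)
}

.check_prob <- function(x, name) {
  if (!.is_num1(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.check_count <- function(x, name, min = 1L) {
  if (!.is_num1(x) || x < min || x != as.integer(x))
    stop(sprintf("`%s` must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
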