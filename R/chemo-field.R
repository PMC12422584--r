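# Finite-difference model of the diffusing chemo-effector field exuded by prey.

#' Create a chemo-effector field state
#'
#' A square 2-D Cartesian lattice carrying the concentration of the
#' chemo-effector (mass per unit area, with unit depth this is interchangeable
#' with mass/volume), advanced by explicit forward-time centred-space (FTCS)
#' isotropic diffusion. The domain is `[0, extent] x [0, extent]` with nodes at
#' cell centres; the boundary is either `"absorbing"` (open bath: concentration
#' clamped to zero outside, appropriate when the domain is much larger than
#' the arena) or `"reflecting"` (closed, mass-conserving).
#'
#' @param extent side length of the square domain (micrometres).
#' @param h grid spacing (micrometres).
#' @param diffusivity diffusion coefficient D (um^2/s). The default 60 um^2/s
#'   is the literature order of magnitude for a ~66 kDa serum albumin in water
#'   at room temperature; it is an exposed assumption, not a measured value.
#' @param boundary `"absorbing"` or `"reflecting"`.
#' @return object of class `field_state` with elements `grid` (matrix, rows =
#'   x index, cols = y index), `nodes_x`, `nodes_y` (node coordinates), `h`,
#'   `extent`, `diffusivity`, `boundary`, `time`.
#' @export
field_state <- function(extent = 2400, h = 20, diffusivity = 60,
                        boundary = c("absorbing", "reflecting")) {
  boundary <- match.arg(boundary)
  .check_pos(extent, "extent")
  .check_pos(h, "h")
  .check_pos(diffusivity, "diffusivity")
  n <- max(3L, round(extent / h))
  h <- extent / n
  nodes <- (seq_len(n) - 0.5) * h
  structure(list(grid = matrix(0, n, n), nodes_x = nodes, nodes_y = nodes,
                 h = h, extent = extent, diffusivity = diffusivity,
                 boundary = boundary, time = 0),
            class = "field_state")
}

#' @export
print.field_state <- function(x, ...) {
  cat(sprintf(
    "<field_state> %dx%d grid, h = %.3g um, D = %g um^2/s, %s boundary, t = %g s\n",
    nrow(x$grid), ncol(x$grid), x$h, x$diffusivity, x$boundary, x$time))
  cat(sprintf("  total mass %.6g, max concentration %.6g\n",
              field_mass(x), max(x$grid)))
  invisible(x)
}

#' Total chemo-effector mass on the grid
#'
#' @param state a `field_state`.
#' @return scalar mass (concentration integrated over the domain).
#' @export
field_mass <- function(state) sum(state$grid) * state$h^2

#' Largest stable time step of the explicit diffusion scheme
#'
#' FTCS in 2-D is stable for `dt <= h^2 / (4 D)`.
#'
#' @param state a `field_state`.
#' @return stability bound in seconds.
#' @export
field_stability_dt <- function(state) state$h^2 / (4 * state$diffusivity)

#' Source model for prey exudation
#'
#' The prey exudes the chemo-effector at a rate dependent on the local
#' attachment of predator cells to its surface (attachment injures the prey
#' and releases more material), on top of a constitutive leak:
#' `rate = base_rate + attachment_coupling * activity`. With the default
#' `mode = "rate"` the activity is the recent attachment rate (events per
#' second, smoothed over `rate_window` seconds), so `attachment_coupling` is
#' the mass released per attachment event; each event yields a transient puff
#' that diffuses away. With `mode = "count"` the activity is the number of
#' currently attached cells and `attachment_coupling` is a sustained mass/s
#' per attached cell.
#'
#' @param base_rate constitutive exudation rate (mass/s), `>= 0`.
#' @param attachment_coupling mass released per attachment event
#'   (`mode = "rate"`) or additional rate per attached cell
#'   (`mode = "count"`); `>= 0`.
#' @param mode `"rate"` (default) or `"count"`.
#' @param rate_window smoothing window for the attachment rate (s).
#' @return object of class `source_model`.
#' @export
source_model <- function(base_rate = 2, attachment_coupling = 1750,
                         mode = c("rate", "count"), rate_window = 60) {
  mode <- match.arg(mode)
  .check_nonneg(base_rate, "base_rate")
  .check_nonneg(attachment_coupling, "attachment_coupling")
  .check_pos(rate_window, "rate_window")
  structure(list(base_rate = base_rate,
                 attachment_coupling = attachment_coupling,
                 mode = mode, rate_window = rate_window),
            class = "source_model")
}

# Nearest node indices of a point; clamped to the grid.
.node_index <- function(state, x, y) {
  i <- pmin(pmax(round(x / state$h + 0.5), 1L), nrow(state$grid))
  j <- pmin(pmax(round(y / state$h + 0.5), 1L), ncol(state$grid))
  cbind(i, j)
}

#' Advance the chemo-effector field by one time step
#'
#' One FTCS step of isotropic diffusion with source injection. Mass
#' `(base_rate + attachment_coupling * n_attached) * dt` is injected into the
#' grid cell containing `source_xy`. Errors (before touching the state) if
#' `dt` violates the stability bound; callers needing a larger `dt` should
#' sub-step.
#'
#' @param state a `field_state`.
#' @param source a `source_model`, or `NULL` for no injection.
#' @param n_attached attachment activity driving the coupled term: the
#'   attached-cell count (`mode = "count"`) or the recent attachment rate in
#'   events/s (`mode = "rate"`).
#' @param dt time step (seconds).
#' @param source_xy source location `c(x, y)` in micrometres (prey centre).
#' @return the advanced `field_state` (time incremented by `dt`);
#'   concentrations remain non-negative.
#' @export
step_field <- function(state, source = NULL, n_attached = 0, dt = 1,
                       source_xy = NULL) {
  stopifnot(inherits(state, "field_state"))
  .check_pos(dt, "dt")
  bound <- field_stability_dt(state)
  if (dt > bound * (1 + 1e-9))
    stop(sprintf("dt = %g s violates the FTCS stability bound %.4g s; sub-step",
                 dt, bound), call. = FALSE)
  g <- state$grid
  n <- nrow(g)
  lam <- state$diffusivity * dt / state$h^2
  # neighbour shifts with boundary handling: absorbing pads with zero,
  # reflecting pads with the edge value (zero-flux)
  pad <- function(gm, side) {
    edge <- switch(side,
                   up = gm[1, , drop = FALSE], down = gm[n, , drop = FALSE],
                   left = gm[, 1, drop = FALSE], right = gm[, n, drop = FALSE])
    if (state$boundary == "absorbing") edge[] <- 0
    edge
  }
  up    <- rbind(pad(g, "up"), g[-n, , drop = FALSE])
  down  <- rbind(g[-1, , drop = FALSE], pad(g, "down"))
  left  <- cbind(pad(g, "left"), g[, -n, drop = FALSE])
  right <- cbind(g[, -1, drop = FALSE], pad(g, "right"))
  g <- g + lam * (up + down + left + right - 4 * g)
  if (!is.null(source)) {
    stopifnot(inherits(source, "source_model"))
    rate <- source$base_rate + source$attachment_coupling * n_attached
    if (rate > 0) {
      if (is.null(source_xy)) source_xy <- rep(state$extent / 2, 2)
      ij <- .node_index(state, source_xy[1], source_xy[2])
      g[ij] <- g[ij] + rate * dt / state$h^2
    }
  }
  state$grid <- g
  state$time <- state$time + dt
  state
}

#' Interpolated concentration at arbitrary points
#'
#' Bilinear interpolation of the field at `(x, y)`; vectorized. Points outside
#' the node hull take the boundary value implied by the boundary condition
#' (zero beyond an absorbing boundary, the nearest edge value beyond a
#' reflecting one); interpolated values always lie between the neighbouring
#' node values and are never negative.
#'
#' @param state a `field_state`.
#' @param x,y coordinates in micrometres (equal-length vectors).
#' @return numeric vector of concentrations.
#' @export
concentration_at <- function(state, x, y) {
  stopifnot(length(x) == length(y))
  n <- nrow(state$grid)
  h <- state$h
  # continuous node-space coordinate: node i sits at (i - 0.5) h
  u <- x / h - 0.5
  v <- y / h - 0.5
  u <- pmin(pmax(u, 0), n - 1)
  v <- pmin(pmax(v, 0), n - 1)
  i0 <- pmin(floor(u), n - 2); j0 <- pmin(floor(v), n - 2)
  fu <- u - i0; fv <- v - j0
  g <- state$grid
  idx <- function(i, j) g[cbind(i + 1L, j + 1L)]
  val <- (1 - fu) * (1 - fv) * idx(i0, j0) +
         fu * (1 - fv) * idx(i0 + 1L, j0) +
         (1 - fu) * fv * idx(i0, j0 + 1L) +
         fu * fv * idx(i0 + 1L, j0 + 1L)
  if (state$boundary == "absorbing") {
    beyond <- x < 0 | y < 0 | x > state$extent | y > state$extent
    val[beyond] <- 0
  }
  pmax(val, 0)
}

#' Analytic Green's function of 2-D diffusion
#'
#' Concentration at radius `r` and time `t` after an instantaneous release of
#' mass `M` at the origin in an unbounded plane:
#' `C(r, t) = M / (4 pi D t) exp(-r^2 / (4 D t))`. Used as the closed-form
#' oracle for the finite-difference solver.
#'
#' @param r radial distance (um), vectorized.
#' @param t elapsed time (s), positive.
#' @param mass released mass.
#' @param diffusivity D (um^2/s).
#' @return concentration values.
#' @export
diffusion_green <- function(r, t, mass, diffusivity) {
  stopifnot(t > 0, diffusivity > 0)
  mass / (4 * pi * diffusivity * t) * exp(-r^2 / (4 * diffusivity * t))
}

#' Initial field for the depleted-prey scenario
#'
#' Builds the starting concentration profile after several nearby prey have
#' just been devoured: each depleted prey contributes a final burst of
#' chemo-effector, modelled as a radially symmetric Gaussian plume of the
#' given mass that has diffused for `age` seconds. Plumes superpose linearly.
#'
#' @param state a `field_state` to receive the profile (its existing grid is
#'   added to, so a live-source initial condition can be layered first).
#' @param centers list (or n-by-2 matrix) of burst centre coordinates in
#'   micrometres; at least one.
#' @param burst_mass mass released per depleted prey (same for all); must be
#'   non-negative.
#' @param age time since the bursts (s, positive); small ages give tightly
#'   concentrated plumes (choose `age` so the plume width `sqrt(4 D age)` is
#'   resolved by the grid if mass accounting matters).
#' @return the `field_state` with the burst profile added.
#' @export
depleted_prey_profile <- function(state, centers, burst_mass, age = 100) {
  stopifnot(inherits(state, "field_state"))
  if (is.list(centers)) centers <- do.call(rbind, centers)
  centers <- matrix(as.numeric(centers), ncol = 2)
  if (nrow(centers) < 1L) stop("need at least one burst centre", call. = FALSE)
  if (!.is_num1(burst_mass) || burst_mass < 0)
    stop("`burst_mass` must be non-negative", call. = FALSE)
  .check_pos(age, "age")
  if (burst_mass == 0) return(state)
  xs <- state$nodes_x
  ys <- state$nodes_y
  for (k in seq_len(nrow(centers))) {
    dx2 <- outer((xs - centers[k, 1])^2, (ys - centers[k, 2])^2, "+")
    state$grid <- state$grid +
      diffusion_green(sqrt(dx2), age, burst_mass, state$diffusivity)
  }
  state
}
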