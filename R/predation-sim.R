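# Agent-based Monte-Carlo simulation of predator cells hunting a stationary
# prey, with and without chemokinesis.

#' Simulation configuration
#'
#' Parameters of the predator-prey simulation: a population of crawling
#' predator cells (persistent random walkers) shares a square arena with one
#' stationary circular prey. A cell reaching the prey surface attaches
#' irreversibly and stops moving; attached cells damage the prey, which then
#' exudes the chemokinesis-inducing chemical faster. When chemokinesis is
#' enabled, each free cell's speed is the response curve evaluated at the
#' local chemo-effector concentration; when disabled the speed is the
#' baseline `v0` throughout.
#'
#' Default motility: per 1-s step the heading turns by a truncated-normal
#' angle with SD `0.3 / sqrt(60)` rad (the 0.3 rad per-minute-frame value
#' rescaled to the simulation step, since heading variance grows linearly in
#' time) and the cell advances by an exponentially distributed step whose mean
#' is `speed * dt`.
#'
#' @param n_cells number of predator cells (default 2000).
#' @param duration simulated time in seconds (default 7200, i.e. 120 min).
#' @param dt time step in seconds; `duration / dt` must be integral.
#' @param arena side length of the square arena (micrometres).
#' @param prey_center prey centre `c(x, y)`; default arena centre. The prey
#'   disk must lie inside the arena.
#' @param prey_radius prey radius (micrometres).
#' @param chemokinesis logical; couple speed to the local field?
#' @param response a [response_curve()] giving speed (um/min) versus
#'   concentration.
#' @param turn_sd,turn_bound turn-angle distribution per step (radians).
#' @param source a [source_model()] for prey exudation.
#' @param field_extent side of the (larger) diffusion domain; default 3x the
#'   arena so the absorbing outer boundary mimics an open bath far away.
#' @param diffusivity chemo-effector diffusivity (um^2/s); default 60, the
#'   serum-albumin order of magnitude.
#' @param field_h diffusion grid spacing (micrometres); must keep the FTCS
#'   scheme stable at `dt` (sub-stepping is applied automatically otherwise).
#' @param field_warmup seconds of prey exudation at the constitutive rate
#'   integrated before the run starts (the prey has been leaking since it was
#'   placed, so cells experience an established near-field from time zero);
#'   0 starts from a clean field.
#' @param replicates number of replicate runs.
#' @param seeds integer seeds, one per replicate.
#' @param trace_interval seconds between rows of the recorded
#'   attached-count/cumulative-residence trace.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_cells = 2000, duration = 7200, dt = 1,
                       arena = 400, prey_center = NULL, prey_radius = 50,
                       chemokinesis = TRUE,
                       response = response_curve(v0 = 2, vmax = 6,
                                                 ec50 = 1, hill = 2),
                       turn_sd = 0.3 / sqrt(60), turn_bound = pi,
                       source = source_model(),
                       field_extent = NULL, field_h = 25, diffusivity = 60,
                       field_warmup = 1800, replicates = 3, seeds = NULL, trace_interval = 60) {
  .check_count(n_cells, "n_cells")
  .check_pos(duration, "duration")
  .check_pos(dt, "dt")
  if (abs(duration / dt - round(duration / dt)) > 1e-9)
    stop("`duration` must be an integer multiple of `dt`", call. = FALSE)
  .check_pos(arena, "arena")
  .check_pos(prey_radius, "prey_radius")
  if (is.null(prey_center)) prey_center <- c(arena / 2, arena / 2)
  stopifnot(length(prey_center) == 2L, all(is.finite(prey_center)))
  if (prey_center[1] - prey_radius < 0 || prey_center[1] + prey_radius > arena ||
      prey_center[2] - prey_radius < 0 || prey_center[2] + prey_radius > arena)
    stop("prey disk must lie inside the arena", call. = FALSE)
  stopifnot(inherits(response, "response_curve"), inherits(source, "source_model"))
  .check_nonneg(turn_sd, "turn_sd")
  .check_pos(turn_bound, "turn_bound")
  .check_count(replicates, "replicates")
  if (is.null(field_extent)) field_extent <- 3 * arena
  .check_pos(field_extent, "field_extent")
  .check_pos(field_h, "field_h")
  .check_pos(diffusivity, "diffusivity")
  .check_nonneg(field_warmup, "field_warmup")
  if (is.null(seeds)) seeds <- seq_len(replicates)
  seeds <- as.integer(seeds)
  if (length(seeds) != replicates)
    stop("`seeds` must have one entry per replicate", call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), duration = duration, dt = dt,
                 arena = arena, prey_center = as.numeric(prey_center),
                 prey_radius = prey_radius, chemokinesis = isTRUE(chemokinesis),
                 response = response, turn_sd = turn_sd, turn_bound = turn_bound,
                 source = source, field_extent = field_extent,
                 field_h = field_h, diffusivity = diffusivity,
                 field_warmup = field_warmup,
                 replicates = as.integer(replicates),
                 seeds = seeds, trace_interval = trace_interval),
            class = "sim_config")
}

# Offset between arena coordinates and field-domain coordinates (the arena is
# centred in the larger diffusion domain).
.field_offset <- function(cfg) (cfg$field_extent - cfg$arena) / 2

#' Advance free agents by one step
#'
#' One Monte-Carlo step for a population of agents: every free (unattached)
#' agent turns by a truncated-normal angle, draws an exponential step length
#' with mean `speed * dt` (speed from the response curve at the local
#' concentration when chemokinesis is on, else the baseline), and moves.
#' Agents whose step segment crosses the prey boundary are clipped to the
#' intersection point and marked attached (segment-circle intersection, so
#' fast steps cannot tunnel through the prey); attached agents never move.
#' Arena edges reflect.
#'
#' @param agents list with numeric vectors `x`, `y`, `heading`, logical
#'   `attached`, numeric `attach_time`.
#' @param cfg a [sim_config()].
#' @param field a `field_state` or `NULL` (treated as zero concentration).
#' @param time current simulation time (s), used to stamp attachment times.
#' @return updated `agents` list.
#' @export
step_agents <- function(agents, cfg, field = NULL, time = 0) {
  free <- which(!agents$attached)
  if (length(free) == 0L) return(agents)
  x <- agents$x[free]; y <- agents$y[free]
  # local speed, um/s
  sf <- speed_function(cfg$response)
  if (cfg$chemokinesis && !is.null(field)) {
    off <- .field_offset(cfg)
    conc <- concentration_at(field, x + off, y + off)
    v <- sf(conc) / 60
  } else {
    v <- rep(cfg$response$v0 / 60, length(free))
  }
  heading <- agents$heading[free] +
    rtruncnorm_sym(length(free), 0, cfg$turn_sd, cfg$turn_bound)
  len <- rexp(length(free)) * v * cfg$dt    # Exp(mean = v dt)
  nx <- x + len * cos(heading)
  ny <- y + len * sin(heading)

  # segment-circle intersection with the prey disk: first t in [0,1] with
  # |p + t d - c| = R
  cx <- cfg$prey_center[1]; cy <- cfg$prey_center[2]; R <- cfg$prey_radius
  dx <- nx - x; dy <- ny - y
  fx <- x - cx; fy <- y - cy
  a <- dx^2 + dy^2
  b <- 2 * (fx * dx + fy * dy)
  cc <- fx^2 + fy^2 - R^2
  disc <- b^2 - 4 * a * cc
  hit <- rep(FALSE, length(free))
  thit <- rep(NA_real_, length(free))
  ok <- disc >= 0 & a > 0
  if (any(ok)) {
    sq <- sqrt(disc[ok])
    t1 <- (-b[ok] - sq) / (2 * a[ok])
    t2 <- (-b[ok] + sq) / (2 * a[ok])
    t1[t1 < 0] <- Inf
    t2[t2 < 0] <- Inf
    tmin <- pmin(t1, t2)
    good <- is.finite(tmin) & tmin <= 1
    hit[ok] <- good
    thit[ok][good] <- tmin[good]
  }
  if (any(hit)) {
    ih <- free[hit]
    th <- thit[hit]
    agents$x[ih] <- x[hit] + th * dx[hit]
    agents$y[ih] <- y[hit] + th * dy[hit]
    agents$attached[ih] <- TRUE
    agents$attach_time[ih] <- time + th * cfg$dt
  }
  if (any(!hit)) {
    im <- free[!hit]
    agents$x[im] <- fold_reflect(nx[!hit], cfg$arena)
    agents$y[im] <- fold_reflect(ny[!hit], cfg$arena)
    agents$heading[im] <- heading[!hit]
  }
  agents
}

# Uniform initial placement outside the prey disk, headings uniform.
.init_agents <- function(cfg) {
  n <- cfg$n_cells
  x <- numeric(0); y <- numeric(0)
  while (length(x) < n) {
    m <- 2 * (n - length(x)) + 16
    px <- runif(m, 0, cfg$arena); py <- runif(m, 0, cfg$arena)
    keep <- .dist2d(px, py, cfg$prey_center[1], cfg$prey_center[2]) >
      cfg$prey_radius
    x <- c(x, px[keep]); y <- c(y, py[keep])
  }
  list(x = x[seq_len(n)], y = y[seq_len(n)],
       heading = runif(n, -pi, pi),
       attached = rep(FALSE, n), attach_time = rep(NA_real_, n))
}

# One replicate; `burst` (list with centers/mass/age, field coordinates) lets
# the depleted scenario lay down its initial profile after field warm-up, so
# the bursts are fresh at simulation start.
.run_one <- function(cfg, seed, burst = NULL) {
  set.seed(seed)
  agents <- .init_agents(cfg)
  field <- field_state(extent = cfg$field_extent, h = cfg$field_h,
                       diffusivity = cfg$diffusivity, boundary = "absorbing")
  need_field <- cfg$chemokinesis
  n_sub <- if (need_field) max(1L, ceiling(cfg$dt / (0.9 * field_stability_dt(field))))
           else 1L
  off <- .field_offset(cfg)
  src_xy <- cfg$prey_center + off
  if (need_field && cfg$field_warmup > 0) {
    # pre-equilibrate the constitutive leak (no attachments yet)
    wdt <- 0.9 * field_stability_dt(field)
    wsteps <- ceiling(cfg$field_warmup / wdt)
    wdt <- cfg$field_warmup / wsteps
    for (k in seq_len(wsteps))
      field <- step_field(field, cfg$source, n_attached = 0, dt = wdt,
                          source_xy = src_xy)
    field$time <- 0
  }
  if (!is.null(burst) && burst$mass > 0)
    field <- depleted_prey_profile(field, burst$centers, burst$mass,
                                   age = burst$age)
  n_steps <- as.integer(round(cfg$duration / cfg$dt))
  rate_mode <- identical(cfg$source$mode, "rate")
  win_steps <- if (rate_mode)
    max(1L, as.integer(round(cfg$source$rate_window / cfg$dt))) else 0L
  att_hist <- integer(n_steps + 1L)   # attached count after each step
  trace_every <- max(1L, as.integer(round(cfg$trace_interval / cfg$dt)))
  trace_t <- numeric(0); trace_attached <- integer(0); trace_cum <- numeric(0)
  cum_residence_trace <- 0
  for (s in seq_len(n_steps)) {
    t_now <- (s - 1L) * cfg$dt
    agents <- step_agents(agents, cfg, field = if (need_field) field else NULL,
                          time = t_now)
    n_att <- sum(agents$attached)
    att_hist[s + 1L] <- n_att
    if (need_field) {
      activity <- if (rate_mode) {
        prev <- att_hist[max(1L, s + 1L - win_steps)]
        (n_att - prev) / (min(s, win_steps) * cfg$dt)
      } else n_att
      for (k in seq_len(n_sub))
        field <- step_field(field, cfg$source, n_attached = activity,
                            dt = cfg$dt / n_sub, source_xy = src_xy)
    }
    cum_residence_trace <- cum_residence_trace + sum(agents$attached) * cfg$dt
    if (s %% trace_every == 0L || s == n_steps) {
      trace_t <- c(trace_t, s * cfg$dt)
      trace_attached <- c(trace_attached, sum(agents$attached))
      trace_cum <- c(trace_cum, cum_residence_trace)
    }
  }
  attach_times <- agents$attach_time[agents$attached]
  residence <- cfg$duration - attach_times
  structure(list(
    seed = seed,
    n_cells = cfg$n_cells,
    duration = cfg$duration,
    attach_times = sort(attach_times),
    attachment_fraction = length(attach_times) / cfg$n_cells,
    residence_times = sort(residence, decreasing = TRUE),
    cumulative_residence = sum(residence),
    trace = data.frame(t = trace_t, attached = trace_attached,
                       cumulative_residence = trace_cum),
    chemokinesis = cfg$chemokinesis
  ), class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat(sprintf(
    "<sim_outcome> seed %d, chemokinesis %s: %.1f%% of %d cells attached,\n",
    x$seed, if (x$chemokinesis) "on" else "off",
    100 * x$attachment_fraction, x$n_cells))
  cat(sprintf("  cumulative residence %.4g cell-s over %g s\n",
              x$cumulative_residence, x$duration))
  invisible(x)
}

#' Run the predation simulation
#'
#' Runs `cfg$replicates` independent replicates of the agent-based
#' simulation, alternating agent stepping and field stepping (the exudation
#' rate is re-coupled to the attached count every step). Each replicate is
#' fully reproducible from its seed.
#'
#' @param cfg a [sim_config()].
#' @return list of `sim_outcome` objects, one per replicate; each carries the
#'   sorted attachment times, the attachment fraction, residence times
#'   (`duration - attach_time`; cells that never attach contribute nothing),
#'   the cumulative residence time, and a thinned time trace of the attached
#'   count and running cumulative residence.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lapply(cfg$seeds, function(s) .run_one(cfg, s))
}

#' Run the depleted-prey scenario
#'
#' Identical engine to [run_simulation()] with chemokinesis enabled, but the
#' field starts from a superposition of Gaussian bursts left by recently
#' devoured prey ([depleted_prey_profile()]) instead of from zero.
#'
#' @param cfg a [sim_config()] with `chemokinesis = TRUE`.
#' @param burst_centers list or n-by-2 matrix of burst centres in arena
#'   coordinates (micrometres); points outside the arena box are allowed (the
#'   diffusion domain is larger). Default: four depleted prey just beyond the
#'   arena corners, 0.325 arena widths outside each corner.
#' @param burst_mass mass per burst; `0` reproduces the standard chemokinesis
#'   run exactly (same seeds give identical outcomes). The default 5e4 is the
#'   documented assumption for a devoured prey's residual contents, roughly a
#'   tenth of what a live prey exudes over the whole simulation.
#' @param burst_age age of the bursts at simulation start (s).
#' @return list of `sim_outcome` objects, one per replicate.
#' @export
run_depleted_scenario <- function(cfg, burst_centers = NULL,
                                  burst_mass = 5e4, burst_age = 100) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!cfg$chemokinesis)
    stop("the depleted-prey scenario requires chemokinesis = TRUE",
         call. = FALSE)
  if (is.null(burst_centers)) {
    d <- 0.325 * cfg$arena
    a <- cfg$arena
    burst_centers <- rbind(c(-d, -d), c(a + d, -d), c(-d, a + d),
                           c(a + d, a + d))
  }
  if (is.list(burst_centers)) burst_centers <- do.call(rbind, burst_centers)
  burst_centers <- matrix(as.numeric(burst_centers), ncol = 2)
  off <- .field_offset(cfg)
  lapply(cfg$seeds, function(s)
    .run_one(cfg, s, burst = list(centers = burst_centers + off,
                                  mass = burst_mass, age = burst_age)))
}

#' Compare chemokinesis-on and chemokinesis-off outcome sets
#'
#' Summarizes the predation benefit of chemokinesis: the ratio of mean
#' cumulative residence time (on / off) with per-condition standard errors
#' across replicates, per-condition attachment fractions, and a comparison of
#' the conditional attachment-time distributions (cells that never attached
#' are excluded): a one-sided Wilcoxon rank-sum test of whether on-condition
#' cells attach earlier, and kernel density estimates of the attach-time
#' distributions.
#'
#' @param outcomes_on,outcomes_off lists of `sim_outcome` objects.
#' @param kde_bw kernel density bandwidth passed to [stats::density()]
#'   (default `"nrd0"`, Silverman's rule).
#' @return object of class `condition_comparison` with elements
#'   `ratio_cumulative_residence`, `mean_on`, `mean_off`, `sem_on`, `sem_off`,
#'   `attachment_fraction_on/off` (per replicate), `earlier_p` (one-sided
#'   rank-test p-value), `kde_on`, `kde_off`. A zero off-condition residence
#'   leaves the ratio `NA` with a warning rather than dividing by zero.
#' @export
compare_conditions <- function(outcomes_on, outcomes_off, kde_bw = "nrd0") {
  stopifnot(length(outcomes_on) >= 1, length(outcomes_off) >= 1)
  cr_on <- vapply(outcomes_on, `[[`, numeric(1), "cumulative_residence")
  cr_off <- vapply(outcomes_off, `[[`, numeric(1), "cumulative_residence")
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
  mean_off <- mean(cr_off)
  ratio <- if (mean_off > 0) mean(cr_on) / mean_off else {
    warning("off-condition cumulative residence is zero; ratio undefined",
            call. = FALSE)
    NA_real_
  }
  at_on <- unlist(lapply(outcomes_on, `[[`, "attach_times"))
  at_off <- unlist(lapply(outcomes_off, `[[`, "attach_times"))
  earlier_p <- if (length(at_on) && length(at_off))
    suppressWarnings(wilcox.test(at_on, at_off, alternative = "less")$p.value)
  else NA_real_
  structure(list(
    ratio_cumulative_residence = ratio,
    mean_on = mean(cr_on), mean_off = mean_off,
    sem_on = sem(cr_on), sem_off = sem(cr_off),
    cumulative_residence_on = cr_on, cumulative_residence_off = cr_off,
    attachment_fraction_on =
      vapply(outcomes_on, `[[`, numeric(1), "attachment_fraction"),
    attachment_fraction_off =
      vapply(outcomes_off, `[[`, numeric(1), "attachment_fraction"),
    earlier_p = earlier_p,
    kde_on = if (length(at_on) > 1) density(at_on, bw = kde_bw) else NULL,
    kde_off = if (length(at_off) > 1) density(at_off, bw = kde_bw) else NULL
  ), class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison>\n")
  cat(sprintf("  cumulative residence on : %.4g +/- %.3g cell-s (SEM)\n",
              x$mean_on, x$sem_on))
  cat(sprintf("  cumulative residence off: %.4g +/- %.3g cell-s (SEM)\n",
              x$mean_off, x$sem_off))
  cat(sprintf("  ratio (on/off): %.3f\n", x$ratio_cumulative_residence))
  cat(sprintf("  attachment fraction on : %s\n",
              paste(sprintf("%.3f", x$attachment_fraction_on), collapse = ", ")))
  cat(sprintf("  attachment fraction off: %s\n",
              paste(sprintf("%.3f", x$attachment_fraction_off), collapse = ", ")))
  cat(sprintf("  P(on attaches earlier), one-sided rank test: %.3g\n",
              x$earlier_p))
  invisible(x)
}
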