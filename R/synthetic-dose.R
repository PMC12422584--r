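# Synthetic dose-response readings and fluorescence traces.

#' Configuration for the synthetic dose-response generator
#'
#' @param doses vector of inducer concentrations (mg/ml or percent v/v);
#'   must be non-empty and non-negative.
#' @param v0 baseline velocity at zero dose (micrometres/minute).
#' @param vmax saturating velocity (micrometres/minute); must be `>= v0`.
#' @param ec50 concentration of half-maximal response; must be positive.
#' @param hill Hill slope (dimensionless, positive).
#' @param noise_sd standard deviation of additive Gaussian reading noise
#'   (micrometres/minute).
#' @param replicates readings per dose.
#' @param seed integer seed.
#' @return an object of class `dose_gen_config`.
#' @seealso [generate_dose_response()], [fit_response_curve()]
#' @export
dose_gen_config <- function(doses, v0 = 1, vmax = 3, ec50 = 1, hill = 1,
                            noise_sd = 0, replicates = 3, seed = 1L) {
  if (length(doses) == 0) stop("`doses` must be non-empty", call. = FALSE)
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("`doses` must be finite and non-negative", call. = FALSE)
  .check_pos(ec50, "ec50")
  .check_pos(hill, "hill")
  .check_nonneg(noise_sd, "noise_sd")
  .check_count(replicates, "replicates")
  if (!.is_num1(v0) || !.is_num1(vmax) || vmax < v0)
    stop("need finite `v0` and `vmax` with vmax >= v0", call. = FALSE)
  structure(list(doses = as.numeric(doses), v0 = v0, vmax = vmax, ec50 = ec50,
                 hill = hill, noise_sd = noise_sd,
                 replicates = as.integer(replicates), seed = as.integer(seed)),
            class = "dose_gen_config")
}

# Hill (saturating) velocity response; c may be a vector, c = 0 allowed.
hill_velocity <- function(conc, v0, vmax, ec50, hill) {
  ch <- conc^hill
  v0 + (vmax - v0) * ch / (ec50^hill + ch)
}

#' Generate synthetic velocity dose-response readings
#'
#' Mean velocities follow a four-parameter Hill curve
#' `v(c) = v0 + (vmax - v0) c^h / (ec50^h + c^h)` with additive Gaussian
#' replicate noise, emulating plate-based motility readings at a dose ladder.
#'
#' @param cfg a [dose_gen_config()].
#' @return data frame with columns `dose`, `replicate`, `velocity` and
#'   attribute `config`.
#' @export
generate_dose_response <- function(cfg) {
  stopifnot(inherits(cfg, "dose_gen_config"))
  set.seed(cfg$seed)
  out <- expand.grid(replicate = seq_len(cfg$replicates), dose = cfg$doses,
                     KEEP.OUT.ATTRS = FALSE)[, c("dose", "replicate")]
  mu <- hill_velocity(out$dose, cfg$v0, cfg$vmax, cfg$ec50, cfg$hill)
  out$velocity <- mu + if (cfg$noise_sd > 0) rnorm(nrow(out), 0, cfg$noise_sd) else 0
  out <- out[order(out$dose, out$replicate), ]
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  out
}

#' Generate synthetic calcium-indicator fluorescence traces
#'
#' Emulates a plate-reader calcium assay: each cell has a constant baseline
#' intensity (varying between cells), a step of height `jump_height` when the
#' test sample is added at `jump_time`, and i.i.d. Gaussian noise per frame.
#'
#' @param n_cells number of cells (traces).
#' @param n_frames frames per trace.
#' @param baseline mean baseline intensity (arbitrary units).
#' @param baseline_sd between-cell SD of the baseline (default 10% of
#'   `baseline`).
#' @param jump_time time of sample addition in seconds (default 25, i.e. after
#'   the baseline reading window).
#' @param jump_height intensity step at `jump_time`.
#' @param noise_sd per-frame Gaussian noise SD.
#' @param frame_interval seconds between frames (default 5).
#' @param well well label stored in the output.
#' @param seed integer seed.
#' @return data frame with columns `well`, `cell_id`, `frame`, `t_seconds`,
#'   `intensity`, plus attribute `truth` (list with `jump_frame` and
#'   `jump_height`).
#' @export
generate_fluorescence_traces <- function(n_cells = 100, n_frames = 36,
                                         baseline = 100, baseline_sd = NULL,
                                         jump_time = 25, jump_height = 50,
                                         noise_sd = 0, frame_interval = 5,
                                         well = "w1", seed = 1L) {
  .check_count(n_cells, "n_cells")
  .check_count(n_frames, "n_frames", min = 2L)
  .check_pos(frame_interval, "frame_interval")
  .check_nonneg(noise_sd, "noise_sd")
  if (is.null(baseline_sd)) baseline_sd <- 0.1 * abs(baseline)
  .check_nonneg(baseline_sd, "baseline_sd")
  t_seconds <- (seq_len(n_frames) - 1L) * frame_interval
  if (jump_time <= 0 || jump_time > max(t_seconds))
    stop("`jump_time` must fall within the trace", call. = FALSE)
  set.seed(seed)
  base_i <- rnorm(n_cells, baseline, baseline_sd)
  step <- ifelse(t_seconds >= jump_time, jump_height, 0)
  out <- data.frame(
    well = well,
    cell_id = rep(seq_len(n_cells), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, n_cells),
    t_seconds = rep(t_seconds, n_cells)
  )
  out$intensity <- rep(base_i, each = n_frames) + rep(step, n_cells) +
    if (noise_sd > 0) rnorm(nrow(out), 0, noise_sd) else 0
  attr(out, "truth") <- list(jump_frame = min(which(t_seconds >= jump_time)) - 1L,
                             jump_height = jump_height)
  out
}
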