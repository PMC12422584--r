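# Synthetic persistent-random-walk track generator with tracking artifacts.

#' Configuration for the synthetic track generator
#'
#' Bundles every parameter of the persistent-random-walk track generator.
#' Cells take one filopodial step per frame: the heading turns by a symmetric
#' truncated-normal angle and the cell advances by an exponentially distributed
#' step length, giving the strong directional persistence and fairly uniform
#' per-step travel observed for crawling filose amoebae. Two tracking
#' artifacts can be injected with known ground truth: spurious "floating cell"
#' jumps (sudden displacements much larger than a crawling step) and dropped
#' detections (gaps).
#'
#' @param n_cells number of tracks.
#' @param n_frames number of frames per track.
#' @param frame_interval seconds between frames (default 60, as in 1-min
#'   time-lapse imaging).
#' @param speed nominal speed in micrometres/minute; used to derive `step_mean`
#'   when that is not given.
#' @param turn_sd standard deviation of the per-frame turn angle (radians).
#' @param turn_bound symmetric truncation bound of the turn angle (radians).
#' @param step_mean mean of the exponential step length (micrometres);
#'   defaults to `speed * frame_interval / 60`.
#' @param step_dist `"exponential"` for exponentially distributed step lengths
#'   (the observed distribution for filopodial steps) or `"fixed"` for the
#'   deterministic limit where every step has length `step_mean`.
#' @param drift_toward_ref additional drift speed toward `ref` in
#'   micrometres/minute; 0 gives the pure-chemokinesis (unbiased) case.
#' @param ref reference point `c(x, y)` for the drift (micrometres); defaults
#'   to the arena centre.
#' @param spurious_rate per-frame probability that a track is hit by a spurious
#'   jump artifact.
#' @param spurious_length length of an artifact jump (micrometres). The default
#'   is 1.5 times the 11.2 micrometre chemotaxis-assay step threshold so that
#'   the standard filter is guaranteed to catch every injected artifact.
#' @param gap_rate per-frame probability that a detection is dropped.
#' @param arena `c(width, height)` of the arena in micrometres; origin at a
#'   corner. Tracks may leave the arena (no reflection is applied); the
#'   analysis layer must tolerate that.
#' @param seed integer seed; identical configurations and seeds give
#'   bit-identical output.
#' @return an object of class `track_gen_config`.
#' @seealso [generate_tracks()]
#' @export
track_gen_config <- function(n_cells = 50, n_frames = 60, frame_interval = 60,
                             speed = 1, turn_sd = 0.3, turn_bound = pi,
                             step_mean = NULL,
                             step_dist = c("exponential", "fixed"),
                             drift_toward_ref = 0, ref = NULL,
                             spurious_rate = 0, spurious_length = 1.5 * 11.2,
                             gap_rate = 0, arena = c(500, 500), seed = 1L) {
  step_dist <- match.arg(step_dist)
  .check_count(n_cells, "n_cells")
  .check_count(n_frames, "n_frames", min = 2L)
  .check_pos(frame_interval, "frame_interval")
  .check_nonneg(speed, "speed")
  .check_nonneg(turn_sd, "turn_sd")
  .check_pos(turn_bound, "turn_bound")
  .check_prob(spurious_rate, "spurious_rate")
  .check_prob(gap_rate, "gap_rate")
  .check_nonneg(drift_toward_ref, "drift_toward_ref")
  .check_pos(spurious_length, "spurious_length")
  if (length(arena) != 2L || any(!is.finite(arena)) || any(arena <= 0))
    stop("`arena` must be c(width, height), both positive", call. = FALSE)
  if (is.null(step_mean)) step_mean <- speed * frame_interval / 60
  .check_nonneg(step_mean, "step_mean")
  if (speed > 0 && step_mean <= 0)
    stop("`step_mean` must be positive when `speed` > 0", call. = FALSE)
  if (is.null(ref)) ref <- arena / 2
  stopifnot(length(ref) == 2L, all(is.finite(ref)))
  structure(list(
    n_cells = as.integer(n_cells), n_frames = as.integer(n_frames),
    frame_interval = frame_interval, speed = speed, turn_sd = turn_sd,
    turn_bound = turn_bound, step_mean = step_mean, step_dist = step_dist,
    drift_toward_ref = drift_toward_ref, ref = as.numeric(ref),
    spurious_rate = spurious_rate, spurious_length = spurious_length,
    gap_rate = gap_rate, arena = as.numeric(arena), seed = as.integer(seed)
  ), class = "track_gen_config")
}

#' Generate synthetic persistent-random-walk cell tracks
#'
#' Simulates `n_cells` independent correlated random walks. Each cell starts
#' at a uniform position in the arena with a uniform heading; at every frame
#' the heading turns by a truncated-normal angle and the cell moves by an
#' exponential (or fixed) step, plus an optional drift toward a reference
#' point. Artifact jumps (uniform direction, fixed length) and dropped
#' detections are then injected and recorded as ground truth.
#'
#' @param cfg a [track_gen_config()].
#' @return a `track_set`: a data frame with columns `cell_id`, `frame`,
#'   `t_seconds`, `x_um`, `y_um` (missing detections are absent rows, never
#'   `NA` rows), with attributes `config` (the generating configuration) and
#'   `truth` (a list with data frames `spurious` and `gaps` locating every
#'   injected artifact by `cell_id` and `frame`).
#' @examples
#' trk <- generate_tracks(track_gen_config(n_cells = 5, n_frames = 20, seed = 7))
#' head(trk)
#' @export
generate_tracks <- function(cfg) {
  stopifnot(inherits(cfg, "track_gen_config"))
  set.seed(cfg$seed)
  n <- cfg$n_cells
  nf <- cfg$n_frames
  frames <- seq_len(nf) - 1L
  t_seconds <- frames * cfg$frame_interval
  drift_step <- cfg$drift_toward_ref * cfg$frame_interval / 60

  pieces <- vector("list", n)
  spurious <- list()
  gaps <- list()
  for (i in seq_len(n)) {
    x <- numeric(nf); y <- numeric(nf)
    x[1] <- runif(1, 0, cfg$arena[1])
    y[1] <- runif(1, 0, cfg$arena[2])
    heading <- runif(1, -pi, pi)
    turns <- rtruncnorm_sym(nf - 1L, 0, cfg$turn_sd, cfg$turn_bound)
    steps <- if (cfg$speed == 0 || cfg$step_mean == 0) {
      rep(0, nf - 1L)
    } else if (cfg$step_dist == "exponential") {
      rexp(nf - 1L, rate = 1 / cfg$step_mean)
    } else {
      rep(cfg$step_mean, nf - 1L)
    }
    for (k in seq_len(nf - 1L)) {
      heading <- heading + turns[k]
      dx <- steps[k] * cos(heading)
      dy <- steps[k] * sin(heading)
      if (drift_step > 0) {
        rx <- cfg$ref[1] - x[k]; ry <- cfg$ref[2] - y[k]
        rn <- sqrt(rx^2 + ry^2)
        if (rn > 0) { dx <- dx + drift_step * rx / rn; dy <- dy + drift_step * ry / rn }
      }
      x[k + 1L] <- x[k] + dx
      y[k + 1L] <- y[k] + dy
    }
    # spurious floating-cell jumps: permanent displacement of the trajectory
    # tail, producing one adjacent-frame step longer than the filter threshold
    if (cfg$spurious_rate > 0) {
      hit <- which(runif(nf - 1L) < cfg$spurious_rate) + 1L
      for (f in hit) {
        ang <- runif(1, -pi, pi)
        x[f:nf] <- x[f:nf] + cfg$spurious_length * cos(ang)
        y[f:nf] <- y[f:nf] + cfg$spurious_length * sin(ang)
      }
      if (length(hit))
        spurious[[length(spurious) + 1L]] <-
          data.frame(cell_id = i, frame = frames[hit])
    }
    keep <- rep(TRUE, nf)
    if (cfg$gap_rate > 0) {
      # never drop the first frame so every track has a defined start
      drop <- which(runif(nf - 1L) < cfg$gap_rate) + 1L
      keep[drop] <- FALSE
      if (length(drop))
        gaps[[length(gaps) + 1L]] <- data.frame(cell_id = i, frame = frames[drop])
    }
    pieces[[i]] <- data.frame(
      cell_id = i, frame = frames[keep], t_seconds = t_seconds[keep],
      x_um = x[keep], y_um = y[keep]
    )
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "config") <- cfg
  attr(out, "truth") <- list(
    spurious = if (length(spurious)) do.call(rbind, spurious)
               else data.frame(cell_id = integer(), frame = integer()),
    gaps = if (length(gaps)) do.call(rbind, gaps)
           else data.frame(cell_id = integer(), frame = integer())
  )
  class(out) <- c("track_set", "data.frame")
  out
}

#' @export
print.track_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<track_set> %d cells, %d detections\n",
              length(unique(x$cell_id)), nrow(x)))
  if (!is.null(cfg))
    cat(sprintf("  frame interval %g s, nominal speed %g um/min\n",
                cfg$frame_interval, cfg$speed))
  print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Split a track table into per-cell data frames
#'
#' Orders the table by `cell_id` and `frame` and splits it into a named list
#' with one data frame per cell.
#'
#' @param tracks track table (dialect columns `cell_id`, `frame`,
#'   `t_seconds`, `x_um`, `y_um`).
#' @return named list of per-cell data frames.
#' @export
split_tracks <- function(tracks) {
  stopifnot(is.data.frame(tracks),
            all(c("cell_id", "frame", "t_seconds", "x_um", "y_um") %in%
                  names(tracks)))
  ord <- order(tracks$cell_id, tracks$frame)
  tracks <- as.data.frame(tracks)[ord, , drop = FALSE]
  split(tracks, tracks$cell_id, drop = TRUE)
}
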