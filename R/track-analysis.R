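# Track filtering and the chemokinesis / chemotaxis velocity statistics.

# Per-cell summaries used by several rules. Assumes rows ordered by frame.
.track_summary <- function(tr) {
  n <- nrow(tr)
  if (n < 2L) {
    return(list(n = n, max_adj_step = 0, max_gap = 0, total_path = 0))
  }
  df <- diff(tr$frame)
  d <- .dist2d(tr$x_um[-n], tr$y_um[-n], tr$x_um[-1], tr$y_um[-1])
  adj <- df == 1L
  list(n = n,
       max_adj_step = if (any(adj)) max(d[adj]) else 0,
       max_gap = max(df) - 1L,
       total_path = sum(d))
}

#' Filter tracks by the standard exclusion rules
#'
#' Applies the assay's exclusion thresholds to a set of tracks and reports how
#' many tracks each rule removed. A track is rejected if any adjacent-frame
#' step exceeds `max_step` (spurious floating-cell motion), any run of lost
#' frames exceeds `max_gap`, it has fewer than `min_frames` detections, or
#' (when a reference point is supplied and the policy has an annulus) its
#' first detected position lies outside `[annulus_min, annulus_max]` from the
#' reference. Gaps are never filled: surviving tracks keep their missing rows.
#'
#' A track failing several rules is counted under the first failing rule in
#' the order step, gap, min_frames, annulus, so rejection counts always sum to
#' the number of rejected tracks.
#'
#' @param tracks a `track_set` or data frame in the track table dialect
#'   (`cell_id`, `frame`, `t_seconds`, `x_um`, `y_um`).
#' @param policy a [filter_policy()].
#' @param ref reference point `c(x, y)` in micrometres (e.g. the prey
#'   centroid); required when the policy carries an annulus.
#' @return a list of class `track_filter_result` with elements `tracks` (the
#'   surviving rows, same dialect), `rejected` (named integer vector of
#'   per-rule counts), `n_in`, `n_kept`.
#' @export
filter_tracks <- function(tracks, policy, ref = NULL) {
  stopifnot(inherits(policy, "filter_policy"))
  has_annulus <- !is.null(policy$annulus_min)
  if (has_annulus && is.null(ref))
    stop("policy has an annulus rule but no `ref` point was given",
         call. = FALSE)
  by_cell <- split_tracks(tracks)
  rules <- c("step", "gap", "min_frames", "annulus")
  rejected <- setNames(integer(4), rules)
  keep_ids <- character(0)
  for (id in names(by_cell)) {
    tr <- by_cell[[id]]
    s <- .track_summary(tr)
    fail <-
      if (!is.null(policy$max_step) && s$max_adj_step > policy$max_step) "step"
      else if (!is.null(policy$max_gap) && s$max_gap > policy$max_gap) "gap"
      else if (!is.null(policy$min_frames) && s$n < policy$min_frames) "min_frames"
      else if (has_annulus) {
        r0 <- .dist2d(tr$x_um[1], tr$y_um[1], ref[1], ref[2])
        if (r0 < policy$annulus_min || r0 > policy$annulus_max) "annulus" else NA
      } else NA
    if (is.na(fail)) keep_ids <- c(keep_ids, id) else
      rejected[fail] <- rejected[fail] + 1L
  }
  kept <- do.call(rbind, by_cell[keep_ids])
  if (is.null(kept))
    kept <- tracks[0, c("cell_id", "frame", "t_seconds", "x_um", "y_um")]
  rownames(kept) <- NULL
  structure(list(tracks = kept, rejected = rejected,
                 n_in = length(by_cell), n_kept = length(keep_ids)),
            class = "track_filter_result")
}

#' @export
print.track_filter_result <- function(x, ...) {
  cat(sprintf("<track_filter_result> kept %d of %d tracks\n", x$n_kept, x$n_in))
  rej <- x$rejected[x$rejected > 0]
  if (length(rej)) {
    cat("  rejected by rule:\n")
    for (nm in names(rej)) cat(sprintf("    %s: %d\n", nm, rej[[nm]]))
  }
  invisible(x)
}

#' Per-step velocities of a single track
#'
#' Euclidean displacement between adjacent detected frames divided by the
#' elapsed time, reported in micrometres/minute. Pairs spanning a tracking gap
#' (frame difference > 1) are skipped rather than averaged over the gap,
#' matching an analysis in which gap filling is disabled.
#'
#' @param track data frame with one cell's rows (dialect columns).
#' @return data frame with columns `frame` (frame index of the step's first
#'   detection), `t_seconds`, `velocity` (um/min). Zero rows when the track
#'   has < 2 detections.
#' @export
step_velocities <- function(track) {
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  if (n < 2L)
    return(data.frame(frame = integer(), t_seconds = numeric(),
                      velocity = numeric()))
  df <- diff(track$frame)
  dt <- diff(track$t_seconds)
  d <- .dist2d(track$x_um[-n], track$y_um[-n], track$x_um[-1], track$y_um[-1])
  adj <- df == 1L
  data.frame(frame = track$frame[-n][adj],
             t_seconds = track$t_seconds[-n][adj],
             velocity = d[adj] / dt[adj] * 60)
}

#' Net movement toward a reference point
#'
#' Radial displacement of a track toward the reference: distance from the
#' reference at the first detection minus distance at the last. Positive
#' values mean net approach; negative values mean net movement away. This is
#' the chemotaxis statistic; it is invariant under rotation of all coordinates
#' about the reference.
#'
#' @param track data frame with one cell's rows.
#' @param ref reference point `c(x, y)` in micrometres.
#' @return net approach in micrometres (scalar).
#' @export
net_movement_toward <- function(track, ref) {
  stopifnot(nrow(track) >= 2L, length(ref) == 2L)
  track <- track[order(track$frame), , drop = FALSE]
  n <- nrow(track)
  .dist2d(track$x_um[1], track$y_um[1], ref[1], ref[2]) -
    .dist2d(track$x_um[n], track$y_um[n], ref[1], ref[2])
}

#' Pooled step velocities in a radial band and time window
#'
#' Pools per-step velocities from all samples within a radial band around the
#' reference and an initial time window -- the region and period where
#' chemokinesis near a freshly introduced prey is most visible. A step is
#' included when its first detection lies in the band and starts before
#' `t_max`.
#'
#' @param tracks track table (ideally already passed through
#'   [filter_tracks()]).
#' @param ref reference point `c(x, y)`.
#' @param r_lo,r_hi radial band in micrometres (default 70-90).
#' @param t_max end of the time window in seconds (default 900, i.e. the
#'   first 15 minutes).
#' @return numeric vector of velocities (um/min); empty (with a warning) when
#'   no step qualifies -- an empty selection is flagged, never reported as a
#'   zero velocity.
#' @export
chemokinesis_window <- function(tracks, ref, r_lo = 70, r_hi = 90,
                                t_max = 900) {
  stopifnot(r_lo < r_hi, t_max > 0, length(ref) == 2L)
  vels <- unlist(lapply(split_tracks(tracks), function(tr) {
    sv <- step_velocities(tr)
    if (nrow(sv) == 0) return(numeric(0))
    i <- match(sv$frame, tr$frame)
    r <- .dist2d(tr$x_um[i], tr$y_um[i], ref[1], ref[2])
    sv$velocity[r >= r_lo & r <= r_hi & sv$t_seconds < t_max]
  }), use.names = FALSE)
  if (length(vels) == 0)
    warning("no steps fall inside the radial band and time window",
            call. = FALSE)
  vels
}

#' Mean velocity of the slow, well-tracked subpopulation
#'
#' Reproduces the plate-reader "mean velocity": cells are restricted to the
#' subpopulation whose total path length does not exceed
#' `policy$max_total_path` (spurious floating cells travel much farther) and
#' that were tracked for at least `policy$min_frames_subpop` frames; each
#' cell's step velocities are averaged, and those per-cell means are averaged
#' across cells.
#'
#' @param tracks track table.
#' @param policy a [filter_policy()] with `max_total_path` and
#'   `min_frames_subpop` set (see [policy_cytation()]).
#' @param path `"total"` (default) interprets the migration limit as total
#'   path length; `"net"` as net displacement between first and last
#'   detection.
#' @return list with `mean_velocity` (um/min, `NA` if the subpopulation is
#'   empty -- flagged by a warning), `n_cells`, and `per_cell` (data frame of
#'   per-cell means).
#' @export
mean_velocity <- function(tracks, policy = policy_cytation(),
                          path = c("total", "net")) {
  path <- match.arg(path)
  stopifnot(inherits(policy, "filter_policy"))
  if (is.null(policy$max_total_path) || is.null(policy$min_frames_subpop))
    stop("policy must set `max_total_path` and `min_frames_subpop`",
         call. = FALSE)
  by_cell <- split_tracks(tracks)
  rows <- lapply(by_cell, function(tr) {
    n <- nrow(tr)
    migrated <- if (n < 2L) 0 else if (path == "total")
      .track_summary(tr)$total_path
    else .dist2d(tr$x_um[1], tr$y_um[1], tr$x_um[n], tr$y_um[n])
    if (n < policy$min_frames_subpop || migrated > policy$max_total_path)
      return(NULL)
    sv <- step_velocities(tr)
    if (nrow(sv) == 0) return(NULL)
    data.frame(cell_id = tr$cell_id[1], n_frames = n, migrated = migrated,
               velocity = mean(sv$velocity))
  })
  per_cell <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(per_cell) || nrow(per_cell) == 0) {
    warning("subpopulation is empty under this policy", call. = FALSE)
    return(list(mean_velocity = NA_real_, n_cells = 0L,
                per_cell = data.frame()))
  }
  rownames(per_cell) <- NULL
  list(mean_velocity = mean(per_cell$velocity), n_cells = nrow(per_cell),
       per_cell = per_cell)
}

#' Cells distant from every other cell
#'
#' Identifies cells whose nearest-neighbour distance exceeds `radius`
#' (default 60 um, comfortably beyond the ~24 um reach of filopodia), i.e.
#' cells that cannot be in physical contact with any other cell. By default
#' the test uses each cell's first detected position; `mode = "all_frames"`
#' requires the separation to hold at every frame where both cells are
#' detected.
#'
#' @param tracks track table with at least one cell.
#' @param radius exclusion radius in micrometres.
#' @param mode `"first_frame"` (default) or `"all_frames"`.
#' @return character vector of distant `cell_id`s. A single-track input is
#'   trivially distant and raises a warning.
#' @export
distant_cells <- function(tracks, radius = 60,
                          mode = c("first_frame", "all_frames")) {
  mode <- match.arg(mode)
  .check_pos(radius, "radius")
  by_cell <- split_tracks(tracks)
  ids <- names(by_cell)
  if (length(ids) < 2L) {
    warning("fewer than two tracks: every cell is trivially distant",
            call. = FALSE)
    return(ids)
  }
  if (mode == "first_frame") {
    x <- vapply(by_cell, function(tr) tr$x_um[1], numeric(1))
    y <- vapply(by_cell, function(tr) tr$y_um[1], numeric(1))
    dm <- as.matrix(stats::dist(cbind(x, y)))
    diag(dm) <- Inf
    return(ids[apply(dm, 1, min) > radius])
  }
  # all_frames: minimum pairwise distance over shared frames
  nn <- setNames(rep(Inf, length(ids)), ids)
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    a <- by_cell[[i]]; b <- by_cell[[j]]
    shared <- intersect(a$frame, b$frame)
    if (length(shared) == 0) next
    ia <- match(shared, a$frame); ib <- match(shared, b$frame)
    d <- min(.dist2d(a$x_um[ia], a$y_um[ia], b$x_um[ib], b$y_um[ib]))
    nn[i] <- min(nn[i], d); nn[j] <- min(nn[j], d)
  }
  ids[nn > radius]
}

#' Normalize and average fluorescence traces
#'
#' Implements the calcium-assay intensity normalization: traces missing any
#' frame are removed; each remaining cell's initial intensity is subtracted
#' from its whole trace (so every cell starts at zero); cells are averaged
#' per well and per frame; and the per-well means are summarized as mean and
#' standard error across wells.
#'
#' @param traces data frame with columns `well`, `cell_id`, `frame`,
#'   `intensity` (as produced by [generate_fluorescence_traces()]; multiple
#'   wells may be row-bound together).
#' @return data frame with columns `frame`, `mean`, `sem` (`NA` with a single
#'   well), `n_wells`. Errors if no complete trace remains.
#' @export
normalize_fluor <- function(traces) {
  stopifnot(all(c("well", "cell_id", "frame", "intensity") %in% names(traces)))
  frames <- sort(unique(traces$frame))
  key <- interaction(traces$well, traces$cell_id, drop = TRUE)
  counts <- tapply(traces$frame, key, length)
  complete <- names(counts)[counts == length(frames)]
  traces <- traces[key %in% complete, , drop = FALSE]
  if (nrow(traces) == 0) stop("no complete traces to normalize", call. = FALSE)
  traces <- traces[order(traces$well, traces$cell_id, traces$frame), ]
  key <- interaction(traces$well, traces$cell_id, drop = TRUE)
  first <- tapply(traces$intensity, key, function(v) v[1])
  traces$norm <- traces$intensity - as.numeric(first[key])
  # per-well, per-frame mean over cells
  wf <- aggregate(norm ~ well + frame, data = traces, FUN = mean)
  # across wells
  agg_mean <- aggregate(norm ~ frame, data = wf, FUN = mean)
  agg_n <- aggregate(norm ~ frame, data = wf, FUN = length)
  agg_sd <- aggregate(norm ~ frame, data = wf, FUN = stats::sd)
  out <- data.frame(frame = agg_mean$frame, mean = agg_mean$norm,
                    sem = ifelse(agg_n$norm > 1,
                                 agg_sd$norm / sqrt(agg_n$norm), NA_real_),
                    n_wells = agg_n$norm)
  out[order(out$frame), ]
}
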