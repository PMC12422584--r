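# Hand-built track fixtures used across test files.

# One track from explicit coordinates; frames default to 0..(n-1) at 60 s.
make_track <- function(cell_id, x, y, frames = seq_along(x) - 1L,
                       frame_interval = 60) {
  data.frame(cell_id = cell_id, frame = as.integer(frames),
             t_seconds = as.integer(frames) * frame_interval,
             x_um = x, y_um = y)
}

# Straight track along +x from (x0, y0), constant step (um per frame).
straight_track <- function(cell_id, n, step, x0 = 0, y0 = 0,
                           frame_interval = 60) {
  make_track(cell_id, x0 + step * (seq_len(n) - 1), rep(y0, n),
             frame_interval = frame_interval)
}

bind_tracks <- function(...) do.call(rbind, list(...))

# Empirical MSD of a track set at the given frame lags, averaged over cells
# and window starts (only windows with both endpoints detected and exactly
# `lag` frames apart).
empirical_msd <- function(tracks, lags) {
  by <- split_tracks(tracks)
  vapply(lags, function(L) {
    mean(unlist(lapply(by, function(tr) {
      idx <- match(tr$frame + L, tr$frame)
      ok <- !is.na(idx)
      if (!any(ok)) return(NULL)
      (tr$x_um[idx[ok]] - tr$x_um[ok])^2 + (tr$y_um[idx[ok]] - tr$y_um[ok])^2
    })))
  }, numeric(1))
}
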