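# Track filtering and the velocity / displacement statistics.

test_that("clean tracks inside the annulus are kept", {
  ref <- c(0, 0)
  trk <- straight_track("a", n = 3, step = 5, x0 = 100)  # 100 um from ref
  res <- filter_tracks(trk, policy_schistosome(), ref = ref)
  expect_equal(res$n_kept, 1L)
  expect_equal(sum(res$rejected), 0L)
})

test_that("a single step over 11.2 um rejects the whole track", {
  ref <- c(0, 0)
  good <- straight_track("a", n = 5, step = 5, x0 = 100)
  bad <- good
  bad$cell_id <- "b"
  bad$x_um[4] <- bad$x_um[3] + 12  # one 12 um jump
  res <- filter_tracks(bind_tracks(good, bad), policy_schistosome(), ref = ref)
  expect_equal(res$n_kept, 1L)
  expect_equal(unname(res$rejected["step"]), 1L)
  expect_equal(unique(res$tracks$cell_id), "a")
})

test_that("rejection counts match hand enumeration over a 10-track fixture", {
  ref <- c(0, 0)
  fx <- bind_tracks(
    straight_track("k1", n = 5, step = 5, x0 = 80),          # kept
    straight_track("k2", n = 3, step = 10, x0 = 200),        # kept (10 < 11.2)
    straight_track("k3", n = 10, step = 2, x0 = 239),        # kept (on edge)
    {t <- straight_track("s1", n = 4, step = 5, x0 = 100)    # step violation
     t$x_um[2] <- t$x_um[1] + 11.3; t},
    {t <- straight_track("s2", n = 6, step = 12, x0 = 150); t},  # all steps 12
    {t <- straight_track("g1", n = 8, step = 5, x0 = 100)    # 4-frame gap
     t[-(3:6), ]},
    straight_track("m1", n = 2, step = 5, x0 = 100),         # too short
    straight_track("m2", n = 1, step = 0, x0 = 100),         # single sample
    straight_track("a1", n = 5, step = 5, x0 = 30),          # inside annulus
    straight_track("a2", n = 5, step = 5, x0 = 300)          # outside annulus
  )
  res <- filter_tracks(fx, policy_schistosome(), ref = ref)
  expect_equal(res$n_in, 10L)
  expect_equal(res$n_kept, 3L)
  expect_equal(as.list(res$rejected),
               list(step = 2L, gap = 1L, min_frames = 2L, annulus = 2L))
  expect_equal(sum(res$rejected), res$n_in - res$n_kept)
})

test_that("filtering is idempotent and order-independent", {
  cfg <- track_gen_config(n_cells = 40, n_frames = 30, speed = 3,
                          turn_sd = 0.4, spurious_rate = 0.01,
                          gap_rate = 0.03, arena = c(400, 400), seed = 21)
  trk <- generate_tracks(cfg)
  pol <- filter_policy(max_step = 11.2, max_gap = 3, min_frames = 3)
  once <- filter_tracks(trk, pol)
  twice <- filter_tracks(once$tracks, pol)
  expect_equal(twice$n_kept, once$n_kept)
  expect_equal(sum(twice$rejected), 0L)
  # permuting rows changes nothing
  perm <- trk[sample(nrow(trk)), ]
  res_perm <- filter_tracks(perm, pol)
  expect_equal(res_perm$rejected, once$rejected)
  expect_equal(res_perm$n_kept, once$n_kept)
})

test_that("every injected spurious jump is caught by the step rule", {
  cfg <- track_gen_config(n_cells = 200, n_frames = 40, speed = 1,
                          turn_sd = 0.3, spurious_rate = 0.02, gap_rate = 0,
                          seed = 31)
  trk <- generate_tracks(cfg)
  truth <- attr(trk, "truth")$spurious
  expect_gt(nrow(truth), 0)
  res <- filter_tracks(trk, filter_policy(max_step = 11.2))
  # no cell with an injected artifact survives: capture is 100%
  expect_length(intersect(unique(res$tracks$cell_id), truth$cell_id), 0)
  expect_gte(res$rejected[["step"]], length(unique(truth$cell_id)))
})

test_that("step velocities handle gaps, units and stationary tracks", {
  still <- make_track("s", rep(1, 5), rep(2, 5))
  expect_equal(step_velocities(still)$velocity, rep(0, 4))
  # 3 um per 1-min frame = 3 um/min
  mv <- straight_track("m", n = 6, step = 3)
  expect_equal(step_velocities(mv)$velocity, rep(3, 5))
  # a 2-frame gap removes exactly two velocity entries
  gap <- make_track("g", x = c(0, 1, 2, 3, 4, 5, 6, 7),
                    y = rep(0, 8))[-c(4, 5), ]
  sv <- step_velocities(gap)
  expect_equal(nrow(sv), nrow(gap) - 1L - 1L)  # n_detections - 2
  expect_error(step_velocities(make_track("x", 1, 1))$velocity, NA)
  expect_equal(nrow(step_velocities(make_track("x", 1, 1))), 0L)
})

test_that("net movement toward the reference is the radial displacement", {
  ref <- c(0, 0)
  still <- make_track("s", rep(50, 4), rep(0, 4))
  expect_equal(net_movement_toward(still, ref), 0)
  inward <- make_track("i", c(100, 80, 50), rep(0, 3))
  expect_equal(net_movement_toward(inward, ref), 50)
  # motion on a circle has zero net radial movement regardless of path
  th <- seq(0, 3 * pi / 2, length.out = 10)
  circ <- make_track("c", 70 * cos(th), 70 * sin(th))
  expect_equal(net_movement_toward(circ, ref), 0, tolerance = 1e-12)
})

test_that("net movement is invariant under rotation about the reference", {
  ref <- c(120, -40)
  cfg <- track_gen_config(n_cells = 8, n_frames = 25, speed = 2,
                          turn_sd = 0.5, seed = 17)
  trk <- generate_tracks(cfg)
  ang <- 1.1
  rot <- trk
  dx <- trk$x_um - ref[1]; dy <- trk$y_um - ref[2]
  rot$x_um <- ref[1] + cos(ang) * dx - sin(ang) * dy
  rot$y_um <- ref[2] + sin(ang) * dx + cos(ang) * dy
  for (id in unique(trk$cell_id))
    expect_equal(
      net_movement_toward(rot[rot$cell_id == id, ], ref),
      net_movement_toward(trk[trk$cell_id == id, ], ref),
      tolerance = 1e-9)
})

test_that("drift toward the reference is recovered from net movement", {
  cfg <- track_gen_config(n_cells = 150, n_frames = 120, speed = 1,
                          turn_sd = 0.6, drift_toward_ref = 0.5,
                          ref = c(5000, 5000), arena = c(800, 800), seed = 5)
  trk <- generate_tracks(cfg)
  # far-away reference: drift is effectively constant-direction; mean net
  # approach grows linearly at the drift speed
  nm <- vapply(split_tracks(trk), net_movement_toward, numeric(1),
               ref = c(5000, 5000))
  duration_min <- (cfg$n_frames - 1) * cfg$frame_interval / 60
  slope <- mean(nm) / duration_min
  expect_gt(mean(nm), 0)
  expect_equal(slope, cfg$drift_toward_ref, tolerance = 0.15)
})

test_that("the chemokinesis window pools only in-band, early steps", {
  ref <- c(0, 0)
  far <- straight_track("far", n = 10, step = 1, x0 = 300)
  expect_warning(v <- chemokinesis_window(far, ref), "no steps")
  expect_length(v, 0)
  # constructed: one cell inside 70-90 um, one outside, one inside but late
  inside <- straight_track("in", n = 10, step = 1, x0 = 75)
  late <- straight_track("late", n = 10, step = 1, x0 = 75)
  late$t_seconds <- late$t_seconds + 3600
  pooled <- chemokinesis_window(bind_tracks(far, inside, late), ref,
                                t_max = 900)
  # steps of "in" starting at x = 75..83 are in-band and early: frames whose
  # start position is within [70, 90] and t < 900 s
  expect_equal(length(pooled), sum(inside$x_um[-10] >= 70 &
                                     inside$x_um[-10] <= 90 &
                                     inside$t_seconds[-10] < 900))
  expect_equal(unique(pooled), 1)
  # doubling the window on stationary-speed tracks leaves the mean unchanged
  p2 <- chemokinesis_window(bind_tracks(inside), ref, t_max = 1800)
  expect_equal(mean(p2), mean(chemokinesis_window(bind_tracks(inside), ref,
                                                  t_max = 900)))
})

test_that("mean velocity averages the compliant subpopulation only", {
  # uniform 2 um/min cells, tracked 20 frames, path 38 um: compliant
  a <- straight_track("a", n = 20, step = 2)
  b <- straight_track("b", n = 20, step = 2, y0 = 100)
  out <- mean_velocity(bind_tracks(a, b))
  expect_equal(out$mean_velocity, 2)
  expect_equal(out$n_cells, 2L)
  # a cell with a 100 um total path is excluded even if long enough
  fast <- straight_track("fast", n = 21, step = 5)  # path 100 um
  out2 <- mean_velocity(bind_tracks(a, b, fast))
  expect_equal(out2$n_cells, 2L)
  expect_equal(out2$mean_velocity, 2)
  # two-level mean: per-cell first, then across cells
  slow <- straight_track("slow", n = 19, step = 1)   # 1 um/min, path 18
  out3 <- mean_velocity(bind_tracks(a, b, slow))
  expect_equal(out3$mean_velocity, mean(c(2, 2, 1)))
  # too short tracks drop out; empty subpopulation is flagged
  short <- straight_track("sh", n = 5, step = 1)
  expect_warning(out4 <- mean_velocity(short), "empty")
  expect_true(is.na(out4$mean_velocity))
})

test_that("distant cells are found by nearest-neighbour radius", {
  two_far <- bind_tracks(straight_track("a", 3, 0, x0 = 0),
                         straight_track("b", 3, 0, x0 = 100))
  expect_setequal(distant_cells(two_far, 60), c("a", "b"))
  two_near <- bind_tracks(straight_track("a", 3, 0, x0 = 0),
                          straight_track("b", 3, 0, x0 = 10))
  expect_length(distant_cells(two_near, 60), 0)
  # 3x3 grid at 50 um spacing plus one isolated cell at 200 um beyond
  grid <- do.call(bind_tracks, lapply(1:9, function(k) {
    i <- (k - 1) %% 3; j <- (k - 1) %/% 3
    straight_track(paste0("g", k), 3, 0, x0 = 50 * i, y0 = 50 * j)
  }))
  iso <- straight_track("iso", 3, 0, x0 = 300, y0 = 300)
  expect_equal(distant_cells(bind_tracks(grid, iso), 60), "iso")
  expect_warning(distant_cells(straight_track("solo", 3, 1), 60),
                 "trivially distant")
})

test_that("fluorescence normalization recovers the induced step height", {
  wells <- do.call(rbind, lapply(1:3, function(w)
    generate_fluorescence_traces(n_cells = 200, n_frames = 36, baseline = 100,
                                 jump_time = 25, jump_height = 50,
                                 noise_sd = 5, well = paste0("w", w),
                                 seed = 100 + w)))
  nm <- normalize_fluor(wells)
  jf <- 5
  post <- nm[nm$frame > jf, ]
  # mean normalized response within 3 SEM of the true step height
  expect_true(all(abs(post$mean - 50) <= 3 * pmax(post$sem, 1e-9)))
  expect_true(all(nm$n_wells == 3))
  # incomplete traces are dropped, and losing every trace errors
  w1 <- generate_fluorescence_traces(n_cells = 2, n_frames = 10,
                                     jump_height = 10, seed = 1)
  holes <- !((w1$cell_id == 1 & w1$frame == 0) |
               (w1$cell_id == 2 & w1$frame == 5))
  expect_error(normalize_fluor(w1[holes, ]), "no complete traces")
})
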