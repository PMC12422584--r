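# Agent engine invariants: absorbing attachment, determinism, equivalences,
# and the free-agent persistent-random-walk oracle.

# Small, fast configuration used in several blocks; overrides win.
small_cfg <- function(...) {
  defaults <- list(
    n_cells = 150, duration = 600, arena = 300, prey_radius = 30,
    field_h = 25, field_warmup = 0, replicates = 1, seeds = 1,
    response = response_curve(v0 = 2, vmax = 6),
    source = source_model(base_rate = 6, attachment_coupling = 1000))
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("attached agents never move and attachment times are stamped once", {
  cfg <- small_cfg()
  agents <- list(x = c(150, 40), y = c(150, 40), heading = c(0, 1),
                 attached = c(TRUE, FALSE), attach_time = c(12, NA))
  set.seed(1)
  for (k in 1:50) agents <- step_agents(agents, cfg, time = k - 1)
  expect_equal(agents$x[1], 150)
  expect_equal(agents$y[1], 150)
  expect_equal(agents$attach_time[1], 12)
  # the free agent moved
  expect_false(agents$x[2] == 40 && agents$y[2] == 40)
})

test_that("agents crossing the prey surface are clipped to it and absorbed", {
  cfg <- small_cfg()
  # aim an agent straight at the prey centre from just outside the disk
  agents <- list(x = cfg$prey_center[1] - cfg$prey_radius - 1,
                 y = cfg$prey_center[2], heading = 0,
                 attached = FALSE, attach_time = NA_real_)
  set.seed(4)
  t_now <- 0
  for (k in 1:200) {
    agents <- step_agents(agents, cfg, time = t_now)
    t_now <- t_now + cfg$dt
    if (agents$attached) break
  }
  expect_true(agents$attached)
  r <- sqrt(sum((c(agents$x, agents$y) - cfg$prey_center)^2))
  expect_equal(r, cfg$prey_radius, tolerance = 1e-9)
  expect_true(agents$attach_time <= t_now)
})

test_that("simulation outcomes are reproducible from the seed", {
  cfg <- small_cfg()
  a <- run_simulation(cfg)[[1]]
  b <- run_simulation(cfg)[[1]]
  expect_identical(a$attach_times, b$attach_times)
  expect_identical(a$trace, b$trace)
})

test_that("with a zero field, chemokinesis on and off are trajectory-identical", {
  src0 <- source_model(base_rate = 0, attachment_coupling = 0)
  on <- run_simulation(small_cfg(chemokinesis = TRUE, source = src0))[[1]]
  off <- run_simulation(small_cfg(chemokinesis = FALSE, source = src0))[[1]]
  expect_identical(on$attach_times, off$attach_times)
  expect_identical(on$trace, off$trace)
})

test_that("attachment is absorbing and the residence trace is consistent", {
  out <- run_simulation(small_cfg(chemokinesis = TRUE))[[1]]
  expect_true(all(diff(out$trace$attached) >= 0))
  expect_equal(out$cumulative_residence, sum(out$residence_times))
  expect_equal(out$attachment_fraction,
               length(out$attach_times) / out$n_cells)
  # the stepwise time-integral of the attached count matches the attach-time
  # bookkeeping up to the sub-step attachment fractions
  n_att <- length(out$attach_times)
  expect_lt(abs(out$cumulative_residence -
                  out$trace$cumulative_residence[nrow(out$trace)]),
            n_att * small_cfg()$dt + 1e-9)
})

test_that("zero-speed agents never reach the prey", {
  rc0 <- response_curve(v0 = 0, vmax = 0, ec50 = 1, hill = 1)
  out <- run_simulation(small_cfg(response = rc0, chemokinesis = FALSE))[[1]]
  expect_equal(out$attachment_fraction, 0)
  expect_equal(out$cumulative_residence, 0)
})

test_that("free-agent ensemble MSD matches the random-walk closed form", {
  # prey shrunk into a corner so essentially no agent is absorbed
  cfg <- sim_config(n_cells = 600, duration = 120, arena = 6000,
                    prey_center = c(3, 3), prey_radius = 3, field_h = 200,
                    field_warmup = 0, replicates = 1, seeds = 2,
                    turn_sd = 0.3, chemokinesis = FALSE,
                    response = response_curve(v0 = 2, vmax = 6),
                    source = source_model(0, 0))
  set.seed(9)
  agents <- list(x = runif(cfg$n_cells, 2000, 4000),
                 y = runif(cfg$n_cells, 2000, 4000),
                 heading = runif(cfg$n_cells, -pi, pi),
                 attached = rep(FALSE, cfg$n_cells),
                 attach_time = rep(NA_real_, cfg$n_cells))
  x0 <- agents$x; y0 <- agents$y
  lags <- c(10, 25, 50, 100)
  msd_emp <- numeric(length(lags))
  step <- 0
  for (L in seq_along(lags)) {
    while (step < lags[L]) {
      agents <- step_agents(agents, cfg, time = step)
      step <- step + 1
    }
    msd_emp[L] <- mean((agents$x - x0)^2 + (agents$y - y0)^2)
  }
  v_um_s <- 2 / 60
  theo <- prw_msd_theory(lags, v_um_s * cfg$dt, cfg$turn_sd, cfg$turn_bound,
                         "exponential")
  expect_true(all(abs(msd_emp / theo - 1) < 0.10))
})

test_that("a flat response makes on and off conditions statistically identical", {
  rc_flat <- response_curve(v0 = 2, vmax = 2, ec50 = 1, hill = 1)
  on <- run_simulation(small_cfg(chemokinesis = TRUE, response = rc_flat,
                                 replicates = 5, seeds = 1:5))
  off <- run_simulation(small_cfg(chemokinesis = FALSE, response = rc_flat,
                                  replicates = 5, seeds = 6:10))
  at_on <- unlist(lapply(on, `[[`, "attach_times"))
  at_off <- unlist(lapply(off, `[[`, "attach_times"))
  ks <- suppressWarnings(ks.test(at_on, at_off))
  expect_gt(ks$p.value, 0.01)
})

test_that("attachment fraction is monotone in constant agent speed", {
  frac <- vapply(c(1, 3, 6), function(v) {
    rc <- response_curve(v0 = v, vmax = v, ec50 = 1, hill = 1)
    outs <- run_simulation(small_cfg(chemokinesis = FALSE, response = rc,
                                     replicates = 4, seeds = 1:4))
    mean(vapply(outs, `[[`, numeric(1), "attachment_fraction"))
  }, numeric(1))
  expect_true(all(diff(frac) > 0))
})

test_that("comparison summaries behave on constructed outcome sets", {
  mk <- function(cr, at) {
    structure(list(seed = 1L, n_cells = 100L, duration = 600,
                   attach_times = at, attachment_fraction = length(at) / 100,
                   residence_times = 600 - at, cumulative_residence = cr,
                   trace = data.frame(), chemokinesis = TRUE),
              class = "sim_outcome")
  }
  a <- mk(1000, c(10, 20)); b <- mk(2000, c(5, 15))
  same <- compare_conditions(list(a), list(a))
  expect_equal(same$ratio_cumulative_residence, 1)
  dbl <- compare_conditions(list(b), list(a))
  expect_equal(dbl$ratio_cumulative_residence, 2)
  zero <- mk(0, numeric(0))
  expect_warning(und <- compare_conditions(list(a), list(zero)), "undefined")
  expect_true(is.na(und$ratio_cumulative_residence))
})

test_that("a zero-mass burst reproduces the standard chemokinesis run", {
  cfg <- small_cfg(chemokinesis = TRUE)
  std <- run_simulation(cfg)[[1]]
  ctr <- cfg$arena / 2
  dep <- run_depleted_scenario(cfg, rbind(c(ctr - 80, ctr), c(ctr + 80, ctr)),
                               burst_mass = 0)[[1]]
  expect_identical(std$attach_times, dep$attach_times)
  expect_error(run_depleted_scenario(small_cfg(chemokinesis = FALSE),
                                     rbind(c(10, 10)), 1), "chemokinesis")
})

test_that("a slow, massive burst changes early dispersal measurably", {
  # limiting behaviour: huge slow-diffusing burst saturates the response, so
  # early attachment differs from the standard run
  cfg <- small_cfg(chemokinesis = TRUE, diffusivity = 2, field_h = 10,
                   duration = 300)
  ctr <- cfg$arena / 2
  std <- run_simulation(cfg)[[1]]
  dep <- run_depleted_scenario(cfg, rbind(c(ctr - 60, ctr)),
                               burst_mass = 1e7, burst_age = 50)[[1]]
  expect_false(identical(std$attach_times, dep$attach_times))
})
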