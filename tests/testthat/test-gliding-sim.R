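sp_test <- motor_species("t", attach_rate = 0.1, v0_max = 50, K_ATP = 0.15,
                         F_stall = 2, kappa = 1, k_det_c = 1, F_c = 1,
                         k_det_s = 0.1, F_s = 2)

test_that("filament velocity solves the driving/resisting force balance", {
  none <- engaged_motors()
  expect_equal(solve_filament_velocity(none, sp_test, 1e-3, 5000, 50), 0)
  one <- engaged_motors(100, "driving", 0)
  expect_equal(solve_filament_velocity(one, sp_test, 0, 5000, 50), 50)
  # 5 driving (F_stall 2, v0 50) against one resisting F = 4:
  # 10 (1 - v/50) = 4  ->  v = 30
  eng <- engaged_motors(c(10, 20, 30, 40, 50, 60),
                        c(rep("driving", 5), "resisting"),
                        c(rep(0, 5), 4))
  expect_equal(solve_filament_velocity(eng, sp_test, 0, 5000, 50), 30)
  # overloaded -> clamped at zero
  heavy <- engaged_motors(c(10, 20), c("driving", "resisting"), c(0, 100))
  expect_equal(solve_filament_velocity(heavy, sp_test, 1e-3, 5000, 50), 0)
})

test_that("anchor force loading integrates kappa*(v - F/xi) with rigid limit", {
  m <- engaged_motors(10, "resisting", 0)
  expect_equal(anchor_force_step(m, 0, sp_test, 0.1)$F, 0)
  expect_equal(anchor_force_step(m, 50, sp_test, 0.1)$F, 5) # kappa v dt
  # finite anchor drag: fixed point at xi * v
  spm <- sp_test; spm$xi_anchor <- 0.1; spm$kappa <- 1
  f <- m
  for (i in 1:4000) f <- anchor_force_step(f, 50, spm, 0.01)
  expect_equal(f$F, 0.1 * 50, tolerance = 1e-3)
  expect_error(anchor_force_step(m, 50, sp_test, 0), "dt")
  expect_error(anchor_force_step(engaged_motors(1, "driving", 0), 1,
                                 sp_test, 0.1), "resisting")
})

test_that("barbed-end rates couple tip load to dissociation only", {
  bb <- barbed_end_model(k_on = 10, k_off0 = 2, delta = 2, ell_tip = 50,
                         kBT = 4.1)
  r <- barbed_end_rates(engaged_motors(), bb, 0.6)
  expect_equal(unname(r["r_on"]), 6)
  expect_equal(unname(r["r_off"]), 2)
  # a resisting motor beyond the tip zone does not load the end
  far <- engaged_motors(200, "resisting", 5)
  expect_equal(unname(barbed_end_rates(far, bb, 0.6)["r_off"]), 2)
  # delta = 0 switches the mechanism off entirely
  bb0 <- barbed_end_model(k_on = 10, k_off0 = 2, delta = 0)
  tip <- engaged_motors(10, "resisting", 8)
  expect_equal(unname(barbed_end_rates(tip, bb0, 0.6)["r_off"]), 2)
  # F * delta = kBT gives exactly one e-fold enhancement
  bb1 <- barbed_end_model(k_on = 10, k_off0 = 2, delta = 2, kBT = 4.1)
  tip1 <- engaged_motors(10, "resisting", 4.1 / 2)
  expect_equal(unname(barbed_end_rates(tip1, bb1, 0.6)["r_off"]),
               2 * exp(1), tolerance = 1e-9)
  # association never depends on the motors
  expect_equal(unname(barbed_end_rates(tip1, bb1, 0.6)["r_on"]), 6)
  expect_error(barbed_end_rates(tip1, bb1, -1), "C_m")
})

test_that("closed-form membrane drag partition has the stated limits", {
  expect_equal(membrane_partition_velocity(50, 10, Inf, 5), 50)
  expect_equal(membrane_partition_velocity(80, 3, 1, 1), 0.75 * 80)
  expect_equal(membrane_partition_velocity(50, 10, 0.5, 5), 25)
  v <- vapply(c(1, 2, 5, 10), function(xb)
    membrane_partition_velocity(50, 10, 0.5, xb), 0)
  expect_true(all(diff(v) < 0)) # decreasing in bulk drag
  expect_error(membrane_partition_velocity(50, 0, 0.5, 5), "N_att")
})

test_that("motor-free simulation reproduces first-order depolymerization", {
  bb <- barbed_end_model(k_on = 10, k_off0 = 1, delta = 0)
  cfg <- sim_config(barbed = bb, motor_density = 0, C_m = 0,
                    duration = 400, initial_length = 2000, seed = 7)
  s <- trajectory_summary(simulate_gliding(cfg))
  # loss rate ~ Poisson(1/s): 3 sigma of the slope estimate
  expect_equal(s$v_p, -1, tolerance = 0.15)
  expect_equal(s$v_f, 0, tolerance = 1e-9)
})

test_that("motor-free elongation matches the exact birth-death oracle", {
  cfg <- sim_config(motor_density = 0, C_m = 0.6, duration = 400,
                    initial_length = 1000, seed = 8)
  s <- trajectory_summary(simulate_gliding(cfg))
  # oracle: same-rate Gillespie net growth over the same horizon
  g <- gillespie_birth_death(11.6 * 0.6, 1.4, 1000, 6000, seed = 8)
  keep <- g$times <= 400
  slope_oracle <- unname(coef(lm(g$length_su[keep] ~ g$times[keep]))[2])
  expect_equal(s$v_p, 11.6 * 0.6 - 1.4, tolerance = 0.25)
  expect_equal(slope_oracle, 11.6 * 0.6 - 1.4, tolerance = 0.25)
  expect_equal(s$v_p, slope_oracle, tolerance = 0.35)
})

test_that("simulation is reproducible and the event log matches the samples", {
  cfg <- sim_config(C_m = 0.4, duration = 60, initial_length = 1800,
                    seed = 42)
  a <- simulate_gliding(cfg)
  b <- simulate_gliding(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$events, b$events)
  n <- nrow(a$samples)
  expect_equal(sum(a$events$kind == "on"), a$samples$n_on[n])
  expect_equal(sum(a$events$kind == "off"), a$samples$n_off[n])
})

test_that("force-enhanced dissociation shortens filaments on a motor bed", {
  mk <- function(delta) {
    cfg <- sim_config(barbed = barbed_end_model(delta = delta),
                      C_m = 0, duration = 200, initial_length = 2000,
                      seed = 5)
    simulate_gliding(cfg)
  }
  t0 <- mk(0); t5 <- mk(5)
  n0 <- tail(t0$samples$length_su, 1)
  n5 <- tail(t5$samples$length_su, 1)
  expect_lt(n5, n0)
  # gliding itself is barely affected by the end chemistry
  expect_equal(trajectory_summary(t5)$v_f, trajectory_summary(t0)$v_f,
               tolerance = 0.15)
})

test_that("unstable time steps are rejected before running", {
  expect_error(sim_config(C_m = 10, dt = 0.01), "unstable")
})

test_that("trajectory summaries are exact on linear trajectories", {
  tr <- make_linear_traj(v_f = 56.4, v_p = 2)
  s <- trajectory_summary(tr)
  expect_equal(s$v_f, 56.4, tolerance = 1e-9)
  expect_equal(s$v_p, 2, tolerance = 1e-9)
  expect_error(trajectory_summary(tr, window = 1e6), "shorter")
  short <- make_linear_traj(duration = 1)
  expect_error(trajectory_summary(short), "3 samples")
})

test_that("trajectories round-trip through the CSV + JSON interface", {
  cfg <- sim_config(C_m = 0.3, duration = 30, initial_length = 1800,
                    seed = 3)
  tr <- simulate_gliding(cfg)
  f <- file.path(tempdir(), "traj.csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_equal(back$x_b_nm, tr$samples$x_b_nm)
  side <- jsonlite::read_json(sub("csv$", "json", f))
  expect_equal(side$seed, 3)
  expect_equal(side$species$label, "myo1b")
  unlink(c(f, sub("csv$", "json", f)))
})
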