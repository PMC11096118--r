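test_that("grating force follows the sinusoidal law with amplitude C", {
  # quarter period of the standard stimulus: peak force
  expect_equal(grating_force(1 / (4 * 164), f = 164, C = 3), 3)
  expect_equal(grating_force(0, f = 120), 0)
  y <- seq(0, 1 / 120, length.out = 10000)
  expect_lt(abs(max(abs(grating_force(y, f = 120, C = 3))) - 3), 1e-6)
  # amplitude never exceeds C anywhere on the table
  y_all <- seq(0, 0.20, length.out = 50000)
  expect_lte(max(abs(grating_force(y_all, 164, 3))), 3)
})

test_that("table force is a one-sided spring-damper", {
  scene <- scene_params()
  expect_equal(table_force(0, 0, scene), 1960 * 0.001)
  expect_equal(table_force(0.002, -5, scene), 0)
  expect_equal(table_force(scene$z_table - 1e-3, -0.01, scene),
               1960 * 1e-3 + 28 * 0.01)
  # continuous at the surface for vz = 0
  expect_equal(table_force(scene$z_table, 0, scene), 0)
  expect_lt(table_force(scene$z_table - 1e-12, 0, scene), 1e-8)
})

test_that("the cycloidal law satisfies its boundary conditions", {
  cy <- cycloidal_reference(0.02, 0.08, T_sweep = 1.5, t = c(0, 0.75, 1.5))
  expect_equal(cy$pos, c(0.02, 0.05, 0.08))
  expect_equal(cy$vel[c(1, 3)], c(0, 0))
  expect_equal(cy$acc[c(1, 3)], c(0, 0), tolerance = 1e-12)
  expect_equal(cy$vel[2], 2 * 0.06 / 1.5)   # peak velocity at midpoint
})

test_that("cycloidal velocity matches the numeric derivative of position", {
  t <- seq(0, 2, by = 1e-4)
  cy <- cycloidal_reference(0, 0.06, 2, t)
  v_num <- diff(cy$pos) / diff(t)
  v_mid <- (cy$vel[-1] + cy$vel[-length(t)]) / 2
  expect_lt(max(abs(v_num - v_mid)) / max(abs(cy$vel)), 1e-6)
  expect_error(cycloidal_reference(0, 1, -1, 0), "T_sweep")
  expect_error(cycloidal_reference(0, 1, 1, 2), "within")
})

test_that("guided exploration tracks the reference closely", {
  trace <- simulate_exploration(seed = 4L)
  scene <- scene_params()
  guidance <- guidance_params()
  ref <- sestrain:::session_reference(trace$t, scene, guidance)
  # after the initial contact transient the PD keeps the hand near the
  # reference
  settled <- trace$t > 0.1
  expect_lt(max(abs(ref$pos[settled] - trace$y[settled])), 0.01)
  # total force decomposes exactly into its components
  expect_equal(trace$F_total_y, trace$F_grating + trace$F_guidance)
  expect_equal(trace$F_total_z, trace$F_table)
  # contact definition matches the table penalty branch
  expect_identical(trace$in_contact, trace$z < scene$z_table)
})

test_that("with no guidance, press or noise the hand stays put", {
  trace <- simulate_exploration(
    guidance = guidance_params(K_hg = 1e-12, B_hg = 1e-12),
    press_force = 0, noise_sd = 0, seed = 1L)
  expect_lt(max(abs(trace$y - trace$y[1])), 1e-9)
  expect_lt(max(abs(trace$z - trace$z[1])), 1e-9)
})

test_that("kinematic metrics recover hand-computed values", {
  # constant-speed pass at 0.05 m/s across one 0.05 m texture
  dt <- 1e-3
  n <- 1000L
  trace <- tibble::tibble(
    t = seq(0, by = dt, length.out = n),
    y = seq(0, by = 0.05 * dt, length.out = n),
    vy = rep(0.05, n),
    in_contact = TRUE,
    region = 1L
  )
  m <- kinematic_metrics(trace)
  # one of three textures visited: per-texture averages divide by 3
  expect_equal(m$scanning_time * 3, 1.0, tolerance = 0.01)
  expect_equal(m$path_length * 3, 0.05, tolerance = 0.01)
  expect_equal(m$scanning_speed, 0.05)

  # piecewise speeds: 0.5 s at 0.04 m/s in region 1, 0.5 s below the
  # floor, 0.5 s at 0.02 m/s in region 2
  seg <- function(v, region, t0) tibble::tibble(
    t = seq(t0, by = dt, length.out = 500L),
    vy = rep(v, 500L), in_contact = TRUE, region = region)
  tr <- dplyr::bind_rows(seg(0.04, 1L, 0), seg(0.005, 1L, 0.5),
                         seg(0.02, 2L, 1.0))
  tr$y <- cumsum(tr$vy * dt)
  m2 <- kinematic_metrics(tr)
  expect_equal(m2$scanning_time, (0.5 + 0.5) / 3, tolerance = 0.01)
  expect_equal(m2$path_length, (0.02 + 0.01) / 3, tolerance = 0.01)
  expect_equal(m2$scanning_speed, (0.04 * 500 + 0.02 * 500) / 1000)
})

test_that("metrics are missing (not zero) when nothing qualifies", {
  trace <- tibble::tibble(t = seq(0, 1, by = 0.01), y = 0, vy = 0.001,
                          in_contact = TRUE, region = 1L)
  m <- kinematic_metrics(trace)
  expect_true(is.na(m$scanning_time))
  expect_true(is.na(m$path_length))
  expect_true(is.na(m$scanning_speed))
})

test_that("metrics are stable under resampling of a simulated trace", {
  trace <- simulate_exploration(seed = 9L)
  m1 <- kinematic_metrics(trace)
  m2 <- kinematic_metrics(trace[seq(1, nrow(trace), by = 2), ])
  expect_equal(m1$scanning_time, m2$scanning_time, tolerance = 0.02)
  expect_equal(m1$path_length, m2$path_length, tolerance = 0.02)
  expect_equal(m1$scanning_speed, m2$scanning_speed, tolerance = 0.02)
})

test_that("guidance remains stable for plausible hand masses", {
  scene <- scene_params()
  guidance <- guidance_params()
  for (m in c(0.5, 2)) {
    trace <- simulate_exploration(scene = scene, guidance = guidance,
                                  seed = 2L, mass = m)
    ref <- sestrain:::session_reference(trace$t, scene, guidance)
    settled <- trace$t > 0.2
    # bounded tracking error, no runaway oscillation
    expect_lt(max(abs(ref$pos[settled] - trace$y[settled])), 0.02)
    expect_lt(max(abs(trace$vy)), 0.5)
  }
})
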