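#' Virtual scene parameters
#'
#' Parameters of the haptically rendered scene: the sinusoidal grating force
#' constant, the penalty-based virtual table, and the layout of the three
#' texture regions along the lateral y-axis. The table footprint is
#' 0.20 m x 0.10 m; textures are three equal-width y-intervals separated by
#' `gap` metres of smooth surface.
#'
#' @param C Grating force constant (N).
#' @param K_z Table stiffness (N/m).
#' @param B_z Table damping (N s/m).
#' @param z_table Table height (m).
#' @param table_length,table_width Table footprint (m); textures span the
#'   length (y) direction.
#' @param gap Smooth gap between adjacent texture regions (m).
#' @return A list of class `ses_scene` with a `regions` tibble
#'   (`region`, `y_min`, `y_max`).
#' @export
scene_params <- function(C = 3, K_z = 1960, B_z = 28, z_table = 0.001,
                         table_length = 0.20, table_width = 0.10,
                         gap = 0.01) {
  check_scalar_number(C, "C", lower = 0)
  check_scalar_number(K_z, "K_z", lower = 0)
  check_scalar_number(B_z, "B_z", lower = 0)
  width <- (table_length - 2 * gap) / 3
  if (width <= 0) abort("Texture regions do not fit the table length.")
  starts <- (width + gap) * (0:2)
  regions <- tibble(region = 1:3, y_min = starts, y_max = starts + width)
  structure(
    list(C = C, K_z = K_z, B_z = B_z, z_table = z_table,
         table_length = table_length, table_width = table_width,
         regions = regions),
    class = "ses_scene"
  )
}

#' Haptic guidance controller parameters
#'
#' PD gains of the haptic guidance force that drives the hand along the
#' cycloidal reference trajectory, plus the duration of one guided sweep
#' across a texture.
#'
#' @param K_hg Guidance stiffness (N/m).
#' @param B_hg Guidance damping (N s/m).
#' @param sweep_duration Seconds per guided pass over one texture.
#' @param transition_duration Seconds for the guided move between adjacent
#'   textures.
#' @return A list of class `ses_guidance`.
#' @export
guidance_params <- function(K_hg = 300, B_hg = 60, sweep_duration = 1.5,
                            transition_duration = 0.4) {
  check_scalar_number(K_hg, "K_hg", lower = 0)
  check_scalar_number(B_hg, "B_hg", lower = 0)
  check_scalar_number(sweep_duration, "sweep_duration", lower = 1e-6)
  check_scalar_number(transition_duration, "transition_duration", lower = 1e-6)
  structure(
    list(K_hg = K_hg, B_hg = B_hg, sweep_duration = sweep_duration,
         transition_duration = transition_duration),
    class = "ses_guidance"
  )
}

#' Lateral grating force of a virtual texture
#'
#' The texture is rendered as a lateral sinusoidal force
#' `F_g = C sin(2 pi f y)` felt while scanning along y. Gating by contact
#' and texture region is the caller's responsibility; this is the raw force
#' law.
#'
#' @param y End-effector position along the y-axis (m); vectorized.
#' @param f Spatial frequency of the grating (m^-1).
#' @param C Force constant (N).
#' @return Lateral force (N), same length as `y`.
#' @examples
#' grating_force(1 / (4 * 164), f = 164) # quarter period: peak force 3 N
#' @export
grating_force <- function(y, f, C = 3) {
  C * sin(2 * pi * f * y)
}

#' Vertical penalty force of the virtual table
#'
#' Spring-damper penalty active only below the table surface:
#' `K_z (z_table - z) - B_z vz` when `z < z_table`, zero otherwise.
#'
#' @param z End-effector height (m); vectorized.
#' @param vz Vertical velocity (m/s); vectorized.
#' @param scene A [scene_params()] object.
#' @return Vertical force (N).
#' @export
table_force <- function(z, vz, scene = scene_params()) {
  below <- z < scene$z_table
  ifelse(below, scene$K_z * (scene$z_table - z) - scene$B_z * vz, 0)
}

#' Cycloidal reference trajectory
#'
#' The standard cycloidal displacement law used for the guided sweeps:
#' position `y0 + (y1 - y0) (t/T - sin(2 pi t/T) / (2 pi))` with analytic
#' velocity and acceleration; both derivatives vanish at `t = 0` and
#' `t = T`, so consecutive segments join smoothly.
#'
#' @param y0,y1 Start and end positions (m).
#' @param T_sweep Segment duration (s), `> 0`.
#' @param t Time(s) within `[0, T_sweep]`; vectorized.
#' @return A tibble with columns `t`, `pos`, `vel`, `acc`.
#' @export
cycloidal_reference <- function(y0, y1, T_sweep, t) {
  check_scalar_number(T_sweep, "T_sweep", lower = 1e-12)
  if (any(t < -1e-12 | t > T_sweep + 1e-12)) {
    abort("`t` must lie within [0, T_sweep].")
  }
  tau <- t / T_sweep
  dy <- y1 - y0
  tibble(
    t = t,
    pos = y0 + dy * (tau - sin(2 * pi * tau) / (2 * pi)),
    vel = dy / T_sweep * (1 - cos(2 * pi * tau)),
    acc = dy * 2 * pi / T_sweep^2 * sin(2 * pi * tau)
  )
}

# Piecewise cycloidal reference covering three sweeps (one per texture) with
# short cycloidal transitions between them. Returns pos/vel/acc at times t.
session_reference <- function(t, scene, guidance) {
  r <- scene$regions
  segs <- list()
  t0 <- 0
  for (k in 1:3) {
    segs[[length(segs) + 1L]] <-
      list(t0 = t0, T = guidance$sweep_duration,
           y0 = r$y_min[k], y1 = r$y_max[k])
    t0 <- t0 + guidance$sweep_duration
    if (k < 3) {
      segs[[length(segs) + 1L]] <-
        list(t0 = t0, T = guidance$transition_duration,
             y0 = r$y_max[k], y1 = r$y_min[k + 1])
      t0 <- t0 + guidance$transition_duration
    }
  }
  total <- t0
  pos <- vel <- acc <- numeric(length(t))
  for (s in segs) {
    idx <- t >= s$t0 & t < s$t0 + s$T
    if (!any(idx)) next
    cy <- cycloidal_reference(s$y0, s$y1, s$T, t[idx] - s$t0)
    pos[idx] <- cy$pos; vel[idx] <- cy$vel; acc[idx] <- cy$acc
  }
  idx <- t >= total
  pos[idx] <- r$y_max[3]
  list(pos = pos, vel = vel, acc = acc, total = total)
}

# Map y positions to texture region index (NA outside all regions).
region_of <- function(y, scene) {
  r <- scene$regions
  out <- rep(NA_integer_, length(y))
  for (k in 1:3) out[y >= r$y_min[k] & y <= r$y_max[k]] <- k
  out
}

#' Simulate robot-guided texture exploration
#'
#' Integrates a planar (y, z) point-mass model of the hand/end-effector under
#' the total rendered force: gated grating force, virtual-table penalty,
#' and the PD haptic guidance force
#' `F_hg = ydd_R + B_hg (yd_R - yd) + K_hg (y_R - y)` active while in
#' contact. The reference sweeps each of the three textures once with a
#' cycloidal motion law. A small seeded random force models the compliance of
#' the passively guided arm. Semi-implicit Euler at the control rate.
#'
#' @param trial One row of a schedule tibble (uses `arrangement`,
#'   `f_standard`, `f_comparison`) or `NULL` for a standard/standard/standard
#'   layout.
#' @param scene A [scene_params()].
#' @param guidance A [guidance_params()].
#' @param seed Integer seed for the compliance noise.
#' @param mass Hand/end-effector mass (kg).
#' @param damping Passive arm viscous damping (N s/m).
#' @param press_force Constant downward hand force maintaining contact (N).
#' @param rate Control rate (Hz).
#' @param noise_sd Standard deviation of the compliance force noise (N).
#' @return A tibble trace of class `ses_trace`: `t`, `y`, `z`, `vy`, `vz`,
#'   `F_grating`, `F_table`, `F_guidance`, `F_total_y`, `F_total_z`,
#'   `in_contact`, `region`.
#' @export
simulate_exploration <- function(trial = NULL, scene = scene_params(),
                                 guidance = guidance_params(), seed = 1L,
                                 mass = 1.0, damping = 5,
                                 press_force = 2, rate = 1000,
                                 noise_sd = 0.05) {
  check_scalar_number(mass, "mass", lower = 1e-6)
  dt <- 1 / rate
  if (is.null(trial)) {
    freqs <- rep(164, 3)
  } else {
    freqs <- drop(triplet_frequencies(
      if (trial$arrangement == "A/B/B") "Co/St/St" else trial$arrangement,
      trial$f_standard, trial$f_comparison))
  }
  total_T <- 3 * guidance$sweep_duration + 2 * guidance$transition_duration
  t <- seq(0, total_T, by = dt)
  ref <- session_reference(t, scene, guidance)
  n <- length(t)
  noise <- with_seed(seed, rnorm(n, sd = noise_sd))

  y <- numeric(n); z <- numeric(n); vy <- numeric(n); vz <- numeric(n)
  Fg <- numeric(n); Ft <- numeric(n); Fh <- numeric(n)
  y[1] <- scene$regions$y_min[1]
  z[1] <- scene$z_table
  for (i in seq_len(n)) {
    in_contact <- z[i] < scene$z_table
    reg <- region_of(y[i], scene)
    Fg[i] <- if (in_contact && !is.na(reg)) {
      grating_force(y[i], freqs[reg], scene$C)
    } else 0
    Ft[i] <- table_force(z[i], vz[i], scene)
    Fh[i] <- if (in_contact) {
      ref$acc[i] + guidance$B_hg * (ref$vel[i] - vy[i]) +
        guidance$K_hg * (ref$pos[i] - y[i])
    } else 0
    if (i == n) break
    ay <- (Fg[i] + Fh[i] + noise[i] - damping * vy[i]) / mass
    az <- (Ft[i] - press_force - damping * vz[i]) / mass
    vy[i + 1] <- vy[i] + ay * dt
    vz[i + 1] <- vz[i] + az * dt
    y[i + 1] <- y[i] + vy[i + 1] * dt
    z[i + 1] <- z[i] + vz[i + 1] * dt
    if (y[i + 1] < -0.05 || y[i + 1] > scene$table_length + 0.05) {
      abort("Integrator divergence: end-effector left the table by > 0.05 m.")
    }
  }
  in_contact <- z < scene$z_table
  region <- region_of(y, scene)
  region[!in_contact] <- NA_integer_
  out <- tibble(
    t = t, y = y, z = z, vy = vy, vz = vz,
    F_grating = Fg, F_table = Ft, F_guidance = Fh,
    F_total_y = Fg + Fh, F_total_z = Ft,
    in_contact = in_contact, region = region
  )
  class(out) <- c("ses_trace", class(out))
  out
}

#' Kinematic exploration metrics of a trace
#'
#' Scanning time, path length and scanning speed over the samples where the
#' hand is in contact with a texture and moving laterally faster than the
#' speed floor. Scanning time and path length are averaged over the three
#' textures; scanning speed is the mean lateral speed over all qualifying
#' samples.
#'
#' @param trace A trace from [simulate_exploration()] (columns `t`, `y`,
#'   `vy`, `in_contact`, `region`).
#' @param speed_floor Minimum lateral speed (m/s) for a sample to count as
#'   texture scanning.
#' @return A one-row tibble: `scanning_time` (s), `path_length` (m),
#'   `scanning_speed` (m/s); all `NA` if no sample qualifies.
#' @export
kinematic_metrics <- function(trace, speed_floor = 0.01) {
  if (nrow(trace) == 0) abort("`trace` must be non-empty.")
  dt <- median(diff(trace$t))
  qual <- trace$in_contact & !is.na(trace$region) & abs(trace$vy) > speed_floor
  if (!any(qual)) {
    return(tibble(scanning_time = NA_real_, path_length = NA_real_,
                  scanning_speed = NA_real_))
  }
  dy <- c(0, abs(diff(trace$y)))
  per_region <- vapply(1:3, function(k) {
    sel <- qual & trace$region %in% k
    c(time = sum(sel) * dt, path = sum(dy[sel]))
  }, numeric(2))
  tibble(
    scanning_time = mean(per_region["time", ]),
    path_length = mean(per_region["path", ]),
    scanning_speed = mean(abs(trace$vy[qual]))
  )
}
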