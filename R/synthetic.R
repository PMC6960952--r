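# Synthetic treadmill-gait generator with exact ground truth.
#
# Heel and toe vertical displacement follow a kinematic foot model built from
# piecewise cubic Hermite segments: flat ground contact with sub-millimetre
# contact (pad-compression) and pre-lift (unweighting) transients, and a
# raised-cosine swing arc blended through fast liftoff and decelerating
# landing segments. The model is C1 everywhere, twice differentiable within
# segments, and places a strict displacement minimum exactly at each strike
# phase and at each off phase. Acceleration is the discrete second derivative
# plus gravity, white sensor noise and a slow sinusoidal drift.

#' Synthetic gait parameters
#'
#' Defaults emulate treadmill walking at constant speed with a 1000 Hz
#' accelerometer and a 100 Hz motion-capture reference: 1 s gait cycles,
#' heel contact from phase 0 (HS) to 0.45 (HO) and toe contact from 0.12
#' (TS) to 0.62 (TO), swing peaks of 15 cm (heel) and 5 cm (toe).
#'
#' @param cycle_s gait-cycle duration (s).
#' @param n_cycles number of complete cycles to generate.
#' @param stance_fraction nominal fraction of the cycle the foot is on the
#'   ground (HS to TO); descriptive, must agree with `event_phases` within
#'   0.1.
#' @param swing_peak_heel_m,swing_peak_toe_m swing arc peak heights (m).
#' @param event_phases named numeric vector of HS, TS, HO, TO phases in
#'   [0, 1), strictly increasing.
#' @param noise_sigma white accelerometer noise SD (m/s^2).
#' @param drift_amp amplitude of the slow sinusoidal drift (m/s^2).
#' @param drift_hz drift frequency (Hz); the 0.05 Hz default sits below the
#'   integration highpass so that wavelet detrending is genuinely exercised.
#' @param fs_accel accelerometer sampling rate (Hz).
#' @param fs_ref reference (motion-capture) sampling rate (Hz); must divide
#'   `fs_accel` and satisfy `fs_accel >= 2 * fs_ref`.
#' @param seed integer RNG seed; trials are bitwise reproducible.
#' @param phase0 gait phase at t = 0 (the record starts mid-swing so the
#'   first heel strike has a preceding descent).
#' @param contact_dip_m depth of the contact/pre-lift displacement
#'   transients (m); kept below 1 mm so stance displacement is ~0.
#' @param landing_ms,liftoff_ms duration of the decelerating landing and the
#'   accelerating liftoff segments (ms).
#' @param approach_frac height (as a fraction of the swing peak) at which the
#'   landing/liftoff segments hand over to the swing arc.
#' @param recovery_ms,unweight_ms durations of the post-contact recovery and
#'   pre-lift unweighting transients (ms).
#' @param swing_peak_frac position of the swing peak as a fraction of the
#'   arc (early peak: the foot rises quickly after lift and descends slowly).
#' @param xy_amp_frac amplitude of the horizontal-axis oscillations as a
#'   fraction of the vertical dynamic range.
#' @param xy_freq_hz length-2 frequencies (Hz) of the ax/ay swing
#'   oscillations.
#' @return validated parameter list of class `gait_params`.
#' @export
gait_params <- function(cycle_s = 1.0, n_cycles = 10L, stance_fraction = 0.6,
                        swing_peak_heel_m = 0.15, swing_peak_toe_m = 0.05,
                        event_phases = c(HS = 0.0, TS = 0.12, HO = 0.45,
                                         TO = 0.62),
                        noise_sigma = 0.2, drift_amp = 0.1, drift_hz = 0.05,
                        fs_accel = 1000, fs_ref = 100, seed = 1L,
                        phase0 = 0.8, contact_dip_m = 8e-4, landing_ms = 35,
                        liftoff_ms = 35, approach_frac = 0.17,
                        recovery_ms = 20, unweight_ms = 20,
                        swing_peak_frac = 0.35, xy_amp_frac = 0.1,
                        xy_freq_hz = c(6, 5)) {
  p <- as.list(environment())
  ph <- p$event_phases
  if (is.null(names(ph)) || !all(c("HS", "TS", "HO", "TO") %in% names(ph))) {
    stop("`event_phases` must be named HS, TS, HO, TO", call. = FALSE)
  }
  ph <- ph[c("HS", "TS", "HO", "TO")]
  if (!(ph["HS"] >= 0 && all(diff(ph) > 0) && ph["TO"] < 1)) {
    stop("event phases must satisfy 0 <= HS < TS < HO < TO < 1",
         call. = FALSE)
  }
  p$event_phases <- ph
  if (abs((ph["TO"] - ph["HS"]) - stance_fraction) > 0.1) {
    stop("`stance_fraction` is inconsistent with the HS..TO span of ",
         "`event_phases`", call. = FALSE)
  }
  if (any(c(swing_peak_heel_m, swing_peak_toe_m, noise_sigma, drift_amp) < 0)) {
    stop("amplitudes must be >= 0", call. = FALSE)
  }
  if (cycle_s <= 0 || n_cycles < 1) stop("invalid cycle/n_cycles",
                                         call. = FALSE)
  if (fs_accel < 2 * fs_ref) stop("need fs_accel >= 2 * fs_ref",
                                  call. = FALSE)
  if (fs_accel %% fs_ref != 0) stop("`fs_ref` must divide `fs_accel`",
                                    call. = FALSE)
  if (contact_dip_m < 0 || contact_dip_m > 1e-3) {
    stop("`contact_dip_m` must be in [0, 1 mm]", call. = FALSE)
  }
  structure(p, class = c("gait_params", "list"))
}

# Quintic Hermite on [0, T]: values y0 -> y1, slopes v0 -> v1 and second
# derivatives a0 -> a1 at the ends. Matching values, slopes AND second
# derivatives at every segment junction makes the trajectory C2, so the
# acceleration is continuous and its singularities are slope breaks
# (Lipschitz order 1), not jumps.
.hermite <- function(u, T, y0, y1, v0 = 0, v1 = 0, a0 = 0, a1 = 0) {
  s <- u / T
  s2 <- s * s
  s3 <- s2 * s
  s4 <- s3 * s
  s5 <- s4 * s
  y0 * (1 - 10 * s3 + 15 * s4 - 6 * s5) +
    v0 * T * (s - 6 * s3 + 8 * s4 - 3 * s5) +
    a0 * T^2 * 0.5 * (s2 - 3 * s3 + 3 * s4 - s5) +
    y1 * (10 * s3 - 15 * s4 + 6 * s5) +
    v1 * T * (-4 * s3 + 7 * s4 - 3 * s5) +
    a1 * T^2 * 0.5 * (s3 - 2 * s4 + s5)
}

# Vertical displacement of one foot at the given gait phases (vectorized).
# p_c = contact phase, p_l = lift phase, both relative to the cycle.
.foot_displacement <- function(phase, p_c, p_l, peak, params) {
  cyc <- params$cycle_s
  dip <- params$contact_dip_m
  wr <- params$recovery_ms / 1000 / cyc     # phase units
  wf <- params$unweight_ms / 1000 / cyc
  Tr <- params$liftoff_ms / 1000 / cyc
  Tl <- params$landing_ms / 1000 / cyc
  hr <- params$approach_frac * peak
  hl <- params$approach_frac * peak
  u <- (phase - p_c) %% 1                    # phase since contact
  stance <- (p_l - p_c) %% 1
  arc0 <- stance + Tr
  arc1 <- 1 - Tl
  tpk <- arc0 + params$swing_peak_frac * (arc1 - arc0)
  # liftoff exit / landing approach velocities (m/s). A quintic arc half with
  # flat peak overshoots above `peak` when its end slope exceeds 2.5x the
  # mean slope; capping at 2.4x keeps the swing maximum at `peak` exactly.
  vr <- min(2 * (hr + dip) / (Tr * cyc),
            2.4 * (peak - hr) / ((tpk - arc0) * cyc))
  vl <- min(2 * (hl + dip) / (Tl * cyc),
            2.4 * (peak - hl) / ((arc1 - tpk) * cyc))
  ac <- 4 * (hl + dip) / (Tl * cyc)^2        # contact-trough curvature (m/s^2)
  al <- 4 * (hr + dip) / (Tr * cyc)^2        # lift-trough curvature
  d <- numeric(length(u))
  seg <- findInterval(u, c(wr, stance - wf, stance, arc0, tpk, arc1))
  # seg 0: post-contact recovery (-dip -> 0), trough curvature ac at contact
  i <- seg == 0L
  d[i] <- .hermite(u[i] * cyc, wr * cyc, -dip, 0, a0 = ac)
  # seg 1: flat mid-stance (d stays 0)
  # seg 2: pre-lift unweighting (0 -> -dip), curvature al at the lift trough
  i <- seg == 2L
  d[i] <- .hermite((u[i] - (stance - wf)) * cyc, wf * cyc, 0, -dip, a1 = al)
  # seg 3: liftoff (-dip -> hr, exit slope vr)
  i <- seg == 3L
  d[i] <- .hermite((u[i] - stance) * cyc, Tr * cyc, -dip, hr, 0, vr, a0 = al)
  # seg 4: swing rise (hr -> peak)
  i <- seg == 4L
  d[i] <- .hermite((u[i] - arc0) * cyc, (tpk - arc0) * cyc, hr, peak, vr, 0)
  # seg 5: swing descent (peak -> hl)
  i <- seg == 5L
  d[i] <- .hermite((u[i] - tpk) * cyc, (arc1 - tpk) * cyc, peak, hl, 0, -vl)
  # seg 6: landing deceleration (hl -> -dip, minimum exactly at contact,
  #        curvature ac there)
  i <- seg == 6L
  d[i] <- .hermite((u[i] - arc1) * cyc, Tl * cyc, hl, -dip, -vl, 0, a1 = ac)
  d
}

#' Ground-truth heel and toe trajectories
#'
#' Evaluates the kinematic foot model at the accelerometer sampling rate.
#'
#' @param params a [gait_params()] list.
#' @return list with `time` (s), `heel`, `toe` displacement vectors (m).
#' @export
heel_toe_trajectories <- function(params = gait_params()) {
  stopifnot(inherits(params, "gait_params"))
  n <- as.integer(round(params$n_cycles * params$cycle_s * params$fs_accel))
  tt <- (seq_len(n) - 1L) / params$fs_accel
  phase <- (tt / params$cycle_s + params$phase0) %% 1
  ph <- params$event_phases
  list(time = tt,
       heel = .foot_displacement(phase, ph[["HS"]], ph[["HO"]],
                                 params$swing_peak_heel_m, params),
       toe = .foot_displacement(phase, ph[["TS"]], ph[["TO"]],
                                params$swing_peak_toe_m, params))
}

# Discrete second derivative; edge samples replicate the interior curvature
# so a nonzero boundary slope does not masquerade as an impact.
.second_derivative <- function(d, fs) {
  n <- length(d)
  core <- d[3:n] - 2 * d[2:(n - 1L)] + d[1:(n - 2L)]
  c(core[1L], core, core[n - 2L]) * fs^2
}

# Swing envelope (0 during stance, raised-cosine bump over the swing).
.swing_envelope <- function(phase, p_c, p_l) {
  u <- (phase - p_c) %% 1
  stance <- (p_l - p_c) %% 1
  tau <- (u - stance) / (1 - stance)
  ifelse(u >= stance, sin(pi * tau)^2, 0)
}

# Evaluate fn with a temporary RNG state seeded by `seed`.
.with_seed <- function(seed, fn) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  fn()
}

#' Generate a synthetic gait trial
#'
#' Builds heel and toe accelerometer recordings from the kinematic model:
#' vertical acceleration is the discrete second derivative of the true
#' displacement plus gravity (9.81 m/s^2), Gaussian sensor noise and a slow
#' sinusoidal drift; the horizontal axes carry swing-synchronous oscillations
#' (10 percent of the vertical dynamic range by default) plus noise, so the
#' 3-D jerk magnitude is exercised. Ground-truth event times are the exact
#' phase times; reference displacement traces are the clean trajectories
#' resampled to `fs_ref`.
#'
#' @param params a [gait_params()] list.
#' @return object of class `synthetic_trial`: `heel_rec`, `toe_rec`
#'   ([accel_recording()]s), `heel_ref`, `toe_ref` (data frames with `time`,
#'   `displacement`), `truth` ([gait_events()]), and `params`.
#' @export
make_trial <- function(params = gait_params()) {
  stopifnot(inherits(params, "gait_params"))
  traj <- heel_toe_trajectories(params)
  fs <- params$fs_accel
  n <- length(traj$time)
  tt <- traj$time
  phase <- (tt / params$cycle_s + params$phase0) %% 1
  ph <- params$event_phases
  g <- 9.81
  drift <- params$drift_amp * sin(2 * pi * params$drift_hz * tt)

  build_site <- function(d_true, p_c, p_l, site) {
    az <- .second_derivative(d_true, fs) + g + drift +
      stats::rnorm(n, 0, params$noise_sigma)
    env <- .swing_envelope(phase, p_c, p_l)
    dyn <- diff(range(az - g))
    amp <- params$xy_amp_frac * dyn
    # two inharmonic components per axis so the combined horizontal jerk has
    # no simultaneous nulls during the swing
    osc <- function(f, ph0) {
      sin(2 * pi * f * tt + ph0) + 0.6 * sin(2 * pi * 2.3 * f * tt + ph0 + 0.7)
    }
    ax <- amp * env * osc(params$xy_freq_hz[1L], 0) +
      stats::rnorm(n, 0, params$noise_sigma)
    ay <- amp * env * osc(params$xy_freq_hz[2L], 1) +
      stats::rnorm(n, 0, params$noise_sigma)
    accel_recording(ax, ay, az, fs = fs, site = site)
  }

  trial <- .with_seed(params$seed, function() {
    heel_rec <- build_site(traj$heel, ph[["HS"]], ph[["HO"]], "heel")
    toe_rec <- build_site(traj$toe, ph[["TS"]], ph[["TO"]], "toe")
    list(heel_rec = heel_rec, toe_rec = toe_rec)
  })

  step <- as.integer(fs / params$fs_ref)
  ref_idx <- seq.int(1L, n, by = step)

  # exact truth event times: phase p occurs at t = ((p - phase0) mod 1 + k) * cycle
  duration <- n / fs
  truth_lab <- character()
  truth_t <- numeric()
  for (lab in names(ph)) {
    t0 <- ((ph[[lab]] - params$phase0) %% 1) * params$cycle_s
    times <- t0 + params$cycle_s * (0:params$n_cycles)
    times <- times[times < duration - 1e-9]
    truth_lab <- c(truth_lab, rep(lab, length(times)))
    truth_t <- c(truth_t, times)
  }
  truth <- gait_events(truth_lab, truth_t,
                       as.integer(round(truth_t * fs)))

  structure(list(
    heel_rec = trial$heel_rec, toe_rec = trial$toe_rec,
    heel_ref = data.frame(time = tt[ref_idx], displacement = traj$heel[ref_idx]),
    toe_ref = data.frame(time = tt[ref_idx], displacement = traj$toe[ref_idx]),
    truth = truth, params = params), class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial> %d cycles of %.2f s at %g Hz, noise sd %.3g m/s^2, %d truth events (seed %d)\n",
    x$params$n_cycles, x$params$cycle_s, x$params$fs_accel,
    x$params$noise_sigma, nrow(x$truth), x$params$seed))
  invisible(x)
}
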