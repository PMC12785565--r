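#' Trial specification for the simulator
#'
#' Mirrors the measurement protocol: single-leg squats are performed as a
#' fixed number of repetitions at the metronome tempo (default 10 reps at
#' 60 beats/min, one repetition per beat), both-leg squats with heel raise
#' run continuously for a fixed duration (default 30 s). Every set starts
#' with a 3 s leg-lift reference mark (sensors unloaded) used for
#' synchronisation.
#'
#' @param exercise `"single_leg_squat"` or `"both_leg_squat_heel_raise"`.
#' @param foot instrumented foot, `"right"` or `"left"`.
#' @param repetitions repetition count for the single-leg squat (default 10).
#' @param duration duration (s) of the both-leg squat (default 30).
#' @param tempo metronome tempo (beats/min, default 60).
#' @param marker_duration leg-lift mark length (s, default 3).
#' @return An object of class `trial_spec`.
#' @export
trial_spec <- function(exercise = c("single_leg_squat",
                                    "both_leg_squat_heel_raise"),
                       foot = c("right", "left"),
                       repetitions = 10, duration = 30, tempo = 60,
                       marker_duration = 3) {
  exercise <- match.arg(exercise)
  foot <- match.arg(foot)
  stop_if_not_scalar_number(tempo, "tempo", positive = TRUE)
  stop_if_not_scalar_number(marker_duration, "marker_duration", positive = TRUE)
  if (exercise == "single_leg_squat") {
    stop_if_not_scalar_number(repetitions, "repetitions", positive = TRUE)
    exercise_duration <- repetitions * 60 / tempo
  } else {
    stop_if_not_scalar_number(duration, "duration", positive = TRUE)
    exercise_duration <- duration
  }
  structure(
    list(exercise = exercise, foot = foot, repetitions = repetitions,
         duration = duration, tempo = tempo,
         marker_duration = marker_duration,
         exercise_duration = exercise_duration),
    class = "trial_spec"
  )
}

# Default trajectory amplitudes per exercise (mm). Single-leg squats keep
# the mediolateral excursion within about +/-20 mm; both-leg squats with
# heel raise move predominantly anteroposteriorly, spanning about -50 to
# +60 mm (offset + amplitude), with smaller mediolateral sway.
default_amplitudes <- function(spec) {
  if (spec$exercise == "single_leg_squat") {
    list(y_amp = 30, y_offset = 0, x_amp = 15, x_freq = 0.25,
         noise_sd = 2, noise_smooth = 0.2)
  } else {
    list(y_amp = 55, y_offset = 5, x_amp = 15, x_freq = 0.25,
         noise_sd = 2, noise_smooth = 0.2)
  }
}

# Band-limited Gaussian noise: white noise smoothed by a moving average of
# `smooth` seconds, rescaled to standard deviation `sd`.
band_limited_noise <- function(n, rate, sd, smooth) {
  if (sd <= 0 || n == 0L) return(numeric(n))
  w <- stats::rnorm(n)
  k <- max(1L, as.integer(round(smooth * rate)))
  if (k > 1L) {
    w <- stats::filter(w, rep(1 / k, k), sides = 2, circular = TRUE)
    w <- as.numeric(w)
  }
  s <- stats::sd(w)
  if (s == 0) return(numeric(n))
  w / s * sd
}

#' Simulate a ground-truth squat CoP trajectory
#'
#' Builds the "true" CoP of one trial as the sum of (i) a periodic
#' anteroposterior excursion at the metronome tempo, (ii) slower
#' mediolateral sway, and (iii) band-limited noise, preceded by a 3 s
#' unloaded lead-in (the leg-lift reference mark, total load zero). The
#' series carries the total plantar load profile (kPa) as attribute
#' `"load"` so the sensor forward model can drive conductances from it.
#'
#' @param spec a [trial_spec()].
#' @param amplitudes optional named list overriding any of `y_amp`,
#'   `y_offset`, `x_amp`, `x_freq` (Hz), `noise_sd` (mm), `noise_smooth`
#'   (s); defaults depend on the exercise (see Details).
#' @param rate sampling rate of the truth grid (Hz, default 125).
#' @param base_load peak-to-mean total plantar load (kPa, default 50),
#'   modulated 20% at the squat tempo.
#' @param seed optional RNG seed (trial-local; caller's RNG untouched).
#' @return A [cop_series()] with `source = "truth"`, attributes `load`
#'   (kPa per sample), `marker_window` (c(start, end) in s) and `spec`.
#' @export
simulate_true_cop <- function(spec, amplitudes = NULL, rate = 125,
                              base_load = 50, seed = NULL) {
  if (!inherits(spec, "trial_spec")) stop("`spec` must be a trial_spec", call. = FALSE)
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  amp <- default_amplitudes(spec)
  if (!is.null(amplitudes)) {
    unknown <- setdiff(names(amplitudes), names(amp))
    if (length(unknown)) {
      stop("unknown amplitude fields: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    amp[names(amplitudes)] <- amplitudes
  }
  total <- spec$marker_duration + spec$exercise_duration
  dt <- 1 / rate
  t <- dt * seq.int(0L, floor(total / dt))
  te <- t - spec$marker_duration          # exercise-relative time
  active <- te >= 0
  f <- spec$tempo / 60                    # squat frequency, Hz

  with_seed(seed, {
    y <- ifelse(active, amp$y_offset + amp$y_amp * sin(2 * pi * f * te), 0)
    x <- ifelse(active, amp$x_amp * sin(2 * pi * amp$x_freq * te + pi / 5), 0)
    n <- length(t)
    x <- x + band_limited_noise(n, rate, amp$noise_sd, amp$noise_smooth) * active
    y <- y + band_limited_noise(n, rate, amp$noise_sd, amp$noise_smooth) * active
    load <- ifelse(active, base_load * (1 + 0.2 * sin(2 * pi * f * te)), 0)
    out <- cop_series(t, x, y, valid = rep(TRUE, n), source = "truth",
                      exercise = spec$exercise, foot = spec$foot)
    attr(out, "load") <- load
    attr(out, "marker_window") <- c(0, spec$marker_duration)
    attr(out, "spec") <- spec
    out
  })
}

# Fan triangulation of the sensor hull: list of index triples, deterministic
# (anchored at the first hull vertex, walking the hull order).
hull_fan <- function(geometry) {
  h <- geometry_hull(geometry)
  lapply(seq_len(length(h) - 2L), function(i) h[c(1L, i + 1L, i + 2L)])
}

# Barycentric weights of points (n x 2) in triangle with vertex matrix v
# (3 x 2). Returns n x 3 matrix.
barycentric <- function(points, v) {
  d <- (v[2, 2] - v[3, 2]) * (v[1, 1] - v[3, 1]) +
       (v[3, 1] - v[2, 1]) * (v[1, 2] - v[3, 2])
  w1 <- ((v[2, 2] - v[3, 2]) * (points[, 1] - v[3, 1]) +
         (v[3, 1] - v[2, 1]) * (points[, 2] - v[3, 2])) / d
  w2 <- ((v[3, 2] - v[1, 2]) * (points[, 1] - v[3, 1]) +
         (v[1, 1] - v[3, 1]) * (points[, 2] - v[3, 2])) / d
  cbind(w1, w2, 1 - w1 - w2)
}

# Vectorised inverse of the CoP summation: for each CoP point, nonnegative
# per-sensor pressures summing to `total` whose conductance-weighted
# centroid is exactly that point. Deterministic: first fan triangle (in
# hull order) containing the point wins. Returns n x 6 matrix.
distribute_load_matrix <- function(points, total, geometry, tol = 1e-9) {
  points <- matrix(points, ncol = 2L)
  n <- nrow(points)
  total <- rep_len(total, n)
  out <- matrix(0, n, 6L)
  todo <- rep(TRUE, n)
  for (tri in hull_fan(geometry)) {
    if (!any(todo)) break
    w <- barycentric(points[todo, , drop = FALSE],
                     geometry$positions[tri, , drop = FALSE])
    ok <- rowSums(w >= -tol) == 3L
    if (!any(ok)) next
    idx <- which(todo)[ok]
    ww <- pmax(w[ok, , drop = FALSE], 0)
    out[idx, tri] <- ww * total[idx]
    todo[idx] <- FALSE
  }
  if (any(todo)) {
    stop(sprintf("CoP outside the sensor hull at sample %d", which(todo)[1]),
         call. = FALSE)
  }
  out
}

#' Distribute a total load over the six sensors for a given CoP
#'
#' Inverts the CoP weighted summation. The inverse problem is
#' under-determined (six unknowns, three constraints); for determinism and
#' exactness the load is placed barycentrically on the triangle of sensors
#' containing the target point (fan triangulation of the sensor hull,
#' first containing triangle in hull order), all other sensors zero.
#' Feeding the resulting pressures back through the CoP summation
#' reproduces the target point to machine precision.
#'
#' @param cop numeric `c(x, y)` target CoP (mm), inside the sensor hull.
#' @param total_pressure total load to distribute (kPa), positive.
#' @param geometry a [sensor_geometry()].
#' @return Numeric vector of 6 nonnegative pressures summing to
#'   `total_pressure`.
#' @export
distribute_load <- function(cop, total_pressure, geometry = sensor_geometry()) {
  stop_if_not_scalar_number(total_pressure, "total_pressure", positive = TRUE)
  cop <- as.numeric(cop)
  if (length(cop) != 2L || any(!is.finite(cop))) {
    stop("`cop` must be a finite (x, y) pair in mm", call. = FALSE)
  }
  as.numeric(distribute_load_matrix(matrix(cop, 1L), total_pressure, geometry))
}

#' Textile sensor forward model
#'
#' Parameters of one sock application. Sensitivities are drawn per sensor
#' and per application from `sensitivity_range` (the knitted sensors'
#' typical 0.5-3.0 uS/kPa span, strongly dependent on how the sock is
#' strained when put on); sensor placement is jittered once per
#' application; conductance saturates at a ceiling and carries additive
#' Gaussian noise.
#'
#' @param sensitivity_range 2-vector (uS/kPa), default `c(0.5, 3.0)`.
#' @param baseline unloaded conductance (uS, default 0.5).
#' @param saturation conductance ceiling of the pressure response
#'   (uS, default 300; `Inf` disables saturation).
#' @param noise_sd additive conductance noise sd (uS, default 1).
#' @param jitter_sd per-application sensor placement jitter sd (mm,
#'   default 2).
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(sensitivity_range = c(0.5, 3.0), baseline = 0.5,
                         saturation = 300, noise_sd = 1, jitter_sd = 2) {
  if (!is.numeric(sensitivity_range) || length(sensitivity_range) != 2L ||
      any(sensitivity_range <= 0) ||
      sensitivity_range[1] > sensitivity_range[2]) {
    stop("`sensitivity_range` must be positive and nondecreasing", call. = FALSE)
  }
  if (!is.numeric(baseline) || baseline < 0) {
    stop("`baseline` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(saturation) || saturation <= baseline) {
    stop("`saturation` must exceed `baseline`", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(jitter_sd) || jitter_sd < 0) stop("`jitter_sd` must be >= 0", call. = FALSE)
  structure(
    list(sensitivity_range = sensitivity_range, baseline = baseline,
         saturation = saturation, noise_sd = noise_sd, jitter_sd = jitter_sd),
    class = "sensor_model"
  )
}

# An ideal sensor model: unit sensitivity everywhere, no baseline, noise,
# saturation or jitter -- makes truth -> sock -> CoP an exact round trip.
#' @rdname sensor_model
#' @export
ideal_sensor_model <- function() {
  sensor_model(sensitivity_range = c(1, 1), baseline = 0, saturation = Inf,
               noise_sd = 0, jitter_sd = 0)
}

#' Simulate a sock conductance recording from a true CoP trajectory
#'
#' Physical forward model of one sock application: the true CoP and total
#' load are (linearly) sampled on the sock's time grid; the load is split
#' over the six sensors barycentrically at the sensors' actual (jittered)
#' positions; each sensor then reports
#' `u = baseline + min(sensitivity * pressure, saturation) + noise`,
#' clipped at zero. Sensitivities and placement jitter are drawn once per
#' call (one sock application). During the unloaded lead-in mark all
#' pressures are zero, so conductances sit at the baseline.
#'
#' @param truth a truth [cop_series()] from [simulate_true_cop()].
#' @param model a [sensor_model()].
#' @param geometry the sensors' nominal [sensor_geometry()]; jitter is
#'   applied to a copy, and reconstruction with the nominal geometry is
#'   what produces realistic placement error.
#' @param rate sock sampling rate (Hz, default 125; hardware supports up
#'   to 200).
#' @param seed optional RNG seed.
#' @return A [conductance_series()]; attribute `params` records the drawn
#'   sensitivities and the jittered geometry.
#' @export
simulate_sock <- function(truth, model = sensor_model(),
                          geometry = sensor_geometry(), rate = 125,
                          seed = NULL) {
  if (!inherits(truth, "cop_series") || truth$source != "truth") {
    stop("`truth` must be a truth cop_series", call. = FALSE)
  }
  if (!inherits(model, "sensor_model")) stop("`model` must be a sensor_model", call. = FALSE)
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  if (rate > 200) stop("sock hardware samples at up to 200 Hz per channel", call. = FALSE)
  load <- attr(truth, "load")
  if (is.null(load)) load <- rep(50, length(truth$time))

  dt <- 1 / rate
  tt <- truth$time
  truth_rate <- 1 / diff(tt[1:2])
  if (isTRUE(all.equal(rate, truth_rate)) && is_uniform_grid(tt)) {
    t <- tt; x <- truth$x; y <- truth$y; w <- load
  } else {
    t <- tt[1] + dt * seq.int(0L, floor((tt[length(tt)] - tt[1]) / dt))
    x <- stats::approx(tt, truth$x, t, ties = "ordered")$y
    y <- stats::approx(tt, truth$y, t, ties = "ordered")$y
    w <- stats::approx(tt, load, t, ties = "ordered")$y
  }

  with_seed(seed, {
    sens <- stats::runif(6, model$sensitivity_range[1], model$sensitivity_range[2])
    geom_actual <- geometry
    if (model$jitter_sd > 0) {
      geom_actual$positions <- geometry$positions +
        matrix(stats::rnorm(12, sd = model$jitter_sd), 6, 2)
    }
    n <- length(t)
    pressures <- matrix(0, n, 6L)
    loaded <- w > 0
    if (any(loaded)) {
      pressures[loaded, ] <- distribute_load_matrix(
        cbind(x[loaded], y[loaded]), w[loaded], geom_actual)
    }
    u <- sweep(pressures, 2L, sens, `*`)
    u <- pmin(u, model$saturation)
    u <- u + model$baseline
    if (model$noise_sd > 0) u <- u + matrix(stats::rnorm(n * 6L, sd = model$noise_sd), n, 6L)
    u <- pmax(u, 0)
    out <- conductance_series(t, u, foot = truth$foot,
                              exercise = truth$exercise)
    attr(out, "params") <- list(sensitivities = sens,
                                geometry_actual = geom_actual)
    out
  })
}

#' Force platform measurement model
#'
#' The platform reports absolute CoP relative to its own origin, so each
#' trial carries a foot-placement offset; measurement noise is additive
#' Gaussian; an optional side-step event adds a further offset from its
#' onset onward (an abrupt change of foot position on the plate).
#'
#' @param rate platform sampling rate (Hz, default 125).
#' @param offset per-trial foot placement offset, mm `c(x, y)` (default
#'   `c(0, 0)`).
#' @param noise_sd CoP noise sd (mm, default 0.5).
#' @param sidestep optional `list(time = <s>, offset = c(x, y))`.
#' @return An object of class `platform_model`.
#' @export
platform_model <- function(rate = 125, offset = c(0, 0), noise_sd = 0.5,
                           sidestep = NULL) {
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  if (!is.numeric(offset) || length(offset) != 2L) {
    stop("`offset` must be c(x, y) in mm", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(sidestep)) {
    if (!is.list(sidestep) || is.null(sidestep$time) || is.null(sidestep$offset) ||
        length(sidestep$offset) != 2L) {
      stop("`sidestep` must be list(time =, offset = c(x, y))", call. = FALSE)
    }
  }
  structure(list(rate = rate, offset = offset, noise_sd = noise_sd,
                 sidestep = sidestep),
            class = "platform_model")
}

#' Simulate the force-platform CoP recording of a trial
#'
#' Samples the true CoP on the platform's grid with the instruments' clock
#' offset `lag` (the platform waveform is the truth delayed by `lag`), adds
#' the foot-placement offset and Gaussian noise, and applies the side-step
#' offset from its onset onward if configured. Samples where the foot is
#' off the plate (zero load, e.g. the lead-in mark) or outside the truth's
#' recorded range are flagged invalid.
#'
#' @param truth a truth [cop_series()].
#' @param model a [platform_model()].
#' @param lag inter-instrument clock offset (s); positive means platform
#'   events appear `lag` seconds later than in the sock recording.
#' @param seed optional RNG seed.
#' @return A [cop_series()] with `source = "platform"`.
#' @export
simulate_platform <- function(truth, model = platform_model(), lag = 0,
                              seed = NULL) {
  if (!inherits(truth, "cop_series") || truth$source != "truth") {
    stop("`truth` must be a truth cop_series", call. = FALSE)
  }
  if (!inherits(model, "platform_model")) {
    stop("`model` must be a platform_model", call. = FALSE)
  }
  stop_if_not_scalar_number(lag, "lag")
  load <- attr(truth, "load")
  if (is.null(load)) load <- rep(50, length(truth$time))
  tt <- truth$time
  dt <- 1 / model$rate
  t <- tt[1] + dt * seq.int(0L, floor((tt[length(tt)] - tt[1]) / dt))
  src <- t - lag
  inside <- src >= tt[1] & src <= tt[length(tt)]
  x <- y <- w <- rep(NA_real_, length(t))
  x[inside] <- stats::approx(tt, truth$x, src[inside], ties = "ordered")$y
  y[inside] <- stats::approx(tt, truth$y, src[inside], ties = "ordered")$y
  w[inside] <- stats::approx(tt, load, src[inside], ties = "ordered")$y
  valid <- inside & !is.na(w) & w > 0

  with_seed(seed, {
    x <- x + model$offset[1]
    y <- y + model$offset[2]
    if (model$noise_sd > 0) {
      x <- x + stats::rnorm(length(t), sd = model$noise_sd)
      y <- y + stats::rnorm(length(t), sd = model$noise_sd)
    }
    if (!is.null(model$sidestep)) {
      on <- t >= model$sidestep$time
      x[on] <- x[on] + model$sidestep$offset[1]
      y[on] <- y[on] + model$sidestep$offset[2]
    }
    x[!valid] <- NA_real_
    y[!valid] <- NA_real_
    cop_series(t, x, y, valid = valid, source = "platform",
               exercise = truth$exercise, foot = truth$foot)
  })
}

#' Study design for the simulator
#'
#' The default mirrors the validation protocol: 10 participants, four
#' foot-conditions (single-leg squat right and left; both-leg squat with
#' heel raise, right and left foot instrumented), two sock applications
#' (don/doff cycles) each, and both CoP axes analysed -- 160 waveform pairs
#' per modality.
#'
#' @param participants number of participants (default 10).
#' @param applications sock applications per condition (default 2).
#' @param conditions data frame with columns `exercise` and `foot`;
#'   defaults to the four conditions above.
#' @param lag_range inter-instrument clock offset range (s), drawn
#'   uniformly per trial (default `c(-0.5, 0.5)`).
#' @param offset_range platform foot-placement offset range per axis (mm),
#'   drawn uniformly per trial (default `c(-30, 30)`).
#' @param foot_scale_range per-participant anthropometric scale factor on
#'   the sensor geometry (foot-morphology variation; default
#'   `c(0.9, 1.1)`).
#' @return An object of class `study_design`.
#' @export
study_design <- function(participants = 10, applications = 2,
                         conditions = NULL, lag_range = c(-0.5, 0.5),
                         offset_range = c(-30, 30),
                         foot_scale_range = c(0.9, 1.1)) {
  stop_if_not_scalar_number(participants, "participants", positive = TRUE)
  stop_if_not_scalar_number(applications, "applications", positive = TRUE)
  if (is.null(conditions)) {
    conditions <- data.frame(
      exercise = rep(c("single_leg_squat", "both_leg_squat_heel_raise"),
                     each = 2),
      foot = c("right", "left", "right", "left"),
      stringsAsFactors = FALSE
    )
  }
  if (!is.data.frame(conditions) || nrow(conditions) == 0L ||
      !all(c("exercise", "foot") %in% names(conditions))) {
    stop("`conditions` must be a nonempty data frame with `exercise`, `foot`",
         call. = FALSE)
  }
  structure(
    list(participants = as.integer(participants),
         applications = as.integer(applications),
         conditions = conditions, lag_range = lag_range,
         offset_range = offset_range, foot_scale_range = foot_scale_range),
    class = "study_design"
  )
}

#' Generate a complete simulated validation study
#'
#' Simulates every trial of a [study_design()]: per participant an
#' anthropometric scale factor perturbs the true sensor geometry; per trial
#' a fresh sock application (sensitivities, placement jitter), a platform
#' foot-placement offset and an inter-instrument lag are drawn. Each trial
#' stores the sock conductance recording, the platform CoP recording, the
#' ground truth and all drawn parameters, and the manifest enumerates one
#' row per waveform pair (trial x axis).
#'
#' @param design a [study_design()].
#' @param seed master seed; every trial's seed derives from it, so the same
#'   seed reproduces the identical dataset.
#' @param sensor_model a [sensor_model()] applied to all trials.
#' @param platform_model a [platform_model()]; its `offset` is overridden
#'   by the per-trial draw unless `offset_range` collapses to zero width.
#' @param sock_rate sock sampling rate (Hz, default 125).
#' @return An object of class `cop_study`: `trials` (list) and `manifest`
#'   (data frame, one row per waveform pair).
#' @export
generate_study <- function(design = study_design(), seed = 1,
                           sensor_model = copagree::sensor_model(),
                           platform_model = copagree::platform_model(),
                           sock_rate = 125) {
  if (!inherits(design, "study_design")) {
    stop("`design` must be a study_design", call. = FALSE)
  }
  n_cond <- nrow(design$conditions)
  n_trials <- design$participants * n_cond * design$applications
  if (n_trials == 0L) stop("empty study design", call. = FALSE)
  seeds <- child_seeds(seed, n_trials + design$participants)
  foot_scales <- with_seed(seeds[n_trials + seq_len(design$participants)][1], {
    stats::runif(design$participants, design$foot_scale_range[1],
                 design$foot_scale_range[2])
  })

  trials <- vector("list", n_trials)
  manifest <- vector("list", n_trials)
  k <- 0L
  for (pid in seq_len(design$participants)) {
    geom_participant <- sensor_geometry(
      sensor_geometry()$positions * foot_scales[pid])
    for (ci in seq_len(n_cond)) {
      for (app in seq_len(design$applications)) {
        k <- k + 1L
        tseed <- seeds[k]
        draws <- with_seed(tseed, {
          list(lag = stats::runif(1, design$lag_range[1], design$lag_range[2]),
               offset = stats::runif(2, design$offset_range[1],
                                     design$offset_range[2]),
               sub = sample.int(.Machine$integer.max - 1L, 3L))
        })
        spec <- trial_spec(exercise = design$conditions$exercise[ci],
                           foot = design$conditions$foot[ci])
        truth <- simulate_true_cop(spec, seed = draws$sub[1])
        sock <- simulate_sock(truth, model = sensor_model,
                              geometry = geom_participant, rate = sock_rate,
                              seed = draws$sub[2])
        pm <- platform_model
        pm$offset <- draws$offset
        platform <- simulate_platform(truth, model = pm, lag = draws$lag,
                                      seed = draws$sub[3])
        pid_lab <- sprintf("P%02d", pid)
        sock$participant <- pid_lab; sock$repetition <- app
        platform$participant <- pid_lab; platform$repetition <- app
        truth$participant <- pid_lab
        trials[[k]] <- list(
          participant = pid_lab, exercise = spec$exercise, foot = spec$foot,
          application = app, sock = sock, platform = platform, truth = truth,
          params = list(lag = draws$lag, offset = draws$offset,
                        foot_scale = foot_scales[pid], seed = tseed))
        manifest[[k]] <- data.frame(
          trial = k, participant = pid_lab, exercise = spec$exercise,
          foot = spec$foot, application = app,
          axis = c("x", "y"),
          n_sock = length(sock$time), n_platform = length(platform$time),
          true_lag_s = draws$lag, seed = tseed,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(trials = trials, manifest = do.call(rbind, manifest),
         design = design, seed = seed),
    class = "cop_study"
  )
}

#' @export
print.cop_study <- function(x, ...) {
  cat(sprintf("Simulated validation study: %d trials, %d waveform pairs per modality (seed %s)\n",
              length(x$trials), nrow(x$manifest), format(x$seed)))
  cat(sprintf("  %d participants x %d conditions x %d applications x 2 axes\n",
              x$design$participants, nrow(x$design$conditions),
              x$design$applications))
  invisible(x)
}
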