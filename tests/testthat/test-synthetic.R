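test_that("trial specs encode the exercise protocol", {
  single <- trial_spec()
  expect_equal(single$exercise_duration, 10)   # 10 reps at 60 bpm
  both <- trial_spec("both_leg_squat_heel_raise")
  expect_equal(both$exercise_duration, 30)
  faster <- trial_spec(repetitions = 10, tempo = 120)
  expect_equal(faster$exercise_duration, 5)
  expect_error(trial_spec(tempo = 0), "positive")
})

test_that("the truth generator respects amplitudes, tempo and determinism", {
  spec <- trial_spec()
  # all amplitude components zero: flat trajectory at the origin
  flat <- simulate_true_cop(spec, amplitudes = list(y_amp = 0, y_offset = 0,
                                                    x_amp = 0, noise_sd = 0),
                            seed = 1)
  expect_true(all(flat$x == 0) && all(flat$y == 0))

  truth <- simulate_true_cop(spec, seed = 4)
  # duration: 3 s marker lead-in + 10 s exercise at 125 Hz
  expect_equal(max(truth$time), 13, tolerance = 1 / 125)
  expect_equal(length(truth$time), 1626)
  # unloaded during the marker window only
  load <- attr(truth, "load")
  expect_true(all(load[truth$time < 3] == 0))
  expect_true(all(load[truth$time >= 3] > 0))
  # single-leg mediolateral excursion stays within about +/-20 mm
  expect_true(all(abs(truth$x) <= 20))

  # dominant anteroposterior frequency is the squat tempo (1 Hz at 60 bpm)
  ex <- truth$y[truth$time >= 3]
  sp <- spec.pgram(ex, plot = FALSE, taper = 0)
  f_peak <- sp$freq[which.max(sp$spec)] * 125
  expect_equal(f_peak, 1, tolerance = 0.15)

  # both-leg squats span roughly -50..+60 mm anteroposteriorly
  bt <- simulate_true_cop(trial_spec("both_leg_squat_heel_raise"), seed = 4)
  expect_gt(max(bt$y), 40)
  expect_lt(min(bt$y), -35)
  expect_true(all(bt$y >= -60 & bt$y <= 70))

  # determinism contract
  expect_identical(simulate_true_cop(spec, seed = 10),
                   simulate_true_cop(spec, seed = 10))
  expect_false(identical(simulate_true_cop(spec, seed = 10)$x,
                         simulate_true_cop(spec, seed = 11)$x))
  expect_error(simulate_true_cop(spec, amplitudes = list(bogus = 1)),
               "unknown amplitude")
})

test_that("barycentric load distribution inverts the CoP summation exactly", {
  g <- sensor_geometry()
  # centre
  p0 <- distribute_load(c(0, 0), 1, g)
  expect_true(all(p0 >= 0))
  expect_equal(sum(p0), 1, tolerance = 1e-12)
  expect_equal(unname(compute_cop(p0, g)[1:2]), c(0, 0), tolerance = 1e-9)
  # generic interior point
  p1 <- distribute_load(c(10, 20), 1, g)
  expect_true(all(p1 >= 0))
  expect_equal(sum(p1), 1, tolerance = 1e-12)
  expect_equal(unname(compute_cop(p1, g)[1:2]), c(10, 20), tolerance = 1e-9)
  # a hull vertex puts everything on that sensor
  pv <- distribute_load(c(50, 100), 2.5, g)
  expect_equal(pv, c(2.5, 0, 0, 0, 0, 0), tolerance = 1e-9)
  expect_error(distribute_load(c(500, 0), 1, g), "outside the sensor hull")
  # property: random interior points round-trip through the CoP summation
  set.seed(31)
  for (i in 1:50) {
    w <- runif(6); w <- w / sum(w)
    target <- as.numeric(w %*% g$positions)   # convex combination -> inside
    pr <- distribute_load(target, 10, g)
    expect_true(all(pr >= 0))
    expect_equal(unname(compute_cop(pr, g)[1:2]), target, tolerance = 1e-9)
  }
})

test_that("the noiseless sensor forward model round-trips the truth exactly", {
  truth <- simulate_true_cop(trial_spec(), seed = 2)
  sock <- simulate_sock(truth, model = ideal_sensor_model(), seed = 3)
  expect_true(all(sock$values >= 0))
  rec <- sock_cop(sock)
  ok <- rec$valid
  expect_gt(sum(ok), 1000)
  expect_lt(max(abs(rec$x[ok] - truth$x[ok])), 1e-9)
  expect_lt(max(abs(rec$y[ok] - truth$y[ok])), 1e-9)
  # the unloaded marker window reconstructs as flagged-invalid samples
  expect_true(all(!rec$valid[truth$time < 3 - 1e-9]))
})

test_that("unequal sensitivities bias the reconstruction but preserve waveform tracking", {
  truth <- simulate_true_cop(trial_spec(), seed = 12)
  sock <- simulate_sock(truth, model = sensor_model(), seed = 13)
  rec <- sock_cop(sock)
  ok <- rec$valid & truth$time >= 3
  cc <- lin_ccc(rec$y[ok] - mean(rec$y[ok]), truth$y[ok] - mean(truth$y[ok]))
  expect_gte(cc$ccc, 0.8)
})

test_that("a low saturation ceiling compresses the reconstructed excursion range", {
  truth <- simulate_true_cop(trial_spec(), seed = 14)
  free <- sock_cop(simulate_sock(truth, model = sensor_model(noise_sd = 0, jitter_sd = 0),
                                 seed = 15))
  sat <- sock_cop(simulate_sock(truth, model = sensor_model(noise_sd = 0, jitter_sd = 0,
                                                            saturation = 30),
                                seed = 15))
  ok <- free$valid & sat$valid
  range_ratio <- diff(range(sat$x[ok])) / diff(range(free$x[ok]))
  expect_lt(range_ratio, 1)
})

test_that("the platform model shifts, delays and flags the truth as configured", {
  truth <- simulate_true_cop(trial_spec(), seed = 20)
  # no offset, noise or lag: platform equals truth at platform sample times
  clean <- simulate_platform(truth, platform_model(noise_sd = 0), lag = 0)
  ok <- clean$valid
  expect_equal(clean$x[ok], truth$x[match(round(clean$time[ok], 9),
                                          round(truth$time, 9))][seq_len(sum(ok))],
               tolerance = 1e-9)
  # the unloaded marker window is flagged invalid (foot off the plate)
  expect_true(all(!clean$valid[clean$time < 3 - 1e-9]))

  # a placement offset moves the mean by that offset
  off <- simulate_platform(truth, platform_model(offset = c(30, -15), noise_sd = 0.3),
                           lag = 0, seed = 21)
  vo <- off$valid & truth$valid & attr(truth, "load") > 0
  expect_equal(mean(off$x[off$valid]) - mean(truth$x[attr(truth, "load") > 0]),
               30, tolerance = 1)
  expect_equal(mean(off$y[off$valid]) - mean(truth$y[attr(truth, "load") > 0]),
               -15, tolerance = 1)

  # a positive lag delays platform content relative to the truth clock
  lagged <- simulate_platform(truth, platform_model(noise_sd = 0), lag = 0.2)
  i <- which(lagged$valid)[100]
  j <- which.min(abs(truth$time - (lagged$time[i] - 0.2)))
  expect_equal(lagged$x[i], truth$x[j], tolerance = 1e-6)
})

test_that("study generation enumerates the design and is seed-deterministic", {
  d <- study_design(participants = 1, applications = 1,
                    conditions = data.frame(exercise = "single_leg_squat",
                                            foot = "right"))
  s1 <- generate_study(d, seed = 5)
  expect_equal(nrow(s1$manifest), 2L)          # one trial, X and Y pairs
  expect_identical(sort(unique(s1$manifest$axis)), c("x", "y"))
  s2 <- generate_study(d, seed = 5)
  expect_identical(s1, s2)
  s3 <- generate_study(d, seed = 6)
  expect_false(identical(s1$trials[[1]]$sock$values,
                         s3$trials[[1]]$sock$values))
  expect_error(study_design(participants = 0), "positive")
})

test_that("written studies are byte-identical under the same seed", {
  d <- study_design(participants = 1, applications = 1,
                    conditions = data.frame(exercise = "single_leg_squat",
                                            foot = "left"))
  s <- generate_study(d, seed = 9)
  d1 <- file.path(tempdir(), "study_a"); d2 <- file.path(tempdir(), "study_b")
  write_study(s, d1)
  write_study(generate_study(d, seed = 9), d2)
  files <- list.files(d1)
  expect_true(length(files) >= 4)
  for (f in files) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("increasing sensor noise monotonically degrades median concordance with truth", {
  noise_levels <- c(1, 5, 20)
  medians <- sapply(noise_levels, function(nsd) {
    ccs <- sapply(1:20, function(r) {
      truth <- simulate_true_cop(trial_spec(repetitions = 5), seed = 100 + r)
      sock <- simulate_sock(truth, model = sensor_model(noise_sd = nsd),
                            seed = 200 + r)
      rec <- sock_cop(sock)
      ok <- rec$valid & attr(truth, "load") > 0
      lin_ccc(rec$y[ok] - mean(rec$y[ok]),
              truth$y[ok] - mean(truth$y[ok]))$ccc
    })
    median(ccs)
  })
  expect_true(all(diff(medians) < 0))
})
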