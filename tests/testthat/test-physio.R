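test_that("cardiac extraction recovers the source from noisy multichannel PT", {
  fx <- pt_sim()
  card <- extract_cardiac_signal(fx$pt)
  expect_gt(abs(cor(as.numeric(card), fx$pt$cardiac_source)), 0.9)
  # invariant (up to sign/scale) to channel permutation
  perm <- fx$pt
  perm$data <- perm$data[c(5:12, 1:4), ]
  card2 <- extract_cardiac_signal(perm)
  expect_gt(abs(cor(as.numeric(card), as.numeric(card2))), 0.99)
  # pure noise refuses to produce a cardiac component
  noise <- list(data = matrix(rnorm(12 * 3000), 12), fs = 50)
  expect_error(extract_cardiac_signal(noise), "cardiac")
  # record length guard
  expect_error(extract_cardiac_signal(list(data = fx$pt$data[, 1:100],
                                           fs = 50)), "10 s")
})

test_that("trigger detection finds local minima on the shared clock", {
  # -cos toy signal: minima at integer seconds
  t <- seq(0, 5, by = 0.01)
  trig <- detect_triggers(-cos(2 * pi * t), fs = 100)
  expect_equal(trig, 1:4, tolerance = 1e-3)
  # constant signal: empty with a warning
  expect_warning(out <- detect_triggers(rep(1, 500), fs = 100), "constant")
  expect_length(out, 0)
  # simulated PT at 1.2 Hz over 60 s: 72 +/- 2 triggers, median error < 50 ms
  fx <- pt_sim()
  card <- extract_cardiac_signal(fx$pt)
  tt <- detect_triggers(card)
  expect_true(abs(length(tt) - 72) <= 2)
  truth <- true_triggers(fx$phantom, c(0, 60))
  err <- vapply(tt, function(x) min(abs(x - truth)), numeric(1))
  expect_lt(median(err) * 1000, 50)
})

test_that("respiratory curve extraction is accurate, detrended and bounded", {
  fx <- pt_sim()
  r <- extract_respiratory_curve(fx$pt)
  expect_gt(abs(cor(as.numeric(r), fx$pt$resp_source)), 0.95)
  expect_equal(max(abs(r)), 1)
  # residual drift below 0.01 per minute
  tt <- attr(r, "t")
  slope <- coef(lm(as.numeric(r) ~ tt))[2]
  expect_lt(abs(slope) * 60, 0.01)
  # an injected inter-sequence step is removed by the per-sequence detrend
  ph <- fx$phantom
  no_step <- simulate_pt(ph, 60, noise_sd = 0.1, drift_per_min = 0.5,
                         gap_time = 25, step_scale = 0)
  with_step <- no_step
  with_step$data <- with_step$data + 5 * outer(rep(1, 12),
                                               as.numeric(no_step$t > 25))
  r0 <- extract_respiratory_curve(no_step)
  r5 <- extract_respiratory_curve(with_step)
  expect_lt(max(abs(as.numeric(r5) - as.numeric(r0))), 0.05 * max(abs(r0)))
})

test_that("cardiac phase assignment bins linearly between triggers", {
  expect_equal(assign_cardiac_phase(0.07, c(0, 1), 20), 1L)  # floor(1.4)
  expect_equal(assign_cardiac_phase(0, c(0, 1), 20), 0L)
  expect_equal(assign_cardiac_phase(0.999, c(0, 1), 20), 19L)
  # out-of-range timestamps are flagged, not errors
  ph <- assign_cardiac_phase(c(-0.5, 0.5, 1.5), c(0, 1), 4)
  expect_equal(is.na(ph), c(TRUE, FALSE, TRUE))
  # uniform timestamps give a uniform phase histogram (3 sigma multinomial)
  set.seed(42)
  t <- runif(6000)
  h <- table(factor(assign_cardiac_phase(t, c(0, 1), 10), levels = 0:9))
  expect_true(all(abs(h - 600) < 3 * sqrt(6000 * 0.1 * 0.9)))
  expect_error(assign_cardiac_phase(0.5, 1, 10), "2 triggers")
})

test_that("one shared trigger set bins both sequences completely", {
  fx <- pt_sim()
  card <- extract_cardiac_signal(fx$pt)
  trig <- detect_triggers(card)
  s1 <- build_schedule(sequence_config("FISS", mode = "2d", n_interleaves = 100,
                                       fov_mm = 128, resolution_mm = 2,
                                       oversampling = 1), 0)
  s2 <- build_schedule(sequence_config("PC", mode = "2d", n_interleaves = 100,
                                       fov_mm = 128, resolution_mm = 2,
                                       oversampling = 1),
                       schedule_end(s1) + 1.5)
  b1 <- assign_cardiac_phase(s1$t, trig, 20)
  b2 <- assign_cardiac_phase(s2$t, trig, 20)
  expect_setequal(unique(na.omit(b1)), 0:19)
  expect_setequal(unique(na.omit(b2)), 0:19)
  # every non-discarded readout maps to exactly one phase
  expect_equal(sum(table(b1)) + sum(table(b2)),
               length(b1) + length(b2) - sum(is.na(b1)) - sum(is.na(b2)))
})
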