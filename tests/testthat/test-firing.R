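test_that("spike detection on synthetic traces", {
  # flat trace: nothing to find
  t <- seq(0, 100, by = 0.01)
  flat <- as_hr_trajectory(t, cbind(rep(-1, length(t)), 0, 0))
  expect_length(detect_spikes(flat)$times, 0)
  # Gaussian bumps at known times are recovered to within the sample step
  centers <- c(10, 13, 16, 40, 43, 46, 70, 73, 76)
  traj <- bump_trajectory(centers)
  train <- detect_spikes(traj)
  expect_length(train$times, length(centers))
  expect_lt(max(abs(train$times - centers)), 0.011)
  expect_equal(train$peaks, rep(2, 9), tolerance = 1e-4)
  # downward troughs on a flat baseline yield no false positives
  trough <- bump_trajectory(centers, amp = -2)
  expect_length(detect_spikes(trough)$times, 0)
  # closer than min_separation: the higher peak wins
  tt <- seq(0, 20, by = 0.01)
  x <- 2 * exp(-(tt - 10)^2 / 0.02) + 1.5 * exp(-(tt - 10.3)^2 / 0.02)
  two <- as_hr_trajectory(tt, cbind(x, 0, 0))
  got <- detect_spikes(two, height_min = 0.5)
  expect_length(got$times, 1)
  expect_equal(got$times, 10, tolerance = 1e-2)
})

test_that("burst segmentation separates bursting from tonic trains", {
  # three spikes then a long gap, repeated
  centers <- as.vector(outer(c(0, 1, 2), seq(10, 90, by = 20), "+"))
  train <- detect_spikes(bump_trajectory(sort(centers), width = 0.1))
  b <- segment_bursts(train)
  expect_true(b$is_bursting)
  expect_true(all(b$spikes_per_burst == 3))
  # uniform ISIs are one tonic segment
  tonic <- detect_spikes(bump_trajectory(seq(5, 95, by = 3), width = 0.1))
  bt <- segment_bursts(tonic)
  expect_false(bt$is_bursting)
  expect_length(bt$bursts, 1)
  # too few spikes is an indeterminate signal
  few <- detect_spikes(bump_trajectory(c(10, 20), width = 0.1))
  expect_true(segment_bursts(few)$indeterminate)
})

test_that("firing-pattern labels combine spikes, bursts, and LE1", {
  t <- seq(0, 500, by = 0.01)
  flat <- as_hr_trajectory(t, cbind(rep(-1.6, length(t)), 0, 0))
  q <- classify_firing(flat, le1 = -0.05)
  expect_identical(q$label, "quiescent")
  expect_false(q$subthreshold)
  # small subthreshold oscillation stays quiescent but is flagged
  sub <- as_hr_trajectory(t, cbind(-1.6 + 0.1 * sin(t), 0, 0))
  qs <- classify_firing(sub, le1 = -0.05)
  expect_identical(qs$label, "quiescent")
  expect_true(qs$subthreshold)
  # alternating-amplitude tonic train: period-2 when regular
  centers <- seq(10, 480, by = 5)
  amps <- rep(c(2, 2.6), length.out = length(centers))
  x <- rep(0, length(t))
  for (i in seq_along(centers))
    x <- x + amps[i] * exp(-(t - centers[i])^2 / (2 * 0.04))
  osc <- as_hr_trajectory(t, cbind(x, 0, 0))
  p2 <- classify_firing(osc, le1 = -0.1)
  expect_identical(p2$label, "periodic spiking")
  expect_identical(p2$period_count, 2L)
  # same train with positive LE1 reads as chaotic spiking
  ch <- classify_firing(osc, le1 = 0.1)
  expect_identical(ch$label, "chaotic spiking")
  expect_true(is.na(ch$period_count))
  # bursting fixture labels carry spikes per burst
  bc <- sort(as.vector(outer(c(0, 1, 2), seq(20, 480, by = 25), "+")))
  xb <- rep(0, length(t))
  for (ct in bc) xb <- xb + 2 * exp(-(t - ct)^2 / (2 * 0.04))
  btraj <- as_hr_trajectory(t, cbind(xb, 0, 0))
  pb <- classify_firing(btraj, le1 = -0.1)
  expect_identical(pb$label, "periodic bursting")
  expect_identical(pb$spikes_per_burst, 3L)
  # indeterminate chaos band propagates
  ind <- classify_firing(osc, le1 = 0.001)
  expect_identical(ind$label, "indeterminate")
})

test_that("the periodic-spiking scenario has near-constant ISIs", {
  traj <- hr_integrate(hr_params(k = 1), hr_drive(A1 = 5.5, f1 = 0.5),
                       c(-5, 0, 0), t_span = c(0, 500))
  train <- detect_spikes(discard_transient(traj, 250))
  expect_gt(length(train$times), 50)
  # the orbit is period-2 (ISIs alternate 1.94 / 2.06), so the CV is
  # small but not zero
  expect_lt(sd(train$isi) / mean(train$isi), 0.05)
  # classification is stable under coarser sampling
  traj2 <- hr_integrate(hr_params(k = 1), hr_drive(A1 = 5.5, f1 = 0.5),
                        c(-5, 0, 0), t_span = c(0, 500), sample_dt = 0.02)
  le <- max_lyapunov(hr_params(k = 1), hr_drive(A1 = 5.5, f1 = 0.5),
                     c(-5, 0, 0), t_transient = 250, t_horizon = 500)
  l1 <- classify_firing(discard_transient(traj, 250), le1 = le)
  l2 <- classify_firing(discard_transient(traj2, 250), le1 = le)
  expect_identical(l1$label, l2$label)
  expect_identical(l1$label, "periodic spiking")
})
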