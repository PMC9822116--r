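test_that("burst detection recovers constructed pulses and rejects constant traces", {
  fx <- generate_fixture("pulse-trace")
  ev <- detect_bursts(fx$data$activity, dt = fx$dt)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$onset, fx$annotation$onset, tolerance = 1.5 * fx$dt)
  expect_equal(ev$offset, fx$annotation$offset, tolerance = 1.5 * fx$dt)
  # constant trace -> no events
  expect_equal(nrow(detect_bursts(rep(3, 1000), dt = 1e-3)), 0)
  # short chatter below the minimum duration is discarded
  v <- rep(1, 2000); v[1000:1004] <- 50
  expect_equal(nrow(detect_bursts(v, dt = 1e-3, min_duration = 0.01)), 0)
  # sub-threshold gaps below merge_gap are bridged
  v2 <- rep(1, 4000); v2[1001:1100] <- 10; v2[1106:1200] <- 10
  ev2 <- detect_bursts(v2, dt = 1e-3)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$duration, 0.2, tolerance = 0.01)
})

test_that("IBI multiset is invariant under time reversal", {
  fx <- generate_fixture("pulse-trace", params = list(
    pulses = data.frame(onset = c(1, 3.5, 7), offset = c(1.4, 4.6, 7.2))))
  ev <- detect_bursts(fx$data$activity, dt = fx$dt)
  evr <- detect_bursts(rev(fx$data$activity), dt = fx$dt)
  ibi <- ev$onset[-1] - ev$offset[-nrow(ev)]
  ibir <- evr$onset[-1] - evr$offset[-nrow(evr)]
  expect_equal(sort(ibi), sort(ibir), tolerance = 1e-9)
})

test_that("IBI cumulant statistics match hand-computed and asymptotic values", {
  expect_error(ibi_statistics(detect_bursts(rep(1, 10), dt = 1)), "2 events")
  s <- ibi_statistics(c(2, 2, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$cv, 0)
  s2 <- ibi_statistics(c(1, 2, 3))
  expect_equal(s2$mean, 2)
  expect_equal(unname(s2$cumulants["k2"]), 2 / 3)
  expect_equal(s2$cv, sqrt(2 / 3) / 2)
  # large exponential sample: CV -> 1, skewness -> 2, kurtosis -> 6,
  # rescaled skewness -> 2/3, rescaled kurtosis -> 6/15
  set.seed(1)
  e <- ibi_statistics(rexp(1e5))
  expect_equal(e$cv, 1, tolerance = 0.02)
  expect_equal(e$skewness, 2, tolerance = 0.1)
  expect_equal(e$kurtosis, 6, tolerance = 0.4)
  expect_equal(e$resc_skewness, e$skewness / (3 * e$cv))
  expect_equal(e$resc_kurtosis, e$kurtosis / (15 * e$cv^2))
})

test_that("serial correlations recover alternating and independent sequences", {
  v <- rep(c(1, -1), 50)
  sc <- serial_correlation(v, 1:2)
  expect_equal(unname(sc), c(-1, 1), tolerance = 1e-12)
  set.seed(2)
  r <- serial_correlation(sample(c(-1, 1), 1e4, replace = TRUE), 1:5)
  expect_true(all(abs(r) < 3 * 2 / sqrt(1e4)))
  expect_true(all(is.na(serial_correlation(rep(1, 50), 1:3))))
})

test_that("PVA decoding is exact on constructed rasters", {
  M <- 40
  th <- 2 * pi * seq_len(M) / M
  # all activity on one unit -> its angle
  A <- matrix(0, 5, M); A[, 7] <- 3
  d <- decode_trajectory(A, th, dt = 0.05, window = 0.05)
  expect_equal(d$positions, rep(mesoreplay:::wrap_angle(th[7]), 5),
               tolerance = 1e-10)
  # equal activity on two adjacent units -> midpoint angle
  A2 <- matrix(0, 4, M); A2[, 10] <- 1; A2[, 11] <- 1
  d2 <- decode_trajectory(A2, th, dt = 0.05, window = 0.05)
  expect_equal(d2$positions,
               rep(mesoreplay:::wrap_angle((th[10] + th[11]) / 2), 4),
               tolerance = 1e-10)
  # linearly drifting bump: all step sizes equal the drift, and the
  # straight-line fit recovers it
  fx <- generate_fixture("drifting-bump",
                         params = list(M = M, frames = 12, drift = 0.3))
  d3 <- decode_trajectory(fx$data, fx$angles, dt = 1, window = 1)
  expect_equal(d3$step_sizes, rep(0.3, 11), tolerance = 1e-9)
  expect_equal(d3$avg_step, 0.3, tolerance = 1e-9)
  # near-uniform activity is flagged undecodable
  A4 <- matrix(1, 4, M)
  d4 <- decode_trajectory(A4, th, dt = 0.05, window = 0.05)
  expect_true(all(d4$undecodable))
})

test_that("event kinematics are exact on a stepping bump and obey symmetries", {
  M <- 100
  kf <- 15
  fx <- generate_fixture("drifting-bump",
                         params = list(M = M, frames = kf, drift = 2 * pi / M))
  # embed the bump in a longer quiet trace so detection finds one event
  A <- matrix(1e-3, 60, M)
  A[21:(20 + kf), ] <- fx$data
  ev <- detect_bursts(A, dt = 1e-3, min_duration = 0)
  expect_equal(nrow(ev), 1)
  ce <- classify_events(ev, A, angles = fx$angles, dt = 1e-3, smooth = 1e-3)
  expect_equal(ce$distance, (kf - 1) * 2 * pi / M, tolerance = 1e-9)
  expect_equal(ce$direction, 1L)  # positive drift = clockwise = backward
  # global rotation leaves the distance unchanged
  ce_rot <- classify_events(ev, A, angles = fx$angles + 1.1, dt = 1e-3,
                            smooth = 1e-3)
  expect_equal(ce_rot$distance, ce$distance, tolerance = 1e-9)
  # reflecting the ring flips the signed speed
  ce_ref <- classify_events(ev, A, angles = -fx$angles, dt = 1e-3,
                            smooth = 1e-3)
  expect_equal(ce_ref$signed_speed, -ce$signed_speed, tolerance = 1e-9)
  expect_equal(abs(ce$signed_speed) * ce$duration, ce$distance,
               tolerance = 1e-9)
})

test_that("peak counting flags single- and multi-peak events correctly", {
  # symmetric triangular burst -> one peak, not an NLE
  tri <- c(rep(0.1, 50), 0.1 + 0.2 * (1:30), 0.1 + 0.2 * (29:0), rep(0.1, 50))
  ev <- detect_bursts(tri, dt = 1e-3, min_duration = 0)
  ce <- classify_events(ev, matrix(tri, ncol = 1), angles = 0, dt = 1e-3,
                        smooth = 2e-3)
  expect_equal(ce$n_peaks, 1L)
  expect_false(ce$is_NLE)
  # two well-separated humps within one supra-threshold epoch
  hump <- function(n, amp) amp * sin(seq(0, pi, length.out = n))
  v <- c(rep(0.0, 30), 1 + hump(60, 5), rep(1.05, 30), 1 + hump(60, 4),
         rep(0.0, 30))
  ev2 <- detect_bursts(v, dt = 1e-3, min_duration = 0, merge_gap = 0.2)
  expect_equal(nrow(ev2), 1)
  ce2 <- classify_events(ev2, matrix(v, ncol = 1), angles = 0, dt = 1e-3,
                         smooth = 2e-3)
  expect_equal(ce2$n_peaks, 2L)
  expect_true(ce2$is_NLE)
})

test_that("environment sequence statistics match brute-force enumeration", {
  lab <- rep(1:3, 10)
  st <- env_sequence_stats(lab, K = 3)
  expect_equal(st$n, 30)
  expect_equal(unname(st$subsequences["1>2>3"]), 10 / 28)
  expect_equal(unname(st$subsequences["2>3>1"]), 9 / 28)
  expect_equal(unname(st$subsequences["3>1>2"]), 9 / 28)
  expect_equal(sum(st$subsequences), 1)  # every window has distinct labels
  expect_equal(unname(st$transition_matrix[1, 2]), 1)
  # i.i.d. uniform labels: transitions near 1/3, subsequence sum equals the
  # fraction of windows with three distinct labels
  set.seed(3)
  lab2 <- sample.int(3, 1e4, replace = TRUE)
  st2 <- env_sequence_stats(lab2, K = 3)
  expect_true(all(abs(st2$transition_matrix - 1 / 3) < 0.03))
  distinct <- mean(lab2[1:9998] != lab2[2:9999] & lab2[2:9999] != lab2[3:10000] &
                     lab2[1:9998] != lab2[3:10000])
  expect_equal(sum(st2$subsequences), distinct, tolerance = 1e-12)
  expect_error(env_sequence_stats(1:2, K = 3), "3 labeled")
})

test_that("Welch spectrum satisfies Parseval and localizes a sinusoid", {
  dt <- 1e-3
  t <- seq(dt, 60, by = dt)
  x <- 2 * sin(2 * pi * 8 * t)
  ps <- power_spectrum(x, dt, segment_length = 2^13)
  df <- ps$freq[2] - ps$freq[1]
  expect_equal(ps$freq[which.max(ps$power)], 8, tolerance = df * 1.5)
  expect_equal(sum(ps$power) * df, 2^2 / 2, tolerance = 0.05)
  # white noise: flat density at sigma^2 * dt across bands
  set.seed(4)
  w <- rnorm(length(t), sd = 1.5)
  pw <- power_spectrum(w, dt, segment_length = 2^10)
  lo <- mean(pw$power[pw$freq > 10 & pw$freq < 150])
  hi <- mean(pw$power[pw$freq > 300 & pw$freq < 480])
  expect_equal(lo / hi, 1, tolerance = 0.1)
  expect_equal(sum(pw$power) * (pw$freq[2] - pw$freq[1]), var(w),
               tolerance = 0.05)
  expect_error(power_spectrum(rnorm(100), dt, segment_length = 1000),
               "segment longer")
})

test_that("Up/Down segmentation recovers a square-wave alternation", {
  dt <- 1e-3
  cyc <- c(rep(0.5, 2000), rep(5.5, 3000))  # 2 s down, 3 s up
  h <- rep(cyc, 8)
  ud <- updown_segmentation(h, dt = dt)
  expect_gt(ud$threshold, 0.5)
  expect_lt(ud$threshold, 5.5)
  expect_equal(ud$mean_up_duration, 3, tolerance = 0.01)
  expect_equal(ud$n_up_long, 8)
  # unimodal trace is refused
  set.seed(5)
  expect_error(updown_segmentation(rnorm(5000, 3, 0.2), dt = dt), "unimodal")
  # explicit threshold bypasses the histogram criterion
  ud2 <- updown_segmentation(h, dt = dt, threshold = 3)
  expect_equal(ud2$mean_up_duration, 3, tolerance = 0.01)
})

test_that("spike-to-Up attribution counts bursts leading into long Up states", {
  dt <- 1e-3
  # two bursts; only the first one is followed by a long Up interval
  h <- rep(0.5, 20000)
  h[5001:12000] <- 5.5        # 7 s Up state starting at t = 5
  act <- rep(0.1, 20000)
  act[4951:5050] <- 10        # burst just before the Up onset
  act[15001:15100] <- 10      # isolated burst in the Down state
  ev <- detect_bursts(act, dt = dt)
  expect_equal(nrow(ev), 2)
  ud <- updown_segmentation(h, dt = dt, events = ev)
  expect_equal(ud$fraction_spike_to_up, 0.5)
})
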