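test_that("decoupled system has the closed-form fixed point and eigenvalues", {
  p <- meso_params(tau = 0.05, mu = 3,
                   transfer = transfer_params(3.15, 0.25, 2),
                   synapse = synapse_params(0.8, 0.4), J_tau = 0, N = 50)
  fp <- find_fixed_points(p)
  expect_equal(nrow(fp), 1)
  f_mu <- transfer_function(3, p$transfer)
  expect_equal(fp$h, 3, tolerance = 1e-10)
  expect_equal(fp$x, 1 / (1 + 0.8 * 0.4 * f_mu), tolerance = 1e-10)
  ev <- linear_stability(c(h = fp$h, x = fp$x), p)$eigenvalues
  expect_equal(sort(Re(ev)), sort(c(-1 / 0.05, -1 / 0.8 - 0.4 * f_mu)),
               tolerance = 1e-8)
  expect_equal(Im(ev), c(0, 0))
})

test_that("bistable parameter set yields node, saddle and focus", {
  fp <- find_fixed_points(preset_params("fig3"))
  expect_equal(nrow(fp), 3)
  expect_equal(fp$classification,
               c("stable node", "saddle", "stable focus"))
  # residuals at machine level
  p <- preset_params("fig3"); J <- 3.5 / 0.05
  for (i in 1:3) {
    f <- transfer_function(fp$h[i], p$transfer)
    expect_lt(abs((p$mu - fp$h[i]) / p$tau + J * 0.4 * fp$x[i] * f), 1e-9)
    expect_lt(abs((1 - fp$x[i]) / 0.6 - 0.4 * fp$x[i] * f), 1e-10)
  }
  # refinement: a 1% perturbation re-converges to the same root
  g <- function(h) {
    f <- transfer_function(h, p$transfer)
    (p$mu - h) / p$tau + J * 0.4 * f / (1 + 0.6 * 0.4 * f)
  }
  for (i in c(1, 3)) {
    h1 <- stats::uniroot(g, fp$h[i] * c(0.99, 1.01), tol = 1e-14)$root
    expect_equal(h1, fp$h[i], tolerance = 1e-9)
  }
})

test_that("excitable parameter set has one stable and two unstable fixed points", {
  fp <- find_fixed_points(preset_params("fig2"))
  expect_equal(nrow(fp), 3)
  stable <- grepl("stable", fp$classification) &
    !grepl("unstable", fp$classification)
  expect_equal(sum(stable), 1)
  expect_equal(sum(fp$classification == "saddle"), 1)
})

test_that("analytic Jacobian matches central finite differences", {
  p <- preset_params("fig3")
  J <- 3.5 / 0.05
  drift <- function(s) {
    f <- transfer_function(s[1], p$transfer)
    c((p$mu - s[1]) / p$tau + J * 0.4 * s[2] * f,
      (1 - s[2]) / 0.6 - 0.4 * s[2] * f)
  }
  fp <- find_fixed_points(p)
  for (i in seq_len(nrow(fp))) {
    s0 <- c(fp$h[i], fp$x[i])
    ls <- linear_stability(c(h = s0[1], x = s0[2]), p)
    num <- matrix(0, 2, 2)
    eps <- 1e-6
    for (j in 1:2) {
      e <- c(0, 0); e[j] <- eps
      num[, j] <- (drift(s0 + e) - drift(s0 - e)) / (2 * eps)
    }
    expect_equal(ls$jacobian, num, tolerance = 1e-5)
    # saddle iff negative determinant
    expect_identical(ls$classification == "saddle", det(ls$jacobian) < 0)
  }
  expect_error(linear_stability(c(h = 0, x = 0.5), p))
})

test_that("manifold tracing seeds along the eigenvector and separates basins", {
  p <- preset_params("fig3")
  fp <- find_fixed_points(p)
  saddle <- c(h = fp$h[2], x = fp$x[2])
  man <- trace_manifold(saddle, p, which = "stable", t_max = 30)
  # first segment parallel to the eigenvector within 1 degree
  seg <- as.numeric(man$branch_pos[2, c("h", "x")]) - unname(saddle)
  ang <- acos(abs(sum(seg * man$eigenvector)) / sqrt(sum(seg^2)))
  expect_lt(ang, pi / 180)
  # points either side of the separatrix converge to different attractors
  W <- single_pop_weights(3.5 / 0.05)
  pick <- man$branch_neg[which.min(abs(man$branch_neg$x - 0.9)), ]
  above <- simulate_macroscopic(p, W, T = 30,
                                init = list(h = pick$h + 0.05, x = pick$x),
                                record = "h")
  below <- simulate_macroscopic(p, W, T = 30,
                                init = list(h = pick$h - 0.05, x = pick$x),
                                record = "h")
  # the separatrix decides between a direct relaxation and a large
  # phase-space excursion around the unstable limit cycle
  exc <- sort(c(max(above$h), max(below$h)))
  expect_lt(exc[1], fp$h[2] + 1)   # one side never leaves the Down basin
  expect_gt(exc[2], 10)            # the other makes a population-spike excursion
  # unstable manifold endpoints approach an attractor
  mu_man <- trace_manifold(saddle, p, which = "unstable", t_max = 60)
  for (br in list(mu_man$branch_pos, mu_man$branch_neg)) {
    endh <- br$h[nrow(br)]
    expect_lt(min(abs(endh - fp$h[c(1, 3)])), 0.3)
  }
  expect_error(trace_manifold(c(h = fp$h[1], x = fp$x[1]), p))
})

test_that("macroscopic run is stationary at a fixed point and oscillates at the focus frequency", {
  p <- preset_params("fig3")
  W <- single_pop_weights(3.5 / 0.05)
  fp <- find_fixed_points(p)
  tr <- simulate_macroscopic(p, W, T = 10,
                             init = list(h = fp$h[1], x = fp$x[1]),
                             record = c("h", "x"))
  expect_lt(max(abs(tr$h - fp$h[1])), 1e-8)
  expect_lt(max(abs(tr$x - fp$x[1])), 1e-8)
  # decaying oscillation near the Up-state focus at Im(lambda)/(2 pi)
  tr2 <- simulate_macroscopic(p, W, T = 8,
                              init = list(h = fp$h[3] + 0.4, x = fp$x[3]),
                              record = "h")
  h <- tr2$h[, 1] - fp$h[3]
  crossings <- which(diff(sign(h)) != 0)
  period <- 2 * mean(diff(crossings)) * tr2$dt
  ev <- attr(fp, "eigen")[[3]]
  expect_equal(1 / period, abs(Im(ev[1])) / (2 * pi), tolerance = 0.05)
})

test_that("Up-state oscillation frequency matches the focus eigenvalue", {
  p <- preset_params("fig3", N = 150)
  fp <- find_fixed_points(p)
  f_pred <- abs(Im(attr(fp, "eigen")[[3]][1])) / (2 * pi)
  tr <- simulate_diffusion(p, single_pop_weights(3.5 / 0.05), T = 605,
                           seed = 13, record = "h")
  ud <- updown_segmentation(tr$h[, 1], dt = tr$dt, burn_in = 5)
  up <- ud$up[ud$up$duration >= 6, ]
  expect_gt(nrow(up), 0)
  acc <- NULL
  for (i in seq_len(nrow(up))) {
    idx <- which(tr$times > up$onset[i] & tr$times < up$offset[i])
    ps <- power_spectrum(tr$h[idx, 1], tr$dt, segment_length = 2^12)
    acc <- if (is.null(acc)) ps$power * ps$n_segments
           else acc + ps$power * ps$n_segments
    freq <- ps$freq
  }
  band <- freq >= 0.5 & freq <= 3
  f_peak <- freq[band][which.max(acc[band])]
  expect_equal(f_peak, f_pred, tolerance = 0.3 / f_pred)
})
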