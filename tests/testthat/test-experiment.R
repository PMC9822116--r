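test_that("experiments are deterministic given config and seed", {
  cfg <- experiment_config("fig2", model = "jumpdiff", N = 30, T = 30,
                           seed = 12)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$trace$A, r2$trace$A)
  expect_equal(r1$summary$n_bursts, r2$summary$n_bursts)
  expect_identical(r1$summary$ibi$intervals, r2$summary$ibi$intervals)
  expect_gt(r1$summary$n_bursts, 3)
})

test_that("run_experiment persists trace, events, summary and parameter log", {
  dir <- tempfile(); dir.create(dir)
  cfg <- experiment_config("fig2", model = "jumpdiff", N = 30, T = 30,
                           seed = 12, out = file.path(dir, "run"))
  r <- run_experiment(cfg, trace_every = 5L)
  files <- list.files(dir)
  expect_setequal(files, c("run_trace.tsv", "run_trace.yml",
                           "run_summary.tsv", "run_events.tsv",
                           "run_log.yml"))
  # trace round-trips bit-identically through the text container
  tr2 <- read_sim_trace(file.path(dir, "run_trace"))
  idx <- seq(1, length(r$trace$times), by = 5L)
  expect_identical(tr2$A, r$trace$A[idx, , drop = FALSE])
  expect_identical(tr2$h, r$trace$h[idx, , drop = FALSE])
  expect_equal(tr2$times, r$trace$times[idx])
  # the summary file carries the standard tabulation vocabulary
  summ <- readLines(file.path(dir, "run_summary.tsv"))
  expect_true(any(grepl("^mean\\(IBI\\)\t", summ)))
  expect_true(any(grepl("^fraction\\(NLE/bursts\\)\t", summ)))
  expect_true(any(grepl("^Lag 1 \\(event speed\\)\t", summ)))
  log <- yaml::read_yaml(file.path(dir, "run_log.yml"))
  expect_equal(log$seed, 12)
  expect_equal(log$burst_threshold, attr(r$summary$events, "threshold"))
})

test_that("simulation traces round-trip through the text container", {
  p <- preset_params("fig2", N = 30)
  tr <- simulate_jump_diffusion(p, fig2_weights(), T = 2, seed = 3)
  path <- tempfile()
  write_sim_trace(tr, path)
  tr2 <- read_sim_trace(path)
  expect_identical(tr2$A, tr$A)
  expect_identical(tr2$h, tr$h)
  expect_identical(tr2$x, tr$x)
  expect_identical(tr2$y, tr$y)
  expect_equal(tr2$model_kind, "jump_diffusion")
})

test_that("fixture generators emit the annotated ground truth", {
  fx <- generate_fixture("pulse-trace")
  expect_equal(nrow(fx$annotation), 2)
  fx2 <- generate_fixture("drifting-bump", params = list(M = 50, frames = 9))
  expect_equal(fx2$annotation$distance, 8 * 2 * pi / 50)
  expect_equal(dim(fx2$data), c(9, 50))
  l1 <- generate_fixture("labeled-sequence", seed = 6)
  l2 <- generate_fixture("labeled-sequence", seed = 6)
  expect_identical(l1$data, l2$data)
  expect_true(all(l1$data %in% 1:3))
  expect_length(l1$data, 100)
  # files written on request
  dir <- tempfile(); dir.create(dir)
  generate_fixture("pulse-trace", path = file.path(dir, "pulse"))
  expect_true(file.exists(file.path(dir, "pulse_trace.tsv")))
  expect_true(file.exists(file.path(dir, "pulse_events.tsv")))
})

test_that("multi-environment experiment attributes bursts across all maps", {
  cfg <- experiment_config("fig6", model = "jumpdiff", T = 35, seed = 4)
  res <- run_experiment(cfg)
  s <- res$summary
  expect_gt(s$n_bursts, 20)
  expect_equal(length(s$env$env_fraction), 3)
  # by the balanced construction no environment dominates
  expect_true(all(s$env$env_fraction > 0.15))
  expect_equal(sum(s$env$env_fraction), 1)
  expect_equal(rowSums(s$env$transition_matrix), rep(1, 3), tolerance = 1e-12)
  # single wave never travels further than once around the circle
  expect_lte(attr(s$events, "n_over_one_lap"), 0.02 * s$n_bursts)
})
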