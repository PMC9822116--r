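#' Experiment configuration
#'
#' Bundles a parameter preset (or explicit [meso_params()]), model kind,
#' network specification, duration and seed into a validated configuration
#' consumed by [run_experiment()]. Explicit arguments override preset
#' defaults.
#'
#' @param preset preset name (see [preset_params()]) or a `meso_params`
#'   object.
#' @param model one of `"micro"`, `"jumpdiff"`, `"diff"`, `"macro"`,
#'   `"fullstp"`.
#' @param N neurons per population; `Inf` allowed for the noise-free limit
#'   of the mesoscopic models.
#' @param M number of populations (defaults from the preset).
#' @param T duration (s).
#' @param dt integration step (s).
#' @param mu external input override (mV); for `model = "macro"` with a ring
#'   preset the preset's macroscopic drive is used unless overridden here.
#' @param seed integer seed (drives weights shuffling and simulation noise).
#' @param burn_in burn-in discarded by the analysis (s).
#' @param record_every recording stride in integration steps.
#' @param out optional output path prefix for [run_experiment()].
#' @return An `"experiment_config"` list.
#' @export
experiment_config <- function(preset = "fig2",
                              model = c("jumpdiff", "micro", "diff", "macro",
                                        "fullstp"),
                              N = NULL, M = NULL, T = 60, dt = 1e-4,
                              mu = NULL, seed = 1L, burn_in = 5,
                              record_every = 10L, out = NULL) {
  model <- match.arg(model)
  if (inherits(preset, "meso_params")) {
    params <- preset
    preset_name <- attr(preset, "preset")
    if (is.null(preset_name)) preset_name <- "custom"
  } else {
    params <- preset_params(preset, N = N, dt = dt)
    preset_name <- preset
  }
  if (!is.null(N)) params$N <- N
  if (is.null(M)) M <- attr(params, "M")
  if (is.null(M)) M <- 1L
  if (model == "macro" && is.null(mu) && !is.null(attr(params, "mu_macro")))
    mu <- attr(params, "mu_macro")
  if (!is.null(mu)) params$mu <- mu
  if (model == "micro" && is.infinite(params$N))
    stop("microscopic model needs finite N")
  structure(list(params = params, preset = preset_name, model = model,
                 M = as.integer(M), T = T, seed = as.integer(seed),
                 burn_in = burn_in, record_every = as.integer(record_every),
                 K = attr(params, "K"), f_select = attr(params, "f_select"),
                 out = out),
            class = "experiment_config")
}

build_experiment_weights <- function(config) {
  p <- config$params
  if (!p$ring) return(single_pop_weights(eff_J(p)))
  if (!is.null(config$K) && config$K > 1) {
    env <- build_selectivity(config$M, config$K, config$f_select,
                             seed = config$seed)
    build_multi_env_weights(env, eff_J0(p), eff_J1(p))
  } else {
    build_single_env_weights(config$M, eff_J0(p), eff_J1(p))
  }
}

#' Run one configured experiment
#'
#' Builds the connectivity, simulates the requested model, and runs the
#' replay summary analysis. Deterministic given (config, seed). With
#' `config$out` set, persists the (down-sampled) trace, the event table, the
#' summary, and a YAML log of every analysis parameter actually used
#' (thresholds, smoothing, burn-in, clamp counts).
#'
#' For deterministic macroscopic ring runs the initial potential receives a
#' small symmetry-breaking perturbation (1e-2 mV on the first spatial
#' Fourier mode): the uniform state is an exact solution of the noise-free
#' dynamics, and the fatigue-driven traveling-wave regime is only reachable
#' after symmetry breaking.
#'
#' @param config an [experiment_config()].
#' @param trace_every down-sampling stride for the persisted trace.
#' @return List: `trace` (a `sim_trace`), `summary` (a `replay_summary`),
#'   `weights`, `env` (environment map or NULL), `config`.
#' @export
run_experiment <- function(config, trace_every = 10L) {
  stopifnot(inherits(config, "experiment_config"))
  p <- config$params
  W <- build_experiment_weights(config)
  env <- if (!is.null(W$env)) W$env else NULL
  init <- NULL
  if (config$model == "macro" && p$ring) {
    base <- default_init(p, W)
    th <- if (is.matrix(W$theta)) 2 * pi * seq_len(W$M) / W$M else W$theta
    init <- list(h = base$h + 1e-2 * cos(th), x = base$x)
  }
  trace <- switch(config$model,
    jumpdiff = simulate_jump_diffusion(p, W, config$T, seed = config$seed,
                                       record_every = config$record_every,
                                       record = if (W$M > 1) "h"
                                                else c("A", "h", "x", "m2")),
    diff = simulate_diffusion(p, W, config$T, seed = config$seed,
                              record_every = config$record_every,
                              record = if (W$M > 1) "h"
                                       else c("A", "h", "x", "m2")),
    macro = simulate_macroscopic(p, W, config$T, init = init,
                                 record_every = config$record_every),
    micro = simulate_microscopic(p, W, config$T, seed = config$seed,
                                 record_every = config$record_every),
    fullstp = simulate_full_stp(p, W, config$T, seed = config$seed,
                                record_every = config$record_every))
  summ <- replay_summary(trace, burn_in = config$burn_in, env = env)
  res <- list(trace = trace, summary = summ, weights = W, env = env,
              config = config)
  if (!is.null(config$out)) {
    write_sim_trace(trace, paste0(config$out, "_trace"), every = trace_every)
    write_replay_summary(summ, config$out)
    log <- list(preset = config$preset, model = config$model,
                M = config$M, N = if (is.infinite(p$N)) "Inf" else p$N,
                T = config$T, dt = p$dt, mu = p$mu, seed = config$seed,
                burn_in = config$burn_in,
                record_dt = p$dt * config$record_every,
                burst_threshold = attr(summ$events, "threshold"),
                min_burst_duration = 0.01, merge_gap = 0.01,
                peak_smoothing = 0.01, peak_prominence_frac = 0.10,
                clamp = as.list(trace$clamp))
    yaml::write_yaml(log, paste0(config$out, "_log.yml"), precision = 17L)
  }
  res
}

#' Generate annotated synthetic fixtures for the analysis operators
#'
#' Constructs the small ground-truth inputs the analysis functions are
#' validated against: `"pulse-trace"` (constant baseline with rectangular
#' pulses; annotation = the event table), `"drifting-bump"` (a localized
#' activity bump stepping a fixed angular increment per frame; annotation =
#' the traveled distance), and `"labeled-sequence"` (i.i.d. uniform
#' environment labels).
#'
#' @param kind fixture kind.
#' @param params named list of fixture parameters, see Details.
#' @param seed integer seed (used by `"labeled-sequence"`).
#' @param path optional output path prefix; data and annotations are then
#'   written as TSV.
#' @details Parameters (with defaults): pulse-trace: `baseline` (1),
#'   `height` (10), `dt` (1e-3), `T` (10), `pulses` (data frame
#'   onset/offset, default two pulses at 2-2.5 s and 6-6.8 s).
#'   drifting-bump: `M` (100), `frames` (20), `drift` (2*pi/M), `width`
#'   (0.5 rad), `start` (pi), `dt` (1e-3). labeled-sequence: `K` (3),
#'   `n` (100).
#' @return List with `data` and `annotation` (both data frames / vectors).
#' @export
generate_fixture <- function(kind = c("pulse-trace", "drifting-bump",
                                      "labeled-sequence"),
                             params = list(), seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    "pulse-trace" = {
      d <- list(baseline = 1, height = 10, dt = 1e-3, T = 10,
                pulses = data.frame(onset = c(2, 6), offset = c(2.5, 6.8)))
      d[names(params)] <- params
      times <- seq(d$dt, d$T, by = d$dt)
      v <- rep(d$baseline, length(times))
      for (i in seq_len(nrow(d$pulses)))
        v[times > d$pulses$onset[i] & times <= d$pulses$offset[i]] <- d$height
      list(data = data.frame(time = times, activity = v),
           annotation = d$pulses, dt = d$dt)
    },
    "drifting-bump" = {
      d <- list(M = 100L, frames = 20L, drift = NULL, width = 0.5,
                start = pi, dt = 1e-3)
      d[names(params)] <- params
      if (is.null(d$drift)) d$drift <- 2 * pi / d$M
      th <- 2 * pi * seq_len(d$M) / d$M
      centers <- d$start + (seq_len(d$frames) - 1L) * d$drift
      A <- t(vapply(centers, function(cc)
        exp(cos(th - cc) / d$width^2), numeric(d$M)))
      list(data = A, angles = th,
           annotation = list(distance = (d$frames - 1L) * abs(d$drift),
                             drift = d$drift, centers = wrap_angle(centers)),
           dt = d$dt)
    },
    "labeled-sequence" = {
      d <- list(K = 3L, n = 100L)
      d[names(params)] <- params
      old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
      set.seed(seed)
      list(data = sample.int(d$K, d$n, replace = TRUE), annotation = d)
    })
  if (!is.null(path)) {
    if (kind == "pulse-trace") {
      utils::write.table(out$data, paste0(path, "_trace.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      utils::write.table(out$annotation, paste0(path, "_events.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    } else if (kind == "drifting-bump") {
      utils::write.table(out$data, paste0(path, "_raster.tsv"), sep = "\t",
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
      yaml::write_yaml(out$annotation, paste0(path, "_annotation.yml"))
    } else {
      utils::write.table(data.frame(label = out$data),
                         paste0(path, "_labels.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  out
}
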