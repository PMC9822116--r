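# Burst / replay statistics battery.
#
# Conventions used throughout: activity matrices are time x population in Hz
# (spikes per neuron per second); angles in radians on [0, 2*pi); positions
# decoded by the population vector average (PVA), i.e. the argument of the
# resultant sum(A_alpha * exp(i*theta_alpha)); angular increments wrapped to
# (-pi, pi] before accumulation; forward replay = anti-clockwise = negative
# signed speed.

wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

unwrap_positions <- function(pos) {
  if (length(pos) <= 1) return(pos)
  cumsum(c(pos[1], wrap_angle(diff(pos))))
}

moving_average <- function(v, k) {
  if (k <= 1) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# local maxima with prominence: for each peak, walk out until a strictly
# higher sample (or the boundary) is met; prominence is peak height minus the
# higher of the two deepest valleys on the way
find_peaks <- function(v, min_prominence = 0) {
  n <- length(v)
  if (n < 3) {
    return(if (n > 0 && which.max(v) >= 1 && stats::var(v) == 0) integer(0)
           else if (n > 0) which.max(v) else integer(0))
  }
  cand <- which(diff(sign(diff(v))) < 0) + 1L
  # plateau peaks: first sample of a flat top that ends in a descent
  if (length(cand) == 0 && v[1] < max(v)) cand <- which.max(v)
  # collapse candidates that share a flat top (no strict valley between)
  if (length(cand) > 1) {
    keep_flat <- rep(TRUE, length(cand))
    for (ii in 2:length(cand)) {
      i <- cand[ii - 1L]; j <- cand[ii]
      if (min(v[i:j]) >= min(v[i], v[j]))
        keep_flat[if (v[j] > v[i]) ii - 1L else ii] <- FALSE
    }
    cand <- cand[keep_flat]
  }
  keep <- logical(length(cand))
  for (ii in seq_along(cand)) {
    i <- cand[ii]
    p <- v[i]
    lmin <- p
    j <- i
    while (j > 1 && v[j - 1] <= p) { j <- j - 1; lmin <- min(lmin, v[j]) }
    rmin <- p
    j <- i
    while (j < n && v[j + 1] <= p) { j <- j + 1; rmin <- min(rmin, v[j]) }
    prom <- p - max(lmin, rmin)
    # boundary-touching peaks use the single interior valley
    if (v[i] == max(v)) prom <- p - min(lmin, rmin)
    keep[ii] <- prom >= min_prominence
  }
  cand[keep]
}

#' Detect bursts of population activity
#'
#' Burst events are maximal contiguous epochs of the population-averaged
#' activity above its whole-trace mean (the grand mean over populations and
#' time of the analysed segment). Supra-threshold epochs separated by gaps
#' shorter than `merge_gap` are merged, and events shorter than
#' `min_duration` are discarded, to suppress single-sample threshold chatter.
#' A constant trace yields zero events.
#'
#' @param x a `sim_trace`, or a numeric matrix (time x population) /
#'   vector of activity.
#' @param dt sampling step (s); taken from the trace if `x` is one.
#' @param burn_in initial period discarded before analysis (s).
#' @param min_duration minimum event duration (s), default 10 ms.
#' @param merge_gap sub-threshold gaps shorter than this are merged (s).
#' @param threshold optional explicit threshold (Hz); default = grand mean.
#' @return A data frame of class `"burst_events"`: columns `onset`, `offset`,
#'   `duration` (s, relative to trace start), `i_on`, `i_off` (sample
#'   indices into the analysed segment); attributes `dt`, `threshold`,
#'   `burn_in`, `t_start`, `T_analyzed`.
#' @export
detect_bursts <- function(x, dt = NULL, burn_in = 0, min_duration = 0.01,
                          merge_gap = 0.01, threshold = NULL) {
  if (inherits(x, "sim_trace")) {
    if (is.null(dt)) dt <- x$dt
    x <- if (!is.null(x$A)) x$A else rate_matrix(x)
    if (is.null(x)) stop("trace recorded neither activity nor potential")
  }
  if (is.null(dt)) stop("'dt' is required for matrix/vector input")
  A <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  i0 <- if (burn_in > 0) sum(seq_len(nrow(A)) * dt <= burn_in) else 0L
  if (i0 >= nrow(A)) stop("burn_in longer than trace")
  A <- A[(i0 + 1):nrow(A), , drop = FALSE]
  avg <- rowMeans(A)
  n <- length(avg)
  empty <- structure(
    data.frame(onset = numeric(0), offset = numeric(0),
               duration = numeric(0), i_on = integer(0), i_off = integer(0)),
    dt = dt, threshold = NA_real_, burn_in = burn_in, t_start = i0 * dt,
    T_analyzed = n * dt, class = c("burst_events", "data.frame"))
  # a trace whose excursions are a negligible fraction of its level is
  # constant for burst purposes (e.g. a deterministic run relaxing to a
  # quiescent fixed point)
  if (diff(range(avg)) <= 1e-3 * max(abs(mean(avg)), 1e-300)) return(empty)
  thr <- if (is.null(threshold)) mean(avg) else threshold
  above <- avg > thr
  if (!any(above)) { attr(empty, "threshold") <- thr; return(empty) }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # merge short sub-threshold gaps (interior only)
  if (length(r$values) > 2) {
    interior <- which(!r$values & seq_along(r$values) > 1 &
                        seq_along(r$values) < length(r$values))
    short <- interior[r$lengths[interior] * dt < merge_gap]
    above[unlist(mapply(seq, starts[short], ends[short],
                        SIMPLIFY = FALSE))] <- TRUE
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
  }
  on <- starts[r$values]
  off <- ends[r$values]
  dur <- (off - on + 1L) * dt
  keep <- dur >= min_duration
  on <- on[keep]; off <- off[keep]; dur <- dur[keep]
  t0 <- i0 * dt
  out <- data.frame(onset = t0 + (on - 1L) * dt, offset = t0 + off * dt,
                    duration = dur, i_on = on, i_off = off)
  structure(out, dt = dt, threshold = thr, burn_in = burn_in, t_start = t0,
            T_analyzed = n * dt, class = c("burst_events", "data.frame"))
}

#' @export
print.burst_events <- function(x, ...) {
  cat(sprintf("<burst_events> %d event(s), threshold = %.4g Hz over %.4g s\n",
              nrow(x), attr(x, "threshold"), attr(x, "T_analyzed")))
  if (nrow(x) > 0) print(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Classify bursts: peak counts, NLE flag, and bump kinematics
#'
#' For each detected burst, counts the local maxima of the population-
#' averaged activity (smoothed with a `smooth`-wide moving average, minimum
#' prominence `min_prominence_frac` of the event's peak height); bursts with
#' more than one peak are flagged as nonlocal replay events (NLEs). The bump
#' position is decoded as the circular centre of mass (PVA) of the smoothed
#' per-population activity, sampled once per smoothing window (consecutive
#' estimates from overlapping windows share their noise, so accumulating arc
#' length at a finer stride would double-count decoding jitter); the
#' traveled distance is the total unwrapped arc length over the event, the
#' signed speed the net unwrapped displacement divided by the duration
#' (negative = anti-clockwise = forward replay), and the absolute speed the
#' arc length divided by the duration.
#'
#' For multi-environment traces pass `env`: each burst is attributed to the
#' environment whose selective populations carry the maximal summed activity
#' during the event (ties broken towards the lowest index and counted), and
#' decoding uses that environment's angles over its selective populations.
#'
#' @param events a [detect_bursts()] result.
#' @param x the `sim_trace` or activity matrix the events came from.
#' @param angles place-field angles per population (radians); taken from the
#'   trace when possible. Ignored when `env` is given.
#' @param env optional [build_selectivity()] environment map.
#' @param dt sampling step (s) for matrix input.
#' @param smooth moving-average window (s), default 10 ms.
#' @param min_prominence_frac peak prominence floor, fraction of the event's
#'   peak height.
#' @return The events data frame with columns `n_peaks`, `is_NLE`,
#'   `peak_activity`, `distance` (rad), `signed_speed` (rad/s), `abs_speed`
#'   (rad/s), `direction` (+1 clockwise / -1 anti-clockwise), and for
#'   multi-environment input `environment`; attribute `n_label_ties`.
#'   Events whose traveled distance exceeds one lap (2*pi) are kept and
#'   counted in attribute `n_over_one_lap`.
#' @export
classify_events <- function(events, x, angles = NULL, env = NULL, dt = NULL,
                            smooth = 0.010, min_prominence_frac = 0.10) {
  stopifnot(inherits(events, "burst_events"))
  if (inherits(x, "sim_trace")) {
    if (is.null(dt)) dt <- x$dt
    if (is.null(angles) && is.null(env) && !is.matrix(x$theta))
      angles <- x$theta
    A <- if (!is.null(x$A)) x$A else rate_matrix(x)
    if (is.null(A)) stop("trace recorded neither activity nor potential")
  } else A <- as.matrix(x)
  if (is.null(dt)) dt <- attr(events, "dt")
  i0 <- as.integer(round(attr(events, "t_start") / dt))
  A <- A[(i0 + 1):nrow(A), , drop = FALSE]
  M <- ncol(A)
  if (is.null(env) && is.null(angles)) angles <- 2 * pi * seq_len(M) / M
  k <- max(1L, as.integer(round(smooth / dt)))
  # smoothing and the population average commute, so the averaged trace is
  # smoothed as one vector; per-population smoothing is done per event block
  # (with a one-window margin) to avoid a full smoothed copy of the trace
  avg_s <- moving_average(rowMeans(A), k)

  n_ev <- nrow(events)
  n_peaks <- integer(n_ev); peak_act <- numeric(n_ev)
  distance <- numeric(n_ev); signed <- numeric(n_ev); absv <- numeric(n_ev)
  env_lab <- integer(n_ev); ties <- 0L; flagged <- 0L
  for (e in seq_len(n_ev)) {
    idx <- events$i_on[e]:events$i_off[e]
    seg <- avg_s[idx]
    pk <- find_peaks(seg, min_prominence = min_prominence_frac * max(seg))
    n_peaks[e] <- max(1L, length(pk))
    peak_act[e] <- max(seg)
    lo <- max(1L, events$i_on[e] - k)
    hi <- min(nrow(A), events$i_off[e] + k)
    blk <- apply(A[lo:hi, , drop = FALSE], 2, moving_average, k = k)
    if (!is.matrix(blk)) blk <- matrix(blk, nrow = 1)
    Aev <- blk[idx - lo + 1L, , drop = FALSE]
    if (!is.null(env)) {
      tot <- colSums(Aev)
      by_env <- vapply(seq_len(env$K),
                       function(kk) sum(tot[env$zeta[, kk] == 1L]),
                       numeric(1))
      best <- which(by_env == max(by_env))
      if (length(best) > 1) ties <- ties + 1L
      env_lab[e] <- best[1]
      sel <- env$zeta[, env_lab[e]] == 1L
      th <- env$theta[sel, env_lab[e]]
      Adec <- Aev[, sel, drop = FALSE]
    } else {
      th <- angles
      Adec <- Aev
    }
    # decode at the smoothing timescale: one position per smoothing window
    sub <- unique(c(seq(1L, nrow(Adec), by = k), nrow(Adec)))
    z <- Adec[sub, , drop = FALSE] %*% exp(1i * th)
    ok <- Mod(z) > 1e-12
    if (sum(ok) < 2) { flagged <- flagged + 1L; next }
    pos <- Arg(z[ok])
    dpos <- wrap_angle(diff(pos))
    distance[e] <- sum(abs(dpos))
    signed[e] <- sum(dpos) / events$duration[e]
    absv[e] <- distance[e] / events$duration[e]
  }
  events$n_peaks <- n_peaks
  events$is_NLE <- n_peaks > 1L
  events$peak_activity <- peak_act
  events$distance <- distance
  events$signed_speed <- signed
  events$abs_speed <- absv
  events$direction <- ifelse(signed < 0, -1L, 1L)
  if (!is.null(env)) events$environment <- env_lab
  attr(events, "n_label_ties") <- ties
  attr(events, "n_undecodable") <- flagged
  attr(events, "n_over_one_lap") <- sum(distance > 2 * pi)
  events
}

#' Interburst-interval cumulant statistics
#'
#' Interburst intervals (IBIs) are the gaps from the end of one burst to the
#' start of the next. Cumulants are computed from raw sample moments without
#' small-sample bias correction: \eqn{\kappa_1 = \langle T\rangle},
#' \eqn{\kappa_2 = \langle T^2\rangle - \kappa_1^2},
#' \eqn{\kappa_3 = \langle T^3\rangle - 3\kappa_1\kappa_2 - \kappa_1^3},
#' \eqn{\kappa_4 = \langle T^4\rangle - 4\kappa_1\kappa_3 - 3\kappa_2^2 -
#' 6\kappa_1^2\kappa_2 - \kappa_1^4}. Reported are the mean, the coefficient
#' of variation \eqn{CV = \sqrt{\kappa_2}/\kappa_1}, skewness
#' \eqn{\gamma_s = \kappa_3 \kappa_2^{-3/2}}, rescaled skewness
#' \eqn{\alpha_s = \gamma_s/(3 CV)}, kurtosis
#' \eqn{\gamma_e = \kappa_4\kappa_2^{-2}}, and rescaled kurtosis
#' \eqn{\alpha_e = \gamma_e/(15 CV^2)} (the inverse Gaussian is the
#' reference for the rescaled quantities).
#'
#' @param events a [detect_bursts()] result with at least 2 events, or a
#'   numeric vector of intervals.
#' @return An `"ibi_stats"` list: `mean`, `cv`, `skewness`,
#'   `resc_skewness`, `kurtosis`, `resc_kurtosis`, `n_intervals`,
#'   `intervals`.
#' @export
ibi_statistics <- function(events) {
  if (inherits(events, "burst_events")) {
    if (nrow(events) < 2) stop("need at least 2 events for IBI statistics")
    ibi <- events$onset[-1] - events$offset[-nrow(events)]
  } else {
    ibi <- as.numeric(events)
    if (length(ibi) < 1) stop("need at least 1 interval")
  }
  m1 <- mean(ibi); m2 <- mean(ibi^2); m3 <- mean(ibi^3); m4 <- mean(ibi^4)
  k1 <- m1
  k2 <- m2 - k1^2
  k3 <- m3 - 3 * k1 * k2 - k1^3
  k4 <- m4 - 4 * k1 * k3 - 3 * k2^2 - 6 * k1^2 * k2 - k1^4
  cv <- sqrt(max(k2, 0)) / k1
  gs <- if (k2 > 0) k3 * k2^(-3 / 2) else NA_real_
  ge <- if (k2 > 0) k4 / k2^2 else NA_real_
  structure(list(mean = k1, cv = cv, skewness = gs,
                 resc_skewness = if (cv > 0) gs / (3 * cv) else NA_real_,
                 kurtosis = ge,
                 resc_kurtosis = if (cv > 0) ge / (15 * cv^2) else NA_real_,
                 n_intervals = length(ibi), intervals = ibi,
                 cumulants = c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)),
            class = "ibi_stats")
}

#' @export
print.ibi_stats <- function(x, ...) {
  cat(sprintf("<ibi_stats> n = %d\n", x$n_intervals))
  cat(sprintf("  mean(IBI) %.4g  CV(IBI) %.4g\n", x$mean, x$cv))
  cat(sprintf("  skewness %.4g (resc. %.4g)  kurtosis %.4g (resc. %.4g)\n",
              x$skewness, x$resc_skewness, x$kurtosis, x$resc_kurtosis))
  invisible(x)
}

#' Serial correlations of an ordered event attribute
#'
#' Pearson correlation between the sequence and its lagged copy,
#' \eqn{\mathrm{cor}(v_k, v_{k+\ell})}, for each requested lag. Zero-variance
#' input yields `NA` at every lag.
#'
#' @param values ordered numeric vector (e.g. signed NLE speeds, or their
#'   signs).
#' @param lags integer lags, default 1:5.
#' @return Named numeric vector of correlations.
#' @export
serial_correlation <- function(values, lags = 1:5) {
  v <- as.numeric(values)
  n <- length(v)
  out <- vapply(lags, function(l) {
    if (n < l + 2) return(NA_real_)
    a <- v[seq_len(n - l)]
    b <- v[seq_len(n - l) + l]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
    stats::cor(a, b)
  }, numeric(1))
  names(out) <- paste0("lag", lags)
  out
}

#' Decode a replay trajectory with the population vector average
#'
#' Bins the per-population activity of one event into consecutive
#' non-overlapping windows (default 50 ms), decodes the position per window
#' as the PVA angle, and measures step sizes between consecutive windows
#' (unwrapped absolute increments). The per-event average step size is the
#' slope of a least-squares straight line through the unwrapped position
#' sequence, times one window.
#'
#' @param raster activity matrix (time x population) within one event, Hz.
#' @param angles place-field angles (radians), length = populations.
#' @param dt sampling step of `raster` (s).
#' @param window window length (s), default 0.05; stride = window
#'   (non-overlapping).
#' @return List: `positions` (rad, one per decodable window), `times`
#'   (window centres, s), `step_sizes` (rad), `avg_step` (rad per window,
#'   straight-line fit), `undecodable` (logical per window).
#' @export
decode_trajectory <- function(raster, angles, dt, window = 0.05) {
  raster <- as.matrix(raster)
  wlen <- max(1L, as.integer(round(window / dt)))
  nw <- nrow(raster) %/% wlen
  if (nw < 2) stop("event shorter than two decoding windows")
  pos <- numeric(nw); und <- logical(nw)
  for (w in seq_len(nw)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    acc <- colSums(raster[idx, , drop = FALSE])
    z <- sum(acc * exp(1i * angles))
    if (Mod(z) < 1e-12) { und[w] <- TRUE; pos[w] <- NA_real_ }
    else pos[w] <- Arg(z)
  }
  ok <- !und
  pu <- rep(NA_real_, nw)
  pu[ok] <- unwrap_positions(pos[ok])
  steps <- abs(diff(pu[ok]))
  avg_step <- if (sum(ok) >= 2) {
    idx <- which(ok)
    unname(stats::coef(stats::lm(pu[ok] ~ idx))[2])
  } else NA_real_
  list(positions = pos, times = (seq_len(nw) - 0.5) * wlen * dt,
       step_sizes = steps, avg_step = avg_step, undecodable = und)
}

#' Up/Down state segmentation of a potential trace
#'
#' Thresholds the input potential at the minimum of its (0.1 mV-binned,
#' lightly smoothed) histogram between the two dominant modes; segmentation
#' is refused when the histogram is unimodal. Up states are the
#' supra-threshold epochs. When burst events are supplied, the fraction of
#' population spikes followed by an Up state is reported: a burst counts as
#' followed if an Up interval of at least `min_up` starts no later than
#' `latency` after the burst ends (the burst's own transient belongs to that
#' interval).
#'
#' @param h input potential series (mV), vector (or single-column matrix).
#' @param dt sampling step (s).
#' @param burn_in discarded initial period (s).
#' @param bin histogram bin width (mV), default 0.1.
#' @param min_up minimum Up duration entering the reported mean (s),
#'   default 1.
#' @param events optional [detect_bursts()] result from the activity of the
#'   same run (same time base).
#' @param latency burst-to-Up latency window (s), default 0.2.
#' @param merge_dip sub-threshold dips shorter than this are absorbed into
#'   the surrounding Up interval (s). Default 0.3 s, about half the period
#'   of the damped Up-state focus oscillation, whose excursions would
#'   otherwise fragment one Up episode into several.
#' @param threshold explicit threshold (mV) overriding the histogram
#'   criterion (useful for parameter sets whose histogram is unimodal, with
#'   a threshold carried over from a bimodal reference run).
#' @return List of class `"updown"`: `threshold`, `modes` (mV), `up` (data
#'   frame onset/offset/duration), `mean_up_duration` (Up >= `min_up`),
#'   `n_up_long`, and with `events`: `fraction_spike_to_up` (share of
#'   bursts whose window `[onset, offset + latency]` intersects an Up
#'   interval of at least `min_up`), `n_bursts`.
#' @export
updown_segmentation <- function(h, dt, burn_in = 0, bin = 0.1, min_up = 1,
                                events = NULL, latency = 0.2,
                                merge_dip = 0.3, threshold = NULL) {
  h <- as.numeric(h)
  i0 <- if (burn_in > 0) sum(seq_along(h) * dt <= burn_in) else 0L
  h <- h[(i0 + 1):length(h)]
  t0 <- i0 * dt
  if (!is.null(threshold)) {
    thr <- threshold
    modes <- c(NA_real_, NA_real_)
  } else {
  br <- seq(floor(min(h) / bin) * bin, ceiling(max(h) / bin) * bin, by = bin)
  if (length(br) < 4) stop("potential histogram is unimodal; segmentation refused")
  cnt <- graphics::hist(h, breaks = br, plot = FALSE)$counts
  mids <- (br[-1] + br[-length(br)]) / 2
  sm <- moving_average(cnt, 5L)
  # mode finding on padded log-counts: the two modes differ by orders of
  # magnitude (the Down state dominates the mass), and one may sit at the
  # histogram boundary; a mode must rise a factor >= 2 above its valley and
  # hold at least 0.1% of the samples
  lsm <- log1p(sm)
  padded <- c(-1, lsm, -1)
  pk <- find_peaks(padded, min_prominence = log(2)) - 1L
  pk <- pk[pk >= 1 & pk <= length(sm)]
  pk <- pk[sm[pk] >= 1e-3 * length(h)]
  if (length(pk) < 2)
    stop("potential histogram is unimodal; segmentation refused")
  ord <- pk[order(sm[pk], decreasing = TRUE)][1:2]
  lo <- min(ord); hi <- max(ord)
  thr_i <- lo + which.min(sm[lo:hi]) - 1L
  thr <- mids[thr_i]
  modes <- mids[ord[order(ord)]]
  }
  above <- h > thr
  # absorb brief intra-Up dips (focus oscillation undershoots)
  if (merge_dip > 0) {
    r <- rle(above)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    interior <- which(!r$values & seq_along(r$values) > 1 &
                        seq_along(r$values) < length(r$values))
    short <- interior[r$lengths[interior] * dt < merge_dip]
    for (s in short) above[starts[s]:ends[s]] <- TRUE
  }
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  on <- starts[r$values]; off <- ends[r$values]
  up <- data.frame(onset = t0 + (on - 1L) * dt, offset = t0 + off * dt)
  up$duration <- up$offset - up$onset
  long <- up$duration >= min_up
  out <- list(threshold = thr, modes = modes,
              up = up, mean_up_duration = mean(up$duration[long]),
              n_up_long = sum(long), min_up = min_up)
  if (!is.null(events) && nrow(events) > 0) {
    upl <- up[long, , drop = FALSE]
    followed <- vapply(seq_len(nrow(events)), function(e) {
      any(upl$onset <= events$offset[e] + latency &
            upl$offset >= events$onset[e])
    }, logical(1))
    out$fraction_spike_to_up <- mean(followed)
    out$n_bursts <- nrow(events)
  }
  class(out) <- "updown"
  out
}

#' @export
print.updown <- function(x, ...) {
  cat(sprintf("<updown> threshold %.3g mV between modes %.3g / %.3g mV\n",
              x$threshold, x$modes[1], x$modes[2]))
  cat(sprintf("  %d Up state(s) >= %g s, mean duration %.3g s\n",
              x$n_up_long, x$min_up, x$mean_up_duration))
  if (!is.null(x$fraction_spike_to_up))
    cat(sprintf("  %.1f%% of %d population spikes followed by an Up state\n",
                100 * x$fraction_spike_to_up, x$n_bursts))
  invisible(x)
}

#' Environment sequence statistics
#'
#' From the ordered sequence of per-burst environment labels, computes the
#' K x K transition matrix (row-normalized counts of consecutive pairs) and
#' the probabilities of all ordered 3-subsequences of distinct environments,
#' each count divided by the number of all possible 3-sequences
#' (= number of bursts - 2).
#'
#' @param labels integer vector of environment labels in temporal order
#'   (e.g. `classify_events()$environment`), or a classified events frame.
#' @param K number of environments.
#' @return List: `transition_matrix` (K x K), `transition_counts`,
#'   `subsequences` (named probabilities, names like `"1>2>3"`),
#'   `env_fraction` (share of bursts per environment), `n`.
#' @export
env_sequence_stats <- function(labels, K) {
  if (is.data.frame(labels)) labels <- labels$environment
  lab <- as.integer(labels)
  n <- length(lab)
  if (n < 3) stop("need at least 3 labeled events")
  tc <- matrix(0, K, K)
  for (i in seq_len(n - 1)) tc[lab[i], lab[i + 1]] <- tc[lab[i], lab[i + 1]] + 1
  tm <- tc / pmax(rowSums(tc), 1)
  perms <- expand.grid(k = 1:K, j = 1:K, l = 1:K)
  perms <- perms[perms$k != perms$j & perms$j != perms$l & perms$k != perms$l, ]
  counts <- apply(perms, 1, function(p)
    sum(lab[1:(n - 2)] == p[1] & lab[2:(n - 1)] == p[2] & lab[3:n] == p[3]))
  probs <- counts / (n - 2)
  names(probs) <- apply(perms, 1, paste, collapse = ">")
  list(transition_matrix = tm, transition_counts = tc,
       subsequences = probs,
       env_fraction = tabulate(lab, K) / n, n = n)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the series is split into
#' Hann-tapered segments with 50% overlap, each segment's one-sided
#' periodogram is normalized so that the integral of the density over
#' frequency equals the variance, and segments are averaged.
#'
#' @param x numeric series (e.g. the input potential after burn-in).
#' @param dt sampling step (s).
#' @param segment_length segment length in samples; default
#'   `2^floor(log2(length(x)/8))`.
#' @param demean subtract the mean before estimation (default TRUE).
#' @return List: `freq` (Hz), `power` (density, x-units^2 per Hz),
#'   `n_segments`.
#' @export
power_spectrum <- function(x, dt, segment_length = NULL, demean = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(segment_length)) segment_length <- 2^floor(log2(n / 8))
  L <- as.integer(segment_length)
  if (L > n) stop("segment longer than trace")
  if (L < 8) stop("trace too short for spectral estimation")
  if (demean) x <- x - mean(x)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))  # Hann
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, n - L + 1L, by = step)
  fs <- 1 / dt
  scale <- fs * sum(w^2)
  nf <- L %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)] * w
    X <- stats::fft(seg)[seq_len(nf)]
    P <- Mod(X)^2 / scale
    P[2:(nf - 1L)] <- 2 * P[2:(nf - 1L)]
    acc <- acc + P
  }
  list(freq = (seq_len(nf) - 1L) * fs / L, power = acc / length(starts),
       n_segments = length(starts))
}

#' Instantaneous-rate representation of a trace
#'
#' Returns the per-population expected rate \eqn{f(h^\alpha(t))} when the
#' trace recorded the input potential, and `NULL` otherwise. The rate is the
#' activity representation used for event statistics whenever available: it
#' is the quantity the model family's raster displays colour-code, and being
#' already low-pass filtered by the membrane time constant it requires no
#' arbitrary smoothing kernel, unlike the empirical spike-count activity.
#'
#' @param trace a `sim_trace`.
#' @return Matrix (time x population) of rates in Hz, or `NULL`.
#' @export
rate_matrix <- function(trace) {
  stopifnot(inherits(trace, "sim_trace"))
  if (is.null(trace$h) || !is.matrix(trace$h) || nrow(trace$h) == 0)
    return(NULL)
  R <- transfer_function(trace$h, trace$params$transfer)
  dim(R) <- dim(trace$h)
  R
}

analysis_activity <- function(trace, on = c("auto", "rate", "activity")) {
  on <- match.arg(on)
  if (on != "activity") {
    R <- rate_matrix(trace)
    if (!is.null(R)) return(R)
    if (on == "rate") stop("trace did not record 'h'; rate unavailable")
  }
  trace$A
}

#' Full replay summary of a simulation trace
#'
#' Runs burst detection, event classification, IBI cumulants, NLE fractions
#' and kinematics, regression slopes of peak count and traveled distance
#' against event duration, the sharp-wave rate during bursts (total peaks
#' over total burst time), and serial correlations of the signed NLE speeds
#' and of the replay directions, mirroring the standard tabulation of this
#' model family.
#'
#' @param trace a `sim_trace` from any of the simulators.
#' @param burn_in discarded initial period (s), default 5.
#' @param env optional environment map for multi-environment traces; adds
#'   transition/subsequence statistics.
#' @param lags lags for the serial correlations.
#' @param on analyse the expected rate `f(h)` (`"rate"`, default when `h`
#'   was recorded) or the empirical activity `A` (`"activity"`); see
#'   [rate_matrix()].
#' @return A `"replay_summary"` list; see `print()` output for the fields.
#' @export
replay_summary <- function(trace, burn_in = 5, env = NULL, lags = 1:5,
                           on = "auto") {
  act <- analysis_activity(trace, on)
  ev <- detect_bursts(act, dt = trace$dt, burn_in = burn_in)
  if (nrow(ev) == 0) {
    return(structure(list(n_bursts = 0L, events = ev,
                          T_analyzed = attr(ev, "T_analyzed")),
                     class = "replay_summary"))
  }
  angles <- if (!is.matrix(trace$theta)) trace$theta else NULL
  ev <- classify_events(ev, act, angles = angles, env = env, dt = trace$dt)
  nle <- ev[ev$is_NLE, ]
  out <- list(
    T_analyzed = attr(ev, "T_analyzed"),
    n_bursts = nrow(ev),
    burst_rate = nrow(ev) / attr(ev, "T_analyzed"),
    slope_peaks_per_duration =
      unname(stats::coef(stats::lm(n_peaks ~ duration, data = ev))[2]),
    slope_distance_per_duration =
      unname(stats::coef(stats::lm(distance ~ duration, data = ev))[2]),
    sw_rate = sum(ev$n_peaks) / sum(ev$duration),
    ibi = if (nrow(ev) >= 2) ibi_statistics(ev) else NULL,
    n_NLE = nrow(nle),
    fraction_NLE = nrow(nle) / nrow(ev),
    fraction_forward = if (nrow(nle) > 0) mean(nle$direction < 0) else NA_real_,
    mean_abs_speed = if (nrow(nle) > 0) mean(nle$abs_speed) else NA_real_,
    serial_speed = serial_correlation(nle$signed_speed, lags),
    serial_direction = serial_correlation(nle$direction, lags),
    events = ev)
  if (!is.null(env)) {
    out$env <- env_sequence_stats(ev$environment, env$K)
  }
  structure(out, class = "replay_summary")
}

#' @export
print.replay_summary <- function(x, ...) {
  cat("<replay_summary>\n")
  fmt <- function(label, value)
    cat(sprintf("  %-28s %s\n", label, value))
  fmt("T_sim [s]", sprintf("%g", x$T_analyzed))
  fmt("# bursts", sprintf("%d", x$n_bursts))
  if (x$n_bursts == 0) return(invisible(x))
  fmt("slope(# peaks/duration)", sprintf("%.2f", x$slope_peaks_per_duration))
  fmt("slope(distance/duration)", sprintf("%.2f", x$slope_distance_per_duration))
  fmt("SW rate in bursts [1/s]", sprintf("%.2f", x$sw_rate))
  if (!is.null(x$ibi)) {
    fmt("mean(IBI)", sprintf("%.3f", x$ibi$mean))
    fmt("CV(IBI)", sprintf("%.3f", x$ibi$cv))
    fmt("skewness (IBI)", sprintf("%.3f", x$ibi$skewness))
    fmt("resc. skewness (IBI)", sprintf("%.3f", x$ibi$resc_skewness))
    fmt("kurtosis (IBI)", sprintf("%.3f", x$ibi$kurtosis))
    fmt("resc. kurtosis (IBI)", sprintf("%.3f", x$ibi$resc_kurtosis))
  }
  fmt("# NLE (>1 peak)", sprintf("%d", x$n_NLE))
  fmt("fraction(NLE/bursts)", sprintf("%.1f%%", 100 * x$fraction_NLE))
  fmt("fraction(forward/NLE)", sprintf("%.2f%%", 100 * x$fraction_forward))
  fmt("mean(abs(NLE speed))", sprintf("%.2f", x$mean_abs_speed))
  for (i in seq_along(x$serial_speed)) {
    fmt(sprintf("Lag %d (event speed)", i), sprintf("%.3f", x$serial_speed[i]))
    fmt(sprintf("Lag %d (forward/backward)", i),
        sprintf("%.3f", x$serial_direction[i]))
  }
  if (!is.null(x$env)) {
    for (k in seq_along(x$env$env_fraction))
      fmt(sprintf("bursts in env. %d", k),
          sprintf("%.2f%%", 100 * x$env$env_fraction[k]))
  }
  invisible(x)
}

#' Write a summary / event table as structured text
#'
#' The summary file mirrors the printed tabulation (one `name<TAB>value` row
#' per statistic) so scaled-down reproductions diff cleanly; the event table
#' has one row per event with documented columns.
#'
#' @param x a `replay_summary`.
#' @param path base path; writes `<path>_summary.tsv` and
#'   `<path>_events.tsv`.
#' @export
write_replay_summary <- function(x, path) {
  stopifnot(inherits(x, "replay_summary"))
  rows <- list(c("T_sim [s]", format(x$T_analyzed, digits = 17)),
               c("# bursts", x$n_bursts))
  if (x$n_bursts > 0) {
    add <- function(n, v) rows[[length(rows) + 1]] <<- c(n, format(v, digits = 17))
    add("slope(# peaks/duration)", x$slope_peaks_per_duration)
    add("slope(distance/duration)", x$slope_distance_per_duration)
    add("SW rate in bursts [1/s]", x$sw_rate)
    if (!is.null(x$ibi)) {
      add("mean(IBI)", x$ibi$mean); add("CV(IBI)", x$ibi$cv)
      add("skewness (IBI)", x$ibi$skewness)
      add("resc. skewness (IBI)", x$ibi$resc_skewness)
      add("kurtosis (IBI)", x$ibi$kurtosis)
      add("resc. kurtosis (IBI)", x$ibi$resc_kurtosis)
    }
    add("# NLE (>1 peak)", x$n_NLE)
    add("fraction(NLE/bursts)", x$fraction_NLE)
    add("fraction(forward/NLE)", x$fraction_forward)
    add("mean(abs(NLE speed))", x$mean_abs_speed)
    for (i in seq_along(x$serial_speed)) {
      add(sprintf("Lag %d (event speed)", i), x$serial_speed[i])
      add(sprintf("Lag %d (forward/backward)", i), x$serial_direction[i])
    }
    if (!is.null(x$env))
      for (k in seq_along(x$env$env_fraction))
        add(sprintf("bursts in env. %d", k), x$env$env_fraction[k])
  }
  m <- do.call(rbind, rows)
  utils::write.table(m, paste0(path, "_summary.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(format(as.data.frame(x$events), digits = 17, trim = TRUE),
                     paste0(path, "_events.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
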