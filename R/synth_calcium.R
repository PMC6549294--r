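# Synthetic calcium recordings: a population of somata sharing a network
# event train. Each neuron adopts every network event with probability
# `synchrony_fraction` (so 1 -> identical burst times, 0 -> independent
# trains) and fires additional independent bursts at the complementary rate,
# keeping the per-neuron burst rate at `burst_rate` regardless of synchrony.
# Transients have an instantaneous rise and exponential decay (tau = 1.5 s,
# fast-indicator regime).

#' Parameters of a synthetic calcium recording
#'
#' @param n_neurons number of somata (>= 1).
#' @param frame_rate acquisition rate in Hz (default 2).
#' @param duration recording length in seconds (default 180, i.e. 3 min).
#' @param width,height frame size in pixels.
#' @param soma_radius soma disc radius in pixels.
#' @param burst_rate expected per-neuron burst rate (Hz).
#' @param synchrony_fraction fraction of each neuron's bursts drawn from the
#'   shared network event train, in \[0, 1\].
#' @param tau_decay transient decay time constant (s).
#' @param baseline resting fluorescence (a.u.).
#' @param amp_range range of burst amplitudes (dF/F units).
#' @param noise_sd Gaussian noise sd as a fraction of baseline.
#' @return object of class `calcium_params`.
#' @export
calcium_params <- function(n_neurons = 20L, frame_rate = 2, duration = 180,
                           width = 128L, height = 128L, soma_radius = 5,
                           burst_rate = 0.04, synchrony_fraction = 0.5,
                           tau_decay = 1.5, baseline = 100,
                           amp_range = c(0.4, 1.2), noise_sd = 0.05) {
  p <- as.list(environment())
  if (p$n_neurons < 1L) stop("n_neurons must be >= 1")
  if (p$synchrony_fraction < 0 || p$synchrony_fraction > 1)
    stop("synchrony_fraction must be in [0, 1]")
  if (p$frame_rate * p$duration < 2)
    stop("duration x frame_rate must give at least 2 frames")
  structure(p, class = "calcium_params")
}

poisson_train <- function(rate, duration, min_gap = 2.5) {
  n <- stats::rpois(1, rate * duration)
  if (n == 0L) return(numeric(0))
  t <- sort(stats::runif(n, 0, duration))
  if (length(t) > 1L) t <- t[c(TRUE, diff(t) >= min_gap)]
  t
}

#' Simulate per-neuron calcium traces (no pixel rendering)
#'
#' The trace-level core of [generate_calcium()], exposed directly because
#' synchrony analyses do not need rendered movies.
#'
#' @param params a [calcium_params()] object.
#' @param seed integer seed.
#' @return list with `traces` (a `trace_matrix` of clean dF/F values, no
#'   noise) and `truth` (a `calcium_truth`: burst times, amplitudes, network
#'   event times, parameters, seed).
#' @export
simulate_calcium_traces <- function(params = calcium_params(), seed = 1L) {
  stopifnot(inherits(params, "calcium_params"))
  with_seed(seed, {
    n_frames <- round(params$frame_rate * params$duration)
    tgrid <- (seq_len(n_frames) - 1) / params$frame_rate
    f <- params$synchrony_fraction
    net <- poisson_train(params$burst_rate, params$duration)
    net_amp <- stats::runif(length(net), params$amp_range[1],
                            params$amp_range[2])
    onsets <- vector("list", params$n_neurons)
    amps <- vector("list", params$n_neurons)
    vals <- matrix(0, params$n_neurons, n_frames)
    for (i in seq_len(params$n_neurons)) {
      adopt <- if (length(net) > 0 && f > 0)
        stats::runif(length(net)) <= f else logical(length(net))
      t_i <- net[adopt]; a_i <- net_amp[adopt]
      if (f < 1) {
        extra <- poisson_train(params$burst_rate * (1 - f), params$duration)
        t_i <- c(t_i, extra)
        a_i <- c(a_i, stats::runif(length(extra), params$amp_range[1],
                                   params$amp_range[2]))
      }
      o <- order(t_i)
      t_i <- t_i[o]; a_i <- a_i[o]
      if (length(t_i) > 1L) {
        keep <- c(TRUE, diff(t_i) >= 1.0)
        t_i <- t_i[keep]; a_i <- a_i[keep]
      }
      onsets[[i]] <- t_i
      amps[[i]] <- a_i
      for (k in seq_along(t_i)) {
        on <- tgrid >= t_i[k]
        vals[i, on] <- vals[i, on] +
          a_i[k] * exp(-(tgrid[on] - t_i[k]) / params$tau_decay)
      }
    }
    truth <- structure(list(params = params, seed = seed,
                            burst_onsets = onsets, burst_amps = amps,
                            network_events = net),
                       class = "calcium_truth")
    traces <- trace_matrix(vals, params$frame_rate,
                           neuron_ids = seq_len(params$n_neurons))
    list(traces = traces, truth = truth)
  })
}

#' Generate a synthetic calcium recording with ground truth
#'
#' Renders an activity movie (one channel, `frame_rate x duration` frames)
#' plus a 3-slice nuclear-reporter reference stack of disjoint somata.
#'
#' @param params a [calcium_params()] object.
#' @param seed integer seed.
#' @return list with `recording` (list: `frames` array `[H, W, T]`,
#'   `reference` array `[H, W, 3]`, `frame_rate`) and `truth`
#'   (a `calcium_truth`, including the clean dF/F trace matrix).
#' @export
generate_calcium <- function(params = calcium_params(), seed = 1L) {
  sim <- simulate_calcium_traces(params, seed)
  with_seed(seed + 1000003L, {
    h <- params$height; w <- params$width; r <- params$soma_radius
    margin <- r + 2
    centers <- place_points(params$n_neurons, c(margin, w - margin),
                            c(margin, h - margin), 2 * r + 4, what = "somata")
    n_frames <- ncol(sim$traces$values)
    # per-soma pixel index sets
    soma_px <- vector("list", params$n_neurons)
    ref_base <- matrix(0, h, w)
    for (i in seq_len(params$n_neurons)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      xs <- max(1, floor(cx - r)):min(w, ceiling(cx + r))
      ys <- max(1, floor(cy - r)):min(h, ceiling(cy + r))
      d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
      sel <- which(d2 <= r^2, arr.ind = TRUE)
      idx <- (xs[sel[, 2]] - 1L) * h + ys[sel[, 1]]
      soma_px[[i]] <- idx
      ref_base[idx] <- 600
    }
    bg <- 20
    noise <- params$noise_sd * params$baseline
    frames <- array(stats::rnorm(h * w * n_frames, bg, max(noise, 1e-12)),
                    dim = c(h, w, n_frames))
    if (noise == 0) frames <- array(bg, dim = c(h, w, n_frames))
    for (t in seq_len(n_frames)) {
      fr <- frames[, , t]
      for (i in seq_len(params$n_neurons))
        fr[soma_px[[i]]] <- fr[soma_px[[i]]] +
          params$baseline * (1 + sim$traces$values[i, t])
      frames[, , t] <- fr
    }
    reference <- array(0, dim = c(h, w, 3L))
    for (z in 1:3) {
      sl <- if (z == 2L) ref_base else gaussian_blur(ref_base, 1.5) / 1.3
      sl <- sl + bg
      if (noise > 0) sl <- sl + stats::rnorm(length(sl), 0, noise)
      reference[, , z] <- pmax(sl, 0)
    }
    truth <- sim$truth
    truth$soma_centers <- centers
    truth$clean_traces <- sim$traces
    list(recording = list(frames = frames, reference = reference,
                          frame_rate = params$frame_rate),
         truth = truth)
  })
}
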