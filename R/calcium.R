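# Functional profiling of calcium recordings: soma segmentation on the
# nuclear-reporter reference, per-soma trace extraction and dF/F
# normalization, MAD-threshold burst detection, and the functional
# descriptor class.

#' Default configuration of the calcium pipeline
#'
#' @param soma_threshold absolute intensity threshold on the reference max
#'   projection.
#' @param min_soma_area minimum soma size (px).
#' @param k_mad burst threshold in robust sd units above the trace median.
#' @param min_interval_s minimal separation between burst onsets (s); closer
#'   crossings are merged into one burst.
#' @param network_bin_s bin width (s) for network-burst detection.
#' @param network_fraction fraction of active neurons that must burst in a
#'   bin for it to count as a network burst.
#' @export
calcium_config <- function(soma_threshold = 250, min_soma_area = 20,
                           k_mad = 3, min_interval_s = 2,
                           network_bin_s = 1, network_fraction = 0.5) {
  structure(as.list(environment()), class = "calcium_config")
}

#' Construct a trace matrix
#' @param values `n_neurons x n_frames` numeric matrix of normalized
#'   fluorescence.
#' @param frame_rate frames per second.
#' @param neuron_ids identifiers aligned to the soma labels.
#' @export
trace_matrix <- function(values, frame_rate, neuron_ids = seq_len(nrow(values))) {
  stopifnot(is.matrix(values), ncol(values) >= 2L, all(is.finite(values)))
  structure(list(values = values, frame_rate = frame_rate,
                 neuron_ids = neuron_ids), class = "trace_matrix")
}

#' Segment somata on the nuclear-reporter reference stack
#'
#' Max-projects the reference and reuses the nucleus segmentation machinery.
#'
#' @param reference_stack 3-D array `[H, W, Z]` (or matrix).
#' @param threshold absolute intensity threshold.
#' @param min_area minimum soma size (px).
#' @return integer label mask.
#' @export
segment_somata <- function(reference_stack, threshold, min_area = 20) {
  segment_nuclei(max_project(reference_stack), threshold, min_area)
}

#' Extract normalized per-soma traces from a movie
#'
#' Raw trace = mean activity intensity over each soma per frame;
#' normalization is dF/F with F0 the 10th percentile of the raw trace.
#'
#' @param movie 3-D array `[H, W, T]`.
#' @param soma_labels integer label mask co-registered with the frames.
#' @param frame_rate frames per second.
#' @return a [trace_matrix()].
#' @export
extract_traces <- function(movie, soma_labels, frame_rate = 2) {
  n <- max(soma_labels)
  if (n == 0L) stop("no somata in label mask")
  sizes <- tabulate(soma_labels[soma_labels > 0L], nbins = n)
  if (any(sizes == 0L))
    stop("label with 0 pixels: ", paste(which(sizes == 0L), collapse = ", "))
  n_frames <- dim(movie)[3]
  fg <- which(soma_labels > 0L)
  lab_fg <- soma_labels[fg]
  hw <- dim(movie)[1] * dim(movie)[2]
  raw <- matrix(0, n, n_frames)
  for (t in seq_len(n_frames)) {
    fr <- movie[, , t]
    raw[, t] <- rowsum(fr[fg], lab_fg)[, 1] / sizes
  }
  f0 <- apply(raw, 1, stats::quantile, probs = 0.10, names = FALSE)
  f0[f0 == 0] <- 1e-9
  dff <- sweep(sweep(raw, 1, f0, "-"), 1, f0, "/")
  trace_matrix(dff, frame_rate)
}

#' Detect calcium bursts by robust threshold crossing
#'
#' Per neuron, the burst threshold is `median + k_mad * 1.4826 * MAD` of the
#' trace; burst onsets are upward crossings merged within `min_interval_s`;
#' the amplitude is the trace maximum between onsets. A neuron is active
#' when it has at least one burst. Network bursts are runs of
#' `network_bin_s`-wide bins in which at least `network_fraction` of the
#' active neurons burst.
#'
#' @param traces a [trace_matrix()].
#' @param k_mad threshold multiplier (> 0).
#' @param min_interval_s onset merge interval (s).
#' @param network_bin_s,network_fraction network-burst parameters.
#' @return object of class `burst_train`: per-neuron `onsets` (s) and
#'   `amplitudes`, `active` flags, `network_times` (s), `frame_rate`,
#'   `duration`.
#' @export
detect_bursts <- function(traces, k_mad = 3, min_interval_s = 2,
                          network_bin_s = 1, network_fraction = 0.5) {
  stopifnot(inherits(traces, "trace_matrix"), k_mad > 0)
  v <- traces$values
  fr <- traces$frame_rate
  n <- nrow(v); n_frames <- ncol(v)
  duration <- n_frames / fr
  onsets <- vector("list", n)
  amps <- vector("list", n)
  for (i in seq_len(n)) {
    x <- v[i, ]
    # mad() includes the 1.4826 consistency factor; sparse trains can have
    # MAD 0 while carrying real transients, so fall back to the sd scale
    scale <- stats::mad(x)
    if (scale == 0) scale <- stats::sd(x)
    theta <- stats::median(x) + k_mad * scale
    above <- x >= theta
    cross <- which(above & !c(FALSE, above[-n_frames]))
    if (length(cross) == 0L || scale == 0) {
      onsets[[i]] <- numeric(0)
      amps[[i]] <- numeric(0)
      next
    }
    t_on <- (cross - 1) / fr
    keep <- rep(TRUE, length(t_on))
    last <- t_on[1]
    for (k in seq_along(t_on)[-1]) {
      if (t_on[k] - last < min_interval_s) keep[k] <- FALSE else last <- t_on[k]
    }
    t_on <- t_on[keep]
    fr_on <- cross[keep]
    ends <- c(fr_on[-1] - 1L, n_frames)
    amps[[i]] <- vapply(seq_along(fr_on),
                        function(k) max(x[fr_on[k]:ends[k]]), numeric(1))
    onsets[[i]] <- t_on
  }
  active <- vapply(onsets, function(o) length(o) > 0L, logical(1))
  network_times <- numeric(0)
  if (any(active)) {
    n_bins <- ceiling(duration / network_bin_s)
    part <- matrix(FALSE, sum(active), n_bins)
    ai <- 0L
    for (i in which(active)) {
      ai <- ai + 1L
      b <- pmin(floor(onsets[[i]] / network_bin_s) + 1L, n_bins)
      part[ai, b] <- TRUE
    }
    qual <- colMeans(part) >= network_fraction
    if (any(qual)) {
      runs <- rle(qual)
      starts <- cumsum(c(1L, runs$lengths))[seq_along(runs$lengths)]
      network_times <- (starts[runs$values] - 1L) * network_bin_s
    }
  }
  structure(list(onsets = onsets, amplitudes = amps, active = active,
                 network_times = network_times, frame_rate = fr,
                 duration = duration), class = "burst_train")
}

#' Functional descriptor vector of one recording
#'
#' Percent active neurons, mean per-neuron burst frequency and amplitude
#' (over active neurons), network burst frequency, and the burst
#' correlation: the mean off-diagonal entry of the pairwise Pearson
#' correlation matrix of the normalized traces (pairs involving a constant
#' trace contribute 0; missing when fewer than 2 neurons).
#'
#' @param traces a [trace_matrix()].
#' @param bursts a `burst_train` from [detect_bursts()].
#' @return one-row data.frame (functional descriptor class).
#' @export
functional_descriptors <- function(traces, bursts) {
  stopifnot(inherits(traces, "trace_matrix"), inherits(bursts, "burst_train"))
  n <- nrow(traces$values)
  dur <- bursts$duration
  active <- bursts$active
  nb <- vapply(bursts$onsets, length, integer(1))
  burst_corr <- if (n < 2L) NA_real_ else {
    cm <- suppressWarnings(stats::cor(t(traces$values)))
    cm[!is.finite(cm)] <- 0  # constant-trace pairs
    mean(cm[upper.tri(cm)])
  }
  data.frame(
    pct_active = 100 * mean(active),
    burst_freq_hz = if (any(active)) mean(nb[active]) / dur else 0,
    burst_amplitude = if (any(active))
      mean(unlist(bursts$amplitudes[active])) else NA_real_,
    network_burst_freq_hz = length(bursts$network_times) / dur,
    burst_correlation = burst_corr)
}

#' Profile one calcium recording end-to-end
#'
#' @param recording list with `frames` `[H, W, T]`, `reference` `[H, W, Z]`
#'   and `frame_rate` (as produced by [generate_calcium()]).
#' @param config a [calcium_config()].
#' @param metadata optional named list prepended as columns.
#' @return list with `labels`, `traces`, `bursts` and `descriptors`
#'   (one-row data.frame).
#' @export
profile_recording <- function(recording, config = calcium_config(),
                              metadata = list()) {
  labels <- segment_somata(recording$reference, config$soma_threshold,
                           config$min_soma_area)
  if (max(labels) == 0L) stop("no somata detected in reference stack")
  traces <- extract_traces(recording$frames, labels, recording$frame_rate)
  bursts <- detect_bursts(traces, config$k_mad, config$min_interval_s,
                          config$network_bin_s, config$network_fraction)
  desc <- functional_descriptors(traces, bursts)
  if (length(metadata) > 0)
    desc <- cbind(as.data.frame(metadata, stringsAsFactors = FALSE), desc)
  list(labels = labels, traces = traces, bursts = bursts, descriptors = desc)
}
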