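# Spike events -> standardized, Gaussian-smoothed spike-density traces:
# conduction delays, 2-ms binning, z-scoring, kernel smoothing.

#' Density trace container
#'
#' A regularly sampled signal at period `dt` ms with the standardization
#' statistics that produced it. Thin S3 wrapper over a numeric vector.
#'
#' @param values Numeric vector of samples.
#' @param dt Sampling period in ms.
#' @param start Time of the first sample in ms.
#' @param label Stream label (e.g. "EC", "DG", "CA3PC").
#' @param stats Optional list with `mean` and `sd` used for standardization.
#' @return A `density_trace` object.
#' @export
density_trace <- function(values, dt = 2, start = 0, label = "",
                          stats = NULL) {
  if (!all(is.finite(values))) stop("trace values must be finite", call. = FALSE)
  structure(list(values = as.numeric(values), dt = dt, start = start,
                 label = label, stats = stats),
            class = "density_trace")
}

#' @export
length.density_trace <- function(x) length(x$values)

#' @export
print.density_trace <- function(x, ...) {
  cat(sprintf("<density_trace '%s': %d samples @ %g ms, t0 = %g ms>\n",
              x$label, length(x$values), x$dt, x$start))
  invisible(x)
}

trace_values <- function(x) if (inherits(x, "density_trace")) x$values else x

#' Conduction delays from path lengths
#'
#' Latency between a presynaptic spike and the arrival of the postsynaptic
#' potential, computed as path length / propagation velocity. Defaults for
#' the perforant path (EC) and mossy fibers (DG) are 0.27 and 0.32 mm/ms.
#'
#' @param path_lengths Path lengths in mm (>= 0).
#' @param velocity Propagation velocity in mm/ms (> 0).
#' @return Delays in ms (not yet rounded to the sampling grid; rounding to
#'   the nearest bin happens at binning time).
#' @examples
#' conduction_delays(3.2, 0.32)  # 10 ms
#' @export
conduction_delays <- function(path_lengths, velocity) {
  if (length(velocity) != 1 || !is.finite(velocity) || velocity <= 0)
    stop("velocity must be a single positive number", call. = FALSE)
  if (any(path_lengths < 0)) stop("path lengths must be >= 0", call. = FALSE)
  path_lengths / velocity
}

#' Default conduction velocities (mm/ms)
#' @return Named numeric vector with elements `EC` and `DG`.
#' @export
default_velocities <- function() c(EC = 0.27, DG = 0.32)

#' Peristimulus time histogram with conduction delays
#'
#' Counts spikes per time bin after shifting each event by its conduction
#' delay. Bins are half-open `[b*bin, (b+1)*bin)` with time origin 0; delays
#' are rounded to the nearest bin multiple (ties toward +Inf) so sub-bin
#' timing never splits a bin. Events falling outside `[0, duration)` after
#' the shift are dropped (with a message counting them).
#'
#' @param times Spike times in ms.
#' @param delays Delay in ms per spike (scalar or vector matching `times`).
#' @param duration Total duration in ms; must be a multiple of `bin`.
#' @param bin Bin width in ms (default 2).
#' @return Integer vector of counts, length `duration/bin`.
#' @export
spike_histogram <- function(times, delays = 0, duration, bin = 2) {
  nb <- duration / bin
  if (abs(nb - round(nb)) > 1e-9)
    stop("duration must be a multiple of the bin width", call. = FALSE)
  nb <- as.integer(round(nb))
  delays <- bin * floor(delays / bin + 0.5)  # nearest bin, ties toward +Inf
  t <- times + rep_len(delays, length(times))
  idx <- floor(t / bin)
  keep <- idx >= 0 & idx < nb
  if (any(!keep))
    message(sum(!keep), " event(s) outside [0, ", duration, ") dropped")
  counts <- tabulate(idx[keep] + 1L, nbins = nb)
  counts
}

#' Standardize a trace (z-score)
#'
#' Subtracts the mean and divides by the standard deviation. When `stats`
#' are supplied (e.g. the training-segment statistics applied to a held-out
#' segment) they are used unchanged, which prevents leakage across the
#' train/validation split.
#'
#' @param trace Numeric vector or [density_trace()].
#' @param stats Optional list with `mean` and `sd`.
#' @param label Label for the returned trace.
#' @param dt Sampling period in ms.
#' @return A [density_trace()] carrying the statistics that were applied.
#' @export
standardize <- function(trace, stats = NULL, label = "", dt = 2) {
  x <- trace_values(trace)
  if (is.null(stats)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("degenerate signal: zero standard deviation", call. = FALSE)
    stats <- list(mean = mean(x), sd = s)
  }
  density_trace((x - stats$mean) / stats$sd, dt = dt, label = label,
                stats = stats)
}

#' Invert standardization
#' @param trace Numeric vector or [density_trace()] in z-units.
#' @param stats List with `mean` and `sd` (defaults to the trace's own).
#' @return Numeric vector on the original scale.
#' @export
destandardize <- function(trace, stats = NULL) {
  if (is.null(stats)) stats <- trace$stats
  if (is.null(stats)) stop("no standardization stats available", call. = FALSE)
  trace_values(trace) * stats$sd + stats$mean
}

#' Gaussian spike-density smoothing
#'
#' Convolves a (standardized) histogram with a sampled Gaussian kernel of
#' bandwidth `w` ms, truncated at +/- `trunc * w` and renormalized to unit
#' sum so the smoothing is mean-preserving. Edges are zero-padded; output
#' length equals input length. Default bandwidths in this pipeline are
#' 100 ms for EC and 10 ms for DG/CA3 streams.
#'
#' @param trace Numeric vector or [density_trace()].
#' @param w Kernel bandwidth (standard deviation) in ms, > 0.
#' @param dt Sampling period in ms.
#' @param trunc Truncation half-width in multiples of `w` (>= 3).
#' @return A [density_trace()] (stats carried over when present).
#' @export
gaussian_density <- function(trace, w, dt = 2, trunc = 4) {
  if (length(w) != 1 || !is.finite(w) || w <= 0)
    stop("bandwidth w must be positive", call. = FALSE)
  if (trunc < 3) stop("truncation must be at least 3 bandwidths", call. = FALSE)
  x <- trace_values(trace)
  half <- max(1L, as.integer(ceiling(trunc * w / dt)))
  tt <- (-half:half) * dt
  k <- exp(-tt^2 / (2 * w^2))
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(0, half), x, rep(0, half))
  sm <- stats::filter(xp, k, method = "convolution", sides = 2)
  out <- as.numeric(sm[(half + 1):(half + n)])
  density_trace(out, dt = dt,
                start = if (inherits(trace, "density_trace")) trace$start else 0,
                label = if (inherits(trace, "density_trace")) trace$label else "",
                stats = if (inherits(trace, "density_trace")) trace$stats else NULL)
}

#' Full spike-density pipeline for one stream
#'
#' Histogram (with delays) -> standardize -> Gaussian smoothing, the order
#' used throughout: the peristimulus histogram is z-scored before smoothing.
#'
#' @param times Spike times in ms.
#' @param delays Conduction delay(s) in ms.
#' @param duration Duration in ms.
#' @param w Gaussian bandwidth in ms.
#' @param dt Bin width / sampling period in ms.
#' @param stats Optional externally supplied standardization stats.
#' @param label Stream label.
#' @return A [density_trace()].
#' @export
spike_density <- function(times, delays = 0, duration, w, dt = 2,
                          stats = NULL, label = "") {
  h <- spike_histogram(times, delays, duration, bin = dt)
  z <- standardize(h, stats = stats, label = label, dt = dt)
  gaussian_density(z, w = w, dt = dt)
}

#' Read / write spike event tables
#'
#' Delimited text with header `neuron_id,time_ms,population,x_mm,y_mm`
#' (coordinates optional).
#'
#' @param path File path.
#' @return `read_spike_events`: a data.frame of events.
#' @export
read_spike_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("neuron_id", "time_ms", "population")
  if (!all(need %in% names(df)))
    stop("spike event file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$time_ms)) || any(df$time_ms < 0))
    stop("spike times must be finite and >= 0", call. = FALSE)
  df
}

#' @rdname read_spike_events
#' @param events Data.frame of spike events.
#' @export
write_spike_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
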