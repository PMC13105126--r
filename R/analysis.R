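# Kernel-strength quantification and spectral summaries of density traces.

#' Kernel strength (RMS of expansion coefficients)
#'
#' \eqn{\rho = \sqrt{\frac{1}{N}\sum_i k_i^2}} over the kernel's expansion
#' coefficients. Applied to the weights, not to sampled kernel values; for
#' the feedback kernel the zero-padded taps are excluded (the stored
#' coefficient vector holds only the free taps).
#'
#' @param coefficients Nonempty numeric vector of kernel coefficients.
#' @return The strength rho (>= 0).
#' @examples
#' kernel_strength(c(3, 4))  # sqrt(12.5)
#' @export
kernel_strength <- function(coefficients) {
  if (length(coefficients) == 0)
    stop("coefficient vector must be nonempty", call. = FALSE)
  sqrt(mean(coefficients^2))
}

#' Kernel-strength profile across fitted masses
#'
#' Tabulates the strength of each of the four kernels for every fitted
#' mass and summarizes the proximodistal trend per kernel (slope of rho on
#' the mass x-coordinate and the Spearman rank correlation).
#'
#' @param models List of at least two fitted [cnmm_model()]s (or
#'   `fit_result`s, whose `$model` is used).
#' @return List with `table` (mass x, y, kernel, rho) and `gradient`
#'   (kernel, slope_per_mm, spearman).
#' @export
strength_profile <- function(models) {
  models <- lapply(models, function(m) if (inherits(m, "fit_result")) m$model else m)
  if (length(models) < 2)
    stop("at least two fitted masses are required", call. = FALSE)
  rows <- lapply(models, function(m) {
    data.frame(x = m$center[1], y = m$center[2],
               kernel = c("EC", "DG", "coupling", "feedback"),
               rho = c(kernel_strength(m$weights$w_ec),
                       kernel_strength(m$weights$w_dg),
                       kernel_strength(m$weights$w_c),
                       kernel_strength(m$weights$w_b)),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  grad <- do.call(rbind, lapply(split(tab, tab$kernel), function(d) {
    slope <- if (stats::sd(d$x) > 0)
      unname(stats::coef(stats::lm(rho ~ x, data = d))[2]) else NA_real_
    sp <- if (stats::sd(d$x) > 0)
      suppressWarnings(stats::cor(d$x, d$rho, method = "spearman"))
      else NA_real_
    data.frame(kernel = d$kernel[1], slope_per_mm = slope, spearman = sp,
               stringsAsFactors = FALSE)
  }))
  rownames(grad) <- NULL
  list(table = tab, gradient = grad)
}

#' Welch power spectral density with band powers
#'
#' Welch's method: the trace is split into Hann-windowed segments with 50%
#' overlap, per-segment periodograms are averaged, and the theta (4-8 Hz)
#' and beta (13-30 Hz) band powers are integrated from the averaged
#' spectrum. At the 2-ms sampling period the Nyquist frequency is 250 Hz.
#'
#' @param trace Numeric vector or [density_trace()].
#' @param dt Sampling period in ms (taken from a `density_trace` input).
#' @param segment Segment length in samples (default 2048, shortened to the
#'   largest power of two allowing two segments for short traces).
#' @param bands Named list of `c(lo, hi)` frequency bands in Hz.
#' @return List with `freq` (Hz), `power`, `band_power` (named vector) and
#'   `peak_freq` (Hz of the spectrum maximum, excluding DC).
#' @export
spectral_summary <- function(trace, dt = NULL, segment = 2048,
                             bands = list(theta = c(4, 8),
                                          beta = c(13, 30))) {
  if (inherits(trace, "density_trace") && is.null(dt)) dt <- trace$dt
  if (is.null(dt)) dt <- 2
  x <- trace_values(trace)
  n <- length(x)
  segment <- min(segment, 2^floor(log2(n / 2)))
  if (n < 2 * segment || segment < 8)
    stop("trace too short for two Welch segments", call. = FALSE)
  step <- segment %/% 2
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(segment) / (segment + 1))
  starts <- seq(1, n - segment + 1, by = step)
  acc <- numeric(segment %/% 2 + 1)
  for (s in starts) {
    seg <- x[s:(s + segment - 1)]
    seg <- (seg - mean(seg)) * win
    p <- Mod(stats::fft(seg))^2
    acc <- acc + p[seq_len(segment %/% 2 + 1)]
  }
  fs <- 1000 / dt  # Hz
  power <- acc / (length(starts) * sum(win^2) * fs)
  freq <- (0:(segment %/% 2)) * fs / segment
  df <- fs / segment
  band_power <- vapply(bands, function(b) {
    sum(power[freq >= b[1] & freq <= b[2]]) * df
  }, numeric(1))
  peak_freq <- freq[-1][which.max(power[-1])]
  list(freq = freq, power = power, band_power = band_power,
       peak_freq = peak_freq)
}
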