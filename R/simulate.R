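# Synthetic inputs: bounded random exploration trajectories, hexagonal
# grid-cell rate maps, Poisson spike generators, teacher-model datasets for
# recovery benchmarks, and a small end-to-end toy network.

#' Bounded random exploration trajectory
#'
#' Piecewise-constant-velocity path in a square environment: speed,
#' direction and segment duration are drawn uniformly (0-30 cm/s, 0-360
#' degrees, 0-500 ms) and motion that would exit the square is reflected at
#' the walls. Positions are sampled on the 2-ms clock.
#'
#' @param duration Duration in ms (> 0).
#' @param seed Random seed.
#' @param side Environment side length in cm (default 80).
#' @param dt Sampling period in ms.
#' @param start Starting position (defaults to the center).
#' @return A `trajectory` object: data.frame `path` (`t_ms`, `x_cm`,
#'   `y_cm`) plus a `segments` log (speed, direction, duration).
#' @export
random_trajectory <- function(duration, seed = 1L, side = 80, dt = 2,
                              start = c(side / 2, side / 2)) {
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  set.seed(seed)
  n <- as.integer(ceiling(duration / dt))
  x <- numeric(n + 1); y <- numeric(n + 1)
  x[1] <- start[1]; y[1] <- start[2]
  segs <- list()
  t_left <- 0; vx <- 0; vy <- 0
  reflect <- function(p) {
    # fold into [0, side], reflecting at both walls
    p <- p %% (2 * side)
    ifelse(p > side, 2 * side - p, p)
  }
  for (i in seq_len(n)) {
    if (t_left <= 0) {
      speed <- stats::runif(1, 0, 30)
      direc <- stats::runif(1, 0, 360)
      t_left <- stats::runif(1, 0, 500)
      vx <- speed * cos(direc * pi / 180) / 1000  # cm per ms
      vy <- speed * sin(direc * pi / 180) / 1000
      segs[[length(segs) + 1]] <- c(speed_cm_s = speed, direction_deg = direc,
                                    duration_ms = t_left)
    }
    step <- min(dt, t_left)
    x[i + 1] <- reflect(x[i] + vx * step)
    y[i + 1] <- reflect(y[i] + vy * step)
    t_left <- t_left - dt
  }
  structure(list(
    path = data.frame(t_ms = (0:n) * dt, x_cm = x, y_cm = y),
    segments = as.data.frame(do.call(rbind, segs)),
    side = side, dt = dt, seed = seed), class = "trajectory")
}

#' Grid-map parameters
#'
#' A hexagonal firing-rate map built from three cosine gratings rotated in
#' 60-degree increments, passed through the exponential link
#' `g(x) = exp(a (x - b)) - 1` and normalized to the peak rate. The offset
#' constant `b = -3/2` is the minimum of the three-cosine interference
#' pattern, so the link zeroes the map minimum.
#'
#' @param lambda Grid field spacing in cm (> 0).
#' @param theta Orientation offset in degrees.
#' @param offset Spatial offset `c(x, y)` in cm (the map peaks there).
#' @param a Field-width parameter (> 0); larger values sharpen the fields.
#' @param b Offset constant, fixed at -3/2.
#' @param peak Peak firing rate in Hz (default 50).
#' @return A `grid_map_params` object (with the normalization constant
#'   computed by dense-grid evaluation).
#' @export
grid_map_params <- function(lambda, theta = 0, offset = c(0, 0), a = 0.3,
                            b = -1.5, peak = 50) {
  if (lambda <= 0) stop("lambda must be positive", call. = FALSE)
  if (peak <= 0) stop("peak rate must be positive", call. = FALSE)
  if (a <= 0) stop("a must be positive", call. = FALSE)
  p <- structure(list(lambda = lambda, theta = theta, offset = offset,
                      a = a, b = b, peak = peak), class = "grid_map_params")
  p$gmax <- grid_map_gmax(p)
  p
}

# Three-cosine interference sum at positions (matrix n x 2), before the link.
grid_cosine_sum <- function(params, pos) {
  k <- 4 * pi / (sqrt(3) * params$lambda)
  dx <- pos[, 1] - params$offset[1]
  dy <- pos[, 2] - params$offset[2]
  s <- 0
  for (ang in (params$theta + c(0, 60, 120)) * pi / 180)
    s <- s + cos(k * (cos(ang) * dx + sin(ang) * dy))
  s
}

# Unnormalized link maximum over a dense grid (step lambda/100, several
# periods); robust alternative to a closed form. g is monotone, so the
# maximum sits where the cosine sum is maximal (3, attained at the offset),
# but the dense grid keeps this honest for any parameterization.
grid_map_gmax <- function(params) {
  step <- params$lambda / 100
  g <- seq(-1.5 * params$lambda, 1.5 * params$lambda, by = step)
  pos <- as.matrix(expand.grid(x = g + params$offset[1],
                               y = g + params$offset[2]))
  s <- grid_cosine_sum(params, pos)
  max(exp(params$a * (s - params$b)) - 1)
}

#' Grid-cell firing rate at a position
#'
#' @param params [grid_map_params()].
#' @param pos Position `c(x, y)` in cm, or an `n x 2` matrix.
#' @return Firing rate(s) in Hz, normalized so the map maximum equals
#'   `params$peak`.
#' @export
grid_rate <- function(params, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  s <- grid_cosine_sum(params, pos)
  params$peak * (exp(params$a * (s - params$b)) - 1) / params$gmax
}

#' Inhomogeneous Poisson spike times by thinning
#'
#' Candidate spikes are drawn from a homogeneous process at the trace
#' maximum and accepted with probability `rate(t) / max(rate)`.
#'
#' @param rate_trace Nonnegative firing rates in Hz, sampled at `dt`.
#' @param dt Sampling period in ms.
#' @param seed Random seed.
#' @return Sorted spike times in ms (empty for an all-zero trace).
#' @export
inhomogeneous_poisson <- function(rate_trace, dt = 2, seed = 1L) {
  if (any(rate_trace < 0)) stop("rates must be >= 0", call. = FALSE)
  rmax <- max(rate_trace)
  if (rmax == 0) return(numeric(0))
  set.seed(seed)
  duration <- length(rate_trace) * dt
  n_cand <- stats::rpois(1, rmax / 1000 * duration)
  if (n_cand == 0) return(numeric(0))
  t_cand <- sort(stats::runif(n_cand, 0, duration))
  bin <- pmin(floor(t_cand / dt) + 1L, length(rate_trace))
  keep <- stats::runif(n_cand) < rate_trace[bin] / rmax
  t_cand[keep]
}

#' Homogeneous Poisson population (LEC-style noise input)
#'
#' Lateral entorhinal cortex neurons carry non-spatial information and are
#' modeled as independent homogeneous Poisson processes at a mean rate of
#' 5.50 Hz, contributing noise to the system.
#'
#' @param n_neurons Number of neurons (> 0).
#' @param duration Duration in ms (>= 0; zero gives no spikes).
#' @param rate Mean firing rate in Hz (default 5.50).
#' @param seed Random seed.
#' @return Spike-event data.frame (`neuron_id`, `time_ms`, `population`).
#' @export
lec_poisson <- function(n_neurons, duration, rate = 5.5, seed = 1L) {
  if (n_neurons < 1) stop("n_neurons must be positive", call. = FALSE)
  if (duration < 0) stop("duration must be >= 0", call. = FALSE)
  set.seed(seed)
  counts <- stats::rpois(n_neurons, rate / 1000 * duration)
  n_spk <- sum(counts)
  events <- data.frame(
    neuron_id = rep(seq_len(n_neurons), counts),
    time_ms = if (duration > 0) stats::runif(n_spk, 0, duration)
              else numeric(0),
    population = rep("LEC", n_spk), stringsAsFactors = FALSE)
  events[order(events$neuron_id, events$time_ms), , drop = FALSE]
}

#' Teacher specification for recovery benchmarks
#'
#' Bundles a ground-truth model with the recipe for generating its inputs:
#' standardized Gaussian-smoothed white noise per stream (bandwidths
#' matching the density pipeline: 100 ms EC, 10 ms DG/CA3) plus additive
#' Gaussian output noise.
#'
#' @param model A [cnmm_model()] acting as ground truth. Its free-running
#'   dynamics must be bounded on bounded inputs.
#' @param lag_x,lag_y Neighbor-lag grid (mm) of the coupling field.
#' @param bw Named list of smoothing bandwidths in ms.
#' @param noise_sd Additive output-noise standard deviation.
#' @param seed Base seed for input generation.
#' @return A `teacher_spec` object.
#' @export
teacher_spec <- function(model, lag_x = 0, lag_y = 0,
                         bw = list(ec = 100, dg = 10, ca3 = 10),
                         noise_sd = 0, seed = 1L) {
  structure(list(model = model, lag_x = lag_x, lag_y = lag_y, bw = bw,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "teacher_spec")
}

# Standardized smoothed-noise stream on the 2-ms clock.
smoothed_noise <- function(n, w, dt, label = "") {
  z <- stats::rnorm(n)
  sm <- gaussian_density(z, w = w, dt = dt)
  standardize(trace_values(sm), label = label, dt = dt)
}

#' Generate a teacher dataset
#'
#' Input streams are smoothed standardized noise; the reference output is
#' the teacher model run free-running on them, plus optional additive
#' Gaussian noise. Everything needed for recovery scoring is returned.
#'
#' @param spec A [teacher_spec()].
#' @param duration Duration in ms (at least twice the memory window).
#' @return A dataset list (`ec`, `dg`, `field`, `y`, `y_clean`, `dt`,
#'   `spec`) suitable for [fit_mass()].
#' @export
teacher_dataset <- function(spec, duration) {
  model <- spec$model
  dt <- model$static$dt
  if (duration < 2 * model$static$M)
    stop("duration must be at least twice the memory window", call. = FALSE)
  n <- as.integer(round(duration / dt))
  set.seed(spec$seed)
  ec <- smoothed_noise(n, spec$bw$ec, dt, "EC")
  dg <- smoothed_noise(n, spec$bw$dg, dt, "DG")
  nx <- length(spec$lag_x); ny <- length(spec$lag_y)
  vals <- array(0, dim = c(nx, ny, n))
  for (a in seq_len(nx)) for (b in seq_len(ny)) {
    if (spec$lag_x[a] == 0 && spec$lag_y[b] == 0 && !model$include_self) next
    vals[a, b, ] <- trace_values(smoothed_noise(n, spec$bw$ca3, dt))
  }
  field <- coupling_field(spec$lag_x, spec$lag_y, vals)
  inputs <- list(ec = ec, dg = dg, field = field)
  y_clean <- trace_values(predict(model, inputs, mode = "free_running"))
  if (any(!is.finite(y_clean)) || max(abs(y_clean)) > 1e6)
    stop("unstable teacher: free-running output unbounded", call. = FALSE)
  y <- y_clean
  if (spec$noise_sd > 0) y <- y + stats::rnorm(n, sd = spec$noise_sd)
  c(inputs, list(y = density_trace(y, dt = dt, label = "CA3PC"),
                 y_clean = y_clean, dt = dt, spec = spec))
}

#' Rectangular neural-mass grid
#'
#' Mass centers on a regular grid with the default CA3 bin size of 0.2 mm
#' (proximodistal) by 0.5 mm (septotemporal). Bins are half-open on each
#' axis so every neuron maps to at most one mass.
#'
#' @param nx,ny Number of masses along each axis.
#' @param bin Bin size `c(x, y)` in mm.
#' @param origin Lower-left corner of the first bin, in mm.
#' @return A `mass_grid` object with a data.frame of centers.
#' @export
mass_grid <- function(nx, ny, bin = c(0.2, 0.5), origin = c(0, 0)) {
  centers <- expand.grid(
    x = origin[1] + (seq_len(nx) - 0.5) * bin[1],
    y = origin[2] + (seq_len(ny) - 0.5) * bin[2])
  centers$mass <- seq_len(nrow(centers))
  structure(list(centers = centers, nx = nx, ny = ny, bin = bin,
                 origin = origin), class = "mass_grid")
}

#' Map neuron positions to masses
#'
#' @param grid A [mass_grid()].
#' @param pos `n x 2` matrix of positions in mm.
#' @return Integer mass index per position (`NA` outside the grid).
#' @export
assign_masses <- function(grid, pos) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 2)
  ix <- floor((pos[, 1] - grid$origin[1]) / grid$bin[1])
  iy <- floor((pos[, 2] - grid$origin[2]) / grid$bin[2])
  ok <- ix >= 0 & ix < grid$nx & iy >= 0 & iy < grid$ny
  out <- rep(NA_integer_, nrow(pos))
  out[ok] <- ix[ok] + 1L + iy[ok] * grid$nx
  out
}

#' CA3 discretization bookkeeping
#'
#' Census of the modeled network: population sizes and the number of masses
#' the CA3 extent is divided into, with the implied mean cells per mass.
#'
#' @param n_pyramidal,n_basket CA3 population sizes (1/10th-scale network).
#' @param n_masses Number of neural masses tiling CA3.
#' @return List with the inputs and `pyramidal_per_mass`,
#'   `basket_per_mass` (rounded means).
#' @export
ca3_census <- function(n_pyramidal = 25000, n_basket = 10000,
                       n_masses = 304) {
  list(n_pyramidal = n_pyramidal, n_basket = n_basket, n_masses = n_masses,
       pyramidal_per_mass = round(n_pyramidal / n_masses),
       basket_per_mass = round(n_basket / n_masses))
}

#' Toy spiking network for end-to-end pipeline tests
#'
#' Grid-cell-driven EC spikes from a shared exploration trajectory,
#' rate-modulated DG spikes, and per-mass CA3 spikes whose rates follow a
#' smoothed mixture of the EC/DG drive (configurable coupling). Neuron
#' positions are included so conduction delays can be computed.
#'
#' @param grid A [mass_grid()] for CA3.
#' @param duration Duration in ms.
#' @param n_ec,n_dg Neurons per input population.
#' @param ca3_per_mass CA3 pyramidal cells per mass.
#' @param coupling Weight of the shared drive in CA3 rates (0-1).
#' @param base_rate Baseline CA3/DG rate in Hz.
#' @param seed Random seed.
#' @return List with `events` (spike data.frame with positions), `grid`,
#'   `trajectory` and `membership` (CA3 neuron -> mass).
#' @export
toy_network_dataset <- function(grid, duration, n_ec = 20, n_dg = 20,
                                ca3_per_mass = 10, coupling = 0.6,
                                base_rate = 8, seed = 1L) {
  set.seed(seed)
  traj <- random_trajectory(duration, seed = seed + 1L)
  pos_t <- as.matrix(traj$path[-1, c("x_cm", "y_cm")])
  n <- nrow(pos_t)
  dt <- traj$dt
  events <- list()
  drive <- numeric(n)
  for (i in seq_len(n_ec)) {
    gp <- grid_map_params(lambda = stats::runif(1, 30, 60),
                          theta = stats::runif(1, 0, 60),
                          offset = stats::runif(2, 0, 80))
    rate <- grid_rate(gp, pos_t)
    drive <- drive + rate / n_ec
    st <- inhomogeneous_poisson(rate, dt = dt, seed = seed + 100L + i)
    if (length(st))
      events[[length(events) + 1]] <- data.frame(
        neuron_id = i, time_ms = st, population = "EC",
        x_mm = stats::runif(1, 0, grid$nx * grid$bin[1]),
        y_mm = stats::runif(1, 0, grid$ny * grid$bin[2]))
  }
  drive_n <- drive / max(drive)
  for (i in seq_len(n_dg)) {
    rate <- base_rate * (1 - coupling + coupling * drive_n * 2)
    st <- inhomogeneous_poisson(rate, dt = dt, seed = seed + 200L + i)
    if (length(st))
      events[[length(events) + 1]] <- data.frame(
        neuron_id = i, time_ms = st, population = "DG",
        x_mm = stats::runif(1, 0, grid$nx * grid$bin[1]),
        y_mm = stats::runif(1, 0, grid$ny * grid$bin[2]))
  }
  n_ca3 <- ca3_per_mass * nrow(grid$centers)
  membership <- rep(grid$centers$mass, each = ca3_per_mass)
  for (i in seq_len(n_ca3)) {
    m <- membership[i]
    cx <- grid$centers$x[m]; cy <- grid$centers$y[m]
    rate <- base_rate * (1 - coupling + coupling * drive_n * 2)
    st <- inhomogeneous_poisson(rate, dt = dt, seed = seed + 300L + i)
    if (length(st))
      events[[length(events) + 1]] <- data.frame(
        neuron_id = i, time_ms = st, population = "CA3PC",
        x_mm = cx + stats::runif(1, -grid$bin[1] / 2, grid$bin[1] / 2),
        y_mm = cy + stats::runif(1, -grid$bin[2] / 2, grid$bin[2] / 2))
  }
  list(events = do.call(rbind, events), grid = grid, trajectory = traj,
       membership = membership, dt = dt, duration = duration)
}

#' Random stable teacher model
#'
#' Draws Gaussian kernel weights for a ground-truth model, scaling each
#' block to a target kernel strength. The feedback coefficients are scaled
#' so their absolute sum stays below `feedback_gain` < 1, which keeps the
#' free-running autoregression a contraction and the teacher bounded on
#' bounded inputs.
#'
#' @param static [static_meta()].
#' @param meta [meta_params()].
#' @param lag_x,lag_y Neighbor-lag grid (mm) the teacher couples over.
#' @param gains Named list of target kernel strengths for `ec`, `dg`, `c`.
#' @param feedback_gain Bound on the L1 norm of the feedback kernel.
#' @param seed Random seed.
#' @param include_self Include the (0, 0) coupling lag.
#' @return A [cnmm_model()] usable as the ground truth in a
#'   [teacher_spec()].
#' @export
random_teacher <- function(static, meta, lag_x = 0, lag_y = 0,
                           gains = list(ec = 1, dg = 1, c = 0.5),
                           feedback_gain = 0.6, seed = 1L,
                           include_self = FALSE) {
  set.seed(seed)
  cp <- static$coupling
  n_ec <- static$ec$nt * static$ec$pt
  n_dg <- static$dg$nt * static$dg$pt
  n_c <- cp$nx * cp$px * cp$ny * cp$py * cp$nt * cp$pt
  n_b <- static$taps - meta$n_delays
  scale_to <- function(w, rho) w * rho / sqrt(mean(w^2))
  w_ec <- scale_to(stats::rnorm(n_ec), gains$ec)
  w_dg <- scale_to(stats::rnorm(n_dg), gains$dg)
  w_c <- scale_to(stats::rnorm(n_c), gains$c)
  w_b <- stats::rnorm(n_b) * exp(-(seq_len(n_b) - 1) / 10)
  w_b <- w_b * feedback_gain / sum(abs(w_b))
  cnmm_model(static, meta,
             kernel_weights(w_ec, w_dg, w_c, w_b),
             include_self = include_self)
}
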