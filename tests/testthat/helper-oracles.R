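# Independent oracles and small fixtures shared across tests.

# Explicit closed-form discrete orthonormal Laguerre function with
# log-domain binomial coefficients; independent of the package's recurrence.
laguerre_explicit <- function(count, alpha, taps) {
  la <- log(alpha); l1a <- log1p(-alpha)
  out <- matrix(0, count, taps)
  for (n in 0:(count - 1)) {
    for (tau in 0:(taps - 1)) {
      ks <- 0:min(n, tau)
      terms <- (-1)^ks * exp(lchoose(tau, ks) + lchoose(n, ks) +
                               (n - ks) * la + ks * l1a)
      out[n + 1, tau + 1] <- alpha^((tau - n) / 2) * sqrt(1 - alpha) *
        sum(terms)
    }
  }
  out
}

# Direct O(T * taps) causal convolution sum.
direct_conv <- function(x, k) {
  n <- length(x)
  out <- numeric(n)
  for (t in seq_len(n)) {
    taus <- 0:min(length(k) - 1, t - 1)
    out[t] <- sum(k[taus + 1] * x[t - taus])
  }
  out
}

# Naive nested-loop evaluation of the full output equation: every kernel
# contribution summed term by term at each time point. Feedback input is
# the reference (teacher-forced) or the accumulating own output.
naive_predict <- function(model, inputs, reference = NULL,
                          mode = "teacher_forced") {
  st <- model$static
  fld <- inputs$field
  bases <- cnmm:::model_bases(st, model$meta,
                              if (is.null(fld)) 0 else fld$lag_x,
                              if (is.null(fld)) 0 else fld$lag_y)
  k_ec <- assemble_temporal_kernel(model$weights$w_ec, bases$ec)
  k_dg <- assemble_temporal_kernel(model$weights$w_dg, bases$dg)
  Kc <- assemble_coupling_kernel(model$weights$w_c, bases$tensor)
  kb <- feedback_kernel(model$weights$w_b, model$meta$n_delays, st$taps)
  u_ec <- cnmm:::trace_values(inputs$ec)
  u_dg <- cnmm:::trace_values(inputs$dg)
  n <- length(u_ec); taps <- st$taps
  lx <- if (is.null(fld)) numeric(0) else fld$lag_x[bases$active_x]
  ly <- if (is.null(fld)) numeric(0) else fld$lag_y[bases$active_y]
  v <- numeric(n)
  for (t in seq_len(n)) {
    acc <- 0
    for (tau in 0:min(taps - 1, t - 1)) {
      acc <- acc + k_ec[tau + 1] * u_ec[t - tau] +
        k_dg[tau + 1] * u_dg[t - tau]
      fb_in <- if (mode == "teacher_forced") reference else v
      if (t - 1 - tau >= 1) acc <- acc + kb[tau + 1] * fb_in[t - 1 - tau]
      if (length(lx)) {
        for (a in seq_along(lx)) for (b in seq_along(ly)) {
          if (!model$include_self && lx[a] == 0 && ly[b] == 0) next
          acc <- acc + Kc[a, b, tau + 1] *
            fld$values[bases$active_x[a], bases$active_y[b], t - tau]
        }
      }
    }
    v[t] <- acc
  }
  v
}

# Small, fast teacher configuration: 50-tap memory window, 3x3 neighbor
# grid, used by recovery and oracle tests.
small_static <- function() {
  static_meta(ec = list(nt = 3, pt = 2), dg = list(nt = 3, pt = 2),
              coupling = list(nt = 2, pt = 2, nx = 2, px = 1,
                              ny = 2, py = 1),
              M = 100, dt = 2)
}

small_meta <- function(n_delays = 5) {
  meta_params(alpha_ec = 0.3, alpha_dg = 0.5, alpha_c = 0.4,
              rx = 0.45, ry = 1.1, n_delays = n_delays)
}

small_teacher <- function(seed = 42L, noise_sd = 0, duration = 8000) {
  lag_x <- c(-0.2, 0, 0.2); lag_y <- c(-0.5, 0, 0.5)
  model <- random_teacher(small_static(), small_meta(), lag_x, lag_y,
                          seed = seed)
  spec <- teacher_spec(model, lag_x, lag_y, noise_sd = noise_sd,
                       seed = seed + 1L)
  teacher_dataset(spec, duration)
}
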