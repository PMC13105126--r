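# Model assembly and simulation: the four kernels (EC, DG, coupling,
# feedback) and the convolutional output equation in teacher-forced or
# free-running mode.

#' Learnable metaparameters
#'
#' The six structural parameters searched by particle-swarm optimization:
#' one Laguerre decay per feedforward kernel, the two spatial extents of the
#' coupling kernel and the feedback zero-padding.
#'
#' @param alpha_ec,alpha_dg,alpha_c Laguerre decay parameters in (0, 1) for
#'   the EC, DG and coupling kernels.
#' @param rx,ry Coupling spatial extents in mm (> 0), proximodistal and
#'   septotemporal.
#' @param n_delays Number of leading zero taps of the feedback kernel
#'   (integer >= 0), i.e. the feedback delay in units of the sampling period.
#' @return A `meta_params` object.
#' @export
meta_params <- function(alpha_ec, alpha_dg, alpha_c, rx, ry, n_delays) {
  for (a in c(alpha_ec, alpha_dg, alpha_c))
    if (!is.finite(a) || a <= 0 || a >= 1)
      stop("alpha values must lie strictly inside (0, 1)", call. = FALSE)
  if (rx <= 0 || ry <= 0) stop("rx and ry must be positive", call. = FALSE)
  if (n_delays < 0 || n_delays != round(n_delays))
    stop("n_delays must be a nonnegative integer", call. = FALSE)
  structure(list(alpha_ec = alpha_ec, alpha_dg = alpha_dg, alpha_c = alpha_c,
                 rx = rx, ry = ry, n_delays = as.integer(n_delays)),
            class = "meta_params")
}

#' Kernel weight container
#'
#' Flat weight vectors in the documented ordering: temporal kernels n-major
#' (order slowest, power fastest); coupling weights ordered
#' `(nx, px, ny, py, nt, pt)` with `pt` fastest; feedback weights are the
#' free (non-padded) taps only.
#'
#' @param w_ec,w_dg Temporal kernel weights, length `nt * pt` each.
#' @param w_c Coupling weights, length `nx*px*ny*py*nt*pt`.
#' @param w_b Feedback coefficients, length `taps - n_delays`.
#' @return A `kernel_weights` object.
#' @export
kernel_weights <- function(w_ec, w_dg, w_c, w_b) {
  for (w in list(w_ec, w_dg, w_c, w_b))
    if (any(!is.finite(w))) stop("weights must be finite", call. = FALSE)
  structure(list(w_ec = as.numeric(w_ec), w_dg = as.numeric(w_dg),
                 w_c = as.numeric(w_c), w_b = as.numeric(w_b)),
            class = "kernel_weights")
}

#' Convolutional neural mass model for one mass
#'
#' @param static [static_meta()] block.
#' @param meta [meta_params()] block.
#' @param weights [kernel_weights()] block.
#' @param center Mass center `(x, y)` in mm.
#' @param stats Named list of per-stream standardization stats.
#' @param target `"spike_density"` or `"layer_current"`.
#' @param include_self Whether the coupling convolution includes the (0, 0)
#'   spatial lag. Defaults to `FALSE`: the mass's own recurrence is carried
#'   by the feedback kernel, so including the self lag would double-count it.
#' @return A `cnmm_model` object.
#' @export
cnmm_model <- function(static, meta, weights, center = c(0, 0),
                       stats = list(),
                       target = c("spike_density", "layer_current"),
                       include_self = FALSE) {
  target <- match.arg(target)
  if (meta$n_delays >= static$taps)
    stop("n_delays must be smaller than the number of taps", call. = FALSE)
  structure(list(static = static, meta = meta, weights = weights,
                 center = center, stats = stats, target = target,
                 include_self = include_self, format_version = 1L),
            class = "cnmm_model")
}

# Per-metaparameter basis sets shared by prediction and design-matrix
# construction. lag_x/lag_y are spatial offsets (mm) of the neighbor grid in
# Eq-8 orientation: the field slice at lag (i, j) holds the activity of the
# mass at (x0 - i, y0 - j). Lags outside the extents rx/ry are masked here.
model_bases <- function(static, meta, lag_x, lag_y) {
  taps <- static$taps
  ec <- powered_basis(laguerre_basis(static$ec$nt, meta$alpha_ec, taps),
                      static$ec$pt)
  dg <- powered_basis(laguerre_basis(static$dg$nt, meta$alpha_dg, taps),
                      static$dg$pt)
  active_x <- which(abs(lag_x) <= meta$rx + 1e-12)
  active_y <- which(abs(lag_y) <= meta$ry + 1e-12)
  cp <- static$coupling
  sx <- powered_basis(chebyshev_basis(cp$nx, meta$rx, lag_x[active_x]), cp$px)
  sy <- powered_basis(chebyshev_basis(cp$ny, meta$ry, lag_y[active_y]), cp$py)
  st <- powered_basis(laguerre_basis(cp$nt, meta$alpha_c, taps), cp$pt)
  list(ec = ec, dg = dg, sx = sx, sy = sy, st = st,
       tensor = coupling_term_tensor(sx, sy, st),
       active_x = active_x, active_y = active_y, taps = taps)
}

#' Assemble a temporal kernel from weights and a powered basis
#'
#' \eqn{K(\tau) = \sum_{n,p} w_{n,p} L_n(\tau)^p}.
#'
#' @param w Weight vector, one per basis-power term.
#' @param powered A [powered_basis()] matrix.
#' @return Numeric kernel of length `taps`.
#' @export
assemble_temporal_kernel <- function(w, powered) {
  if (length(w) != nrow(powered))
    stop("weight count must equal the number of basis-power terms",
         call. = FALSE)
  as.numeric(crossprod(powered, w))
}

#' Assemble the 3-D coupling kernel
#'
#' Weighted sum of separable outer-product terms, evaluated at the masked
#' neighbor lags.
#'
#' @param w Coupling weight vector (one per tensor term).
#' @param tensor A [coupling_term_tensor()].
#' @return Array of dim `(n_lags_x, n_lags_y, taps)`.
#' @export
assemble_coupling_kernel <- function(w, tensor) {
  if (length(w) != tensor$n_terms)
    stop("weight count must equal the tensor term count", call. = FALSE)
  nx <- ncol(tensor$sx); ny <- ncol(tensor$sy); nt <- ncol(tensor$st)
  idx <- tensor$index
  K <- array(0, dim = c(nx, ny, nt))
  # group by temporal term: K[a,b,.] = sum_q S_q[a,b] * st[q,.] where S_q is
  # the spatial map accumulated from all terms sharing temporal factor q
  for (q in seq_len(nrow(tensor$st))) {
    sel <- which(idx$t == q & w != 0)
    if (length(sel) == 0) next
    S <- matrix(0, nx, ny)
    for (k in sel)
      S <- S + w[k] * outer(tensor$sx[idx$x[k], ], tensor$sy[idx$y[k], ])
    K <- K + outer(S, tensor$st[q, ])
  }
  K
}

#' Feedback (autoregressive) kernel
#'
#' `n_delays` exact zeros followed by the free coefficients; total length
#' equals the memory window in taps.
#'
#' @param coeffs Free coefficients.
#' @param n_delays Leading zero taps.
#' @param taps Total kernel length; must equal `n_delays + length(coeffs)`.
#' @return Numeric kernel of length `taps`.
#' @export
feedback_kernel <- function(coeffs, n_delays, taps) {
  if (n_delays + length(coeffs) != taps)
    stop("n_delays + length(coeffs) must equal taps", call. = FALSE)
  c(rep(0, n_delays), as.numeric(coeffs))
}

# Causal FIR convolution y[t] = sum_{tau=0}^{K-1} k[tau] x[t - tau], zero
# pre-history, output length = length(x). FFT-based.
causal_conv <- function(x, k) {
  nx <- length(x); nk <- length(k)
  # pad to a 5-smooth length: mixed-radix FFTs degrade badly on lengths
  # with large prime factors
  n <- stats::nextn(nx + nk - 1, c(2, 3, 5))
  X <- stats::fft(c(x, rep(0, n - nx)))
  K <- stats::fft(c(k, rep(0, n - nk)))
  out <- Re(stats::fft(X * K, inverse = TRUE)) / n
  out[seq_len(nx)]
}

#' Neighbor-field container for the coupling input
#'
#' @param lag_x,lag_y Spatial lags in mm (Eq-8 orientation: slice `(a, b)`
#'   is the activity of the mass at `x0 - lag_x[a]`, `y0 - lag_y[b]`).
#' @param values Array `(length(lag_x), length(lag_y), T)` of spike density;
#'   masses missing from the grid are all-zero slices.
#' @return A `coupling_field` object.
#' @export
coupling_field <- function(lag_x, lag_y, values) {
  stopifnot(length(dim(values)) == 3,
            dim(values)[1] == length(lag_x),
            dim(values)[2] == length(lag_y))
  structure(list(lag_x = lag_x, lag_y = lag_y, values = values),
            class = "coupling_field")
}

# Feedforward part of the output: EC + DG + coupling convolutions.
# Returns a numeric vector of length T.
feedforward_sum <- function(model, inputs, bases) {
  u_ec <- trace_values(inputs$ec); u_dg <- trace_values(inputs$dg)
  if (length(u_ec) != length(u_dg))
    stop("input traces must share one clock", call. = FALSE)
  k_ec <- assemble_temporal_kernel(model$weights$w_ec, bases$ec)
  k_dg <- assemble_temporal_kernel(model$weights$w_dg, bases$dg)
  out <- causal_conv(u_ec, k_ec) + causal_conv(u_dg, k_dg)
  fld <- inputs$field
  if (!is.null(fld) && length(model$weights$w_c) > 0) {
    Kc <- assemble_coupling_kernel(model$weights$w_c, bases$tensor)
    lx <- fld$lag_x[bases$active_x]; ly <- fld$lag_y[bases$active_y]
    for (a in seq_along(bases$active_x)) {
      for (b in seq_along(bases$active_y)) {
        if (!model$include_self && lx[a] == 0 && ly[b] == 0) next
        u <- fld$values[bases$active_x[a], bases$active_y[b], ]
        if (length(u) != length(u_ec))
          stop("coupling field must share the input clock", call. = FALSE)
        if (any(u != 0)) out <- out + causal_conv(u, Kc[a, b, ])
      }
    }
  }
  out
}

#' Compute the model output
#'
#' Sums the four kernel contributions: EC and DG temporal convolutions, the
#' 3-D coupling convolution over neighboring masses, and the feedback
#' convolution against either the reference output delayed by one sample
#' (teacher-forced) or the model's own history (free-running). Inputs before
#' t = 0 are zero, so the first `taps` samples are burn-in and carried as an
#' attribute.
#'
#' @param object A [cnmm_model()].
#' @param inputs List with `ec`, `dg` (numeric or [density_trace()]) and
#'   optionally `field` (a [coupling_field()]).
#' @param mode `"teacher_forced"` (requires `reference`) or `"free_running"`.
#' @param reference Reference output trace for teacher forcing.
#' @param ... Unused.
#' @return A [density_trace()] with attribute `burn_in = taps`.
#' @export
predict.cnmm_model <- function(object, inputs,
                               mode = c("teacher_forced", "free_running"),
                               reference = NULL, ...) {
  mode <- match.arg(mode)
  fld <- inputs$field
  lag_x <- if (is.null(fld)) 0 else fld$lag_x
  lag_y <- if (is.null(fld)) 0 else fld$lag_y
  bases <- model_bases(object$static, object$meta, lag_x, lag_y)
  ff <- feedforward_sum(object, inputs, bases)
  taps <- bases$taps
  kb <- feedback_kernel(object$weights$w_b, object$meta$n_delays, taps)
  n <- length(ff)
  if (mode == "teacher_forced") {
    if (is.null(reference))
      stop("teacher-forced mode requires a reference trace", call. = FALSE)
    r <- trace_values(reference)
    if (length(r) != n) stop("reference length mismatch", call. = FALSE)
    r_lag <- c(0, r[-n])  # v(t - dt)
    v <- ff + causal_conv(r_lag, kb)
  } else {
    v <- numeric(n)
    if (all(kb == 0)) {
      v <- ff
    } else {
      kbr <- rev(kb)
      vp <- numeric(n + taps)  # taps zeros of pre-history
      for (t in seq_len(n)) {
        v[t] <- ff[t] + sum(kbr * vp[t:(t + taps - 1)])
        vp[t + taps] <- v[t]
      }
    }
  }
  out <- density_trace(v, dt = object$static$dt, label = "prediction")
  attr(out, "burn_in") <- taps
  out
}

#' Pearson correlation between prediction and reference
#'
#' Computed on the post-burn-in segment only.
#'
#' @param pred,ref Traces of equal length.
#' @param burn_in Number of leading samples to exclude (typically `taps`).
#' @return The correlation coefficient R.
#' @export
correlation_score <- function(pred, ref, burn_in = 0) {
  p <- trace_values(pred); r <- trace_values(ref)
  if (length(p) != length(r)) stop("length mismatch", call. = FALSE)
  if (burn_in >= length(p)) stop("burn-in leaves no samples", call. = FALSE)
  keep <- (burn_in + 1):length(p)
  p <- p[keep]; r <- r[keep]
  if (stats::sd(p) == 0 || stats::sd(r) == 0)
    stop("degenerate signal: zero variance on the retained segment",
         call. = FALSE)
  stats::cor(p, r)
}
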