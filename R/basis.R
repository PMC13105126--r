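# Temporal (Laguerre) and spatial (Chebyshev) basis construction, elementwise
# power expansion, and the separable 3-D term set for the coupling kernel.

#' Static metaparameters of a convolutional neural mass model
#'
#' Bundles the fixed structural choices of the model: per-kernel basis orders
#' and maximum powers, the memory window and the sampling period. These are
#' set once and not searched during optimization (unlike [meta_params()]).
#'
#' @param ec,dg Lists with elements `nt` (Laguerre basis count) and `pt`
#'   (maximum power) for the entorhinal-cortex and dentate-gyrus kernels.
#' @param coupling List with `nt`, `pt` (temporal), `nx`, `px` (proximodistal
#'   Chebyshev count/power) and `ny`, `py` (septotemporal).
#' @param M Memory window in ms. Must be a positive integer multiple of `dt`.
#' @param dt Sampling period in ms.
#' @return An object of class `static_meta`. `$taps` is `M/dt`.
#' @examples
#' sm <- static_meta()
#' sm$taps
#' @export
static_meta <- function(ec = list(nt = 8, pt = 5),
                        dg = list(nt = 8, pt = 5),
                        coupling = list(nt = 3, pt = 3, nx = 4, px = 3,
                                        ny = 4, py = 3),
                        M = 1000, dt = 2) {
  for (blk in list(ec, dg, coupling)) {
    counts <- unlist(blk)
    if (any(counts < 1) || any(counts != round(counts)))
      stop("basis counts and powers must be positive integers", call. = FALSE)
  }
  if (M <= 0 || dt <= 0) stop("M and dt must be positive", call. = FALSE)
  taps <- M / dt
  if (abs(taps - round(taps)) > 1e-9)
    stop("M must be an integer multiple of dt", call. = FALSE)
  structure(list(ec = ec, dg = dg, coupling = coupling,
                 M = M, dt = dt, taps = as.integer(round(taps))),
            class = "static_meta")
}

#' Discrete orthonormal Laguerre basis
#'
#' Builds the first `count` discrete-time orthonormal Laguerre functions with
#' decay parameter `alpha`, evaluated at lags 0 .. `taps - 1`. Row `n + 1`
#' holds the order-`n` function (order 0 first). Computed with the stable
#' two-term recurrence
#' \deqn{L_n(\tau) = \sqrt{\alpha}\,L_n(\tau-1) + \sqrt{\alpha}\,L_{n-1}(\tau)
#'   - L_{n-1}(\tau-1)}
#' seeded by \eqn{L_0(\tau) = \sqrt{1-\alpha}\,\alpha^{\tau/2}}, which avoids
#' the binomial overflow of the closed form at large lag counts.
#'
#' Over a support long enough for the exponential envelope to die out the
#' functions are orthonormal: their Gram matrix is the identity.
#'
#' @param count Number of basis functions (orders 0 .. count-1).
#' @param alpha Decay parameter, strictly inside (0, 1). Larger values decay
#'   more slowly and reach further back in time.
#' @param taps Number of time lags.
#' @return A `temporal_basis` object: list with `alpha` and `values`
#'   (`count` x `taps` matrix).
#' @examples
#' b <- laguerre_basis(4, 0.6, 500)
#' max(abs(tcrossprod(b$values) - diag(4)))  # ~ 0
#' @export
laguerre_basis <- function(count, alpha, taps) {
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)", call. = FALSE)
  if (count < 1 || taps < 1)
    stop("count and taps must be >= 1", call. = FALSE)
  count <- as.integer(count); taps <- as.integer(taps)
  sa <- sqrt(alpha)
  values <- matrix(0, count, taps)
  values[1, ] <- sqrt(1 - alpha) * sa^(seq_len(taps) - 1)
  if (count > 1) {
    for (n in 2:count) {
      prev <- values[n - 1, ]
      cur <- numeric(taps)
      cur[1] <- sa * prev[1]
      if (taps > 1)
        for (t in 2:taps) cur[t] <- sa * cur[t - 1] + sa * prev[t] - prev[t - 1]
      values[n, ] <- cur
    }
  }
  structure(list(alpha = alpha, values = values), class = "temporal_basis")
}

#' Scaled Chebyshev spatial basis
#'
#' Chebyshev polynomials of the first kind rescaled from \eqn{[-1, 1]} to the
#' physical extent \eqn{[-r, r]} (mm), evaluated at the supplied spatial lags:
#' \deqn{T_{n,r}(x) = \sum_{k=0}^{\lfloor n/2\rfloor} \binom{n}{2k}
#'   \frac{x^{n-2k}(x^2 - r^2)^k}{r^n}.}
#' Order 0 is identically 1 and every order equals 1 at `x = r`.
#'
#' @param count Number of basis functions (orders 0 .. count-1).
#' @param r Spatial extent in mm (> 0).
#' @param lags Evaluation offsets in mm; all must satisfy `|lag| <= r`
#'   (callers mask out-of-range masses before evaluation).
#' @return A `spatial_basis` object: list with `r`, `lags` and `values`
#'   (`count` x `length(lags)` matrix).
#' @examples
#' chebyshev_basis(3, r = 1, lags = c(-1, 0, 1))$values
#' @export
chebyshev_basis <- function(count, r, lags) {
  if (length(r) != 1 || !is.finite(r) || r <= 0)
    stop("r must be a positive spatial extent", call. = FALSE)
  if (count < 1) stop("count must be >= 1", call. = FALSE)
  if (any(abs(lags) > r + 1e-12))
    stop("all lags must lie within [-r, r]; mask out-of-range masses first",
         call. = FALSE)
  count <- as.integer(count)
  x <- lags / r  # reduce to the classical [-1, 1] domain
  values <- matrix(0, count, length(lags))
  for (n in 0:(count - 1)) {
    ks <- 0:(n %/% 2)
    row <- rep(0, length(x))
    for (k in ks) row <- row + choose(n, 2 * k) * x^(n - 2 * k) * (x^2 - 1)^k
    values[n + 1, ] <- row
  }
  structure(list(r = r, lags = lags, values = values), class = "spatial_basis")
}

#' Elementwise power expansion of a basis
#'
#' Expands a basis of `count` functions into `count * P` terms, where term
#' `(n, p)` is the elementwise p-th power of basis function `n`. Terms are
#' ordered n-major (order varies slowest, power fastest), the same ordering
#' used for serialized weight vectors.
#'
#' @param basis A [laguerre_basis()] or [chebyshev_basis()] object.
#' @param P Maximum power (>= 1). `P = 1` returns the basis rows unchanged.
#' @return A matrix with `count * P` rows and an `index` attribute: a
#'   data.frame with columns `n` (0-based order) and `p` (power).
#' @export
powered_basis <- function(basis, P) {
  if (P < 1 || P != round(P)) stop("P must be a positive integer", call. = FALSE)
  v <- basis$values
  count <- nrow(v)
  out <- matrix(0, count * P, ncol(v))
  idx <- data.frame(n = integer(count * P), p = integer(count * P))
  row <- 0L
  for (n in seq_len(count)) {
    for (p in seq_len(P)) {
      row <- row + 1L
      out[row, ] <- if (p == 1) v[n, ] else v[n, ]^p
      idx$n[row] <- n - 1L
      idx$p[row] <- p
    }
  }
  attr(out, "index") <- idx
  out
}

#' Separable 3-D term set for the coupling kernel
#'
#' The spatio-temporal coupling kernel is a weighted sum of outer products
#' of one proximodistal spatial term, one septotemporal spatial term and one
#' temporal term. Terms are kept in separable (factored) form; use
#' [coupling_term()] to materialize a single 3-D array when needed.
#'
#' Term ordering is nx-major: `(nx, px, ny, py, nt, pt)` with `pt` varying
#' fastest, matching the serialized coupling weight vector.
#'
#' @param sx Powered spatial set for the proximodistal axis
#'   ([powered_basis()] of a [chebyshev_basis()]).
#' @param sy Powered spatial set for the septotemporal axis.
#' @param st Powered temporal set ([powered_basis()] of a
#'   [laguerre_basis()]).
#' @return A `coupling_tensor` object with the three factor matrices, the
#'   term `index` data.frame and `n_terms = nrow(sx) * nrow(sy) * nrow(st)`.
#' @export
coupling_term_tensor <- function(sx, sy, st) {
  if (nrow(sx) == 0 || nrow(sy) == 0 || nrow(st) == 0)
    stop("all three powered sets must be nonempty", call. = FALSE)
  # pt fastest, then nt block, then py, ny, px, nx
  grid <- expand.grid(t = seq_len(nrow(st)), y = seq_len(nrow(sy)),
                      x = seq_len(nrow(sx)))
  grid <- grid[, c("x", "y", "t")]
  structure(list(sx = sx, sy = sy, st = st, index = grid,
                 n_terms = nrow(grid)),
            class = "coupling_tensor")
}

#' Materialize one coupling term as a 3-D array
#'
#' @param tensor A [coupling_term_tensor()] object.
#' @param k Term index (1 .. `tensor$n_terms`).
#' @return Array of dim `(n_lags_x, n_lags_y, taps)` equal to the outer
#'   product of the three 1-D factors.
#' @export
coupling_term <- function(tensor, k) {
  if (k < 1 || k > tensor$n_terms) stop("term index out of range", call. = FALSE)
  i <- tensor$index[k, ]
  outer(outer(tensor$sx[i$x, ], tensor$sy[i$y, ]), tensor$st[i$t, ])
}
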