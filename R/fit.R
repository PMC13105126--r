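# Weight estimation and metaparameter search: linear-in-weights design
# matrix, ridge regression, global-best particle swarm, and the per-mass
# nested fit.

#' Fitting configuration
#'
#' Defaults follow the reference training recipe: ridge strength 10,
#' chronological 80/20 train/validation split, 200 particles with inertia
#' 0.25, cognitive weight 2.0 and social weight 1.0, and a 140-generation
#' budget.
#'
#' @param lambda_ridge Ridge regularization strength (>= 0).
#' @param train_frac Fraction of the duration used for training, in (0, 1).
#'   The split is chronological: training first, validation last.
#' @param particles Swarm size (>= 2).
#' @param inertia,cognitive,social PSO velocity weights.
#' @param generations Generation budget.
#' @param bounds Named list of `c(lower, upper)` per metaparameter, in the
#'   order `alpha_ec, alpha_dg, alpha_c, rx, ry, n_delays`.
#' @param seed Random seed for the swarm.
#' @return A `fit_config` object.
#' @export
fit_config <- function(lambda_ridge = 10, train_frac = 0.8,
                       particles = 200, inertia = 0.25, cognitive = 2.0,
                       social = 1.0, generations = 140,
                       bounds = default_pso_bounds(), seed = 1L) {
  if (lambda_ridge < 0) stop("lambda_ridge must be >= 0", call. = FALSE)
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must lie in (0, 1)", call. = FALSE)
  if (particles < 2) stop("at least 2 particles required", call. = FALSE)
  structure(list(lambda_ridge = lambda_ridge, train_frac = train_frac,
                 particles = as.integer(particles), inertia = inertia,
                 cognitive = cognitive, social = social,
                 generations = as.integer(generations), bounds = bounds,
                 seed = as.integer(seed)),
            class = "fit_config")
}

#' Default metaparameter search bounds
#'
#' Decay parameters span almost the full admissible interval; spatial
#' extents span the neighbor bin sizes (0.2 mm proximodistal, 0.5 mm
#' septotemporal) up to a few bins; the feedback delay spans 0-50 taps
#' (0-100 ms at 2-ms sampling), covering plausible synaptic loop delays.
#'
#' @return Named list of `c(lower, upper)` bounds.
#' @export
default_pso_bounds <- function() {
  list(alpha_ec = c(0.05, 0.95), alpha_dg = c(0.05, 0.95),
       alpha_c = c(0.05, 0.95), rx = c(0.2, 1.0), ry = c(0.5, 2.5),
       n_delays = c(0, 50))
}

#' Linear-in-weights design matrix
#'
#' Reformulates the convolutional output equation as `X w`: one column per
#' weight, holding the convolution of the matching input with each
#' basis-power term (EC, DG), each separable coupling term applied to the
#' neighbor field, and each lagged reference-output tap for the
#' teacher-forced feedback kernel. Rows are the post-burn-in time points.
#'
#' @param inputs List with `ec`, `dg` and optionally `field`
#'   (a [coupling_field()]).
#' @param reference Reference output trace (teacher-forced feedback).
#' @param static [static_meta()].
#' @param meta [meta_params()].
#' @param include_self Include the (0, 0) coupling lag (default `FALSE`).
#' @param feedback_lags Optional precomputed full feedback lag matrix
#'   (rows x taps) to avoid rebuilding it per metaparameter candidate.
#' @return List with `X` (rows x columns matrix), `map` (data.frame naming
#'   each column), `burn_in` (taps) and `bases`.
#' @export
design_matrix <- function(inputs, reference, static, meta,
                          include_self = FALSE, feedback_lags = NULL) {
  u_ec <- trace_values(inputs$ec); u_dg <- trace_values(inputs$dg)
  r <- trace_values(reference)
  n <- length(u_ec)
  taps <- static$taps
  if (n * static$dt < 2 * static$M)
    stop("insufficient duration: need at least twice the memory window",
         call. = FALSE)
  fld <- inputs$field
  lag_x <- if (is.null(fld)) 0 else fld$lag_x
  lag_y <- if (is.null(fld)) 0 else fld$lag_y
  bases <- model_bases(static, meta, lag_x, lag_y)
  rows <- (taps + 1):n

  conv_block <- function(u, powered, label) {
    m <- matrix(0, length(rows), nrow(powered))
    for (k in seq_len(nrow(powered)))
      m[, k] <- causal_conv(u, powered[k, ])[rows]
    idx <- attr(powered, "index")
    colnames(m) <- sprintf("%s[n=%d,p=%d]", label, idx$n, idx$p)
    m
  }
  X_ec <- conv_block(u_ec, bases$ec, "EC")
  X_dg <- conv_block(u_dg, bases$dg, "DG")

  tensor <- bases$tensor
  X_c <- matrix(0, length(rows), tensor$n_terms)
  colnames(X_c) <- sprintf("C[%d]", seq_len(tensor$n_terms))
  n_ax <- length(bases$active_x); n_ay <- length(bases$active_y)
  if (!is.null(fld) && n_ax > 0 && n_ay > 0) {
    lx <- fld$lag_x[bases$active_x]; ly <- fld$lag_y[bases$active_y]
    # pair (a, b) -> row index of the per-temporal-term convolution stack
    keep <- matrix(TRUE, n_ax, n_ay)
    if (!include_self)
      keep <- !outer(lx == 0, ly == 0, "&")
    ab <- which(keep, arr.ind = TRUE)
    if (nrow(ab) > 0) {
      nq <- nrow(tensor$st)
      idx <- tensor$index
      for (q in seq_len(nq)) {
        M_q <- matrix(0, nrow(ab), length(rows))
        for (m in seq_len(nrow(ab))) {
          u <- fld$values[bases$active_x[ab[m, 1]],
                          bases$active_y[ab[m, 2]], ]
          if (any(u != 0)) M_q[m, ] <- causal_conv(u, tensor$st[q, ])[rows]
        }
        terms_q <- which(idx$t == q)
        # spatial coefficient of term k at pair (a, b)
        S <- tensor$sx[idx$x[terms_q], ab[, 1], drop = FALSE] *
          tensor$sy[idx$y[terms_q], ab[, 2], drop = FALSE]
        X_c[, terms_q] <- t(S %*% M_q)
      }
    }
  }

  if (is.null(feedback_lags)) feedback_lags <- feedback_lag_matrix(r, taps)
  free <- (meta$n_delays + 1):taps
  X_b <- feedback_lags[, free, drop = FALSE]
  colnames(X_b) <- sprintf("B[tau=%d]", free - 1L)

  X <- cbind(X_ec, X_dg, X_c, X_b)
  map <- data.frame(
    kernel = rep(c("EC", "DG", "coupling", "feedback"),
                 c(ncol(X_ec), ncol(X_dg), ncol(X_c), ncol(X_b))),
    name = colnames(X), stringsAsFactors = FALSE)
  list(X = X, map = map, burn_in = taps, bases = bases, rows = rows)
}

# Full teacher-forced feedback lag matrix: column tau + 1 holds
# r(t - dt - tau*dt) on the post-burn-in rows. Independent of the
# metaparameters, so callers can precompute it once per dataset.
feedback_lag_matrix <- function(r, taps) {
  n <- length(r)
  rows <- (taps + 1):n
  m <- matrix(0, length(rows), taps)
  for (tau in 0:(taps - 1)) {
    shift <- tau + 1L
    lagged <- c(rep(0, shift), r[seq_len(n - shift)])
    m[, tau + 1L] <- lagged[rows]
  }
  m
}

#' Ridge regression
#'
#' Minimizes `||y - X w||^2 + lambda ||w||^2` with no intercept (signals are
#' standardized). Solved through the singular value decomposition, which is
#' stable for the rank-deficient blocks that arise when spatial extents
#' exclude every neighbor lag.
#'
#' @param X Design matrix.
#' @param y Target vector, `length(y) == nrow(X)`.
#' @param lambda Regularization strength (>= 0).
#' @return Weight vector of length `ncol(X)`.
#' @export
ridge_fit <- function(X, y, lambda) {
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    stop("non-finite entries in the regression problem", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  sv <- svd(X)
  d <- sv$d
  shrink <- ifelse(d > 0, d / (d^2 + lambda), 0)
  as.numeric(sv$v %*% (shrink * crossprod(sv$u, y)))
}

#' Global-best particle swarm optimization
#'
#' Standard gbest PSO: each particle's velocity is an inertia-weighted blend
#' of its previous velocity, attraction to its personal best and attraction
#' to the swarm best. Velocities are clamped to half the bound width per
#' dimension and positions to the bounds. Dimensions listed in
#' `integer_dims` are rounded to the nearest integer at evaluation time
#' (mixed-integer handling for the feedback delay).
#'
#' @param objective Function mapping a parameter vector to a finite loss.
#' @param bounds Named list of `c(lower, upper)` per dimension.
#' @param particles Swarm size.
#' @param generations Generation budget (normal termination).
#' @param inertia,cognitive,social Velocity weights.
#' @param integer_dims Names (or indices) of integer dimensions.
#' @param seed Random seed; identical seeds give identical histories.
#' @return List with `par` (best position, integer dims rounded), `value`
#'   (best loss) and `history` (data.frame of per-generation best loss and
#'   position).
#' @export
pso_optimize <- function(objective, bounds, particles = 200,
                         generations = 140, inertia = 0.25,
                         cognitive = 2.0, social = 1.0,
                         integer_dims = character(), seed = 1L) {
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  if (any(!is.finite(lo)) || any(!is.finite(hi)) || any(hi < lo))
    stop("bounds must be finite intervals", call. = FALSE)
  D <- length(bounds)
  nm <- names(bounds)
  int_idx <- if (is.character(integer_dims)) match(integer_dims, nm)
             else as.integer(integer_dims)
  round_int <- function(x) {
    if (length(int_idx)) x[int_idx] <- round(x[int_idx])
    x
  }
  vmax <- 0.5 * (hi - lo)
  set.seed(seed)
  pos <- matrix(stats::runif(particles * D, lo, hi), particles, D,
                byrow = TRUE, dimnames = list(NULL, nm))
  vel <- matrix(0, particles, D)
  evals <- apply(pos, 1, function(p) objective(round_int(p)))
  pbest <- pos; pbest_val <- evals
  g <- which.min(pbest_val)
  gbest <- pbest[g, ]; gbest_val <- pbest_val[g]
  hist <- vector("list", generations)
  for (gen in seq_len(generations)) {
    r1 <- matrix(stats::runif(particles * D), particles, D)
    r2 <- matrix(stats::runif(particles * D), particles, D)
    vel <- inertia * vel +
      cognitive * r1 * (pbest - pos) +
      social * r2 * sweep(pos, 2, gbest, function(x, g) g - x)
    vel <- pmin(pmax(vel, matrix(-vmax, particles, D, byrow = TRUE)),
                matrix(vmax, particles, D, byrow = TRUE))
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lo, particles, D, byrow = TRUE)),
                matrix(hi, particles, D, byrow = TRUE))
    evals <- apply(pos, 1, function(p) objective(round_int(p)))
    improved <- evals < pbest_val
    pbest[improved, ] <- pos[improved, ]
    pbest_val[improved] <- evals[improved]
    g <- which.min(pbest_val)
    if (pbest_val[g] < gbest_val) {
      gbest <- pbest[g, ]; gbest_val <- pbest_val[g]
    }
    hist[[gen]] <- c(generation = gen, loss = gbest_val,
                     stats::setNames(round_int(gbest), nm))
  }
  history <- as.data.frame(do.call(rbind, hist))
  list(par = stats::setNames(round_int(gbest), nm), value = gbest_val,
       history = history)
}

# Ridge fit + training MSE for one metaparameter candidate. Shared by the
# PSO objective and the final refit.
fit_at_meta <- function(dataset, static, meta, lambda, n_train_rows,
                        feedback_lags, include_self = FALSE) {
  dm <- design_matrix(dataset, dataset$y, static, meta,
                      include_self = include_self,
                      feedback_lags = feedback_lags)
  y <- trace_values(dataset$y)[dm$rows]
  tr <- seq_len(n_train_rows)
  w <- ridge_fit(dm$X[tr, , drop = FALSE], y[tr], lambda)
  res <- y[tr] - dm$X[tr, , drop = FALSE] %*% w
  list(w = w, train_mse = mean(res^2), dm = dm, y_rows = y)
}

meta_from_vector <- function(p, taps) {
  meta_params(alpha_ec = p[["alpha_ec"]], alpha_dg = p[["alpha_dg"]],
              alpha_c = p[["alpha_c"]], rx = p[["rx"]], ry = p[["ry"]],
              n_delays = min(round(p[["n_delays"]]), taps - 1L))
}

#' Fit one neural mass
#'
#' The outer loop searches the six metaparameters by PSO; for each candidate
#' the bases are rebuilt, the teacher-forced design matrix is formed on the
#' training segment and the weights are estimated by ridge regression, with
#' the training MSE as the swarm loss. The final model is refit at the best
#' metaparameters and evaluated on the held-out chronological tail, both
#' teacher-forced and free-running.
#'
#' @param dataset List with `ec`, `dg`, optional `field`
#'   (a [coupling_field()]) and reference output `y`, all on one clock.
#' @param static [static_meta()].
#' @param config [fit_config()].
#' @param meta Optional [meta_params()]: when supplied the PSO search is
#'   skipped and weights are estimated at these fixed metaparameters.
#' @param center Mass center (x, y) in mm, stored on the model.
#' @param target Model target kind.
#' @param include_self Include the (0, 0) coupling lag.
#' @return A `fit_result` list: `model`, `train_mse`, `val_mse`,
#'   `val_r_teacher`, `val_r_free`, `history` (PSO trace or NULL), `split`
#'   (last training sample index).
#' @export
fit_mass <- function(dataset, static, config = fit_config(), meta = NULL,
                     center = c(0, 0), target = "spike_density",
                     include_self = FALSE) {
  y_full <- trace_values(dataset$y)
  if (stats::sd(y_full) == 0)
    stop("degenerate reference: zero variance", call. = FALSE)
  n <- length(y_full)
  taps <- static$taps
  if (n * static$dt < 2 * static$M)
    stop("dataset shorter than twice the memory window", call. = FALSE)
  split <- floor(config$train_frac * n)
  if (split <= taps)
    stop("training segment must extend beyond the burn-in window",
         call. = FALSE)
  n_train_rows <- split - taps  # rows are indexed from taps + 1
  feedback_lags <- feedback_lag_matrix(y_full, taps)

  history <- NULL
  if (is.null(meta)) {
    bounds <- config$bounds
    bounds$n_delays[2] <- min(bounds$n_delays[2], taps - 1L)
    objective <- function(p) {
      m <- meta_from_vector(p, taps)
      fit_at_meta(dataset, static, m, config$lambda_ridge, n_train_rows,
                  feedback_lags, include_self)$train_mse
    }
    sw <- pso_optimize(objective, bounds, particles = config$particles,
                       generations = config$generations,
                       inertia = config$inertia,
                       cognitive = config$cognitive, social = config$social,
                       integer_dims = "n_delays", seed = config$seed)
    meta <- meta_from_vector(sw$par, taps)
    history <- sw$history
  }

  fit <- fit_at_meta(dataset, static, meta, config$lambda_ridge,
                     n_train_rows, feedback_lags, include_self)
  map <- fit$dm$map
  w <- fit$w
  weights <- kernel_weights(
    w_ec = w[map$kernel == "EC"], w_dg = w[map$kernel == "DG"],
    w_c = w[map$kernel == "coupling"], w_b = w[map$kernel == "feedback"])
  model <- cnmm_model(static, meta, weights, center = center,
                      stats = dataset$stats %||% list(), target = target,
                      include_self = include_self)

  val <- (n_train_rows + 1):length(fit$y_rows)
  pred_tf <- as.numeric(fit$dm$X[val, , drop = FALSE] %*% w)
  y_val <- fit$y_rows[val]
  val_mse <- mean((y_val - pred_tf)^2)
  val_r_teacher <- stats::cor(pred_tf, y_val)
  pred_fr <- predict(model, dataset, mode = "free_running")
  val_idx <- (split + 1):n
  val_r_free <- stats::cor(trace_values(pred_fr)[val_idx], y_full[val_idx])

  structure(list(model = model, train_mse = fit$train_mse,
                 val_mse = val_mse, val_r_teacher = val_r_teacher,
                 val_r_free = val_r_free, history = history, split = split),
            class = "fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(paste0("<fit_result: train MSE %.4g, validation MSE %.4g, ",
                     "R (teacher-forced) %.4f, R (free-running) %.4f>\n"),
              x$train_mse, x$val_mse, x$val_r_teacher, x$val_r_free))
  invisible(x)
}
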