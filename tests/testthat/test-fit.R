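test_that("design matrix has one column per weight and reproduces prediction", {
  ds <- small_teacher(seed = 101, duration = 2000)
  st <- small_static(); meta <- small_meta()
  dm <- design_matrix(ds, ds$y, st, meta)

  n_ec <- 3 * 2; n_c <- 2 * 1 * 2 * 1 * 2 * 2
  n_b <- st$taps - meta$n_delays
  expect_equal(ncol(dm$X), n_ec + n_ec + n_c + n_b)
  expect_equal(nrow(dm$X), length(ds$y$values) - st$taps)
  expect_equal(table(dm$map$kernel)[["coupling"]], n_c)

  # X %*% w reproduces the teacher-forced prediction on the retained rows
  model <- random_teacher(st, meta, ds$spec$lag_x, ds$spec$lag_y,
                          seed = 55)
  w <- c(model$weights$w_ec, model$weights$w_dg, model$weights$w_c,
         model$weights$w_b)
  pred <- predict(model, ds, mode = "teacher_forced", reference = ds$y)
  expect_equal(as.numeric(dm$X %*% w), pred$values[dm$rows],
               tolerance = 1e-10)

  expect_error(design_matrix(ds, ds$y, static_meta(M = 10000, dt = 2),
                             meta), "duration")
})

test_that("design matrix column count matches the full reference configuration", {
  # 8x5 EC + 8x5 DG + 4*3*4*3*3*3 coupling + (500 - 9) feedback taps
  st <- static_meta()
  meta <- meta_params(0.5, 0.5, 0.5, rx = 0.45, ry = 1.1, n_delays = 9)
  n <- 1200
  set.seed(6)
  fld <- coupling_field(c(-0.2, 0, 0.2), c(-0.5, 0, 0.5),
                        array(rnorm(9 * n), dim = c(3, 3, n)))
  inputs <- list(ec = rnorm(n), dg = rnorm(n), field = fld)
  dm <- design_matrix(inputs, rnorm(n), st, meta)
  expect_equal(ncol(dm$X), 40 + 40 + 1296 + 491)
  expect_equal(nrow(dm$X), n - 500)
})

test_that("ridge regression matches the normal-equation oracle and shrinks monotonically", {
  set.seed(12)
  # lambda = 0 on a full-rank square system is an exact solve
  A <- matrix(rnorm(64), 8, 8); b <- rnorm(8)
  expect_equal(ridge_fit(A, b, 0), solve(A, b), tolerance = 1e-8)

  X <- matrix(rnorm(2000), 100, 20); y <- rnorm(100)
  prev <- Inf
  for (lam in c(0, 1, 10, 100, 1e4)) {
    w <- ridge_fit(X, y, lam)
    oracle <- solve(crossprod(X) + lam * diag(20), crossprod(X, y))
    expect_equal(w, as.numeric(oracle), tolerance = 1e-8)
    nw <- sqrt(sum(w^2))
    expect_lte(nw, prev + 1e-12)
    prev <- nw
  }
  expect_error(ridge_fit(X, c(y, 1), 1), "rows")
  expect_error(ridge_fit(X * NA, y, 1), "finite")
})

test_that("particle swarm respects bounds and is seed-deterministic", {
  bounds <- list(a = c(-2, 2), b = c(-1, 3), k = c(0, 10))
  seen <- new.env(); seen$ok <- TRUE; seen$int_ok <- TRUE
  obj <- function(p) {
    if (p[1] < -2 || p[1] > 2 || p[2] < -1 || p[2] > 3 ||
        p[3] < 0 || p[3] > 10) seen$ok <- FALSE
    if (abs(p[3] - round(p[3])) > 1e-12) seen$int_ok <- FALSE
    sum((p - c(0.5, 1, 3))^2)
  }
  r1 <- pso_optimize(obj, bounds, particles = 20, generations = 30,
                     integer_dims = "k", seed = 5)
  r2 <- pso_optimize(obj, bounds, particles = 20, generations = 30,
                     integer_dims = "k", seed = 5)
  expect_true(seen$ok)       # every evaluated position within bounds
  expect_true(seen$int_ok)   # integer dimension rounded at evaluation
  expect_identical(r1$history, r2$history)
  expect_equal(r1$par[["k"]], 3)
  expect_lt(r1$value, 0.05)
  expect_error(pso_optimize(obj, list(a = c(0, Inf)), seed = 1), "finite")
})

test_that("fixed-metaparameter fits are deterministic and beat the mean predictor", {
  ds <- small_teacher(seed = 140, duration = 3000)
  st <- small_static()
  cfg <- fit_config(seed = 3)
  f1 <- fit_mass(ds, st, cfg, meta = small_meta())
  f2 <- fit_mass(ds, st, cfg, meta = small_meta())
  expect_identical(f1$model$weights, f2$model$weights)
  expect_lt(f1$train_mse, var(ds$y$values))
  # chronological split: training strictly precedes validation
  expect_equal(f1$split, floor(0.8 * length(ds$y$values)))
})

test_that("teacher recovery degrades with output noise and with extreme shrinkage", {
  rs <- sapply(c(0, 0.1, 0.5), function(sd) {
    ds <- small_teacher(seed = 200, noise_sd = sd, duration = 3000)
    fit_mass(ds, small_static(), fit_config(seed = 1),
             meta = small_meta())$val_r_teacher
  })
  expect_true(all(diff(rs) < 0))  # R falls monotonically in noise sd
  expect_gt(rs[1], 0.999)

  ds <- small_teacher(seed = 201, duration = 3000)
  lo <- fit_mass(ds, small_static(), fit_config(lambda_ridge = 10),
                 meta = small_meta())
  hi <- fit_mass(ds, small_static(), fit_config(lambda_ridge = 1e6),
                 meta = small_meta())
  expect_lte(lo$val_mse, hi$val_mse)
})
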