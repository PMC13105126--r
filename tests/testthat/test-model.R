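make_inputs <- function(n, lag_x = c(-0.2, 0, 0.2), lag_y = c(-0.5, 0, 0.5),
                        seed = 7) {
  set.seed(seed)
  vals <- array(rnorm(length(lag_x) * length(lag_y) * n),
                dim = c(length(lag_x), length(lag_y), n))
  list(ec = rnorm(n), dg = rnorm(n),
       field = coupling_field(lag_x, lag_y, vals))
}

random_small_model <- function(seed, n_delays = 5, include_self = FALSE) {
  random_teacher(small_static(), small_meta(n_delays),
                 lag_x = c(-0.2, 0, 0.2), lag_y = c(-0.5, 0, 0.5),
                 seed = seed, include_self = include_self)
}

test_that("temporal kernel assembly is the weighted basis-power sum", {
  b <- powered_basis(laguerre_basis(3, 0.4, 50), 2)
  w <- rep(0, 6); w[4] <- 1
  expect_equal(assemble_temporal_kernel(w, b), b[4, ])
  w1 <- rnorm(6); w2 <- rnorm(6)
  expect_equal(assemble_temporal_kernel(w1 + w2, b),
               assemble_temporal_kernel(w1, b) +
                 assemble_temporal_kernel(w2, b), tolerance = 1e-12)
  expect_equal(assemble_temporal_kernel(rep(0, 6), b), rep(0, 50))
  expect_error(assemble_temporal_kernel(rnorm(5), b), "term")
})

test_that("coupling kernel assembly matches materialized outer-product terms", {
  sx <- powered_basis(chebyshev_basis(2, 0.4, c(-0.2, 0, 0.2)), 2)
  sy <- powered_basis(chebyshev_basis(2, 1.0, c(-0.5, 0, 0.5)), 2)
  st <- powered_basis(laguerre_basis(2, 0.5, 20), 2)
  tensor <- coupling_term_tensor(sx, sy, st)

  w <- rep(0, tensor$n_terms); w[11] <- 1
  expect_equal(assemble_coupling_kernel(w, tensor),
               coupling_term(tensor, 11), tolerance = 1e-12)

  # general weights equal the brute-force sum of materialized terms
  set.seed(5)
  w <- rnorm(tensor$n_terms)
  brute <- Reduce(`+`, lapply(seq_len(tensor$n_terms),
                              function(k) w[k] * coupling_term(tensor, k)))
  expect_equal(assemble_coupling_kernel(w, tensor), brute,
               tolerance = 1e-10)

  # order-0-only spatial weights at the endpoint lags reduce to the
  # temporal factor (order-0 Chebyshev is 1 everywhere)
  idx <- tensor$index
  w0 <- rep(0, tensor$n_terms)
  pick <- which(attr(sx, "index")$n[idx$x] == 0 &
                  attr(sx, "index")$p[idx$x] == 1 &
                  attr(sy, "index")$n[idx$y] == 0 &
                  attr(sy, "index")$p[idx$y] == 1 & idx$t == 1)[1]
  w0[pick] <- 1
  K <- assemble_coupling_kernel(w0, tensor)
  expect_equal(K[3, 3, ], st[1, ], tolerance = 1e-12)
  expect_true(all(assemble_coupling_kernel(rep(0, tensor$n_terms),
                                           tensor) == 0))
})

test_that("feedback kernel is zero-padded then the free coefficients", {
  co <- rnorm(45)
  k <- feedback_kernel(co, 5, 50)
  expect_equal(k[1:5], rep(0, 5))
  expect_equal(k[6:50], co)
  expect_equal(feedback_kernel(co, 0, 45), co)
  expect_error(feedback_kernel(co, 4, 50), "taps")
})

test_that("prediction matches direct-summation and nested-loop oracles", {
  n <- 300
  # EC-only model vs brute-force convolution
  st <- small_static()
  m <- random_small_model(1)
  w0 <- m$weights
  ec_only <- cnmm_model(st, m$meta,
                        kernel_weights(w0$w_ec, w0$w_dg * 0, w0$w_c * 0,
                                       w0$w_b * 0))
  inputs <- make_inputs(n)
  pred <- predict(ec_only, inputs, mode = "teacher_forced",
                  reference = rep(0, n))
  bases <- cnmm:::model_bases(st, m$meta, inputs$field$lag_x,
                              inputs$field$lag_y)
  k_ec <- assemble_temporal_kernel(w0$w_ec, bases$ec)
  expect_equal(pred$values, direct_conv(inputs$ec, k_ec),
               tolerance = 1e-10)

  # full model, teacher-forced and free-running, vs the nested-loop oracle
  for (seed in 1:3) {
    mod <- random_small_model(seed + 10, n_delays = seed)
    inp <- make_inputs(n, seed = seed)
    ref <- rnorm(n)
    tf <- predict(mod, inp, mode = "teacher_forced", reference = ref)
    expect_equal(tf$values, naive_predict(mod, inp, ref, "teacher_forced"),
                 tolerance = 1e-8)
    fr <- predict(mod, inp, mode = "free_running")
    expect_equal(fr$values, naive_predict(mod, inp, mode = "free_running"),
                 tolerance = 1e-8)
  }
})

test_that("prediction is linear in the weights, causal, and zero on zero input", {
  n <- 250
  st <- small_static(); meta <- small_meta()
  inp <- make_inputs(n, seed = 21)
  ref <- rnorm(n)
  m1 <- random_small_model(31); m2 <- random_small_model(32)
  wsum <- kernel_weights(m1$weights$w_ec + m2$weights$w_ec,
                         m1$weights$w_dg + m2$weights$w_dg,
                         m1$weights$w_c + m2$weights$w_c,
                         m1$weights$w_b + m2$weights$w_b)
  msum <- cnmm_model(st, meta, wsum)
  p1 <- predict(m1, inp, mode = "teacher_forced", reference = ref)$values
  p2 <- predict(m2, inp, mode = "teacher_forced", reference = ref)$values
  ps <- predict(msum, inp, mode = "teacher_forced", reference = ref)$values
  expect_equal(ps, p1 + p2, tolerance = 1e-10)

  # causality: perturbing a future sample leaves earlier outputs unchanged
  inp2 <- inp; inp2$ec[200] <- inp2$ec[200] + 100
  q1 <- predict(m1, inp, mode = "free_running")$values
  q2 <- predict(m1, inp2, mode = "free_running")$values
  expect_equal(q1[1:199], q2[1:199], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(q1[200:n], q2[200:n])))

  # all-zero inputs give zero output
  z <- list(ec = rep(0, n), dg = rep(0, n),
            field = coupling_field(inp$field$lag_x, inp$field$lag_y,
                                   array(0, dim = dim(inp$field$values))))
  expect_true(all(predict(m1, z, mode = "free_running")$values == 0))

  # zero feedback weights: teacher-forced equals free-running
  m0 <- cnmm_model(st, meta, kernel_weights(m1$weights$w_ec,
                                            m1$weights$w_dg,
                                            m1$weights$w_c,
                                            m1$weights$w_b * 0))
  expect_equal(predict(m0, inp, mode = "teacher_forced",
                       reference = ref)$values,
               predict(m0, inp, mode = "free_running")$values,
               tolerance = 1e-12)
})

test_that("free-running output stays bounded when the feedback loop is a contraction", {
  m <- random_small_model(77)  # |K_B| has L1 norm < 1 by construction
  inp <- make_inputs(2000, seed = 8)
  v <- predict(m, inp, mode = "free_running")$values
  expect_true(all(is.finite(v)))
  expect_lt(max(abs(v)), 1e3)
})

test_that("correlation score handles identical, negated and independent traces", {
  set.seed(11)
  x <- rnorm(500)
  expect_equal(correlation_score(x, x), 1)
  expect_equal(correlation_score(x, -x), -1)
  a <- rnorm(1e5); b <- rnorm(1e5)
  expect_lt(abs(correlation_score(a, b)), 0.02)
  # burn-in exclusion: corrupt the head, retained segment still perfect
  y <- x; y[1:50] <- 0
  expect_equal(correlation_score(y, x, burn_in = 50), 1)
  expect_error(correlation_score(rep(1, 100), rnorm(100)), "degenerate")
})
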