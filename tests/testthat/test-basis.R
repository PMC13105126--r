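test_that("Laguerre basis matches the explicit closed form and is orthonormal", {
  expect_equal(laguerre_basis(1, 0.5, 10)$values[1, 1], sqrt(0.5),
               tolerance = 1e-12)

  for (alpha in c(0.2, 0.5, 0.9)) {
    b <- laguerre_basis(5, alpha, 2000)
    expect_equal(b$values, laguerre_explicit(5, alpha, 2000),
                 tolerance = 1e-9)
    gram <- tcrossprod(b$values)
    expect_lt(max(abs(gram - diag(5))), 1e-6)
  }

  # alpha -> 0+: order-0 function tends to a unit impulse at tau = 0
  b0 <- laguerre_basis(1, 1e-10, 50)$values[1, ]
  expect_equal(b0[1], 1, tolerance = 1e-9)
  expect_lt(max(abs(b0[-1])), 1e-4)

  # stays finite where naive binomials overflow
  big <- laguerre_basis(9, 0.7, 500)
  expect_true(all(is.finite(big$values)))

  expect_error(laguerre_basis(3, 1.0, 10), "alpha")
  expect_error(laguerre_basis(3, 0, 10), "alpha")
  expect_error(laguerre_basis(0, 0.5, 10), ">= 1")
})

test_that("scaled Chebyshev basis has unit order-0 row, unit endpoint, and correct low orders", {
  lags <- seq(-0.8, 0.8, by = 0.2)
  b <- chebyshev_basis(4, r = 0.8, lags = lags)
  expect_equal(b$values[1, ], rep(1, length(lags)))
  at_r <- chebyshev_basis(5, r = 0.8, lags = 0.8)
  expect_equal(as.numeric(at_r$values), rep(1, 5))

  # order 2 at lag 0 with r = 1 is 2x^2 - 1 = -1
  expect_equal(chebyshev_basis(3, r = 1, lags = 0)$values[3, 1], -1)
  # order 1 is x/r
  expect_equal(chebyshev_basis(2, r = 2, lags = c(-2, 1))$values[2, ],
               c(-1, 0.5))

  # boundedness on the unscaled domain for orders up to 8
  x <- seq(-1, 1, length.out = 2001)
  vals <- chebyshev_basis(9, r = 1, lags = x)$values
  expect_lte(max(abs(vals)), 1 + 1e-9)
  # agrees with the trigonometric definition cos(n acos x)
  for (n in c(3, 8))
    expect_equal(vals[n + 1, ], cos(n * acos(x)), tolerance = 1e-9)

  expect_error(chebyshev_basis(3, r = 0.5, lags = 0.6), "within")
  expect_error(chebyshev_basis(3, r = -1, lags = 0), "positive")
})

test_that("power expansion sizes, ordering and identity case", {
  b <- laguerre_basis(8, 0.4, 200)
  p1 <- powered_basis(b, 1)
  expect_identical(unname(p1[, ]), unname(b$values))  # P = 1: unchanged

  p5 <- powered_basis(b, 5)
  expect_equal(nrow(p5), 40)  # EC configuration: 8 orders x 5 powers
  idx <- attr(p5, "index")
  # term (n, 1) is bit-identical to basis row n
  for (n in 0:7)
    expect_identical(p5[which(idx$n == n & idx$p == 1), ], b$values[n + 1, ])
  # even powers are nonnegative
  even <- p5[idx$p %% 2 == 0, , drop = FALSE]
  expect_true(all(even >= 0))
  expect_error(powered_basis(b, 0), "positive")
})

test_that("coupling term set has the full product size and separable entries", {
  taps <- 30
  sx <- powered_basis(chebyshev_basis(4, 0.4, c(-0.4, -0.2, 0, 0.2, 0.4)), 3)
  sy <- powered_basis(chebyshev_basis(4, 1.0, c(-1, -0.5, 0, 0.5, 1)), 3)
  st <- powered_basis(laguerre_basis(3, 0.5, taps), 3)
  tensor <- coupling_term_tensor(sx, sy, st)
  expect_equal(tensor$n_terms, 3 * 3 * 4 * 3 * 4 * 3)  # 1296

  k <- 517
  term <- coupling_term(tensor, k)
  i <- tensor$index[k, ]
  for (probe in list(c(1, 1, 1), c(3, 2, 10), c(5, 5, 30)))
    expect_equal(term[probe[1], probe[2], probe[3]],
                 sx[i$x, probe[1]] * sy[i$y, probe[2]] * st[i$t, probe[3]])

  # zero temporal factor gives an all-zero term
  st0 <- st; st0[2, ] <- 0
  t0 <- coupling_term_tensor(sx, sy, st0)
  k0 <- which(t0$index$t == 2)[1]
  expect_true(all(coupling_term(t0, k0) == 0))

  expect_error(coupling_term_tensor(sx[0, , drop = FALSE], sy, st),
               "nonempty")
})

test_that("static metaparameter container validates its invariants", {
  sm <- static_meta()
  expect_equal(sm$taps, 500)
  expect_equal(sm$ec$nt * sm$ec$pt, 40)
  expect_error(static_meta(M = 1001, dt = 2), "multiple")
  expect_error(static_meta(ec = list(nt = 0, pt = 5)), "positive")
})
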