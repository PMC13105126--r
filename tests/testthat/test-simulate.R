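test_that("exploration trajectory stays inside the arena and respects speed limits", {
  tr <- random_trajectory(20000, seed = 3)
  p <- tr$path
  expect_true(all(p$x_cm >= 0 & p$x_cm <= 80))
  expect_true(all(p$y_cm >= 0 & p$y_cm <= 80))
  # per-step displacement bounded by max speed (30 cm/s over 2 ms)
  step <- sqrt(diff(p$x_cm)^2 + diff(p$y_cm)^2)
  expect_lte(max(step), 30 * 2 / 1000 + 1e-12)
  expect_true(all(tr$segments$speed_cm_s <= 30))
  expect_true(all(tr$segments$duration_ms <= 500))
  expect_identical(random_trajectory(2000, seed = 3)$path[1:100, ],
                   p[1:100, ])
  expect_false(isTRUE(all.equal(random_trajectory(2000, seed = 4)$path,
                                random_trajectory(2000, seed = 5)$path)))
})

test_that("grid maps peak at the configured rate, bottom out at zero, and tile hexagonally", {
  gp <- grid_map_params(lambda = 40, theta = 17, offset = c(12, 30),
                        a = 0.4)
  expect_equal(as.numeric(grid_rate(gp, gp$offset)), 50, tolerance = 1e-9)

  g <- seq(-60, 60, by = 0.4)
  pos <- as.matrix(expand.grid(g + 12, g + 30))
  rates <- grid_rate(gp, pos)
  expect_gte(min(rates), 0)
  expect_lt(min(rates), 1e-3)           # b = -3/2 zeroes the minimum
  expect_equal(max(rates), 50, tolerance = 1e-6)

  # translating by a lattice vector leaves the rate unchanged: solve for
  # the vector with k1.a = 2*pi, k2.a = 0 from the wave vectors
  k <- 4 * pi / (sqrt(3) * gp$lambda)
  ang <- (gp$theta + c(0, 60)) * pi / 180
  K <- k * rbind(c(cos(ang[1]), sin(ang[1])), c(cos(ang[2]), sin(ang[2])))
  a1 <- solve(K, c(2 * pi, 0))
  probe <- matrix(runif(200, 0, 80), ncol = 2)
  expect_equal(grid_rate(gp, sweep(probe, 2, a1, "+")),
               grid_rate(gp, probe), tolerance = 1e-9)
})

test_that("inhomogeneous Poisson thinning tracks its rate profile", {
  expect_length(inhomogeneous_poisson(rep(0, 100)), 0)

  # constant 20 Hz for 100 s: count within the 99% Poisson interval
  st <- inhomogeneous_poisson(rep(20, 50000), dt = 2, seed = 10)
  expect_gte(length(st), qpois(0.005, 2000))
  expect_lte(length(st), qpois(0.995, 2000))

  # binned empirical rate regresses on a sinusoidal profile with slope ~ 1
  dur_bins <- 10000  # 20 s
  tt <- seq_len(dur_bins) * 2 / 1000
  rate <- 20 + 15 * sin(2 * pi * 1 * tt)
  emp <- rep(0, dur_bins)
  reps <- 200
  for (r in seq_len(reps)) {
    s <- inhomogeneous_poisson(rate, dt = 2, seed = 1000 + r)
    emp <- emp + tabulate(pmin(floor(s / 2) + 1, dur_bins), dur_bins)
  }
  emp_hz <- emp / reps / 0.002
  slope <- coef(lm(emp_hz ~ rate))[2]
  expect_gt(slope, 0.95); expect_lt(slope, 1.05)
  expect_error(inhomogeneous_poisson(c(1, -1)), ">= 0")
})

test_that("homogeneous Poisson population matches its rate and exponential intervals", {
  ev <- lec_poisson(100, 1000 * 1000, seed = 4)
  pooled <- nrow(ev) / 100 / 1000  # Hz
  expect_lt(abs(pooled - 5.5) / 5.5, 0.01)

  isi <- unlist(lapply(split(ev$time_ms, ev$neuron_id),
                       function(t) diff(sort(t))))
  ks <- suppressWarnings(ks.test(isi, "pexp", rate = 5.5 / 1000))
  expect_gt(ks$p.value, 0.01)
  expect_equal(nrow(lec_poisson(10, 0)), 0)
})

test_that("teacher datasets are reproducible, noise-responsive and file-round-trippable", {
  d1 <- small_teacher(seed = 77, duration = 1000)
  d2 <- small_teacher(seed = 77, duration = 1000)
  expect_identical(d1$y$values, d2$y$values)

  spec0 <- d1$spec
  noisy <- teacher_dataset(teacher_spec(spec0$model, spec0$lag_x,
                                        spec0$lag_y, noise_sd = 0.5,
                                        seed = spec0$seed), 1000)
  expect_identical(noisy$y_clean, d1$y_clean)
  expect_gt(var(noisy$y$values), var(d1$y$values))

  path <- withr::local_tempfile(fileext = ".csv")
  write_density_traces(list(ec = d1$ec, dg = d1$dg, y = d1$y), path)
  back <- read_density_traces(path)
  expect_equal(back$y$values, d1$y$values, tolerance = 1e-12)
  expect_equal(back$ec$stats, d1$ec$stats, tolerance = 1e-12)

  # an expansive feedback loop is rejected as unstable
  unstable <- random_teacher(small_static(), small_meta(),
                             c(-0.2, 0, 0.2), c(-0.5, 0, 0.5),
                             feedback_gain = 40, seed = 3)
  expect_error(teacher_dataset(teacher_spec(unstable, c(-0.2, 0, 0.2),
                                            c(-0.5, 0, 0.5)), 1000),
               "unstable")
})

test_that("mass grid assignment and the CA3 census bookkeeping", {
  g <- mass_grid(4, 3)
  expect_equal(nrow(g$centers), 12)
  pos <- as.matrix(g$centers[, c("x", "y")])
  expect_equal(assign_masses(g, pos), g$centers$mass)
  expect_true(is.na(assign_masses(g, c(-0.1, 0.2))))
  expect_equal(ca3_census()$pyramidal_per_mass, 82)
})

test_that("toy network conserves per-mass counts and standardizes cleanly", {
  g <- mass_grid(2, 2)
  net <- toy_network_dataset(g, duration = 4000, n_ec = 6, n_dg = 6,
                             ca3_per_mass = 6, seed = 11)
  ca3 <- net$events[net$events$population == "CA3PC", ]
  mass_of <- assign_masses(g, cbind(ca3$x_mm, ca3$y_mm))
  expect_false(any(is.na(mass_of)))
  # each spiking neuron's position maps back to its assigned mass
  by_neuron <- tapply(mass_of, ca3$neuron_id, unique)
  expect_true(all(lengths(by_neuron) == 1))
  expect_equal(as.vector(unlist(by_neuron)),
               net$membership[as.integer(names(by_neuron))])

  net2 <- toy_network_dataset(g, duration = 4000, n_ec = 6, n_dg = 6,
                              ca3_per_mass = 6, seed = 11)
  expect_identical(net$events, net2$events)

  ds <- prepare_mass_dataset(net$events, g, target_mass = 1,
                             duration = 4000)
  # histograms are z-scored before smoothing, so traces are centered and
  # the smoothing can only shrink the unit variance
  expect_lt(abs(mean(ds$ec$values)), 0.05)
  expect_lt(abs(mean(ds$y$values)), 0.05)
  expect_gt(sd(ds$y$values), 0.1)
  expect_lte(sd(ds$y$values), 1 + 1e-9)
  expect_equal(dim(ds$field$values)[3], 2000)
})
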