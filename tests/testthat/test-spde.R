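test_that("a noiseless field at a basin center is a fixed point", {
  l1 <- landscape(rbind(c(0.3, 0.7)), 1.5, "w")
  m <- mollifier(0.05)
  tr <- simulate_spde(l1, m, sigma = 0, start = c(0.3, 0.7), T = 1, dt = 0.01,
                      N = 16, d1 = 0, d2 = 0, seed = 1)
  expect_equal(max(abs(tr$u - 0.3)), 0)
  expect_equal(max(abs(tr$v - 0.7)), 0)
})

test_that("noiseless relaxation follows the mollified single-well closed form", {
  a <- 1.5; delta <- 0.1
  l1 <- landscape(rbind(c(0.3, 0.7)), a, "w")
  m <- mollifier(0.05)
  tr <- simulate_spde(l1, m, sigma = 0, start = c(0.3 + delta, 0.7), T = 0.5,
                      dt = 5e-4, N = 4, d1 = 0, d2 = 0, seed = 1,
                      save_every = 100)
  expect_equal(tr$u[, 1] - 0.3, delta * exp(-2 * a * tr$times),
               tolerance = 1e-3)
})

test_that("the zero-noise field reproduces the 0-D gradient flow at every grid point", {
  land <- landscape(rbind(c(0, 0), c(2, 0)), c(1, 1.5), c("a", "b"))
  m <- mollifier(0.05)
  sp <- simulate_spde(land, m, sigma = 0, start = c(1.6, 0.4), T = 5,
                      dt = 0.01, N = 8, d1 = 0.02, d2 = 0.02, seed = 1,
                      save_every = 50)
  sd0 <- simulate_sde(land, m, sigma = 0, start = c(1.6, 0.4), T = 5,
                      dt = 0.01, save_every = 50)
  # constant-in-space field + diffusion of a constant = 0: exact agreement
  for (s in seq_along(sp$times)) {
    expect_equal(unname(sp$u[s, ]), rep(sd0$u[s], 8), tolerance = 1e-9)
    expect_equal(unname(sp$v[s, ]), rep(sd0$v[s], 8), tolerance = 1e-9)
  }
})

test_that("diffusion alone conserves the spatial mean under Neumann boundaries", {
  flat <- landscape(rbind(c(0, 0)), 1e-8, "w")   # negligible drift
  m <- mollifier(0.05)
  init <- list(u = sin(seq_len(32)), v = cos(seq_len(32)))
  tr <- simulate_spde(flat, m, sigma = 0, start = init, T = 3, dt = 0.01,
                      N = 32, d1 = 0.05, d2 = 0.08, seed = 1)
  expect_equal(rowMeans(tr$u), rep(mean(init$u), nrow(tr$u)), tolerance = 1e-6)
  expect_equal(rowMeans(tr$v), rep(mean(init$v), nrow(tr$v)), tolerance = 1e-6)
  # and the field homogenises toward that mean
  expect_lt(sd(tr$u[nrow(tr$u), ]), sd(init$u) / 10)
})

test_that("white-noise increments have variance sigma^2 dt / dxi", {
  cfg <- noise_config(sigma = 0.5, dt = 0.01, dxi = 1 / 16, N = 16,
                      kind = "white")
  set.seed(3)
  draws <- replicate(6000, noise_increment(cfg))
  v <- var(as.vector(draws))
  target <- 0.5^2 * 0.01 * 16
  n <- length(draws)
  expect_lt(abs(v - target), 3 * target * sqrt(2 / n))
})

test_that("colored noise is a weighted sum of cosine modes", {
  # single mode: increments perfectly correlated with profile phi_1
  cfg <- noise_config(sigma = 0.5, dt = 0.01, dxi = 1 / 16, N = 16,
                      kind = "colored", modes = 1, mode_weights = 1)
  set.seed(2)
  inc <- noise_increment(cfg)
  xi <- (seq_len(16) - 0.5) / 16
  phi <- sqrt(2) * cos(pi * xi)
  expect_equal(inc, (inc[1] / phi[1]) * phi, tolerance = 1e-12)

  expect_error(noise_config(0.5, 0.01, 1 / 16, 16, kind = "colored",
                            modes = 0), "non-empty")
})

test_that("u- and v-channel noise are independent in the integrated field", {
  l1 <- landscape(rbind(c(0, 0)), 0.5, "w")
  m <- mollifier(0.05)
  tr <- simulate_spde(l1, m, sigma = 0.4, start = c(0, 0), T = 100, dt = 0.01,
                      N = 1, L = 1, d1 = 0, d2 = 0, seed = 10, save_every = 1)
  du <- diff(tr$u[, 1]); dv <- diff(tr$v[, 1])
  r <- cor(du, dv)
  expect_lt(abs(r), 3 / sqrt(length(du)))
})

test_that("field trajectories are reproducible given the seed", {
  land <- make_double_well()
  m <- mollifier(0.02)
  a1 <- simulate_spde(land, m, sigma = 0.4, start = "left", T = 2, dt = 0.005,
                      N = 16, seed = 9)
  a2 <- simulate_spde(land, m, sigma = 0.4, start = "left", T = 2, dt = 0.005,
                      N = 16, seed = 9)
  expect_identical(a1$u, a2$u)
  b <- simulate_spde(land, m, sigma = 0.4, start = "left", T = 2, dt = 0.005,
                     N = 16, seed = 10, noise = "colored")
  expect_false(identical(a1$u, b$u))
})
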