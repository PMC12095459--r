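test_that("synchronous step evaluates rules and honors clamps", {
  net <- toy3()
  expect_equal(step_state(net, c(0, 1, 0)), c(A = 1L, B = 0L, C = 1L))
  expect_equal(step_state(net, c(1, 1, 0)), c(A = 1L, B = 1L, C = 0L))

  clamped <- perturb(net, "C", 1)
  for (s in list(c(0, 0, 0), c(1, 1, 0), c(0, 1, 1))) {
    expect_equal(unname(step_state(clamped, s)["C"]), 1L)
  }
})

test_that("rule parsing rejects undeclared identifiers and bad operators", {
  expect_error(boolean_network(c("A", "B"), c(A = "B", B = "X OR A")),
               "undeclared")
  expect_error(boolean_network(c("A", "B"), c(A = "B + A", B = "A")),
               "operator")
  expect_error(boolean_network(c("A", "B"), c(A = "B")), "rules must cover")
})

test_that("exhaustive enumeration of the 3-node fixture matches the hand oracle", {
  aset <- find_attractors(toy3())
  expect_equal(length(aset), 3L)
  df <- as.data.frame(aset)
  expect_setequal(df$state_sequence, c("001", "110", "010;101"))
  expect_equal(df$basin_size[df$state_sequence == "010;101"], 4)
  expect_equal(sort(df$basin_size), c(2, 2, 4))
  expect_equal(sum(df$basin_fraction), 1)
  # cycle is consistent: one step maps each cycle state to the next
  cyc <- aset$attractors[[which(df$state_sequence == "010;101")]]$states
  expect_equal(unname(step_state(toy3(), cyc[1, ])), unname(cyc[2, ]))
  expect_equal(unname(step_state(toy3(), cyc[2, ])), unname(cyc[1, ]))
})

test_that("basin sizes partition the free state space on random networks", {
  for (seed in 1:5) {
    net <- make_toy_network("random_k", n = 8, k = 2, seed = seed)
    df <- as.data.frame(find_attractors(net))
    expect_equal(sum(df$basin_size), 2^8)
    expect_true(all(df$basin_fraction > 0))
  }
})

test_that("sampled mode converges to exhaustive fractions within 3 binomial SEs", {
  net <- toy3()
  ex <- as.data.frame(find_attractors(net))
  sm <- as.data.frame(find_attractors(net, mode = "sampled",
                                      n_samples = 10000L, seed = 42L))
  m <- merge(ex, sm, by = "state_sequence")
  p <- m$basin_fraction.x
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(m$basin_fraction.y - p) <= 3 * se))
  # deterministic given seed
  sm2 <- as.data.frame(find_attractors(net, mode = "sampled",
                                       n_samples = 10000L, seed = 42L))
  expect_identical(sm, sm2)
})

test_that("sampled mode agrees with exhaustive on a larger random network", {
  net <- make_toy_network("random_k", n = 10, k = 2, seed = 3)
  ex <- as.data.frame(find_attractors(net))
  sm <- as.data.frame(find_attractors(net, mode = "sampled",
                                      n_samples = 5000L, seed = 9L))
  m <- merge(ex, sm, by = "state_sequence", all.x = TRUE)
  m$basin_fraction.y[is.na(m$basin_fraction.y)] <- 0
  se <- pmax(sqrt(m$basin_fraction.x * (1 - m$basin_fraction.x) / 5000), 1e-4)
  expect_true(all(abs(m$basin_fraction.y - m$basin_fraction.x) <= 3 * se))
})

test_that("clamps restrict enumeration to free nodes and propagate to attractors", {
  net <- perturb(toy3(), "C", 1)
  aset <- find_attractors(net)
  df <- as.data.frame(aset)
  expect_equal(aset$n_states, 4L)            # 2 free nodes
  expect_setequal(df$state_sequence, c("001", "111", "011;101"))
  expect_equal(sort(df$basin_size), c(1, 1, 2))
  # clamp-ON node is ON in every attractor state
  for (a in aset$attractors) expect_true(all(a$states[, "C"] == 1L))

  off <- find_attractors(perturb(toy3(), "A", 0))
  for (a in off$attractors) expect_true(all(a$states[, "A"] == 0L))
})

test_that("perturb copies the network and replaces existing clamps", {
  net <- toy3()
  p1 <- perturb(net, "C", 1)
  expect_length(net$clamps, 0L)              # original untouched
  p2 <- perturb(p1, "C", 0)
  expect_equal(unname(p2$clamps["C"]), 0L)
  expect_length(p2$clamps, 1L)
  expect_error(perturb(net, "Z", 1), "unknown node")
  expect_error(perturb(net, "C", 2), "0 or 1")
})

test_that("exhaustive mode enforces the free-node capacity cap", {
  net <- make_toy_network("ring", n = 6)
  expect_error(find_attractors(net, max_nodes = 4L), "capped")
  expect_silent(find_attractors(net, max_nodes = 6L))
})
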