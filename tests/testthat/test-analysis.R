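test_that("occupancy fractions sum to one and track constructed fields", {
  land <- landscape(rbind(c(0, 0), c(2, 0)), c(1, 1), c("a", "b"))
  m <- mollifier(0.05)

  # constant field at center 1: occupancy 1 for basin 1 at all times
  tr <- simulate_spde(land, m, sigma = 0, start = "a", T = 1, dt = 0.01,
                      N = 8, d1 = 0, d2 = 0, seed = 1)
  prof <- occupancy(tr, land)
  expect_true(all(prof$fractions[, "a"] == 1))
  expect_equal(rowSums(prof$fractions), rep(1, length(prof$times)))

  # half the grid at each center: fractions 0.5 / 0.5
  tr2 <- simulate_spde(land, m, sigma = 0, start = list(
    u = c(rep(0, 4), rep(2, 4)), v = rep(0, 8)), T = 0.02, dt = 0.01,
    N = 8, d1 = 0, d2 = 0, seed = 1)
  prof2 <- occupancy(tr2, land)
  expect_equal(unname(prof2$fractions[1, ]), c(0.5, 0.5))

  # 0-D reduction: one-hot occupancy
  tr3 <- simulate_sde(land, m, sigma = 0, start = c(1.8, 0), T = 1, dt = 0.01)
  prof3 <- occupancy(tr3, land)
  expect_equal(rowSums(prof3$fractions), rep(1, nrow(tr3)))
  expect_true(all(prof3$fractions %in% c(0, 1)))
})

test_that("transition detection emits events only at dominance flips", {
  labs <- c("a", "b")
  # constant occupancy: no events
  p0 <- fake_profile(0:5, matrix(rep(c(1, 0), each = 6), ncol = 2), labs)
  expect_equal(nrow(detect_transitions(p0)), 0L)

  # one switch: exactly one event with the right crossing data
  fr <- rbind(c(1, 0), c(1, 0), c(0.2, 0.8), c(0, 1))
  p1 <- fake_profile(c(0, 1, 2, 3), fr, labs,
                     mean_u = c(0, 0.2, 1.1, 2), mean_v = rep(0, 4))
  ev <- detect_transitions(p1)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$source, "a")
  expect_equal(ev$target, "b")
  expect_equal(ev$time, 2)
  expect_equal(ev$u_cross, 1.1)

  # mixed snapshots (no basin above threshold) never emit events
  fr2 <- rbind(c(1, 0), c(0.5, 0.5), c(1, 0))
  p2 <- fake_profile(0:2, fr2, labs)
  expect_equal(nrow(detect_transitions(p2)), 0L)

  # back-and-forth keeps every return
  fr3 <- rbind(c(1, 0), c(0, 1), c(1, 0))
  p3 <- fake_profile(0:2, fr3, labs)
  ev3 <- detect_transitions(p3)
  expect_equal(nrow(ev3), 2L)
  expect_equal(polarization_sequence(ev3), c("a", "b", "a"))

  expect_error(detect_transitions(p0, dominance = 0), "dominance")
})

test_that("polarization itineraries read off the event list", {
  ev <- data.frame(time = c(1, 2), source = c("M0", "M2d"),
                   target = c("M2d", "M2bM2d"))
  expect_equal(polarization_sequence(ev), c("M0", "M2d", "M2bM2d"))
  none <- data.frame(time = numeric(), source = character(),
                     target = character())
  expect_equal(polarization_sequence(none, start = "M1"), "M1")
})

test_that("exit-time studies censor, summarise and order by noise", {
  dw <- make_double_well()
  m <- mollifier(0.02)
  ex <- exit_time_study(dw, m, "left", sigmas = c(0.8, 0.3), replicates = 40,
                        T = 50, dt = 0.005, seed = 2)
  expect_equal(ex$n, c(40, 40))
  # sigma = 0.8 crosses easily; sigma = 0.3 (barrier 1) essentially never
  expect_equal(ex$n_censored[1], 0)
  expect_equal(ex$n_censored[2], 40)
  expect_true(is.finite(ex$mean[1]) && is.finite(ex$se[1]))
  expect_true(is.na(ex$mean[2]))
  det <- attr(ex, "detail")
  expect_equal(nrow(det), 80L)
  expect_true(all(det$exit_time <= 50, na.rm = TRUE))
  expect_error(exit_time_study(dw, m, "left", 0.5, replicates = 1), "replicates")
})

test_that("pass localization matches events to their saddle", {
  dw <- make_double_well()
  ps <- find_passes(dw)
  ev <- data.frame(time = c(1, 2), source = c("left", "right"),
                   target = c("right", "left"),
                   u_cross = c(0.52, 0.4), v_cross = c(0.05, 0.3))
  loc <- pass_localization(ev, ps, tolerance = 0.1)
  expect_equal(loc$fraction, 0.5)
  expect_equal(loc$distances[1], sqrt(0.02^2 + 0.05^2), tolerance = 1e-12)

  # no events: fraction undefined
  none <- data.frame(time = numeric(), source = character(),
                     target = character(), u_cross = numeric(),
                     v_cross = numeric())
  expect_true(is.na(pass_localization(none, ps, 0.1)$fraction))

  # event between basins with no shared pass counts as unmatched
  ev2 <- data.frame(time = 1, source = "left", target = "elsewhere",
                    u_cross = 0, v_cross = 0)
  expect_warning(loc2 <- pass_localization(ev2, ps, 0.1), "no shared pass")
  expect_equal(loc2$fraction, 0)
})

test_that("events replay from the occupancy profile they came from", {
  land <- make_double_well()
  m <- mollifier(0.02)
  tr <- simulate_sde(land, m, sigma = 0.8, start = "left", T = 30, dt = 0.005,
                     seed = 21, save_every = 5)
  prof <- occupancy(tr, land)
  ev <- detect_transitions(prof)
  expect_gt(nrow(ev), 0)
  dom <- polarscape:::dominant_basin(prof, 0.5)
  flips <- sum(diff(dom[dom > 0]) != 0)
  expect_equal(nrow(ev), flips)
  expect_true(all(ev$source != ev$target))
  expect_true(all(ev$time >= 0 & ev$time <= 30))
})
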