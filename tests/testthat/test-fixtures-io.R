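test_that("toy network generators have their advertised attractor structure", {
  df <- as.data.frame(find_attractors(make_toy_network("toy3")))
  expect_equal(sort(df$basin_size), c(2, 2, 4))

  # ring with one negation: bijective update, so every state lies on a cycle
  ring <- make_toy_network("ring", n = 5)
  aset <- find_attractors(ring)
  adf <- as.data.frame(aset)
  expect_equal(adf$basin_size, adf$length)   # basin = the cycle itself
  expect_true(all(adf$length > 1))           # odd negative loop: no fixed points

  # random generator is reproducible
  r1 <- make_toy_network("random_k", n = 6, k = 2, seed = 4)
  r2 <- make_toy_network("random_k", n = 6, k = 2, seed = 4)
  expect_identical(r1$rules, r2$rules)
  r3 <- make_toy_network("random_k", n = 6, k = 2, seed = 5)
  expect_false(identical(r1$rules, r3$rules))
})

test_that("the reference landscape honors the published topology", {
  rl <- make_reference_landscape()
  expect_equal(rl$n, 13L)
  expect_equal(sum(rl$fractions), 1)
  cl <- cluster_centers(rl)
  expect_equal(cl$k, 5L)
  anti <- Filter(function(x) "M1" %in% x, cl$clusters)
  expect_length(anti, 1L)
  expect_true("M1M2d" %in% anti[[1]])
  pure_m2 <- Filter(function(x) all(!grepl("M1", x) & x != "M0"), cl$clusters)
  expect_length(pure_m2, 4L)
  # deterministic irrespective of seed
  expect_identical(make_reference_landscape(1), make_reference_landscape(99))
})

test_that("network JSON round-trips exactly", {
  net <- perturb(make_toy_network("toy3"), "C", 1)
  f <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, f)
  back <- read_network_json(f)
  expect_identical(back$nodes, net$nodes)
  expect_identical(back$rules, net$rules)
  expect_identical(back$clamps, net$clamps)
})

test_that("landscape JSON round-trips to full precision", {
  rl <- make_reference_landscape()
  f <- withr::local_tempfile(fileext = ".json")
  write_landscape_json(rl, f)
  back <- read_landscape_json(f)
  expect_identical(back$labels, rl$labels)
  expect_equal(back$centers, rl$centers, tolerance = 1e-12)
  expect_equal(back$steepness, rl$steepness, tolerance = 1e-12)
  expect_equal(back$fractions, rl$fractions, tolerance = 1e-12)
  expect_equal(back$scale, rl$scale)
})

test_that("attractor, events and exit CSVs round-trip", {
  aset <- label_attractors(find_attractors(toy3()),
                           phenotype_rules(c(M1 = "A AND B", M2d = "C")))
  f <- withr::local_tempfile(fileext = ".csv")
  write_attractors_csv(aset, f)
  back <- read_attractors_csv(f)
  expect_equal(back, as.data.frame(aset))

  ev <- structure(data.frame(time = c(1.5, 2.25), source = c("a", "b"),
                             target = c("b", "a"),
                             u_cross = c(0.123456789012345, 1),
                             v_cross = c(-1, 2)),
                  class = c("transition_events", "data.frame"))
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(ev, f2)
  ev_back <- read_events_csv(f2)
  expect_equal(as.data.frame(ev_back), as.data.frame(ev), tolerance = 1e-12)
})

test_that("trajectory stores round-trip with their provenance", {
  land <- make_double_well()
  m <- mollifier(0.02)
  tr <- simulate_sde(land, m, sigma = 0.5, start = "left", T = 1, dt = 0.01,
                     seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f)
  expect_s3_class(back, "sde_trajectory")
  expect_equal(back$u, tr$u, tolerance = 1e-12)
  expect_equal(attr(back, "config")$sigma, 0.5)

  fld <- simulate_spde(land, m, sigma = 0.4, start = "left", T = 0.5,
                       dt = 0.01, N = 8, seed = 3)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(fld, f2)
  fback <- read_trajectory_csv(f2)
  expect_s3_class(fback, "field_trajectory")
  expect_equal(fback$u, fld$u, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fback$times, fld$times)
})

test_that("malformed files fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".json")
  writeLines('{"nodes": ["A"]}', f)
  expect_error(read_network_json(f), "format version")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("attractor_id,state_sequence", "1,001"), f2)
  expect_error(read_attractors_csv(f2), "missing required column")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,source,target,u_cross,v_cross",
               "1,a,b,0.5,0", "oops,a,b,xx,0"), f3)
  expect_error(read_events_csv(f3), "row 2")

  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines("t,u,v", f4)
  expect_error(read_trajectory_csv(f4), "provenance")
})

test_that("the CLI drives the fixture-to-attractors pipeline", {
  dir <- withr::local_tempdir()
  net_f <- file.path(dir, "net.json")
  out_f <- file.path(dir, "attr.csv")
  expect_output(code <- ps_cli(c("fixtures", "--toy3", "--out", net_f)))
  expect_equal(code, 0L)
  expect_output(code2 <- ps_cli(c("attractors", "--network", net_f,
                                  "--mode", "exhaustive", "--out", out_f)))
  expect_equal(code2, 0L)
  df <- read_attractors_csv(out_f)
  expect_equal(nrow(df), 3L)
  expect_equal(sum(df$basin_size), 8)

  # identical seeds give identical trajectory files
  land_f <- file.path(dir, "land.json")
  expect_output(ps_cli(c("fixtures", "--double-well", "--out", land_f)))
  t1 <- file.path(dir, "t1.csv"); t2 <- file.path(dir, "t2.csv")
  args <- c("simulate", "--landscape", land_f, "--sigma", "0.5",
            "--start", "left", "--T", "1", "--dt", "0.005",
            "--epsilon", "0.02", "--seed", "3")
  expect_output(ps_cli(c(args, "--out", t1)))
  expect_output(ps_cli(c(args, "--out", t2)))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("CLI usage errors exit with code 2", {
  expect_message(code <- ps_cli(character(0)))
  expect_equal(code, 2L)
  expect_message(code2 <- ps_cli(c("frobnicate", "--x", "1")))
  expect_equal(code2, 2L)
  expect_message(code3 <- ps_cli(c("attractors", "--mode", "exhaustive")))
  expect_equal(code3, 2L)
  expect_message(code4 <- ps_cli(c("fixtures", "--out", "x.json")))
  expect_equal(code4, 2L)
})
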