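test_that("two-finger contacts sit at opposing orientations", {
  sc <- input_scenario(p_contacts = c(0, 0, 1), seed = NULL)
  set.seed(4)
  for (i in 1:50) {
    ct <- sample_contacts(sc)
    expect_equal(nrow(ct), 2L)
    expect_equal((ct$orientation[2] - ct$orientation[1]) %% 360, 180)
    expect_true(all(ct$orientation >= 0 & ct$orientation < 360))
    expect_true(all(ct$circularity > 0 & ct$circularity < 1))
  }
})

test_that("a degenerate contact law yields empty frames", {
  sc <- input_scenario(p_contacts = c(1, 0, 0))
  set.seed(1)
  for (i in 1:20) expect_equal(nrow(sample_contacts(sc)), 0L)
})

test_that("contact counts follow the configured probabilities within binomial bounds", {
  sc <- input_scenario(p_contacts = c(0.2, 0.5, 0.3))
  set.seed(99)
  n <- 5e4
  counts <- integer(3)
  for (i in seq_len(n)) {
    k <- nrow(sample_contacts(sc))
    counts[k + 1L] <- counts[k + 1L] + 1L
  }
  for (j in 1:3) {
    p <- c(0.2, 0.5, 0.3)[j]
    expect_lt(abs(counts[j] - n * p), 3 * sqrt(n * p * (1 - p)))
  }
})

test_that("population encoding is a circular Gaussian bump with wraparound mass", {
  grid <- field_grid(100)
  sc <- input_scenario(blur_sigma = 10.8, amplitude_scale = 6)
  ct <- data.frame(orientation = 10, circularity = 0.7)
  frame <- encode_population(ct, grid, sc)
  # explicit per-site evaluation of the circular Gaussian
  ref <- numeric(100)
  for (i in 1:100) {
    ang <- (i - 1) * 3.6
    d <- abs(ang - 10); d <- min(d, 360 - d)
    ref[i] <- 6 * 0.7 * exp(-d^2 / (2 * 10.8^2))
  }
  expect_equal(frame, ref)
  # wraparound: sites near 350 degrees receive mass
  expect_gt(frame[98], 0.05 * max(frame))
  expect_equal(encode_population(ct[0, ], grid, sc), numeric(100))
})

test_that("zero blur degenerates to a single site at the nearest orientation", {
  grid <- field_grid(100)
  sc <- input_scenario(blur_sigma = 0, amplitude_scale = 6)
  frame <- encode_population(data.frame(orientation = 10.9, circularity = 0.5),
                             grid, sc)
  expect_equal(sum(frame != 0), 1L)
  expect_equal(frame[4], 3)   # site 4 sits at 10.8 degrees
})

test_that("overlapping bumps combine by maximum (default) or sum", {
  grid <- field_grid(100)
  ct <- data.frame(orientation = c(90, 97.2), circularity = c(0.5, 0.5))
  f_max <- encode_population(ct, grid, input_scenario(combine = "max"))
  f_sum <- encode_population(ct, grid, input_scenario(combine = "sum"))
  expect_lte(max(f_max), 6 * 0.5)
  expect_gt(max(f_sum), max(f_max))
})

test_that("contacts at mirrored orientations produce circularly mirrored frames", {
  grid <- field_grid(100)
  sc <- input_scenario()
  f1 <- encode_population(data.frame(orientation = 1, circularity = 0.6), grid, sc)
  f2 <- encode_population(data.frame(orientation = 359, circularity = 0.6), grid, sc)
  mirror <- c(1, rev(2:100))   # site angle theta -> -theta mod 360
  expect_equal(f2, f1[mirror], tolerance = 1e-12)
})

test_that("series generation counts frames, loops blocks and is seed-deterministic", {
  grid <- field_grid(100)
  expect_equal(nrow(generate_series(input_scenario(fps = 1, duration = 3,
                                                   seed = 2), grid)$frames), 3L)
  s1 <- generate_series(input_scenario(duration = 30, seed = 8), grid)
  s2 <- generate_series(input_scenario(duration = 30, seed = 8), grid)
  expect_identical(s1$frames, s2$frames)
  s3 <- generate_series(input_scenario(duration = 30, seed = 9), grid)
  expect_false(identical(s1$frames, s3$frames))
  # looped mode: a 10-frame block repeats at 10-19 and 20-24
  lp <- generate_series(input_scenario(fps = 1, duration = 25, loop_block = 10,
                                       seed = 5), grid)
  expect_equal(lp$frames[11:20, ], lp$frames[1:10, ])
  expect_equal(lp$frames[21:25, ], lp$frames[1:5, ])
})

test_that("series generation does not disturb the caller's RNG stream", {
  grid <- field_grid(50)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(generate_series(input_scenario(duration = 10, seed = 77), grid))
  expect_identical(runif(1), before)
})

test_that("unmanipulated frames stay inside the amplitude envelope", {
  grid <- field_grid(100)
  ser <- generate_series(input_scenario(duration = 120, seed = 14), grid)
  expect_gte(min(ser$frames), 0)
  expect_lte(max(ser$frames), 6)
})

test_that("manipulation rescales and shifts only the post-switch frames", {
  grid <- field_grid(100)
  base_sc <- input_scenario(duration = 60, seed = 3)
  ser <- generate_series(base_sc, grid)
  # identity
  expect_identical(manipulate_series(ser, base_sc)$frames, ser$frames)
  # down-scaling by 6: post-switch range [0, 1]
  sc_div <- input_scenario(duration = 60, seed = 3, scale_factor = 1 / 6,
                           switch_time = 30)
  m <- manipulate_series(ser, sc_div)
  post <- frame_times(ser) >= 30
  expect_equal(m$frames[post, ], ser$frames[post, ] / 6)
  expect_identical(m$frames[!post, ], ser$frames[!post, ])
  expect_lte(max(m$frames[post, ]), 1)
  # shift by -12: post-switch range [-12, -6] for full-scale inputs
  sc_off <- input_scenario(duration = 60, seed = 3, offset = -12,
                           switch_time = 30)
  m2 <- manipulate_series(ser, sc_off)
  expect_equal(m2$frames[post, ], ser$frames[post, ] - 12)
  expect_true(all(m2$frames[post, ] >= -12 & m2$frames[post, ] <= -6))
})

test_that("input series survive a CSV round trip exactly", {
  grid <- field_grid(20)
  ser <- generate_series(input_scenario(duration = 6, fps = 2, seed = 6), grid)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_input_series(ser, path)
  back <- read_input_series(path)
  expect_equal(back$frames, ser$frames, tolerance = 1e-15)
  expect_equal(back$frame_dt, ser$frame_dt)
  expect_equal(back$n_sites, 20L)
  expect_true(back$periodic)
})
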