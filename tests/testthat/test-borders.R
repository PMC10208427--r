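test_that("redundancy index: straight, semicircular, degenerate borders", {
  straight <- cbind(seq(0, 10, length.out = 100), 0)
  expect_identical(redundancy_index(straight), 1)

  th <- seq(0, pi, length.out = 4000)
  semi <- cbind(cos(th), sin(th))
  expect_equal(redundancy_index(semi), pi / 2, tolerance = 1e-5)

  loop <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 0))
  expect_error(redundancy_index(loop), "coincide")

  # triangle inequality: any polyline >= 1
  for (seed in 1:10) {
    pts <- epitess:::with_seed(seed, cbind(cumsum(runif(20)), rnorm(20)))
    expect_gte(redundancy_index(pts), 1)
  }
})

test_that("interdigitation counting on analytic sinusoids", {
  t <- seq(0, 1, length.out = 4000)
  ch <- 30
  three_periods <- cbind(t * ch, 5 * sin(2 * pi * 3 * t))   # 6 extrema, amp 10x prominence
  expect_equal(count_interdigitations(three_periods, 1, 0.5), 6L)

  sub <- cbind(t * ch, 0.05 * sin(2 * pi * 3 * t))          # amp 0.1x prominence
  expect_equal(count_interdigitations(sub, 1, 0.5), 0L)

  expect_error(count_interdigitations(cbind(c(0, 1), c(0, 0)), smooth_window = 2,
                                      prominence = 0.5), "smooth_window")
})

test_that("straight borders give 0 peaks and index 1 for any smoothing", {
  straight <- cbind(seq(0, 20, length.out = 300), 7)
  for (w in c(0.25, 1, 3)) for (pr in c(0.1, 0.5, 2)) {
    expect_equal(count_interdigitations(straight, w, pr), 0L)
  }
  expect_identical(redundancy_index(straight), 1)
})

test_that("redundancy strictly increases with synthesis amplitude", {
  tess <- relaxed_tess(40, 8, seed = 11)
  amps <- c(0.4, 0.9, 1.4, 1.8)
  truths <- lapply(amps, function(a)
    synthesize_wavy(tess, a, peaks_per_border = 2, rng_seed = 5,
                    resolution_px = 512, pixel_size = 0.25)$truth)
  deformed <- Reduce(intersect, lapply(truths, function(tr)
    paste(tr$cell_a, tr$cell_b)[tr$deformed]))
  expect_gt(length(deformed), 10)
  ri <- sapply(truths, function(tr)
    tr$redundancy_index[match(deformed, paste(tr$cell_a, tr$cell_b))])
  expect_true(all(apply(ri, 1, function(r) all(diff(r) > 0))))

  # measured index from the raster follows the same ordering on average
  mri <- vapply(amps, function(a) {
    w <- synthesize_wavy(tess, a, 2, rng_seed = 5, resolution_px = 512,
                         pixel_size = 0.25)
    mean(analyze_borders(extract_cells(w$label_image))$redundancy_index)
  }, 0)
  expect_true(all(diff(mri) > 0))
})

test_that("peaks-vs-length regression: exact, degenerate and simulated cases", {
  r <- peaks_vs_length_regression(lengths = 1:3, peaks = 1:3)
  expect_equal(r$slope, 1, tolerance = 1e-12)
  expect_equal(r$intercept, 0, tolerance = 1e-12)
  expect_equal(r$r_squared, 1)

  rc <- peaks_vs_length_regression(lengths = c(1, 2, 3, 4), peaks = rep(2, 4))
  expect_equal(rc$r_squared, 0)

  expect_error(peaks_vs_length_regression(lengths = rep(2, 5), peaks = 1:5),
               "degenerate")
  expect_error(peaks_vs_length_regression(lengths = 1:2, peaks = 1:2),
               "at least 3")

  # slope recovery: truth inside the 95% CI for the vast majority of seeds
  hits <- 0
  for (seed in 1:50) {
    n <- 60
    len <- epitess:::with_seed(seed, runif(n, 5, 50))
    pk <- epitess:::with_seed(seed + 1000, round(0.4 * len + rnorm(n, 0, 1.5)))
    fit <- lm(pk ~ len)
    ci <- confint(fit)[2, ]
    if (ci[1] <= 0.4 && 0.4 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 43)   # binomial(50, 0.95) lower tail
})
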