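test_that("seed generation is reproducible, in-domain, and validates n", {
  s1 <- generate_seeds(100, rng_seed = 7)
  s2 <- generate_seeds(100, rng_seed = 7)
  expect_identical(s1$points, s2$points)
  expect_true(all(s1$points >= 0 & s1$points <= 1))

  one <- generate_seeds(1, rng_seed = 3, epi_domain(mode = "bounded"))
  expect_equal(nrow(one$points), 1)
  expect_true(all(one$points >= 0 & one$points <= 1))

  expect_error(generate_seeds(0, 1), "positive integer")
  expect_error(generate_seeds(-3, 1), "positive integer")
})

test_that("two-seed Voronoi splits the unit square at the bisector", {
  s <- epi_seeds(rbind(c(0.25, 0.5), c(0.75, 0.5)), epi_domain(mode = "bounded"))
  tess <- voronoi_tessellate(s)
  expect_equal(tess$areas, c(0.5, 0.5), tolerance = 1e-12)
  expect_identical(tess$adjacency, list(2L, 1L))
  # all cell-1 vertices lie left of or on x = 0.5
  expect_true(all(tess$cells[[1]][, 1] <= 0.5 + 1e-12))
})

test_that("single bounded seed owns the whole domain", {
  tess <- voronoi_tessellate(
    epi_seeds(matrix(c(0.3, 0.6), 1), epi_domain(mode = "bounded")))
  expect_equal(tess$areas, 1, tolerance = 1e-12)
  expect_length(tess$adjacency[[1]], 0)
})

test_that("coincident seeds are rejected", {
  expect_error(epi_seeds(rbind(c(0.5, 0.5), c(0.5, 0.5)), epi_domain()),
               "coincident")
})

test_that("triangular-lattice seeds give a 6-regular hexagonal tiling", {
  hx <- hexagonal_lattice(8, 8)
  expect_true(all(polygon_classes(hx) == 6L))
  expect_equal(sum(hx$areas), 1, tolerance = 1e-9)
  # adjacency symmetric by brute-force audit
  for (i in seq_along(hx$adjacency))
    for (j in hx$adjacency[[i]])
      expect_true(i %in% hx$adjacency[[j]])
  expect_error(hexagonal_lattice(7, 8), "even")
  expect_error(hexagonal_lattice(2, 2), ">= 3")
})

test_that("one noiseless Lloyd step moves seeds to cell centroids", {
  s <- epi_seeds(rbind(c(0.2, 0.5), c(0.8, 0.5)), epi_domain(mode = "bounded"))
  lp <- lloyd_path(s, n_iter = 1)
  expect_equal(lp$diagrams[[1]]$centroids,
               rbind(c(0.25, 0.5), c(0.75, 0.5)), tolerance = 1e-12)
})

test_that("a hexagonal lattice is a Lloyd fixed point", {
  hx <- hexagonal_lattice(8, 8)
  lp <- lloyd_path(epi_seeds(hx$seeds, hx$domain), n_iter = 2)
  disp <- sqrt(rowSums((lp$diagrams[[2]]$seeds - hx$seeds)^2))
  expect_lt(max(disp), 1e-9)
})

test_that("Lloyd energy descends for random initializations (noise 0)", {
  for (seed in 1:20) {
    lp <- lloyd_path(generate_seeds(60, seed), n_iter = 25)
    expect_true(all(diff(lp$energy_trace) <= 1e-12), label = paste("seed", seed))
  }
})

test_that("lloyd_path validates arguments and records strided diagrams", {
  s <- generate_seeds(50, 1)
  expect_error(lloyd_path(s, n_iter = 0), "n_iter")
  expect_error(lloyd_path(s, n_iter = 5, noise_amplitude = -1), "noise")
  lp <- lloyd_path(s, n_iter = 20, record_stride = 7L)
  expect_equal(lp$iterations, c(1L, 8L, 15L, 20L))
  expect_equal(vapply(lp$diagrams, function(d) d$iteration_index, 0L),
               lp$iterations)
  expect_length(lp$energy_trace, 20)
})

test_that("periodic trivalent tessellations have mean polygon class 6 exactly", {
  for (seed in c(2, 11)) {
    tess <- voronoi_tessellate(generate_seeds(150, seed))
    expect_equal(mean(polygon_classes(tess)), 6, tolerance = 1e-9)
  }
})

test_that("isotropic rescaling preserves topology and scales areas", {
  tess <- relaxed_tess(80, 5, seed = 9, mode = "periodic")
  sc <- rescale_tessellation(tess, 1.5)
  expect_identical(sc$adjacency, tess$adjacency)
  expect_equal(sc$areas, tess$areas * 2.25, tolerance = 1e-12)
  expect_identical(polygon_distribution(sc)$freq,
                   polygon_distribution(tess)$freq)
})

test_that("rasterization labels every pixel and matches analytic areas", {
  s <- epi_seeds(rbind(c(0.25, 0.5), c(0.75, 0.5)), epi_domain(mode = "bounded"))
  img <- rasterize(voronoi_tessellate(s), 512, 512, 1)
  expect_equal(sum(img$pixels == 0), 0)
  frac1 <- mean(img$pixels == 1L)
  expect_lt(abs(frac1 - 0.5), 0.005)
  expect_error(rasterize(voronoi_tessellate(s), 32, 32), "64")
})

test_that("wavy synthesis carries its ground truth", {
  tess <- relaxed_tess(40, 8, seed = 11)
  w0 <- synthesize_wavy(tess, amplitude = 0, peaks_per_border = 3,
                        rng_seed = 5, resolution_px = 256, pixel_size = 0.25)
  expect_true(all(w0$truth$redundancy_index == 1))
  expect_true(all(w0$truth$peak_count == 0L))

  w <- synthesize_wavy(tess, amplitude = 1.5, peaks_per_border = 3,
                       rng_seed = 5, resolution_px = 512, pixel_size = 0.25)
  expect_true(all(w$truth$peak_count[w$truth$deformed] == 3L))
  expect_true(all(w$truth$redundancy_index[w$truth$deformed] > 1))
  expect_equal(sum(w$label_image$pixels == 0L), 0)

  expect_error(synthesize_wavy(tess, amplitude = 50, peaks_per_border = 3,
                               resolution_px = 256, pixel_size = 0.25),
               "self-intersect")
  expect_error(synthesize_wavy(tess, amplitude = -1, peaks_per_border = 1),
               "amplitude")
})
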