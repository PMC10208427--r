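test_that("reference set is reproducible and self-consistent", {
  refs <- test_refs()
  refs2 <- build_reference_set(196, rng_seed = 4)
  expect_identical(refs$hex_graph$edges, refs2$hex_graph$edges)
  expect_identical(refs$random_graph$edges, refs2$random_graph$edges)
  expect_identical(refs$voronoi5_graph$edges, refs2$voronoi5_graph$edges)

  expect_equal(as.numeric(gdd_distance(refs$hex_orbits, refs$hex_orbits)), 0)
  expect_lt(abs(mean(lengths(refs$voronoi5_graph$adj)) - 6), 0.05)
  expect_error(build_reference_set(50), ">= 100")
})

test_that("GDD triplets: hexagonal sample at zero, components in range", {
  refs <- test_refs()
  hx <- contact_graph(hexagonal_lattice(14, 14))
  tr <- gdd_triplet(hx, refs, sample_id = "hex")
  expect_equal(unname(tr$triplet["d_hex"]), 0)
  expect_true(all(tr$triplet >= 0 & tr$triplet <= 1))
  expect_error(gdd_triplet(contact_graph(hexagonal_lattice(4, 5)), refs),
               "insufficient")
})

test_that("random Voronoi samples sit nearer Epi-Random than Epi-Hexagons", {
  refs <- test_refs()
  closer <- vapply(1:50, function(seed) {
    tr <- gdd_triplet(contact_graph(voronoi_tessellate(generate_seeds(150, seed + 300))),
                      refs)$triplet
    tr["d_random"] < tr["d_hex"]
  }, NA)
  expect_gte(mean(closer), 0.95)
})

test_that("CVTn scale orders samples: closest iteration behaves as a scale", {
  refs <- test_refs()
  sc <- fixture("scale_small", function()
    build_cvtn_scale(refs, n_seeds = 120, n_iter = 40, stride = 13,
                     replicates = 3, rng_seed = 2))
  # self-lookup: the scale's own mean triplets map to their iterations
  for (i in seq_along(sc$iterations))
    expect_equal(closest_cvtn(sc$mean[i, ], sc), sc$iterations[i])

  hx_tr <- gdd_triplet(contact_graph(hexagonal_lattice(14, 14)), refs)
  rv_tr <- gdd_triplet(contact_graph(voronoi_tessellate(generate_seeds(150, 77))), refs)
  expect_gt(closest_cvtn(hx_tr, sc), closest_cvtn(rv_tr, sc))

  # ensemble-mean hexagon distance decreases along the path
  expect_lt(sc$mean[nrow(sc$mean), "d_hex"], sc$mean[1, "d_hex"])

  one <- fake_scale(c(0.5, 0.2, 0.2), diag(3) * 1e-4, iterations = 9L)
  expect_equal(closest_cvtn(c(0, 0, 0), one), 9L)
  expect_error(closest_cvtn(c(0, 0, 0), structure(list(iterations = integer(0)),
                                                  class = "epi_cvtn_scale")),
               "empty")
})

test_that("randomization significance is calibrated on the null and detects off-path samples", {
  mu <- c(0.5, 0.3, 0.2)
  S <- diag(c(4e-4, 2e-4, 3e-4)) + 1e-4
  sc <- fake_scale(mu, S, iterations = 1L, replicates = 60, rng_seed = 9)
  null_samples <- epitess:::with_seed(42, MASS::mvrnorm(500, mu, S))
  pvals <- vapply(seq_len(nrow(null_samples)), function(i)
    randomization_significance(null_samples[i, ], sc, at_iteration = 1L,
                               n_draws = 400, rng_seed = i)$p, 0)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)

  far <- mu + c(0.3, -0.2, 0.2)
  rs <- randomization_significance(far, sc, at_iteration = 1L,
                                   n_draws = 999, rng_seed = 1)
  expect_lte(rs$p, 0.01)
  expect_error(randomization_significance(far, sc, 1L, n_draws = 0), "n_draws")
})

test_that("MANOVA distinguishes shifted groups and validates input", {
  expect_error(manova_groups(data.frame(group = "a", d_hex = runif(5),
                                        d_random = runif(5), d_voronoi5 = runif(5))),
               "2 groups")
  # power: 3-SD mean shift detected essentially always
  hits <- vapply(1:100, function(seed) {
    y <- epitess:::with_seed(seed, {
      rbind(matrix(rnorm(20 * 3), 20), matrix(rnorm(20 * 3, mean = 3), 20))
    })
    df <- data.frame(group = rep(c("a", "b"), each = 20),
                     d_hex = y[, 1], d_random = y[, 2], d_voronoi5 = y[, 3])
    manova_groups(df)$p_value < 0.01
  }, NA)
  expect_gte(mean(hits), 0.99)

  m <- manova_groups(data.frame(group = rep(c("a", "b"), each = 20),
                                d_hex = rnorm(40), d_random = rnorm(40),
                                d_voronoi5 = rnorm(40)))
  expect_true(m$wilks_lambda > 0 && m$wilks_lambda <= 1)
  expect_true(m$p_value >= 0 && m$p_value <= 1)
})

test_that("GDD triplets are invariant under isotropic rescaling", {
  refs <- test_refs()
  tess <- relaxed_tess(150, 5, seed = 13, mode = "periodic")
  tr1 <- gdd_triplet(contact_graph(tess), refs)$triplet
  tr2 <- gdd_triplet(contact_graph(rescale_tessellation(tess, 3.7)), refs)$triplet
  expect_identical(tr1, tr2)
})
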