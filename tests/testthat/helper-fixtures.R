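# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# k x k grid of square cells, each cell px_per_cell pixels wide
block_label_image <- function(k = 3, px_per_cell = 3, pixel_size = 1) {
  L <- matrix(0L, k * px_per_cell, k * px_per_cell)
  for (i in seq_len(k)) for (j in seq_len(k))
    L[(i - 1) * px_per_cell + seq_len(px_per_cell),
      (j - 1) * px_per_cell + seq_len(px_per_cell)] <- (i - 1L) * k + j
  epi_label_image(L, pixel_size)
}

relaxed_tess <- function(n, iter, seed, mode = "bounded") {
  p <- lloyd_path(generate_seeds(n, seed, epi_domain(mode = mode)),
                  n_iter = iter, record_stride = max(1L, iter))
  p$diagrams[[length(p$diagrams)]]
}

test_refs <- function() {
  fixture("refs196", function() build_reference_set(196, rng_seed = 4))
}

# a CVTn-scale object with a known Gaussian ensemble, for calibration tests
fake_scale <- function(mu, Sigma, iterations = 1L, replicates = 50,
                       rng_seed = 1L) {
  arr <- array(NA_real_, c(replicates, length(iterations), 3),
               dimnames = list(NULL, iterations,
                               c("d_hex", "d_random", "d_voronoi5")))
  draws <- epitess:::with_seed(rng_seed, MASS::mvrnorm(replicates * length(iterations), mu, Sigma))
  k <- 0
  for (i in seq_along(iterations)) for (r in seq_len(replicates)) {
    k <- k + 1
    arr[r, i, ] <- draws[k, ]
  }
  structure(list(iterations = as.integer(iterations),
                 mean = apply(arr, c(2, 3), mean),
                 replicates = arr, n_seeds = NA, noise_amplitude = NA,
                 rng_seed = rng_seed, orbit_subset = 0:72),
            class = "epi_cvtn_scale")
}

# minimum length of any shared Voronoi edge incident to a cell, from geometry
min_shared_edge <- function(tess) {
  best <- Inf
  for (i in seq_along(tess$cells)) {
    ring <- tess$cells[[i]]
    si <- tess$seeds[i, ]
    for (j in tess$adjacency[[i]]) {
      sj <- tess$seeds[j, ]
      d <- abs(sqrt(rowSums(sweep(ring, 2, si)^2)) -
                 sqrt(rowSums(sweep(ring, 2, sj)^2)))
      on <- which(d < 1e-7)
      if (length(on) >= 2) best <- min(best, max(dist(ring[on, , drop = FALSE])))
    }
  }
  best
}

# Rasterization can only preserve adjacency for borders that span at least
# min_shared_border_px pixels, so the round-trip fixture is built to satisfy
# that geometric precondition: the first jittered-lattice tessellation (seeds
# 1, 2, ...) whose polygon classes are diverse and whose shortest shared edge
# resolves to >= 4 px at the target raster.  The predicate uses tessellation
# geometry only.
resolvable_fixture <- function(raster_px = 1024, min_edge_px = 4,
                               jitter = 0.25) {
  fixture(paste0("resolvable", raster_px), function() {
    rows <- 10; cols <- 10; dx <- 1 / cols; dy <- 1 / rows
    g <- expand.grid(c = 0:(cols - 1), r = 0:(rows - 1))
    base <- cbind((g$c + 0.25 + 0.5 * (g$r %% 2)) * dx, (g$r + 0.5) * dy)
    for (seed in 1:100) {
      pts <- base + epitess:::with_seed(seed,
        matrix(runif(nrow(base) * 2, -jitter, jitter) * dx, ncol = 2))
      pts[, 1] <- pmin(pmax(pts[, 1], 1e-4), 1 - 1e-4)
      pts[, 2] <- pmin(pmax(pts[, 2], 1e-4), 1 - 1e-4)
      tess <- voronoi_tessellate(pts, epi_domain(mode = "bounded"))
      if (length(unique(polygon_classes(tess))) >= 3 &&
          min_shared_edge(tess) * raster_px >= min_edge_px)
        return(tess)
    }
    stop("no resolvable fixture found")
  })
}

triangle_graph <- function() contact_graph_from_edges(3, rbind(c(1, 2), c(1, 3), c(2, 3)))
path3_graph <- function() contact_graph_from_edges(3, rbind(c(1, 2), c(2, 3)))
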