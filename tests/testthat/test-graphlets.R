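test_that("the graphlet catalog has 30 graphlets / 73 orbits with the classic small-orbit layout", {
  cat_obj <- graphlet_catalog()
  expect_equal(nrow(cat_obj$graphlets), 30)
  expect_equal(cat_obj$n_orbits, 73)
  # orbits 0-14 (2-4 node graphlets): degree of each orbit in catalog order
  o <- cat_obj$orbits[cat_obj$orbits$k <= 4, ]
  expect_equal(o$orbit, 0:14)
  expect_equal(o$degree, c(1, 1, 2, 2, 1, 2, 1, 3, 2, 1, 2, 3, 2, 3, 3))
})

test_that("triangle, path and star orbit counts match closed forms", {
  ok3 <- unclass(count_orbits(triangle_graph()))
  expect_true(all(ok3[, "O0"] == 2))
  expect_true(all(ok3[, "O3"] == 1))
  expect_true(all(ok3[, c("O1", "O2")] == 0))

  op3 <- unclass(count_orbits(path3_graph()))
  expect_equal(unname(op3[, "O1"]), c(1, 0, 1))
  expect_equal(unname(op3[, "O2"]), c(0, 1, 0))

  s4 <- contact_graph_from_edges(5, cbind(1, 2:5))
  os <- unclass(count_orbits(s4))
  expect_equal(unname(os[1, "O2"]), choose(4, 2))  # path centers through hub
  expect_equal(unname(os[1, "O7"]), choose(4, 3))  # claw centers
  expect_equal(unname(os[1, "O23"]), choose(4, 4)) # 4-star center
})

test_that("orbit counting equals brute-force enumeration on random and lattice graphs", {
  for (seed in 1:20) {
    n <- 10 + (seed %% 3) * 5
    g <- random_graph(n, 0.2, seed)
    expect_identical(unclass(count_orbits(g)), unclass(brute_force_orbits(g)),
                     label = paste("seed", seed))
  }
  hx <- contact_graph(hexagonal_lattice(4, 5))
  expect_identical(unclass(count_orbits(hx)), unclass(brute_force_orbits(hx)))

  empty <- contact_graph_from_edges(6, matrix(integer(0), 0, 2))
  expect_true(all(unclass(count_orbits(empty)) == 0))
  expect_true(all(unclass(brute_force_orbits(empty)) == 0))
  expect_error(brute_force_orbits(random_graph(61, 0.1, 1)), "n <= 60")
})

test_that("orbit 0 is the degree and orbit 3 triples count triangles", {
  for (seed in c(5, 17)) {
    g <- random_graph(20, 0.25, seed)
    om <- unclass(count_orbits(g))
    expect_equal(unname(om[, "O0"]), lengths(g$adj))
    A <- matrix(0, g$n, g$n)
    A[g$edges] <- 1; A[g$edges[, 2:1]] <- 1
    ntri <- sum(diag(A %*% A %*% A)) / 6
    expect_equal(sum(om[, "O3"]), 3 * ntri)
  }
})

test_that("GDD distance: identity, symmetry, range, and a hand-computed value", {
  for (seed in 1:5) {
    g <- random_graph(20, 0.2, seed)
    expect_equal(as.numeric(gdd_distance(g, g)), 0)
  }
  for (seed in 1:20) {
    a <- random_graph(15, 0.25, seed)
    b <- random_graph(18, 0.2, seed + 100)
    dab <- as.numeric(gdd_distance(a, b))
    expect_equal(dab, as.numeric(gdd_distance(b, a)))
    expect_gte(dab, 0); expect_lte(dab, 1)
  }
  # K3 vs P3 on orbit 0: N_K3 = {2: 1}, N_P3 = {1: 0.8, 2: 0.2}
  # D = sqrt(0.8^2 + 0.8^2) / sqrt(2) = 0.8
  d0 <- gdd_distance(triangle_graph(), path3_graph(), orbit_subset = 0)
  expect_equal(as.numeric(d0), 0.8, tolerance = 1e-12)
  # orbit present in one graph only contributes the maximal distance 1
  d3 <- gdd_distance(triangle_graph(), path3_graph(), orbit_subset = 3)
  expect_equal(as.numeric(d3), 1)
})

test_that("GDD grows monotonically with lattice rewiring", {
  hx <- contact_graph(hexagonal_lattice(14, 14))
  fracs <- c(0, 0.05, 0.10, 0.15, 0.20)
  rewire <- function(seed, f) {
    e <- hx$edges
    k <- round(f * nrow(e))
    if (k == 0) return(e)
    epitess:::with_seed(seed, {
      e2 <- e[-sample(nrow(e), k), , drop = FALSE]
      have <- paste(e2[, 1], e2[, 2])
      while (nrow(e2) < nrow(e)) {
        cand <- sort(sample(hx$n, 2))
        key <- paste(cand[1], cand[2])
        if (!(key %in% have)) {
          e2 <- rbind(e2, cand)
          have <- c(have, key)
        }
      }
      e2
    })
  }
  d <- sapply(1:10, function(seed) vapply(fracs, function(f)
    as.numeric(gdd_distance(contact_graph_from_edges(hx$n, rewire(seed, f)), hx)),
    0))                                     # fractions x seeds
  # pooled monotone trend and strictly increasing ensemble means
  expect_gt(cor(rep(fracs, 10), as.vector(d), method = "spearman"), 0.9)
  expect_true(all(diff(rowMeans(d)) > 0))
})

test_that("contact-graph exclusion border matches a breadth-first audit", {
  tess <- relaxed_tess(300, 4, seed = 8)
  ce <- extract_cells(rasterize(tess, 512, 512, 0.5))
  g <- build_contact_graph(ce, exclusion_depth = 4)
  # independent BFS from all border/gap cells
  df <- ce$cells
  bad <- which(df$touches_border | df$touches_gap)
  dist <- rep(Inf, g$n)
  dist[bad] <- 0
  frontier <- bad
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(g$adj[frontier])), which(is.finite(dist)))
    dist[nxt] <- d
    frontier <- nxt
  }
  expect_identical(g$valid, dist > 4)
  expect_gt(sum(g$valid), 0)

  # periodic lattice: all nodes valid, 6-regular
  hx <- contact_graph(hexagonal_lattice(8, 8))
  expect_true(all(hx$valid))
  expect_true(all(lengths(hx$adj) == 6))
})

test_that("edge lists round trip through plain text", {
  g <- random_graph(12, 0.3, 2)
  f <- tempfile(fileext = ".txt")
  write_edgelist(g, f)
  g2 <- read_edgelist(f, n = 12)
  expect_identical(g2$edges, g$edges)
})
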