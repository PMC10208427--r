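#' Reference tessellation graphs (hexagonal, random Voronoi, Voronoi-5)
#'
#' Builds the three reference contact graphs against which samples are
#' placed: a periodic hexagonal lattice ("Epi-Hexagons"), the contact graph
#' of a uniform-random-seed Voronoi diagram ("Epi-Random", iteration 0, i.e.
#' pre-relaxation), and the diagram after five noiseless Lloyd iterations
#' ("Epi-Voronoi5").  Orbit matrices are precomputed.  Reproducible from
#' `rng_seed`.
#'
#' @param n_cells target number of cells (>= 100); the hexagonal lattice uses
#'   the nearest realizable even-rows grid, reported in the result.
#' @param rng_seed integer seed.
#' @return an `epi_reference_set`: `hex_graph`, `random_graph`,
#'   `voronoi5_graph` (+ `*_orbits`), `n_cells`, `rng_seed`.
#' @export
build_reference_set <- function(n_cells = 400, rng_seed = 1L) {
  if (n_cells < 100) .stop_invalid("n_cells must be >= 100")
  rows <- 2L * max(2L, round(sqrt(n_cells) / 2))
  cols <- max(3L, round(n_cells / rows))
  if (rows * cols != n_cells)
    message(sprintf("hex lattice uses %d x %d = %d cells (nearest to %d)",
                    rows, cols, rows * cols, n_cells))
  hex <- contact_graph(hexagonal_lattice(rows, cols))
  rnd_tess <- voronoi_tessellate(
    generate_seeds(n_cells, derive_seed(rng_seed, "epi-random")))
  rnd <- contact_graph(rnd_tess)
  v5_path <- lloyd_path(
    generate_seeds(n_cells, derive_seed(rng_seed, "epi-voronoi5")),
    n_iter = 5, noise_amplitude = 0, record_stride = 1L)
  v5 <- contact_graph(v5_path$diagrams[[length(v5_path$diagrams)]])
  structure(list(hex_graph = hex, random_graph = rnd, voronoi5_graph = v5,
                 hex_orbits = count_orbits(hex),
                 random_orbits = count_orbits(rnd),
                 voronoi5_orbits = count_orbits(v5),
                 n_cells = n_cells, rng_seed = rng_seed),
            class = "epi_reference_set")
}

#' @export
print.epi_reference_set <- function(x, ...) {
  cat(sprintf("<epi_reference_set> hex %d / random %d / voronoi5 %d nodes (seed %d)\n",
              x$hex_graph$n, x$random_graph$n, x$voronoi5_graph$n, x$rng_seed))
  invisible(x)
}

#' GDD coordinates of a sample against the reference set
#'
#' The sample's (distance-to-hexagons, distance-to-random,
#' distance-to-Voronoi5) triplet: its coordinates in the reference scatter
#' and the input to closest-CVTn selection and MANOVA.
#'
#' @param sample an `epi_contact_graph` (>= 30 valid nodes) or its
#'   `epi_orbits` matrix.
#' @param refs an [build_reference_set()] result.
#' @param orbit_subset orbits used in the GDD (default all 73).
#' @param sample_id,group optional identifiers carried along.
#' @return an `epi_gdd_triplet`: numeric `d_hex`, `d_random`, `d_voronoi5`
#'   in `[0,1]`, plus ids.
#' @export
gdd_triplet <- function(sample, refs, orbit_subset = 0:72,
                        sample_id = NA_character_, group = NA_character_) {
  orbits <- if (inherits(sample, "epi_contact_graph")) {
    if (sum(sample$valid) < 30)
      .stop_invalid("insufficient sample: fewer than 30 valid nodes")
    count_orbits(sample)
  } else sample
  if (nrow(orbit_rows_valid(orbits)) < 30)
    .stop_invalid("insufficient sample: fewer than 30 valid nodes")
  tr <- c(d_hex = as.numeric(gdd_distance(orbits, refs$hex_orbits, orbit_subset)),
          d_random = as.numeric(gdd_distance(orbits, refs$random_orbits, orbit_subset)),
          d_voronoi5 = as.numeric(gdd_distance(orbits, refs$voronoi5_orbits, orbit_subset)))
  if (any(!is.finite(tr))) .stop_invalid("non-finite GDD triplet")
  structure(list(triplet = tr, sample_id = sample_id, group = group),
            class = "epi_gdd_triplet")
}

#' @export
print.epi_gdd_triplet <- function(x, ...) {
  cat(sprintf("<epi_gdd_triplet> d_hex %.4f, d_random %.4f, d_voronoi5 %.4f%s\n",
              x$triplet[1], x$triplet[2], x$triplet[3],
              if (!is.na(x$sample_id)) paste0(" [", x$sample_id, "]") else ""))
  invisible(x)
}

as_triplet_vec <- function(x) {
  if (inherits(x, "epi_gdd_triplet")) x$triplet else {
    stopifnot(is.numeric(x), length(x) == 3)
    setNames(as.numeric(x), c("d_hex", "d_random", "d_voronoi5"))
  }
}

#' Build the CVTn reference scale
#'
#' Runs an ensemble of noisy Lloyd paths (CVTn) and records the GDD triplet
#' of every recorded iteration of every replicate.  The per-iteration
#' ensemble mean traces the CVTn path in triplet space (the gray-scale
#' reference curve); the replicate spread supplies the covariance used by
#' [randomization_significance()].
#'
#' @param refs a [build_reference_set()].
#' @param n_seeds cells per CVTn diagram.
#' @param n_iter total Lloyd iterations (700 in the full-scale protocol).
#' @param stride record every `stride`-th iteration (1 records all).
#' @param replicates ensemble size per iteration (>= 2; 20 in the full-scale
#'   protocol).
#' @param noise_amplitude CVTn seed noise (fraction of mean inter-seed
#'   spacing).  0.15 keeps the path ordered (hexagon fraction and
#'   hexagon-distance improve along iterations) while adding biological
#'   disorder; amplitudes near 0.5 overwhelm the Lloyd contraction and the
#'   path no longer orders.
#' @param rng_seed master seed.
#' @param orbit_subset orbits for the GDD.
#' @return an `epi_cvtn_scale`: `iterations`, `mean` (iterations x 3),
#'   `replicates` (array replicate x iteration x 3), parameters.
#' @export
build_cvtn_scale <- function(refs, n_seeds = 200, n_iter = 700, stride = 7,
                             replicates = 20, noise_amplitude = 0.15,
                             rng_seed = 1L, orbit_subset = 0:72) {
  if (replicates < 2) .stop_invalid("need >= 2 replicates")
  iters <- unique(c(1L, seq(1L, n_iter, by = as.integer(stride)), n_iter))
  arr <- array(NA_real_, c(replicates, length(iters), 3),
               dimnames = list(NULL, iters, c("d_hex", "d_random", "d_voronoi5")))
  for (r in seq_len(replicates)) {
    seeds <- generate_seeds(n_seeds, derive_seed(rng_seed, paste0("cvtn-init-", r)))
    path <- lloyd_path(seeds, n_iter = n_iter,
                       noise_amplitude = noise_amplitude,
                       rng_seed = derive_seed(rng_seed, paste0("cvtn-noise-", r)),
                       record_stride = as.integer(stride))
    for (i in seq_along(iters)) {
      d <- path$diagrams[[match(iters[i], path$iterations)]]
      arr[r, i, ] <- gdd_triplet(contact_graph(d), refs,
                                 orbit_subset = orbit_subset)$triplet
    }
  }
  structure(list(iterations = iters,
                 mean = apply(arr, c(2, 3), mean),
                 replicates = arr, n_seeds = n_seeds,
                 noise_amplitude = noise_amplitude, rng_seed = rng_seed,
                 orbit_subset = orbit_subset),
            class = "epi_cvtn_scale")
}

#' @export
print.epi_cvtn_scale <- function(x, ...) {
  cat(sprintf(
    "<epi_cvtn_scale> iterations %d..%d (%d recorded), %d replicates of %d cells\n",
    min(x$iterations), max(x$iterations), length(x$iterations),
    dim(x$replicates)[1], x$n_seeds))
  invisible(x)
}

#' Closest CVTn iteration to a sample
#'
#' The iteration whose ensemble-mean triplet has the smallest Euclidean
#' distance to the sample triplet; ties resolve to the lowest iteration.
#'
#' @param sample_triplet an `epi_gdd_triplet` or numeric length-3 vector.
#' @param scale an [build_cvtn_scale()] result.
#' @return the iteration number (integer).
#' @export
closest_cvtn <- function(sample_triplet, scale) {
  if (!length(scale$iterations)) .stop_invalid("empty CVTn scale")
  v <- as_triplet_vec(sample_triplet)
  d2 <- rowSums(sweep(scale$mean, 2, v)^2)
  as.integer(scale$iterations[which.min(d2)])
}

#' Randomization significance of a sample against the CVTn ensemble
#'
#' Tests whether a sample sits on the CVTn path: the ensemble replicates at
#' `at_iteration` define a Gaussian (mean and covariance) in triplet space;
#' `n_draws` draws from it give the null distribution of Mahalanobis
#' distances, and the empirical p-value is the fraction of draws at least as
#' far from the mean as the sample (with the standard +1 correction).  A
#' small p marks a sample off the CVTn path.  A near-singular covariance is
#' ridge-regularized with a message.
#'
#' @param sample_triplet `epi_gdd_triplet` or numeric length 3.
#' @param scale an `epi_cvtn_scale`.
#' @param at_iteration iteration at which to test (default: the closest one).
#' @param n_draws number of null draws (>= 1).
#' @param rng_seed seed for the draws.
#' @return list with `p`, `mahalanobis_sample`, `at_iteration`.
#' @export
randomization_significance <- function(sample_triplet, scale,
                                       at_iteration = NULL, n_draws = 1000,
                                       rng_seed = 1L) {
  if (n_draws < 1) .stop_invalid("invalid-argument: n_draws must be >= 1")
  v <- as_triplet_vec(sample_triplet)
  if (is.null(at_iteration)) at_iteration <- closest_cvtn(v, scale)
  i <- match(at_iteration, scale$iterations)
  if (is.na(i)) .stop_invalid("at_iteration is not on the scale")
  reps <- scale$replicates[, i, ]
  mu <- colMeans(reps)
  S <- stats::cov(reps)
  if (rcond(S) < 1e-10) {
    message("near-singular ensemble covariance; ridge-regularizing")
    S <- S + diag(3) * (sum(diag(S)) / 3 * 1e-6 + 1e-12)
  }
  d2s <- mahalanobis(v, mu, S)
  draws <- with_seed(rng_seed, MASS::mvrnorm(n_draws, mu, S))
  d2n <- mahalanobis(draws, mu, S)
  list(p = (1 + sum(d2n >= d2s)) / (n_draws + 1),
       mahalanobis_sample = sqrt(d2s), at_iteration = at_iteration)
}

#' MANOVA across groups of GDD triplets
#'
#' Wilks' lambda test of the hypothesis that the groups' triplets arise from
#' one population, on the three GDD coordinates as responses.
#'
#' @param groups a named list mapping group label to a list of
#'   `epi_gdd_triplet`s (or 3-column matrices), or a data frame with columns
#'   `group`, `d_hex`, `d_random`, `d_voronoi5`.
#' @return an `epi_manova`: `wilks_lambda`, `approx_f`, `df` (num, den),
#'   `p_value`, `group_means`.
#' @export
manova_groups <- function(groups) {
  df <- if (is.data.frame(groups)) groups else {
    if (length(groups) < 2) .stop_invalid("need at least 2 groups")
    do.call(rbind, lapply(names(groups), function(g) {
      m <- do.call(rbind, lapply(groups[[g]], as_triplet_vec))
      data.frame(group = g, d_hex = m[, 1], d_random = m[, 2],
                 d_voronoi5 = m[, 3])
    }))
  }
  df$group <- factor(df$group)
  if (nlevels(df$group) < 2) .stop_invalid("need at least 2 groups")
  sizes <- table(df$group)
  if (any(sizes < 4))
    .stop_invalid("each group needs more samples than response dimensions (>= 4)")
  y <- as.matrix(df[, c("d_hex", "d_random", "d_voronoi5")])
  fit <- manova(y ~ group, data = df)
  st <- tryCatch(summary(fit, test = "Wilks")$stats,
                 error = function(e) .stop_invalid(
                   "singular within-group covariance; reduce dimensions or pool groups: ",
                   conditionMessage(e)))
  gm <- aggregate(y, list(group = df$group), mean)
  structure(list(wilks_lambda = unname(st["group", "Wilks"]),
                 approx_f = unname(st["group", "approx F"]),
                 df = c(num = unname(st["group", "num Df"]),
                        den = unname(st["group", "den Df"])),
                 p_value = unname(st["group", "Pr(>F)"]),
                 group_means = gm),
            class = "epi_manova")
}

#' @export
print.epi_manova <- function(x, ...) {
  cat(sprintf(
    "<epi_manova> Wilks' lambda %.4f, F(%g, %g) = %.3f, p = %.4g\n",
    x$wilks_lambda, x$df["num"], x$df["den"], x$approx_f, x$p_value))
  invisible(x)
}
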