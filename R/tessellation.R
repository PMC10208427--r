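#' Voronoi tessellation of a seed set
#'
#' Computes the Voronoi diagram of the seeds: each cell is the locus of
#' points nearer to its seed than to any other (Euclidean distance; periodic
#' distance on a periodic domain).  In bounded mode cells are clipped to the
#' domain rectangle; in periodic mode the diagram tessellates the torus and
#' cell polygons may extend past the rectangle edges.
#'
#' @param seeds an [epi_seeds()] object (or a plain n x 2 matrix, taken to
#'   live on `domain`).
#' @param domain domain used when `seeds` is a bare matrix.
#' @param jitter deterministic perturbation amplitude applied to the seeds
#'   before tessellating; used by lattice constructors to break degenerate
#'   4-valent vertices (e.g. square grids) into generic trivalent ones.
#' @return an object of class `epi_tessellation` with fields `cells` (list of
#'   polygon vertex rings), `seeds`, `adjacency` (list of neighbor index
#'   vectors, symmetric), `areas`, `centroids`, `domain`, `energy` (the
#'   quantization energy \eqn{\sum_i \int_{V_i} \|x - s_i\|^2 dx}) and
#'   `iteration_index` (0 for a raw random-seed diagram).
#' @export
#' @examples
#' s <- generate_seeds(50, rng_seed = 1)
#' tess <- voronoi_tessellate(s)
#' mean(lengths(tess$adjacency))   # ~6 on a periodic domain
voronoi_tessellate <- function(seeds, domain = epi_domain(), jitter = 0) {
  if (is.matrix(seeds)) seeds <- epi_seeds(seeds, domain)
  if (!inherits(seeds, "epi_seeds")) .stop_invalid("seeds must be epi_seeds")
  domain <- seeds$domain
  pts <- seeds$points
  n <- nrow(pts)
  if (domain_is_periodic(domain) && n < 4)
    .stop_invalid("periodic mode requires at least 4 seeds")
  if (jitter > 0) {
    ang <- (seq_len(n) * 0.61803398874989) %% 1 * 2 * pi  # deterministic
    pts <- domain_constrain(pts + jitter * cbind(cos(ang), sin(ang)), domain)
  }
  res <- cpp_voronoi(pts, domain$xlim[1], domain$xlim[2],
                     domain$ylim[1], domain$ylim[2],
                     domain_is_periodic(domain))
  adj <- res$neighbors
  # symmetrize (micro-edges at numerical tolerance can be seen one-sidedly)
  for (i in seq_len(n)) for (j in adj[[i]])
    if (!(i %in% adj[[j]])) adj[[j]] <- sort(c(adj[[j]], i))
  new_tessellation(cells = res$cells, seeds = pts, adjacency = adj,
                   areas = res$areas, centroids = res$centroids,
                   domain = domain, energy = res$energy, iteration_index = 0L)
}

new_tessellation <- function(cells, seeds, adjacency, areas, centroids,
                             domain, energy = NA_real_, iteration_index = 0L) {
  rel <- abs(sum(areas) - domain_area(domain)) / domain_area(domain)
  if (rel > 1e-6)
    .stop_invalid(sprintf("cell areas do not tile the domain (rel err %.2g)",
                          rel))
  structure(list(cells = cells, seeds = seeds, adjacency = adjacency,
                 areas = areas, centroids = centroids, domain = domain,
                 energy = energy, iteration_index = as.integer(iteration_index)),
            class = "epi_tessellation")
}

#' Number of sides (polygon class) of every cell in a tessellation
#'
#' The polygon class of a cell is its number of neighbors, which for
#' trivalent vertices equals its number of sides.
#'
#' @param tess an `epi_tessellation`.
#' @return integer vector of neighbor counts.
#' @export
polygon_classes <- function(tess) {
  lengths(tess$adjacency)
}

#' Isotropically rescale a tessellation
#'
#' Multiplies every coordinate by `s`.  Topology (adjacency, polygon classes,
#' contact graph) is untouched; areas scale by `s^2`.
#'
#' @param tess an `epi_tessellation`.
#' @param s positive scale factor.
#' @return the rescaled `epi_tessellation`.
#' @export
rescale_tessellation <- function(tess, s) {
  if (!is.numeric(s) || length(s) != 1 || s <= 0)
    .stop_invalid("invalid-argument: s must be a positive scalar")
  dom <- epi_domain(tess$domain$xlim * s, tess$domain$ylim * s,
                    tess$domain$mode)
  new_tessellation(cells = lapply(tess$cells, function(r) r * s),
                   seeds = tess$seeds * s,
                   adjacency = tess$adjacency, areas = tess$areas * s^2,
                   centroids = tess$centroids * s, domain = dom,
                   energy = tess$energy * s^4,
                   iteration_index = tess$iteration_index)
}

#' Lloyd (centroidal Voronoi) iteration path
#'
#' Runs Lloyd's algorithm: at every iteration each seed moves to the centroid
#' of its Voronoi cell; with `noise_amplitude > 0` each seed is then
#' displaced by an isotropic random vector of fixed length
#' `noise_amplitude * mean inter-seed spacing` (the noisy CVTn variant used
#' as an ordered reference scale of epithelial-like organization).  The
#' quantization energy of the current diagram is recorded at every
#' iteration; with zero noise it is non-increasing (Lloyd descent).
#'
#' @param seeds starting [epi_seeds()].
#' @param n_iter number of Lloyd iterations (>= 1); the classic reference
#'   scale uses 700.
#' @param noise_amplitude noise length as a fraction of the mean inter-seed
#'   spacing `sqrt(domain area / n)`; 0 gives the plain CVT path.
#' @param rng_seed seed for the noise displacements (ignored when
#'   `noise_amplitude = 0`).
#' @param record_stride keep every `record_stride`-th diagram (iteration 1 is
#'   always kept); 1 keeps all of them.
#' @return an object of class `epi_cvt_path`: `diagrams` (list of
#'   `epi_tessellation`, with `iteration_index` set), `energy_trace`
#'   (length `n_iter`), `noise_amplitude`, `iterations` (indices of the
#'   recorded diagrams).
#' @export
lloyd_path <- function(seeds, n_iter = 700, noise_amplitude = 0,
                       rng_seed = 0L, record_stride = 1L) {
  if (n_iter < 1) .stop_invalid("invalid-argument: n_iter must be >= 1")
  if (noise_amplitude < 0) .stop_invalid("invalid-argument: negative noise")
  domain <- seeds$domain
  n <- nrow(seeds$points)
  spacing <- sqrt(domain_area(domain) / n)
  amp <- noise_amplitude * spacing
  pts <- seeds$points
  energy <- numeric(n_iter)
  keep <- unique(c(1L, seq(1L, n_iter, by = as.integer(record_stride)), n_iter))
  diagrams <- vector("list", length(keep))
  with_seed(rng_seed, {
    for (k in seq_len(n_iter)) {
      tess <- voronoi_tessellate(epi_seeds(pts, domain))
      tess$iteration_index <- k
      energy[k] <- tess$energy
      if (k %in% keep) diagrams[[match(k, keep)]] <- tess
      pts <- tess$centroids
      if (amp > 0) {
        ang <- runif(n, 0, 2 * pi)
        pts <- pts + amp * cbind(cos(ang), sin(ang))
      }
      pts <- domain_constrain(pts, domain)
    }
  })
  structure(list(diagrams = diagrams, energy_trace = energy,
                 noise_amplitude = noise_amplitude, iterations = keep,
                 n_iter = as.integer(n_iter)),
            class = "epi_cvt_path")
}

#' Regular hexagonal lattice tessellation
#'
#' Builds a honeycomb of `rows x cols` hexagons by Voronoi-tessellating a
#' triangular lattice of seeds.  On a periodic domain every cell has exactly
#' six neighbors; `rows` must be even for the lattice to wrap.
#'
#' @param rows,cols lattice dimensions (>= 3; `rows` even when periodic).
#' @param domain an [epi_domain()].
#' @return an `epi_tessellation` of `rows * cols` hexagonal cells.
#' @export
#' @examples
#' hx <- hexagonal_lattice(8, 8)
#' table(polygon_classes(hx))       # all cells are hexagons
hexagonal_lattice <- function(rows, cols, domain = epi_domain()) {
  if (rows < 3 || cols < 3)
    .stop_invalid("invalid-argument: rows and cols must be >= 3")
  if (domain_is_periodic(domain) && rows %% 2 != 0)
    .stop_invalid("invalid-argument: periodic wrapping needs an even number of rows")
  Lx <- diff(domain$xlim); Ly <- diff(domain$ylim)
  dx <- Lx / cols; dy <- Ly / rows
  g <- expand.grid(c = seq_len(cols) - 1L, r = seq_len(rows) - 1L)
  pts <- cbind(domain$xlim[1] + (g$c + 0.25 + 0.5 * (g$r %% 2)) * dx,
               domain$ylim[1] + (g$r + 0.5) * dy)
  voronoi_tessellate(epi_seeds(pts, domain), jitter = 1e-9 * min(dx, dy))
}

#' @export
print.epi_tessellation <- function(x, ...) {
  pc <- polygon_classes(x)
  cat(sprintf("<epi_tessellation> %d cells on %s domain, iteration %d\n",
              length(x$cells), x$domain$mode, x$iteration_index))
  cat(sprintf("  mean polygon class %.3f, total area %.6g\n",
              mean(pc), sum(x$areas)))
  invisible(x)
}

#' @export
print.epi_cvt_path <- function(x, ...) {
  cat(sprintf(
    "<epi_cvt_path> %d iterations (%d diagrams kept), noise %.3g\n",
    x$n_iter, length(x$diagrams), x$noise_amplitude))
  cat(sprintf("  energy %.4g -> %.4g\n", x$energy_trace[1],
              x$energy_trace[x$n_iter]))
  invisible(x)
}
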