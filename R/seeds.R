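#' Generate a reproducible set of random seed points
#'
#' Draws `n` i.i.d. uniform points in the domain.  The draw is a pure
#' function of `(n, rng_seed, domain)`: the global RNG state is saved and
#' restored, so identical arguments always give bitwise-identical seed sets.
#'
#' @param n number of seeds (>= 1).
#' @param rng_seed integer RNG seed.
#' @param domain an [epi_domain()].
#' @return an object of class `epi_seeds` with fields `points` (n x 2
#'   matrix), `domain`, and `rng_seed`.
#' @export
#' @examples
#' s <- generate_seeds(100, rng_seed = 7)
#' identical(s$points, generate_seeds(100, rng_seed = 7)$points)
generate_seeds <- function(n, rng_seed, domain = epi_domain()) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != round(n))
    .stop_invalid("invalid-argument: n must be a positive integer")
  pts <- with_seed(rng_seed, cbind(
    runif(n, domain$xlim[1], domain$xlim[2]),
    runif(n, domain$ylim[1], domain$ylim[2])
  ))
  epi_seeds(pts, domain, rng_seed)
}

epi_seeds <- function(points, domain, rng_seed = NA_integer_) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2) .stop_invalid("seed points must be n x 2")
  if (anyDuplicated(points)) .stop_invalid("invalid-argument: coincident seeds")
  structure(list(points = points, domain = domain, rng_seed = rng_seed),
            class = "epi_seeds")
}

# evaluate expr under a local RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-stage seed derived from a master seed and a label
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483629)
}

#' @export
print.epi_seeds <- function(x, ...) {
  cat(sprintf("<epi_seeds> %d points, rng_seed = %s\n", nrow(x$points),
              format(x$rng_seed)))
  print(x$domain)
  invisible(x)
}
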