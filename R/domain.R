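#' Rectangular analysis domain
#'
#' Defines the rectangle on which tessellations live and how its boundary is
#' treated: `"bounded"` clips cells at the rectangle walls, `"periodic"`
#' wraps the rectangle into a torus (no boundary artifacts; every vertex of a
#' generic Voronoi diagram is trivalent, so the mean polygon class is exactly
#' six by the Euler relation).
#'
#' @param xlim,ylim numeric length-2 extents.
#' @param mode `"periodic"` or `"bounded"`.
#' @return an object of class `epi_domain`.
#' @export
#' @examples
#' epi_domain()                      # periodic unit square (the default)
#' epi_domain(c(0, 2), c(0, 1), "bounded")
epi_domain <- function(xlim = c(0, 1), ylim = c(0, 1),
                       mode = c("periodic", "bounded")) {
  mode <- match.arg(mode)
  if (length(xlim) != 2 || length(ylim) != 2 ||
      !all(is.finite(c(xlim, ylim))) || xlim[2] <= xlim[1] ||
      ylim[2] <= ylim[1])
    .stop_invalid("invalid domain extents")
  structure(list(xlim = as.numeric(xlim), ylim = as.numeric(ylim),
                 mode = mode), class = "epi_domain")
}

domain_area <- function(domain) {
  diff(domain$xlim) * diff(domain$ylim)
}

domain_is_periodic <- function(domain) identical(domain$mode, "periodic")

# wrap (periodic) or clamp (bounded) points into the domain
domain_constrain <- function(pts, domain) {
  Lx <- diff(domain$xlim); Ly <- diff(domain$ylim)
  if (domain_is_periodic(domain)) {
    pts[, 1] <- domain$xlim[1] + (pts[, 1] - domain$xlim[1]) %% Lx
    pts[, 2] <- domain$ylim[1] + (pts[, 2] - domain$ylim[1]) %% Ly
  } else {
    eps <- 1e-12 * max(Lx, Ly)
    pts[, 1] <- pmin(pmax(pts[, 1], domain$xlim[1] + eps), domain$xlim[2] - eps)
    pts[, 2] <- pmin(pmax(pts[, 2], domain$ylim[1] + eps), domain$ylim[2] - eps)
  }
  pts
}

#' @export
print.epi_domain <- function(x, ...) {
  cat(sprintf("<epi_domain> [%g, %g] x [%g, %g], %s\n",
              x$xlim[1], x$xlim[2], x$ylim[1], x$ylim[2], x$mode))
  invisible(x)
}
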