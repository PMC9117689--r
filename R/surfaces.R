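#' Analytic potential surfaces
#'
#' A `potential_surface` bundles an energy function and its analytic
#' gradient; it is the shared oracle behind the elastic-band relaxer and
#' the Brownian simulator. `energy()` and `gradient()` accept a single
#' point (numeric vector) or a matrix of points in rows.
#'
#' @param energy_fn Function: matrix of points (rows) -> numeric vector.
#' @param gradient_fn Function: matrix of points -> matrix of gradients.
#' @param dim Dimensionality of the surface.
#' @param name Label used in printing.
#' @return Object of class `potential_surface`.
#' @export
potential_surface <- function(energy_fn, gradient_fn, dim, name = "custom") {
  structure(list(energy_fn = energy_fn, gradient_fn = gradient_fn,
                 dim = dim, name = name),
            class = "potential_surface")
}

as_points <- function(x, dim) {
  if (is.null(nrow(x))) x <- matrix(x, ncol = dim, byrow = TRUE)
  stopifnot(ncol(x) == dim)
  x
}

#' @rdname potential_surface
#' @param surface A `potential_surface`.
#' @param x Point (vector) or matrix of points in rows.
#' @export
surface_energy <- function(surface, x) {
  surface$energy_fn(as_points(x, surface$dim))
}

#' @rdname potential_surface
#' @export
surface_gradient <- function(surface, x) {
  surface$gradient_fn(as_points(x, surface$dim))
}

#' @export
print.potential_surface <- function(x, ...) {
  cat("<potential_surface>", x$name, "(", x$dim, "dimensional )\n")
  invisible(x)
}

#' Mueller-Brown surface
#'
#' The standard two-dimensional four-Gaussian benchmark for
#' minimum-energy-path methods, with its three minima and two saddle
#' points.
#'
#' @return A 2-D `potential_surface`.
#' @export
muller_brown <- function() {
  A <- c(-200, -100, -170, 15)
  a <- c(-1, -1, -6.5, 0.7)
  b <- c(0, 0, 11, 0.6)
  cc <- c(-10, -10, -6.5, 0.7)
  x0 <- c(1, 0, -0.5, -1)
  y0 <- c(0, 0.5, 1.5, 1)
  energy_fn <- function(X) {
    V <- numeric(nrow(X))
    for (k in 1:4) {
      dx <- X[, 1] - x0[k]
      dy <- X[, 2] - y0[k]
      V <- V + A[k] * exp(a[k] * dx^2 + b[k] * dx * dy + cc[k] * dy^2)
    }
    V
  }
  gradient_fn <- function(X) {
    G <- matrix(0, nrow(X), 2)
    for (k in 1:4) {
      dx <- X[, 1] - x0[k]
      dy <- X[, 2] - y0[k]
      e <- A[k] * exp(a[k] * dx^2 + b[k] * dx * dy + cc[k] * dy^2)
      G[, 1] <- G[, 1] + e * (2 * a[k] * dx + b[k] * dy)
      G[, 2] <- G[, 2] + e * (b[k] * dx + 2 * cc[k] * dy)
    }
    G
  }
  potential_surface(energy_fn, gradient_fn, dim = 2, name = "muller_brown")
}

#' One-dimensional double well
#'
#' `V(x) = x^4 - 2 x^2`, minima at x = -1 and 1, barrier (saddle) at 0.
#'
#' @return A 1-D `potential_surface`.
#' @export
double_well_1d <- function() {
  potential_surface(
    function(X) X[, 1]^4 - 2 * X[, 1]^2,
    function(X) matrix(4 * X[, 1]^3 - 4 * X[, 1], ncol = 1),
    dim = 1, name = "double_well_1d"
  )
}

#' Multi-well Gaussian surface in collective-variable space
#'
#' `V(x) = -sum_w depth_w * exp(-sum_axis ((x - center)/width)^2)`, an
#' inverted-Gaussian well per metastable basin, with analytic gradient.
#' A soft quadratic confinement wall bounds the landscape (collective
#' variables are physically bounded: distances by the fold, dihedrals by
#' their period), keeping the Boltzmann measure of the flat inter-basin
#' plateau finite.
#'
#' @param wells Tibble/data frame with columns `center_distance`,
#'   `center_dihedral`, `depth`, `width_distance`, `width_dihedral`
#'   (depths and widths > 0); see [at2r_cv_wells()] for the default
#'   three-basin layout.
#' @param confinement `NULL` for none; `"auto"` (default) places the
#'   walls at the well centers padded by two widths, with wall length
#'   scale half the smallest width per axis; or a list with
#'   `lower`, `upper`, `scale` (length-2 each) and `strength`.
#' @return A 2-D `potential_surface` with the wells stored in
#'   `$wells` and the wall in `$confinement`.
#' @export
make_cv_surface <- function(wells = at2r_cv_wells(), confinement = "auto") {
  wells <- tibble::as_tibble(wells)
  stopifnot(nrow(wells) >= 1,
            all(wells$depth > 0),
            all(wells$width_distance > 0), all(wells$width_dihedral > 0))
  if (identical(confinement, "auto")) {
    confinement <- list(
      lower = c(min(wells$center_distance - 2 * wells$width_distance),
                min(wells$center_dihedral - 2 * wells$width_dihedral)),
      upper = c(max(wells$center_distance + 2 * wells$width_distance),
                max(wells$center_dihedral + 2 * wells$width_dihedral)),
      scale = c(min(wells$width_distance), min(wells$width_dihedral)) / 2,
      strength = 1
    )
  }
  wall_energy <- function(X) {
    if (is.null(confinement)) return(0)
    v <- 0
    for (ax in 1:2) {
      over <- pmax(0, X[, ax] - confinement$upper[ax]) +
        pmax(0, confinement$lower[ax] - X[, ax])
      v <- v + confinement$strength * (over / confinement$scale[ax])^2
    }
    v
  }
  wall_gradient <- function(X) {
    G <- matrix(0, nrow(X), 2)
    if (is.null(confinement)) return(G)
    for (ax in 1:2) {
      signed <- pmax(0, X[, ax] - confinement$upper[ax]) -
        pmax(0, confinement$lower[ax] - X[, ax])
      G[, ax] <- 2 * confinement$strength * signed / confinement$scale[ax]^2
    }
    G
  }
  energy_fn <- function(X) {
    V <- numeric(nrow(X))
    for (w in seq_len(nrow(wells))) {
      V <- V - wells$depth[w] * exp(
        -((X[, 1] - wells$center_distance[w]) / wells$width_distance[w])^2 -
          ((X[, 2] - wells$center_dihedral[w]) / wells$width_dihedral[w])^2)
    }
    V + wall_energy(X)
  }
  gradient_fn <- function(X) {
    G <- matrix(0, nrow(X), 2)
    for (w in seq_len(nrow(wells))) {
      u <- (X[, 1] - wells$center_distance[w]) / wells$width_distance[w]
      v <- (X[, 2] - wells$center_dihedral[w]) / wells$width_dihedral[w]
      e <- wells$depth[w] * exp(-u^2 - v^2)
      G[, 1] <- G[, 1] + e * 2 * u / wells$width_distance[w]
      G[, 2] <- G[, 2] + e * 2 * v / wells$width_dihedral[w]
    }
    G + wall_gradient(X)
  }
  srf <- potential_surface(energy_fn, gradient_fn, dim = 2, name = "cv_wells")
  srf$wells <- wells
  srf$confinement <- confinement
  srf
}

#' Boltzmann weights of the wells of a Gaussian multi-well surface
#'
#' Integrates `exp(-V/kT)` on a dense grid and partitions the mass by
#' nearest well center (in width-scaled coordinates), giving the
#' equilibrium population each basin should attract.
#'
#' @param surface A [make_cv_surface()] result.
#' @param kT Thermal energy in the surface's units.
#' @param n_grid Grid points per axis.
#' @return Numeric vector of well weights summing to 1.
#' @export
well_boltzmann_weights <- function(surface, kT = 1, n_grid = 400) {
  wells <- surface$wells
  pad_d <- 4 * max(wells$width_distance)
  pad_x <- 4 * max(wells$width_dihedral)
  gx <- seq(min(wells$center_distance) - pad_d,
            max(wells$center_distance) + pad_d, length.out = n_grid)
  gy <- seq(min(wells$center_dihedral) - pad_x,
            max(wells$center_dihedral) + pad_x, length.out = n_grid)
  pts <- cbind(rep(gx, times = n_grid), rep(gy, each = n_grid))
  w <- exp(-surface_energy(surface, pts) / kT)
  lab <- nearest_well(surface, pts)
  m <- tapply(w, factor(lab, levels = seq_len(nrow(wells))), sum)
  m <- ifelse(is.na(m), 0, m)
  as.numeric(m / sum(m))
}

# Nearest well center in width-scaled coordinates.
nearest_well <- function(surface, X) {
  wells <- surface$wells
  d2 <- sapply(seq_len(nrow(wells)), function(w) {
    ((X[, 1] - wells$center_distance[w]) / wells$width_distance[w])^2 +
      ((X[, 2] - wells$center_dihedral[w]) / wells$width_dihedral[w])^2
  })
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  max.col(-d2, ties.method = "first")
}
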