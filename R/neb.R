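# Nudged elastic band: a chain of replicas between two fixed endpoints is
# relaxed so spring forces act along the local band tangent and the true
# potential force acts only perpendicular to it, yielding a discretised
# minimum-energy path that cannot slide into the basins.

#' Initialise an elastic band
#'
#' Replicas are linearly interpolated between the endpoints (inclusive);
#' the endpoints are flagged fixed and never move.
#'
#' @param start,end Endpoint coordinates (numeric vectors, same length).
#' @param n_interior Number of interior replicas (default 52).
#' @param spring_k Spring constant in energy/length^2 (default 50).
#' @return Object of class `neb_band`: `replicas` (matrix, one row per
#'   replica), `fixed`, `spring_k`, plus `energies`/`tangents` once
#'   evaluated.
#' @export
init_band <- function(start, end, n_interior = 52, spring_k = 50) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  stopifnot(length(start) == length(end))
  if (all(start == end)) {
    abort("coincident endpoints give a degenerate band",
          class = "conformscape_degenerate_error")
  }
  if (n_interior < 1) abort("need at least 1 interior replica")
  n <- n_interior + 2
  t <- seq(0, 1, length.out = n)
  reps <- outer(1 - t, start) + outer(t, end)
  structure(list(replicas = reps,
                 fixed = c(TRUE, rep(FALSE, n_interior), TRUE),
                 spring_k = spring_k,
                 energies = NULL, tangents = NULL,
                 converged = NA, residual = NA_real_),
            class = "neb_band")
}

#' @export
print.neb_band <- function(x, ...) {
  cat("<neb_band>", nrow(x$replicas), "replicas in", ncol(x$replicas),
      "dimensions; k =", x$spring_k,
      if (isTRUE(x$converged)) "; converged" else "", "\n")
  invisible(x)
}

#' Band tangent at an interior replica
#'
#' The energy-weighted upwind tangent: uphill replicas take the forward
#' difference, downhill ones the backward difference, and local extrema
#' blend both differences with the larger energy jump weighting the
#' higher-energy side. The result is normalised to unit length (the
#' force projections need a direction).
#'
#' @param band A `neb_band` with current `energies`.
#' @param i Interior replica index (`1 < i < n`).
#' @return Unit tangent vector.
#' @export
neb_tangent <- function(band, i) {
  R <- band$replicas
  V <- band$energies
  n <- nrow(R)
  stopifnot(!is.null(V), i > 1, i < n)
  fwd <- R[i + 1, ] - R[i, ]
  bwd <- R[i, ] - R[i - 1, ]
  tau <- if (V[i + 1] > V[i] && V[i] > V[i - 1]) {
    fwd
  } else if (V[i + 1] < V[i] && V[i] < V[i - 1]) {
    bwd
  } else {
    dmax <- max(abs(V[i + 1] - V[i]), abs(V[i - 1] - V[i]))
    dmin <- min(abs(V[i + 1] - V[i]), abs(V[i - 1] - V[i]))
    if (V[i + 1] >= V[i - 1]) dmax * fwd + dmin * bwd
    else dmin * fwd + dmax * bwd
  }
  nt <- vec_norm(tau)
  if (nt < 1e-12) {
    # energy weights can cancel when annealing noise disorders the band;
    # fall back to the central difference before declaring degeneracy
    tau <- R[i + 1, ] - R[i - 1, ]
    nt <- vec_norm(tau)
  }
  if (nt < 1e-12) {
    abort(paste0("degenerate geometry: zero-length tangent at replica ", i),
          class = "conformscape_degenerate_error")
  }
  tau / nt
}

#' Band forces
#'
#' For each interior replica: the true force with its parallel part
#' removed, `F_perp = -grad V + (grad V . tau) tau`, plus the spring
#' force projected onto the tangent, `F_par = k (|R_{i+1} - R_i| -
#' |R_i - R_{i-1}|) tau`. Endpoints receive zero force.
#'
#' @param band A `neb_band`.
#' @param surface A [potential_surface()].
#' @return List: `total`, `perp`, `parallel` (matrices), `energies`,
#'   `tangents`.
#' @export
band_forces <- function(band, surface) {
  R <- band$replicas
  n <- nrow(R)
  V <- surface_energy(surface, R)
  G <- surface_gradient(surface, R)
  if (any(!is.finite(V)) || any(!is.finite(G))) {
    bad <- which(!is.finite(V) | rowSums(!is.finite(G)) > 0)[1]
    abort(paste0("non-finite surface evaluation at replica ", bad),
          class = "conformscape_surface_error")
  }
  band$energies <- V
  tangents <- matrix(0, n, ncol(R))
  perp <- matrix(0, n, ncol(R))
  par <- matrix(0, n, ncol(R))
  for (i in 2:(n - 1)) {
    tau <- neb_tangent(band, i)
    tangents[i, ] <- tau
    g <- G[i, ]
    perp[i, ] <- -g + sum(g * tau) * tau
    smag <- band$spring_k *
      (vec_norm(R[i + 1, ] - R[i, ]) - vec_norm(R[i, ] - R[i - 1, ]))
    par[i, ] <- smag * tau
  }
  list(total = perp + par, perp = perp, parallel = par,
       energies = V, tangents = tangents)
}

#' Annealing schedule for band relaxation
#'
#' Ordered phases of (temperature, steps, spring constant, step size),
#' mirroring the usual protocol: heat with a soft spring, equilibrate
#' with the production spring, a hot anneal that cools to zero, then a
#' zero-temperature descent (the final phase must be at temperature 0).
#' Temperatures are in the surface's energy units and step counts in
#' optimizer steps.
#'
#' @param base_temperature Plateau temperature of the first phases, in
#'   the surface's energy units. Keep it small against
#'   `spring_k * spacing^2` or the thermal spread disorders the replica
#'   ordering along the band.
#' @param step_size Descent step (surface units); all phases share it
#'   unless overridden in the returned tibble.
#' @param steps_scale Multiplies all phase step counts.
#' @param spring_soft,spring_production Spring constants for the initial
#'   heating and the later phases (default 10 and 50).
#' @return Tibble of class `anneal_schedule`: `temperature_start`,
#'   `temperature_end`, `steps`, `spring_k`, `step_size`.
#' @export
anneal_schedule <- function(base_temperature = 0.01, step_size = 1e-4,
                            steps_scale = 1,
                            spring_soft = 10, spring_production = 50) {
  sched <- tibble::tibble(
    temperature_start = c(0, base_temperature, base_temperature * 5 / 3, 0),
    temperature_end = c(base_temperature, base_temperature, 0, 0),
    steps = ceiling(c(500, 600, 1500, 2000) * steps_scale),
    spring_k = c(spring_soft, rep(spring_production, 3)),
    step_size = step_size
  )
  class(sched) <- c("anneal_schedule", class(sched))
  sched
}

#' Relax an elastic band on a potential surface
#'
#' Damped Langevin steps on the total band force with per-phase
#' temperatures (noise amplitude proportional to the square root of
#' temperature) and spring constants, ending with a zero-temperature
#' descent that runs until the force residual drops below `tol` (or
#' `max_steps` is exhausted, in which case the band is returned flagged
#' non-converged). The final descent uses FIRE (fast inertial
#' relaxation), the standard accelerated quench for elastic bands.
#' Convergence requires the perpendicular true force and the projected
#' spring force to both fall below `tol`, i.e. the band lies on the
#' minimum-energy path with equilibrated spacing.
#'
#' @param band An [init_band()] result.
#' @param surface A [potential_surface()].
#' @param schedule An [anneal_schedule()] tibble.
#' @param seed Integer seed for the annealing noise.
#' @param tol Convergence tolerance on the max interior force component
#'   norms (default 1e-3).
#' @param max_steps Cap on the final descent (default 100000).
#' @return The relaxed `neb_band` with `energies`, `tangents`,
#'   `converged`, `residual` (max interior |F_perp|).
#' @export
relax_band <- function(band, surface, schedule = anneal_schedule(),
                       seed = 1, tol = 1e-3, max_steps = 100000) {
  stopifnot(inherits(band, "neb_band"))
  set.seed(seed)
  d <- ncol(band$replicas)
  interior <- which(!band$fixed)
  residuals <- function(f) {
    c(max(sqrt(rowSums(f$perp[interior, , drop = FALSE]^2))),
      max(sqrt(rowSums(f$parallel[interior, , drop = FALSE]^2))))
  }
  for (p in seq_len(nrow(schedule))) {
    band$spring_k <- schedule$spring_k[p]
    h <- schedule$step_size[p]
    final_phase <- p == nrow(schedule)
    if (!final_phase || schedule$temperature_start[p] > 0) {
      temps <- seq(schedule$temperature_start[p], schedule$temperature_end[p],
                   length.out = schedule$steps[p])
      for (s in seq_len(schedule$steps[p])) {
        f <- band_forces(band, surface)
        step <- h * f$total
        if (temps[s] > 0) {
          step[interior, ] <- step[interior, ] +
            sqrt(2 * temps[s] * h) * matrix(rnorm(length(interior) * d),
                                            length(interior), d)
        }
        step[band$fixed, ] <- 0
        band$replicas <- band$replicas + step
      }
    }
    if (final_phase) {
      # FIRE quench at zero temperature
      v <- matrix(0, nrow(band$replicas), d)
      dt <- h
      dt_max <- 4 * h
      alpha <- 0.1
      n_pos <- 0
      for (s in seq_len(max_steps)) {
        f <- band_forces(band, surface)
        F <- f$total
        F[band$fixed, ] <- 0
        if (s %% 10 == 1 && max(residuals(f)) < tol) break
        P <- sum(F * v)
        if (P > 0) {
          n_pos <- n_pos + 1
          vn <- sqrt(sum(v^2))
          fn <- sqrt(sum(F^2))
          v <- (1 - alpha) * v + alpha * vn * F / max(fn, 1e-30)
          if (n_pos > 5) {
            dt <- min(dt * 1.1, dt_max)
            alpha <- alpha * 0.99
          }
        } else {
          v[] <- 0
          dt <- dt * 0.5
          alpha <- 0.1
          n_pos <- 0
        }
        v <- v + dt * F
        band$replicas <- band$replicas + dt * v
      }
    }
  }
  f <- band_forces(band, surface)
  band$energies <- f$energies
  band$tangents <- f$tangents
  band$residual <- max(sqrt(rowSums(f$perp[interior, , drop = FALSE]^2)))
  res_par <- max(sqrt(rowSums(f$parallel[interior, , drop = FALSE]^2)))
  band$converged <- max(band$residual, res_par) < tol
  if (!band$converged) {
    warn(paste0("band not converged: residual force ",
                format(max(band$residual, res_par), digits = 3)))
  }
  band
}

#' @export
tidy.neb_band <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$replicas),
                           .name_repair = ~ paste0("coord_", seq_along(.)))
  out <- dplyr::mutate(out, replica = dplyr::row_number(),
                       fixed = x$fixed, .before = 1)
  if (!is.null(x$energies)) out$energy <- x$energies
  out
}

#' @export
autoplot.neb_band <- function(object, ...) {
  df <- tidy(object)
  stopifnot(!is.null(df$energy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$replica, y = .data$energy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "replica", y = "energy") +
    ggplot2::theme_minimal()
}

#' Align a band of structures
#'
#' Translates every replica's coordinate set to a common centroid and
#' rotates it onto the previous (already aligned) replica with the
#' optimal least-squares rotation (proper rotation enforced), removing
#' rigid-body differences along the band.
#'
#' @param replicas List of `(n_atoms x 3)` coordinate matrices.
#' @return List of aligned matrices.
#' @export
align_replicas <- function(replicas) {
  stopifnot(length(replicas) >= 2)
  na <- unique(vapply(replicas, nrow, integer(1)))
  if (length(na) != 1) abort("replicas differ in atom count")
  out <- replicas
  out[[1]] <- sweep(replicas[[1]], 2, colMeans(replicas[[1]]))
  for (i in 2:length(replicas)) {
    P <- sweep(replicas[[i]], 2, colMeans(replicas[[i]]))
    W <- kabsch_rotation(P, out[[i - 1]])
    out[[i]] <- P %*% W
  }
  out
}

#' Pick maximally diverse replicas
#'
#' Greedy max-min selection: both endpoints are always included, then
#' the replica farthest (in minimum distance) from the current selection
#' is added repeatedly. Ties break to the lower index. With
#' `mode = "adjacent_gap"` the n-2 interior replicas with the largest
#' distance to their predecessor are taken instead.
#'
#' @param x A `neb_band`, a matrix of replica coordinates (rows), or a
#'   precomputed symmetric distance matrix (with `is_distance = TRUE`).
#' @param n Number of replicas to select (>= 2).
#' @param mode `"maxmin"` (default) or `"adjacent_gap"`.
#' @param is_distance Treat `x` as a distance matrix.
#' @return Sorted integer indices of the selected replicas.
#' @export
select_diverse_replicas <- function(x, n, mode = c("maxmin", "adjacent_gap"),
                                    is_distance = FALSE) {
  mode <- match.arg(mode)
  D <- if (is_distance) {
    as.matrix(x)
  } else {
    R <- if (inherits(x, "neb_band")) x$replicas else as.matrix(x)
    as.matrix(stats::dist(R))
  }
  m <- nrow(D)
  if (n > m) abort(paste0("cannot select ", n, " from ", m, " replicas"))
  if (n < 2) abort("n must be at least 2")
  sel <- c(1L, m)
  if (mode == "adjacent_gap" && n > 2) {
    gaps <- D[cbind(2:m, 1:(m - 1))]
    cand <- setdiff(order(gaps, decreasing = TRUE) + 1L, c(1L, m + 1L))
    sel <- c(sel, head(setdiff(cand, sel), n - 2))
  } else {
    while (length(sel) < n) {
      rest <- setdiff(seq_len(m), sel)
      mind <- apply(D[rest, sel, drop = FALSE], 1, min)
      sel <- c(sel, rest[which.max(mind)])
    }
  }
  sort(sel)
}
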