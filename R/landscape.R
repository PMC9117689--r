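#' Free-energy landscape over the two collective variables
#'
#' Bins feature samples on a 2-D grid and converts occupancies to free
#' energies by Boltzmann inversion, `F(bin) = -kT ln(n_bin / n_max)`, so
#' the modal (deepest) bin sits at zero. Empty bins are `NA`, never 0:
#' an unvisited region carries no free-energy estimate.
#'
#' `kT` uses the gas constant 0.0019872041 kcal/(mol K); with
#' `units = "kT"` energies are reported in units of kT instead.
#'
#' @param features A feature series tibble (columns `distance_sum`,
#'   `dihedral`), or a list of them (trajectories are pooled).
#' @param n_bins Length-2 integer vector: bins along distance and
#'   dihedral (default `c(100, 100)`).
#' @param temperature Simulation temperature in kelvin (default 300).
#' @param units `"kcal/mol"` (default) or `"kT"`.
#' @param limits Optional list with `distance_sum` and `dihedral`
#'   length-2 ranges; default the observed range padded by 2%.
#' @return Object of class `conf_landscape`: bin edges, count matrix,
#'   free-energy matrix, temperature, kT.
#' @export
estimate_landscape <- function(features, n_bins = c(100, 100),
                               temperature = 300, units = c("kcal/mol", "kT"),
                               limits = NULL) {
  units <- match.arg(units)
  feats <- bind_feature_series(features)
  if (nrow(feats) < 1) abort("no feature samples")
  if (any(n_bins < 2)) abort("need at least 2 bins per axis")
  kT <- if (units == "kT") 1 else 0.0019872041 * temperature

  pad_range <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) r + c(-0.5, 0.5) else r + c(-1, 1) * 0.02 * diff(r)
  }
  rd <- limits$distance_sum %||% pad_range(feats$distance_sum)
  rx <- limits$dihedral %||% pad_range(feats$dihedral)
  d_edges <- seq(rd[1], rd[2], length.out = n_bins[1] + 1)
  x_edges <- seq(rx[1], rx[2], length.out = n_bins[2] + 1)

  bd <- findInterval(feats$distance_sum, d_edges, all.inside = FALSE)
  bx <- findInterval(feats$dihedral, x_edges, all.inside = FALSE)
  keep <- bd >= 1 & bd <= n_bins[1] & bx >= 1 & bx <= n_bins[2]
  counts <- matrix(0L, n_bins[1], n_bins[2])
  tab <- table(factor(bd[keep], levels = seq_len(n_bins[1])),
               factor(bx[keep], levels = seq_len(n_bins[2])))
  counts[] <- as.integer(tab)
  if (sum(counts > 0) == 1) {
    warn("all samples fall in a single bin; landscape is degenerate")
  }
  fe <- matrix(NA_real_, n_bins[1], n_bins[2])
  occ <- counts > 0
  fe[occ] <- -kT * log(counts[occ] / max(counts))
  structure(list(distance_edges = d_edges, dihedral_edges = x_edges,
                 counts = counts, free_energy = fe,
                 temperature = temperature, kT = kT, units = units),
            class = "conf_landscape")
}

# Accepts a tibble, a list of tibbles, or anything with the two CV
# columns; returns one pooled tibble.
bind_feature_series <- function(features) {
  if (is.data.frame(features)) features <- list(features)
  out <- dplyr::bind_rows(features)
  stopifnot(all(c("distance_sum", "dihedral") %in% names(out)))
  out
}

#' Locate a point on a landscape
#'
#' Bin assignment uses the half-open convention `[lo, hi)`: a point
#' exactly on an interior edge belongs to the higher bin.
#'
#' @param grid A [estimate_landscape()] result.
#' @param point Length-2 numeric `(distance_sum, dihedral)`.
#' @return List: `bin` (length-2 indices), `free_energy` (`NA` for an
#'   unvisited bin), `count`.
#' @export
locate_on_landscape <- function(grid, point) {
  de <- grid$distance_edges
  xe <- grid$dihedral_edges
  if (point[1] < de[1] || point[1] >= de[length(de)]) {
    abort(paste0("distance_sum ", point[1], " outside landscape range [",
                 round(de[1], 3), ", ", round(de[length(de)], 3), ")"),
          class = "conformscape_range_error")
  }
  if (point[2] < xe[1] || point[2] >= xe[length(xe)]) {
    abort(paste0("dihedral ", point[2], " outside landscape range [",
                 round(xe[1], 3), ", ", round(xe[length(xe)], 3), ")"),
          class = "conformscape_range_error")
  }
  i <- findInterval(point[1], de)
  j <- findInterval(point[2], xe)
  list(bin = c(i, j), free_energy = grid$free_energy[i, j],
       count = grid$counts[i, j])
}

#' @export
print.conf_landscape <- function(x, ...) {
  cat("<conf_landscape>", nrow(x$counts), "x", ncol(x$counts), "bins;",
      sum(x$counts), "samples;", x$units, "at", x$temperature, "K\n")
  invisible(x)
}

#' @describeIn estimate_landscape Long-format tibble of the grid
#'   (`bin_distance`, `bin_dihedral`, bin centers, `count`,
#'   `free_energy`).
#' @param x A `conf_landscape`.
#' @param ... Unused.
#' @export
tidy.conf_landscape <- function(x, ...) {
  dc <- (head(x$distance_edges, -1) + tail(x$distance_edges, -1)) / 2
  xc <- (head(x$dihedral_edges, -1) + tail(x$dihedral_edges, -1)) / 2
  tibble::tibble(
    bin_distance = rep(seq_along(dc), times = length(xc)),
    bin_dihedral = rep(seq_along(xc), each = length(dc)),
    distance_sum = rep(dc, times = length(xc)),
    dihedral = rep(xc, each = length(dc)),
    count = as.vector(x$counts),
    free_energy = as.vector(x$free_energy)
  )
}

#' @export
autoplot.conf_landscape <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df[!is.na(df$free_energy), ],
                  ggplot2::aes(x = .data$distance_sum, y = .data$dihedral,
                               fill = .data$free_energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0("F (", object$units, ")")) +
    ggplot2::labs(x = "distance sum (Å)", y = "H8 dihedral (deg)") +
    ggplot2::theme_minimal()
}
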