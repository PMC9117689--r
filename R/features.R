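#' Collective variables for one frame
#'
#' Computes the two conformation-describing parameters used throughout
#' the package: the sum of Calpha distances 2.40-5.63 and 2.40-6.25
#' (movement of intracellular TM5/TM6 relative to the stable TM2), and
#' the helix-8 dihedral over the Calpha atoms of 8.54, 7.56, 7.54 and
#' 7.47 (orientation of H8 relative to the TM bundle), wrapped to
#' `[0, 360)` degrees.
#'
#' Both observables are internal coordinates, so the result is invariant
#' under rigid rotation and translation of the frame.
#'
#' @param coords Calpha coordinate matrix with residue numbers as
#'   rownames (as from [ca_coords()] or [frame_coords()]).
#' @param bw A [bw_map()] able to resolve codes 2.40, 5.63, 6.25, 8.54,
#'   7.56, 7.54 and 7.47.
#' @return Named numeric vector `c(distance_sum, dihedral)` (angstrom,
#'   degrees).
#' @export
compute_cv <- function(coords, bw) {
  codes <- c("2.40", "5.63", "6.25", "8.54", "7.56", "7.54", "7.47")
  res <- bw_resolve(bw, codes)
  idx <- match(res, as.integer(rownames(coords)))
  if (anyNA(idx)) {
    missing <- codes[is.na(idx)]
    abort(paste0("no Calpha for Ballesteros-Weinstein position(s): ",
                 paste(missing, collapse = ", ")),
          class = "conformscape_featurization_error")
  }
  p <- lapply(idx, function(i) coords[i, ])
  names(p) <- codes
  dsum <- vec_norm(p[["2.40"]] - p[["5.63"]]) + vec_norm(p[["2.40"]] - p[["6.25"]])
  dih <- torsion_angle(p[["8.54"]], p[["7.56"]], p[["7.54"]], p[["7.47"]])
  c(distance_sum = dsum, dihedral = dih)
}

#' Featurize a trajectory into per-frame collective variables
#'
#' @param traj A [ca_trajectory()].
#' @param bw A [bw_map()].
#' @return A tibble with columns `frame`, `time_ns`, `distance_sum`,
#'   `dihedral` (a feature series).
#' @export
featurize <- function(traj, bw) {
  nf <- n_frames(traj)
  cvs <- vapply(seq_len(nf), function(i) compute_cv(frame_coords(traj, i), bw),
                numeric(2))
  tibble::tibble(
    frame = seq_len(nf),
    time_ns = (seq_len(nf) - 1) * traj$frame_interval,
    distance_sum = cvs[1, ],
    dihedral = cvs[2, ]
  )
}

#' Per-residue root-mean-square fluctuation
#'
#' RMSF of each Calpha around its time-averaged position, after
#' superposing every frame onto the mean structure (iterated twice; set
#' `superpose = FALSE` for pre-aligned input).
#'
#' @param traj A [ca_trajectory()] with at least two frames.
#' @param selection Optional residue numbers to restrict the output.
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @return Tibble with `residue` and `rmsf` (angstrom).
#' @export
rmsf <- function(traj, selection = NULL, superpose = TRUE) {
  if (n_frames(traj) < 2) {
    abort("RMSF needs at least two frames", class = "conformscape_degenerate_error")
  }
  if (superpose) traj <- superpose_trajectory(traj)
  mean_xyz <- apply(traj$xyz, c(2, 3), mean)
  dev2 <- sweep(traj$xyz, c(2, 3), mean_xyz)^2
  msf <- apply(dev2, 2, sum) / n_frames(traj)
  out <- tibble::tibble(residue = traj$resno, rmsf = sqrt(msf))
  if (!is.null(selection)) out <- out[out$residue %in% selection, ]
  out
}

#' Principal components of Calpha motion
#'
#' Eigendecomposition of the `3N x 3N` coordinate covariance (maximum
#' likelihood normalisation, divisor `n_frames`) after superposition.
#' With that normalisation the eigenvalues partition the total
#' fluctuation: `sum(eigenvalues) == sum(rmsf^2)`.
#'
#' @param traj A [ca_trajectory()].
#' @param n_modes Number of leading modes to return.
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @return List of class `pca_modes`: `eigenvalues` (all, non-increasing),
#'   `modes` (`3N x n_modes`), and `residue_amplitudes` (tibble: residue,
#'   mode, amplitude = norm of the residue's 3-vector in the mode).
#' @export
pca_modes <- function(traj, n_modes = 3, superpose = TRUE) {
  nf <- n_frames(traj)
  if (nf < n_modes) abort("more modes requested than frames")
  if (superpose) traj <- superpose_trajectory(traj)
  X <- matrix(traj$xyz, nrow = nf)  # frames x (atom-major per axis)
  # reorder to atom-contiguous xyz triples
  na <- length(traj$resno)
  ord <- as.vector(t(matrix(seq_len(3 * na), nrow = na)))
  X <- X[, ord, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / nf
  e <- eigen(C, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-10)
  if (n_modes > rank) {
    abort(paste0("n_modes (", n_modes, ") exceeds covariance rank (", rank, ")"),
          class = "conformscape_rank_error")
  }
  modes <- e$vectors[, seq_len(n_modes), drop = FALSE]
  amp <- purrr::map_dfr(seq_len(n_modes), function(m) {
    v <- matrix(modes[, m], ncol = 3, byrow = TRUE)
    tibble::tibble(residue = traj$resno, mode = m,
                   amplitude = sqrt(rowSums(v^2)))
  })
  structure(list(eigenvalues = e$values, modes = modes,
                 residue_amplitudes = amp),
            class = "pca_modes")
}

#' Dynamic cross-correlation matrix
#'
#' `C[i, j] = <dri . drj> / sqrt(<dri^2><drj^2>)` with `dr` the
#' displacement of a residue's Calpha from its time mean after
#' superposition; +1 is fully correlated motion, -1 fully
#' anti-correlated. Residues with zero displacement variance yield `NA`
#' entries (undefined correlation), never 0.
#'
#' @param traj A [ca_trajectory()] with at least two frames.
#' @param mask_threshold Magnitude below which entries are blanked in
#'   display exports ([tidy()] with `masked = TRUE` and [autoplot()]);
#'   stored values are never altered.
#' @param superpose Remove rigid-body motion first (default `TRUE`).
#' @return Object of class `dccm_matrix`: list with `cor` (square
#'   matrix, residue-number dimnames), `mask_threshold`.
#' @export
dccm <- function(traj, mask_threshold = 0.3, superpose = TRUE) {
  if (n_frames(traj) < 2) {
    abort("DCCM needs at least two frames", class = "conformscape_degenerate_error")
  }
  if (superpose) traj <- superpose_trajectory(traj)
  mean_xyz <- apply(traj$xyz, c(2, 3), mean)
  dev <- sweep(traj$xyz, c(2, 3), mean_xyz)
  nf <- dim(dev)[1]
  # <dri . drj> = sum over axes of cross-moments
  cc <- matrix(0, length(traj$resno), length(traj$resno))
  for (ax in 1:3) {
    cc <- cc + crossprod(dev[, , ax]) / nf
  }
  v <- diag(cc)
  denom <- sqrt(outer(v, v))
  cor <- cc / denom
  cor[denom == 0] <- NA_real_
  dimnames(cor) <- list(traj$resno, traj$resno)
  structure(list(cor = cor, mask_threshold = mask_threshold),
            class = "dccm_matrix")
}

#' @export
print.dccm_matrix <- function(x, ...) {
  cat("<dccm_matrix>", nrow(x$cor), "residues; display mask |c| <",
      x$mask_threshold, "\n")
  invisible(x)
}

#' Ligand contact fractions per residue
#'
#' A residue is in contact in a frame when its Calpha lies within
#' `threshold` of any ligand atom; the contact fraction is the share of
#' frames in contact. Residues with fraction at or above `min_fraction`
#' form the highly-contacting set.
#'
#' @param traj A [ca_trajectory()].
#' @param ligand Per-frame ligand coordinates: a 3-D array
#'   `(n_frames, n_ligand_atoms, 3)`, a list of matrices (one per
#'   frame), or a single matrix reused for all frames.
#' @param threshold Contact distance cutoff in angstrom (default 4).
#' @param min_fraction Selection cutoff on the fraction (default 0.6).
#' @return Tibble with `residue`, `fraction`, `selected`.
#' @export
contact_fraction <- function(traj, ligand, threshold = 4, min_fraction = 0.6) {
  nf <- n_frames(traj)
  lig_frame <- function(i) {
    if (is.array(ligand) && length(dim(ligand)) == 3) {
      m <- ligand[i, , , drop = TRUE]
      dim(m) <- c(dim(ligand)[2], 3)
      m
    } else if (is.list(ligand)) {
      ligand[[i]]
    } else {
      ligand
    }
  }
  n_lig_frames <- if (is.array(ligand) && length(dim(ligand)) == 3) {
    dim(ligand)[1]
  } else if (is.list(ligand)) {
    length(ligand)
  } else {
    nf
  }
  if (n_lig_frames != nf) {
    abort(paste0("ligand frames (", n_lig_frames, ") do not align with ",
                 "trajectory frames (", nf, ")"),
          class = "conformscape_alignment_error")
  }
  hits <- matrix(FALSE, nf, length(traj$resno))
  for (i in seq_len(nf)) {
    P <- frame_coords(traj, i)
    L <- lig_frame(i)
    d2 <- outer(rowSums(P^2), rowSums(L^2), `+`) - 2 * P %*% t(L)
    hits[i, ] <- apply(d2, 1, min) <= threshold^2
  }
  frac <- colMeans(hits)
  tibble::tibble(residue = traj$resno, fraction = frac,
                 selected = frac >= min_fraction)
}
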