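#' Default three-basin layout of the AT2R collective-variable landscape
#'
#' Wells are placed at the reported basin coordinates of the receptor's
#' free-energy landscape: an active-like basin (distance sum near 54 A,
#' helix-8 dihedral near 105 degrees), an intermediate basin (near 53.5
#' A, 188 degrees) and an inactive-like basin (near 55.5 A, 216
#' degrees). Depths (in kT) are chosen so the equilibrium weights of the
#' three basins are distinct and comparable to the reported macrostate
#' proportions (roughly 0.25/0.38/0.37), with barriers low enough that a
#' desk-scale Brownian run hops between basins many times.
#'
#' @return Tibble of well specifications for [make_cv_surface()].
#' @export
at2r_cv_wells <- function() {
  tibble::tibble(
    well = c("active", "intermediate", "inactive"),
    center_distance = c(54, 53.5, 55.5),
    center_dihedral = c(105, 188, 216),
    depth = c(3.2, 4.4, 4.1),
    width_distance = c(1.5, 1.6, 1.6),
    width_dihedral = c(8, 8, 11)
  )
}

#' Brownian (overdamped Langevin) simulation configuration
#'
#' @param n_traj Number of independent trajectories.
#' @param steps Integration steps per trajectory.
#' @param dt Time step (surface time units).
#' @param kT Thermal energy in surface energy units.
#' @param mobility Per-axis mobility (diffusion is `mobility * kT`). The
#'   collective variables live on incommensurate unit scales (angstrom
#'   vs degree), so the default mobilities are chosen per axis to make
#'   both coordinates decorrelate on comparable timescales; an isotropic
#'   mobility in these units would create an artificial slow diffusive
#'   mode along one axis.
#' @param save_every Keep every n-th step as a frame.
#' @param starts Matrix of initial points (rows, recycled over
#'   trajectories); default spreads the walkers over the surface's well
#'   centers, mimicking seeding production runs from structures spaced
#'   along a transition path.
#' @param seed Integer seed.
#' @return List of class `brownian_config`.
#' @export
brownian_config <- function(n_traj = 10, steps = 50000, dt = 0.02, kT = 1,
                            mobility = c(5, 300), save_every = 20,
                            starts = NULL, seed = 1) {
  stopifnot(kT >= 0, dt > 0, steps >= 1, n_traj >= 1, all(mobility > 0))
  structure(list(n_traj = n_traj, steps = steps, dt = dt, kT = kT,
                 mobility = mobility, save_every = save_every,
                 starts = starts, seed = seed),
            class = "brownian_config")
}

#' Simulate Brownian dynamics on a potential surface
#'
#' Overdamped update `x <- x - mobility * grad(V) * dt +
#' sqrt(2 * mobility * kT * dt) * xi` with seeded Gaussian noise `xi`.
#' All walkers advance in lockstep (vectorised over trajectories). Each
#' saved frame carries its ground-truth label: the nearest well center
#' in width-scaled coordinates (for surfaces built by
#' [make_cv_surface()]).
#'
#' @param surface A 2-D [potential_surface()].
#' @param config A [brownian_config()].
#' @return Tibble (feature series collection) with columns `traj`,
#'   `frame`, `distance_sum`, `dihedral`, and `well` (ground-truth
#'   label, `NA` when the surface has no well registry).
#' @export
simulate_brownian <- function(surface, config = brownian_config()) {
  stopifnot(inherits(config, "brownian_config"), surface$dim == 2)
  set.seed(config$seed)
  starts <- config$starts
  if (is.null(starts)) {
    if (!is.null(surface$wells)) {
      w <- surface$wells
      idx <- rep(seq_len(nrow(w)), length.out = config$n_traj)
      # deal the walkers round-robin over the basins
      starts <- cbind(w$center_distance[idx], w$center_dihedral[idx])
    } else {
      abort("surface has no wells; supply explicit starts")
    }
  }
  X <- matrix(as.matrix(starts)[rep(seq_len(nrow(as.matrix(starts))),
                                    length.out = config$n_traj), ],
              ncol = 2)
  amp <- sqrt(2 * config$mobility * config$kT * config$dt)
  nsave <- config$steps %/% config$save_every
  out_d <- matrix(0, nsave, config$n_traj)
  out_x <- matrix(0, nsave, config$n_traj)
  for (s in seq_len(config$steps)) {
    G <- surface_gradient(surface, X)
    X[, 1] <- X[, 1] - config$mobility[1] * G[, 1] * config$dt +
      amp[1] * rnorm(config$n_traj)
    X[, 2] <- X[, 2] - config$mobility[2] * G[, 2] * config$dt +
      amp[2] * rnorm(config$n_traj)
    if (any(!is.finite(X)) || any(abs(X) > 1e8)) {
      abort("Brownian trajectory diverged; reduce dt or mobility",
            class = "conformscape_step_size_error")
    }
    if (s %% config$save_every == 0) {
      k <- s %/% config$save_every
      out_d[k, ] <- X[, 1]
      out_x[k, ] <- X[, 2]
    }
  }
  res <- tibble::tibble(
    traj = rep(seq_len(config$n_traj), each = nsave),
    frame = rep(seq_len(nsave), times = config$n_traj),
    distance_sum = as.vector(out_d),
    dihedral = as.vector(out_x)
  )
  res$well <- if (!is.null(surface$wells)) {
    nearest_well(surface, cbind(res$distance_sum, res$dihedral))
  } else {
    NA_integer_
  }
  res
}

#' Sample a discrete Markov chain
#'
#' Seeded categorical sampling from a row-stochastic transition matrix.
#'
#' @param tpm Row-stochastic square matrix.
#' @param steps Chain length to return.
#' @param seed Integer seed.
#' @param start Initial state (default 1) or probability vector.
#' @return Integer vector of states (1-based), length `steps`.
#' @export
simulate_chain <- function(tpm, steps, seed = 1, start = 1L) {
  tpm <- as.matrix(tpm)
  if (any(tpm < 0)) abort("transition matrix has negative entries")
  if (any(abs(rowSums(tpm) - 1) > 1e-8)) abort("rows must sum to 1")
  set.seed(seed)
  k <- nrow(tpm)
  cum <- t(apply(tpm, 1, cumsum))
  s <- integer(steps)
  s[1] <- if (length(start) > 1) {
    sample.int(k, 1, prob = start)
  } else {
    as.integer(start)
  }
  u <- runif(steps)
  for (t in 2:steps) {
    s[t] <- findInterval(u[t], cum[s[t - 1], ]) + 1L
  }
  s
}

#' Specification of a synthetic multiple sequence alignment
#'
#' Positions are independent background draws unless listed as conserved
#' (one designated residue at a target frequency) or as members of a
#' coupled group. Each group shares a per-sequence hidden binary state;
#' with probability `coupling` a member position copies the
#' state-designated residue, otherwise it draws from background. A weak
#' global latent state applied to every position (`global_coupling`)
#' emulates the shared phylogenetic signal of real alignments, which is
#' what makes the first eigenvector of a coupling matrix a global mode.
#'
#' @param n_seq,n_pos Alignment dimensions.
#' @param conserved Tibble with `position`, `residue`, `frequency`, or
#'   `NULL`.
#' @param groups List of coupled groups, each a list with `positions`
#'   (disjoint from other groups and from conserved positions) and
#'   `coupling` in `[0, 1]`.
#' @param global_coupling Probability a position copies its
#'   global-state residue (default 0.5, strong enough that the global
#'   mode carries the leading eigenvalue of the coupling matrix even
#'   when a tightly coupled sector is planted, as shared phylogeny does
#'   in real alignments).
#' @param background Residue alphabet weights; default uniform over the
#'   20 amino acids.
#' @param seed Integer seed.
#' @return List of class `msa_spec`.
#' @export
msa_spec <- function(n_seq = 500, n_pos = 100, conserved = NULL,
                     groups = list(), global_coupling = 0.5,
                     background = NULL, seed = 1) {
  background <- background %||% setNames(rep(1 / 20, 20), AA_ALPHABET)
  gpos <- unlist(lapply(groups, `[[`, "positions"))
  if (anyDuplicated(gpos)) abort("coupled groups overlap")
  if (!is.null(conserved) && any(conserved$position %in% gpos)) {
    abort("groups overlap conserved positions")
  }
  for (g in groups) {
    if (g$coupling < 0 || g$coupling > 1) abort("coupling must be in [0, 1]")
  }
  structure(list(n_seq = n_seq, n_pos = n_pos, conserved = conserved,
                 groups = groups, global_coupling = global_coupling,
                 background = background, seed = seed),
            class = "msa_spec")
}

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a synthetic alignment with planted structure
#'
#' @param spec An [msa_spec()].
#' @return An `msa` object (see [load_msa()]) with attributes
#'   `sector_positions` (ground-truth coupled positions per group) and
#'   `spec`.
#' @export
generate_msa <- function(spec = msa_spec()) {
  set.seed(spec$seed)
  aa <- names(spec$background)
  p <- spec$background / sum(spec$background)
  M <- matrix(sample(aa, spec$n_seq * spec$n_pos, replace = TRUE, prob = p),
              spec$n_seq, spec$n_pos)
  # global latent state: each position has its own pair of state residues
  g_state <- sample(c(1L, 2L), spec$n_seq, replace = TRUE)
  g_res <- replicate(spec$n_pos, sample(aa, 2))
  if (spec$global_coupling > 0) {
    for (j in seq_len(spec$n_pos)) {
      use <- runif(spec$n_seq) < spec$global_coupling
      M[use, j] <- g_res[g_state[use], j]
    }
  }
  if (!is.null(spec$conserved)) {
    for (r in seq_len(nrow(spec$conserved))) {
      j <- spec$conserved$position[r]
      use <- runif(spec$n_seq) < spec$conserved$frequency[r]
      M[use, j] <- spec$conserved$residue[r]
    }
  }
  for (g in spec$groups) {
    state <- sample(c(1L, 2L), spec$n_seq, replace = TRUE)
    res_pair <- if (!is.null(g$residues)) g$residues else sample(aa, 2)
    for (j in g$positions) {
      use <- runif(spec$n_seq) < g$coupling
      M[use, j] <- res_pair[state[use]]
    }
  }
  seqs <- apply(M, 1, paste, collapse = "")
  names(seqs) <- paste0("synthetic_seq_", seq_along(seqs))
  msa <- load_msa_strings(seqs)
  attr(msa, "sector_positions") <- lapply(spec$groups, `[[`, "positions")
  attr(msa, "spec") <- spec
  msa
}

#' Idealised helix-bundle fixture in PDB format
#'
#' Builds a toy receptor: ideal alpha helices (3.6 residues per turn,
#' 1.5 A rise per residue, 2.3 A helix radius) standing on a circle,
#' with a small pseudo-ligand HETATM group at the bundle center. Useful
#' as a self-contained structure fixture with a known
#' Ballesteros-Weinstein map (each helix's mid residue is its x.50
#' anchor).
#'
#' @param n_helices Number of helices (>= 4).
#' @param res_per_helix Residues per helix.
#' @param bundle_radius Circle radius for helix axes (angstrom).
#' @param seed Seed for the small random jitter applied to positions.
#' @return List: `pdb_text` (character vector of PDB lines), `bw`
#'   (matching [bw_map()]), `n_atoms` (declared atom count incl.
#'   ligand), `ligand_atoms`.
#' @export
make_toy_bundle <- function(n_helices = 4, res_per_helix = 21,
                            bundle_radius = 6, seed = 1) {
  stopifnot(n_helices >= 4)
  set.seed(seed)
  rise <- 1.5
  radius <- 2.3
  twist <- 100 * pi / 180
  lines <- character(0)
  serial <- 0
  resno <- 0
  anchors <- numeric(0)
  ranges <- list()
  for (h in seq_len(n_helices)) {
    phi <- 2 * pi * (h - 1) / n_helices
    cx <- bundle_radius * cos(phi)
    cy <- bundle_radius * sin(phi)
    first <- resno + 1
    for (r in seq_len(res_per_helix)) {
      resno <- resno + 1
      serial <- serial + 1
      ang <- twist * r
      pos <- c(cx + radius * cos(ang), cy + radius * sin(ang),
               (r - (res_per_helix + 1) / 2) * rise) +
        rnorm(3, sd = 0.01)
      lines <- c(lines, sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        serial, resno, pos[1], pos[2], pos[3]))
    }
    mid <- first + (res_per_helix - 1) %/% 2
    anchors[as.character(h)] <- mid
    ranges[[as.character(h)]] <- c(first, resno)
  }
  # pseudo-ligand at the bundle center: the inward-facing Calpha of each
  # helix sits at bundle_radius - 2.3 from the axis, within the 4 A
  # contact cutoff of the center for the default radius
  lig <- matrix(rnorm(9, sd = 0.3), 3, 3)
  for (i in 1:3) {
    serial <- serial + 1
    lines <- c(lines, sprintf(
      "HETATM%5d  C%d  LIG A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, i, resno + 1, lig[i, 1], lig[i, 2], lig[i, 3]))
  }
  lines <- c(lines, "END")
  list(pdb_text = lines, bw = bw_map(anchors, ranges),
       n_atoms = serial, ligand_atoms = 3)
}
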