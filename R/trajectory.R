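#' Calpha trajectory container
#'
#' A minimal container for multi-frame Calpha coordinates with a
#' consistent atom ordering across frames.
#'
#' @param xyz 3-D numeric array `(n_frames, n_atoms, 3)`, or a list of
#'   `(n_atoms x 3)` matrices.
#' @param resno Integer residue numbers, one per atom. Defaults to
#'   `1:n_atoms`.
#' @param frame_interval Time per saved frame in nanoseconds (> 0).
#' @return An object of class `ca_trajectory`.
#' @export
ca_trajectory <- function(xyz, resno = NULL, frame_interval = 1) {
  if (is.list(xyz)) {
    n <- vapply(xyz, nrow, integer(1))
    if (length(unique(n)) != 1) {
      abort("all frames must have the same atom count")
    }
    arr <- array(0, c(length(xyz), n[1], 3))
    for (i in seq_along(xyz)) arr[i, , ] <- xyz[[i]]
    xyz <- arr
  }
  stopifnot(length(dim(xyz)) == 3, dim(xyz)[3] == 3)
  if (frame_interval <= 0) abort("frame_interval must be > 0")
  resno <- as.integer(resno %||% seq_len(dim(xyz)[2]))
  stopifnot(length(resno) == dim(xyz)[2])
  structure(list(xyz = xyz, resno = resno, frame_interval = frame_interval),
            class = "ca_trajectory")
}

#' @export
print.ca_trajectory <- function(x, ...) {
  cat("<ca_trajectory>", n_frames(x), "frames x", length(x$resno),
      "atoms; frame interval", x$frame_interval, "ns\n")
  invisible(x)
}

n_frames <- function(traj) dim(traj$xyz)[1]

# Single frame as an (n_atoms x 3) matrix with residue-number rownames.
frame_coords <- function(traj, i) {
  m <- traj$xyz[i, , , drop = TRUE]
  dim(m) <- c(length(traj$resno), 3)
  rownames(m) <- traj$resno
  m
}

#' Read a trajectory from a multi-model PDB file
#'
#' Each MODEL block becomes one frame; only Calpha atoms of the chosen
#' chain are kept.
#'
#' @param path PDB file with MODEL/ENDMDL records.
#' @param frame_interval Time per frame (ns).
#' @param chain Optional chain id; default the longest protein chain.
#' @return A `ca_trajectory`.
#' @export
read_trajectory_pdb <- function(path, frame_interval = 1, chain = NULL) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  sel_chain <- chain %||% {
    ca <- pdb$atom[pdb$atom$elety == "CA" & pdb$atom$type == "ATOM", ]
    names(sort(table(ca$chain), decreasing = TRUE))[1]
  }
  sel <- bio3d::atom.select(pdb, elety = "CA", chain = sel_chain,
                            type = "ATOM", verbose = FALSE)
  xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
  resno <- as.integer(pdb$atom$resno[sel$atom])
  arr <- array(0, c(nrow(xyz), length(resno), 3))
  for (i in seq_len(nrow(xyz))) {
    arr[i, , ] <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
  }
  ca_trajectory(arr, resno = resno, frame_interval = frame_interval)
}

#' Read a trajectory from a long coordinate table
#'
#' Expects columns `frame`, `residue`, `x`, `y`, `z` (CSV or whitespace
#' delimited; a data frame is also accepted).
#'
#' @param x Path or data frame.
#' @param frame_interval Time per frame (ns).
#' @return A `ca_trajectory`.
#' @export
read_trajectory_csv <- function(x, frame_interval = 1) {
  df <- if (is.data.frame(x)) {
    x
  } else if (grepl("\\.csv$", x, ignore.case = TRUE)) {
    utils::read.csv(x)
  } else {
    utils::read.table(x, header = TRUE)
  }
  stopifnot(all(c("frame", "residue", "x", "y", "z") %in% names(df)))
  df <- df[order(df$frame, df$residue), ]
  resno <- sort(unique(df$residue))
  frames <- sort(unique(df$frame))
  if (nrow(df) != length(resno) * length(frames)) {
    abort("coordinate table is not a complete frame x residue grid")
  }
  arr <- array(0, c(length(frames), length(resno), 3))
  arr[, , 1] <- matrix(df$x, nrow = length(frames), byrow = TRUE)
  arr[, , 2] <- matrix(df$y, nrow = length(frames), byrow = TRUE)
  arr[, , 3] <- matrix(df$z, nrow = length(frames), byrow = TRUE)
  ca_trajectory(arr, resno = as.integer(resno), frame_interval = frame_interval)
}

# Superpose every frame onto the mean structure, iterated (mean -> fit ->
# new mean -> fit), as trajectory analysis tools do by default before
# computing fluctuations. Returns a new trajectory.
superpose_trajectory <- function(traj, iterations = 2) {
  arr <- traj$xyz
  nf <- dim(arr)[1]
  for (it in seq_len(iterations)) {
    ref <- apply(arr, c(2, 3), mean)
    for (i in seq_len(nf)) {
      m <- arr[i, , , drop = TRUE]
      dim(m) <- dim(ref)
      arr[i, , ] <- superpose_onto(m, ref)
    }
  }
  out <- traj
  out$xyz <- arr
  out
}
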