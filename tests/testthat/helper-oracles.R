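# Shared fixtures and independent oracles used across the suite.

# Random proper rotation matrix (QR of a Gaussian matrix, det fixed).
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

apply_rigid <- function(coords, R, t) {
  sweep(coords %*% R, 2, t, `+`)
}

# Horn's quaternion method for optimal superposition: an independent
# route to the least-squares rotation (the implementation uses SVD).
quaternion_rotation <- function(P, Q) {
  M <- crossprod(P, Q)
  K <- matrix(c(
    M[1,1]+M[2,2]+M[3,3], M[2,3]-M[3,2], M[3,1]-M[1,3], M[1,2]-M[2,1],
    M[2,3]-M[3,2], M[1,1]-M[2,2]-M[3,3], M[1,2]+M[2,1], M[3,1]+M[1,3],
    M[3,1]-M[1,3], M[1,2]+M[2,1], -M[1,1]+M[2,2]-M[3,3], M[2,3]+M[3,2],
    M[1,2]-M[2,1], M[3,1]+M[1,3], M[2,3]+M[3,2], -M[1,1]-M[2,2]+M[3,3]
  ), 4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    w^2+x^2-y^2-z^2, 2*(x*y+w*z), 2*(x*z-w*y),
    2*(x*y-w*z), w^2-x^2+y^2-z^2, 2*(y*z+w*x),
    2*(x*z+w*y), 2*(y*z-w*x), w^2-x^2-y^2+z^2
  ), 3, 3, byrow = TRUE)
}

# All 6 relabelings of three macrostates.
permutations3 <- function() {
  rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
}

# Best frame-label agreement between predicted and true 3-state labels.
label_agreement <- function(pred, truth) {
  max(apply(permutations3(), 1, function(p) mean(p[pred] == truth, na.rm = TRUE)))
}

# Random reversible transition matrix from symmetric positive counts.
random_reversible_tpm <- function(n, seed) {
  set.seed(seed)
  W <- matrix(runif(n * n, 0.01, 1), n, n)
  W <- (W + t(W)) / 2
  W / rowSums(W)
}

# Dense oracle for mean first passage times: explicit fundamental-matrix
# inversion of the absorbing chain, source-averaged by the stationary
# weights.
mfpt_oracle <- function(T, pi, source, sink, step_time = 1) {
  nonsink <- setdiff(seq_len(nrow(T)), sink)
  N <- solve(diag(length(nonsink)) - T[nonsink, nonsink, drop = FALSE])
  t_all <- numeric(nrow(T))
  t_all[nonsink] <- N %*% rep(1, length(nonsink))
  w <- pi[source] / sum(pi[source])
  sum(w * t_all[source]) * step_time
}

# Empirical mean first passage time: run a chain where entering the sink
# teleports the walker (next step) to a pi-weighted source state, and
# average the lengths of the source->sink segments.
empirical_mfpt <- function(T, pi, source, sink, steps, seed) {
  Tm <- T
  src_w <- numeric(nrow(T))
  src_w[source] <- pi[source] / sum(pi[source])
  for (s in sink) Tm[s, ] <- src_w
  traj <- simulate_chain(Tm, steps, seed = seed, start = source[1])
  at_sink <- which(traj %in% sink)
  if (length(at_sink) < 2) return(NA_real_)
  mean(diff(at_sink) - 1)
}

# Saddle points of a 2-D surface by dense grid search: grid nodes where
# the gradient norm is locally minimal and the discrete Hessian is
# indefinite.
grid_saddles <- function(surface, xlim, ylim, n = 300) {
  gx <- seq(xlim[1], xlim[2], length.out = n)
  gy <- seq(ylim[1], ylim[2], length.out = n)
  pts <- cbind(rep(gx, times = n), rep(gy, each = n))
  G <- surface_gradient(surface, pts)
  gn <- matrix(sqrt(rowSums(G^2)), n, n)
  V <- matrix(surface_energy(surface, pts), n, n)
  hits <- NULL
  for (i in 2:(n - 1)) {
    for (j in 2:(n - 1)) {
      if (gn[i, j] <= min(gn[(i-1):(i+1), (j-1):(j+1)])) {
        dxx <- V[i+1, j] - 2 * V[i, j] + V[i-1, j]
        dyy <- V[i, j+1] - 2 * V[i, j] + V[i, j-1]
        dxy <- (V[i+1, j+1] - V[i+1, j-1] - V[i-1, j+1] + V[i-1, j-1]) / 4
        if (dxx * dyy - dxy^2 < 0) hits <- rbind(hits, c(gx[i], gy[j], gn[i, j]))
      }
    }
  }
  hits <- hits[order(hits[, 3]), , drop = FALSE]
  # deduplicate nearby hits, keep the flattest of each cluster
  keep <- NULL
  for (r in seq_len(nrow(hits))) {
    if (is.null(keep) ||
        min(sqrt(rowSums(sweep(keep, 2, hits[r, 1:2])^2))) > 0.15) {
      keep <- rbind(keep, hits[r, 1:2, drop = FALSE])
    }
  }
  keep
}

# Exhaustive max-min diversity oracle: the n-subset (containing both
# endpoints) maximising the minimum pairwise distance.
maxmin_subset_oracle <- function(D, n) {
  m <- nrow(D)
  best <- NULL
  best_v <- -Inf
  for (comb in utils::combn(setdiff(seq_len(m), c(1, m)), n - 2,
                            simplify = FALSE)) {
    sel <- c(1, comb, m)
    v <- min(D[sel, sel][upper.tri(diag(length(sel)))])
    if (v > best_v) {
      best_v <- v
      best <- sel
    }
  }
  list(subset = sort(best), value = best_v)
}

# Tiny helix-bundle trajectory fixture: base conformation from
# make_toy_bundle jittered per frame.
toy_trajectory <- function(n_frames = 20, sd = 0.05, seed = 1,
                           frame_interval = 1) {
  tb <- make_toy_bundle(seed = seed)
  ca <- ca_coords(read_structure(tb$pdb_text))
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    ca + matrix(rnorm(length(ca), sd = sd), nrow(ca), 3)
  })
  ca_trajectory(frames, resno = as.integer(rownames(ca)),
                frame_interval = frame_interval)
}
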