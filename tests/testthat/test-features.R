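cv_fixture <- function() {
  bw <- at2r_bw_map()
  coords <- rbind(
    `80` = c(0, 0, 0), `236` = c(3, 4, 0), `246` = c(0, 0, 5),
    `329` = c(1, 1, 0), `321` = c(0, 1, 0), `319` = c(0, 0, 0),
    `312` = c(1, 0, 0.5)
  )
  list(bw = bw, coords = coords)
}

test_that("the distance sum follows the two-leg construction", {
  f <- cv_fixture()
  cv <- compute_cv(f$coords, f$bw)
  expect_equal(unname(cv["distance_sum"]), 5 + 5)  # 3-4-5 triangle + z-leg
})

test_that("coplanar trans points give a 180 degree helix-8 dihedral", {
  f <- cv_fixture()
  coords <- f$coords
  coords["329", ] <- c(1, 1, 0)
  coords["321", ] <- c(0, 1, 0)
  coords["319", ] <- c(0, 0, 0)
  coords["312", ] <- c(-1, 0, 0)   # anti-periplanar arrangement
  cv <- compute_cv(coords, f$bw)
  expect_equal(unname(cv["dihedral"]), 180)
  # eclipsed (cis) arrangement wraps to 0
  coords["312", ] <- c(1, 0, 0)
  expect_equal(unname(compute_cv(coords, f$bw)["dihedral"]), 0)
})

test_that("missing atoms and degenerate geometry are reported by name", {
  f <- cv_fixture()
  expect_error(compute_cv(f$coords[-2, ], f$bw),
               class = "conformscape_featurization_error")
  expect_error(compute_cv(f$coords[-2, ], f$bw), "5.63")
  collinear <- f$coords
  collinear["329", ] <- c(0, 2, 0)
  collinear["321", ] <- c(0, 1, 0)
  collinear["319", ] <- c(0, 0, 0)
  expect_error(compute_cv(collinear, f$bw),
               class = "conformscape_collinear_error")
})

test_that("collective variables are rigid-motion invariant and wrapped", {
  f <- cv_fixture()
  ref <- compute_cv(f$coords, f$bw)
  expect_gte(ref["dihedral"], 0)
  expect_lt(ref["dihedral"], 360)
  set.seed(42)
  for (i in 1:20) {
    moved <- apply_rigid(f$coords, random_rotation(), rnorm(3, sd = 50))
    rownames(moved) <- rownames(f$coords)
    cv <- compute_cv(moved, f$bw)
    expect_equal(unname(cv["distance_sum"]), unname(ref["distance_sum"]),
                 tolerance = 1e-9)
    # compare angles on the circle (wrap-safe)
    dd <- (cv["dihedral"] - ref["dihedral"] + 180) %% 360 - 180
    expect_lt(abs(dd), 1e-9)
  }
})

test_that("RMSF is zero for static input and matches the isotropic closed form", {
  tb <- toy_trajectory(n_frames = 5, sd = 0)
  r <- rmsf(tb)
  expect_true(all(r$rmsf < 1e-9))
  expect_error(rmsf(ca_trajectory(array(0, c(1, 4, 3)))),
               class = "conformscape_degenerate_error")

  # a single jittered residue among many fixed ones: RMSF ~ sigma * sqrt(3)
  set.seed(9)
  sigma <- 0.3
  n_res <- 30
  base <- matrix(rnorm(n_res * 3, sd = 5), n_res, 3)
  frames <- lapply(1:10000, function(i) {
    m <- base
    m[7, ] <- m[7, ] + rnorm(3, sd = sigma)
    m
  })
  traj <- ca_trajectory(frames)
  r <- rmsf(traj, superpose = FALSE)
  expect_equal(r$rmsf[7], sigma * sqrt(3), tolerance = 0.05)

  # duplicated residue columns fluctuate identically
  frames2 <- lapply(frames, function(m) rbind(m, m[7, ]))
  r2 <- rmsf(ca_trajectory(frames2), superpose = FALSE)
  expect_equal(r2$rmsf[7], r2$rmsf[n_res + 1])
})

test_that("PCA modes capture constructed variance structure exactly", {
  # all motion along one direction: PC1 holds all the variance
  base <- matrix(rnorm(12), 4, 3)
  dir <- c(1, 0, 0)
  frames <- lapply(seq(-2, 2, length.out = 9), function(a) {
    m <- base
    m[2, ] <- m[2, ] + a * dir
    m
  })
  p <- pca_modes(ca_trajectory(frames), n_modes = 1, superpose = FALSE)
  expect_equal(p$eigenvalues[1] / sum(p$eigenvalues), 1, tolerance = 1e-12)

  # two orthogonal motions with variances 4:1
  set.seed(2)
  a1 <- rnorm(200, sd = 2)
  a2 <- rnorm(200, sd = 1)
  a1 <- (a1 - mean(a1)) / sd(a1) * 2
  a2 <- resid(lm(a2 ~ a1))
  a2 <- a2 / sd(a2)
  frames <- lapply(1:200, function(i) {
    m <- base
    m[1, 1] <- m[1, 1] + a1[i]
    m[3, 2] <- m[3, 2] + a2[i]
    m
  })
  p <- pca_modes(ca_trajectory(frames), n_modes = 2, superpose = FALSE)
  expect_equal(p$eigenvalues[1] / p$eigenvalues[2], 4, tolerance = 1e-6)

  expect_error(pca_modes(ca_trajectory(frames), n_modes = 50),
               class = "conformscape_rank_error")
})

test_that("PCA agrees with a direct covariance eigendecomposition oracle", {
  set.seed(11)
  frames <- lapply(1:5, function(i) matrix(rnorm(9), 3, 3))
  traj <- ca_trajectory(frames)
  p <- pca_modes(traj, n_modes = 2, superpose = FALSE)
  X <- t(sapply(frames, function(m) as.vector(t(m))))
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(crossprod(Xc) / 5, symmetric = TRUE)$values
  expect_equal(p$eigenvalues, ev, tolerance = 1e-10)
})

test_that("RMSF and PCA partition the same total variance", {
  traj <- toy_trajectory(n_frames = 30, sd = 0.2, seed = 5)
  r <- rmsf(traj)
  p <- pca_modes(traj, n_modes = 3)
  expect_equal(sum(r$rmsf^2), sum(p$eigenvalues), tolerance = 1e-8)
})

test_that("DCCM has exact structure on constructed motions", {
  set.seed(4)
  base <- matrix(rnorm(12, sd = 3), 4, 3)
  disp <- matrix(rnorm(3 * 50), 50, 3)
  jitter3 <- matrix(rnorm(3 * 50), 50, 3)
  frames <- lapply(1:50, function(i) {
    m <- base
    m[1, ] <- m[1, ] + disp[i, ]
    m[2, ] <- m[2, ] - disp[i, ]   # exact anti-correlation
    m[3, ] <- m[3, ] + jitter3[i, ]
    m
  })
  d <- dccm(ca_trajectory(frames), superpose = FALSE)
  expect_equal(unname(diag(d$cor)[1:3]), rep(1, 3))
  expect_equal(d$cor[1, 2], -1)
  expect_equal(d$cor, t(d$cor))
  expect_true(all(abs(d$cor) <= 1 + 1e-12, na.rm = TRUE))
  # residue 4 never moves: correlation undefined, not zero
  expect_true(all(is.na(d$cor[4, ])))
})

test_that("independently driven residues decorrelate and bio3d agrees", {
  set.seed(8)
  n <- 10000
  frames <- lapply(1:n, function(i) rbind(rnorm(3), rnorm(3) + 10))
  d <- dccm(ca_trajectory(frames), superpose = FALSE)
  expect_lt(abs(d$cor[1, 2]), 0.1)

  small <- toy_trajectory(n_frames = 15, sd = 0.3, seed = 13)
  ours <- dccm(small, superpose = FALSE)
  na <- length(small$resno)
  ord <- as.vector(t(matrix(seq_len(3 * na), ncol = 3)))
  xyz <- matrix(small$xyz, nrow = 15)[, ord]
  ref <- suppressMessages(bio3d::dccm(xyz))
  expect_equal(unname(ours$cor), unname(ref[, ]), tolerance = 1e-6)
})

test_that("contact fractions count threshold crossings per frame", {
  base <- rbind(c(0, 0, 0), c(10, 0, 0))
  frames <- lapply(1:10, function(i) base)
  traj <- ca_trajectory(frames)
  lig_near <- matrix(c(3, 0, 0), 1, 3)
  cp <- contact_fraction(traj, lig_near)
  expect_equal(cp$fraction, c(1, 0))
  expect_true(cp$selected[1])
  expect_false(cp$selected[2])

  # within 4 A in exactly 6 of 10 frames
  ligs <- lapply(1:10, function(i) {
    matrix(c(if (i <= 6) 3 else 8, 0, 0), 1, 3)
  })
  cp <- contact_fraction(traj, ligs)
  expect_equal(cp$fraction[1], 0.6)
  expect_true(cp$selected[1])

  expect_error(contact_fraction(traj, ligs[1:5]),
               class = "conformscape_alignment_error")
})
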