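test_that("microstate clustering separates clouds and is deterministic", {
  set.seed(1)
  f <- tibble::tibble(
    distance_sum = c(rnorm(50, 50, 0.1), rnorm(50, 60, 0.1)),
    dihedral = c(rnorm(50, 100, 1), rnorm(50, 200, 1))
  )
  m <- cluster_microstates(f, k = 2, seed = 3)
  a <- m$assignments[[1]]
  expect_equal(length(unique(a[1:50])), 1)
  expect_equal(length(unique(a[51:100])), 1)
  expect_false(a[1] == a[51])

  m1 <- cluster_microstates(f, k = 1, seed = 3)
  expect_equal(m1$k, 1)

  m2 <- cluster_microstates(f, k = 5, seed = 9)
  m3 <- cluster_microstates(f, k = 5, seed = 9)
  expect_identical(m2$assignments, m3$assignments)
})

test_that("transition counting follows the sliding window within trajectories", {
  tm <- estimate_tpm(list(c(1, 2, 1, 2)), lag = 1, mode = "naive")
  expect_equal(unname(tm$counts), matrix(c(0, 1, 2, 0), 2))
  expect_equal(unname(tm$T), matrix(c(0, 1, 1, 0), 2))

  # boundaries between trajectories contribute no counts
  joined <- estimate_tpm(list(c(1, 2, 2, 1)), lag = 1, mode = "naive")
  split2 <- estimate_tpm(list(c(1, 2), c(2, 1)), lag = 1, mode = "naive")
  expect_equal(sum(joined$counts), 3)
  expect_equal(sum(split2$counts), 2)
})

test_that("a symmetric two-state chain has a uniform stationary distribution", {
  T0 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  s <- simulate_chain(T0, 20000, seed = 5)
  tm <- estimate_tpm(list(s), lag = 1)
  expect_equal(tm$pi, c(0.5, 0.5), tolerance = 0.02)
})

test_that("the naive estimator concentrates on the generating matrix", {
  T0 <- matrix(c(0.90, 0.08, 0.02,
                 0.05, 0.90, 0.05,
                 0.02, 0.08, 0.90), 3, byrow = TRUE)
  s <- simulate_chain(T0, 100000, seed = 11)
  tm <- estimate_tpm(list(s), lag = 1, mode = "naive")
  expect_lt(max(abs(tm$T - T0)), 0.01)
})

test_that("transition models satisfy their spectral invariants", {
  set.seed(7)
  s <- simulate_chain(random_reversible_tpm(5, 2), 20000, seed = 7)
  tm <- estimate_tpm(list(s), lag = 2)
  expect_equal(unname(rowSums(tm$T)), rep(1, 5), tolerance = 1e-12)
  expect_equal(tm$eigenvalues[1], 1, tolerance = 1e-10)
  expect_equal(as.numeric(tm$pi %*% tm$T), tm$pi, tolerance = 1e-10)
  expect_equal(sum(tm$pi), 1, tolerance = 1e-12)
  # detailed balance for the symmetrized estimator
  F <- tm$pi * tm$T
  expect_equal(F, t(F), tolerance = 1e-10)
})

test_that("implied timescales follow the closed form exactly", {
  expect_identical(implied_timescale(exp(-1), 4), 4)
  expect_equal(implied_timescale(0.5, 4), 4 / log(2), tolerance = 1e-12)
  expect_true(is.infinite(implied_timescale(1, 4)))
  expect_true(is.na(implied_timescale(-0.2, 4)))
  expect_true(is.na(implied_timescale(0, 4)))
})

test_that("scanned timescales converge on sampled Markovian data", {
  T0 <- matrix(c(0.95, 0.05, 0.03, 0.97), 2, byrow = TRUE)
  lam2 <- sort(eigen(T0)$values)[1]
  truth <- -1 / log(lam2)
  s <- lapply(1:4, function(i) simulate_chain(T0, 25000, seed = 30 + i))
  scan <- implied_timescales(s, lags = 1:10, n_timescales = 1)
  t2 <- scan$timescale_ns[scan$index == 2]
  expect_true(all(abs(t2 - truth) / truth < 0.1))
  # decreasing in index at fixed lag (lazy chain: positive spectrum)
  T3 <- 0.5 * diag(6) + 0.5 * random_reversible_tpm(6, 4)
  s3 <- simulate_chain(T3, 30000, seed = 44)
  scan3 <- implied_timescales(list(s3), lags = c(1, 2), n_timescales = 3)
  one_lag <- scan3[scan3$lag_frames == 1, ]
  expect_true(all(diff(one_lag$timescale_ns) <= 1e-9))
})

test_that("lag selection applies the flatness rule", {
  mk_scan <- function(tau) {
    s <- tibble::tibble(lag_frames = seq_along(tau), lag_ns = seq_along(tau),
                        index = 2, eigenvalue = NA_real_, timescale_ns = tau)
    class(s) <- c("its_scan", class(s))
    s
  }
  pick <- choose_lag(mk_scan(c(10, 14, 14.5, 14.6, 14.7)), flatness_tol = 0.1)
  expect_equal(pick$lag_frames, 2)
  expect_true(pick$markovian)

  expect_warning(
    bad <- choose_lag(mk_scan(c(10, 12, 14.4, 17.3, 20.8)), flatness_tol = 0.1),
    "non-Markovian")
  expect_false(bad$markovian)
  expect_equal(bad$lag_frames, 5)

  # an exactly Markovian chain admits the smallest scanned lag
  T0 <- matrix(c(0.9, 0.1, 0.05, 0.95), 2, byrow = TRUE)
  s <- lapply(1:3, function(i) simulate_chain(T0, 30000, seed = 50 + i))
  scan <- implied_timescales(s, lags = 1:6, n_timescales = 1)
  expect_equal(choose_lag(scan)$lag_frames, 1)
})

test_that("PCCA+ recovers block structure and degenerates gracefully", {
  # two strong diagonal blocks with weak coupling
  blocks <- list(1:3, 4:6)
  T0 <- matrix(0.001, 6, 6)
  for (b in blocks) T0[b, b] <- 1
  T0 <- T0 / rowSums(T0)
  s <- simulate_chain(T0, 40000, seed = 77)
  tm <- estimate_tpm(list(s), lag = 1)
  mac <- pcca_macrostates(tm, 2)
  lab <- mac$macrostate
  expect_equal(length(unique(lab[tm$states %in% 1:3])), 1)
  expect_equal(length(unique(lab[tm$states %in% 4:6])), 1)
  expect_false(lab[tm$states == 1] == lab[tm$states == 6])
  expect_equal(sum(mac$proportions$pi_weight), 1, tolerance = 1e-12)

  # identity lumping at n_macro = number of microstates
  tm2 <- estimate_tpm(list(simulate_chain(random_reversible_tpm(4, 5),
                                          20000, seed = 6)), lag = 1)
  mac2 <- pcca_macrostates(tm2, nrow(tm2$T))
  expect_equal(sort(unique(mac2$macrostate)), seq_len(nrow(tm2$T)))
})

test_that("committor and MFPT honour boundary conditions and closed forms", {
  # 2-state chain with hop probability 0.1: MFPT = 10 steps
  T0 <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  tm <- structure(list(T = T0, pi = c(0.5, 0.5), counts = T0 * 100,
                       lag_frames = 1, frame_interval = 0.5,
                       eigenvalues = c(1, 0.8), mode = "symmetrized"),
                  class = "transition_model")
  r <- mfpt(tm, source = 1, sink = 2)
  expect_equal(r$mfpt_steps, 10, tolerance = 1e-12)
  expect_equal(r$mfpt, 10 * 0.5, tolerance = 1e-12)
  expect_equal(r$committor[1], 0)
  expect_equal(r$committor[2], 1)

  # 3-state birth-death chain vs the dense oracle
  T3 <- matrix(c(0.8, 0.2, 0.0,
                 0.3, 0.4, 0.3,
                 0.0, 0.1, 0.9), 3, byrow = TRUE)
  pi3 <- abs(Re(eigen(t(T3))$vectors[, 1]))
  pi3 <- pi3 / sum(pi3)
  tm3 <- structure(list(T = T3, pi = pi3, counts = T3, lag_frames = 1,
                        frame_interval = 1, eigenvalues = eigen(T3)$values,
                        mode = "symmetrized"),
                   class = "transition_model")
  r3 <- mfpt(tm3, source = 1, sink = 3)
  expect_equal(r3$mfpt_steps, mfpt_oracle(T3, pi3, 1, 3), tolerance = 1e-8)
  expect_gte(min(r3$committor), 0)
  expect_lte(max(r3$committor), 1)

  # unreachable sink reports infinity, not an error
  T_dead <- matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)
  tm_dead <- structure(list(T = T_dead, pi = c(1, 0), counts = T_dead,
                            lag_frames = 1, frame_interval = 1,
                            eigenvalues = c(1, 0.5), mode = "naive"),
                       class = "transition_model")
  r_dead <- mfpt(tm_dead, source = 1, sink = 2)
  expect_true(is.infinite(r_dead$mfpt_steps) || !r_dead$reachable)
})

test_that("representative-frame selection maximises total similarity", {
  # identical frames: tie broken to the first
  expect_equal(representative_frame(matrix(0, 4, 4)), 1L)

  # the printed three-frame example: frame 1 is closest to both others
  d <- matrix(c(0, 1, 1,
                1, 0, 4,
                1, 4, 0), 3, byrow = TRUE)
  expect_equal(representative_frame(d), 1L)
  # exhaustive oracle: direct evaluation of the similarity sums
  ds <- sd(d[upper.tri(d)])
  scores <- rowSums(exp(-d / ds))
  expect_equal(representative_frame(d), which.max(scores))

  # an outlier among near-duplicates is never representative
  d2 <- as.matrix(stats::dist(c(0, 0.01, 0.02, 9)))
  expect_lt(representative_frame(d2), 4)
})
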