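# Markov state modelling: microstate clustering, transition matrix
# estimation, implied timescales, PCCA+ lumping, committor / first
# passage statistics, and representative-frame selection.

# Normalise feature input to a tibble with a traj column.
feature_frames <- function(features) {
  if (is.data.frame(features)) {
    if (!"traj" %in% names(features)) features$traj <- 1L
    out <- features
  } else {
    out <- dplyr::bind_rows(
      purrr::imap(features, function(df, i) dplyr::mutate(df, traj = i)))
  }
  stopifnot(all(c("distance_sum", "dihedral") %in% names(out)))
  out
}

#' Cluster frames into microstates
#'
#' The two collective variables are z-scored (they live on
#' incommensurate scales: angstrom vs degree) and clustered with
#' k-means. For large frame counts the clustering is fitted on a seeded
#' subsample and all frames are then assigned to the nearest fitted
#' center, which is the standard way trajectory frameworks scale
#' microstate clustering.
#'
#' @param features Feature series tibble or list of them.
#' @param k Number of microstates (default 500, reduced automatically to
#'   `floor(frames / 10)` when frames are scarce).
#' @param seed Integer seed (k-means and subsampling).
#' @param max_fit_points Subsample size for the k-means fit.
#' @return Object of class `microstate_model`: `k`, `centers`
#'   (z-scored), `scaling`, `assignments` (list of integer vectors per
#'   trajectory), `features`.
#' @export
cluster_microstates <- function(features, k = 500, seed = 1,
                                max_fit_points = 20000) {
  feats <- feature_frames(features)
  n <- nrow(feats)
  if (n < 2) abort("need at least 2 frames")
  k <- min(k, max(1, floor(n / 10)))
  if (n < k) {
    abort(paste0("fewer frames (", n, ") than microstates (", k,
                 "); reduce k"), class = "conformscape_k_error")
  }
  X <- cbind(feats$distance_sum, feats$dihedral)
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd)
  sdv[sdv == 0] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  set.seed(seed)
  fit_idx <- if (n > max_fit_points) sample.int(n, max_fit_points) else seq_len(n)
  km <- suppressWarnings(
    kmeans(Z[fit_idx, , drop = FALSE], centers = min(k, length(fit_idx)),
           iter.max = 100, nstart = 1))
  centers <- km$centers
  assign_all <- nearest_center(Z, centers)
  used <- sort(unique(assign_all))
  if (length(used) < nrow(centers)) {  # prune empty clusters, relabel
    centers <- centers[used, , drop = FALSE]
    assign_all <- match(assign_all, used)
  }
  structure(list(
    k = nrow(centers), centers = centers, scaling = list(mean = mu, sd = sdv),
    assignments = split(assign_all, feats$traj), features = feats,
    seed = seed
  ), class = "microstate_model")
}

# Chunked nearest-center assignment (avoids an n x k distance matrix).
nearest_center <- function(Z, centers, chunk = 20000L) {
  n <- nrow(Z)
  out <- integer(n)
  cn2 <- rowSums(centers^2)
  for (s in seq(1, n, by = chunk)) {
    e <- min(n, s + chunk - 1)
    D <- outer(rowSums(Z[s:e, , drop = FALSE]^2), cn2, `+`) -
      2 * Z[s:e, , drop = FALSE] %*% t(centers)
    out[s:e] <- max.col(-D, ties.method = "first")
  }
  out
}

#' @export
print.microstate_model <- function(x, ...) {
  cat("<microstate_model>", x$k, "microstates over",
      sum(lengths(x$assignments)), "frames in",
      length(x$assignments), "trajectories\n")
  invisible(x)
}

#' Estimate a transition model at a lag time
#'
#' Counts sliding-window transitions `C[s_t, s_(t+lag)]` within each
#' trajectory (never across trajectory boundaries), restricts to the
#' largest connected set, and row-normalises. The default
#' `"symmetrized"` mode normalises `(C + t(C)) / 2`, giving a reversible
#' chain whose stationary distribution is proportional to the
#' symmetrized row sums and which satisfies detailed balance exactly;
#' `"naive"` normalises the raw counts.
#'
#' @param assignments List of integer label vectors (one per
#'   trajectory), or a `microstate_model`.
#' @param lag Lag in frames (>= 1).
#' @param mode `"symmetrized"` (reversible, default) or `"naive"`.
#' @param frame_interval Physical time per frame (ns); taken from the
#'   feature series when a `microstate_model` built from timed features
#'   is supplied.
#' @return Object of class `transition_model`: `lag_frames`, `lag_ns`,
#'   `counts`, `T` (row-stochastic), `eigenvalues` (magnitude
#'   descending), `right_eigenvectors` (symmetrized mode), `pi`,
#'   `states` (original labels of the retained connected set), `mode`.
#' @export
estimate_tpm <- function(assignments, lag = 1,
                         mode = c("symmetrized", "naive"),
                         frame_interval = 1) {
  mode <- match.arg(mode)
  if (inherits(assignments, "microstate_model")) {
    assignments <- assignments$assignments
  }
  if (!is.list(assignments)) assignments <- list(assignments)
  lens <- lengths(assignments)
  if (any(lens < lag + 1)) {
    abort(paste0("every trajectory needs at least lag + 1 = ", lag + 1,
                 " frames"))
  }
  k <- max(unlist(assignments))
  C <- matrix(0, k, k)
  for (s in assignments) {
    n <- length(s)
    from <- s[1:(n - lag)]
    to <- s[(1 + lag):n]
    idx <- (to - 1) * k + from
    tab <- tabulate(idx, nbins = k * k)
    C <- C + matrix(tab, k, k)
  }
  # largest connected set (strong connectivity on the raw counts for the
  # naive estimator; weak suffices for the symmetrized one)
  g <- igraph::graph_from_adjacency_matrix(
    (C > 0) * 1, mode = if (mode == "symmetrized") "max" else "directed")
  comp <- igraph::components(g, mode = if (mode == "symmetrized") "weak" else "strong")
  sizes_frames <- tapply(rowSums(C) + colSums(C), comp$membership, sum)
  keep_comp <- as.integer(names(which.max(sizes_frames)))
  states <- which(comp$membership == keep_comp & (rowSums(C) + colSums(C)) > 0)
  if (length(states) < k) {
    warn(paste0("count graph not connected; keeping ", length(states),
                " of ", k, " states"))
  }
  Cs <- C[states, states, drop = FALSE]
  if (mode == "symmetrized") {
    S <- (Cs + t(Cs)) / 2
    pi <- rowSums(S) / sum(S)
    T <- S / rowSums(S)
    # similarity transform to a symmetric matrix: real spectrum
    d <- sqrt(pi)
    Sym <- T * outer(d, 1 / d)
    Sym <- (Sym + t(Sym)) / 2
    e <- eigen(Sym, symmetric = TRUE)
    ord <- order(abs(e$values), decreasing = TRUE)
    vals <- e$values[ord]
    right <- (1 / d) * e$vectors[, ord, drop = FALSE]
    right[, 1] <- 1  # the stationary process: T 1 = 1
  } else {
    rs <- rowSums(Cs)
    T <- Cs / rs
    e <- eigen(T)
    ord <- order(Mod(e$values), decreasing = TRUE)
    vals <- e$values[ord]
    vals <- if (all(abs(Im(vals)) < 1e-12)) Re(vals) else vals
    right <- NULL
    le <- eigen(t(T))
    v <- Re(le$vectors[, which.max(Mod(le$values))])
    pi <- abs(v) / sum(abs(v))
  }
  structure(list(lag_frames = lag, lag_ns = lag * frame_interval,
                 counts = Cs, T = T, eigenvalues = vals,
                 right_eigenvectors = right, pi = pi,
                 states = states, mode = mode,
                 frame_interval = frame_interval),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("<transition_model>", nrow(x$T), "states; lag", x$lag_frames,
      "frames (", x$lag_ns, "ns );", x$mode, "estimator\n")
  invisible(x)
}

#' @export
tidy.transition_model <- function(x, ...) {
  tibble::tibble(state = x$states, pi = x$pi)
}

#' @export
glance.transition_model <- function(x, ...) {
  l2 <- if (length(x$eigenvalues) > 1) Re(x$eigenvalues[2]) else NA_real_
  tibble::tibble(
    n_states = nrow(x$T), lag_frames = x$lag_frames, lag_ns = x$lag_ns,
    lambda_2 = l2,
    t2_ns = if (!is.na(l2) && l2 > 0 && l2 < 1) -x$lag_ns / log(l2) else NA_real_
  )
}

#' Closed-form implied timescale
#'
#' `t_i = -lag / ln(lambda_i)`: the relaxation time of the process
#' carried by eigenvalue `lambda_i` of a transition matrix estimated at
#' lag time `lag`. Non-positive eigenvalues have no defined timescale
#' (`NA`); eigenvalues at or above 1 relax infinitely slowly (`Inf`).
#'
#' @param lambda Eigenvalue(s) of a transition matrix.
#' @param lag_time Lag time (any time unit; the result shares it).
#' @return Timescale(s) in the units of `lag_time`.
#' @export
implied_timescale <- function(lambda, lag_time) {
  out <- rep(NA_real_, length(lambda))
  out[lambda >= 1] <- Inf
  pos <- lambda > 0 & lambda < 1
  out[pos] <- -lag_time / log(lambda[pos])
  out
}

#' Implied timescale scan
#'
#' For each lag, estimates a transition model and converts eigenvalues
#' 2..m into relaxation timescales `t_i = -lag / ln(lambda_i)` in
#' physical time. Timescales are undefined (`NA`) for non-positive
#' eigenvalues and infinite for eigenvalues at or above 1. A scan that
#' is flat in lag indicates the microstate dynamics are Markovian at
#' that resolution.
#'
#' @inheritParams estimate_tpm
#' @param lags Integer vector of lags (frames).
#' @param n_timescales How many timescales to report per lag.
#' @return Tibble of class `its_scan`: `lag_frames`, `lag_ns`, `index`
#'   (2..m), `eigenvalue`, `timescale_ns`.
#' @export
implied_timescales <- function(assignments, lags = 1:10,
                               mode = c("symmetrized", "naive"),
                               frame_interval = 1, n_timescales = 4) {
  mode <- match.arg(mode)
  stopifnot(all(lags >= 1))
  rows <- purrr::map_dfr(lags, function(lag) {
    m <- estimate_tpm(assignments, lag = lag, mode = mode,
                      frame_interval = frame_interval)
    nv <- min(n_timescales + 1, length(m$eigenvalues))
    lam <- Re(m$eigenvalues[2:nv])
    tibble::tibble(
      lag_frames = lag, lag_ns = m$lag_ns,
      index = 2:nv, eigenvalue = lam,
      timescale_ns = implied_timescale(lam, m$lag_ns)
    )
  })
  class(rows) <- c("its_scan", class(rows))
  rows
}

#' @export
autoplot.its_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$lag_ns, y = .data$timescale_ns,
                               colour = factor(.data$index - 1))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time (ns)", y = "implied timescale (ns)",
                  colour = "process") +
    ggplot2::theme_minimal()
}

#' Choose a Markovian lag from an implied timescale scan
#'
#' Returns the smallest lag from which the slowest implied timescale
#' varies by less than `flatness_tol` (relative) across all larger
#' scanned lags. When no lag before the last satisfies the rule the
#' scan is flagged non-Markovian and the largest lag is returned with a
#' diagnostic.
#'
#' @param scan An [implied_timescales()] tibble.
#' @param flatness_tol Relative flatness tolerance (default 0.1).
#' @return List: `lag_frames`, `lag_ns`, `markovian` (logical),
#'   `max_variation`.
#' @export
choose_lag <- function(scan, flatness_tol = 0.1) {
  slow <- scan[scan$index == 2, ]
  slow <- slow[order(slow$lag_frames), ]
  if (nrow(slow) < 3) abort("scan needs at least 3 lags")
  tau <- slow$timescale_ns
  for (j in seq_len(nrow(slow) - 1)) {
    later <- tau[(j + 1):nrow(slow)]
    variation <- abs(later - tau[j]) / tau[j]
    if (all(is.finite(variation)) && all(variation < flatness_tol)) {
      return(list(lag_frames = slow$lag_frames[j], lag_ns = slow$lag_ns[j],
                  markovian = TRUE, max_variation = max(variation)))
    }
  }
  warn("no scanned lag reaches a flat slowest timescale; dynamics look non-Markovian")
  j <- nrow(slow)
  list(lag_frames = slow$lag_frames[j], lag_ns = slow$lag_ns[j],
       markovian = FALSE, max_variation = NA_real_)
}

#' Lump microstates into metastable macrostates (PCCA+)
#'
#' Spectral lumping on the first `n_macro` right eigenvectors of a
#' reversible transition model: the rows of the eigenvector matrix lie
#' in an `n_macro`-vertex simplex whose vertices are found by the inner
#' simplex (maximal spread) construction; fuzzy memberships are the
#' barycentric coordinates and crisp states their argmax.
#'
#' @param model A symmetrized-mode [estimate_tpm()] result.
#' @param n_macro Number of macrostates.
#' @return Object of class `macrostate_model`: `n_macro`, `membership`
#'   (fuzzy matrix), `macrostate` (crisp assignment per microstate),
#'   `proportions` (tibble: macrostate, pi_weight, count_weight),
#'   `states` (microstate labels), `model`.
#' @export
pcca_macrostates <- function(model, n_macro = 3) {
  stopifnot(inherits(model, "transition_model"))
  if (model$mode != "symmetrized" || is.null(model$right_eigenvectors)) {
    abort("PCCA+ needs a reversible (symmetrized) transition model")
  }
  n <- nrow(model$T)
  if (n_macro == n) {
    membership <- diag(n)
    crisp <- seq_len(n)
  } else {
    lam <- Re(model$eigenvalues)
    if (sum(lam > 0) < n_macro) {
      abort("n_macro exceeds the number of positive eigenvalues")
    }
    if (length(lam) > n_macro &&
        abs(lam[n_macro] - lam[n_macro + 1]) < 1e-6) {
      warn("no spectral gap after the requested macrostate count; lumping is ambiguous")
    }
    psi <- model$right_eigenvectors[, seq_len(n_macro), drop = FALSE]
    vert <- integer(n_macro)
    X <- psi
    # first vertex: farthest row from the centroid
    ctr <- colMeans(X)
    d2 <- rowSums(sweep(X, 2, ctr)^2)
    vert[1] <- which.max(d2)
    X <- sweep(X, 2, psi[vert[1], ])
    for (m in seq_len(n_macro - 1)) {
      # project out the span of the vertices found so far
      v <- X[vert[m], ]
      nv <- sqrt(sum(v^2))
      if (nv > 0) {
        v <- v / nv
        X <- X - outer(as.vector(X %*% v), v)
      }
      vert[m + 1] <- which.max(rowSums(X^2))
    }
    W <- psi[vert, , drop = FALSE]
    membership <- psi %*% solve(W)
    crisp <- max.col(membership, ties.method = "first")
  }
  pi <- model$pi
  counts <- rowSums(model$counts)
  prop <- tibble::tibble(
    macrostate = seq_len(n_macro),
    pi_weight = as.numeric(tapply(pi, factor(crisp, seq_len(n_macro)), sum)),
    count_weight = as.numeric(tapply(counts, factor(crisp, seq_len(n_macro)),
                                     sum) / sum(counts))
  )
  prop$pi_weight[is.na(prop$pi_weight)] <- 0
  prop$count_weight[is.na(prop$count_weight)] <- 0
  if (any(prop$pi_weight == 0)) warn("empty macrostate after crisp assignment")
  structure(list(n_macro = n_macro, membership = membership,
                 macrostate = crisp, proportions = prop,
                 states = model$states, model = model),
            class = "macrostate_model")
}

#' @export
print.macrostate_model <- function(x, ...) {
  cat("<macrostate_model>", x$n_macro, "macrostates; pi weights:",
      paste(sprintf("%.3f", x$proportions$pi_weight), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.macrostate_model <- function(x, ...) {
  tibble::tibble(state = x$states, macrostate = x$macrostate,
                 pi = x$model$pi)
}

#' @export
glance.macrostate_model <- function(x, ...) {
  tibble::tibble(n_macro = x$n_macro,
                 min_pi_weight = min(x$proportions$pi_weight),
                 max_pi_weight = max(x$proportions$pi_weight))
}

#' Committor and mean first passage time between state sets
#'
#' Solves the forward committor linear system (probability of reaching
#' the sink before the source) and the first-passage system on the
#' transition matrix with the sink absorbing. The reported MFPT averages
#' the per-state passage times over the source states weighted by the
#' stationary distribution restricted to the source, and is converted to
#' physical time (one matrix step = `lag_frames * frame_interval`).
#'
#' @param model A [estimate_tpm()] result.
#' @param source,sink Disjoint, non-empty sets of state indices (in
#'   1..nrow(T), i.e. positions within the model's retained states).
#' @return Object of class `tpt_result`: `committor` (per state),
#'   `mfpt_steps`, `mfpt` (physical units), `source`, `sink`.
#' @export
mfpt <- function(model, source, sink) {
  stopifnot(inherits(model, "transition_model"))
  n <- nrow(model$T)
  source <- as.integer(source)
  sink <- as.integer(sink)
  if (length(source) == 0 || length(sink) == 0) {
    abort("source and sink must be non-empty")
  }
  if (length(intersect(source, sink)) > 0) {
    abort("source and sink must be disjoint")
  }
  T <- model$T
  # forward committor: q = 0 on source, 1 on sink
  inter <- setdiff(seq_len(n), c(source, sink))
  q <- numeric(n)
  q[sink] <- 1
  if (length(inter) > 0) {
    A <- diag(length(inter)) - T[inter, inter, drop = FALSE]
    b <- rowSums(T[inter, sink, drop = FALSE])
    q[inter] <- tryCatch(solve(A, b), error = function(e) rep(NA_real_, length(inter)))
  }
  # first passage times with sink absorbing
  nonsink <- setdiff(seq_len(n), sink)
  t_steps <- numeric(n)
  ok <- TRUE
  A <- diag(length(nonsink)) - T[nonsink, nonsink, drop = FALSE]
  sol <- tryCatch(solve(A, rep(1, length(nonsink))),
                  error = function(e) {
                    ok <<- FALSE
                    rep(Inf, length(nonsink))
                  })
  t_steps[nonsink] <- sol
  w <- model$pi[source] / sum(model$pi[source])
  mfpt_steps <- sum(w * t_steps[source])
  structure(list(
    committor = q, mfpt_steps = mfpt_steps,
    mfpt = mfpt_steps * model$lag_frames * model$frame_interval,
    per_state_steps = t_steps,
    source = source, sink = sink, reachable = ok && is.finite(mfpt_steps)
  ), class = "tpt_result")
}

#' @export
print.tpt_result <- function(x, ...) {
  cat("<tpt_result> MFPT", format(x$mfpt, digits = 5), "time units (",
      format(x$mfpt_steps, digits = 5), "lag steps )\n")
  invisible(x)
}

#' @export
tidy.tpt_result <- function(x, ...) {
  tibble::tibble(state = seq_along(x$committor), committor = x$committor,
                 passage_steps = x$per_state_steps)
}

#' @export
glance.tpt_result <- function(x, ...) {
  tibble::tibble(mfpt = x$mfpt, mfpt_steps = x$mfpt_steps,
                 reachable = x$reachable)
}

#' Representative frame by similarity score
#'
#' Converts a symmetric distance matrix (RMSD between snapshots, or
#' Euclidean distance in standardized collective-variable space) into
#' similarities `S = exp(-d / d_scale)` with `d_scale` the standard
#' deviation of the pairwise distances (upper triangle), and returns the
#' frame with the highest total similarity to all others. Ties break to
#' the lowest index; a fully degenerate (all-zero) distance matrix
#' returns the first frame.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @return Integer index of the representative frame (1-based).
#' @export
representative_frame <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d))
  if (nrow(d) == 1) return(1L)
  ut <- d[upper.tri(d)]
  d_scale <- sd(ut)
  if (!is.finite(d_scale) || d_scale == 0) return(1L)
  S <- exp(-d / d_scale)
  score <- rowSums(S)
  which.max(score)  # which.max already breaks ties low
}

#' Representative frames of each macrostate
#'
#' Pools the frames assigned to each macrostate's microstates, keeps the
#' `n_candidates` closest to their microstate centers (in z-scored
#' collective-variable space), and applies [representative_frame()] to
#' their pairwise Euclidean distances.
#'
#' @param micro A [cluster_microstates()] model.
#' @param macro A [pcca_macrostates()] model built from it.
#' @param n_candidates Candidate pool size per macrostate.
#' @return Tibble: `macrostate`, `traj`, `frame`, `distance_sum`,
#'   `dihedral`.
#' @export
representative_frames <- function(micro, macro, n_candidates = 200) {
  feats <- micro$features
  all_assign <- unlist(micro$assignments, use.names = FALSE)
  Z <- sweep(sweep(cbind(feats$distance_sum, feats$dihedral), 2,
                   micro$scaling$mean), 2, micro$scaling$sd, `/`)
  center_dist <- sqrt(rowSums((Z - micro$centers[all_assign, , drop = FALSE])^2))
  # map microstate (model state space) -> macrostate
  micro_to_macro <- rep(NA_integer_, micro$k)
  micro_to_macro[macro$states] <- macro$macrostate
  frame_macro <- micro_to_macro[all_assign]
  purrr::map_dfr(seq_len(macro$n_macro), function(m) {
    idx <- which(frame_macro == m)
    if (length(idx) == 0) return(NULL)
    idx <- idx[order(center_dist[idx])][seq_len(min(n_candidates, length(idx)))]
    D <- as.matrix(stats::dist(Z[idx, , drop = FALSE]))
    rep_i <- idx[representative_frame(D)]
    tibble::tibble(macrostate = m, traj = feats$traj[rep_i],
                   frame = feats$frame[rep_i],
                   distance_sum = feats$distance_sum[rep_i],
                   dihedral = feats$dihedral[rep_i])
  })
}
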