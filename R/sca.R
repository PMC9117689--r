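#' Load a multiple sequence alignment
#'
#' Reads an aligned FASTA, uppercases, maps any character outside the
#' 20-residue alphabet to the gap symbol `-`, and appends a single
#' all-gap row. The gap row is a pseudocount guard: with it appended no
#' residue can reach frequency exactly 1, so the relative-entropy
#' conservation score and its derivative stay finite.
#'
#' @param x Path to a FASTA file, or FASTA text.
#' @return Object of class `msa`: character matrix (rows = sequences
#'   incl. the gap row, columns = positions) with attributes
#'   `n_sequences` (excluding the gap row) and `gap_row_appended`.
#' @export
load_msa <- function(x) {
  path <- x
  if (length(x) > 1 || grepl("\n", x[1], fixed = TRUE) || !file.exists(x[1])) {
    path <- tempfile(fileext = ".fasta")
    writeLines(if (length(x) > 1) x else strsplit(x, "\n", fixed = TRUE)[[1]],
               path)
    on.exit(unlink(path))
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- setNames(as.character(ss), names(ss))
  load_msa_strings(seqs)
}

# Core constructor from named character vector of aligned sequences.
load_msa_strings <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) {
    bad <- names(seqs)[which(lens != lens[1])[1]]
    abort(paste0("alignment is ragged: sequence '", bad, "' has length ",
                 nchar(seqs[bad]), ", expected ", lens[1]),
          class = "conformscape_length_error")
  }
  M <- do.call(rbind, strsplit(toupper(seqs), ""))
  M[!M %in% AA_ALPHABET] <- "-"
  M <- rbind(M, matrix("-", 1, ncol(M)))  # zero-frequency guard
  rownames(M) <- c(names(seqs), ".gap_row")
  structure(M, class = "msa", n_sequences = nrow(M) - 1L,
            gap_row_appended = TRUE)
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa>", attr(x, "n_sequences"), "sequences (+1 gap row) x",
      ncol(x), "positions\n")
  invisible(x)
}

#' Positional conservation score
#'
#' Relative entropy (cross-entropy loss) between the observed frequency
#' `f` of a residue at a position and its background frequency `q`:
#' `D = f ln(f/q) + (1 - f) ln((1 - f)/(1 - q))`, with the `0 ln 0 = 0`
#' convention at `f` of 0 or 1. `D` is zero at `f = q` and grows as the
#' position's usage departs from background.
#'
#' @param f Observed frequency in `[0, 1]` (vectorised).
#' @param q Background frequency in `(0, 1)`.
#' @return Conservation score(s).
#' @export
conservation_score <- function(f, q) {
  if (any(q <= 0 | q >= 1)) {
    abort("background frequency must lie strictly inside (0, 1)",
          class = "conformscape_background_error")
  }
  stopifnot(all(f >= 0 & f <= 1))
  xlx <- function(p, r) ifelse(p == 0, 0, p * log(p / r))
  xlx(f, q) + xlx(1 - f, 1 - q)
}

# d D / d f, finite for f strictly inside (0, 1).
conservation_slope <- function(f, q) log(f * (1 - q) / (q * (1 - f)))

#' Conservation profile of an alignment
#'
#' Per position, the dominant residue (modal amino acid, gaps never
#' dominant, frequency ties broken alphabetically), its frequency over
#' all alignment rows (the appended gap row inflates the denominator
#' once), and the conservation score against the background frequency.
#'
#' @param msa An [load_msa()] object.
#' @param q Background frequency: a single number applied to every
#'   residue (default 0.05, uniform over the 20 amino acids) or a named
#'   vector over residues.
#' @return Tibble: `position`, `residue`, `frequency`, `score`.
#' @export
conservation_profile <- function(msa, q = 0.05) {
  stats <- column_stats(msa)
  qv <- if (length(q) == 1) rep(q, ncol(msa)) else unname(q[stats$residue])
  tibble::tibble(
    position = seq_len(ncol(msa)),
    residue = stats$residue,
    frequency = stats$frequency,
    score = ifelse(is.na(stats$residue), NA_real_,
                   conservation_score(stats$frequency, qv))
  )
}

# Dominant residue and its frequency per column; NA for all-gap columns.
column_stats <- function(msa) {
  n <- nrow(msa)
  residue <- character(ncol(msa))
  frequency <- numeric(ncol(msa))
  for (j in seq_len(ncol(msa))) {
    col <- msa[, j]
    tab <- table(col[col != "-"])
    if (length(tab) == 0) {
      residue[j] <- NA_character_
      frequency[j] <- 0
    } else {
      tab <- tab[order(-tab, names(tab))]  # alphabetical tie-break
      residue[j] <- names(tab)[1]
      frequency[j] <- tab[[1]] / n
    }
  }
  list(residue = residue, frequency = frequency)
}

#' Co-evolution (statistical coupling) matrix
#'
#' For the dominant residue `a` at position `i` and `b` at `j`,
#' `C[i, j] = dD/df(i) * dD/df(j) * |f_ij - f_i f_j|`, where `f_ij` is
#' the joint frequency of observing both dominant residues in the same
#' sequence and the slope `dD/df = ln(f (1 - q) / (q (1 - f)))` is the
#' analytic derivative of the conservation score. Exactly independent
#' column pairs have `f_ij = f_i f_j` and score 0.
#'
#' @inheritParams conservation_profile
#' @return Object of class `sca_matrix`: list with `C` (positions x
#'   positions, symmetric), `profile` (the conservation tibble) and `q`.
#' @export
sca_matrix <- function(msa, q = 0.05) {
  if (ncol(msa) < 2) abort("need at least 2 positions")
  profile <- conservation_profile(msa, q)
  all_gap <- is.na(profile$residue)
  if (any(all_gap)) {
    warn(paste0("all-gap position(s) ", paste(which(all_gap), collapse = ", "),
                "; their coupling rows are zero"))
  }
  # indicator of "row carries the dominant residue of position j"
  Ind <- matrix(0, nrow(msa), ncol(msa))
  ok <- which(!all_gap)
  for (j in ok) Ind[, j] <- as.numeric(msa[, j] == profile$residue[j])
  f <- profile$frequency
  Fij <- crossprod(Ind) / nrow(msa)
  qv <- if (length(q) == 1) rep(q, ncol(msa)) else unname(q[profile$residue])
  slope <- numeric(ncol(msa))
  slope[ok] <- conservation_slope(f[ok], qv[ok])
  C <- outer(slope, slope) * abs(Fij - outer(f, f))
  C[all_gap, ] <- 0
  C[, all_gap] <- 0
  dimnames(C) <- list(seq_len(ncol(msa)), seq_len(ncol(msa)))
  structure(list(C = C, profile = profile, q = q), class = "sca_matrix")
}

#' @export
print.sca_matrix <- function(x, ...) {
  cat("<sca_matrix>", nrow(x$C), "positions\n")
  invisible(x)
}

#' Eigenvector-defined co-evolution sectors
#'
#' Eigendecomposes the coupling matrix (diagonal zeroed by default so
#' sectors are driven by coupling, not self-conservation), drops the
#' first mode as the global signal, and applies the loading rules on the
#' second and fourth eigenvectors: red positions satisfy
#' `v2 > v4` and `v2 > eps`; blue positions satisfy
#' `(v2 < v4 and v2 < -eps)` or `(v4 > v2 and v4 > eps)`. "Weight" is
#' the signed loading; each eigenvector's sign is fixed so its
#' largest-magnitude component is positive, making the rules
#' reproducible.
#'
#' @param sca An [sca_matrix()] result (or a bare symmetric matrix).
#' @param eps Loading threshold (default 0.05).
#' @param zero_diagonal Zero the diagonal before decomposition
#'   (default `TRUE`).
#' @return Object of class `sca_sectors`: list with `loadings` (tibble
#'   of positions x eigenvectors 2-4), `red`, `blue` (position sets),
#'   `eigenvalues`, `eps`.
#' @export
define_sectors <- function(sca, eps = 0.05, zero_diagonal = TRUE) {
  C <- if (inherits(sca, "sca_matrix")) sca$C else as.matrix(sca)
  if (nrow(C) < 4) abort("need at least 4 positions for sector eigenvectors",
                         class = "conformscape_rank_error")
  if (zero_diagonal) diag(C) <- 0
  e <- eigen(C, symmetric = TRUE)
  V <- e$vectors[, 1:4, drop = FALSE]
  for (k in 1:4) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  v2 <- V[, 2]
  v3 <- V[, 3]
  v4 <- V[, 4]
  pos <- seq_len(nrow(C))
  red <- pos[v2 > v4 & v2 > eps]
  blue <- pos[(v2 < v4 & v2 < -eps) | (v4 > v2 & v4 > eps)]
  structure(list(
    loadings = tibble::tibble(position = pos, v2 = v2, v3 = v3, v4 = v4),
    red = red, blue = blue,
    eigenvalues = e$values, eps = eps
  ), class = "sca_sectors")
}

#' @export
print.sca_sectors <- function(x, ...) {
  cat("<sca_sectors> red:", length(x$red), "positions; blue:",
      length(x$blue), "positions (eps =", x$eps, ")\n")
  invisible(x)
}

#' @export
tidy.sca_sectors <- function(x, ...) {
  dplyr::mutate(x$loadings,
                sector = dplyr::case_when(
                  .data$position %in% x$red ~ "red",
                  .data$position %in% x$blue ~ "blue",
                  TRUE ~ "none"))
}

#' @export
autoplot.sca_sectors <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v2, y = .data$v4,
                                   colour = .data$sector)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-1, 1) * object$eps, linetype = 3) +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$eps, linetype = 3) +
    ggplot2::scale_colour_manual(values = c(red = "firebrick", blue = "steelblue",
                                            none = "grey60")) +
    ggplot2::labs(x = "eigenvector 2 loading", y = "eigenvector 4 loading") +
    ggplot2::theme_minimal()
}

#' Receptor domain table for conservation summaries
#'
#' Residue ranges of the AT2R domains (N-terminal, TM1-TM7, H8, the
#' intra- and extracellular loops) plus the pooled composites "All
#' loops" and "All TMD". Positions here are structure residue numbers;
#' supply `position_offset` to [domain_conservation()] when alignment
#' columns are numbered from 1.
#'
#' @return Tibble: `domain`, `start`, `end` (one row per range;
#'   composite domains repeat the name).
#' @export
at2r_domains <- function() {
  tibble::tribble(
    ~domain, ~start, ~end,
    "N-terminal", 35L, 44L,
    "TM1", 45L, 72L,
    "TM2", 78L, 107L,
    "TM3", 112L, 148L,
    "TM4", 156L, 182L,
    "TM5", 203L, 241L,
    "TM6", 245L, 285L,
    "TM7", 289L, 321L,
    "H8", 322L, 335L,
    "ICLs", 73L, 77L,
    "ICLs", 149L, 155L,
    "ICLs", 242L, 244L,
    "ECLs", 108L, 111L,
    "ECLs", 183L, 202L,
    "ECLs", 286L, 288L
  )
}

#' Domain-averaged conservation
#'
#' Mean and sample standard deviation of the conservation score over
#' each named domain; composite rows pool all ranges sharing a name.
#' When the domain table carries TM and loop rows, pooled "All TMD"
#' (TM1-TM7) and "All loops" (ICLs + ECLs) rows are appended.
#'
#' @param profile A [conservation_profile()] tibble.
#' @param domains Tibble of `domain`, `start`, `end` ranges (default
#'   [at2r_domains()]).
#' @param position_offset Added to profile positions before matching
#'   ranges (use when alignment columns do not start at the structure's
#'   first residue number).
#' @return Tibble: `domain`, `n_positions`, `mean`, `sd`.
#' @export
domain_conservation <- function(profile, domains = at2r_domains(),
                                position_offset = 0) {
  pos <- profile$position + position_offset
  one <- function(name, ranges) {
    sel <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(ranges))) {
      sel <- sel | (pos >= ranges$start[r] & pos <= ranges$end[r])
    }
    d <- profile$score[sel & !is.na(profile$score)]
    if (length(d) == 0) {
      warn(paste0("domain ", name, " covers no aligned positions; omitted"))
      return(NULL)
    }
    tibble::tibble(domain = name, n_positions = length(d),
                   mean = mean(d), sd = if (length(d) > 1) sd(d) else 0)
  }
  base <- dplyr::bind_rows(lapply(split(domains, domains$domain), function(dd) {
    one(dd$domain[1], dd)
  }))
  tms <- domains[grepl("^TM[1-7]$", domains$domain), ]
  loops <- domains[domains$domain %in% c("ICLs", "ECLs"), ]
  extra <- dplyr::bind_rows(
    if (nrow(tms) > 0) one("All TMD", tms),
    if (nrow(loops) > 0) one("All loops", loops)
  )
  out <- dplyr::bind_rows(base, extra)
  ord <- match(unique(domains$domain), out$domain)
  dplyr::bind_rows(out[ord[!is.na(ord)], ],
                   out[!out$domain %in% unique(domains$domain), ])
}
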