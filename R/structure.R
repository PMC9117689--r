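#' Read a PDB-format structure
#'
#' Parses ATOM/HETATM records (fixed-column PDB format, through
#' [bio3d::read.pdb()]) into a tidy atom table. Protein and hetero
#' (ligand) atoms are kept side by side and can be extracted with
#' [ca_coords()] and [ligand_coords()].
#'
#' @param x Path to a PDB file, or PDB-format text (a single string with
#'   newlines or a character vector of lines).
#' @return An object of class `conf_structure`: a list with `atoms`
#'   (tibble: `chain`, `resno`, `resid`, `elety`, `x`, `y`, `z`, `het`)
#'   and `title`.
#' @export
read_structure <- function(x) {
  path <- x
  if (length(x) > 1 || grepl("\n", x[1], fixed = TRUE) || !file.exists(x[1])) {
    path <- tempfile(fileext = ".pdb")
    writeLines(if (length(x) > 1) x else strsplit(x, "\n", fixed = TRUE)[[1]], path)
    on.exit(unlink(path))
  }
  raw <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", raw)
  if (!any(rec)) {
    abort("no ATOM/HETATM records found", class = "conformscape_parse_error")
  }
  coords_txt <- substr(raw[rec], 31, 54)
  bad <- which(is.na(suppressWarnings(as.numeric(substr(coords_txt, 1, 8)))) |
                 is.na(suppressWarnings(as.numeric(substr(coords_txt, 9, 16)))) |
                 is.na(suppressWarnings(as.numeric(substr(coords_txt, 17, 24)))))
  if (length(bad) > 0) {
    abort(paste0("malformed coordinate field at line ", which(rec)[bad[1]], ": ",
                 raw[rec][bad[1]]),
          class = "conformscape_parse_error")
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  atoms <- tibble::tibble(
    chain = at$chain,
    resno = as.integer(at$resno),
    resid = at$resid,
    elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    het = at$type == "HETATM"
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("non-finite coordinates in PDB input", class = "conformscape_parse_error")
  }
  title <- sub("^TITLE\\s+", "", grep("^TITLE", raw, value = TRUE)[1])
  structure(list(atoms = atoms, title = if (is.na(title)) "" else title),
            class = "conf_structure")
}

#' @export
print.conf_structure <- function(x, ...) {
  cat("<conf_structure>", x$title, "\n")
  cat(" ", nrow(x$atoms), "atoms;",
      sum(!x$atoms$het), "protein,", sum(x$atoms$het), "hetero\n")
  invisible(x)
}

# Longest protein chain by count of Calpha atoms (multi-chain entries often
# carry antibody fragments next to the receptor).
longest_protein_chain <- function(s) {
  ca <- s$atoms[!s$atoms$het & s$atoms$elety == "CA", ]
  if (nrow(ca) == 0) {
    abort("structure contains no Calpha atoms",
          class = "conformscape_empty_selection_error")
  }
  names(sort(table(ca$chain), decreasing = TRUE))[1]
}

#' Extract Calpha coordinates
#'
#' @param s A `conf_structure`.
#' @param chain Chain identifier; default the longest protein chain.
#' @return Numeric matrix (n residues x 3) with residue numbers as
#'   rownames, ordered by residue number.
#' @export
ca_coords <- function(s, chain = NULL) {
  chain <- chain %||% longest_protein_chain(s)
  ca <- s$atoms[!s$atoms$het & s$atoms$elety == "CA" & s$atoms$chain %in% chain, ]
  if (nrow(ca) == 0) {
    abort(paste0("no Calpha atoms in chain ", chain),
          class = "conformscape_empty_selection_error")
  }
  ca <- ca[!duplicated(ca$resno), ]
  ca <- ca[order(ca$resno), ]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

#' Extract hetero-atom (ligand) coordinates
#'
#' Water molecules are excluded.
#'
#' @param s A `conf_structure`.
#' @param resid Optional 3-letter residue name to select one ligand.
#' @return Numeric matrix (n atoms x 3).
#' @export
ligand_coords <- function(s, resid = NULL) {
  het <- s$atoms[s$atoms$het & !s$atoms$resid %in% c("HOH", "WAT"), ]
  if (!is.null(resid)) het <- het[het$resid %in% resid, ]
  if (nrow(het) == 0) {
    abort("no ligand (HETATM) atoms found",
          class = "conformscape_empty_selection_error")
  }
  as.matrix(het[, c("x", "y", "z")])
}

#' Download the AT2R crystal structures used in the worked example
#'
#' Fetches the antagonist-bound (5UNG, inactive-like) and angiotensin
#' II-bound (6JOD, active-like) AT2R entries from the RCSB PDB. The
#' worked-example collective variables require these deposited
#' coordinates; they are not redistributed with the package.
#'
#' @param dir Directory to write `5UNG.pdb` and `6JOD.pdb` into.
#' @param quiet Passed to [utils::download.file()].
#' @return Invisibly, the paths of the downloaded files.
#' @export
fetch_at2r_structures <- function(dir = ".", quiet = FALSE) {
  ids <- c("5UNG", "6JOD")
  paths <- file.path(dir, paste0(ids, ".pdb"))
  for (i in seq_along(ids)) {
    utils::download.file(
      paste0("https://files.rcsb.org/download/", ids[i], ".pdb"),
      paths[i], quiet = quiet
    )
  }
  invisible(paths)
}
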