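#' Ballesteros-Weinstein residue maps
#'
#' In the Ballesteros-Weinstein scheme each transmembrane helix position
#' is written `helix.index`, with `x.50` the most conserved residue of
#' helix `x`. Resolution to sequence numbering is pure arithmetic within
#' a helix: `residue(x.n) = anchor(x) + (n - 50)`. Positions resolving
#' outside the helix's residue range are rejected rather than
#' extrapolated.
#'
#' @param anchors Named numeric vector: helix label -> residue number of
#'   the `x.50` position (names like `"2"`, `"7"`, `"8"`).
#' @param helix_ranges Named list of length-2 integer vectors: helix
#'   label -> `(first, last)` residue numbers.
#' @return An object of class `bw_map`.
#' @examples
#' bw <- bw_map(c(`6` = 271), list(`6` = c(245, 285)))
#' bw_resolve(bw, "6.25")  # 246
#' @export
bw_map <- function(anchors, helix_ranges) {
  stopifnot(length(anchors) > 0, !is.null(names(anchors)))
  for (h in names(anchors)) {
    r <- helix_ranges[[h]]
    if (is.null(r)) {
      abort(paste0("anchor for helix ", h, " has no helix range"))
    }
    if (anchors[[h]] < r[1] || anchors[[h]] > r[2]) {
      abort(paste0("anchor ", anchors[[h]], " outside helix ", h,
                   " range [", r[1], ", ", r[2], "]"))
    }
  }
  structure(list(anchors = anchors, helix_ranges = helix_ranges),
            class = "bw_map")
}

#' @rdname bw_map
#' @param bw A `bw_map`.
#' @param code Position code(s) as strings `"helix.index"` (e.g.
#'   `"6.25"`). The index is read as an integer offset from 50, so
#'   `"7.56"` means position 56 on helix 7.
#' @export
bw_resolve <- function(bw, code) {
  vapply(as.character(code), function(cd) {
    parts <- strsplit(cd, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2) {
      abort(paste0("malformed Ballesteros-Weinstein code: ", cd))
    }
    h <- parts[1]
    n <- as.integer(parts[2])
    if (!h %in% names(bw$anchors)) {
      abort(paste0("no x.50 anchor for helix ", h),
            class = "conformscape_missing_anchor_error")
    }
    anchor <- bw$anchors[[h]]
    res <- anchor + (n - 50L)
    r <- bw$helix_ranges[[h]]
    if (res < r[1] || res > r[2]) {
      abort(paste0(cd, " resolves to residue ", res,
                   ", outside helix ", h, " range [", r[1], ", ", r[2], "]"),
            class = "conformscape_range_error")
    }
    as.integer(res)
  }, integer(1))
}

#' @export
print.bw_map <- function(x, ...) {
  cat("<bw_map> helices:", paste(names(x$anchors), collapse = ", "), "\n")
  invisible(x)
}

#' Ballesteros-Weinstein map for the angiotensin II type 2 receptor
#'
#' Anchors follow the published position labels for AT2R (e.g. W100 at
#' 2.60 places 2.50 at residue 90; P271 is 6.50; N315 is 7.50; R324 at
#' 8.49 places 8.50 at 325) and helix ranges follow the receptor's
#' domain table (TM2 78-107, TM3 112-148, TM5 203-241, TM6 245-285,
#' TM7 289-321, H8 322-335). TM1 and TM4 carry no published anchor and
#' are omitted.
#'
#' @return A `bw_map`.
#' @export
at2r_bw_map <- function() {
  bw_map(
    anchors = c(`2` = 90, `3` = 142, `5` = 223, `6` = 271, `7` = 315, `8` = 325),
    helix_ranges = list(
      `2` = c(78L, 107L), `3` = c(112L, 148L), `5` = c(203L, 241L),
      `6` = c(245L, 285L), `7` = c(289L, 321L), `8` = c(322L, 335L)
    )
  )
}
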