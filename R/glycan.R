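#' @useDynLib iggfc, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Residue masses of the four monosaccharide building blocks used in HxNyFzSw
# composition strings: hexose (H), N-acetylhexosamine (N), deoxyhexose/fucose
# (F) and N-acetylneuraminic acid (S).
RESIDUE_AVG  <- c(H = 162.1406, N = 203.1925, F = 146.1412, S = 291.2546)
RESIDUE_MONO <- c(H = 162.05282, N = 203.07937, F = 146.05791, S = 291.09542)

# Average mass of a proton; charge carrier for positive-mode ESI.
PROTON_MASS <- 1.00728

#' Parse a glycan composition string
#'
#' Compositions are written in the HxNyFzSw convention, e.g. `"H3N4F1"` for
#' the agalactosylated core-fucosylated biantennary glycan (G0F). Letters may
#' appear in any order; omitted letters count zero. The empty string denotes
#' the empty composition.
#'
#' @param x character vector of composition strings.
#' @return an integer matrix with one row per input and columns H, N, F, S.
#' @examples
#' glycan_composition(c("H3N4F1", "H5N2"))
#' @export
glycan_composition <- function(x) {
  x <- as.character(x)
  out <- matrix(0L, nrow = length(x), ncol = 4,
                dimnames = list(x, c("H", "N", "F", "S")))
  for (i in seq_along(x)) {
    s <- x[i]
    if (is.na(s) || s == "" || s == "none") next
    m <- gregexpr("([HNFS])(\\d+)", s, perl = TRUE)[[1]]
    toks <- regmatches(s, gregexpr("([HNFS])(\\d+)", s, perl = TRUE))[[1]]
    if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(s))
      stop("invalid glycan composition string: '", s, "'")
    letters <- substr(toks, 1, 1)
    counts <- as.integer(substring(toks, 2))
    if (anyDuplicated(letters))
      stop("duplicated residue letter in composition: '", s, "'")
    out[i, letters] <- counts
  }
  out
}

#' Format glycan counts as a composition string
#'
#' Inverse of [glycan_composition()]: zero counts are omitted and residues are
#' printed in canonical H, N, F, S order, so strings round-trip.
#'
#' @param counts integer matrix (columns H, N, F, S) or a single named vector.
#' @return character vector of composition strings.
#' @export
format_glycan <- function(counts) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1,
                                             dimnames = list(NULL, names(counts)))
  counts <- counts[, c("H", "N", "F", "S"), drop = FALSE]
  apply(counts, 1, function(r) {
    keep <- r > 0
    paste0(c("H", "N", "F", "S")[keep], r[keep], collapse = "")
  })
}

#' Glycan residue mass
#'
#' Additive mass of a glycan composition from standard residue masses.
#' Average masses are the working currency throughout the package because
#' isotopes are unresolved for ~25 kDa subunits at the resolutions modelled;
#' monoisotopic masses are available for bookkeeping.
#'
#' @param g composition string(s) or a counts matrix from [glycan_composition()].
#' @param monoisotopic use monoisotopic residue masses instead of average.
#' @return numeric vector of masses in Da.
#' @examples
#' glycan_mass("H3N4F1")                      # G0F, average
#' glycan_mass("H3N4F1", monoisotopic = TRUE)
#' @export
glycan_mass <- function(g, monoisotopic = FALSE) {
  if (is.character(g)) g <- glycan_composition(g)
  if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
  if (any(g < 0)) stop("negative residue counts are not a valid composition")
  res <- if (monoisotopic) RESIDUE_MONO else RESIDUE_AVG
  as.numeric(g[, c("H", "N", "F", "S"), drop = FALSE] %*% res)
}

#' Classify a glycan composition
#'
#' Assigns each composition to exactly one structural type and derives the
#' features used by the trait calculations:
#' * `high_mannose` — N = 2 and H >= 4 (Man4+ on the chitobiose core);
#' * `stub` — N <= 1, the chitobiose remnant left by EndoS2 treatment;
#' * `complex` — everything else, interpreted on the biantennary IgG Fc
#'   convention: the Man3GlcNAc2 core accounts for H3, so the galactose count
#'   is `min(2, max(0, H - 3))`; a fifth HexNAc marks a bisecting GlcNAc;
#'   any deoxyhexose is read as core fucose; sialic acids cap at 2.
#'
#' @param g composition string(s) or counts matrix.
#' @return data.frame with columns `composition`, `type`, `n_gal`,
#'   `bisecting`, `fucosylated`, `n_sia`.
#' @examples
#' classify_glycan(c("H3N4F1", "H5N2", "H5N5F1S1"))
#' @export
classify_glycan <- function(g) {
  if (is.character(g)) {
    comp <- g
    g <- glycan_composition(g)
  } else {
    if (is.null(dim(g))) g <- matrix(g, nrow = 1, dimnames = list(NULL, names(g)))
    comp <- format_glycan(g)
  }
  H <- g[, "H"]; N <- g[, "N"]; Fu <- g[, "F"]; S <- g[, "S"]
  type <- ifelse(N <= 1, "stub", ifelse(N == 2 & H >= 4, "high_mannose", "complex"))
  data.frame(
    composition = comp,
    type = type,
    n_gal = ifelse(type == "complex", pmin(2L, pmax(0L, H - 3L)), 0L),
    bisecting = type == "complex" & N >= 5,
    fucosylated = Fu >= 1,
    n_sia = ifelse(type == "complex", pmin(2L, S), 0L),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
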