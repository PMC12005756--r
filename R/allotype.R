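# Average residue masses of the 20 amino acids (Da), used when a backbone
# sequence rather than a backbone mass is supplied.
AA_AVG <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_AVG <- 18.01528
# Mass removed per closed disulfide bridge (two hydrogens).
DISULFIDE_DELTA <- 2.016

# Fixed post-translational modification deltas (average Da). The
# openSS_truncation delta is sequence-dependent and stored per allotype in
# the reference table.
PTM_DELTAS <- c(
  none = 0,
  plusK = 128.17,             # incomplete C-terminal lysine clipping
  minusGK = -185.22,          # C-terminal GK truncation
  cysteinylation = 119.14,    # free cysteine capped by cysteine
  open_disulfide = 2.016      # open CH2 disulfide (+2 H)
)

#' Fixed PTM mass deltas
#'
#' Average-mass deltas of the Fc/2 PTM variants handled by the package.
#' The DP-hydrolysis truncation that reveals open CH2 disulfides
#' (`openSS_truncation`) is sequence dependent and therefore stored per
#' allotype in the reference table, not here.
#'
#' @return named numeric vector of mass deltas in Da.
#' @export
ptm_deltas <- function() PTM_DELTAS

#' Load an allotype reference table
#'
#' Reads a TSV with columns `name`, `subclass`, `backbone_mass_avg`,
#' `n_glyc_sites`, `openSS_truncation_delta` and `rt_ref` (the canonical
#' elution apex of the allotype on the reference gradient, seconds). The
#' package ships a synthetic reference table covering the common IGHG1-4
#' allotype heterozygosities; its backbone masses were constructed so that
#' glycoform ladders of distinct allotypes do not collide within the mass
#' matching tolerances (they are not database masses).
#'
#' @param file path to a TSV; `NULL` loads the shipped synthetic table.
#' @return data.frame of class `allotype_reference`.
#' @export
allotype_reference <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "allotype_reference_synthetic.tsv",
                        package = "iggfc", mustWork = TRUE)
  ref <- utils::read.delim(file, stringsAsFactors = FALSE)
  needed <- c("name", "subclass", "backbone_mass_avg", "n_glyc_sites",
              "openSS_truncation_delta", "rt_ref")
  missing <- setdiff(needed, names(ref))
  if (length(missing))
    stop("allotype reference lacks columns: ", paste(missing, collapse = ", "))
  if (any(ref$backbone_mass_avg <= 0)) stop("backbone masses must be positive")
  if (!all(ref$n_glyc_sites %in% 1:2)) stop("n_glyc_sites must be 1 or 2")
  pre <- sub("IGHG(\\d).*", "IgG\\1", ref$name)
  if (!all(pre == ref$subclass))
    stop("subclass inconsistent with allotype name prefix")
  if (any(ref$n_glyc_sites == 2 & ref$subclass != "IgG3"))
    stop("a second (CH3) glycosylation site is only modelled for IgG3 allotypes")
  class(ref) <- c("allotype_reference", "data.frame")
  ref
}

#' Backbone mass from an amino-acid sequence
#'
#' Average mass of an unglycosylated Fc/2 chain computed from standard
#' amino-acid residue masses plus one water, with `n_disulfides` closed
#' intrachain bridges (each removes two hydrogens).
#'
#' @param sequence one-letter amino-acid string.
#' @param n_disulfides number of closed intrachain disulfide bridges
#'   (default 2: one CH2 and one CH3 bridge).
#' @return mass in Da.
#' @export
backbone_mass_from_sequence <- function(sequence, n_disulfides = 2) {
  aa <- strsplit(toupper(gsub("\\s", "", sequence)), "")[[1]]
  bad <- setdiff(aa, names(AA_AVG))
  if (length(bad)) stop("unknown amino acids: ", paste(unique(bad), collapse = ""))
  sum(AA_AVG[aa]) + WATER_AVG - n_disulfides * DISULFIDE_DELTA
}

#' Average mass of a proteoform species
#'
#' Additive bookkeeping: backbone mass plus glycan residue masses of the CH2
#' (and, for doubly glycosylated IgG3, CH3) glycan plus the PTM delta.
#' All arguments are vectorised and recycled.
#'
#' @param backbone_mass_avg backbone average mass(es), Da.
#' @param ch2 CH2 glycan composition string(s); `NA`/`""`/`"none"` for a
#'   non-glycosylated chain.
#' @param ch3 CH3 glycan composition string(s), or `NA` when the site is
#'   unoccupied/absent.
#' @param ptm_delta PTM mass delta(s) in Da (see [ptm_deltas()]).
#' @return numeric vector of species masses in Da.
#' @examples
#' species_mass(24108.0, "H3N4F1")
#' @export
species_mass <- function(backbone_mass_avg, ch2 = NA, ch3 = NA, ptm_delta = 0) {
  n <- max(length(backbone_mass_avg), length(ch2), length(ch3), length(ptm_delta))
  backbone_mass_avg <- rep_len(backbone_mass_avg, n)
  ch2 <- rep_len(as.character(ch2), n)
  ch3 <- rep_len(as.character(ch3), n)
  ptm_delta <- rep_len(ptm_delta, n)
  gmass <- function(x) {
    m <- numeric(length(x))
    has <- !is.na(x) & x != "" & x != "none"
    if (any(has)) m[has] <- glycan_mass(x[has])
    m
  }
  backbone_mass_avg + gmass(ch2) + gmass(ch3) + ptm_delta
}
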