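# The glycoform ladder used as identification evidence: G0F, G1F, G2F.
CALLING_GLYCANS <- c("H3N4F1", "H4N4F1", "H5N4F1")

#' Call allotypes from a deconvolved spectrum
#'
#' An allotype is called when at least `min_evidence` of its expected
#' glycoform masses (backbone + G0F/G1F/G2F) match picked peaks within `tol`;
#' requiring a ladder of glycoforms rather than a single mass prevents
#' single-peak false calls. At most the two best-supported allotypes (by
#' summed matched intensity) are retained per subclass. Pairs of called
#' allotypes whose expected masses coincide within `tol` are both reported
#' and flagged ambiguous.
#'
#' @param deconv a `deconvolved_spectrum` (see [deconvolve()]).
#' @param reference allotype reference table.
#' @param tol mass matching tolerance, Da (default 2.0).
#' @param min_evidence minimum number of matched ladder masses (default 2).
#' @param max_per_subclass maximum allotypes kept per subclass (default 2).
#' @return list of class `allotype_call` with `allotypes` (data.frame `name`,
#'   `subclass`, `evidence_n`, `support`, `ambiguous`) and `evidence` (per
#'   allotype, the matched glycoform masses).
#' @export
call_allotypes <- function(deconv, reference = allotype_reference(), tol = 2.0,
                           min_evidence = 2, max_per_subclass = 2) {
  pk <- deconv$peaks
  res <- list(); evidence <- list()
  for (i in seq_len(nrow(reference))) {
    expected <- reference$backbone_mass_avg[i] + glycan_mass(CALLING_GLYCANS)
    if (nrow(pk) == 0) next
    dd <- abs(outer(expected, pk$mass, "-"))
    hit <- apply(dd, 1, function(d) {
      j <- which.min(d)
      if (d[j] <= tol) j else NA_integer_
    })
    n_hit <- sum(!is.na(hit))
    if (n_hit >= min_evidence) {
      ev <- data.frame(glycan = CALLING_GLYCANS[!is.na(hit)],
                       expected = expected[!is.na(hit)],
                       observed = pk$mass[hit[!is.na(hit)]],
                       intensity = pk$intensity[hit[!is.na(hit)]])
      ev$delta <- ev$observed - ev$expected
      evidence[[reference$name[i]]] <- ev
      res[[length(res) + 1]] <- data.frame(
        name = reference$name[i], subclass = reference$subclass[i],
        evidence_n = n_hit, support = sum(ev$intensity),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) {
    return(structure(list(allotypes = data.frame(
      name = character(0), subclass = character(0), evidence_n = integer(0),
      support = numeric(0), ambiguous = logical(0)), evidence = list()),
      class = "allotype_call"))
  }
  tab <- do.call(rbind, res)
  keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$subclass), function(ix) {
    ix[order(-tab$support[ix])][seq_len(min(max_per_subclass, length(ix)))]
  }))
  tab <- tab[sort(keep), , drop = FALSE]
  bm <- reference$backbone_mass_avg[match(tab$name, reference$name)]
  tab$ambiguous <- vapply(seq_len(nrow(tab)), function(r)
    any(abs(bm[-r] - bm[r]) <= tol), logical(1))
  rownames(tab) <- NULL
  structure(list(allotypes = tab, evidence = evidence[tab$name]),
            class = "allotype_call")
}

#' Call allotypes from a run, one retention-time segment per candidate
#'
#' Deconvolves the run around each reference allotype's expected elution apex
#' and applies [call_allotypes()] with only that allotype as candidate;
#' restricting mass matching to co-eluting signal avoids evidence from
#' species of other allotypes. Uses the charge-consensus (`median`) combine by
#' default to suppress charge-misassignment images.
#'
#' @param run a `spectrum_run` (preprocessing not required; deconvolution
#'   operates on summed raw scans).
#' @param reference allotype reference table.
#' @param tol mass tolerance, Da.
#' @param seg_halfwidth retention-time half-width of each segment, s.
#' @param charges charge states assumed.
#' @param charge_weights relative envelope weights (see [deconvolve()]).
#' @param combine charge combination rule for [deconvolve()].
#' @return an `allotype_call`.
#' @export
call_allotypes_run <- function(run, reference = allotype_reference(), tol = 2.0,
                               seg_halfwidth = 15, charges = 18:22,
                               charge_weights = c(1, 2, 3, 2, 1),
                               combine = "median") {
  res <- list(); evidence <- list()
  for (i in seq_len(nrow(reference))) {
    b <- reference$backbone_mass_avg[i]
    dec <- deconvolve(run, rt_range = reference$rt_ref[i] + c(-1, 1) * seg_halfwidth,
                      charges = charges, mass_range = b + c(-200, 2300),
                      combine = combine, charge_weights = charge_weights)
    call_i <- call_allotypes(dec, reference[i, , drop = FALSE], tol = tol)
    if (nrow(call_i$allotypes)) {
      res[[length(res) + 1]] <- call_i$allotypes
      evidence <- c(evidence, call_i$evidence)
    }
  }
  if (!length(res))
    return(structure(list(allotypes = data.frame(
      name = character(0), subclass = character(0), evidence_n = integer(0),
      support = numeric(0), ambiguous = logical(0)), evidence = list()),
      class = "allotype_call"))
  tab <- do.call(rbind, res)
  keep <- unlist(lapply(split(seq_len(nrow(tab)), tab$subclass), function(ix) {
    ix[order(-tab$support[ix])][seq_len(min(2, length(ix)))]
  }))
  tab <- tab[sort(keep), , drop = FALSE]
  bm <- reference$backbone_mass_avg[match(tab$name, reference$name)]
  tab$ambiguous <- vapply(seq_len(nrow(tab)), function(r)
    any(abs(bm[-r] - bm[r]) <= tol), logical(1))
  rownames(tab) <- NULL
  structure(list(allotypes = tab, evidence = evidence[tab$name]),
            class = "allotype_call")
}

#' Annotate a doubly glycosylated mass by combinatorial search
#'
#' Exhaustively enumerates CH2 x CH3 composition pairs and keeps every pair
#' whose combined mass matches the observed mass within `tol`, ranked by
#' absolute mass error. Isobaric pairs (e.g. the site-swapped assignment of
#' the same two compositions) are all reported, never collapsed.
#'
#' @param observed_mass deconvolved mass, Da.
#' @param backbone_mass allotype backbone mass, Da.
#' @param ch2_candidates,ch3_candidates character vectors of composition
#'   strings.
#' @param tol tolerance, Da (default 1.5).
#' @return list of class `annotation_result`: `observed_mass`, `tolerance`,
#'   `candidates` (data.frame `ch2`, `ch3`, `mass`, `delta`, ranked by
#'   `|delta|`) and `nearest_miss` (closest enumerated pair when no candidate
#'   matches).
#' @export
annotate_double_glyc <- function(observed_mass, backbone_mass,
                                 ch2_candidates = CH2_GLYCANS,
                                 ch3_candidates = CH3_GLYCANS, tol = 1.5) {
  grid <- expand.grid(ch2 = ch2_candidates, ch3 = ch3_candidates,
                      stringsAsFactors = FALSE)
  grid$mass <- species_mass(backbone_mass, grid$ch2, grid$ch3)
  grid$delta <- observed_mass - grid$mass
  hit <- abs(grid$delta) <= tol
  cand <- grid[hit, , drop = FALSE]
  cand <- cand[order(abs(cand$delta)), , drop = FALSE]
  rownames(cand) <- NULL
  nearest <- if (!any(hit)) grid[which.min(abs(grid$delta)), ] else NULL
  structure(list(observed_mass = observed_mass, tolerance = tol,
                 candidates = cand, nearest_miss = nearest),
            class = "annotation_result")
}

#' Annotate all doubly glycosylated peaks of an IgG3 allotype
#'
#' Runs [annotate_double_glyc()] on every picked peak of a deconvolved
#' doubly glycosylated mass region and returns a tidy table (one row per
#' candidate assignment, with ranks and an ambiguity flag when several
#' candidates match one peak).
#'
#' @param peaks data.frame with a `mass` column (picked peaks).
#' @param backbone_mass allotype backbone mass, Da.
#' @param ch2_candidates,ch3_candidates composition sets.
#' @param tol tolerance, Da.
#' @return data.frame `observed_mass`, `rank`, `ch2`, `ch3`, `delta_mass`,
#'   `ambiguity_flag`.
#' @export
annotate_double_peaks <- function(peaks, backbone_mass,
                                  ch2_candidates = CH2_GLYCANS,
                                  ch3_candidates = CH3_GLYCANS, tol = 1.5) {
  rows <- list()
  for (m in peaks$mass) {
    ann <- annotate_double_glyc(m, backbone_mass, ch2_candidates,
                                ch3_candidates, tol)
    if (nrow(ann$candidates))
      rows[[length(rows) + 1]] <- data.frame(
        observed_mass = m, rank = seq_len(nrow(ann$candidates)),
        ch2 = ann$candidates$ch2, ch3 = ann$candidates$ch3,
        delta_mass = ann$candidates$delta,
        ambiguity_flag = nrow(ann$candidates) > 1)
  }
  if (!length(rows))
    return(data.frame(observed_mass = numeric(0), rank = integer(0),
                      ch2 = character(0), ch3 = character(0),
                      delta_mass = numeric(0), ambiguity_flag = logical(0)))
  do.call(rbind, rows)
}
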