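#' Choose the charge states used for EIC quantification
#'
#' Selects the three consecutive charge states with maximal summed expected
#' envelope intensity whose m/z positions fall inside the acquisition window.
#' The choice is made once per allotype (from a representative species mass)
#' and reused for all its glycoforms so profiles are internally consistent.
#'
#' @param mass representative species mass, Da.
#' @param charges candidate charge states.
#' @param charge_weights relative envelope weights of `charges`.
#' @param mz_window acquisition m/z window.
#' @param n number of consecutive charges to select (default 3).
#' @return integer vector of selected charges.
#' @export
select_charges <- function(mass, charges = 18:22,
                           charge_weights = c(1, 2, 3, 2, 1),
                           mz_window = c(1000, 1600), n = 3) {
  mz <- (mass + charges * PROTON_MASS) / charges
  w <- charge_weights * (mz >= mz_window[1] & mz <= mz_window[2])
  if (length(charges) < n) stop("fewer candidate charges than requested")
  best <- which.max(vapply(seq_len(length(charges) - n + 1),
                           function(i) sum(w[i:(i + n - 1)]), numeric(1)))
  sel <- charges[best:(best + n - 1)]
  if (all(w[best:(best + n - 1)] == 0))
    stop("no charge state places the species inside the m/z window")
  sel
}

#' EIC window definition for one species
#'
#' Computes the m/z extraction windows of a species for the given charge
#' states: window half-width is `w` times the expected peak FWHM,
#' FWHM = m/z / resolution (base-peak of the unresolved isotope envelope).
#'
#' @param mass species average mass, Da.
#' @param charges charge states (typically 3 consecutive).
#' @param resolution FWHM-based resolution (default 15000).
#' @param w window half-width in FWHM units (default 2).
#' @return data.frame with columns `charge`, `mz`, `lo`, `hi`.
#' @export
eic_definition <- function(mass, charges, resolution = 15000, w = 2) {
  mz <- (mass + charges * PROTON_MASS) / charges
  fwhm <- mz / resolution
  data.frame(charge = charges, mz = mz, lo = mz - w * fwhm, hi = mz + w * fwhm)
}

#' Extract an ion chromatogram
#'
#' Per scan, sums the intensity inside the m/z windows of an
#' [eic_definition()].
#'
#' @param run a `spectrum_run`.
#' @param definition data.frame from [eic_definition()].
#' @return data.frame with columns `rt` and `intensity`.
#' @export
build_eic <- function(run, definition) {
  inside <- definition$hi >= min(run$mz) & definition$lo <= max(run$mz)
  if (!any(inside)) stop("all EIC windows fall outside the acquired m/z range")
  total <- numeric(length(run$rt))
  for (r in which(inside)) {
    i1 <- findInterval(definition$lo[r], run$mz) + 1L
    i2 <- findInterval(definition$hi[r], run$mz)
    if (i2 >= i1)
      total <- total + colSums(run$intensity[i1:i2, , drop = FALSE])
  }
  data.frame(rt = run$rt, intensity = total)
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal area of the EIC above zero within a retention-time window.
#' With `baseline = "flank"`, the median EIC level in flanking regions on both
#' sides of the window is subtracted first (then clipped at zero), which
#' removes the constant background that survives spectrum-level baseline
#' subtraction in noisy data.
#'
#' @param eic data.frame from [build_eic()].
#' @param rt_window `c(lo, hi)`, seconds.
#' @param baseline `"none"` or `"flank"`.
#' @param flank_gap,flank_width flank placement relative to the window edges,
#'   seconds.
#' @return peak area (intensity x seconds).
#' @export
integrate_peak <- function(eic, rt_window, baseline = c("none", "flank"),
                           flank_gap = 15, flank_width = 30) {
  baseline <- match.arg(baseline)
  j <- which(eic$rt >= rt_window[1] & eic$rt <= rt_window[2])
  if (length(j) < 2) {
    warning("empty retention-time window; area set to 0")
    return(0)
  }
  y <- eic$intensity[j]
  if (baseline == "flank") {
    fl <- which((eic$rt >= rt_window[1] - flank_gap - flank_width &
                   eic$rt <= rt_window[1] - flank_gap) |
                  (eic$rt >= rt_window[2] + flank_gap &
                     eic$rt <= rt_window[2] + flank_gap + flank_width))
    if (length(fl) >= 3) y <- pmax(0, y - stats::median(eic$intensity[fl]))
  }
  t <- eic$rt[j]
  sum((y[-1] + y[-length(y)]) / 2 * diff(t))
}

#' Relative glycoform profile of one allotype
#'
#' Normalises integrated areas of one allotype's CH2 glycoform species (the
#' non-glycosylated backbone included, PTM-modified species excluded) to
#' percentages.
#'
#' @param areas named numeric vector of peak areas.
#' @return named numeric vector of percentages summing to 100, or all-`NA`
#'   when the total area is zero (profile undefined).
#' @export
glycoform_profile <- function(areas) {
  tot <- sum(areas)
  if (!is.finite(tot) || tot <= 0)
    return(stats::setNames(rep(NA_real_, length(areas)), names(areas)))
  100 * areas / tot
}

#' Allotype-abundance-weighted subclass glycoform profile
#'
#' Weighted mean of (one or two) allotype glycoform profiles using relative
#' allotype abundances as weights; reduces to the single profile for
#' homozygous subclasses.
#'
#' @param profiles list of named percentage vectors (one per allotype).
#' @param abundances numeric vector of allotype abundances (same order).
#' @return named percentage vector.
#' @export
subclass_average <- function(profiles, abundances) {
  stopifnot(length(profiles) == length(abundances), length(profiles) >= 1)
  w <- abundances / sum(abundances)
  nm <- names(profiles[[1]])
  out <- stats::setNames(numeric(length(nm)), nm)
  for (i in seq_along(profiles)) out <- out + w[i] * profiles[[i]][nm]
  out
}

#' Allotype ratio within a subclass
#'
#' Fraction of the first allotype among the summed intensities of both
#' allotypes of a subclass (all glycoforms considered).
#'
#' @param a1_area,a2_area summed areas of the two allotypes.
#' @return `a1 / (a1 + a2)`, in `[0, 1]`.
#' @export
allotype_ratio <- function(a1_area, a2_area) {
  tot <- a1_area + a2_area
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  a1_area / tot
}

#' CH3-domain glycosylation site occupancy
#'
#' The doubly glycosylated anchor glycoform (CH2 = H3N4F1, CH3 = H5N2) is
#' quantified by EIC; dividing its area by its relative abundance among all
#' doubly glycosylated glycoforms (from the deconvolved spectrum) gives the
#' total doubly glycosylated area, which is compared with the combined area of
#' the singly glycosylated species.
#'
#' @param area_double_anchor EIC area of the anchor doubly glycosylated
#'   glycoform.
#' @param rel_abund_anchor relative abundance of the anchor among all doubly
#'   glycosylated glycoforms, in `(0, 1]`.
#' @param area_single_total combined area of singly (CH2-only) glycosylated
#'   species.
#' @return occupancy fraction in `[0, 1]`, `NA` if `rel_abund_anchor` is 0 or
#'   missing.
#' @export
ch3_occupancy <- function(area_double_anchor, rel_abund_anchor,
                          area_single_total) {
  if (!is.finite(rel_abund_anchor) || rel_abund_anchor <= 0) return(NA_real_)
  total_double <- area_double_anchor / rel_abund_anchor
  total_double / (total_double + area_single_total)
}

#' Fc/2 occupancy to intact-IgG3 occupancy
#'
#' Under independent pairing of the two heavy chains, the fraction of intact
#' IgG3 molecules carrying at least one CH3 glycan is `1 - (1 - p)^2` for a
#' per-chain occupancy `p`.
#'
#' @param p Fc/2 (per-chain) occupancy fraction in `[0, 1]`.
#' @return intact-molecule occupancy fraction.
#' @examples
#' intact_occupancy(c(0.137, 0.241))  # 0.2552, 0.4239
#' @export
intact_occupancy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("occupancy must lie in [0, 1]")
  1 - (1 - p)^2
}

#' PTM level relative to the unmodified anchor glycoform
#'
#' PTM variants are quantified against the non-modified H3N4F1 glycoform of
#' the same allotype. The default bounded form reports
#' `100 * modified / (modified + unmodified)` so values are percentages in
#' `[0, 100]`; `bounded = FALSE` reports the plain ratio
#' `100 * modified / unmodified`.
#'
#' @param area_modified,area_unmodified peak areas.
#' @param bounded use the bounded percentage (default).
#' @return percentage, `NA` when the unmodified anchor is absent.
#' @export
ptm_level <- function(area_modified, area_unmodified, bounded = TRUE) {
  if (!is.finite(area_unmodified) || area_unmodified <= 0) return(NA_real_)
  area_modified <- max(0, area_modified)
  if (bounded) 100 * area_modified / (area_modified + area_unmodified)
  else 100 * area_modified / area_unmodified
}

# default candidate sets
CH2_GLYCANS <- c("H3N4F1", "H4N4F1", "H5N4F1", "H3N4", "H3N5F1", "H5N2",
                 "H4N4F1S1", "H5N4F1S1")
CH3_GLYCANS <- c("H5N2", "H6N2", "H3N4", "H4N4", "H3N4F1")
PTM_KINDS <- c("plusK", "minusGK", "open_disulfide", "cysteinylation")

# Relative abundance of the anchor glycoform among all doubly glycosylated
# glycoforms, from a deconvolved spectrum of the doubly glycosylated mass
# region. Integrates the (baseline-subtracted) deconvolved intensity over the
# union of windows around the expected CH2 x CH3 combination masses rather
# than over picked peaks, so that combinations too small to pass the picking
# threshold still contribute to the denominator.
double_anchor_share <- function(dec, anchor_mass, combo_masses, window = 2) {
  base <- stats::median(dec$intensity)
  in_any <- rep(FALSE, length(dec$mass))
  for (m in unique(round(combo_masses, 3)))
    in_any <- in_any | abs(dec$mass - m) <= window
  anchor <- abs(dec$mass - anchor_mass) <= window
  tot <- sum(dec$intensity[in_any] - base)
  num <- sum(dec$intensity[anchor] - base)
  if (!is.finite(tot) || tot <= 0 || num <= 0) return(NA_real_)
  min(1, num / tot)
}

#' Quantify one run
#'
#' EIC-based relative quantification of all targets of the called allotypes:
#' CH2 glycoforms, the non-glycosylated backbone, PTM variants of the H3N4F1
#' anchor, and (for two-site IgG3 allotypes) the doubly glycosylated anchor
#' glycoform plus deconvolution of the doubly glycosylated mass region for the
#' CH3 site occupancy. Open-disulfide species are integrated in a
#' retention-time window offset from the parent because the +2 Da shift is not
#' resolvable in m/z.
#'
#' @param run a preprocessed, aligned `spectrum_run`.
#' @param allotypes character vector of called allotype names.
#' @param deconv_run optional `spectrum_run` used for the occupancy
#'   deconvolution (typically the raw, aligned run: deconvolution operates on
#'   summed unsmoothed scans, separately from the smoothed EIC path); defaults
#'   to `run`.
#' @param reference allotype reference table.
#' @param charges,charge_weights candidate charge envelope.
#' @param resolution TOF resolution used for EIC windows.
#' @param w EIC window half-width, in FWHM units.
#' @param rt_halfwidth integration half-width around the allotype apex, s.
#' @param od_offset retention-time offset of open-disulfide species, s.
#' @param ch2_glycans,ch3_glycans candidate composition sets.
#' @param baseline EIC baseline handling (see [integrate_peak()]).
#' @param deconv_combine charge combination used for the occupancy
#'   deconvolution (default `"median"`, see [deconvolve()]).
#' @return list of class `quant_result`: `targets` (tidy area table),
#'   `profiles`, `subclass_profiles`, `allotype_abundance`, `subclass_abundance`,
#'   `allotype_ratios`, `occupancy`, `ptm` and `run_id`.
#' @export
quantify_run <- function(run, allotypes, reference = allotype_reference(),
                         deconv_run = NULL,
                         charges = 18:22, charge_weights = c(1, 2, 3, 2, 1),
                         resolution = 15000, w = 2, rt_halfwidth = 9,
                         od_offset = 15, ch2_glycans = CH2_GLYCANS,
                         ch3_glycans = CH3_GLYCANS,
                         baseline = "flank", deconv_combine = "median") {
  if (is.null(deconv_run)) deconv_run <- run
  mz_window <- range(run$mz)
  targets <- list(); profiles <- list(); areas_total <- numeric(0)
  occupancy <- numeric(0); ptm_tab <- list()
  for (a in allotypes) {
    i <- match(a, reference$name)
    if (is.na(i)) stop("allotype not in reference: ", a)
    b <- reference$backbone_mass_avg[i]
    rt0 <- reference$rt_ref[i]
    two_site <- reference$n_glyc_sites[i] == 2
    zsel <- select_charges(b + glycan_mass("H3N4F1"), charges, charge_weights,
                          mz_window)
    tg <- data.frame(
      label = c(ch2_glycans, "none", PTM_KINDS,
                if (two_site) "double_anchor"),
      kind = c(rep("single", length(ch2_glycans)), "none",
               rep("ptm", length(PTM_KINDS)), if (two_site) "double"),
      mass = c(species_mass(b, ch2_glycans), b,
               species_mass(b, "H3N4F1", ptm_delta = PTM_DELTAS[PTM_KINDS]),
               if (two_site) species_mass(b, "H3N4F1", "H5N2")),
      stringsAsFactors = FALSE)
    tg$rt_lo <- rt0 - rt_halfwidth
    tg$rt_hi <- rt0 + rt_halfwidth
    od <- tg$label == "open_disulfide"
    tg$rt_lo[od] <- rt0 + rt_halfwidth
    tg$rt_hi[od] <- rt0 + od_offset + 4 * rt_halfwidth / 3
    tg$area <- NA_real_
    for (s in seq_len(nrow(tg))) {
      def <- eic_definition(tg$mass[s], zsel, resolution, w)
      eic <- build_eic(run, def)
      tg$area[s] <- integrate_peak(eic, c(tg$rt_lo[s], tg$rt_hi[s]),
                                   baseline = baseline)
    }
    tg$allotype <- a
    tg$subclass <- reference$subclass[i]
    tg$charges <- paste(zsel, collapse = ";")
    targets[[a]] <- tg

    gl <- tg$kind %in% c("single", "none")
    profiles[[a]] <- glycoform_profile(stats::setNames(tg$area[gl], tg$label[gl]))

    single_total <- sum(tg$area[tg$kind == "single"])
    total_double <- 0
    if (two_site) {
      dec <- deconvolve(deconv_run,
                        rt_range = c(rt0 - rt_halfwidth, rt0 + rt_halfwidth),
                        charges = charges,
                        mass_range = b + c(2300, 3600), combine = deconv_combine,
                        charge_weights = charge_weights)
      anchor_mass <- species_mass(b, "H3N4F1", "H5N2")
      rel <- double_anchor_share(dec, anchor_mass,
                                 species_mass(b, rep(ch2_glycans,
                                                     times = length(ch3_glycans)),
                                              rep(ch3_glycans,
                                                  each = length(ch2_glycans))))
      anchor_area <- tg$area[tg$label == "double_anchor"]
      occupancy[a] <- ch3_occupancy(anchor_area, rel, single_total)
      if (is.finite(occupancy[a]) && occupancy[a] < 1)
        total_double <- single_total * occupancy[a] / (1 - occupancy[a])
    }
    areas_total[a] <- sum(tg$area[tg$kind != "double"]) + total_double

    unmod <- tg$area[tg$label == "H3N4F1"]
    ptm_tab[[a]] <- vapply(PTM_KINDS, function(k)
      ptm_level(tg$area[tg$label == k], unmod), numeric(1))
  }
  targets <- do.call(rbind, targets)
  rownames(targets) <- NULL

  ref_sub <- reference$subclass[match(allotypes, reference$name)]
  allot_ab <- 100 * areas_total / sum(areas_total)
  subclass_profiles <- list(); ratios <- numeric(0); subclass_ab <- numeric(0)
  for (sc in unique(ref_sub)) {
    al <- allotypes[ref_sub == sc]
    subclass_ab[sc] <- sum(allot_ab[al])
    subclass_profiles[[sc]] <- subclass_average(profiles[al], areas_total[al])
    if (length(al) == 2)
      ratios[sc] <- allotype_ratio(areas_total[al[1]], areas_total[al[2]])
  }
  structure(list(run_id = run$metadata$run_id, targets = targets,
                 profiles = profiles, subclass_profiles = subclass_profiles,
                 allotype_abundance = allot_ab, subclass_abundance = subclass_ab,
                 allotype_ratios = ratios, occupancy = occupancy,
                 ptm = ptm_tab),
            class = "quant_result")
}

#' Export a Skyline-style transition list
#'
#' Writes the EIC extraction scheme of a quantified run (species, charges,
#' m/z borders, retention-time window) as a tidy TSV for interoperability.
#'
#' @param quant a `quant_result`.
#' @param reference allotype reference table.
#' @param path output TSV path.
#' @param resolution,w EIC window parameters (must match the quantification).
#' @return the transition table, invisibly.
#' @export
export_transition_list <- function(quant, reference = allotype_reference(),
                                   path = NULL, resolution = 15000, w = 2) {
  rows <- list()
  for (s in seq_len(nrow(quant$targets))) {
    tgt <- quant$targets[s, ]
    ch <- as.integer(strsplit(tgt$charges, ";")[[1]])
    def <- eic_definition(tgt$mass, ch, resolution, w)
    rows[[s]] <- data.frame(allotype = tgt$allotype, species = tgt$label,
                            charge = def$charge, mz = def$mz, mz_lo = def$lo,
                            mz_hi = def$hi, rt_lo = tgt$rt_lo, rt_hi = tgt$rt_hi)
  }
  out <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out)
}
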