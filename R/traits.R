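TRAIT_NAMES <- c("galactosylation", "agalactosylation", "sialylation",
                 "afucosylation", "bisection", "high_mannose",
                 "non_glycosylated")

#' Derived glycosylation traits of a glycoform profile
#'
#' Summarises a relative glycoform profile (percentages per composition, with
#' an optional `none` entry for the non-glycosylated species) into derived
#' traits. Doubly galactosylated (or sialylated) glycans are weighted twice
#' relative to singly modified ones, i.e. galactosylation is
#' `sum(a_i * n_gal_i) / 2` and sialylation `sum(a_i * n_sia_i) / 2` over
#' complex-type forms. Traits defined on the complex-type repertoire
#' (galactosylation, agalactosylation, sialylation, afucosylation, bisection)
#' are expressed relative to the complex-type fraction; `high_mannose` and
#' `non_glycosylated` are expressed relative to the full species total, which
#' matches the separated reporting of complex-type traits and high-mannose
#' levels in this field.
#'
#' @param profile named numeric vector of relative abundances (any positive
#'   scale; normalised internally). Names are composition strings plus
#'   optionally `none`.
#' @param subtraits also emit mono-/di-galactosylation and mono-/di-sialylation.
#' @return named numeric vector of trait percentages (all in `[0, 100]`), or
#'   all-`NA` for an empty/undefined profile.
#' @export
derive_traits <- function(profile, subtraits = FALSE) {
  nm <- c(TRAIT_NAMES, if (subtraits) c("mono_galactosylation",
                                        "di_galactosylation",
                                        "mono_sialylation", "di_sialylation"))
  empty <- stats::setNames(rep(NA_real_, length(nm)), nm)
  if (!length(profile) || all(is.na(profile)) || sum(profile, na.rm = TRUE) <= 0)
    return(empty)
  a <- 100 * profile / sum(profile, na.rm = TRUE)
  a[is.na(a)] <- 0
  none <- if ("none" %in% names(a)) a[["none"]] else 0
  comps <- setdiff(names(a), "none")
  cls <- classify_glycan(comps)
  ac <- a[comps]
  cx <- cls$type == "complex"
  denom <- sum(ac[cx])
  cxtrait <- function(x) if (denom > 0) 100 * x / denom else NA_real_
  out <- c(
    galactosylation = cxtrait(sum(ac[cx] * cls$n_gal[cx]) / 2),
    agalactosylation = cxtrait(sum(ac[cx & cls$n_gal == 0])),
    sialylation = cxtrait(sum(ac[cx] * cls$n_sia[cx]) / 2),
    afucosylation = cxtrait(sum(ac[cx & !cls$fucosylated])),
    bisection = cxtrait(sum(ac[cls$bisecting])),
    high_mannose = sum(ac[cls$type == "high_mannose"]),
    non_glycosylated = none)
  if (subtraits)
    out <- c(out,
             mono_galactosylation = cxtrait(sum(ac[cx & cls$n_gal == 1])),
             di_galactosylation = cxtrait(sum(ac[cx & cls$n_gal == 2])),
             mono_sialylation = cxtrait(sum(ac[cx & cls$n_sia == 1])),
             di_sialylation = cxtrait(sum(ac[cx & cls$n_sia == 2])))
  out
}

# Shared row builder for trait tables, used both for simulator ground truth
# and for quantified estimates so the two are directly comparable.
build_trait_rows <- function(patient, fraction, profiles, subclass_map,
                             allotype_totals, occupancy, ptm_pct) {
  empty_traits <- stats::setNames(rep(NA_real_, length(TRAIT_NAMES)), TRAIT_NAMES)
  rows <- list()
  subclasses <- unique(subclass_map)
  total_all <- sum(allotype_totals)
  for (sc in subclasses) {
    al <- names(subclass_map)[subclass_map == sc]
    prof_sc <- subclass_average(profiles[al], allotype_totals[al])
    tr <- derive_traits(prof_sc)
    ratio <- if (length(al) == 2)
      allotype_ratio(allotype_totals[al[1]], allotype_totals[al[2]]) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      patient = patient, fraction = fraction, level = "subclass", unit = sc,
      subclass = sc, t(tr),
      subclass_abundance = 100 * sum(allotype_totals[al]) / total_all,
      allotype_ratio = ratio, occupancy = NA_real_, plusK = NA_real_,
      minusGK = NA_real_, open_disulfide = NA_real_, cysteinylation = NA_real_,
      stringsAsFactors = FALSE)
    for (a in al) {
      tr_a <- derive_traits(profiles[[a]])
      pt <- ptm_pct[[a]]
      rows[[length(rows) + 1]] <- data.frame(
        patient = patient, fraction = fraction, level = "allotype", unit = a,
        subclass = sc, t(tr_a), subclass_abundance = NA_real_,
        allotype_ratio = NA_real_,
        occupancy = if (a %in% names(occupancy)) 100 * occupancy[[a]] else NA_real_,
        plusK = pt[["plusK"]], minusGK = pt[["minusGK"]],
        open_disulfide = pt[["open_disulfide"]],
        cysteinylation = pt[["cysteinylation"]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Ground-truth trait table of a patient's fraction profiles
#'
#' Computes, from the simulated profiles themselves, the exact values that the
#' quantification layer estimates: derived traits per allotype and subclass
#' (allotype-abundance-weighted), subclass abundances, allotype ratios, CH3
#' occupancies and PTM levels. Uses the same formulas as the estimation path,
#' so differences measure quantification error only.
#'
#' @param profiles named list of the four [fraction_profile()]s.
#' @param reference allotype reference table.
#' @param patient_id patient identifier.
#' @return data.frame trait table.
#' @export
ground_truth_traits <- function(profiles, reference, patient_id) {
  rows <- list()
  for (fr in names(profiles)) {
    pr <- profiles[[fr]]
    st <- species_table(pr, reference)
    allot <- names(pr$allotype_abundances)
    totals <- vapply(allot, function(a) sum(st$abundance[st$allotype == a]),
                     numeric(1))
    prof <- lapply(stats::setNames(allot, allot), function(a)
      100 * pr$glycoform_dists[[a]])
    sc_map <- stats::setNames(reference$subclass[match(allot, reference$name)],
                              allot)
    ptm_pct <- lapply(stats::setNames(allot, allot), function(a) {
      lam <- pr$ptm_levels[[a]]
      if (is.null(lam))
        lam <- c(plusK = NA, minusGK = NA, open_disulfide = NA,
                 cysteinylation = NA)
      100 * lam
    })
    rows[[fr]] <- build_trait_rows(patient_id, fr, prof, sc_map, totals,
                                   pr$ch3_occupancy, ptm_pct)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trait table from a quantified run
#'
#' @param quant a `quant_result` from [quantify_run()].
#' @param patient,fraction manifest fields of the run.
#' @param reference allotype reference table.
#' @return data.frame trait table (same shape as [ground_truth_traits()]).
#' @export
quant_traits <- function(quant, patient, fraction,
                         reference = allotype_reference()) {
  allot <- names(quant$profiles)
  sc_map <- stats::setNames(reference$subclass[match(allot, reference$name)],
                            allot)
  totals <- stats::setNames(quant$allotype_abundance[allot], allot)
  occupancy <- quant$occupancy
  ptm_pct <- quant$ptm
  out <- build_trait_rows(patient, fraction, quant$profiles, sc_map, totals,
                          occupancy, ptm_pct)
  rownames(out) <- NULL
  out
}

#' Feature matrix for fraction-level multivariate analysis
#'
#' Pivots the subclass-level rows of a trait table into one row per
#' patient x fraction with one column per subclass x feature (derived traits
#' plus subclass abundance), the input layout for [pca_fractions()].
#'
#' @param traits trait table ([ground_truth_traits()]/[quant_traits()] rows).
#' @return data.frame with `patient`, `fraction` and numeric feature columns.
#' @export
traits_feature_matrix <- function(traits) {
  sub <- traits[traits$level == "subclass", ]
  feats <- c(TRAIT_NAMES, "subclass_abundance")
  keys <- unique(sub[, c("patient", "fraction")])
  out <- keys
  for (sc in unique(sub$unit)) for (f in feats) {
    col <- paste(sc, f, sep = ".")
    m <- sub[sub$unit == sc, c("patient", "fraction", f)]
    out[[col]] <- m[[f]][match(paste(keys$patient, keys$fraction),
                               paste(m$patient, m$fraction))]
  }
  out
}
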