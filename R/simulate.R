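#' Acquisition and rendering parameters for a simulated run
#'
#' Defaults reproduce the acquisition window and instrument characteristics of
#' the profiling setup the package models: MS1 spectra over m/z 1000-1600,
#' retention time 600-1320 s, TOF resolution 15000 (FWHM-based), and a charge
#' envelope z = 18-22 with triangular weights peaking at z = 20 that places
#' ~25 kDa Fc/2 species inside the m/z window. Profile spectra are rendered on
#' a uniform m/z grid (spacing 0.02) so that downstream peak handling is
#' exercised. Elution peaks are Gaussian with sigma `peak_width_rt` seconds;
#' open-disulfide species elute `od_rt_offset` seconds after their parent,
#' which makes the +2 Da variants chromatographically resolvable.
#'
#' @param rt_window retention-time window, seconds.
#' @param mz_window m/z window.
#' @param resolution FWHM-based TOF resolution.
#' @param charges charge states rendered per species.
#' @param charge_weights relative intensity weights of `charges`.
#' @param mz_spacing uniform m/z grid spacing.
#' @param scan_interval time between MS1 scans, seconds.
#' @param peak_width_rt Gaussian sigma of elution peaks, seconds.
#' @param noise_sd standard deviation of additive Gaussian noise, intensity
#'   units. The default keeps 0.3 %-abundance species (the typical level of
#'   non-glycosylated IgG) clearly detectable in extracted ion chromatograms.
#' @param baseline_level constant detector baseline offset added to every grid
#'   point before noise. Keeping the baseline above ~3 noise SD means the
#'   non-negativity clipping of the detector almost never truncates the noise,
#'   so weak signals stay unbiased; the preprocessing Tophat stage removes the
#'   offset, as it would for real instrument baselines.
#' @param intensity_scale total rendered ion current per unit abundance.
#' @param od_rt_offset retention-time offset of open-disulfide species, s.
#' @param seed integer seed; fully determines the rendered output.
#' @return list of class `run_spec`.
#' @export
run_spec <- function(rt_window = c(600, 1320), mz_window = c(1000, 1600),
                     resolution = 15000, charges = 18:22,
                     charge_weights = c(1, 2, 3, 2, 1), mz_spacing = 0.02,
                     scan_interval = 3, peak_width_rt = 3, noise_sd = 20,
                     baseline_level = 3 * noise_sd, intensity_scale = 1e6,
                     od_rt_offset = 15, seed = 1L) {
  stopifnot(length(charges) == length(charge_weights), all(charge_weights > 0),
            diff(rt_window) > 0, diff(mz_window) > 0, resolution > 0)
  structure(list(rt_window = rt_window, mz_window = mz_window,
                 resolution = resolution, charges = as.integer(charges),
                 charge_weights = charge_weights / sum(charge_weights),
                 mz_spacing = mz_spacing, scan_interval = scan_interval,
                 peak_width_rt = peak_width_rt, noise_sd = noise_sd,
                 baseline_level = baseline_level,
                 intensity_scale = intensity_scale, od_rt_offset = od_rt_offset,
                 seed = as.integer(seed)),
            class = "run_spec")
}

#' Cohort-level simulation parameters
#'
#' Encodes the study conditions the simulator emulates: four IgG fractions per
#' patient (total/ACPA x plasma/SF), up to two allotypes per subclass,
#' per-allotype CH2 glycoform distributions, CH3 glycans on two-site IgG3
#' allotypes, PTM variants and the fraction effects reported for rheumatoid
#' arthritis cohorts: ACPA fractions show lower afucosylation, bisection and
#' non-glycosylated IgG than total IgG; SF-derived (especially ACPA) fractions
#' show lower galactosylation and sialylation than plasma; C-terminal lysine
#' occurs only in SF; CH3 high-mannose glycans are elevated in ACPA; CH3 site
#' occupancy varies over 7-45 %.
#'
#' @param reference allotype reference table ([allotype_reference()]).
#' @param subclass_abundance mean relative subclass levels (will be jittered
#'   per patient and renormalised).
#' @param base_glycoforms mean CH2 glycoform distribution (must sum to 1;
#'   `none` is the non-glycosylated species).
#' @param ch3_glycoforms mean CH3 glycan distribution for two-site IgG3.
#' @param het_prob probability that a subclass is heterozygous in a patient.
#' @param occupancy_range per patient x fraction, CH3 occupancy is drawn
#'   uniformly from this range.
#' @param effects multiplicative fraction effects, see Details in the package
#'   vignette.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(
    reference = allotype_reference(),
    subclass_abundance = c(IgG1 = 0.60, IgG2 = 0.27, IgG3 = 0.07, IgG4 = 0.06),
    base_glycoforms = c(H3N4F1 = 0.32, H4N4F1 = 0.295, H5N4F1 = 0.12,
                        H3N4 = 0.03, H3N5F1 = 0.07, H5N2 = 0.025,
                        H4N4F1S1 = 0.05, H5N4F1S1 = 0.085, none = 0.005),
    ch3_glycoforms = c(H5N2 = 0.35, H6N2 = 0.15, H3N4 = 0.20, H4N4 = 0.20,
                       H3N4F1 = 0.10),
    het_prob = 0.6,
    occupancy_range = c(0.07, 0.45),
    effects = list(
      acpa_afuco = 0.45, acpa_bisect = 0.55, acpa_nonglyc = 0.40,
      sf_gal = c(total = 0.95, ACPA = 0.80), sf_sia = c(total = 0.92, ACPA = 0.75),
      acpa_ch3_highman = 1.4,
      acpa_ratio_shift = 0.10,
      plusK_total_SF = c(0.004, 0.016), plusK_ACPA_SF = c(0.010, 0.053),
      minusGK_IgG4 = c(0.010, 0.040), minusGK_SF_factor = 0.7,
      open_disulfide = c(0.005, 0.020), cysteinylation = c(0.002, 0.015)
    )) {
  stopifnot(abs(sum(base_glycoforms) - 1) < 1e-9,
            abs(sum(ch3_glycoforms) - 1) < 1e-9,
            "none" %in% names(base_glycoforms))
  structure(list(reference = reference, subclass_abundance = subclass_abundance,
                 base_glycoforms = base_glycoforms, ch3_glycoforms = ch3_glycoforms,
                 het_prob = het_prob, occupancy_range = occupancy_range,
                 effects = effects),
            class = "cohort_config")
}

IGG_FRACTIONS <- c("total_plasma", "total_SF", "ACPA_plasma", "ACPA_SF")

# Allotype pairs used for heterozygous subclasses (the common
# heterozygosities); homozygous patients carry the first allotype.
HET_PAIRS <- list(IgG1 = c("IGHG1*01", "IGHG1*03"),
                  IgG2 = c("IGHG2*01", "IGHG2*02"),
                  IgG3 = c("IGHG3*01", "IGHG3*11"),
                  IgG4 = c("IGHG4*01", "IGHG4*02"))

renorm <- function(x) x / sum(x)

# Apply the fraction-specific multiplicative tilts to a CH2 glycoform
# distribution and renormalise.
tilt_glycoforms <- function(g, fraction, eff) {
  cls <- classify_glycan(setdiff(names(g), "none"))
  w <- g
  acpa <- grepl("^ACPA", fraction)
  sf <- grepl("SF$", fraction)
  if (acpa) {
    afuco <- cls$composition[cls$type == "complex" & !cls$fucosylated]
    bis <- cls$composition[cls$bisecting]
    w[afuco] <- w[afuco] * eff$acpa_afuco
    w[bis] <- w[bis] * eff$acpa_bisect
    w["none"] <- w["none"] * eff$acpa_nonglyc
  }
  if (sf) {
    key <- if (acpa) "ACPA" else "total"
    gal_f <- eff$sf_gal[[key]]; sia_f <- eff$sf_sia[[key]]
    for (i in seq_len(nrow(cls))) {
      cmp <- cls$composition[i]
      w[cmp] <- w[cmp] * gal_f^cls$n_gal[i] * sia_f^cls$n_sia[i]
    }
  }
  renorm(w)
}

#' Sample the four fraction profiles of one patient
#'
#' Draws a patient's allotype constitution (heterozygosity per subclass),
#' subclass and allotype abundances, glycoform distributions, PTM levels and
#' CH3 occupancies for the four IgG fractions, applying the configured
#' fraction effects. The returned ground truth is computed from the profiles
#' with the same trait formulas the quantification layer uses, so parameter
#' recovery can be assessed exactly.
#'
#' @param config a [cohort_config()].
#' @param patient_id identifier used in tables.
#' @param seed integer; fixes all draws for this patient.
#' @param fully_heterozygous force two allotypes in all four subclasses.
#' @return list with elements `patient`, `allotypes`, `profiles` (named list
#'   of four `fraction_profile`s) and `truth` (ground-truth trait table rows).
#' @export
sample_patient <- function(config, patient_id = "P1", seed = 1L,
                           fully_heterozygous = FALSE) {
  set.seed(seed)
  ref <- config$reference
  subclasses <- names(HET_PAIRS)
  het <- if (fully_heterozygous) rep(TRUE, 4) else stats::runif(4) < config$het_prob
  names(het) <- subclasses
  allotypes <- unlist(lapply(subclasses, function(sc)
    HET_PAIRS[[sc]][seq_len(1 + het[[sc]])]))
  stopifnot(all(allotypes %in% ref$name))

  sc_ab <- renorm(config$subclass_abundance *
                    stats::rlnorm(4, 0, 0.3))
  ratio_base <- stats::setNames(stats::runif(4, 0.30, 0.70), subclasses)

  # patient-level glycoform baseline (shared across fractions before tilts)
  base_g <- lapply(stats::setNames(allotypes, allotypes), function(a)
    renorm(config$base_glycoforms * stats::rlnorm(length(config$base_glycoforms), 0, 0.15)))

  eff <- config$effects
  profiles <- list()
  for (fr in IGG_FRACTIONS) {
    acpa <- grepl("^ACPA", fr); sf <- grepl("SF$", fr)
    ab <- numeric(0)
    for (sc in subclasses) {
      al <- HET_PAIRS[[sc]][seq_len(1 + het[[sc]])]
      r <- ratio_base[[sc]]
      if (acpa)
        r <- min(0.95, max(0.05, r + stats::runif(1, -eff$acpa_ratio_shift,
                                                  eff$acpa_ratio_shift)))
      wal <- if (length(al) == 2) c(r, 1 - r) else 1
      ab <- c(ab, stats::setNames(sc_ab[[sc]] * wal, al))
    }
    ab <- renorm(ab)

    gly <- lapply(base_g, tilt_glycoforms, fraction = fr, eff = eff)

    ch3 <- list(); occ <- numeric(0)
    for (a in allotypes) {
      i <- match(a, ref$name)
      if (ref$n_glyc_sites[i] == 2) {
        h <- config$ch3_glycoforms
        if (acpa) {
          hm <- names(h) %in% c("H5N2", "H6N2")
          h[hm] <- h[hm] * eff$acpa_ch3_highman
        }
        ch3[[a]] <- renorm(h)
        occ[a] <- stats::runif(1, config$occupancy_range[1], config$occupancy_range[2])
      }
    }

    ptm <- list()
    for (a in allotypes) {
      sc <- ref$subclass[match(a, ref$name)]
      lam <- c(plusK = 0, minusGK = 0, open_disulfide = 0, cysteinylation = 0)
      if (sf) {
        rng <- if (acpa) eff$plusK_ACPA_SF else eff$plusK_total_SF
        lam["plusK"] <- stats::runif(1, rng[1], rng[2])
      }
      if (sc == "IgG4") {
        lam["minusGK"] <- stats::runif(1, eff$minusGK_IgG4[1], eff$minusGK_IgG4[2])
        if (sf) lam["minusGK"] <- lam["minusGK"] * eff$minusGK_SF_factor
      }
      lam["open_disulfide"] <- stats::runif(1, eff$open_disulfide[1], eff$open_disulfide[2])
      lam["cysteinylation"] <- stats::runif(1, eff$cysteinylation[1], eff$cysteinylation[2])
      ptm[[a]] <- lam
    }

    profiles[[fr]] <- fraction_profile(fr, ab, gly, ch3, occ, ptm)
  }

  truth <- ground_truth_traits(profiles, ref, patient_id)
  list(patient = patient_id, allotypes = allotypes, profiles = profiles,
       truth = truth)
}

#' Construct and validate a fraction profile
#'
#' @param fraction one of `total_plasma`, `total_SF`, `ACPA_plasma`, `ACPA_SF`.
#' @param allotype_abundances named vector, sums to 1.
#' @param glycoform_dists named list (per allotype) of CH2 glycoform
#'   distributions including `none`; each sums to 1.
#' @param ch3_dists named list (per two-site allotype) of CH3 glycan
#'   distributions; each sums to 1.
#' @param ch3_occupancy named vector in `[0, 1]` per two-site allotype:
#'   probability that a CH2-glycosylated chain also carries a CH3 glycan.
#' @param ptm_levels named list (per allotype) of PTM levels in `[0, 1]`,
#'   expressed as modified / (modified + unmodified) of the H3N4F1 anchor.
#' @return list of class `fraction_profile`.
#' @export
fraction_profile <- function(fraction, allotype_abundances, glycoform_dists,
                             ch3_dists = list(), ch3_occupancy = numeric(0),
                             ptm_levels = list()) {
  stopifnot(fraction %in% IGG_FRACTIONS)
  if (abs(sum(allotype_abundances) - 1) > 1e-9)
    stop("allotype abundances must sum to 1")
  for (a in names(glycoform_dists))
    if (abs(sum(glycoform_dists[[a]]) - 1) > 1e-9)
      stop("glycoform distribution of ", a, " must sum to 1")
  for (a in names(ch3_dists))
    if (abs(sum(ch3_dists[[a]]) - 1) > 1e-9)
      stop("CH3 glycan distribution of ", a, " must sum to 1")
  if (length(ch3_occupancy) && any(ch3_occupancy < 0 | ch3_occupancy > 1))
    stop("ch3_occupancy must lie in [0, 1]")
  for (a in names(ptm_levels))
    if (any(ptm_levels[[a]] < 0 | ptm_levels[[a]] >= 1))
      stop("PTM levels must lie in [0, 1)")
  structure(list(fraction = fraction, allotype_abundances = allotype_abundances,
                 glycoform_dists = glycoform_dists, ch3_dists = ch3_dists,
                 ch3_occupancy = ch3_occupancy, ptm_levels = ptm_levels),
            class = "fraction_profile")
}

#' Expand a fraction profile into a species table
#'
#' Enumerates every rendered proteoform species: CH2 glycoforms (singly
#' glycosylated), the non-glycosylated backbone, doubly glycosylated IgG3
#' (CH2 x CH3 combinations weighted by occupancy), and PTM variants of the
#' H3N4F1 anchor glycoform. PTM variants are added with weight
#' `w_anchor * lambda / (1 - lambda)` so that the bounded level
#' modified / (modified + unmodified) equals `lambda` exactly.
#'
#' @param profile a [fraction_profile()].
#' @param reference allotype reference table.
#' @return data.frame with one row per species: `allotype`, `subclass`,
#'   `kind` (`single`, `none`, `double`, `ptm`), `ch2`, `ch3`, `ptm`, `mass`,
#'   `rt`, `weight` (within allotype) and `abundance`.
#' @export
species_table <- function(profile, reference) {
  rows <- list()
  for (a in names(profile$allotype_abundances)) {
    i <- match(a, reference$name)
    if (is.na(i)) stop("allotype not in reference: ", a)
    b <- reference$backbone_mass_avg[i]
    rt <- reference$rt_ref[i]
    sc <- reference$subclass[i]
    g <- profile$glycoform_dists[[a]]
    two_site <- reference$n_glyc_sites[i] == 2 && !is.null(profile$ch3_dists[[a]])
    p <- if (two_site) profile$ch3_occupancy[[a]] else 0
    glycs <- setdiff(names(g), "none")

    rows[[length(rows) + 1]] <- data.frame(
      allotype = a, subclass = sc, kind = "single", ch2 = glycs, ch3 = NA,
      ptm = "none", mass = species_mass(b, glycs), rt = rt,
      weight = (1 - p) * unname(g[glycs]), stringsAsFactors = FALSE)
    if (g[["none"]] > 0)
      rows[[length(rows) + 1]] <- data.frame(
        allotype = a, subclass = sc, kind = "none", ch2 = NA, ch3 = NA,
        ptm = "none", mass = b, rt = rt, weight = unname(g[["none"]]),
        stringsAsFactors = FALSE)
    if (two_site && p > 0) {
      h <- profile$ch3_dists[[a]]
      grid <- expand.grid(ch2 = glycs, ch3 = names(h), stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        allotype = a, subclass = sc, kind = "double", ch2 = grid$ch2,
        ch3 = grid$ch3, ptm = "none",
        mass = species_mass(b, grid$ch2, grid$ch3), rt = rt,
        weight = p * unname(g[grid$ch2]) * unname(h[grid$ch3]),
        stringsAsFactors = FALSE)
    }
    lam <- profile$ptm_levels[[a]]
    if (!is.null(lam)) {
      w_anchor <- (1 - p) * unname(g[["H3N4F1"]])
      for (k in names(lam)) if (lam[[k]] > 0) {
        rows[[length(rows) + 1]] <- data.frame(
          allotype = a, subclass = sc, kind = "ptm", ch2 = "H3N4F1", ch3 = NA,
          ptm = k, mass = species_mass(b, "H3N4F1", ptm_delta = PTM_DELTAS[[k]]),
          rt = rt + if (k == "open_disulfide") 15 else 0,
          weight = w_anchor * lam[[k]] / (1 - lam[[k]]), stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  tab$abundance <- tab$weight * profile$allotype_abundances[tab$allotype]
  rownames(tab) <- NULL
  tab
}

#' Render a simulated MS1 run
#'
#' Renders every species of a fraction profile as a Gaussian elution peak at
#' its allotype-specific retention time; at each scan, each charge state
#' produces a Gaussian m/z peak at `(M + z * 1.00728) / z` with FWHM
#' `m/z / resolution`, with total rendered ion current proportional to the
#' species abundance. Additive Gaussian noise (sd `noise_sd`) is applied and
#' clipped at zero. Glycoforms of one allotype co-elute; open-disulfide PTM
#' species are offset in retention time.
#'
#' @param profile a [fraction_profile()] or a species table from
#'   [species_table()].
#' @param spec a [run_spec()].
#' @param reference allotype reference (needed when `profile` is a profile).
#' @param rt_shift global retention-time shift of this run, seconds.
#' @param metadata list with `run_id`, `patient`, `fraction`, `replicate`.
#' @param seed overrides `spec$seed` for the noise draw.
#' @return object of class `spectrum_run`: common m/z grid `mz`, scan times
#'   `rt`, intensity matrix (m/z x scans) and `metadata`.
#' @export
render_run <- function(profile, spec = run_spec(), reference = allotype_reference(),
                       rt_shift = 0, metadata = list(run_id = "run1"),
                       seed = NULL) {
  tab <- if (inherits(profile, "fraction_profile"))
    species_table(profile, reference) else profile
  mz <- seq(spec$mz_window[1], spec$mz_window[2], by = spec$mz_spacing)
  rt <- seq(spec$rt_window[1], spec$rt_window[2], by = spec$scan_interval)
  X <- matrix(0, nrow = length(mz), ncol = length(rt))
  sig_rt <- spec$peak_width_rt
  for (s in seq_len(nrow(tab))) {
    M <- tab$mass[s]
    rt0 <- tab$rt[s] + rt_shift
    jt <- which(abs(rt - rt0) <= 5 * sig_rt)
    if (!length(jt)) next
    phi_t <- stats::dnorm(rt[jt], rt0, sig_rt)
    n_in <- 0L
    for (k in seq_along(spec$charges)) {
      z <- spec$charges[k]
      mz0 <- (M + z * PROTON_MASS) / z
      if (mz0 < spec$mz_window[1] || mz0 > spec$mz_window[2]) next
      n_in <- n_in + 1L
      sig_mz <- mz0 / spec$resolution / (2 * sqrt(2 * log(2)))
      im <- which(abs(mz - mz0) <= 6 * sig_mz)
      if (!length(im)) next
      amp <- tab$abundance[s] * spec$intensity_scale * spec$charge_weights[k]
      X[im, jt] <- X[im, jt] +
        amp * outer(stats::dnorm(mz[im], mz0, sig_mz), phi_t)
    }
    if (n_in == 0L)
      warning("species at mass ", round(M, 1),
              " falls entirely outside the m/z window; skipped")
  }
  if (spec$noise_sd > 0) {
    set.seed(if (is.null(seed)) spec$seed else seed)
    X <- X + (spec$baseline_level %||% 0) +
      matrix(stats::rnorm(length(X), 0, spec$noise_sd), nrow = nrow(X))
    X[X < 0] <- 0
  }
  structure(list(mz = mz, rt = rt, intensity = X, metadata = metadata),
            class = "spectrum_run")
}

#' @export
print.spectrum_run <- function(x, ...) {
  cat("<spectrum_run>", x$metadata$run_id %||% "", "\n",
      length(x$rt), "scans, RT", min(x$rt), "-", max(x$rt), "s; m/z grid",
      length(x$mz), "points,", min(x$mz), "-", max(x$mz), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plan a simulated cohort without rendering
#'
#' Draws everything that defines a cohort — patient profiles, ground-truth
#' species tables and trait table, per-run retention-time shifts and noise
#' seeds — without rendering any spectra. [simulate_cohort()] renders every
#' run of a plan; the pipeline instead renders runs one at a time from the
#' plan, which keeps memory flat for large cohorts. Both routes are
#' byte-identical because all seeds are drawn here.
#'
#' @param config a [cohort_config()].
#' @param n_patients number of patients.
#' @param seed master seed; determines all patient and run draws.
#' @param rt_shift_range per-run global retention-time shift drawn uniformly
#'   from this range (exercises the alignment stage).
#' @return list with `manifest`, `species` (per-run ground-truth species
#'   tables), `truth` (trait table), `patients`, `rt_shifts` and `run_seeds`.
#' @export
cohort_plan <- function(config = cohort_config(), n_patients = 20, seed = 1L,
                        rt_shift_range = c(-6, 6)) {
  set.seed(seed)
  pat_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  run_seeds <- sample.int(.Machine$integer.max - 1L, n_patients * 4)
  shifts <- stats::runif(n_patients * 4, rt_shift_range[1], rt_shift_range[2])
  species <- list(); manifest <- list(); truth <- list(); patients <- list()
  rt_shifts <- numeric(0); seeds <- integer(0)
  k <- 0
  for (i in seq_len(n_patients)) {
    pid <- sprintf("P%02d", i)
    pat <- sample_patient(config, pid, seed = pat_seeds[i])
    patients[[pid]] <- pat
    truth[[pid]] <- pat$truth
    for (fr in IGG_FRACTIONS) {
      k <- k + 1
      run_id <- paste(pid, fr, sep = "_")
      species[[run_id]] <- species_table(pat$profiles[[fr]], config$reference)
      rt_shifts[run_id] <- shifts[k]
      seeds[run_id] <- run_seeds[k]
      manifest[[k]] <- data.frame(run_id = run_id, patient = pid, fraction = fr,
                                  replicate = 1L, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(manifest = do.call(rbind, manifest), species = species, truth = truth,
       patients = patients, rt_shifts = rt_shifts, run_seeds = seeds)
}

# Render one run of a cohort plan.
render_plan_run <- function(plan, run_id, spec) {
  i <- match(run_id, plan$manifest$run_id)
  render_run(plan$species[[run_id]], spec,
             rt_shift = plan$rt_shifts[[run_id]],
             metadata = as.list(plan$manifest[i, ]),
             seed = plan$run_seeds[[run_id]])
}

#' Simulate a patient cohort
#'
#' Generates the four-fraction run set for `n_patients` patients. Returns the
#' in-memory runs, a run manifest, the per-run ground-truth species tables and
#' the ground-truth trait table. When `out_dir` is given, runs are also
#' written as mzML plus ground-truth and manifest TSVs. Note that rendered
#' runs are large (tens of MB each); for big cohorts prefer [cohort_plan()]
#' plus per-run rendering, which is what [run_pipeline()] does.
#'
#' @param config a [cohort_config()].
#' @param spec a [run_spec()].
#' @param n_patients number of patients.
#' @param seed master seed; determines all patient and run draws.
#' @param out_dir optional output directory for mzML/TSV files.
#' @param rt_shift_range per-run global retention-time shift drawn uniformly
#'   from this range (exercises the alignment stage).
#' @return list with `runs` (named list of `spectrum_run`), `manifest`
#'   (data.frame), `species` (named list of ground-truth species tables),
#'   `truth` (trait table), `patients` (per-patient profile sets) and
#'   `rt_shifts`.
#' @export
simulate_cohort <- function(config = cohort_config(), spec = run_spec(),
                            n_patients = 20, seed = 1L, out_dir = NULL,
                            rt_shift_range = c(-6, 6)) {
  plan <- cohort_plan(config, n_patients, seed, rt_shift_range)
  runs <- lapply(stats::setNames(plan$manifest$run_id, plan$manifest$run_id),
                 function(rid) render_plan_run(plan, rid, spec))
  out <- list(runs = runs, manifest = plan$manifest, species = plan$species,
              truth = plan$truth, patients = plan$patients,
              rt_shifts = plan$rt_shifts)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(plan$manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(plan$truth, file.path(out_dir, "ground_truth_traits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    for (run_id in names(runs)) {
      write_mzml(runs[[run_id]], file.path(out_dir, paste0(run_id, ".mzML")))
      utils::write.table(plan$species[[run_id]],
                         file.path(out_dir, paste0(run_id, "_truth.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  out
}

#' Write a run as mzML (MS1 only)
#'
#' @param run a `spectrum_run`.
#' @param path output file path.
#' @export
write_mzml <- function(run, path) {
  n <- length(run$rt)
  pks <- lapply(seq_len(n), function(j)
    cbind(mz = run$mz, intensity = run$intensity[, j]))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = length(run$mz),
    totIonCurrent = colSums(run$intensity), retentionTime = run$rt,
    basePeakMZ = run$mz[max.col(t(run$intensity))],
    basePeakIntensity = apply(run$intensity, 2, max),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = min(run$mz), highMZ = max(run$mz),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = FALSE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_, isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(run$mz), scanWindowUpperLimit = max(run$mz),
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read an MS1 mzML file into a spectrum_run
#'
#' Expects all scans to share a common m/z grid (true for files written by
#' [write_mzml()]; profile-mode instrument files resampled onto a uniform
#' grid also qualify).
#'
#' @param path mzML file.
#' @param metadata optional manifest entry for the run.
#' @return a `spectrum_run`.
#' @export
read_mzml <- function(path, metadata = list(run_id = basename(path))) {
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh))
  hd <- mzR::header(fh)
  pk <- mzR::peaks(fh)
  if (is.matrix(pk)) pk <- list(pk)
  mz <- pk[[1]][, 1]
  for (j in seq_along(pk))
    if (length(pk[[j]][, 1]) != length(mz) ||
        max(abs(pk[[j]][, 1] - mz)) > 1e-6)
      stop("scans do not share a common m/z grid: ", path)
  X <- vapply(pk, function(p) p[, 2], numeric(length(mz)))
  structure(list(mz = mz, rt = hd$retentionTime, intensity = X,
                 metadata = metadata), class = "spectrum_run")
}
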