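gauss_kernel <- function(width, spacing) {
  sigma <- width / (2 * sqrt(2 * log(2))) / spacing
  half <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-half, half), 0, sigma)
  k / sum(k)
}

#' Gaussian smoothing of a mass spectrum
#'
#' Convolution with a Gaussian kernel of FWHM `width_mz` (m/z units) on a
#' uniformly spaced spectrum; total intensity is conserved away from the
#' boundaries (the kernel is renormalised where it is truncated).
#'
#' @param mz m/z grid (uniform spacing).
#' @param intensity intensity vector (or matrix with one column per scan).
#' @param width_mz kernel FWHM in m/z units (default 1.0).
#' @return smoothed intensity, same shape as the input.
#' @export
smooth_spectrum <- function(mz, intensity, width_mz = 1.0) {
  if (length(mz) < 2L || width_mz <= 0) return(intensity)
  vec <- is.null(dim(intensity))
  X <- if (vec) matrix(intensity, ncol = 1) else intensity
  out <- conv_columns(X, gauss_kernel(width_mz, mz[2] - mz[1]))
  if (vec) as.numeric(out) else out
}

#' Tophat baseline subtraction
#'
#' Morphological opening (erosion followed by dilation with a flat
#' structuring element of total width `width_mz`) estimates the baseline,
#' which is subtracted from the signal. Peaks narrower than the structuring
#' element are preserved; the output is non-negative wherever the input is.
#'
#' @inheritParams smooth_spectrum
#' @param width_mz structuring-element width in m/z units (default 1.0).
#' @return baseline-subtracted intensity, same shape as the input.
#' @export
baseline_tophat <- function(mz, intensity, width_mz = 1.0) {
  if (length(mz) < 2L || width_mz <= 0) return(intensity)
  half <- max(1L, round(width_mz / (mz[2] - mz[1]) / 2))
  vec <- is.null(dim(intensity))
  X <- if (vec) matrix(intensity, ncol = 1) else intensity
  out <- X - opening_columns(X, half)
  if (vec) as.numeric(out) else out
}

#' Preprocess all scans of a run
#'
#' Applies Gaussian smoothing followed by Tophat baseline subtraction to each
#' scan. The default smoothing width is matched to the simulated peak width at
#' resolution 15000 (FWHM ~0.085 m/z); see the methods vignette for why the
#' quantification path uses a narrower kernel than the generic
#' [smooth_spectrum()] default.
#'
#' @param run a `spectrum_run`.
#' @param smooth_width smoothing kernel FWHM, m/z (0 disables).
#' @param tophat_width structuring-element width, m/z (0 disables).
#' @return the run with preprocessed intensities.
#' @export
preprocess_run <- function(run, smooth_width = 0.2, tophat_width = 1.0) {
  X <- run$intensity
  if (smooth_width > 0) X <- smooth_spectrum(run$mz, X, smooth_width)
  if (tophat_width > 0) X <- baseline_tophat(run$mz, X, tophat_width)
  run$intensity <- X
  run
}

#' Sum scans of a run over a retention-time range
#'
#' @param run a `spectrum_run`.
#' @param rt_range `c(lo, hi)` in seconds, or `NULL` for all scans.
#' @return list with `mz` and summed `intensity`.
#' @export
sum_scans <- function(run, rt_range = NULL) {
  j <- if (is.null(rt_range)) seq_along(run$rt)
       else which(run$rt >= rt_range[1] & run$rt <= rt_range[2])
  list(mz = run$mz,
       intensity = if (length(j)) rowSums(run$intensity[, j, drop = FALSE])
                   else numeric(length(run$mz)),
       n_scans = length(j))
}

#' Zero-charge deconvolution by charge-assignment summation
#'
#' For each candidate mass M on a 1.0 Da grid, reads the summed-spectrum
#' intensity at `(M + z * 1.00728) / z` for every charge in `charges`
#' (linear interpolation; positions outside the acquired m/z window are
#' excluded) and combines across charges. `combine = "sum"` accumulates all
#' charge states; `combine = "median"` takes the per-charge median, which
#' suppresses images of charge misassignment (a peak of true charge z read as
#' z' appears at M z'/z but only in a single charge channel). Peaks are local
#' maxima (3-point neighbourhood, plateau ties to the lower mass) above a
#' noise-adaptive threshold, median + k MAD. Reported peak intensity is the
#' summed grid intensity within +/- 2 Da of the apex.
#'
#' @param run a `spectrum_run`.
#' @param rt_range retention-time range summed before deconvolution
#'   (`NULL` = whole run).
#' @param charges charge states assumed.
#' @param mass_range `c(lo, hi)` in Da.
#' @param grid mass grid spacing, Da (contract: 1.0).
#' @param combine `"sum"` (default) or `"median"`.
#' @param charge_weights optional relative envelope weights of `charges`; used
#'   by the median combine to normalise per-charge reads by their expected
#'   peak height (weight divided by m/z, since at constant resolving power the
#'   m/z peak width shrinks — and the height grows — with charge). With the
#'   normalisation the clean channels are exchangeable, so the median tolerates
#'   up to two contaminated charge channels without bias.
#' @param threshold_k multiplier k of the MAD threshold.
#' @param tophat_width Tophat baseline-subtraction width (m/z) applied to the
#'   summed spectrum before charge reading (0 disables).
#' @return list of class `deconvolved_spectrum` with `mass`, `intensity`,
#'   `peaks` (data.frame `mass`, `intensity`, `apex`), `threshold`.
#' @export
deconvolve <- function(run, rt_range = NULL, charges = 18:22,
                       mass_range = c(23000, 27500), grid = 1.0,
                       combine = c("sum", "median"), charge_weights = NULL,
                       threshold_k = 5, tophat_width = 1.0) {
  combine <- match.arg(combine)
  if (is.null(charge_weights)) charge_weights <- rep(1, length(charges))
  sm <- sum_scans(run, rt_range)
  mass <- seq(mass_range[1], mass_range[2], by = grid)
  if (sm$n_scans == 0) {
    return(structure(list(mass = mass, intensity = numeric(length(mass)),
                          peaks = data.frame(mass = numeric(0),
                                             intensity = numeric(0),
                                             apex = numeric(0)),
                          threshold = NA_real_, grid = grid),
                     class = "deconvolved_spectrum"))
  }
  if (tophat_width > 0)
    sm$intensity <- baseline_tophat(sm$mz, sm$intensity, tophat_width)
  I <- matrix(NA_real_, nrow = length(mass), ncol = length(charges))
  Q <- matrix(NA_real_, nrow = length(mass), ncol = length(charges))
  for (k in seq_along(charges)) {
    z <- charges[k]
    q <- (mass + z * PROTON_MASS) / z
    Q[, k] <- q
    inside <- q >= min(run$mz) & q <= max(run$mz)
    if (any(inside))
      I[inside, k] <- stats::approx(sm$mz, sm$intensity, q[inside])$y
  }
  if (combine == "sum") {
    intensity <- rowSums(I, na.rm = TRUE)
  } else {
    # expected per-charge peak height is proportional to weight / m/z;
    # normalise, take the channel median, restore the overall scale
    H <- sweep(I * Q, 2, charge_weights, "/")
    intensity <- apply(H, 1, stats::median, na.rm = TRUE) *
      mean(charge_weights) / rowMeans(Q)
  }
  intensity[is.na(intensity)] <- 0
  # MAD threshold with a small relative floor so that noiseless spectra do not
  # degenerate to a zero threshold (interpolation tails are not peaks)
  thr <- max(stats::median(intensity) + threshold_k * stats::mad(intensity),
             1e-3 * max(intensity))
  n <- length(intensity)
  i <- 2:(n - 1)
  is_peak <- intensity[i] >= intensity[i - 1] & intensity[i] >= intensity[i + 1] &
    intensity[i] != intensity[i - 1] & intensity[i] > thr
  apex_idx <- i[is_peak]
  w <- round(2 / grid)
  peak_int <- vapply(apex_idx, function(ix)
    sum(intensity[max(1, ix - w):min(n, ix + w)]), numeric(1))
  structure(list(mass = mass, intensity = intensity,
                 peaks = data.frame(mass = mass[apex_idx], intensity = peak_int,
                                    apex = intensity[apex_idx]),
                 threshold = thr, grid = grid),
            class = "deconvolved_spectrum")
}

# Locate the apex of an extracted ion chromatogram near an expected RT by
# quadratic interpolation around the maximum scan.
eic_apex <- function(eic, rt_expected, search = 45) {
  j <- which(abs(eic$rt - rt_expected) <= search)
  if (!length(j)) return(NA_real_)
  jm <- j[which.max(eic$intensity[j])]
  if (jm <= 1 || jm >= length(eic$rt)) return(eic$rt[jm])
  y <- eic$intensity[(jm - 1):(jm + 1)]
  denom <- y[1] - 2 * y[2] + y[3]
  off <- if (denom < 0) 0.5 * (y[1] - y[3]) / denom else 0
  eic$rt[jm] + off * (eic$rt[2] - eic$rt[1])
}

#' Retention-time alignment against anchor species
#'
#' Fits a piecewise-linear retention-time warp per run through the observed
#' apexes of high-abundance anchor species (their expected retention times are
#' taken from the anchor table), then applies it to the scan times. Outside
#' the anchor range the warp continues as a constant shift. Runs in which an
#' anchor cannot be detected (apex below `min_snr` times the EIC median) are
#' flagged via `metadata$alignment = "failed"` and returned unwarped.
#'
#' @param runs list of `spectrum_run`s.
#' @param anchors data.frame with columns `mass` (species average mass, Da)
#'   and `rt` (expected apex, seconds).
#' @param resolution,charges EIC extraction parameters (see [build_eic()]).
#' @param search half-width of the apex search window around the expected
#'   retention time, seconds.
#' @param min_snr detection criterion for an anchor apex.
#' @return list of runs, warped, with `metadata$alignment` set to `"ok"` or
#'   `"failed"`.
#' @export
align_runs <- function(runs, anchors, resolution = 15000, charges = 19:21,
                       search = 45, min_snr = 10) {
  lapply(runs, function(run) {
    obs <- rep(NA_real_, nrow(anchors))
    for (a in seq_len(nrow(anchors))) {
      def <- eic_definition(anchors$mass[a], charges = charges,
                            resolution = resolution)
      eic <- build_eic(run, def)
      j <- which(abs(eic$rt - anchors$rt[a]) <= search)
      noise <- stats::median(eic$intensity) + 1e-12
      if (length(j) && max(eic$intensity[j]) > min_snr * noise)
        obs[a] <- eic_apex(eic, anchors$rt[a], search)
    }
    ok <- !is.na(obs)
    if (!any(ok)) {
      run$metadata$alignment <- "failed"
      return(run)
    }
    o <- obs[ok]; e <- anchors$rt[ok]
    ord <- order(o); o <- o[ord]; e <- e[ord]
    t <- run$rt
    if (length(o) == 1) {
      warped <- t + (e - o)
    } else {
      warped <- stats::approx(o, e, t, rule = 1)$y
      lo <- t < o[1]; hi <- t > o[length(o)]
      warped[lo] <- t[lo] + (e[1] - o[1])
      warped[hi] <- t[hi] + (e[length(e)] - o[length(o)])
    }
    run$rt <- warped
    run$metadata$alignment <- "ok"
    run
  })
}

#' Write a deconvolved spectrum as a two-column TSV
#'
#' @param dec a `deconvolved_spectrum`.
#' @param path output file; columns `mass` and `intensity`.
#' @export
write_deconvolved <- function(dec, path) {
  utils::write.table(data.frame(mass = dec$mass, intensity = dec$intensity),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
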