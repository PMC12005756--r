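test_that("Gaussian smoothing conserves intensity and has the right impulse", {
  mz <- seq(1000, 1100, 0.02)
  flat <- rep(5, length(mz))
  expect_equal(smooth_spectrum(mz, flat, 1.0), flat, tolerance = 1e-9)
  # impulse response: Gaussian of FWHM 1.0 m/z
  delta <- numeric(length(mz)); delta[2500] <- 1
  sm <- smooth_spectrum(mz, delta, 1.0)
  half_height <- which(sm >= max(sm) / 2)
  fwhm <- (max(half_height) - min(half_height)) * 0.02
  expect_equal(fwhm, 1.0, tolerance = 0.05)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  # variance reduction on white noise
  set.seed(1)
  noise <- rnorm(length(mz))
  expect_lt(var(smooth_spectrum(mz, noise, 1.0)), var(noise))
  # empty scan: identity
  expect_identical(smooth_spectrum(numeric(0), numeric(0), 1.0), numeric(0))
})

test_that("Tophat removes offsets and ramps but preserves narrow peaks", {
  mz <- seq(1000, 1100, 0.02)
  expect_equal(baseline_tophat(mz, rep(7, length(mz)), 1.0),
               rep(0, length(mz)))
  expect_equal(baseline_tophat(mz, numeric(length(mz)), 1.0),
               numeric(length(mz)))
  # narrow peak (FWHM 0.1 m/z) on a linear ramp: area preserved within 5%
  peak <- 100 * dnorm(mz, 1050, 0.1 / 2.3548)
  ramp <- seq(0, 50, length.out = length(mz))
  out <- baseline_tophat(mz, peak + ramp, 1.0)
  expect_equal(sum(out), sum(peak), tolerance = 0.05)
  expect_true(all(out >= 0))
})

test_that("smoothing and baseline subtraction are homogeneous of degree 1", {
  mz <- seq(1000, 1020, 0.02)
  set.seed(3)
  y <- abs(rnorm(length(mz))) + 50 * dnorm(mz, 1010, 0.05)
  for (c in c(0.1, 7)) {
    expect_equal(smooth_spectrum(mz, c * y, 1.0),
                 c * smooth_spectrum(mz, y, 1.0), tolerance = 1e-12)
    expect_equal(baseline_tophat(mz, c * y, 1.0),
                 c * baseline_tophat(mz, y, 1.0), tolerance = 1e-12)
  }
})

test_that("alignment removes a global retention-time shift", {
  tab <- species_rows(c(24900, 25800), c(660, 740), c(0.5, 0.4))
  spec <- small_spec(noise_sd = 10, seed = 21)
  anchors <- data.frame(mass = c(24900, 25800), rt = c(660, 740))
  shifted <- render_run(tab, spec, rt_shift = 10, metadata = list(run_id = "s"))
  aligned <- align_runs(list(shifted), anchors)[[1]]
  expect_equal(aligned$metadata$alignment, "ok")
  expect_lt(max(abs(aligned$rt - (shifted$rt - 10))), 1)
  # identical run: identity warp (within apex estimation error)
  plain <- render_run(tab, spec, rt_shift = 0, metadata = list(run_id = "p"))
  ident <- align_runs(list(plain), anchors)[[1]]
  expect_lt(max(abs(ident$rt - plain$rt)), 1)
  # anchors not present in the run: flagged, unwarped
  bad <- align_runs(list(plain), data.frame(mass = 23300, rt = 700))[[1]]
  expect_equal(bad$metadata$alignment, "failed")
  expect_identical(bad$rt, plain$rt)
})

test_that("deconvolution recovers masses within one grid step", {
  for (M in c(23123.4, 25000.0, 26987.6)) {
    run <- render_run(species_rows(M, 700, 0.5), run_spec(noise_sd = 0))
    # summation combine: the dominant peak is the true mass
    dsum <- deconvolve(run, rt_range = c(680, 720),
                       mass_range = c(22800, 27400))
    expect_lt(abs(dsum$peaks$mass[which.max(dsum$peaks$intensity)] - M), 1.0)
    # charge-consensus combine: the true mass is the only peak
    dmed <- deconvolve(run, rt_range = c(680, 720),
                       mass_range = c(22800, 27400), combine = "median",
                       charge_weights = c(1, 2, 3, 2, 1))
    expect_equal(nrow(dmed$peaks), 1)
    expect_lt(abs(dmed$peaks$mass - M), 1.0)
  }
})

test_that("deconvolution resolves two species 1.2 kDa apart", {
  run <- render_run(species_rows(c(25000, 26200), 700, c(0.5, 0.25)),
                    run_spec(noise_sd = 0))
  dec <- deconvolve(run, rt_range = c(680, 720), mass_range = c(24500, 26700),
                    combine = "median", charge_weights = c(1, 2, 3, 2, 1))
  expect_equal(nrow(dec$peaks), 2)
  expect_lt(abs(dec$peaks$mass[1] - 25000), 1.0)
  expect_lt(abs(dec$peaks$mass[2] - 26200), 1.0)
})

test_that("two-species intensity ratios are recovered within 10% at default SNR", {
  for (r in c(0.05, 1, 20)) {
    run <- render_run(species_rows(c(25000, 26200), 700, c(0.4, 0.4 / r)),
                      run_spec(seed = 3))
    dec <- deconvolve(run, rt_range = c(680, 720), mass_range = c(24500, 26700))
    pk <- dec$peaks
    est <- pk$intensity[which.min(abs(pk$mass - 25000))] /
      pk$intensity[which.min(abs(pk$mass - 26200))]
    expect_equal(est, r, tolerance = 0.1)
  }
})

test_that("pure noise yields no picked peaks at the default threshold", {
  zero_peaks <- 0
  for (s in 1:20) {
    run <- render_run(species_rows(numeric(0), numeric(0), numeric(0)),
                      run_spec(seed = s))
    dec <- deconvolve(run, rt_range = c(680, 720), mass_range = c(24000, 26000))
    if (nrow(dec$peaks) == 0) zero_peaks <- zero_peaks + 1
  }
  expect_gte(zero_peaks, 19)  # >= 95% of seeds
})

test_that("an empty retention-time range gives an empty deconvolution", {
  run <- render_run(species_rows(25000, 700, 0.5), small_spec(noise_sd = 0))
  dec <- deconvolve(run, rt_range = c(10, 20), mass_range = c(24000, 26000))
  expect_equal(nrow(dec$peaks), 0)
  expect_true(all(dec$intensity == 0))
})

test_that("charge-consensus combine suppresses single-charge images", {
  # one abundant species; its charge-misassignment images appear under "sum"
  # in exactly one charge channel and must vanish under "median"
  run <- render_run(species_rows(25000, 700, 1), run_spec(noise_sd = 0))
  ghosts <- 25000 * c(19, 20, 21, 22) / c(18, 19, 20, 21)
  rng <- c(25600, 26600)
  dsum <- deconvolve(run, rt_range = c(680, 720), mass_range = rng,
                     combine = "sum", threshold_k = 0)
  dmed <- deconvolve(run, rt_range = c(680, 720), mass_range = rng,
                     combine = "median", charge_weights = c(1, 2, 3, 2, 1),
                     threshold_k = 0)
  near_ghost <- function(dec) {
    sapply(ghosts, function(g) max(dec$intensity[abs(dec$mass - g) <= 3]))
  }
  expect_true(all(near_ghost(dsum) > 100 * pmax(near_ghost(dmed), 1e-9)))
})

test_that("deconvolved spectra export as two-column TSV", {
  run <- render_run(species_rows(25000, 700, 0.5), small_spec(noise_sd = 0))
  dec <- deconvolve(run, rt_range = c(680, 720), mass_range = c(24500, 25500))
  f <- tempfile(fileext = ".tsv")
  write_deconvolved(dec, f)
  back <- read.delim(f)
  expect_equal(names(back), c("mass", "intensity"))
  expect_equal(back$mass, dec$mass)
  expect_equal(back$intensity, dec$intensity, tolerance = 1e-9)
})
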