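test_that("patient sampling is deterministic and respects the configuration", {
  cfg <- cohort_config()
  p1 <- sample_patient(cfg, "P1", seed = 5)
  p2 <- sample_patient(cfg, "P1", seed = 5)
  expect_identical(p1, p2)
  p3 <- sample_patient(cfg, "P1", seed = 6)
  expect_false(identical(p1$profiles, p3$profiles))
  # ACPA afucosylation set below total is reflected in the ground truth
  tr <- p1$truth
  for (pt in unique(tr$patient)) {
    afu_tot <- tr$afucosylation[tr$fraction == "total_plasma" &
                                  tr$level == "subclass" & tr$unit == "IgG1"]
    afu_acpa <- tr$afucosylation[tr$fraction == "ACPA_plasma" &
                                   tr$level == "subclass" & tr$unit == "IgG1"]
    expect_lt(afu_acpa, afu_tot)
  }
})

test_that("profile validation rejects inconsistent distributions", {
  g <- c(H3N4F1 = 0.6, none = 0.5)  # sums to 1.1
  expect_error(fraction_profile("total_plasma", c("IGHG1*01" = 1),
                                list("IGHG1*01" = g)), "sum to 1")
  expect_error(fraction_profile("total_plasma", c("IGHG1*01" = 0.7),
                                list("IGHG1*01" = c(H3N4F1 = 1))), "sum to 1")
  expect_error(fraction_profile("nope", c("IGHG1*01" = 1),
                                list("IGHG1*01" = c(H3N4F1 = 1))))
})

test_that("zero CH3 occupancy produces no doubly glycosylated species", {
  cfg <- cohort_config()
  pat <- sample_patient(cfg, "P1", seed = 3, fully_heterozygous = TRUE)
  pr <- pat$profiles$total_plasma
  pr$ch3_occupancy[] <- 0
  st <- species_table(pr, cfg$reference)
  expect_false(any(st$kind == "double"))
  pr$ch3_occupancy[] <- 0.3
  expect_true(any(species_table(pr, cfg$reference)$kind == "double"))
})

test_that("PTM species weights reproduce the configured bounded levels", {
  g <- c(H3N4F1 = 0.5, H4N4F1 = 0.45, none = 0.05)
  pr <- fraction_profile("total_SF", c("IGHG1*01" = 1), list("IGHG1*01" = g),
                         ptm_levels = list("IGHG1*01" = c(plusK = 0.016)))
  st <- species_table(pr, allotype_reference())
  m <- st$weight[st$ptm == "plusK"]
  u <- st$weight[st$kind == "single" & st$ch2 == "H3N4F1"]
  expect_equal(m / (m + u), 0.016, tolerance = 1e-12)
})

test_that("rendered charge peaks appear at (M + z p)/z", {
  run <- render_run(species_rows(25553.0, 700, 1),
                    small_spec(noise_sd = 0, charges = 20, charge_weights = 1))
  j <- which.min(abs(run$rt - 700))
  apex <- run$mz[which.max(run$intensity[, j])]
  expect_equal(apex, 1278.66, tolerance = 0.02)
})

test_that("noiseless EIC area is proportional to configured abundance", {
  spec <- small_spec(noise_sd = 0)
  for (a in c(0.2, 0.9)) {
    run <- render_run(species_rows(25000, 700, a), spec)
    def <- eic_definition(25000, 19:21)
    area <- integrate_peak(build_eic(run, def), c(680, 720))
    # expected: a * scale * (sum of the 3 central charge weights) / grid spacing
    expected <- a * spec$intensity_scale * sum(spec$charge_weights[2:4]) /
      spec$mz_spacing
    expect_equal(area, expected, tolerance = 1e-3)
  }
})

test_that("two allotypes give two chromatographic maxima at their RTs", {
  run <- render_run(species_rows(c(24900, 25800), c(700, 760), c(0.5, 0.5)),
                    small_spec(noise_sd = 0))
  tic <- colSums(run$intensity)
  expect_equal(run$rt[which.max(tic * (abs(run$rt - 700) < 30))], 700,
               tolerance = 3)
  expect_equal(run$rt[which.max(tic * (abs(run$rt - 760) < 30))], 760,
               tolerance = 3)
})

test_that("species outside the m/z window are skipped with a warning", {
  expect_warning(render_run(species_rows(60000, 700, 1),
                            small_spec(noise_sd = 0)), "outside")
})

test_that("rendering is byte-identical under a fixed seed", {
  tab <- species_rows(25000, 700, 0.5)
  r1 <- render_run(tab, small_spec(seed = 9))
  r2 <- render_run(tab, small_spec(seed = 9))
  expect_identical(r1$intensity, r2$intensity)
  r3 <- render_run(tab, small_spec(seed = 10))
  expect_false(identical(r1$intensity, r3$intensity))
})

test_that("mzML write/read round-trips a run", {
  run <- render_run(species_rows(25000, 700, 0.5),
                    run_spec(rt_window = c(650, 750), mz_window = c(1180, 1350),
                             scan_interval = 10, seed = 2))
  f <- tempfile(fileext = ".mzML")
  write_mzml(run, f)
  back <- read_mzml(f)
  expect_equal(back$rt, run$rt)
  expect_equal(back$mz, run$mz, tolerance = 1e-9)
  expect_equal(back$intensity, run$intensity, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("cohort simulation emits consistent manifest, truth and runs", {
  sim <- simulate_cohort(n_patients = 1, seed = 4,
                         spec = small_spec(noise_sd = 5))
  expect_equal(nrow(sim$manifest), 4)
  expect_setequal(sim$manifest$fraction,
                  c("total_plasma", "total_SF", "ACPA_plasma", "ACPA_SF"))
  expect_named(sim$runs, sim$manifest$run_id, ignore.order = TRUE)
  expect_true(all(c("galactosylation", "occupancy", "allotype_ratio") %in%
                    names(sim$truth)))
})
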