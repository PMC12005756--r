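test_that("EIC windows follow the resolution-based FWHM rule", {
  def <- eic_definition(25553.0, 20, resolution = 15000, w = 2)
  expect_equal(def$mz, 1278.66, tolerance = 0.01)
  expect_equal(def$hi - def$mz, 2 * 1278.66 / 15000, tolerance = 1e-4)
  expect_equal(def$mz - def$lo, 2 * 1278.66 / 15000, tolerance = 1e-4)
})

test_that("the three consecutive charges with maximal envelope weight win", {
  expect_equal(select_charges(25000), 19:21)
  # heavier species pushed against the window edge shift the selection
  # z = 16 falls above m/z 1500 and loses its weight, so 17:19 wins
  expect_equal(select_charges(25000, charges = 16:20,
                              charge_weights = c(3, 2, 1, 1, 1),
                              mz_window = c(1000, 1500)),
               17:19)
  expect_error(select_charges(10000), "window")
})

test_that("peak integration is exact for Gaussians and linear in intensity", {
  rt <- seq(0, 200, 1)
  eic <- data.frame(rt = rt, intensity = dnorm(rt, 100, 5))
  expect_equal(integrate_peak(eic, c(50, 150)), 1, tolerance = 1e-6)
  unit_height <- data.frame(rt = rt, intensity = dnorm(rt, 100, 5) /
                              dnorm(100, 100, 5))
  expect_equal(integrate_peak(unit_height, c(50, 150)), sqrt(2 * pi) * 5,
               tolerance = 1e-4)  # 12.533
  expect_equal(integrate_peak(data.frame(rt = rt, intensity = 0), c(50, 150)), 0)
  doubled <- eic; doubled$intensity <- 2 * eic$intensity
  expect_equal(integrate_peak(doubled, c(50, 150)),
               2 * integrate_peak(eic, c(50, 150)))
  expect_warning(a <- integrate_peak(eic, c(300, 310)), "empty")
  expect_equal(a, 0)
})

test_that("flank baseline subtraction removes constant backgrounds", {
  rt <- seq(0, 300, 3)
  sig <- 100 * dnorm(rt, 150, 5)
  eic <- data.frame(rt = rt, intensity = sig + 40)
  raw <- integrate_peak(eic, c(130, 170), baseline = "none")
  corr <- integrate_peak(eic, c(130, 170), baseline = "flank")
  expect_equal(corr, 100, tolerance = 0.01)
  expect_gt(raw, corr + 1000)
})

test_that("glycoform profiles normalise to 100% and flag empty input", {
  p <- glycoform_profile(c(G0F = 50, G1F = 30, G2F = 20))
  expect_equal(unname(p), c(50, 30, 20))
  expect_equal(sum(p), 100)
  expect_equal(unname(glycoform_profile(c(a = 7))), 100)
  expect_equal(unname(glycoform_profile(c(a = 1, b = 1, c = 1, d = 1))),
               rep(25, 4))
  expect_true(all(is.na(glycoform_profile(c(a = 0, b = 0)))))
})

test_that("subclass averages weight allotype profiles by abundance", {
  p <- c(G0F = 60, G1F = 40); q <- c(G0F = 20, G1F = 80)
  expect_equal(subclass_average(list(p), 1), p)
  expect_equal(subclass_average(list(p, q), c(1, 1)), (p + q) / 2)
  expect_equal(subclass_average(list(p, q), c(3, 1)), 0.75 * p + 0.25 * q)
})

test_that("allotype ratios behave at the boundaries", {
  expect_equal(allotype_ratio(5, 5), 0.5)
  expect_equal(allotype_ratio(5, 0), 1.0)
  expect_true(is.na(allotype_ratio(0, 0)))
})

test_that("occupancy arithmetic follows the anchor-glycoform scheme", {
  # anchor area 30 at 25% relative abundance implies 120 total double
  expect_equal(ch3_occupancy(30, 0.25, 900), 120 / (120 + 900),
               tolerance = 1e-12)  # 0.1176
  expect_equal(ch3_occupancy(30, 1.0, 900), 30 / 930, tolerance = 1e-12)
  expect_true(is.na(ch3_occupancy(30, 0, 900)))
})

test_that("intact occupancy conversion is exact, monotone and concave", {
  expect_equal(intact_occupancy(0), 0)
  expect_equal(intact_occupancy(1), 1)
  p <- seq(0, 1, 0.01)
  f <- intact_occupancy(p)
  expect_true(all(diff(f) > 0))            # monotone increasing
  expect_true(all(diff(diff(f)) < 1e-12))  # concave
  expect_error(intact_occupancy(1.2), "0, 1")
})

test_that("PTM levels are bounded percentages of the anchor pair", {
  expect_equal(ptm_level(5, 95), 5)
  expect_equal(ptm_level(0, 50), 0)
  expect_true(is.na(ptm_level(5, 0)))
  expect_equal(ptm_level(5, 95, bounded = FALSE), 100 * 5 / 95)
})

test_that("quantified relative abundances are normalised and scale-invariant", {
  pr <- five_allotype_profile()
  ref <- allotype_reference()
  run <- render_run(species_table(pr, ref), run_spec(seed = 8),
                    metadata = list(run_id = "r"))
  pre <- preprocess_run(run)
  q <- quantify_run(pre, names(pr$allotype_abundances), ref, deconv_run = run)
  for (a in names(q$profiles)) expect_equal(sum(q$profiles[[a]]), 100,
                                            tolerance = 1e-6)
  expect_equal(sum(q$allotype_abundance), 100, tolerance = 1e-6)
  expect_equal(sum(q$subclass_abundance), 100, tolerance = 1e-6)
  expect_true(all(q$allotype_ratios >= 0 & q$allotype_ratios <= 1))
  # scale invariance
  pre2 <- pre; pre2$intensity <- pre$intensity * 13
  run2 <- run; run2$intensity <- run$intensity * 13
  q2 <- quantify_run(pre2, names(pr$allotype_abundances), ref,
                     deconv_run = run2)
  expect_equal(q$profiles, q2$profiles, tolerance = 1e-9)
  expect_equal(q$allotype_ratios, q2$allotype_ratios, tolerance = 1e-9)
})

test_that("transition lists expose charges, m/z borders and RT windows", {
  pr <- five_allotype_profile()
  ref <- allotype_reference()
  run <- render_run(species_table(pr, ref), run_spec(seed = 8),
                    metadata = list(run_id = "r"))
  q <- quantify_run(preprocess_run(run), names(pr$allotype_abundances), ref,
                    deconv_run = run)
  f <- tempfile(fileext = ".tsv")
  tl <- export_transition_list(q, ref, f)
  expect_true(file.exists(f))
  expect_true(all(c("allotype", "species", "charge", "mz_lo", "mz_hi",
                    "rt_lo", "rt_hi") %in% names(tl)))
  expect_true(all(tl$mz_hi > tl$mz_lo))
  expect_equal(nrow(tl), 3 * nrow(q$targets))
})
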