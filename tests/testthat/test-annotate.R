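test_that("allotype calling recovers a five-allotype constitution", {
  pr <- five_allotype_profile()
  ref <- allotype_reference()
  tab <- species_table(pr, ref)
  run <- render_run(tab, run_spec(seed = 12), metadata = list(run_id = "r"))
  call <- call_allotypes_run(run, ref)
  expect_setequal(call$allotypes$name, names(pr$allotype_abundances))
  expect_true(all(call$allotypes$evidence_n >= 2))
})

test_that("an empty spectrum yields an empty call", {
  dec <- structure(list(mass = seq(23000, 27000), intensity = numeric(4001),
                        peaks = data.frame(mass = numeric(0),
                                           intensity = numeric(0),
                                           apex = numeric(0)),
                        threshold = NA, grid = 1),
                   class = "deconvolved_spectrum")
  call <- call_allotypes(dec)
  expect_equal(nrow(call$allotypes), 0)
})

test_that("calling is invariant to global intensity scaling", {
  pr <- five_allotype_profile()
  ref <- allotype_reference()
  run <- render_run(species_table(pr, ref), run_spec(noise_sd = 0),
                    metadata = list(run_id = "r"))
  scaled <- run
  scaled$intensity <- run$intensity * 50
  c1 <- call_allotypes_run(run, ref)
  c2 <- call_allotypes_run(scaled, ref)
  expect_identical(c1$allotypes$name, c2$allotypes$name)
  expect_identical(c1$allotypes$evidence_n, c2$allotypes$evidence_n)
})

test_that("at most two allotypes are retained per subclass", {
  # fabricate a deconvolved spectrum containing the calling ladders of all
  # three IGHG1 reference allotypes
  ref <- allotype_reference()
  ig1 <- ref[ref$subclass == "IgG1", ]
  masses <- unlist(lapply(ig1$backbone_mass_avg, function(b)
    b + glycan_mass(c("H3N4F1", "H4N4F1", "H5N4F1"))))
  dec <- structure(list(
    peaks = data.frame(mass = masses, intensity = rep(c(3, 2, 1), each = 3),
                       apex = 1)), class = "deconvolved_spectrum")
  call <- call_allotypes(dec, ref)
  expect_equal(sum(call$allotypes$subclass == "IgG1"), 2)
  # the two best-supported ladders win
  expect_setequal(call$allotypes$name[call$allotypes$subclass == "IgG1"],
                  ig1$name[order(-c(3, 2, 1))][1:2])
})

test_that("double-glycan annotation matches constructed identities", {
  b <- 24095.9
  obs <- b + glycan_mass("H3N4F1") + glycan_mass("H5N2")
  ann <- annotate_double_glyc(obs, b)
  expect_gte(nrow(ann$candidates), 1)
  top <- ann$candidates[1, ]
  expect_equal(abs(top$delta), 0, tolerance = 1e-9)
  # the site swap (H5N2 on CH2, H3N4F1 on CH3) is isobaric and co-reported
  expect_true(any(ann$candidates$ch2 == "H3N4F1" & ann$candidates$ch3 == "H5N2"))
  expect_true(any(ann$candidates$ch2 == "H5N2" & ann$candidates$ch3 == "H3N4F1"))
})

test_that("a +1 hexose shift moves every top candidate up by one hexose", {
  b <- 24095.9
  obs <- b + glycan_mass("H3N4F1") + glycan_mass("H5N2") + glycan_mass("H1")
  ann <- annotate_double_glyc(obs, b)
  bf <- brute_force_double(obs, b, iggfc:::CH2_GLYCANS, iggfc:::CH3_GLYCANS, 1.5)
  expect_equal(nrow(ann$candidates), nrow(bf))
  tot_hex <- glycan_composition(ann$candidates$ch2)[, "H"] +
    glycan_composition(ann$candidates$ch3)[, "H"]
  expect_true(all(tot_hex == 9))  # one hexose more than H3..+H5..
})

test_that("zero tolerance with an offset mass yields an empty result", {
  b <- 24095.9
  obs <- b + glycan_mass("H3N4F1") + glycan_mass("H5N2") + 0.5
  ann <- annotate_double_glyc(obs, b, tol = 0)
  expect_equal(nrow(ann$candidates), 0)
  expect_false(is.null(ann$nearest_miss))
})

test_that("annotation equals exhaustive enumeration on random cases", {
  set.seed(11)
  b <- 24057.9
  for (i in 1:100) {
    obs <- b + runif(1, 2400, 3600)
    tol <- sample(c(0.5, 1.5, 3), 1)
    ann <- annotate_double_glyc(obs, b, tol = tol)
    bf <- brute_force_double(obs, b, iggfc:::CH2_GLYCANS,
                             iggfc:::CH3_GLYCANS, tol)
    expect_equal(nrow(ann$candidates), nrow(bf))
    if (nrow(bf)) {
      expect_equal(sort(paste(ann$candidates$ch2, ann$candidates$ch3)),
                   sort(paste(bf$ch2, bf$ch3)))
      expect_equal(abs(ann$candidates$delta), sort(abs(bf$delta)),
                   tolerance = 1e-9)
    }
  }
})
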