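make_features <- function(n_pat = 8, seed = 1, effect = 0) {
  set.seed(seed)
  frs <- c("total_plasma", "total_SF", "ACPA_plasma", "ACPA_SF")
  out <- expand.grid(patient = sprintf("P%02d", seq_len(n_pat)),
                     fraction = frs, stringsAsFactors = FALSE)
  base <- matrix(rnorm(nrow(out) * 5), ncol = 5,
                 dimnames = list(NULL, paste0("f", 1:5)))
  base[grepl("ACPA", out$fraction), 1:2] <-
    base[grepl("ACPA", out$fraction), 1:2] + effect
  cbind(out, as.data.frame(base))
}

test_that("per-patient centering zeroes identical fraction profiles", {
  f <- make_features()
  for (p in unique(f$patient))  # make all four fractions identical per patient
    f[f$patient == p, -(1:2)] <- f[f$patient == p, -(1:2)][rep(1, 4), ]
  pca <- pca_fractions(f, mode = "per_patient_centered")
  expect_true(all(abs(pca$scores$PC1) < 1e-10))
})

test_that("duplicated feature rows give identical scores", {
  f <- make_features(effect = 1)
  f2 <- rbind(f, f[1, ])
  pca <- pca_fractions(f2, mode = "per_patient_centered")
  n <- nrow(f)
  expect_equal(unlist(pca$scores[n + 1, -(1:2)]),
               unlist(pca$scores[1, -(1:2)]), tolerance = 1e-9)
})

test_that("PCA separates fraction groups under a configured effect", {
  f <- make_features(n_pat = 12, seed = 4, effect = 3)
  pca <- pca_fractions(f, mode = "per_patient_centered")
  lab <- ifelse(grepl("ACPA", pca$scores$fraction), "ACPA", "total")
  expect_gt(silhouette_score(pca$scores[, c("PC1", "PC2")], lab), 0)
})

test_that("PCA refuses fewer than three rows and imputes missing values", {
  f <- make_features()[1:2, ]
  expect_error(pca_fractions(f), "3 rows")
  f2 <- make_features()
  f2$f1[3] <- NA
  expect_silent(pca_fractions(f2))
  # concatenated mode: one row per patient
  pc <- pca_fractions(make_features(), mode = "concatenated")
  expect_equal(nrow(pc$scores), 8)
})

test_that("paired tests handle identical and degenerate inputs", {
  x <- matrix(rnorm(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  res <- paired_tests(x, x)
  expect_equal(res$p, c(1, 1))
  expect_equal(res$t, c(0, 0))
  shifted <- x + 2  # zero-variance non-zero differences
  res2 <- paired_tests(shifted, x)
  expect_true(all(res2$degenerate))
  expect_true(all(is.na(res2$p)))
  # NA pairs are dropped
  x2 <- x; x2[1, 1] <- NA
  expect_equal(paired_tests(x2, x)$n, c(9, 10))
})

test_that("paired t-test rejection rate matches analytic power", {
  n <- 11; d <- 1; nsim <- 400
  set.seed(123)
  rej <- 0
  for (i in seq_len(nsim)) {
    diffs <- rnorm(n, mean = d, sd = 1)
    res <- paired_tests(matrix(diffs, ncol = 1), matrix(0, n, 1))
    if (res$p < 0.05) rej <- rej + 1
  }
  pow <- power.t.test(n = n, delta = d, sd = 1, sig.level = 0.05,
                      type = "paired")$power
  mc_se <- sqrt(pow * (1 - pow) / nsim)
  expect_lt(abs(rej / nsim - pow), 4 * mc_se)
})

test_that("Sidak adjustment matches the closed form and is monotone", {
  expect_equal(sidak_adjust(0.05, k = 1), 0.05)
  expect_equal(sidak_adjust(0.01, k = 4), 1 - 0.99^4)  # 0.0394
  expect_equal(sidak_adjust(0, k = 7), 0)
  p <- seq(0, 1, 0.05)
  expect_true(all(diff(sidak_adjust(p, k = 4)) >= 0))       # monotone in p
  expect_true(all(sidak_adjust(0.2, k = 1:6) ==
                    cummax(sidak_adjust(0.2, k = 1:6))))    # monotone in k
})

test_that("predefined fraction comparisons are Sidak-adjusted together", {
  cfg <- cohort_config()
  tr <- do.call(rbind, lapply(1:6, function(i)
    sample_patient(cfg, sprintf("P%02d", i), seed = i)$truth))
  cmp <- list(c("total_plasma", "ACPA_plasma"), c("total_SF", "ACPA_SF"),
              c("ACPA_plasma", "ACPA_SF"), c("total_plasma", "total_SF"))
  res <- sidak_comparisons(tr, "afucosylation", cmp, unit = "IgG1")
  expect_equal(nrow(res), 4)
  expect_equal(res$p_adj, 1 - (1 - res$p)^4, tolerance = 1e-12)
  # ACPA afucosylation is constructed lower than total: strong signal
  expect_lt(res$p_adj[1], 0.05)
})

test_that("Spearman correlations use pairwise deletion and a pair minimum", {
  x <- data.frame(a = 1:10, b = c(1:8, NA, NA))
  y <- data.frame(c = (1:10)^2, d = c(NA, NA, NA, NA, NA, NA, NA, 8:10))
  res <- spearman_matrix(x, y, min_pairs = 4)
  expect_equal(res$rho["a", "c"], 1)           # perfectly monotone
  expect_equal(res$n["b", "d"], 1)
  expect_false(res$available["b", "d"])        # < 4 pairs: flagged
  expect_true(is.na(res$rho["b", "d"]))
  expect_equal(res$n["a", "d"], 3)
  expect_false(res$available["a", "d"])
})

test_that("permuted pairings give correlations centred at zero", {
  set.seed(77)
  x <- data.frame(a = rnorm(30))
  rhos <- replicate(200, {
    y <- data.frame(c = sample(x$a))
    spearman_matrix(x, y)$rho[1, 1]
  })
  expect_lt(abs(mean(rhos)), 0.05)
})
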