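#' Principal component analysis of IgG fraction features
#'
#' Missing values are imputed with the minimum positive number used in the
#' profiling workflow (0.01), columns are standardised, and a standard PCA is
#' computed. In `per_patient_centered` mode each patient's mean feature vector
#' (over their four fractions) is subtracted before the PCA, so the analysis
#' reflects within-patient differences between fractions; in `concatenated`
#' mode each patient is one row with the features of all four fractions side
#' by side.
#'
#' @param features data.frame with `patient`, `fraction` and numeric feature
#'   columns (see [traits_feature_matrix()]).
#' @param mode `"per_patient_centered"` or `"concatenated"`.
#' @param impute_value imputation constant for missing values (default 0.01).
#' @return list of class `fraction_pca`: `scores` (data.frame with `patient`,
#'   `fraction` where applicable, and PCs), `loadings`, `sdev`,
#'   `var_explained`.
#' @export
pca_fractions <- function(features, mode = c("per_patient_centered",
                                             "concatenated"),
                          impute_value = 0.01) {
  mode <- match.arg(mode)
  num <- vapply(features, is.numeric, logical(1))
  num[names(features) %in% c("patient", "fraction")] <- FALSE
  X <- as.matrix(features[, num, drop = FALSE])
  X[is.na(X)] <- impute_value
  if (mode == "concatenated") {
    pats <- unique(features$patient)
    frs <- unique(features$fraction)
    wide <- matrix(NA_real_, length(pats), ncol(X) * length(frs),
                   dimnames = list(pats, paste(rep(frs, each = ncol(X)),
                                               rep(colnames(X), length(frs)),
                                               sep = ".")))
    for (i in seq_len(nrow(features)))
      wide[match(features$patient[i], pats),
           (match(features$fraction[i], frs) - 1) * ncol(X) + seq_len(ncol(X))] <-
        X[i, ]
    wide[is.na(wide)] <- impute_value
    X <- wide
    keys <- data.frame(patient = pats, stringsAsFactors = FALSE)
  } else {
    keys <- features[, c("patient", "fraction")]
  }
  if (nrow(X) < 3) stop("PCA needs at least 3 rows")
  sds <- apply(X, 2, stats::sd)
  X <- scale(X, center = TRUE, scale = ifelse(sds > 0, sds, 1))
  if (mode == "per_patient_centered") {
    for (p in unique(keys$patient)) {
      r <- keys$patient == p
      X[r, ] <- sweep(X[r, , drop = FALSE], 2,
                      colMeans(X[r, , drop = FALSE]))
    }
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  scores <- cbind(keys, as.data.frame(pc$x))
  structure(list(scores = scores, loadings = pc$rotation, sdev = pc$sdev,
                 var_explained = pc$sdev^2 / sum(pc$sdev^2)),
            class = "fraction_pca")
}

#' Mean silhouette width between groups
#'
#' Average silhouette width of points labelled by group, a scale-free measure
#' of group separation (positive values mean points lie closer to their own
#' group than to the other).
#'
#' @param x numeric matrix (e.g. PC1/PC2 scores).
#' @param labels group labels, one per row.
#' @return mean silhouette width.
#' @export
silhouette_score <- function(x, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Paired t-tests per feature
#'
#' Two-sided paired t-tests, feature by feature; pairs with a missing value
#' are dropped. Two degenerate situations are distinguished: all differences
#' exactly zero gives t = 0, p = 1; differences with zero variance but
#' non-zero mean are flagged degenerate (p is undefined).
#'
#' @param x,y numeric matrices or data.frames of paired observations (same
#'   dimensions; rows are pairs, columns are features), or plain vectors.
#' @return data.frame with `feature`, `n`, `estimate` (mean difference), `t`,
#'   `p`, `degenerate`.
#' @export
paired_tests <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(identical(dim(x), dim(y)))
  feats <- colnames(x)
  if (is.null(feats)) feats <- paste0("V", seq_len(ncol(x)))
  rows <- lapply(seq_len(ncol(x)), function(j) {
    d <- x[, j] - y[, j]
    d <- d[!is.na(d)]
    n <- length(d)
    if (n < 2)
      return(data.frame(feature = feats[j], n = n, estimate = NA_real_,
                        t = NA_real_, p = NA_real_, degenerate = TRUE))
    if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), 1)) {
      if (all(abs(d) <= 1e-12))
        return(data.frame(feature = feats[j], n = n, estimate = 0, t = 0,
                          p = 1, degenerate = FALSE))
      return(data.frame(feature = feats[j], n = n, estimate = mean(d),
                        t = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    tt <- stats::t.test(d)
    data.frame(feature = feats[j], n = n, estimate = unname(tt$estimate),
               t = unname(tt$statistic), p = tt$p.value, degenerate = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sidak adjustment for predefined comparisons
#'
#' Adjusts p-values for a family of `k` predefined comparisons:
#' `p_adj = 1 - (1 - p)^k`.
#'
#' @param p numeric vector of raw p-values.
#' @param k family size (default: number of p-values supplied).
#' @return adjusted p-values.
#' @examples
#' sidak_adjust(0.01, k = 4)  # 0.0394
#' @export
sidak_adjust <- function(p, k = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), k >= 1)
  1 - (1 - p)^k
}

#' Paired comparisons with Sidak adjustment
#'
#' Runs [paired_tests()] for each predefined comparison of fractions on
#' complete cases and adjusts the p-values for the family of comparisons.
#'
#' @param traits trait table with `patient` and `fraction` columns.
#' @param feature trait column to test.
#' @param comparisons list of `c(fraction1, fraction2)` pairs.
#' @param level,unit optional filters on the trait-table rows.
#' @return data.frame with one row per comparison and `p_adj`.
#' @export
sidak_comparisons <- function(traits, feature, comparisons,
                              level = "subclass", unit = NULL) {
  tt <- traits[traits$level == level, ]
  if (!is.null(unit)) tt <- tt[tt$unit == unit, ]
  rows <- lapply(comparisons, function(cmp) {
    a <- tt[tt$fraction == cmp[1], c("patient", feature)]
    b <- tt[tt$fraction == cmp[2], c("patient", feature)]
    pats <- intersect(a$patient, b$patient)
    x <- a[[feature]][match(pats, a$patient)]
    y <- b[[feature]][match(pats, b$patient)]
    res <- paired_tests(matrix(x, ncol = 1), matrix(y, ncol = 1))
    data.frame(comparison = paste(cmp, collapse = " vs "), n = res$n,
               estimate = res$estimate, t = res$t, p = res$p,
               degenerate = res$degenerate)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- sidak_adjust(out$p, k = length(comparisons))
  rownames(out) <- NULL
  out
}

#' Spearman correlation of traits with clinical parameters
#'
#' Spearman rho and p-value per (feature, clinical variable) pair using
#' pairwise-complete observations; cells based on fewer than `min_pairs`
#' complete pairs are flagged unavailable (rho and p set to `NA`).
#'
#' @param traits data.frame of numeric features, one row per patient.
#' @param clinical data.frame of clinical variables, same rows/patients.
#' @param min_pairs minimum number of complete pairs per cell (default 4).
#' @return list with matrices `rho`, `p`, `n` and logical `available`.
#' @export
spearman_matrix <- function(traits, clinical, min_pairs = 4) {
  traits <- as.data.frame(traits); clinical <- as.data.frame(clinical)
  tn <- names(traits)[vapply(traits, is.numeric, logical(1))]
  cn <- names(clinical)[vapply(clinical, is.numeric, logical(1))]
  rho <- p <- n <- matrix(NA_real_, length(tn), length(cn),
                          dimnames = list(tn, cn))
  avail <- matrix(FALSE, length(tn), length(cn), dimnames = list(tn, cn))
  for (i in seq_along(tn)) for (j in seq_along(cn)) {
    x <- traits[[tn[i]]]; y <- clinical[[cn[j]]]
    ok <- stats::complete.cases(x, y)
    n[i, j] <- sum(ok)
    if (n[i, j] >= min_pairs) {
      ct <- suppressWarnings(stats::cor.test(x[ok], y[ok], method = "spearman",
                                             exact = FALSE))
      rho[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
      avail[i, j] <- TRUE
    }
  }
  list(rho = rho, p = p, n = n, available = avail)
}
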