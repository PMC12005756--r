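# Small acquisition spec for fast unit tests: narrow windows, short gradient.
small_spec <- function(...) {
  run_spec(rt_window = c(600, 800), mz_window = c(1050, 1500),
           scan_interval = 3, ...)
}

# Minimal species table for hand-built rendering tests.
species_rows <- function(mass, rt, abundance) {
  data.frame(mass = mass, rt = rt, abundance = abundance)
}

# A compact five-allotype fraction profile (heterozygous IgG1 and IgG2,
# homozygous IgG4, no IgG3) used by annotation tests.
five_allotype_profile <- function() {
  g <- c(H3N4F1 = 0.40, H4N4F1 = 0.30, H5N4F1 = 0.15, H3N5F1 = 0.10,
         none = 0.05)
  al <- c("IGHG1*01", "IGHG1*03", "IGHG2*01", "IGHG2*02", "IGHG4*01")
  fraction_profile(
    "total_plasma",
    stats::setNames(c(0.35, 0.25, 0.15, 0.10, 0.15), al),
    lapply(stats::setNames(al, al), function(a) g))
}

# Literal re-implementation of the derived-trait formulas, used as an
# independent oracle: plain loops, no shared code with derive_traits().
brute_force_traits <- function(profile) {
  a <- 100 * profile / sum(profile)
  tot_complex <- 0; gal <- 0; agal <- 0; sia <- 0; afu <- 0; bis <- 0
  hm <- 0; none <- 0
  for (nm in names(a)) {
    if (nm == "none") { none <- none + a[[nm]]; next }
    cnt <- c(H = 0, N = 0, F = 0, S = 0)
    for (tok in regmatches(nm, gregexpr("[HNFS]\\d+", nm))[[1]])
      cnt[substr(tok, 1, 1)] <- as.integer(substring(tok, 2))
    if (cnt[["N"]] <= 1) next                      # stub
    if (cnt[["N"]] == 2 && cnt[["H"]] >= 4) {      # high mannose
      hm <- hm + a[[nm]]; next
    }
    tot_complex <- tot_complex + a[[nm]]
    ngal <- min(2, max(0, cnt[["H"]] - 3))
    gal <- gal + a[[nm]] * ngal / 2
    if (ngal == 0) agal <- agal + a[[nm]]
    sia <- sia + a[[nm]] * min(2, cnt[["S"]]) / 2
    if (cnt[["F"]] == 0) afu <- afu + a[[nm]]
    if (cnt[["N"]] >= 5) bis <- bis + a[[nm]]
  }
  c(galactosylation = if (tot_complex > 0) 100 * gal / tot_complex else NA,
    agalactosylation = if (tot_complex > 0) 100 * agal / tot_complex else NA,
    sialylation = if (tot_complex > 0) 100 * sia / tot_complex else NA,
    afucosylation = if (tot_complex > 0) 100 * afu / tot_complex else NA,
    bisection = if (tot_complex > 0) 100 * bis / tot_complex else NA,
    high_mannose = hm, non_glycosylated = none)
}

# Independent brute force for the combinatorial double-glycan annotation.
brute_force_double <- function(observed, backbone, ch2set, ch3set, tol) {
  hits <- list()
  for (c2 in ch2set) for (c3 in ch3set) {
    m <- backbone + glycan_mass(c2) + glycan_mass(c3)
    if (abs(observed - m) <= tol)
      hits[[length(hits) + 1]] <- data.frame(ch2 = c2, ch3 = c3,
                                             delta = observed - m)
  }
  if (!length(hits)) return(data.frame(ch2 = character(0), ch3 = character(0),
                                       delta = numeric(0)))
  out <- do.call(rbind, hits)
  out[order(abs(out$delta)), ]
}

random_composition <- function() {
  paste0("H", sample(0:9, 1), "N", sample(0:9, 1),
         "F", sample(0:2, 1), "S", sample(0:2, 1))
}
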