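test_that("hybrid BLUEs equal cell means on balanced data and the GLS solution otherwise", {
  ds <- tiny_design(n_env = 1, r = 3, nf = 3, nm = 2)
  rec <- tiny_trial_records(ds, seed = 1)
  b <- fit_blues(rec, "GY")
  means <- tapply(rec$GY, rec$hybrid, mean)
  expect_equal(b[names(means)], c(means[]), tolerance = 1e-6,
               ignore_attr = TRUE)

  # unbalanced toy: one missing cell -> matches a brute-force GLS solve
  # assembled from the same mixed model's variance estimates
  rec2 <- rec[-3, ]
  b2 <- fit_blues(rec2, "GY")
  fit <- lme4::lmer(GY ~ 0 + hybrid + (1 | rep),
                    data = transform(rec2, hybrid = factor(hybrid),
                                     rep = factor(rep)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  Zr <- stats::model.matrix(~ 0 + factor(rec2$rep))
  V <- vc$vcov[1] * tcrossprod(Zr) + vc$vcov[2] * diag(nrow(rec2))
  X <- stats::model.matrix(~ 0 + factor(rec2$hybrid))
  beta <- solve(t(X) %*% solve(V, X), t(X) %*% solve(V, rec2$GY))
  expect_equal(unname(b2), as.numeric(beta), tolerance = 1e-6)

  expect_error(fit_blues(rec[rec$hybrid == "F01xM01", ], "GY"), ">= 2 hybrids")
})

test_that("band-wise BLUE matrices agree with per-band fits", {
  ds <- tiny_design(n_env = 1, r = 2, nf = 3, nm = 3)
  sp <- simulate_spectra_records(ds, spectra_gen_spec(stop = 410, n_basis = 6),
                                 seed = 2)
  B <- fit_blues_matrix(sp$records, sp$spectra)
  expect_equal(dim(B), c(9, 20))
  one <- fit_blues(cbind(sp$records, y = sp$spectra[, 7]), "y")
  expect_equal(B[names(one), 7], one, tolerance = 1e-6)
})

test_that("single-environment REML recovers planted variance components", {
  comps <- c(female = 4, male = 4, sca = 1, env = 0, female_env = 0,
             male_env = 0, sca_env = 0, rep_env = 0.5, residual = 2)
  ds <- design_spec(8, 8, environments = "E1", replicates = 2)
  ests <- vapply(1:150, function(i) {
    rec <- tiny_trial_records(ds, seed = 3000 + i, components = comps)
    reml_single_env(rec, "GY")$estimates
  }, numeric(5))
  truth <- c(female = 4, male = 4, sca = 1, rep_env = 0.5, residual = 2)
  for (nm in names(truth)) {
    mc_se <- stats::sd(ests[nm, ]) / sqrt(ncol(ests))
    expect_lt(abs(mean(ests[nm, ]) - truth[[nm]]), 3.3 * mc_se)
  }
})

test_that("null genetic signal drives genetic components to the zero boundary", {
  comps <- c(female = 0, male = 0, sca = 0, env = 0, female_env = 0,
             male_env = 0, sca_env = 0, rep_env = 0, residual = 1)
  ds <- design_spec(6, 6, environments = "E1", replicates = 2)
  at_zero <- vapply(1:150, function(i) {
    rec <- tiny_trial_records(ds, seed = 5000 + i, components = comps)
    est <- reml_single_env(rec, "GY")$estimates
    est[c("female", "male", "sca")] < 1e-8
  }, logical(3))
  # asymptotically ~50% of null REML estimates sit on the boundary
  expect_gt(mean(at_zero), 0.4)
})

test_that("degenerate and multi-environment inputs are handled explicitly", {
  ds <- tiny_design(n_env = 1)
  rec <- tiny_trial_records(ds, seed = 4)
  rec$flat <- 5
  vc <- reml_single_env(rec, "flat")
  expect_true(all(vc$estimates == 0))
  ds2 <- tiny_design(n_env = 3)
  rec2 <- tiny_trial_records(ds2, seed = 5)
  expect_error(reml_single_env(rec2, "GY"), "reml_combined")
  expect_error(reml_combined(rec, "GY"), ">= 2 environments")
})

test_that("combined REML estimates all terms and percent columns sum to 100", {
  ds <- design_spec(8, 8, environments = paste0("E", 1:4), replicates = 2)
  rec <- tiny_trial_records(ds, seed = 6, components = gy_components)
  vc <- reml_combined(rec, "GY")
  expect_named(vc$estimates, c("female", "male", "sca", "env", "female_env",
                               "male_env", "sca_env", "rep_env", "residual"))
  expect_true(all(vc$estimates >= 0))
  expect_equal(sum(vc$percents), 100, tolerance = 0.2)
  # estimates are invariant to record shuffling and to a constant shift
  perm <- sample(nrow(rec))
  vc2 <- reml_combined(rec[perm, ], "GY")
  expect_equal(vc2$estimates, vc$estimates, tolerance = 1e-2)
  rec$GY <- rec$GY + 100
  vc3 <- reml_combined(rec, "GY")
  expect_equal(vc3$estimates, vc$estimates, tolerance = 1e-2)
})

test_that("omitted environment structure is absorbed by the remaining terms", {
  comps <- c(female = 0.5, male = 0.5, sca = 0, env = 3, female_env = 0,
             male_env = 0, sca_env = 0, rep_env = 0, residual = 1)
  ds <- design_spec(6, 6, environments = paste0("E", 1:6), replicates = 2)
  rec <- tiny_trial_records(ds, seed = 7, components = comps)
  full <- reml_combined(rec, "GY")
  reduced <- reml_combined(rec, "GY",
                           drop = c("env", "female_env", "male_env",
                                    "sca_env", "rep_env"))
  inflation <- reduced$estimates[["residual"]] - full$estimates[["residual"]]
  # residual picks up roughly the omitted between-environment variance
  expect_lt(abs(inflation - full$estimates[["env"]]),
            0.5 * full$estimates[["env"]])
  expect_gt(inflation, 1)
})

test_that("likelihood-ratio tests behave at the null, the boundary, and under strong signal", {
  ds <- design_spec(6, 6, environments = "E1", replicates = 2)
  rec <- tiny_trial_records(ds, seed = 8)
  full <- reml_single_env(rec, "GY")
  # identical fits: statistic 0, p 1
  out <- lrt_term(full, full)
  expect_equal(out$statistic, 0)
  expect_equal(out$p, 1)
  expect_error(lrt_term(reml_single_env(rec, "GY", drop = "sca"), full),
               "nested")

  # type-I error under a true-zero component stays below nominal 5%
  # (boundary makes the plain chi-square 1 reference conservative)
  comps0 <- c(female = 0, male = 1, sca = 0.3, env = 0, female_env = 0,
              male_env = 0, sca_env = 0, rep_env = 0.2, residual = 1)
  rejections <- vapply(1:200, function(i) {
    r <- tiny_trial_records(ds, seed = 7000 + i, components = comps0)
    f <- reml_single_env(r, "GY")
    red <- reml_single_env(r, "GY", drop = "female")
    lrt_term(f, red)$p < 0.05
  }, logical(1))
  expect_lte(mean(rejections), 0.05)

  # a planted female component 5x the residual is detected essentially always
  comps1 <- replace(comps0, c("female", "residual"), c(5, 1))
  strong <- vapply(1:60, function(i) {
    r <- tiny_trial_records(ds, seed = 9000 + i, components = comps1)
    f <- reml_single_env(r, "GY")
    red <- reml_single_env(r, "GY", drop = "female")
    lrt_term(f, red)$p < 0.001
  }, logical(1))
  expect_gte(mean(strong), 0.95)

  # per-term LRT table carries significance stars
  vc <- reml_single_env(rec, "GY", lrt = TRUE)
  expect_setequal(vc$lrt$term, c("female", "male", "sca", "rep_env"))
  expect_true(all(vc$lrt$p >= 0 & vc$lrt$p <= 1))
})

test_that("heritability formulas follow their closed forms", {
  v <- c(female = 1, male = 1, sca = 0, residual = 2)
  h <- heritability_single(v, r = 2)
  expect_equal(h$H2, 2 / 3)           # g=2, e/r=1
  expect_equal(h$h2, h$h2_f + h$h2_m) # additive split
  expect_equal(heritability_single(c(female = 1, male = 1, sca = 1,
                                     residual = 0), r = 3)$H2, 1)

  hc <- heritability_combined(c(female = 2, male = 1, sca = 1, female_env = 1,
                                male_env = 0.5, sca_env = 0.5, residual = 2),
                              t = 4, r = 2)
  den <- 4 + 2 / 4 + 2 / 8
  expect_equal(hc$H2, 4 / den)
  expect_equal(hc$h2, 3 / den)
  expect_equal(hc$h2_f, 2 / den)
  # no G x E, no residual -> heritability 1
  expect_equal(heritability_combined(c(hybrid = 5, hybrid_env = 0,
                                       residual = 0), t = 2, r = 1)$H2, 1)
  expect_error(heritability_combined(c(hybrid = 1, hybrid_env = 1), t = 2, r = 2),
               "residual")
  expect_error(heritability_single(c(female = 0, male = 0, sca = 0,
                                     residual = 0), r = 2), "denominator")
})

test_that("coefficient of residual variation matches its definition", {
  expect_equal(cve(c(residual = 1), mean = 10), 10)
  expect_equal(cve(c(residual = 0), mean = 3), 0)
  expect_error(cve(c(residual = 1), mean = 0), "zero")
})

test_that("presentation rounding is half-up", {
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(0.825, 2), 0.83)
  expect_equal(round_half_up(-0.4, 0), 0)
})

test_that("band-wise decomposition recovers configured spectral shares and heritability", {
  sh <- c(female = 0.20, male = 0.25, sca = 0.05, env = 0.30, gxe = 0.12,
          rep = 0.02, residual = 0.06)
  ds <- design_spec(6, 6, environments = paste0("E", 1:4), replicates = 2)
  n_bands <- 12
  set.seed(11)
  fem_share <- matrix(NA_real_, 20, n_bands)
  H2 <- matrix(NA_real_, 20, n_bands)
  for (rep_i in 1:20) {
    sp <- simulate_spectra_records(
      ds, spectra_gen_spec(stop = 406, shares = sh, n_basis = 5),
      seed = 400 + rep_i)
    dec <- spectra_band_decomposition(sp$spectra, sp$records, r = 2)
    fem_share[rep_i, ] <- dec$percents[, "female"]
    H2[rep_i, ] <- dec$heritability$H2
  }
  expect_equal(mean(fem_share), 20, tolerance = 3)
  expected_H2 <- heritability_combined(
    c(hybrid = 0.50, hybrid_env = 0.12, residual = 0.06), t = 4, r = 2)$H2
  expect_equal(mean(H2), expected_H2, tolerance = 0.03)
  # zero-genetics spectra have a flat ~0 heritability profile
  sh0 <- c(female = 0, male = 0, sca = 0, env = 0.6, gxe = 0,
           rep = 0, residual = 0.4)
  sp0 <- simulate_spectra_records(
    ds, spectra_gen_spec(stop = 406, shares = sh0, n_basis = 5), seed = 12)
  dec0 <- spectra_band_decomposition(sp0$spectra, sp0$records, r = 2)
  expect_lt(mean(dec0$heritability$H2, na.rm = TRUE), 0.15)
})

test_that("the trial report assembles estimates, stars, heritability, and CVe", {
  ds <- tiny_design(n_env = 2, nf = 6, nm = 6)
  rec <- tiny_trial_records(ds, seed = 90)
  rep <- varcomp_report(rec, "GY")
  expect_named(rep, c("components", "heritability", "cve", "varcomp"))
  expect_equal(nrow(rep$components), 9)
  tested <- rep$components$term != "residual"  # residual carries no LRT
  expect_true(all(rep$components$stars[tested] %in% c("NS", "*", "**", "***")))
  expect_true(is.na(rep$components$stars[!tested]))
  expect_equal(sum(rep$components$percent), 100, tolerance = 0.3)
  expect_true(rep$heritability$H2 >= rep$heritability$h2)
  expect_gt(rep$cve, 0)
})
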