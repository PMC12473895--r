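# BLUE-level record table for a design without fitting anything
blue_table <- function(n_env = 8, seed = 51) {
  ds <- design_spec(10, 10, environments = paste0("E", seq_len(n_env)))
  rec <- design_records(ds)
  rec <- rec[rec$rep == "R1", c("env", "female", "male", "hybrid")]
  rec$record_id <- paste(rec$env, rec$hybrid, sep = "_")
  set.seed(seed)
  rec$GY <- stats::rnorm(nrow(rec), 6, 1)
  rec
}

test_that("partitions reproduce the factorial trial's printed record counts", {
  rec8 <- blue_table(8)
  # CV1 agronomic: 70 x 8 = 560 training, 30 x 8 = 240 testing records
  p <- make_partitions(rec8, "CV1", n_repeats = 3, seed = 1)[[1]]
  expect_length(p$train, 560)
  expect_length(p$masked, 240)
  # CV2/CV3 agronomic: 70 x 7 = 490 training, 30 x 7 + 100 = 310 masked
  p2 <- make_partitions(rec8, "CV2", n_repeats = 1, held_out_env = "E1",
                        seed = 2)[[1]]
  expect_length(p2$train, 490)
  expect_length(p2$masked, 310)
  # kernel traits run in 4 environments: 280/120 and 210/190
  rec4 <- blue_table(4)
  p3 <- make_partitions(rec4, "CV1", n_repeats = 1, seed = 3)[[1]]
  expect_length(p3$train, 280)
  expect_length(p3$masked, 120)
  p4 <- make_partitions(rec4, "CV3", n_repeats = 1, held_out_env = "E4",
                        seed = 4)[[1]]
  expect_length(p4$train, 210)
  expect_length(p4$masked, 190)

  # hybrid split is a disjoint 70:30 cover, deterministic under the seed
  expect_length(intersect(p$train_hybrids, p$test_hybrids), 0)
  expect_setequal(c(p$train_hybrids, p$test_hybrids), unique(rec8$hybrid))
  again <- make_partitions(rec8, "CV1", n_repeats = 3, seed = 1)
  expect_identical(lapply(again, `[[`, "masked"),
                   lapply(make_partitions(rec8, "CV1", n_repeats = 3, seed = 1),
                          `[[`, "masked"))
  expect_error(make_partitions(rec8, "CV2", seed = 1), "held_out_env")
  expect_error(make_partitions(rec8, "CV3", held_out_env = "nope", seed = 1),
               "absent")
})

test_that("scoring computes per-environment correlations over the scheme's target records", {
  rec <- blue_table(4)
  p <- make_partitions(rec, "CV1", n_repeats = 1, seed = 5)[[1]]
  # perfect predictions -> r = 1 in every environment
  preds <- stats::setNames(rec$GY, rec$record_id)
  tab <- score_partition(preds, p, rec, "GY", model = "GP")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$r, rep(1, 4))
  expect_true(all(tab$n == 30))
  # sign-flipped predictions -> r = -1
  tab2 <- score_partition(-preds, p, rec, "GY")
  expect_equal(tab2$r, rep(-1, 4))
  # CV2 scores 70 train hybrids, CV3 the 30 test hybrids, in the held-out env
  p2 <- make_partitions(rec, "CV2", n_repeats = 1, held_out_env = "E2",
                        seed = 6)[[1]]
  t2 <- score_partition(preds, p2, rec, "GY")
  expect_equal(t2$env, "E2"); expect_equal(t2$n, 70)
  p3 <- make_partitions(rec, "CV3", n_repeats = 1, held_out_env = "E2",
                        seed = 6)[[1]]
  t3 <- score_partition(preds, p3, rec, "GY")
  expect_equal(t3$n, 30)
  expect_error(score_partition(preds[-1], p, rec, "GY"), "missing")
})

test_that("accuracy summaries and the full scheme runner are reproducible", {
  ds <- design_spec(6, 5, environments = paste0("E", 1:2))
  tr <- simulate_trial(ds, trait_architecture(), spectra_spec = NULL,
                       n_markers = 300, seed = 52)
  inputs <- prediction_inputs(tr)
  acc <- run_scheme(inputs$records, "GY", models = "GP", scheme = "CV1",
                    n_repeats = 2, G_f = inputs$G_f, G_m = inputs$G_m,
                    H = inputs$H, scope = "combined", iters = 400,
                    burnin = 100, thin = 4, seed = 7)
  expect_equal(nrow(acc), 4)  # 2 repeats x 2 environments
  expect_true(all(abs(acc$r) <= 1))
  s <- summarize_accuracy(acc)
  expect_equal(s$n_repeats, 2L)
  acc2 <- run_scheme(inputs$records, "GY", models = "GP", scheme = "CV1",
                     n_repeats = 2, G_f = inputs$G_f, G_m = inputs$G_m,
                     H = inputs$H, scope = "combined", iters = 400,
                     burnin = 100, thin = 4, seed = 7)
  expect_identical(acc$r, acc2$r)
})

test_that("Tukey letters separate what the studentized range separates", {
  set.seed(53)
  base <- tibble::tibble(scheme = "CV1", rep = rep(1:10, 3), env = "E1",
                         trait = "GY",
                         model = rep(c("GP", "PP", "GP+PP"), each = 10))
  # identical accuracies: everyone shares one letter
  same <- base; same$r <- rep(stats::rnorm(10, 0.5, 0.02), 3)
  tc <- tukey_compare(same)
  expect_equal(length(unique(tc$summary$letters)), 1)
  # two models 10 SDs apart get distinct letters
  apart <- base
  apart$r <- c(stats::rnorm(10, 0.2, 0.01), stats::rnorm(10, 0.8, 0.01),
               stats::rnorm(10, 0.8, 0.01))
  tc2 <- tukey_compare(apart)
  s2 <- tc2$summary
  expect_false(s2$letters[s2$model == "GP"] ==
                 s2$letters[s2$model == "PP"])
  expect_equal(unname(s2$letters[s2$model == "PP"]),
               unname(s2$letters[s2$model == "GP+PP"]))

  # statistic matches a direct studentized-range computation on a 3-group toy
  rep_means <- stats::aggregate(r ~ model + rep, data = apart, FUN = mean)
  fit <- stats::aov(r ~ model, data = transform(rep_means, model = factor(model)))
  tk <- stats::TukeyHSD(fit)$model
  mse <- summary(fit)[[1]]["Residuals", "Mean Sq"]
  q_obs <- abs(diff(tapply(rep_means$r, rep_means$model, mean)[c("GP", "PP")])) /
    sqrt(mse / 10)
  p_direct <- stats::ptukey(q_obs, nmeans = 3, df = 27, lower.tail = FALSE)
  expect_equal(unname(tk["PP-GP", "p adj"]), unname(p_direct), tolerance = 1e-8)

  # agreement with multcomp's letter display on the same fit
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(model = "Tukey"))
  cld_letters <- multcomp::cld(glht)$mcletters$Letters
  ours <- tc2$summary$letters
  names(ours) <- tc2$summary$model
  # same partition into letter groups (letter names may differ)
  expect_equal(unname(ours["GP"] == ours["PP"]),
               unname(cld_letters["GP"] == cld_letters["PP"]))
  expect_equal(unname(ours["PP"] == ours["GP+PP"]),
               unname(cld_letters["PP"] == cld_letters["GP+PP"]))

  expect_error(tukey_compare(same[same$model == "GP", ]), ">= 2 models")
})

test_that("prediction accuracy rises with simulated heritability", {
  # single-environment CV1 at three entry-mean heritability levels
  ds <- design_spec(10, 10, environments = "E1", replicates = 2)
  lv <- c(0.2, 0.5, 0.8)
  acc_by_h2 <- matrix(NA_real_, 20, 3, dimnames = list(NULL, lv))
  geno <- list(female = simulate_parent_genotypes(10, 800, seed = 61, prefix = "F"),
               male = simulate_parent_genotypes(10, 800, seed = 62, prefix = "M"))
  for (j in seq_along(lv)) {
    g <- 1
    e <- 2 * g * (1 - lv[j]) / lv[j]  # H2 = g / (g + e/2)
    comps <- c(female = 0.45, male = 0.45, sca = 0.1, env = 0, female_env = 0,
               male_env = 0, sca_env = 0, rep_env = 0, residual = e)
    tr <- list(design = ds, genotypes = geno,
               phenotypes = simulate_trait_records(
                 ds, trait_architecture(comps, genomic = TRUE),
                 genotypes = geno, seed = 63 + j),
               spectra = NULL)
    inputs <- prediction_inputs(tr)
    acc <- run_scheme(inputs$records, "GY", models = "GP", scheme = "CV1",
                      n_repeats = 20, G_f = inputs$G_f, G_m = inputs$G_m,
                      H = inputs$H, scope = "single", iters = 1000,
                      burnin = 250, thin = 5, seed = 70 + j)
    acc_by_h2[, j] <- acc$r
  }
  m <- colMeans(acc_by_h2)
  expect_true(all(diff(m) > 0))
  # paired one-sided comparison of the extremes
  expect_lt(stats::t.test(acc_by_h2[, 3] - acc_by_h2[, 1],
                          alternative = "greater")$p.value, 0.05)
})
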