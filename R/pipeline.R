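#' Simulate a complete factorial trial
#'
#' One-call generator for a synthetic trial: parent genotypes, plot-level
#' trait records, and per-plot NIR spectra, all from a single seed.
#'
#' @param design A [design_spec()].
#' @param arch A [trait_architecture()] or list of them.
#' @param spectra_spec A [spectra_gen_spec()], or `NULL` to skip spectra.
#' @param n_markers Markers per parent panel (desk-scale default 2000).
#' @param seed Integer seed.
#' @return List with `design`, `genotypes` (list `female`, `male`),
#'   `hybrid_genotypes`, `phenotypes` (plot records), and `spectra`
#'   (see [simulate_spectra_records()]).
#' @export
simulate_trial <- function(design = design_spec(),
                           arch = trait_architecture(),
                           spectra_spec = spectra_gen_spec(),
                           n_markers = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genotypes <- list(
    female = simulate_parent_genotypes(design$n_female, n_markers, prefix = "F"),
    male = simulate_parent_genotypes(design$n_male, n_markers, prefix = "M")
  )
  phenotypes <- simulate_trait_records(design, arch, genotypes = genotypes)
  spectra <- if (!is.null(spectra_spec))
    simulate_spectra_records(design, spectra_spec)
  list(design = design,
       genotypes = genotypes,
       hybrid_genotypes = derive_hybrid_genotypes(genotypes$female,
                                                  genotypes$male, design),
       phenotypes = phenotypes,
       spectra = spectra)
}

#' Per-environment BLUEs stacked across environments
#'
#' Computes hybrid BLUEs for each trait within every environment and stacks
#' them into the hybrid x environment record table used by the combined
#' prediction models (one row per hybrid per environment).
#'
#' @param phenotypes Plot-record table (`env`, `rep`, `female`, `male`,
#'   `hybrid`, trait columns).
#' @param traits Trait columns to extract (default: all non-factor columns).
#' @return Tibble: `record_id`, `env`, `female`, `male`, `hybrid`, one
#'   column per trait.
#' @export
trial_blues <- function(phenotypes, traits = NULL) {
  factors <- c("env", "rep", "female", "male", "hybrid", "record_id")
  if (is.null(traits)) traits <- setdiff(names(phenotypes), factors)
  envs <- unique(phenotypes$env)
  hyb <- unique(phenotypes[, c("hybrid", "female", "male")])
  out <- lapply(envs, function(e) {
    rows <- tibble::tibble(
      record_id = paste(e, hyb$hybrid, sep = "_"),
      env = e, female = hyb$female, male = hyb$male, hybrid = hyb$hybrid)
    for (tr in traits) {
      b <- fit_blues(phenotypes, tr, env = e)
      rows[[tr]] <- as.numeric(b[hyb$hybrid])
    }
    rows
  })
  do.call(rbind, out)
}

#' Build all prediction inputs from a (simulated or ingested) trial
#'
#' Computes the standard kernel set of the factorial prediction pipeline:
#' parent genomic kernels (`G = Xc Xc' / n`), the Kronecker SCA kernel, the
#' phenomic kernel from Savitzky-Golay first-derivative, band-scaled
#' per-environment spectral BLUEs, and the trait BLUE record table.
#'
#' @param trial A [simulate_trial()] result, or a list with the same
#'   elements built from ingested files.
#' @param window,polyorder Savitzky-Golay settings (defaults 11 / 2).
#' @return List: `records` (BLUE table), `G_f`, `G_m`, `H`, `P`
#'   (record-level phenomic kernel aligned with `records`), and
#'   `spectra_blues` (records x derivative bands matrix).
#' @export
prediction_inputs <- function(trial, window = 11, polyorder = 2) {
  records <- trial_blues(trial$phenotypes)
  G_f <- vanraden_relationship(trial$genotypes$female,
                               provenance = "genomic-female")
  G_m <- vanraden_relationship(trial$genotypes$male,
                               provenance = "genomic-male")
  H <- sca_kronecker(G_f, G_m, trial$design$hybrids)
  P <- NULL
  spectra_blues <- NULL
  if (!is.null(trial$spectra)) {
    sp <- trial$spectra
    blues_env <- lapply(unique(records$env), function(e) {
      B <- fit_blues_matrix(sp$records, sp$spectra, env = e)
      hyb <- records$hybrid[records$env == e]
      B[hyb, , drop = FALSE]
    })
    raw <- do.call(rbind, blues_env)
    rownames(raw) <- records$record_id
    D <- savitzky_golay_first_derivative(raw, window = window,
                                         polyorder = polyorder)
    D <- scale_bands(D)
    spectra_blues <- D
    P <- phenomic_relationship(D)
  }
  list(records = records, G_f = G_f, G_m = G_m, H = H, P = P,
       spectra_blues = spectra_blues)
}
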