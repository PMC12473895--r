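#' Trait-generating architecture for a factorial trial
#'
#' Bundles the variance components of the combined-environment factorial
#' model that the analysis estimates: female GCA, male GCA, SCA (female x
#' male), environment, the three G x E interactions, replicate within
#' environment, and plot residual. The defaults are the grain-yield variance
#' component estimates of the motivating sorghum trial (trait units t/ha,
#' components in (t/ha)^2, trial mean 6.44 t/ha), so simulated data sit at a
#' realistic scale.
#'
#' @param components Named non-negative numeric vector with entries `female`,
#'   `male`, `sca`, `env`, `female_env`, `male_env`, `sca_env`, `rep_env`,
#'   `residual` (trait-units squared).
#' @param mean Trait grand mean (trait units).
#' @param trait Trait name used for the response column.
#' @param genomic If `TRUE` (default), female and male GCA effects are sums
#'   of marker effects over the parents' SNP dosages, so genomic kernels
#'   carry real signal; if `FALSE`, all effects are drawn i.i.d. normal.
#'
#' @return An object of class `trait_architecture`.
#' @export
trait_architecture <- function(components = c(female = 0.18, male = 0.18,
                                              sca = 0.03, env = 1.30,
                                              female_env = 0.16,
                                              male_env = 0.09,
                                              sca_env = 0.078,
                                              rep_env = 0.02,
                                              residual = 0.634),
                               mean = 6.44, trait = "GY", genomic = TRUE) {
  need <- c("female", "male", "sca", "env", "female_env", "male_env",
            "sca_env", "rep_env", "residual")
  miss <- setdiff(need, names(components))
  if (length(miss)) stop("missing variance components: ",
                         paste(miss, collapse = ", "))
  components <- components[need]
  if (any(components < 0)) stop("variance components must be non-negative")
  structure(list(components = components, mean = mean, trait = trait,
                 genomic = isTRUE(genomic)),
            class = "trait_architecture")
}

# iid effects for the levels of a factor, variance s2
.draw_effects <- function(levels, s2) {
  stats::setNames(stats::rnorm(length(levels), 0, sqrt(s2)), levels)
}

# marker-driven GCA effects: u = Xc alpha with alpha scaled so the expected
# sample variance (n-1 divisor) of u across parents equals s2
.draw_marker_effects <- function(dosages, ids, s2) {
  X <- dosages[ids, , drop = FALSE]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  tr <- sum(Xc^2)
  if (tr <= 0 || s2 == 0) return(stats::setNames(rep(0, length(ids)), ids))
  alpha <- stats::rnorm(ncol(Xc), 0, sqrt(s2 * (length(ids) - 1) / tr))
  stats::setNames(drop(Xc %*% alpha), ids)
}

#' Simulate plot-level trait records for a factorial trial
#'
#' Generates plot observations `y = mu + f + m + fm + s + fs + ms + fms +
#' r(s) + e`, with every term drawn zero-mean at its configured variance:
#' female GCA (`f`), male GCA (`m`), SCA (`fm`), environment (`s`), the three
#' G x E interactions, replicate nested in environment, and residual. In
#' genomic mode the GCA effects are marker-effect sums over parent dosages,
#' so they covary according to the VanRaden relationship of the parents; SCA
#' and all non-genetic terms are i.i.d. draws.
#'
#' @param design A [design_spec()].
#' @param arch A [trait_architecture()] or a list of them (one response
#'   column per architecture).
#' @param genotypes Optional list with elements `female` and `male`: parent
#'   dosage matrices whose rownames cover the design parents. Required
#'   implicitly by genomic mode; if absent, desk-scale genotypes
#'   (2000 markers) are simulated.
#' @param seed Optional integer seed; fixed seeds give bit-identical tables.
#'
#' @return A tibble of plot records (`env`, `rep`, `female`, `male`,
#'   `hybrid`, one column per trait) with attributes `truth` (list per trait:
#'   drawn effect vectors and the architecture) and `genotypes`.
#' @examples
#' ds <- design_spec(n_female = 4, n_male = 3, environments = c("E1", "E2"))
#' pr <- simulate_trait_records(ds, trait_architecture(genomic = FALSE), seed = 7)
#' head(pr)
#' @export
simulate_trait_records <- function(design, arch = trait_architecture(),
                                   genotypes = NULL, seed = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (inherits(arch, "trait_architecture")) arch <- list(arch)
  if (!length(arch)) stop("empty architecture list")
  if (!is.null(seed)) set.seed(seed)

  needs_geno <- any(vapply(arch, function(a) a$genomic, logical(1)))
  if (needs_geno && is.null(genotypes)) {
    genotypes <- list(
      female = simulate_parent_genotypes(design$n_female, 2000, prefix = "F"),
      male = simulate_parent_genotypes(design$n_male, 2000, prefix = "M")
    )
  }

  records <- design_records(design)
  hyb <- design$hybrids
  envs <- design$environments
  rep_lv <- unlist(lapply(envs, function(e)
    paste(e, paste0("R", seq_len(design$replicates[[e]])), sep = ":")))
  truth <- list()

  for (a in arch) {
    v <- a$components
    f <- if (a$genomic) .draw_marker_effects(genotypes$female, design$females, v["female"])
         else .draw_effects(design$females, v["female"])
    m <- if (a$genomic) .draw_marker_effects(genotypes$male, design$males, v["male"])
         else .draw_effects(design$males, v["male"])
    fm <- .draw_effects(hyb$hybrid, v["sca"])
    s <- .draw_effects(envs, v["env"])
    fs <- .draw_effects(as.vector(outer(design$females, envs, paste, sep = ":")), v["female_env"])
    ms <- .draw_effects(as.vector(outer(design$males, envs, paste, sep = ":")), v["male_env"])
    fms <- .draw_effects(as.vector(outer(hyb$hybrid, envs, paste, sep = ":")), v["sca_env"])
    rs <- .draw_effects(rep_lv, v["rep_env"])
    e <- stats::rnorm(nrow(records), 0, sqrt(v["residual"]))

    y <- a$mean +
      f[records$female] + m[records$male] + fm[records$hybrid] + s[records$env] +
      fs[paste(records$female, records$env, sep = ":")] +
      ms[paste(records$male, records$env, sep = ":")] +
      fms[paste(records$hybrid, records$env, sep = ":")] +
      rs[paste(records$env, records$rep, sep = ":")] + e
    records[[a$trait]] <- unname(y)
    truth[[a$trait]] <- list(arch = a, female = f, male = m, sca = fm, env = s,
                             female_env = fs, male_env = ms, sca_env = fms,
                             rep_env = rs)
  }
  attr(records, "truth") <- truth
  attr(records, "genotypes") <- genotypes
  records
}
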