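#' Specification for synthetic NIR spectra
#'
#' Describes the wavelength grid and the per-band variance decomposition of
#' simulated grain reflectance spectra. The default grid runs 400-2500 nm at
#' 0.5 nm on a half-open interval, giving the 4200 bands of a FOSS-type
#' instrument. Per-band variance shares default to the decomposition observed
#' for real sorghum grain spectra: female 17.6%, male 26.3%, female x male
#' 5.1%, environment 37.1%, G x E 10%, replicate 1%, residual the remainder
#' (2.9%), which yields band-wise broad-sense heritability near 0.97.
#'
#' @param start,stop,step Wavelength grid in nm; bands are
#'   `seq(start, by = step, length.out = (stop - start) / step)` (half-open,
#'   so the default yields exactly 4200 bands).
#' @param shares Named non-negative numeric vector (`female`, `male`, `sca`,
#'   `env`, `gxe`, `rep`, `residual`) of variance fractions; must sum to 1
#'   (tolerance 1e-9). Alternatively a matrix with one row per band for
#'   band-varying shares.
#' @param total_var Total per-band variance (reflectance units squared).
#' @param n_basis Number of cubic B-spline basis functions used to draw
#'   smooth spectral effects (~40 knots mimics smooth NIR curves).
#' @return An object of class `spectra_gen_spec`.
#' @export
spectra_gen_spec <- function(start = 400, stop = 2500, step = 0.5,
                             shares = c(female = 0.176, male = 0.263,
                                        sca = 0.051, env = 0.371,
                                        gxe = 0.100, rep = 0.010,
                                        residual = 0.029),
                             total_var = 1, n_basis = 40) {
  n_bands <- as.integer(round((stop - start) / step))
  if (n_bands < 1) stop("empty wavelength grid")
  need <- c("female", "male", "sca", "env", "gxe", "rep", "residual")
  if (is.matrix(shares)) {
    if (nrow(shares) != n_bands) stop("share matrix needs one row per band")
    if (!all(need %in% colnames(shares))) stop("share matrix lacks components")
    shares <- shares[, need, drop = FALSE]
  } else {
    miss <- setdiff(need, names(shares))
    if (length(miss)) stop("missing shares: ", paste(miss, collapse = ", "))
    shares <- matrix(shares[need], nrow = n_bands, ncol = length(need),
                     byrow = TRUE, dimnames = list(NULL, need))
  }
  if (any(shares < 0)) stop("variance shares must be non-negative")
  bad <- abs(rowSums(shares) - 1) > 1e-9
  if (any(bad)) stop("variance shares must sum to 1 at every band")
  structure(list(wavelengths = seq(start, by = step, length.out = n_bands),
                 shares = shares, total_var = total_var,
                 n_basis = as.integer(n_basis)),
            class = "spectra_gen_spec")
}

# bands x k cubic spline basis with unit row norms: i.i.d. N(0,1) coefficients
# then give unit variance at every band
.smooth_basis <- function(n_bands, k) {
  x <- seq(0, 1, length.out = n_bands)
  knots <- seq(0, 1, length.out = max(k - 2, 2))[-c(1, max(k - 2, 2))]
  B <- splines::bs(x, knots = knots, degree = 3, intercept = TRUE)
  B <- unclass(B)
  B / sqrt(pmax(rowSums(B^2), .Machine$double.eps))
}

# smooth zero-mean effect curves: bands x n_levels, unit variance per band
.draw_curves <- function(B, n_levels) {
  B %*% matrix(stats::rnorm(ncol(B) * n_levels), ncol(B), n_levels)
}

#' Simulate per-plot NIR spectra for a factorial trial
#'
#' Draws one reflectance spectrum per plot whose per-band value decomposes
#' additively into smooth female, male, hybrid (SCA), environment, G x E,
#' replicate, and residual curves, each scaled to its configured variance
#' share. All effects (including the residual) are drawn on a low-dimensional
#' cubic-spline basis, so spectra are smooth across adjacent bands. The G x E
#' share is split equally across female x env, male x env, and hybrid x env
#' curves.
#'
#' @param design A [design_spec()].
#' @param spec A [spectra_gen_spec()].
#' @param seed Optional integer seed.
#' @return A list with `spectra` (records x bands matrix, columns named by
#'   wavelength), `records` (tibble: `record_id`, `env`, `rep`, `female`,
#'   `male`, `hybrid`), `wavelengths`, and `spec`.
#' @examples
#' ds <- design_spec(2, 2, environments = "E1")
#' sp <- simulate_spectra_records(ds, spectra_gen_spec(stop = 420), seed = 1)
#' dim(sp$spectra)
#' @export
simulate_spectra_records <- function(design, spec = spectra_gen_spec(),
                                     seed = NULL) {
  stopifnot(inherits(design, "design_spec"), inherits(spec, "spectra_gen_spec"))
  if (!is.null(seed)) set.seed(seed)
  records <- design_records(design)
  n <- nrow(records)
  n_bands <- length(spec$wavelengths)
  B <- .smooth_basis(n_bands, spec$n_basis)
  sh <- sqrt(spec$shares * spec$total_var)

  lv <- list(
    female = design$females, male = design$males,
    hybrid = design$hybrids$hybrid, env = design$environments
  )
  idx <- list(
    female = match(records$female, lv$female),
    male = match(records$male, lv$male),
    hybrid = match(records$hybrid, lv$hybrid),
    env = match(records$env, lv$env)
  )
  # interaction levels
  fe <- paste(records$female, records$env, sep = ":")
  me <- paste(records$male, records$env, sep = ":")
  he <- paste(records$hybrid, records$env, sep = ":")
  re <- paste(records$env, records$rep, sep = ":")

  curves <- function(n_levels) .draw_curves(B, n_levels)
  baseline <- drop(.draw_curves(B, 1))

  S <- matrix(0, n, n_bands)
  add <- function(S, share_col, level_ids) {
    u <- unique(level_ids)
    E <- curves(length(u))                  # bands x levels, unit variance
    S + t(E[, match(level_ids, u), drop = FALSE] * sh[, share_col])
  }
  S <- add(S, "female", records$female)
  S <- add(S, "male", records$male)
  S <- add(S, "sca", records$hybrid)
  S <- add(S, "env", records$env)
  gx <- sqrt(1 / 3)
  for (ids in list(fe, me, he)) {
    u <- unique(ids)
    E <- curves(length(u))
    S <- S + t(E[, match(ids, u), drop = FALSE] * (gx * sh[, "gxe"]))
  }
  S <- add(S, "rep", re)
  Eres <- curves(n)                          # one smooth residual per record
  S <- S + t(Eres * sh[, "residual"])
  S <- S + matrix(baseline, n, n_bands, byrow = TRUE)

  rid <- paste(records$env, records$rep, records$hybrid, sep = "_")
  dimnames(S) <- list(rid, format(spec$wavelengths, trim = TRUE))
  records$record_id <- rid
  records <- records[, c("record_id", "env", "rep", "female", "male", "hybrid")]
  list(spectra = S, records = records, wavelengths = spec$wavelengths,
       spec = spec)
}
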