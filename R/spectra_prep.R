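#' Savitzky-Golay first derivative of a spectra matrix
#'
#' Applies first-derivative Savitzky-Golay smoothing band-wise to each
#' spectrum: at every interior band, a polynomial of order `polyorder` is fit
#' by least squares to the `window` surrounding reflectance values and its
#' first derivative at the window centre is taken. Edge bands with incomplete
#' windows are dropped (no padding), so the band count shrinks by
#' `window - 1`; an 11-point window reduces 4200 bands to 4190.
#'
#' @param spectra Numeric records x bands matrix, columns optionally named by
#'   wavelength (nm); no missing values.
#' @param window Odd window width (default 11).
#' @param polyorder Polynomial order (default 2; must be < `window`).
#' @return Matrix records x (bands - window + 1), in derivative units of
#'   reflectance per band-step, with trimmed column names preserved.
#' @examples
#' X <- matrix(seq(0, 1, length.out = 50), nrow = 2, ncol = 50, byrow = TRUE)
#' D <- savitzky_golay_first_derivative(X)
#' dim(D)  # 2 x 40
#' @export
savitzky_golay_first_derivative <- function(spectra, window = 11, polyorder = 2) {
  spectra <- as.matrix(spectra)
  if (anyNA(spectra)) stop("spectra contain missing values")
  if (window %% 2 != 1) stop("window must be odd")
  if (window < 3 || window > ncol(spectra))
    stop("window must be between 3 and the number of bands")
  if (polyorder >= window) stop("polyorder must be smaller than window")
  h <- (window - 1) / 2
  A <- outer(-h:h, 0:polyorder, `^`)
  # least-squares polynomial fit; derivative at centre = coefficient of x^1
  w <- solve(crossprod(A), t(A))[2, ]
  n_out <- ncol(spectra) - window + 1
  out <- matrix(0, nrow(spectra), n_out)
  for (j in seq_len(window)) {
    out <- out + w[j] * spectra[, j:(j + n_out - 1), drop = FALSE]
  }
  keep <- (h + 1):(ncol(spectra) - h)
  dimnames(out) <- list(rownames(spectra), colnames(spectra)[keep])
  out
}

#' Centre and scale spectral bands
#'
#' Scales every band (column) to zero mean and unit sample standard
#' deviation, the pretreatment applied between the derivative step and
#' kernel construction. Bands with zero variance cannot be scaled and are
#' dropped with a warning.
#'
#' @param spectra Numeric records x bands matrix with >= 2 records.
#' @return The scaled matrix; possibly with fewer columns (attribute
#'   `dropped` lists removed band names).
#' @export
scale_bands <- function(spectra) {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 2) stop("need >= 2 records to scale bands")
  sds <- apply(spectra, 2, stats::sd)
  zero <- sds < .Machine$double.eps^0.5
  dropped <- colnames(spectra)[zero]
  if (any(zero)) {
    warning(sum(zero), " zero-variance band(s) dropped")
    spectra <- spectra[, !zero, drop = FALSE]
  }
  out <- scale(spectra)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Phenomic relationship matrix from pretreated spectra
#'
#' Computes the phenomic analogue of a genomic relationship matrix,
#' `P = D D' / q`, where `D` is the scaled first-derivative spectra matrix
#' (records x q bands). With 4190 retained derivative bands this is the
#' NIR x NIR' / 4190 kernel used for phenomic prediction.
#'
#' @param derivative_spectra Pretreated (derivative + scaled) records x q
#'   matrix with row names identifying records/hybrids.
#' @return A [rel_kernel()] of provenance `"phenomic"`.
#' @export
phenomic_relationship <- function(derivative_spectra) {
  D <- as.matrix(derivative_spectra)
  if (ncol(D) == 0) stop("no bands in spectra matrix")
  P <- tcrossprod(D) / ncol(D)
  rel_kernel(P, ids = rownames(D), provenance = "phenomic")
}

#' Band-trait Pearson correlation profile
#'
#' Correlates each spectral band with a trait over hybrids, producing the
#' per-wavelength correlation profile used to locate trait-informative
#' regions of the spectrum.
#'
#' @param spectra_blues Hybrids x bands matrix of spectral BLUEs.
#' @param trait_blues Numeric vector of trait BLUEs in matching hybrid order.
#' @return Numeric vector, one Pearson r per band (named by band).
#' @export
band_trait_correlation <- function(spectra_blues, trait_blues) {
  spectra_blues <- as.matrix(spectra_blues)
  if (nrow(spectra_blues) != length(trait_blues))
    stop("spectra and trait BLUEs must cover the same hybrids")
  if (length(trait_blues) < 3) stop("need >= 3 hybrids")
  r <- drop(stats::cor(spectra_blues, trait_blues))
  stats::setNames(as.numeric(r), colnames(spectra_blues))
}
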