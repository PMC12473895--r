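#' Simulate parent SNP dosage matrices
#'
#' Draws biallelic SNP dosages (0/1/2 copies of the counted allele) for a set
#' of parents. Markers are independent; each marker's allele frequency is
#' drawn uniformly from `maf_range`. For inbred lines (the default, matching
#' parents of hybrid breeding programs) individuals are fully homozygous, so
#' dosages are 0 or 2 with P(2) = p.
#'
#' @param n_parents Number of individuals (>= 2).
#' @param n_markers Number of markers (>= 1). Desk-scale default in the
#'   simulators is 2000; real GBS panels run to tens of thousands.
#' @param maf_range Length-2 numeric interval in (0, 0.5] from which marker
#'   allele frequencies are drawn (a single value fixes the frequency).
#' @param inbred If `TRUE`, force homozygosity (dosages in \{0, 2\}).
#' @param seed Optional integer seed for reproducibility.
#' @param prefix Prefix for individual IDs.
#'
#' @return Integer matrix `n_parents x n_markers` with dimnames
#'   (individual IDs, marker IDs).
#' @examples
#' X <- simulate_parent_genotypes(10, 50, seed = 1)
#' all(X %in% c(0, 2))
#' @export
simulate_parent_genotypes <- function(n_parents, n_markers,
                                      maf_range = c(0.05, 0.5),
                                      inbred = TRUE, seed = NULL,
                                      prefix = "P") {
  if (n_parents < 2) stop("n_parents must be >= 2")
  if (n_markers < 1) stop("n_markers must be >= 1")
  if (length(maf_range) == 1) maf_range <- rep(maf_range, 2)
  if (diff(maf_range) < 0 || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be an interval within (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(n_markers, maf_range[1], maf_range[2])
  if (inbred) {
    X <- matrix(2L * stats::rbinom(n_parents * n_markers, 1L, rep(p, each = n_parents)),
                nrow = n_parents)
  } else {
    X <- matrix(stats::rbinom(n_parents * n_markers, 2L, rep(p, each = n_parents)),
                nrow = n_parents)
  }
  dimnames(X) <- list(sprintf("%s%02d", prefix, seq_len(n_parents)),
                      sprintf("snp%05d", seq_len(n_markers)))
  X
}

#' Derive expected F1 hybrid dosages from parent genotypes
#'
#' Builds in-silico F1 genotypes for every hybrid of a factorial design as the
#' mean of its parents' dosages (the expected F1 dosage). For fully inbred
#' parents this is the deterministic F1 genotype: crossing opposite
#' homozygotes (0 x 2) gives a heterozygote (1).
#'
#' @param female_geno,male_geno Dosage matrices (individuals x markers) whose
#'   rownames contain the design's female/male parent IDs. Both must share
#'   the same marker set in the same order.
#' @param design A [design_spec()]; rownames of the inputs must cover
#'   `design$females` and `design$males`.
#' @return Numeric matrix `n_hybrids x n_markers`, rows named by hybrid ID.
#' @export
derive_hybrid_genotypes <- function(female_geno, male_geno, design) {
  stopifnot(inherits(design, "design_spec"))
  if (!identical(colnames(female_geno), colnames(male_geno)))
    stop("female and male genotype matrices must share an identical marker set")
  if (!all(design$females %in% rownames(female_geno)))
    stop("female_geno lacks rows for some design females")
  if (!all(design$males %in% rownames(male_geno)))
    stop("male_geno lacks rows for some design males")
  H <- (female_geno[design$hybrids$female, , drop = FALSE] +
          male_geno[design$hybrids$male, , drop = FALSE]) / 2
  rownames(H) <- design$hybrids$hybrid
  H
}
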