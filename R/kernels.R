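#' Relationship kernel constructor
#'
#' Wraps a symmetric positive semi-definite similarity matrix with entity
#' IDs and a provenance tag. Symmetry is enforced within 1e-10 and the
#' minimum eigenvalue must exceed -1e-8; small negative eigenvalues from
#' floating-point noise are tolerated here and clipped where decompositions
#' are taken.
#'
#' @param mat Square numeric matrix.
#' @param ids Character vector of unique entity IDs (defaults to rownames).
#' @param provenance Tag describing the construction, e.g. `"genomic-female"`,
#'   `"genomic-male"`, `"SCA"`, `"phenomic"`, `"environment"`, `"interaction"`.
#' @param check If `TRUE` (default), validate symmetry and PSD.
#' @return A matrix of class `rel_kernel` with attributes `ids`, `provenance`.
#' @export
rel_kernel <- function(mat, ids = rownames(mat), provenance = "custom",
                       check = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("kernel must be square")
  if (is.null(ids)) stop("kernel requires entity IDs")
  ids <- as.character(ids)
  if (length(ids) != nrow(mat)) stop("ids must match kernel dimension")
  if (anyDuplicated(ids)) stop("kernel IDs must be unique")
  if (check) {
    if (max(abs(mat - t(mat))) > 1e-10) stop("kernel is not symmetric")
    ev <- min(eigen(mat, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8 * max(1, max(abs(mat))))
      stop("kernel is not PSD (min eigenvalue ", signif(ev, 3), ")")
  }
  mat <- (mat + t(mat)) / 2
  dimnames(mat) <- list(ids, ids)
  structure(mat, ids = ids, provenance = provenance,
            class = c("rel_kernel", "matrix", "array"))
}

#' @export
print.rel_kernel <- function(x, ...) {
  cat("<rel_kernel> ", attr(x, "provenance"), ": ", nrow(x), " x ", ncol(x),
      " entities\n", sep = "")
  invisible(x)
}

#' VanRaden-style genomic relationship matrix
#'
#' Centres each marker column of a dosage matrix and computes
#' `G = Xc Xc' / n`, with `n` the number of markers. This is the literal
#' marker-count denominator; the classical `2 * sum(p * (1 - p))`
#' denominator is available via `denominator = "2pq"` and differs only by a
#' scalar.
#'
#' @param dosages Individuals x markers numeric matrix (0/1/2 allele counts;
#'   fractional dosages allowed). Rownames identify individuals.
#' @param denominator `"n_markers"` (default) or `"2pq"`.
#' @param provenance Provenance tag for the resulting kernel.
#' @return A [rel_kernel()] over individuals.
#' @examples
#' X <- rbind(a = c(0), b = c(1), c = c(2))
#' vanraden_relationship(X)  # centred (-1, 0, 1) -> unit diagonal corners
#' @export
vanraden_relationship <- function(dosages, denominator = c("n_markers", "2pq"),
                                  provenance = "genomic") {
  denominator <- match.arg(denominator)
  X <- as.matrix(dosages)
  if (ncol(X) < 1) stop("need at least one marker")
  if (anyNA(X)) stop("dosages contain missing values; impute first")
  p <- colMeans(X) / 2
  Xc <- sweep(X, 2, colMeans(X))
  d <- if (denominator == "n_markers") ncol(X) else 2 * sum(p * (1 - p))
  if (d <= 0) stop("degenerate denominator (all markers monomorphic?)")
  G <- tcrossprod(Xc) / d
  rel_kernel(G, ids = rownames(X), provenance = provenance)
}

#' SCA kernel as a Kronecker product restricted to realized hybrids
#'
#' Builds the specific-combining-ability relationship among hybrids from the
#' parental genomic kernels:
#' `H[(f1, m1), (f2, m2)] = G_f[f1, f2] * G_m[m1, m2]`,
#' i.e. the Kronecker product `G_f %x% G_m` restricted to the hybrids that
#' exist in the design (all of them, for a complete factorial).
#'
#' @param G_f,G_m Female and male [rel_kernel()]s (or plain labelled
#'   matrices).
#' @param hybrids Data frame with columns `hybrid`, `female`, `male` (e.g.
#'   `design_spec(...)$hybrids`).
#' @return A [rel_kernel()] over hybrids with provenance `"SCA"`.
#' @export
sca_kronecker <- function(G_f, G_m, hybrids) {
  need <- c("hybrid", "female", "male")
  if (!all(need %in% names(hybrids))) stop("hybrids needs hybrid/female/male")
  fi <- match(hybrids$female, rownames(G_f))
  mi <- match(hybrids$male, rownames(G_m))
  if (anyNA(fi)) stop("hybrid references unknown female parent")
  if (anyNA(mi)) stop("hybrid references unknown male parent")
  H <- as.matrix(G_f)[fi, fi, drop = FALSE] * as.matrix(G_m)[mi, mi, drop = FALSE]
  rel_kernel(H, ids = hybrids$hybrid, provenance = "SCA")
}

#' Expand an entity kernel to record level
#'
#' Computes `Z K Z'` where `Z` is the 0/1 incidence matrix assigning each
#' record to one entity of `factor`: the record-level covariance has entry
#' `K[entity(i), entity(j)]`. PSD is preserved.
#'
#' @param K Entity-level [rel_kernel()] (or labelled matrix).
#' @param map An [incidence_map()] (or data frame acceptable to it).
#' @param factor One of the map's factors (`"female"`, `"male"`, `"hybrid"`,
#'   `"env"`, `"rep"`).
#' @return A record-level `rel_kernel` (n_records x n_records); record IDs
#'   are positional (`rec1...`) unless the map carries `record_id`.
#' @export
expand_to_records <- function(K, map, factor = "hybrid") {
  if (!inherits(map, "incidence_map")) map <- incidence_map(map)
  if (!factor %in% names(map)) stop("unknown factor: ", factor)
  lev <- as.character(map[[factor]])
  idx <- match(lev, rownames(K))
  if (anyNA(idx)) stop("records map to entities absent from the kernel: ",
                       paste(unique(lev[is.na(idx)]), collapse = ", "))
  V <- as.matrix(K)[idx, idx, drop = FALSE]
  rel_kernel(V, ids = sprintf("rec%04d", seq_along(idx)),
             provenance = paste0("expanded-", attr(K, "provenance") %||% factor),
             check = FALSE)
}

#' Hadamard genotype-by-environment interaction kernel
#'
#' Multiplies a record-level main-effect covariance element-wise with the
#' environment-sharing indicator `Z_E Z_E'`: entries between records in
#' different environments are zeroed, entries within an environment are kept.
#' By the Schur product theorem the result is PSD.
#'
#' @param expanded_kernel Record-level kernel (`Z K Z'`), e.g. from
#'   [expand_to_records()].
#' @param env Factor/character vector of environment labels in record order.
#' @return A record-level `rel_kernel` with provenance `"interaction"`.
#' @export
interaction_hadamard <- function(expanded_kernel, env) {
  V <- as.matrix(expanded_kernel)
  if (length(env) != nrow(V)) stop("env labels and kernel records mismatch")
  same <- outer(as.character(env), as.character(env), `==`)
  rel_kernel(V * same, ids = rownames(V) %||% sprintf("rec%04d", seq_len(nrow(V))),
             provenance = "interaction", check = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
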