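#' Read a parent dosage matrix
#'
#' Reads SNP genotypes either from a dosage CSV (rows = individuals, first
#' column = individual ID, remaining header = marker IDs) or from a VCF
#' (dosage taken from the GT field). Markers with more than `max_missing`
#' missing genotypes are removed; remaining missing values are imputed to
#' the marker mean.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, or `"vcf"`.
#' @param max_missing Maximum tolerated missing fraction per marker
#'   (default 0.05); markers above it are dropped.
#' @return Numeric individuals x markers matrix; attribute `n_dropped`
#'   counts removed markers.
#' @export
read_genotypes <- function(path, format = c("auto", "csv", "vcf"),
                           max_missing = 0.05) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "csv"
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"),
                    function(a) sum(a == "1"), numeric(1)))
    }
    X <- apply(gt, 2, count_alt)
    if (is.null(dim(X))) X <- matrix(X, nrow = nrow(gt))
    dimnames(X) <- dimnames(gt)
    X <- t(X)
  } else {
    tab <- utils::read.csv(path, check.names = FALSE)
    ids <- as.character(tab[[1]])
    X <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(X)) stop("non-numeric dosage values in ", path)
    rownames(X) <- ids
  }
  if (anyDuplicated(rownames(X))) stop("duplicated individual IDs")
  if (anyDuplicated(colnames(X))) stop("duplicated marker IDs")
  miss_frac <- colMeans(is.na(X))
  drop <- miss_frac > max_missing
  X <- X[, !drop, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  attr(X, "n_dropped") <- sum(drop)
  X
}

#' Write a dosage matrix as CSV
#' @param dosages Individuals x markers matrix with dimnames.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(dosages, path) {
  df <- data.frame(id = rownames(dosages), dosages, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a wide spectra CSV
#'
#' Expects a `record_id` column followed by one numeric column per band,
#' headers being wavelengths in nm, strictly increasing on a uniform step.
#' Missing or non-numeric reflectance values are errors, as is an unsorted
#' wavelength header.
#'
#' @param path File path.
#' @return List with `spectra` (records x bands matrix) and `wavelengths`.
#' @export
read_spectra <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!"record_id" %in% names(tab)) stop("spectra file needs a record_id column")
  wl <- suppressWarnings(as.numeric(setdiff(names(tab), "record_id")))
  if (anyNA(wl)) stop("non-numeric wavelength header")
  if (any(diff(wl) <= 0))
    stop("wavelength header out of order at column ",
         names(tab)[-1][which(diff(wl) <= 0)[1] + 1])
  steps <- diff(wl)
  if (max(steps) - min(steps) > 1e-6) stop("non-uniform wavelength step")
  M <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(M) || anyNA(M)) stop("missing or non-numeric reflectance values")
  rownames(M) <- tab$record_id
  list(spectra = M, wavelengths = wl)
}

#' Write spectra as a wide CSV
#' @param spectra Records x bands matrix (columns named by wavelength).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  df <- data.frame(record_id = rownames(spectra), spectra, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plot-level phenotype table
#'
#' Validates a long CSV of plot records: requires `env`, `rep`, `female`,
#' `male` and at least one trait column; `hybrid` is derived from
#' female x male if absent. Duplicate (env, rep, hybrid) rows are an error,
#' reported with their row numbers.
#'
#' @param path File path.
#' @return A tibble of plot records.
#' @export
read_phenotypes <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("env", "rep", "female", "male")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("phenotype file lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!"hybrid" %in% names(tab))
    tab$hybrid <- paste(tab$female, tab$male, sep = "x")
  key <- paste(tab$env, tab$rep, tab$hybrid)
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicated (env, rep, hybrid) rows: ",
         paste(utils::head(dup, 6), collapse = ", "))
  }
  traits <- setdiff(names(tab), c(need, "hybrid"))
  if (!length(traits)) stop("no trait columns found")
  for (tr in traits) {
    if (!is.numeric(tab[[tr]]))
      stop("trait column `", tr, "` is not numeric")
  }
  tibble::as_tibble(tab)
}

#' Write plot records as CSV
#' @param records Plot record table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a labelled square kernel CSV
#' @param kernel A [rel_kernel()].
#' @param path File path.
#' @return `write_kernel`: `path` invisibly; `read_kernel`: a `rel_kernel`.
#' @export
write_kernel <- function(kernel, path) {
  df <- data.frame(id = rownames(kernel), unclass(kernel)[, , drop = FALSE],
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @param provenance Provenance tag to attach on read.
#' @export
read_kernel <- function(path, provenance = "custom") {
  tab <- utils::read.csv(path, check.names = FALSE)
  M <- as.matrix(tab[, -1, drop = FALSE])
  rownames(M) <- tab[[1]]
  rel_kernel(M, ids = tab[[1]], provenance = provenance)
}

#' Create, save, and load a run configuration
#'
#' A `run_config` bundles everything needed to reproduce an analysis run
#' bit-for-bit: input paths, design parameters, preprocessing settings,
#' chain settings, cross-validation settings, and the master seed. It is a
#' plain named list that serializes losslessly to JSON.
#'
#' @param genotypes,phenotypes,spectra,out_dir Input/output paths.
#' @param t,r Environments and replicates assumed in heritability formulas.
#' @param window,polyorder Savitzky-Golay pretreatment settings.
#' @param iters,burnin,thin Gibbs chain settings.
#' @param scheme,n_repeats,held_out_env Cross-validation settings.
#' @param seed Master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(genotypes = NULL, phenotypes = NULL, spectra = NULL,
                       out_dir = ".", t = 8, r = 2, window = 11,
                       polyorder = 2, iters = 5000, burnin = 1000, thin = 10,
                       scheme = "CV1", n_repeats = 50, held_out_env = NULL,
                       seed = 1) {
  structure(list(genotypes = genotypes, phenotypes = phenotypes,
                 spectra = spectra, out_dir = out_dir, t = t, r = r,
                 window = window, polyorder = polyorder, iters = iters,
                 burnin = burnin, thin = thin, scheme = scheme,
                 n_repeats = n_repeats, held_out_env = held_out_env,
                 seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config A `run_config`.
#' @param path JSON file path.
#' @export
write_run_config <- function(config, path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("writing run configs requires the jsonlite package")
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("reading run configs requires the jsonlite package")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}
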