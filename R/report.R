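#' Variance-component and heritability report for one trait
#'
#' Convenience wrapper producing the standard multi-environment trial report:
#' REML estimates with percent-of-total and likelihood-ratio significance
#' stars for every random term, followed by entry-mean heritabilities
#' (broad-sense, narrow-sense, and the parental split) and the residual
#' coefficient of variation.
#'
#' @param records Plot-record table covering >= 2 environments.
#' @param response Trait column name.
#' @param r Replicates per environment used in the heritability denominator
#'   (default: rounded mean plot count per hybrid-environment cell).
#' @param lrt Run per-term likelihood-ratio tests (default `TRUE`).
#' @return A list with `components` (tibble: term, estimate, percent, stars),
#'   `heritability` (a `heritability_report`), `cve` (percent), and the
#'   underlying `variance_decomposition`.
#' @export
varcomp_report <- function(records, response, r = NULL, lrt = TRUE) {
  t_env <- length(unique(records$env))
  if (is.null(r))
    r <- round(nrow(records) / (t_env * length(unique(records$hybrid))))
  vc <- reml_combined(records, response, lrt = lrt)
  stars <- if (!is.null(vc$lrt))
    vc$lrt$stars[match(names(vc$estimates), vc$lrt$term)]
  else rep(NA_character_, length(vc$estimates))
  comp <- tibble::tibble(
    term = names(vc$estimates),
    estimate = round_half_up(unname(vc$estimates), 3),
    percent = round_half_up(unname(vc$percents), 1),
    stars = stars)
  list(components = comp,
       heritability = heritability_combined(vc, t = t_env, r = r),
       cve = cve(vc, mean(records[[response]])),
       varcomp = vc)
}
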