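#' Per-environment hybrid BLUEs
#'
#' Fits the within-environment model `y = hybrid (fixed) + replicate (random)
#' + error` and returns the estimable hybrid means (intercept-free fixed
#' effects), the best linear unbiased estimates used as responses for the
#' prediction models. With a single replicate the replicate term drops and
#' the fit reduces to ordinary least squares.
#'
#' @param records Plot-record data frame with columns `hybrid`, `rep`, and
#'   the response; optionally `env`.
#' @param response Name of the response column.
#' @param env If given, restrict to that environment first.
#' @return Named numeric vector of hybrid BLUEs.
#' @export
fit_blues <- function(records, response, env = NULL) {
  if (!is.null(env)) records <- records[records$env == env, , drop = FALSE]
  if (!nrow(records)) stop("no records", if (!is.null(env)) paste0(" in ", env))
  y <- records[[response]]
  if (is.null(y)) stop("no column `", response, "`")
  hybrid <- factor(records$hybrid)
  if (nlevels(hybrid) < 2) stop("need >= 2 hybrids")
  if (any(table(hybrid) == 0)) stop("hybrid with no observations")
  rep_f <- factor(records$rep)
  if (nlevels(rep_f) >= 2) {
    fit <- suppressMessages(lme4::lmer(
      y ~ 0 + hybrid + (1 | rep_f),
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    b <- lme4::fixef(fit)
  } else {
    b <- stats::coef(stats::lm(y ~ 0 + hybrid))
  }
  stats::setNames(as.numeric(b), sub("^hybrid", "", names(b)))
}

#' Band-wise hybrid BLUEs for a spectra matrix
#'
#' Applies [fit_blues()] to every band of a records x bands matrix within
#' one environment, reusing the fitted model structure across bands for
#' speed. For a 100-hybrid trial this yields the hybrids x bands BLUE matrix
#' used for phenomic kernels and band-trait correlation profiles.
#'
#' @param records Record table aligned with the rows of `spectra`.
#' @param spectra Records x bands numeric matrix.
#' @param env Optional environment filter.
#' @return Hybrids x bands matrix of BLUEs.
#' @export
fit_blues_matrix <- function(records, spectra, env = NULL) {
  spectra <- as.matrix(spectra)
  if (nrow(records) != nrow(spectra)) stop("records/spectra row mismatch")
  if (!is.null(env)) {
    keep <- records$env == env
    records <- records[keep, , drop = FALSE]
    spectra <- spectra[keep, , drop = FALSE]
  }
  hybrid <- factor(records$hybrid)
  rep_f <- factor(records$rep)
  use_lmer <- nlevels(rep_f) >= 2
  if (use_lmer) {
    y <- spectra[, 1]
    base_fit <- suppressMessages(lme4::lmer(
      y ~ 0 + hybrid + (1 | rep_f),
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    out <- vapply(seq_len(ncol(spectra)), function(j) {
      f <- suppressMessages(suppressWarnings(lme4::refit(base_fit, spectra[, j])))
      as.numeric(lme4::fixef(f))
    }, numeric(nlevels(hybrid)))
  } else {
    X <- stats::model.matrix(~ 0 + hybrid)
    out <- solve(crossprod(X), crossprod(X, spectra))
  }
  out <- matrix(out, nrow = nlevels(hybrid),
                dimnames = list(levels(hybrid), colnames(spectra)))
  out
}

.vc_names_single <- c(female = "female", male = "male", sca = "hybrid",
                      rep_env = "rep_f")
.vc_names_combined <- c(female = "female", male = "male", sca = "hybrid",
                        env = "env", female_env = "female:env",
                        male_env = "male:env", sca_env = "hybrid:env",
                        rep_env = "env:rep_f")

.extract_vc <- function(fit, name_map) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  est <- stats::setNames(vc$vcov[match(name_map, vc$grp)], names(name_map))
  est["residual"] <- vc$vcov[vc$grp == "Residual"]
  est
}

.vc_object <- function(estimates, loglik, converged, n_obs, model, fit,
                       lrt = NULL) {
  estimates[is.na(estimates)] <- 0
  pct <- 100 * estimates / sum(estimates)
  structure(list(estimates = estimates, percents = pct, loglik = loglik,
                 converged = converged, n_obs = n_obs, model = model,
                 lrt = lrt, fit = fit),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition (", x$model, " environment model, n = ",
      x$n_obs, ")\n", sep = "")
  tab <- data.frame(estimate = round(x$estimates, 4),
                    percent = round(x$percents, 1))
  if (!is.null(x$lrt)) {
    tab$p_LRT <- signif(x$lrt$p[match(rownames(tab), x$lrt$term)], 3)
    tab$sig <- significance_stars(tab$p_LRT)
  }
  print(tab)
  if (!x$converged) cat("WARNING: REML fit did not converge cleanly\n")
  invisible(x)
}

.fit_factorial_reml <- function(records, response, terms) {
  dat <- data.frame(y = records[[response]],
                    female = factor(records$female),
                    male = factor(records$male),
                    hybrid = factor(records$hybrid),
                    env = if ("env" %in% names(records)) factor(records$env) else factor(1),
                    rep_f = factor(records$rep))
  rhs <- paste(sprintf("(1 | %s)", terms), collapse = " + ")
  fit <- suppressMessages(lme4::lmer(
    stats::as.formula(paste("y ~", rhs)), data = dat,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)))
  conv <- is.null(fit@optinfo$conv$lme4$code) && fit@optinfo$conv$opt == 0
  list(fit = fit, converged = conv, data = dat)
}

#' Single-environment REML variance components
#'
#' Estimates female GCA, male GCA, SCA (hybrid), replicate, and residual
#' variance components of the within-environment factorial model
#' `y = mu + f + m + fm + r + e` by REML with non-negativity constraints.
#'
#' @param records Plot records with `female`, `male`, `hybrid`, `rep`
#'   columns (single environment).
#' @param response Response column name.
#' @param lrt If `TRUE`, run a likelihood-ratio test for each random term
#'   (term dropped, chi-square with 1 df).
#' @param drop Optional component name to leave out of the model (yielding a
#'   reduced fit for use with [lrt_term()]).
#' @return A `variance_decomposition` with estimates, percent-of-total,
#'   restricted log-likelihood, convergence flag, and (optionally) LRT table.
#' @export
reml_single_env <- function(records, response, lrt = FALSE, drop = NULL) {
  if ("env" %in% names(records) && length(unique(records$env)) > 1)
    stop("multiple environments present; use reml_combined()")
  y <- records[[response]]
  if (stats::sd(y) == 0) {           # degenerate: no variation at all
    est <- stats::setNames(rep(0, 5),
                           c(names(.vc_names_single), "residual"))
    return(.vc_object(est, loglik = NA_real_, converged = TRUE,
                      n_obs = length(y), model = "single", fit = NULL))
  }
  for (f in c("female", "male")) {
    if (length(unique(records[[f]])) < 2) stop("need >= 2 levels of ", f)
  }
  name_map <- .vc_names_single
  if (!is.null(drop)) {
    if (!all(drop %in% names(name_map))) stop("unknown component: ",
      paste(setdiff(drop, names(name_map)), collapse = ", "))
    name_map <- name_map[!names(name_map) %in% drop]
  }
  terms <- unname(name_map)
  res <- .fit_factorial_reml(records, response, terms)
  est <- .extract_vc(res$fit, name_map)
  lrt_tab <- if (lrt) .lrt_all_terms(res, terms, name_map) else NULL
  .vc_object(est, loglik = as.numeric(stats::logLik(res$fit)),
             converged = res$converged, n_obs = length(y), model = "single",
             fit = res$fit, lrt = lrt_tab)
}

#' Combined-environment REML variance components
#'
#' Estimates all random terms of the multi-environment factorial model:
#' female, male, and SCA main effects, environment, the three G x E
#' interactions (female x env, male x env, SCA x env), replicate within
#' environment, and residual.
#'
#' @inheritParams reml_single_env
#' @return A `variance_decomposition` covering all nine components.
#' @export
reml_combined <- function(records, response, lrt = FALSE, drop = NULL) {
  if (!"env" %in% names(records) || length(unique(records$env)) < 2)
    stop("need >= 2 environments; use reml_single_env() for one")
  y <- records[[response]]
  if (stats::sd(y) == 0) {
    est <- stats::setNames(rep(0, 9),
                           c(names(.vc_names_combined), "residual"))
    return(.vc_object(est, loglik = NA_real_, converged = TRUE,
                      n_obs = length(y), model = "combined", fit = NULL))
  }
  name_map <- .vc_names_combined
  if (!is.null(drop)) {
    if (!all(drop %in% names(name_map))) stop("unknown component: ",
      paste(setdiff(drop, names(name_map)), collapse = ", "))
    name_map <- name_map[!names(name_map) %in% drop]
  }
  terms <- unname(name_map)
  res <- .fit_factorial_reml(records, response, terms)
  est <- .extract_vc(res$fit, name_map)
  lrt_tab <- if (lrt) .lrt_all_terms(res, terms, name_map) else NULL
  .vc_object(est, loglik = as.numeric(stats::logLik(res$fit)),
             converged = res$converged, n_obs = length(y), model = "combined",
             fit = res$fit, lrt = lrt_tab)
}

.lrt_all_terms <- function(res, terms, name_map) {
  full_ll <- as.numeric(stats::logLik(res$fit))
  out <- lapply(seq_along(terms), function(i) {
    red <- terms[-i]
    rhs <- paste(sprintf("(1 | %s)", red), collapse = " + ")
    rfit <- suppressMessages(lme4::lmer(
      stats::as.formula(paste("y ~", rhs)), data = res$data,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE)))
    stat <- max(0, 2 * (full_ll - as.numeric(stats::logLik(rfit))))
    c(stat = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  data.frame(term = names(name_map)[match(terms, name_map)],
             statistic = out[, "stat"], p = out[, "p"],
             stars = significance_stars(out[, "p"]))
}

#' Likelihood-ratio test between nested REML fits
#'
#' Compares a full and a reduced variance-component fit differing by one
#' random term: the statistic is minus twice the difference in restricted
#' log-likelihood, referred to a chi-square with 1 df (the plain reference
#' distribution; `boundary = TRUE` uses the 50:50 mixture of chi-square 0
#' and 1 appropriate for a variance tested at its boundary, which halves the
#' p-value).
#'
#' @param full,reduced `variance_decomposition` objects (reduced nested in
#'   full, one term fewer).
#' @param boundary Use the boundary mixture reference instead of plain
#'   chi-square 1.
#' @return List with `statistic`, `p`, and `stars`.
#' @export
lrt_term <- function(full, reduced, boundary = FALSE) {
  stopifnot(inherits(full, "variance_decomposition"),
            inherits(reduced, "variance_decomposition"))
  lost <- setdiff(names(full$estimates), names(reduced$estimates))
  gained <- setdiff(names(reduced$estimates), names(full$estimates))
  if (length(gained) || length(lost) > 1)
    stop("models are not nested: reduced must drop at most one variance term")
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary) p <- p / 2
  if (stat == 0) p <- 1
  list(statistic = stat, p = p, stars = significance_stars(p))
}

#' Significance stars at 0.05 / 0.01 / 0.001
#' @param p Numeric vector of p-values.
#' @return Character vector: `***`, `**`, `*`, or `NS`.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "NS"))))
}

.as_components <- function(x) {
  if (inherits(x, "variance_decomposition")) return(x$estimates)
  if (!is.numeric(x) || is.null(names(x))) stop("need named components")
  x
}

.h2_report <- function(H2, h2, h2_f, h2_m, t, r) {
  structure(list(H2 = H2, h2 = h2, h2_f = h2_f, h2_m = h2_m, t = t, r = r),
            class = "heritability_report")
}

#' @export
print.heritability_report <- function(x, ...) {
  cat(sprintf("H2 = %.3f  h2 = %.3f  h2_f = %.3f  h2_m = %.3f  (t = %s, r = %s)\n",
              x$H2, x$h2, x$h2_f, x$h2_m, x$t, x$r))
  invisible(x)
}

#' Single-environment heritability
#'
#' Entry-mean heritabilities for one environment:
#' `H2 = s2_g / (s2_g + s2_e / r)` with `s2_g` the total hybrid variance
#' (female + male + SCA); `h2` replaces the numerator with the additive part
#' (female + male), and `h2_f` / `h2_m` with the single-parent components.
#' By construction `h2_f + h2_m = h2`.
#'
#' @param vc A `variance_decomposition` or named component vector with
#'   entries `female`, `male`, `sca`, `residual`.
#' @param r Number of replicates per environment (>= 1).
#' @return A `heritability_report`.
#' @export
heritability_single <- function(vc, r) {
  stopifnot(r >= 1)
  v <- .as_components(vc)
  g <- sum(v[c("female", "male", "sca")])
  den <- g + v[["residual"]] / r
  if (den <= 0) stop("all-zero denominator")
  .h2_report(g / den, sum(v[c("female", "male")]) / den,
             v[["female"]] / den, v[["male"]] / den, t = 1, r = r)
}

#' Combined-environment heritability
#'
#' Entry-mean heritabilities across `t` environments with `r` replicates
#' each. The denominator is `s2_g* + s2_gxe*/t + s2_e/(t r)`, where
#' `s2_g* = female + male + SCA` and `s2_gxe* = female x env + male x env +
#' SCA x env`. Numerators: `s2_g*` for `H2`, `female + male` for `h2`,
#' and the single-parent components for `h2_f` / `h2_m`. Components may be
#' REML estimates or percent-of-total values (the statistic is scale-free).
#' Aggregate inputs are also accepted: `hybrid` (total), `hybrid_env`
#' (total G x E), `residual`, plus optionally `female` and `male`.
#'
#' @param vc A `variance_decomposition` or named numeric vector.
#' @param t Number of environments (>= 2).
#' @param r Number of replicates per environment (>= 1).
#' @return A `heritability_report` (`h2`, `h2_f`, `h2_m` are `NA` when the
#'   parental split is not supplied).
#' @examples
#' # percent-of-total inputs work unchanged:
#' heritability_combined(c(hybrid = 14.5, hybrid_env = 12.1, residual = 23.8),
#'                       t = 8, r = 2)
#' @export
heritability_combined <- function(vc, t, r) {
  stopifnot(t >= 2, r >= 1)
  v <- .as_components(vc)
  g <- if ("hybrid" %in% names(v)) v[["hybrid"]]
       else sum(v[c("female", "male", "sca")])
  gs <- if ("hybrid_env" %in% names(v)) v[["hybrid_env"]]
        else sum(v[c("female_env", "male_env", "sca_env")])
  if (!"residual" %in% names(v)) stop("missing residual component")
  den <- g + gs / t + v[["residual"]] / (t * r)
  if (den <= 0) stop("all-zero denominator")
  f <- if ("female" %in% names(v)) v[["female"]] else NA_real_
  m <- if ("male" %in% names(v)) v[["male"]] else NA_real_
  .h2_report(g / den, (f + m) / den, f / den, m / den, t = t, r = r)
}

#' Residual coefficient of variation
#'
#' `CVe = 100 * sqrt(s2_e) / xbar`, the residual standard deviation as a
#' percentage of the trait mean.
#'
#' @param vc A `variance_decomposition` or named vector with `residual`.
#' @param mean Trait grand mean (non-zero).
#' @return CVe in percent.
#' @export
cve <- function(vc, mean) {
  if (mean == 0) stop("zero trait mean")
  v <- .as_components(vc)
  100 * sqrt(v[["residual"]]) / mean
}

#' Round half up to a number of decimals
#'
#' Presentation rounding (0.005 -> 0.01) used for report tables, as opposed
#' to R's round-half-even.
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5 + 1e-12) / 10^digits
}

#' Per-band spectral variance decomposition and heritability profiles
#'
#' Runs the combined-environment REML decomposition independently for every
#' spectral band, reusing the fitted model structure across bands, and
#' stacks percent-of-total profiles together with band-wise H2, h2, h2_f,
#' h2_m curves.
#'
#' @param spectra Records x bands numeric matrix.
#' @param records Record table aligned with `spectra` rows (needs `env`,
#'   `rep`, `female`, `male`, `hybrid`).
#' @param r Replicate count used in the heritability denominator (default:
#'   rounded mean plots per hybrid-environment).
#' @return A list with `estimates` and `percents` (bands x component
#'   matrices), `heritability` (tibble: band, H2, h2, h2_f, h2_m), and
#'   `converged` (logical per band).
#' @export
spectra_band_decomposition <- function(spectra, records, r = NULL) {
  spectra <- as.matrix(spectra)
  if (nrow(records) != nrow(spectra)) stop("records/spectra row mismatch")
  t_env <- length(unique(records$env))
  if (t_env < 2) stop("need >= 2 environments")
  if (is.null(r))
    r <- round(nrow(records) / (t_env * length(unique(records$hybrid))))
  terms <- c("female", "male", "hybrid", "env", "female:env", "male:env",
             "hybrid:env", "env:rep_f")
  rec <- records
  rec$.y <- spectra[, 1]
  base <- .fit_factorial_reml(rec, ".y", terms)
  comp_names <- c(names(.vc_names_combined), "residual")
  n_bands <- ncol(spectra)
  est <- matrix(NA_real_, n_bands, length(comp_names),
                dimnames = list(colnames(spectra), comp_names))
  conv <- logical(n_bands)
  for (j in seq_len(n_bands)) {
    fj <- tryCatch(
      suppressMessages(suppressWarnings(lme4::refit(base$fit, spectra[, j]))),
      error = function(e) NULL)
    if (is.null(fj)) next
    e <- .extract_vc(fj, .vc_names_combined)
    e[is.na(e)] <- 0
    est[j, ] <- e
    conv[j] <- TRUE
  }
  pct <- 100 * est / rowSums(est)
  her <- t(apply(est, 1, function(v) {
    if (anyNA(v)) return(c(H2 = NA, h2 = NA, h2_f = NA, h2_m = NA))
    h <- heritability_combined(v, t = t_env, r = r)
    c(H2 = h$H2, h2 = h$h2, h2_f = h$h2_f, h2_m = h$h2_m)
  }))
  list(estimates = est, percents = pct,
       heritability = tibble::tibble(band = colnames(spectra),
                                     H2 = her[, "H2"], h2 = her[, "h2"],
                                     h2_f = her[, "h2_f"], h2_m = her[, "h2_m"]),
       converged = conv, t = t_env, r = r)
}
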