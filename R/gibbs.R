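#' Assemble the record-level kernel stack for a prediction model
#'
#' Builds the named list of record-aligned covariance kernels that defines a
#' GP, PP, or GP+PP model. In single-environment scope, GP uses the female
#' GCA, male GCA, and SCA kernels; PP uses the phenomic kernel; GP+PP uses
#' both. Combined scope adds an environment main-effect block (an
#' identity kernel over environment levels, equivalent to a Gaussian ridge
#' on environment indicators) and the Hadamard interaction kernels of each
#' main-effect term with environment.
#'
#' @param model `"GP"`, `"PP"`, or `"GP+PP"`.
#' @param scope `"single"` or `"combined"` (multi-environment).
#' @param records Record table (`env`, `female`, `male`, `hybrid`, ...)
#'   defining record order.
#' @param G_f,G_m Parent genomic kernels ([rel_kernel()]), required for GP
#'   models.
#' @param H SCA kernel over hybrids (e.g. [sca_kronecker()]); required for
#'   GP models.
#' @param P Phenomic kernel: either record-level (rows = records, in order)
#'   or hybrid-level (expanded through the hybrid incidence); required for
#'   PP models.
#' @return Named list of record-level kernels suitable for [build_model()].
#' @export
model_kernel_stack <- function(model = c("GP", "PP", "GP+PP"),
                               scope = c("single", "combined"),
                               records, G_f = NULL, G_m = NULL, H = NULL,
                               P = NULL) {
  model <- match.arg(model)
  scope <- match.arg(scope)
  map <- incidence_map(records)
  n <- map$n_records
  ks <- list()
  if (model %in% c("GP", "GP+PP")) {
    if (is.null(G_f) || is.null(G_m) || is.null(H))
      stop(model, " needs G_f, G_m and H kernels")
    ks$female <- expand_to_records(G_f, map, "female")
    ks$male <- expand_to_records(G_m, map, "male")
    ks$sca <- expand_to_records(H, map, "hybrid")
  }
  if (model %in% c("PP", "GP+PP")) {
    if (is.null(P)) stop(model, " needs a phenomic kernel P")
    if (nrow(P) == n) {
      ks$phenomic <- rel_kernel(as.matrix(P),
                                ids = sprintf("rec%04d", seq_len(n)),
                                provenance = "phenomic", check = FALSE)
    } else {
      ks$phenomic <- expand_to_records(P, map, "hybrid")
    }
  }
  if (scope == "combined") {
    envs <- levels(map$env)
    if (length(envs) < 2) stop("combined scope needs >= 2 environments")
    I_env <- rel_kernel(diag(length(envs)), ids = envs,
                        provenance = "environment", check = FALSE)
    ks$env <- expand_to_records(I_env, map, "env")
    if (!is.null(ks$female)) {
      ks$female_env <- interaction_hadamard(ks$female, map$env)
      ks$male_env <- interaction_hadamard(ks$male, map$env)
      ks$sca_env <- interaction_hadamard(ks$sca, map$env)
    }
    if (!is.null(ks$phenomic))
      ks$nir_env <- interaction_hadamard(ks$phenomic, map$env)
  }
  ks
}

#' Assemble a multi-kernel RKHS model
#'
#' Eigen-decomposes each record-level kernel once (eigenvalues below
#' `1e-8 * max` are dropped, which also clips small negative values from
#' floating-point noise) so that Gibbs updates can be performed in the
#' eigenbasis, where the conditional posterior of a kernel's effect vector
#' factorizes into independent Gaussians.
#'
#' @param kernels Named list of record-level kernels (all `n x n` in the
#'   same record order).
#' @param record_ids Character IDs for the records (defaults to positional).
#' @return An object of class `kernel_model`.
#' @export
build_model <- function(kernels, record_ids = NULL) {
  if (!length(kernels) || is.null(names(kernels)) || any(names(kernels) == ""))
    stop("kernels must be a non-empty named list")
  n <- nrow(kernels[[1]])
  if (is.null(record_ids)) record_ids <- sprintf("rec%04d", seq_len(n))
  if (length(record_ids) != n) stop("record_ids length mismatch")
  terms <- lapply(names(kernels), function(nm) {
    K <- as.matrix(kernels[[nm]])
    if (nrow(K) != n || ncol(K) != n)
      stop("kernel `", nm, "` is not aligned with the record set")
    ed <- eigen(K, symmetric = TRUE)
    if (min(ed$values) < -1e-8 * max(abs(ed$values), 1))
      stop("kernel `", nm, "` is not PSD")
    keep <- ed$values > 1e-8 * max(ed$values, 0)
    if (!any(keep)) stop("kernel `", nm, "` is numerically zero")
    list(V = ed$vectors[, keep, drop = FALSE], lambda = ed$values[keep],
         mean_diag = mean(diag(K)))
  })
  names(terms) <- names(kernels)
  structure(list(terms = terms, n = n, record_ids = record_ids),
            class = "kernel_model")
}

#' @export
print.kernel_model <- function(x, ...) {
  cat("<kernel_model> ", x$n, " records; kernels: ",
      paste(sprintf("%s(%d)", names(x$terms),
                    vapply(x$terms, function(t) length(t$lambda), 1L)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fit a multi-kernel RKHS model by Gibbs sampling
#'
#' Bayesian mixed model `y = mu + sum_k u_k + e` with `u_k ~ N(0, s2_k K_k)`
#' for each kernel and `e ~ N(0, s2_e I)`. Kernel effects are sampled in the
#' eigenbasis of their kernel (Gaussian conditionals, vectorized over
#' eigencomponents); variances get scaled-inverse-chi-square conditionals
#' with `df0` prior degrees of freedom and prior scales that split `R2` of
#' the response variance equally among kernels at the prior mode. Missing
#' responses are imputed by data augmentation each sweep, so posterior-mean
#' fitted values double as predictions for unobserved records.
#'
#' @param model A [build_model()] result.
#' @param y Numeric response of length `model$n`; `NA` marks records to
#'   predict.
#' @param iters,burnin,thin Chain settings (defaults 5000 / 1000 / 10).
#' @param seed Optional integer seed (reproducible chains).
#' @param df0 Prior degrees of freedom for every variance (default 5).
#' @param R2 Prior proportion of response variance attributed to the
#'   kernels jointly (default 0.5).
#' @param fix_varcomp Optional named numeric of variance components to hold
#'   fixed (kernel names and/or `"residual"`); fixed components skip their
#'   Gibbs update, turning the fit into a BLUP-style conditional model.
#' @return An object of class `rkhs_fit`: posterior means of fitted values
#'   (`yhat`), record effects per kernel (`effects`), variance components
#'   (`varcomp`, posterior mean and SD), thinned variance samples, a
#'   split-chain potential-scale-reduction diagnostic per variance
#'   (warned about if > 1.1), and the chain settings.
#' @export
gibbs_fit <- function(model, y, iters = 5000, burnin = 1000, thin = 10,
                      seed = NULL, df0 = 5, R2 = 0.5, fix_varcomp = NULL) {
  stopifnot(inherits(model, "kernel_model"))
  if (length(y) != model$n) stop("response length must match record count")
  obs <- !is.na(y)
  if (!any(obs)) stop("all responses missing")
  if (iters <= burnin) stop("iters must exceed burnin")
  if (!is.null(seed)) set.seed(seed)

  n <- model$n
  K <- length(model$terms)
  knames <- names(model$terms)
  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy == 0) vy <- 1e-8

  fixed <- function(nm) !is.null(fix_varcomp) && nm %in% names(fix_varcomp)
  s2 <- vapply(knames, function(nm) {
    if (fixed(nm)) fix_varcomp[[nm]]
    else R2 * vy / (K * model$terms[[nm]]$mean_diag)
  }, numeric(1))
  s2e <- if (fixed("residual")) fix_varcomp[["residual"]] else (1 - R2) * vy
  S0 <- vapply(knames, function(nm)
    R2 * vy / (K * model$terms[[nm]]$mean_diag) * (df0 + 2), numeric(1))
  Se0 <- (1 - R2) * vy * (df0 + 2)

  mu <- mean(y[obs])
  ystar <- y
  ystar[!obs] <- mu
  U <- matrix(0, n, K, dimnames = list(NULL, knames))
  b <- lapply(model$terms, function(t) numeric(length(t$lambda)))
  e <- ystar - mu

  n_keep <- floor((iters - burnin) / thin)
  var_samples <- matrix(NA_real_, n_keep, K + 1,
                        dimnames = list(NULL, c(knames, "residual")))
  yhat_sum <- numeric(n)
  U_sum <- matrix(0, n, K)
  mu_sum <- 0
  kept <- 0

  for (it in seq_len(iters)) {
    # intercept
    emu <- e + mu
    mu <- stats::rnorm(1, mean(emu), sqrt(s2e / n))
    e <- emu - mu
    # kernel effects in the eigenbasis
    for (k in seq_len(K)) {
      tk <- model$terms[[k]]
      ek <- e + U[, k]
      d <- crossprod(tk$V, ek)
      lam_s2 <- tk$lambda * s2[k]
      shrink <- lam_s2 / (lam_s2 + s2e)
      bk <- shrink * d + sqrt(shrink * s2e) * stats::rnorm(length(d))
      b[[k]] <- drop(bk)
      uk <- drop(tk$V %*% bk)
      U[, k] <- uk
      e <- ek - uk
      if (!fixed(knames[k])) {
        ss <- sum(b[[k]]^2 / tk$lambda)
        s2[k] <- (S0[k] + ss) / stats::rchisq(1, df0 + length(tk$lambda))
      }
    }
    # residual variance
    if (!fixed("residual"))
      s2e <- (Se0 + sum(e^2)) / stats::rchisq(1, df0 + n)
    # impute missing responses
    if (any(!obs)) {
      fitted_miss <- mu + rowSums(U[!obs, , drop = FALSE])
      ystar[!obs] <- fitted_miss + stats::rnorm(sum(!obs), 0, sqrt(s2e))
      e[!obs] <- ystar[!obs] - fitted_miss
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      kept <- kept + 1
      var_samples[kept, ] <- c(s2, s2e)
      yhat_sum <- yhat_sum + mu + rowSums(U)
      U_sum <- U_sum + U
      mu_sum <- mu_sum + mu
    }
  }

  rhat <- apply(var_samples[seq_len(kept), , drop = FALSE], 2, .split_rhat)
  if (any(rhat > 1.1, na.rm = TRUE))
    warning("potential-scale-reduction > 1.1 for: ",
            paste(names(rhat)[which(rhat > 1.1)], collapse = ", "),
            " - consider a longer chain")
  varcomp <- data.frame(
    term = colnames(var_samples),
    mean = colMeans(var_samples[seq_len(kept), , drop = FALSE]),
    sd = apply(var_samples[seq_len(kept), , drop = FALSE], 2, stats::sd),
    rhat = rhat, row.names = NULL)
  structure(list(
    yhat = stats::setNames(yhat_sum / kept, model$record_ids),
    mu = mu_sum / kept,
    effects = U_sum / kept,
    varcomp = varcomp,
    var_samples = var_samples[seq_len(kept), , drop = FALSE],
    record_ids = model$record_ids, observed = obs,
    settings = list(iters = iters, burnin = burnin, thin = thin,
                    df0 = df0, R2 = R2, seed = seed)),
    class = "rkhs_fit")
}

.split_rhat <- function(x) {
  m <- length(x) %/% 2
  if (m < 2) return(NA_real_)
  a <- x[seq_len(m)]; bb <- x[(m + 1):(2 * m)]
  W <- (stats::var(a) + stats::var(bb)) / 2
  if (W <= 0) return(1)
  mu_all <- mean(c(a, bb))
  B <- m * ((mean(a) - mu_all)^2 + (mean(bb) - mu_all)^2)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' @export
print.rkhs_fit <- function(x, ...) {
  cat("<rkhs_fit> ", length(x$yhat), " records (",
      sum(!x$observed), " predicted); ", nrow(x$var_samples),
      " kept samples\n", sep = "")
  print(x$varcomp, digits = 3)
  invisible(x)
}

#' Posterior-mean predictions for records
#'
#' Extracts posterior-mean fitted values (`mu + sum of kernel effects`) for
#' the requested records of a stored fit; deterministic given the fit.
#' Records must have been part of the model's record set (observed or
#' masked).
#'
#' @param fit An `rkhs_fit`.
#' @param ids Record IDs to predict (default: all masked records).
#' @return Named numeric vector of predictions.
#' @export
predict_records <- function(fit, ids = NULL) {
  stopifnot(inherits(fit, "rkhs_fit"))
  if (is.null(ids)) ids <- fit$record_ids[!fit$observed]
  idx <- match(ids, fit$record_ids)
  if (anyNA(idx)) stop("unknown record ID(s): ",
                       paste(ids[is.na(idx)], collapse = ", "))
  fit$yhat[idx]
}
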