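#' Cross-validation partitions for hybrid prediction
#'
#' Generates seeded train/test partitions of the hybrids for the three
#' prediction scenarios of multi-environment hybrid trials:
#' * **CV1** - untested hybrids in characterized environments: a 70:30
#'   hybrid split; all records of test hybrids are masked (e.g. 30 x 8 = 240
#'   masked records for 100 hybrids in 8 environments, leaving 560 for
#'   training).
#' * **CV2** - tested hybrids in an uncharacterized environment: the
#'   held-out environment is masked entirely, plus test-hybrid records
#'   everywhere (100 + 30 x 7 = 310 masked; 490 training); accuracy is later
#'   scored on the *train* hybrids in the held-out environment.
#' * **CV3** - untested hybrids in an uncharacterized environment: same
#'   masking as CV2, scored on the *test* hybrids in the held-out
#'   environment.
#'
#' @param records Record table with `record_id`, `env`, `hybrid` (one row
#'   per hybrid x environment, e.g. per-environment BLUEs).
#' @param scheme `"CV1"`, `"CV2"`, or `"CV3"`.
#' @param n_repeats Number of repeated partitions (default 50).
#' @param held_out_env Environment label to hold out (required for CV2/CV3).
#' @param seed Integer seed; partitions are deterministic given it.
#' @param train_frac Training fraction of hybrids (default 0.7).
#' @return List of `cv_partition` objects with elements `scheme`, `rep`,
#'   `train_hybrids`, `test_hybrids`, `held_out_env`, `masked` (record IDs),
#'   `train` (record IDs).
#' @export
make_partitions <- function(records, scheme = c("CV1", "CV2", "CV3"),
                            n_repeats = 50, held_out_env = NULL, seed = NULL,
                            train_frac = 0.7) {
  scheme <- match.arg(scheme)
  stopifnot(n_repeats >= 1)
  if (!"record_id" %in% names(records))
    records$record_id <- paste(records$env, records$hybrid, sep = "_")
  hybrids <- unique(records$hybrid)
  if (scheme %in% c("CV2", "CV3")) {
    if (is.null(held_out_env)) stop(scheme, " requires held_out_env")
    if (!held_out_env %in% records$env)
      stop("held-out environment absent: ", held_out_env)
  }
  if (!is.null(seed)) set.seed(seed)
  n_train <- round(train_frac * length(hybrids))
  lapply(seq_len(n_repeats), function(i) {
    train_h <- sample(hybrids, n_train)
    test_h <- setdiff(hybrids, train_h)
    masked <- records$hybrid %in% test_h
    if (scheme != "CV1") masked <- masked | records$env == held_out_env
    structure(list(scheme = scheme, rep = i,
                   train_hybrids = train_h, test_hybrids = test_h,
                   held_out_env = held_out_env,
                   masked = records$record_id[masked],
                   train = records$record_id[!masked]),
              class = "cv_partition")
  })
}

#' Score one partition's predictions
#'
#' Pearson correlation of predictions with the masked observed values,
#' computed per test environment over the hybrids the scheme targets: CV1
#' scores test hybrids in every environment; CV2 scores train hybrids in the
#' held-out environment; CV3 scores test hybrids there.
#'
#' @param predictions Named numeric (by `record_id`) covering all masked
#'   records.
#' @param partition A `cv_partition`.
#' @param records Record table with observed values.
#' @param response Response column name (truth).
#' @param model Optional model label carried into the result.
#' @return Tibble rows: `scheme`, `rep`, `env`, `model`, `trait`, `r`, `n`.
#' @export
score_partition <- function(predictions, partition, records, response,
                            model = NA_character_) {
  if (!"record_id" %in% names(records))
    records$record_id <- paste(records$env, records$hybrid, sep = "_")
  miss <- setdiff(partition$masked, names(predictions))
  if (length(miss)) stop("predictions missing for masked records: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  cells <- switch(partition$scheme,
    CV1 = lapply(unique(records$env), function(e)
      list(env = e, hybrids = partition$test_hybrids)),
    CV2 = list(list(env = partition$held_out_env,
                    hybrids = partition$train_hybrids)),
    CV3 = list(list(env = partition$held_out_env,
                    hybrids = partition$test_hybrids)))
  rows <- lapply(cells, function(cell) {
    sel <- records$env == cell$env & records$hybrid %in% cell$hybrids
    ids <- records$record_id[sel]
    if (length(ids) < 3) stop("fewer than 3 test records in ", cell$env)
    tibble::tibble(scheme = partition$scheme, rep = partition$rep,
                   env = cell$env, model = model, trait = response,
                   r = stats::cor(predictions[ids], records[[response]][sel]),
                   n = length(ids))
  })
  do.call(rbind, rows)
}

#' Run a cross-validation scheme over prediction models
#'
#' Fits each requested model on each partition's unmasked records with the
#' RKHS Gibbs sampler, predicts the masked records, and scores them
#' according to the scheme. Kernels are eigen-decomposed once per model and
#' reused across repeats.
#'
#' @param records BLUE-level record table (`record_id`, `env`, `female`,
#'   `male`, `hybrid`, response column).
#' @param response Response column name.
#' @param models Character subset of `c("GP", "PP", "GP+PP")`.
#' @param scheme `"CV1"`, `"CV2"`, or `"CV3"`.
#' @param n_repeats Number of repeats (default 50).
#' @param held_out_env Required for CV2/CV3.
#' @param G_f,G_m,H,P Kernels passed to [model_kernel_stack()].
#' @param scope `"combined"` (default) or `"single"`.
#' @param iters,burnin,thin Chain settings per fit.
#' @param seed Master seed: partitions and chains are reproducible given it.
#' @return An accuracy table (tibble): one row per scheme x repeat x
#'   environment x model with Pearson `r` and test-record count `n`.
#' @export
run_scheme <- function(records, response, models = c("GP", "PP", "GP+PP"),
                       scheme = "CV1", n_repeats = 50, held_out_env = NULL,
                       G_f = NULL, G_m = NULL, H = NULL, P = NULL,
                       scope = "combined", iters = 5000, burnin = 1000,
                       thin = 10, seed = NULL) {
  if (!"record_id" %in% names(records))
    records$record_id <- paste(records$env, records$hybrid, sep = "_")
  built <- lapply(models, function(mod) {
    ks <- model_kernel_stack(mod, scope = scope, records = records,
                             G_f = G_f, G_m = G_m, H = H, P = P)
    build_model(ks, record_ids = records$record_id)
  })
  names(built) <- models
  parts <- make_partitions(records, scheme, n_repeats = n_repeats,
                           held_out_env = held_out_env, seed = seed)
  y_full <- records[[response]]
  out <- list()
  for (p in parts) {
    y <- y_full
    y[records$record_id %in% p$masked] <- NA
    for (mod in models) {
      chain_seed <- if (is.null(seed)) NULL
                    else (seed + 97L * p$rep + match(mod, models)) %% .Machine$integer.max
      fit <- gibbs_fit(built[[mod]], y, iters = iters, burnin = burnin,
                       thin = thin, seed = chain_seed)
      preds <- predict_records(fit, p$masked)
      out[[length(out) + 1]] <-
        score_partition(preds, p, records, response, model = mod)
    }
  }
  do.call(rbind, out)
}

#' Summarize an accuracy table
#'
#' Averages per-environment accuracies within each repeat (unweighted), then
#' reports mean and standard error over repeats per scheme x model x trait.
#'
#' @param accuracies Accuracy table from [run_scheme()]/[score_partition()].
#' @return Tibble: `scheme`, `model`, `trait`, `mean`, `se`, `n_repeats`.
#' @export
summarize_accuracy <- function(accuracies) {
  rep_means <- stats::aggregate(r ~ scheme + model + trait + rep,
                                data = accuracies, FUN = mean)
  agg <- stats::aggregate(r ~ scheme + model + trait, data = rep_means,
                          FUN = function(x) c(mean = mean(x),
                                              se = stats::sd(x) / sqrt(length(x)),
                                              n = length(x)))
  tibble::tibble(scheme = agg$scheme, model = agg$model, trait = agg$trait,
                 mean = agg$r[, "mean"], se = agg$r[, "se"],
                 n_repeats = as.integer(agg$r[, "n"]))
}

#' Tukey comparison of model accuracies
#'
#' One-way comparison of prediction models on repeat-level mean accuracies:
#' ANOVA followed by Tukey's honest significant difference at `alpha`, with
#' a compact letter display (models sharing a letter are not significantly
#' different).
#'
#' @param accuracies Accuracy table (needs >= 2 models, >= 2 repeats each).
#' @param alpha Significance level (default 0.05).
#' @return List with `summary` (tibble: model, mean, se, letters) and
#'   `tukey` (the [stats::TukeyHSD()] pair table).
#' @export
tukey_compare <- function(accuracies, alpha = 0.05) {
  rep_means <- stats::aggregate(r ~ model + rep, data = accuracies, FUN = mean)
  if (length(unique(rep_means$model)) < 2) stop("need >= 2 models")
  if (min(table(rep_means$model)) < 2) stop("need >= 2 repeats per model")
  rep_means$model <- factor(rep_means$model)
  fit <- stats::aov(r ~ model, data = rep_means)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$model
  means <- tapply(rep_means$r, rep_means$model, mean)
  ses <- tapply(rep_means$r, rep_means$model,
                function(x) stats::sd(x) / sqrt(length(x)))
  letters <- .compact_letters(names(means), tk[, "p adj"], means, alpha)
  list(summary = tibble::tibble(model = names(means),
                                mean = as.numeric(means),
                                se = as.numeric(ses),
                                letters = letters[names(means)]),
       tukey = tk)
}

# compact letter display from pairwise adjusted p-values: one letter per
# maximal clique of the "not significantly different" graph
.compact_letters <- function(groups, p_adj, means, alpha) {
  g <- length(groups)
  same <- matrix(TRUE, g, g, dimnames = list(groups, groups))
  for (nm in names(p_adj)) {
    pair <- strsplit(nm, "-", fixed = TRUE)[[1]]
    if (length(pair) == 2 && all(pair %in% groups) && !is.na(p_adj[nm])) {
      sig <- p_adj[nm] < alpha
      same[pair[1], pair[2]] <- same[pair[2], pair[1]] <- !sig
    }
  }
  # enumerate maximal cliques (few groups, brute force over subsets)
  cliques <- list()
  for (bits in seq_len(2^g - 1)) {
    members <- which(bitwAnd(bits, 2^(seq_len(g) - 1)) > 0)
    if (all(same[members, members])) cliques[[length(cliques) + 1]] <- members
  }
  keep <- vapply(cliques, function(cl)
    !any(vapply(cliques, function(other)
      length(other) > length(cl) && all(cl %in% other), logical(1))),
    logical(1))
  cliques <- cliques[keep]
  ord <- order(vapply(cliques, function(cl) -max(means[cl]), numeric(1)))
  cliques <- cliques[ord]
  out <- stats::setNames(rep("", g), groups)
  for (i in seq_along(cliques)) {
    out[cliques[[i]]] <- paste0(out[cliques[[i]]], letters[i])
  }
  out
}
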