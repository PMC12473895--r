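#' Factorial trial design specification
#'
#' Describes a female x male factorial (NC-II) mating design evaluated in one
#' or more environments with replicated plots. Every female parent is crossed
#' to every male parent, so the design enumerates `n_female * n_male` hybrids,
#' each mapping to exactly one (female, male) pair.
#'
#' @param n_female Number of female parents (>= 1).
#' @param n_male Number of male parents (>= 1).
#' @param environments Character vector of environment labels. Defaults to
#'   eight environments, the size of the motivating multi-environment trial.
#' @param replicates Integer replicate count per environment; either a single
#'   value recycled across environments or one value per environment. All
#'   counts must be >= 1.
#' @param traits Character vector of trait names the design carries.
#'
#' @return An object of class `design_spec`: a list with elements `n_female`,
#'   `n_male`, `females`, `males`, `environments`, `replicates` (named per
#'   environment), `traits`, and `hybrids`, a [tibble::tibble()] with columns
#'   `hybrid`, `female`, `male` enumerating all crosses.
#' @examples
#' ds <- design_spec(n_female = 3, n_male = 2, environments = c("E1", "E2"))
#' ds$hybrids
#' @export
design_spec <- function(n_female = 10, n_male = 10,
                        environments = paste0("E", 1:8),
                        replicates = 2,
                        traits = "GY") {
  stopifnot(n_female >= 1, n_male >= 1, length(environments) >= 1)
  environments <- as.character(environments)
  if (anyDuplicated(environments)) stop("duplicated environment labels")
  if (length(replicates) == 1) replicates <- rep(replicates, length(environments))
  if (length(replicates) != length(environments))
    stop("`replicates` must have length 1 or one entry per environment")
  if (any(replicates < 1)) stop("every environment needs replicate count >= 1")
  replicates <- stats::setNames(as.integer(replicates), environments)

  females <- sprintf("F%02d", seq_len(n_female))
  males <- sprintf("M%02d", seq_len(n_male))
  grid <- expand.grid(male = males, female = females,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  hybrids <- tibble::tibble(
    hybrid = paste(grid$female, grid$male, sep = "x"),
    female = grid$female,
    male = grid$male
  )
  structure(
    list(n_female = as.integer(n_female), n_male = as.integer(n_male),
         females = females, males = males,
         environments = environments, replicates = replicates,
         traits = traits, hybrids = hybrids),
    class = "design_spec"
  )
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Factorial design:", x$n_female, "females x", x$n_male, "males =",
      nrow(x$hybrids), "hybrids\n")
  cat("Environments:", paste(x$environments, collapse = ", "), "\n")
  cat("Replicates:", paste(x$replicates, collapse = "/"),
      "| traits:", paste(x$traits, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate plot records implied by a design
#'
#' Expands a [design_spec()] into its full plot layout: one row per
#' (environment, replicate, hybrid) combination.
#'
#' @param design A [design_spec()].
#' @return A tibble with columns `env`, `rep`, `female`, `male`, `hybrid`.
#' @export
design_records <- function(design) {
  stopifnot(inherits(design, "design_spec"))
  out <- lapply(design$environments, function(env) {
    reps <- seq_len(design$replicates[[env]])
    grid <- expand.grid(row = seq_len(nrow(design$hybrids)), rep = reps,
                        KEEP.OUT.ATTRS = FALSE)
    tibble::tibble(
      env = env,
      rep = paste0("R", grid$rep),
      female = design$hybrids$female[grid$row],
      male = design$hybrids$male[grid$row],
      hybrid = design$hybrids$hybrid[grid$row]
    )
  })
  do.call(rbind, out)
}

#' Record-to-entity incidence map
#'
#' Collects the factor assignments that define the 0/1 incidence matrices of
#' the mixed models: each record maps to exactly one level of each factor.
#' All record-level kernel algebra is driven by these assignments rather than
#' by positional indexing.
#'
#' @param records A data frame with (at least) columns `env`, `female`,
#'   `male`, `hybrid`, and optionally `rep`.
#' @return An object of class `incidence_map`: a list of factors, one per
#'   design dimension, all of equal length `n_records`.
#' @export
incidence_map <- function(records) {
  need <- c("env", "female", "male", "hybrid")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  out <- list(
    env = factor(records$env),
    female = factor(records$female),
    male = factor(records$male),
    hybrid = factor(records$hybrid)
  )
  if ("rep" %in% names(records))
    out$rep <- factor(paste(records$env, records$rep, sep = ":"))
  out$n_records <- length(out$env)
  class(out) <- "incidence_map"
  out
}
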