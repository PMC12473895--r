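# Shared fixtures: small factorial trials built in code.

tiny_design <- function(n_env = 2, r = 2, nf = 4, nm = 3) {
  design_spec(n_female = nf, n_male = nm,
              environments = paste0("E", seq_len(n_env)), replicates = r)
}

# plot records with known iid effect draws (kernel-free mode)
tiny_trial_records <- function(design = tiny_design(), seed = 101,
                               components = NULL) {
  arch <- if (is.null(components)) trait_architecture(genomic = FALSE)
          else trait_architecture(components, genomic = FALSE)
  simulate_trait_records(design, arch, seed = seed)
}

# Table 1 grain-yield parameterization (the generator default)
gy_components <- c(female = 0.18, male = 0.18, sca = 0.03, env = 1.30,
                   female_env = 0.16, male_env = 0.09, sca_env = 0.078,
                   rep_env = 0.02, residual = 0.634)

# closed-form GLS/BLUP oracle for fixed variance components:
# mu by GLS on observed records, u = C V^-1 (y_o - mu), predictions for all
# records via the cross-covariance block
blup_oracle <- function(kernels, s2, s2e, y) {
  obs <- !is.na(y)
  C <- Reduce(`+`, Map(function(K, s) s * as.matrix(K), kernels, s2))
  V <- C[obs, obs] + s2e * diag(sum(obs))
  one <- rep(1, sum(obs))
  mu <- sum(one * solve(V, y[obs])) / sum(one * solve(V, one))
  mu + C[, obs] %*% solve(V, y[obs] - mu)
}
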