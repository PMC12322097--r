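# Shared fixtures: small schemas, quick designs and a hand-built fit object
# used by the post-estimation and ranking tests.

# 3-attribute schema (2 x 2 x 2 = 8 profiles) for brute-force oracles
small_schema <- function() {
  attribute_schema(
    attribute("ppv", c(40, 80), "categorical", reference = 80),
    attribute("site", c("yes", "no"), "categorical", reference = "no"),
    attribute("form", c("blood", "faecal"), "categorical", reference = "blood")
  )
}

# schema with a single binary attribute
binary_schema <- function() {
  attribute_schema(attribute("site", c("yes", "no"), "categorical", reference = "no"))
}

# deterministic small design on the canonical schema (cheap: few sweeps)
cached_design <- local({
  des <- NULL
  function() {
    if (is.null(des)) {
      pri <- read_priors()
      des <<- generate_design(mct_schema(), pri, n_tasks = 24, n_blocks = 2,
                              seed = 11, n_sweeps = 10, n_prior_draws = 50)
    }
    des
  }
})

# a dce_fit-shaped object from explicit coefficients (single-group: the
# estimates ARE the gp-level coefficients); used to test post-estimation
# arithmetic against closed forms
manual_fit <- function(est, cov = NULL, schema = mct_schema()) {
  if (is.null(cov)) cov <- diag(1e-12, length(est))
  dimnames(cov) <- list(names(est), names(est))
  structure(list(
    estimates = est, covariance = cov, se = sqrt(diag(cov)),
    tstat = est / sqrt(diag(cov)),
    ll_final = NA_real_, ll_zero = NA_real_, n_draws = 0L,
    draw_type = "none", convergence = list(converged = TRUE),
    seed = 1L, n_respondents = 0L, n_obs = 0L,
    spec = utility_spec(schema, scale = "none", weights = FALSE),
    latent = NULL, measurement = NULL, groups = "gp",
    param_names = names(est), removal_trail = NULL), class = "dce_fit")
}

# truth restricted to what the pooled estimator models (no covariate or
# latent-variable shifts)
pooled_truth <- function(...) true_parameters(covariate = 0, tau = 0, ...)

# log-mean-exp helper for R-side likelihood oracles
lse_mean <- function(x) { m <- max(x); m + log(mean(exp(x - m))) }
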