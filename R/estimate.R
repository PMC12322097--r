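#' Estimation options
#'
#' @param n_draws Halton draws per respondent for simulated likelihoods.
#' @param seed Integer seed driving the draw scrambling (and recorded in the
#'   result).
#' @param max_iter Maximum BFGS iterations.
#' @param grad_tol Gradient-norm threshold below which the fit is declared
#'   converged.
#' @param hessian If `TRUE`, compute the clustered sandwich covariance
#'   (numerical Hessian bread, per-respondent score meat).
#' @param start Optional named start vector (defaults: zeros, then a
#'   two-stage start for mixed/ICLV models).
#' @param verbose Print optimizer progress.
#' @return List of class `dce_options`.
#' @export
estimation_options <- function(n_draws = 500L, seed = 1L, max_iter = 1000L,
                               grad_tol = 1e-5, hessian = TRUE, start = NULL,
                               verbose = FALSE) {
  structure(list(n_draws = as.integer(n_draws), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), grad_tol = grad_tol,
                 hessian = hessian, start = start, verbose = verbose),
            class = "dce_options")
}

#' Estimate a (mixed) multinomial logit choice model
#'
#' Maximises the weighted (simulated) log-likelihood by BFGS with analytic
#' gradients. Models without random coefficients are plain multinomial logit;
#' models with random coefficients are panel mixed logit estimated by
#' simulated maximum likelihood over scrambled Halton draws, started from the
#' fixed-coefficient estimates. Scale parameters are estimated on the log
#' scale (positivity by construction). The reported covariance is the
#' respondent-clustered sandwich, appropriate under sample weighting.
#'
#' @param data Long-format choice data.
#' @param spec A [utility_spec()].
#' @param options An [estimation_options()] list.
#' @return Object of class `dce_fit`: estimates, covariance, standard
#'   errors, t-ratios, log-likelihoods, convergence diagnostics, seed.
#' @export
estimate <- function(data, spec, options = estimation_options()) {
  bundle <- encode(data, spec)
  fit_bundle(bundle, options)
}

fit_bundle <- function(bundle, options, two_stage = TRUE) {
  tmpl <- param_template(bundle)
  Krand <- length(bundle$rand_cols)
  draws <- make_draws(bundle$n_respondents, options$n_draws, Krand,
                      latent = FALSE, seed = options$seed)
  start <- options$start
  if (is.null(start)) {
    start <- tmpl
    if (Krand > 0L && two_stage) {
      # stage 1: fixed-coefficient logit for starting values
      mnl <- stats::optim(unname(tmpl), fn = neg_ll, gr = neg_gr,
                          bundle = bundle, draws = list(xi = NULL, eta = NULL, R = 1L),
                          fixed_sigma = TRUE,
                          method = "BFGS",
                          control = list(maxit = options$max_iter, reltol = 1e-10))
      start[] <- mnl$par
      start[grep("^sd_", names(start))] <- 0.1
    }
  }
  use_draws <- if (Krand > 0L) draws else list(xi = NULL, eta = NULL, R = 1L)
  opt <- stats::optim(unname(start), fn = neg_ll, gr = neg_gr,
                      bundle = bundle, draws = use_draws, fixed_sigma = FALSE,
                      method = "BFGS",
                      control = list(maxit = options$max_iter, reltol = 1e-12,
                                     trace = if (options$verbose) 1L else 0L))
  est <- stats::setNames(opt$par, names(tmpl))
  ll <- eval_loglik(est, bundle, use_draws, want_scores = TRUE)
  grad_norm <- max(abs(attr(ll, "gradient")))
  build_fit(bundle, est, ll, use_draws, options, opt, grad_norm,
            class = "dce_fit")
}

neg_ll <- function(p, bundle, draws, fixed_sigma = FALSE) {
  if (fixed_sigma) p[grep("^sd_", names(param_template(bundle)))] <- 0
  -as.numeric(eval_loglik(p, bundle, draws))
}

neg_gr <- function(p, bundle, draws, fixed_sigma = FALSE) {
  nm <- names(param_template(bundle))
  sdi <- grep("^sd_", nm)
  if (fixed_sigma) p[sdi] <- 0
  g <- attr(eval_loglik(p, bundle, draws), "gradient")
  if (fixed_sigma) g[sdi] <- 0
  -as.numeric(g)
}

build_fit <- function(bundle, est, ll, draws, options, opt, grad_norm, class) {
  scores <- attr(ll, "scores")
  covm <- NULL; se <- rep(NA_real_, length(est))
  if (isTRUE(options$hessian)) {
    H <- numeric_hessian(function(p) {
      attr(eval_loglik(stats::setNames(p, names(est)), bundle, draws), "gradient")
    }, unname(est))
    covm <- sandwich_cov(H, scores)
    dimnames(covm) <- list(names(est), names(est))
    se <- sqrt(pmax(diag(covm), 0))
  }
  structure(list(
    estimates = est, covariance = covm, se = se,
    tstat = est / se,
    ll_final = as.numeric(ll), ll_zero = null_loglik(bundle),
    n_draws = draws$R, draw_type = "scrambled halton",
    convergence = list(grad_norm = grad_norm, code = opt$convergence,
                       converged = opt$convergence == 0L &&
                         grad_norm < max(options$grad_tol * max(1, abs(as.numeric(ll))), options$grad_tol * 100),
                       message = opt$message),
    seed = options$seed,
    n_respondents = bundle$n_respondents, n_obs = bundle$n_obs,
    spec = bundle$spec, latent = bundle$latent, measurement = bundle$measurement,
    groups = unique(bundle$group),
    param_names = names(est), removal_trail = NULL
  ), class = c(class, "dce_fit"))
}

# central-difference Hessian of the log-likelihood from the analytic gradient
numeric_hessian <- function(grad_fun, par, eps = 1e-5) {
  P <- length(par)
  H <- matrix(0, P, P)
  for (j in seq_len(P)) {
    h <- eps * max(1, abs(par[j]))
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    H[, j] <- (grad_fun(up) - grad_fun(dn)) / (2 * h)
  }
  (H + t(H)) / 2
}

# respondent-clustered sandwich: bread = inverse Hessian of the weighted LL,
# meat = sum of outer products of the (weighted) respondent scores
sandwich_cov <- function(H, scores) {
  bread <- tryCatch(solve(-H), error = function(e) MASS::ginv(-H))
  meat <- crossprod(scores)
  V <- bread %*% meat %*% t(bread)
  (V + t(V)) / 2
}

#' @export
print.dce_fit <- function(x, ...) {
  cat("Choice model fit:", x$n_respondents, "respondents,", x$n_obs, "tasks\n")
  cat(sprintf("  logLik %.2f (null %.2f), %s draws: %d, converged: %s\n",
              x$ll_final, x$ll_zero, x$draw_type, x$n_draws,
              x$convergence$converged))
  tab <- summary(x)
  print(round(tab, 4))
  invisible(x)
}

#' @export
summary.dce_fit <- function(object, ...) {
  cbind(estimate = object$estimates, se = object$se, t = object$tstat)
}

#' @export
coef.dce_fit <- function(object, ...) object$estimates

#' @export
vcov.dce_fit <- function(object, ...) object$covariance

#' @export
logLik.dce_fit <- function(object, ...) {
  structure(object$ll_final, df = length(object$estimates), class = "logLik")
}

#' Backward refinement of interaction terms
#'
#' Fits the full model, then iteratively removes the single interaction term
#' with the smallest |t| below the threshold and refits, until every
#' remaining interaction passes. Main effects (and scale/spread parameters)
#' are never removed.
#'
#' @param data Long-format choice data.
#' @param spec A [utility_spec()] including candidate interaction terms.
#' @param alpha_t |t| threshold below which an interaction is removable
#'   (default 1.96).
#' @param options An [estimation_options()] list.
#' @param candidates Encoded interaction column names eligible for removal;
#'   defaults to all sample and covariate interaction columns.
#' @return A `dce_fit` for the final model, with `removal_trail` recording
#'   the removed terms and their |t| at removal.
#' @export
refine_interactions <- function(data, spec, alpha_t = 1.96,
                                options = estimation_options(),
                                candidates = NULL) {
  trail <- list()
  cur <- spec
  repeat {
    fit <- estimate(data, cur, options)
    cand <- candidates
    if (is.null(cand))
      cand <- grep("^(pub_x_|cov_)", names(fit$estimates), value = TRUE)
    cand <- intersect(cand, names(fit$estimates))
    if (!length(cand)) break
    tv <- abs(fit$tstat[cand])
    if (all(tv >= alpha_t) || !any(is.finite(tv))) break
    drop_col <- cand[which.min(tv)]
    trail[[length(trail) + 1L]] <- list(term = drop_col, t = unname(tv[drop_col]))
    cur <- remove_interaction(cur, drop_col)
    candidates <- setdiff(cand, drop_col)
  }
  fit$removal_trail <- trail
  fit
}

remove_interaction <- function(spec, col) {
  if (startsWith(col, "pub_x_")) {
    spec$sample_interactions <- setdiff(spec$sample_interactions,
                                        sub("^pub_x_", "", col))
  } else if (startsWith(col, "cov_")) {
    body <- sub("^cov_", "", col)
    for (cv in names(spec$covariate_interactions)) {
      pre <- paste0(cv, "_x_")
      if (startsWith(body, pre)) {
        tgt <- sub(pre, "", body, fixed = TRUE)
        spec$covariate_interactions[[cv]] <-
          setdiff(spec$covariate_interactions[[cv]], tgt)
        if (!length(spec$covariate_interactions[[cv]]))
          spec$covariate_interactions[[cv]] <- NULL
        break
      }
    }
  } else stop("'", col, "' is not an interaction term")
  spec
}

#' Write / read an estimation result as JSON
#'
#' Serialises estimates, standard errors, t-ratios, the covariance matrix,
#' log-likelihoods, convergence diagnostics and the utility specification
#' (including its schema), so post-estimation and ranking can run in a later
#' session without refitting.
#'
#' @param fit A `dce_fit` (or `dce_iclv_fit`).
#' @param path JSON file path.
#' @return `write_fit` returns `path` invisibly; `read_fit` a `dce_fit`.
#' @export
write_fit <- function(fit, path) {
  spec <- fit$spec
  obj <- list(
    class = class(fit)[1L],
    estimates = as.list(fit$estimates),
    se = as.list(stats::setNames(fit$se, names(fit$estimates))),
    tstat = as.list(stats::setNames(fit$tstat, names(fit$estimates))),
    covariance = fit$covariance,
    ll_final = fit$ll_final, ll_zero = fit$ll_zero,
    n_draws = fit$n_draws, draw_type = fit$draw_type,
    convergence = fit$convergence, seed = fit$seed,
    n_respondents = fit$n_respondents, n_obs = fit$n_obs,
    groups = fit$groups,
    spec = list(
      schema = lapply(spec$schema, function(a)
        list(name = a$name, coding = a$coding, numeric = is.numeric(a$levels),
             levels = as.list(a$levels), reference = a$reference,
             arm_visibility = a$arm_visibility)),
      random = spec$random, sample_interactions = spec$sample_interactions,
      covariate_interactions = spec$covariate_interactions,
      latent_terms = spec$latent_terms, scale = spec$scale,
      weights = spec$weights, divisors = as.list(spec$divisors)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- attribute_schema(lapply(unname(x$spec$schema), function(a) {
    lv <- unlist(a$levels)
    if (isTRUE(a$numeric)) lv <- as.numeric(lv)
    attribute(a$name, lv, a$coding,
              reference = if (is.null(a$reference)) NULL
                          else if (isTRUE(a$numeric)) as.numeric(a$reference)
                          else a$reference,
              arm_visibility = a$arm_visibility)
  }))
  spec <- utility_spec(
    schema,
    random = if (length(x$spec$random)) unlist(x$spec$random) else character(0),
    sample_interactions = if (length(x$spec$sample_interactions))
      unlist(x$spec$sample_interactions) else character(0),
    covariate_interactions = if (length(x$spec$covariate_interactions))
      lapply(x$spec$covariate_interactions, unlist) else list(),
    latent_terms = if (length(x$spec$latent_terms))
      unlist(x$spec$latent_terms) else character(0),
    scale = x$spec$scale, weights = x$spec$weights,
    divisors = unlist(x$spec$divisors))
  est <- unlist(x$estimates)
  covm <- x$covariance
  if (!is.null(covm)) {
    covm <- as.matrix(covm)
    dimnames(covm) <- list(names(est), names(est))
  }
  structure(list(
    estimates = est, covariance = covm,
    se = stats::setNames(unlist(x$se), names(est)),
    tstat = stats::setNames(unlist(x$tstat), names(est)),
    ll_final = x$ll_final, ll_zero = x$ll_zero,
    n_draws = x$n_draws, draw_type = x$draw_type,
    convergence = x$convergence, seed = x$seed,
    n_respondents = x$n_respondents, n_obs = x$n_obs,
    spec = spec, latent = NULL, measurement = NULL,
    groups = unlist(x$groups), param_names = names(est),
    removal_trail = NULL),
    class = unique(c(x$class, "dce_fit")))
}
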