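#' Generating ("true") parameters for synthetic stated-choice data
#'
#' Returns the parameter set the synthetic-data generator inverts from the
#' estimator's assumptions: mean utility coefficients on the GP (reference
#' scale) encoded columns, random-coefficient spreads, the two scale
#' multipliers, public-sample coefficient shifts, covariate and
#' latent-variable utility shifts, the structural coefficients of the latent
#' cancer-knowledge/experience variable, and the measurement parameters of
#' its indicators (three binary indicators plus a 0-16 symptom-recognition
#' count).
#'
#' The default values are log odds-ratios transcribed from published
#' GP/public preference estimates for multi-cancer tests, so synthetic runs
#' are qualitatively faithful; they are illustrative, not the original
#' study's estimates. Levels the source does not report are filled in
#' monotonically (the package vignette documents each choice). Every
#' component can be overridden; passing `0` (or `NULL` where noted) to
#' `delta`, `sigma`, `tau` or `covariate` zeroes that block out, which is how
#' matched recovery experiments are set up.
#'
#' @param beta Named mean coefficients (GP scale) per encoded column.
#' @param sigma Named nonnegative spreads of the random coefficients.
#' @param delta Named public-sample additive shifts.
#' @param covariate Named list: covariate -> named shifts per column.
#' @param tau Named latent-variable utility shifts per column.
#' @param lambda_pub,lambda_arm Positive scale multipliers: public utilities
#'   carry `lambda_pub` (GPs are the reference, scale 1), the public NPV arm
#'   additionally carries `lambda_arm`.
#' @param gamma Structural coefficients of the latent variable (intercept
#'   plus the six demographic indicators); disturbance is standard normal.
#' @param alpha,zeta Measurement intercepts and loadings of the binary
#'   indicators.
#' @param zeta_symptoms Loading of the symptom-recognition count.
#' @param cuts Increasing cut-point vector (16 values) of the ordered-logit
#'   symptom-count model.
#' @return An object of class `true_parameters`.
#' @export
true_parameters <- function(beta = NULL, sigma = NULL, delta = NULL,
                            covariate = NULL, tau = NULL,
                            lambda_pub = 0.407, lambda_arm = 1.15,
                            gamma = NULL, alpha = NULL, zeta = NULL,
                            zeta_symptoms = 1.0, cuts = NULL) {
  d_beta <- c(ppv_20 = 3 * log(0.21), ppv_40 = 2 * log(0.21), ppv_60 = log(0.21),
              npv_96 = -2.528, npv_99 = -1.00, npv_99.5 = log(0.56),
              wait_1_2wk = -0.02, cancers_per10 = log(1.57),
              site_yes = log(2.31),
              form_faecal = log(0.85), form_urine = 0, form_breath = 0,
              early_yes = log(1.21))
  d_sigma <- c(ppv_20 = 0.5, ppv_40 = 0.5, ppv_60 = 0.5,
               npv_96 = 0.5, npv_99 = 0.5, npv_99.5 = 0.5)
  # public shifts chosen so lambda_pub * (beta + delta) matches the public
  # log odds-ratios (PPV-arm scale)
  lp <- lambda_pub
  d_delta <- c(npv_96 = log(0.64) / lp - (-2.528),
               npv_99 = -0.10 / lp - (-1.00),
               npv_99.5 = -0.03 / lp - log(0.56),
               cancers_per10 = log(1.36) / lp - log(1.57),
               site_yes = log(1.30) / lp - log(2.31),
               early_yes = log(2.61) / lp - log(1.21),
               form_faecal = log(0.85) / lp - log(0.85),
               form_urine = 0, form_breath = 0)
  d_cov <- list(
    age65 = c(ppv_60 = (log(0.60) - log(0.41)) / lp),
    ethnic_minority = c(ppv_60 = (log(0.30) - log(0.41)) / lp,
                        cancers_per10 = (log(1.14) - log(1.36)) / lp),
    rural = c(form_faecal = (log(0.78) - log(0.89)) / lp)
  )
  d_tau <- c(ppv_60 = (log(0.13) - log(0.41)) / lp,
             site_yes = (log(1.83) - log(1.31)) / lp,
             early_yes = (log(5.85) - log(2.76)) / lp)
  d_gamma <- c(intercept = 0, age65 = 0.3, female = 0.3, ethnic_minority = -0.4,
               degree = 0.3, rural = 0, suburban = 0)
  d_alpha <- c(screened = stats::qlogis(0.35), had_cancer = stats::qlogis(0.10),
               tested = stats::qlogis(0.33))
  d_zeta <- c(screened = 1.0, had_cancer = 0.8, tested = 0.8)
  d_cuts <- (seq_len(16) - 8.5) * 0.45

  zero_out <- function(x, default) {
    if (is.null(x)) return(default)
    if (identical(x, 0) || identical(x, 0L)) return(default * 0)
    x
  }
  obj <- list(
    beta = if (is.null(beta)) d_beta else beta,
    sigma = zero_out(sigma, d_sigma),
    delta = zero_out(delta, d_delta),
    covariate = if (is.null(covariate)) d_cov else if (identical(covariate, 0)) list() else covariate,
    tau = zero_out(tau, d_tau),
    lambda_pub = lambda_pub, lambda_arm = lambda_arm,
    gamma = if (is.null(gamma)) d_gamma else gamma,
    alpha = if (is.null(alpha)) d_alpha else alpha,
    zeta = if (is.null(zeta)) d_zeta else zeta,
    zeta_symptoms = zeta_symptoms,
    cuts = if (is.null(cuts)) d_cuts else cuts
  )
  validate_truth(obj)
  structure(obj, class = "true_parameters")
}

validate_truth <- function(x) {
  stopifnot(x$lambda_pub > 0, x$lambda_arm > 0)
  if (any(x$sigma < 0)) stop("random-coefficient spreads must be nonnegative")
  if (length(x$cuts) && any(diff(x$cuts) <= 0)) stop("cut-points must be strictly increasing")
  invisible(x)
}

#' @export
print.true_parameters <- function(x, ...) {
  cat("Generating parameters:", length(x$beta), "mean coefficients;",
      sum(x$sigma != 0), "random;", sum(x$delta != 0), "public shifts;",
      length(x$tau), "latent utility terms\n")
  cat("  scales: lambda_pub =", x$lambda_pub, ", lambda_arm =", x$lambda_arm, "\n")
  invisible(x)
}

#' Save / load a generating truth as JSON (for recovery bookkeeping)
#'
#' @param truth A `true_parameters` object.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  # named atomic vectors must become lists to keep their names in JSON
  listify <- function(x) {
    if (is.list(x)) lapply(x, listify)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(listify(unclass(truth)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("beta", "sigma", "delta", "tau", "gamma", "alpha", "zeta", "cuts"))
    x[[f]] <- unlist(x[[f]])
  x$covariate <- if (length(x$covariate)) lapply(x$covariate, unlist) else 0
  x$zeta_symptoms <- as.numeric(x$zeta_symptoms)
  do.call(true_parameters, x)
}
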