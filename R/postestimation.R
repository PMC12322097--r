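#' Effective attribute coefficients for a stakeholder group
#'
#' Maps a pooled fit's parameters to the group-level utility coefficients on
#' the main-effect columns: GPs are the reference (their coefficients are the
#' base terms); public coefficients are `lambda_pub * (beta + delta)`, the
#' public PPV-arm scale, with the `pub_x_*` shifts added where the model has
#' them. The NPV-arm layout multiplier is excluded from reporting: it
#' reflects survey format, not preference. The covariance of the effective
#' coefficients is propagated by the delta method (exact for GPs, first-order
#' through the log-scale parameter for the public).
#'
#' @param fit A `dce_fit`.
#' @param group `"gp"` or `"public"`.
#' @return List with `est` (named vector over main-effect columns) and `cov`.
#' @export
group_coefficients <- function(fit, group = c("gp", "public")) {
  group <- match.arg(group)
  nm <- names(fit$estimates)
  main <- main_effect_columns(fit$spec$schema, fit$spec$divisors)
  main <- intersect(main, nm)
  P <- length(nm)
  J <- matrix(0, length(main), P, dimnames = list(main, nm))
  est <- numeric(length(main)); names(est) <- main
  if (group == "gp" || !"log_lambda_pub" %in% nm) {
    b <- fit$estimates[main]
    if (group == "public") {
      pubcols <- paste0("pub_x_", main)
      has <- pubcols %in% nm
      b[has] <- b[has] + fit$estimates[pubcols[has]]
    }
    est <- b
    for (j in main) J[j, j] <- 1
    if (group == "public")
      for (j in main[paste0("pub_x_", main) %in% nm]) J[j, paste0("pub_x_", j)] <- 1
  } else {
    lam <- exp(fit$estimates[["log_lambda_pub"]])
    for (j in main) {
      b <- fit$estimates[[j]]
      pc <- paste0("pub_x_", j)
      d <- if (pc %in% nm) fit$estimates[[pc]] else 0
      est[j] <- lam * (b + d)
      J[j, j] <- lam
      if (pc %in% nm) J[j, pc] <- lam
      J[j, "log_lambda_pub"] <- lam * (b + d)
    }
  }
  covm <- if (is.null(fit$covariance)) NULL else J %*% fit$covariance %*% t(J)
  list(est = est, cov = covm, group = group)
}

#' Odds ratios with Krinsky-Robb confidence intervals
#'
#' Exponentiates the group-level utility coefficients and attaches 95%
#' Krinsky-Robb intervals: parameter vectors are drawn from the estimator's
#' asymptotic multivariate normal distribution, transformed to group
#' coefficients and exponentiated, and the empirical 2.5/97.5 percentiles
#' reported. A non-positive-semidefinite covariance is repaired by clipping
#' negative eigenvalues to zero (with a warning).
#'
#' @param fit A `dce_fit`.
#' @param n_draws Simulation draws (default 10000).
#' @param seed Integer seed.
#' @param groups Groups to report (defaults to the groups in the fit).
#' @return Data frame of class `or_table`: group, term, odds ratio, 95%
#'   bounds, method tag, draw count and seed.
#' @export
odds_ratios <- function(fit, n_draws = 10000L, seed = 1L, groups = NULL) {
  if (is.null(fit$covariance)) stop("fit has no covariance; rerun with hessian = TRUE")
  if (is.null(groups))
    groups <- if ("public" %in% fit$groups && "gp" %in% fit$groups)
      c("gp", "public") else "gp"
  covm <- fit$covariance
  ev <- eigen((covm + t(covm)) / 2, symmetric = TRUE)
  if (any(ev$values < -1e-8 * max(abs(ev$values)))) {
    warning("covariance repaired by clipping negative eigenvalues")
  }
  covm <- ev$vectors %*% diag(pmax(ev$values, 0), length(ev$values)) %*% t(ev$vectors)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draws <- MASS::mvrnorm(n_draws, mu = fit$estimates, Sigma = covm)
  out <- list()
  for (g in groups) {
    gc <- group_coefficients(fit, g)
    fake <- fit
    point <- exp(gc$est)
    # transform each simulated parameter vector to group coefficients
    sim <- apply(draws, 1L, function(p) {
      fake$estimates[] <- p
      group_coefficients(fake, g)$est
    })
    qs <- apply(exp(sim), 1L, stats::quantile, probs = c(0.025, 0.975))
    out[[g]] <- data.frame(group = g, term = names(gc$est),
                           or = unname(point),
                           lower = unname(qs[1L, ]), upper = unname(qs[2L, ]),
                           method = "krinsky-robb", n_draws = n_draws,
                           seed = seed, row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("or_table", "data.frame")
  res
}

# least-squares contrast for the per-percentage-point PPV slope through
# (20, b20), (40, b40), (60, b60), (80, 0)
ppv_slope_contrast <- function(levels = c(20, 40, 60, 80)) {
  x <- levels - mean(levels)
  cvec <- x / sum(x^2)
  stats::setNames(cvec[-length(cvec)], paste0("ppv_", levels[-length(levels)]))
}

#' Linearised PPV slope
#'
#' Fits a least-squares line through the PPV level coefficients (reference
#' 80% at zero) in PPV-percentage coordinates and returns the slope — utility
#' per PPV percentage point — with its variance propagated exactly from the
#' coefficient covariance (the slope is a linear contrast of the dummies).
#' The linearisation is justified by the near-linear decline of the level
#' coefficients; its residual is reported for inspection.
#'
#' @param fit A `dce_fit`.
#' @param group Stakeholder group.
#' @return List: `slope`, `se`, `var`, `residual` (max absolute deviation of
#'   the level coefficients from the fitted line), and the contrast used.
#' @export
ppv_slope <- function(fit, group = "gp") {
  gc <- group_coefficients(fit, group)
  cvec <- ppv_slope_contrast()
  if (!all(names(cvec) %in% names(gc$est)))
    stop("fit lacks PPV level coefficients: ",
         paste(setdiff(names(cvec), names(gc$est)), collapse = ", "))
  b <- gc$est[names(cvec)]
  slope <- sum(cvec * b)
  v <- if (is.null(gc$cov)) NA_real_ else
    drop(t(cvec) %*% gc$cov[names(cvec), names(cvec)] %*% cvec)
  lv <- c(20, 40, 60, 80)
  bb <- c(b, 0)
  fitline <- mean(bb) + slope * (lv - mean(lv))
  list(slope = unname(slope), se = sqrt(v), var = v,
       residual = max(abs(bb - fitline)), contrast = cvec, group = group)
}

#' Marginal rate of substitution between NPV and PPV
#'
#' The PPV gain (percentage points) that compensates a drop in NPV from
#' `npv_from` to `npv_to` at equal utility: `-(b_to - b_from) / s`, where `s`
#' is the linearised PPV slope. The scale parameters cancel in the ratio, so
#' the MRS is invariant to rescaling all utilities. The 95% CI comes from the
#' delta method on the ratio with its analytic gradient and the full
#' coefficient covariance; if the slope's |t| is below 1 the result is
#' flagged unstable (returned with a warning).
#'
#' @param fit A `dce_fit`.
#' @param npv_from,npv_to Schema NPV levels (percent), e.g. 99.9 and 96.
#' @param group Stakeholder group.
#' @return List of class `mrs_result`: `mrs` (PPV percentage points), `se`,
#'   95% `lower`/`upper`, the gradient used, and a stability flag.
#' @export
mrs_npv_ppv <- function(fit, npv_from = 99.9, npv_to = 96, group = "gp") {
  schema <- fit$spec$schema
  npv_levels <- schema[["npv"]]$levels
  if (!npv_from %in% npv_levels || !npv_to %in% npv_levels)
    stop("npv_from and npv_to must be schema NPV levels")
  gc <- group_coefficients(fit, group)
  cvec <- ppv_slope_contrast()
  b <- gc$est
  coef_of <- function(lv) {
    if (lv == schema[["npv"]]$reference) 0 else
      unname(b[paste0("npv_", sanitize_level(lv))])
  }
  dbeta <- coef_of(npv_to) - coef_of(npv_from)
  s <- sum(cvec * b[names(cvec)])
  point <- -dbeta / s
  # gradient wrt the effective coefficient vector
  g <- stats::setNames(numeric(length(b)), names(b))
  nto <- paste0("npv_", sanitize_level(npv_to))
  nfrom <- paste0("npv_", sanitize_level(npv_from))
  if (nto %in% names(g)) g[nto] <- g[nto] - 1 / s
  if (nfrom %in% names(g)) g[nfrom] <- g[nfrom] + 1 / s
  g[names(cvec)] <- g[names(cvec)] + dbeta / s^2 * cvec
  v <- if (is.null(gc$cov)) NA_real_ else drop(t(g) %*% gc$cov %*% g)
  se <- sqrt(v)
  slope_t <- s / ppv_slope(fit, group)$se
  unstable <- is.finite(slope_t) && abs(slope_t) < 1
  if (unstable) warning("PPV slope not distinguishable from zero; MRS unstable")
  structure(list(npv_from = npv_from, npv_to = npv_to, group = group,
                 mrs = unname(point), se = se,
                 lower = unname(point - 1.96 * se),
                 upper = unname(point + 1.96 * se),
                 gradient = g, unstable = unstable),
            class = "mrs_result")
}

#' @export
print.mrs_result <- function(x, ...) {
  cat(sprintf("MRS (%s): NPV %.1f%% -> %.1f%% compensated by %+.2f PPV points (95%% CI %.2f to %.2f)%s\n",
              x$group, x$npv_from, x$npv_to, x$mrs, x$lower, x$upper,
              if (x$unstable) " [UNSTABLE]" else ""))
  invisible(x)
}
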