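#' Encode choice data into an estimation bundle
#'
#' Builds the difference-coded design matrix (alternative 1 minus
#' alternative 2) for every respondent-task, with main-effect columns,
#' public-sample interaction columns (`pub_x_*`), covariate interaction
#' columns (`cov_<covariate>_x_*`), the respondent scale-cell loadings,
#' weights, and (for ICLV models) structural covariates and indicator data.
#' Attributes hidden from a respondent's arm are structurally zero in both
#' alternatives, so their columns drop out of that respondent's likelihood
#' (arm-specific utility functions; nothing is imputed).
#'
#' @param data Long-format choice data (see [simulate_choices()] for the
#'   dialect): two rows per respondent-task, exactly one `chosen`.
#' @param spec A [utility_spec()].
#' @param latent Optional [latent_spec()]; adds structural covariates.
#' @param measurement Optional [measurement_spec()]; adds indicator data.
#' @return An object of class `dce_bundle`.
#' @export
encode <- function(data, spec, latent = NULL, measurement = NULL) {
  schema <- spec$schema
  ord <- order(data$respondent_id, data$task_id, data$alternative)
  d <- data[ord, , drop = FALSE]
  n2 <- nrow(d)
  if (n2 %% 2L != 0L) stop("expected two rows per respondent-task")
  i1 <- seq(1L, n2, 2L); i2 <- seq(2L, n2, 2L)
  if (any(d$respondent_id[i1] != d$respondent_id[i2]) ||
      any(d$task_id[i1] != d$task_id[i2]))
    stop("rows do not pair into respondent-tasks")
  ch <- d$chosen[i1] + d$chosen[i2]
  if (any(ch != 1L)) stop("each respondent-task needs exactly one chosen alternative")

  X <- encode_profiles(d[names(schema)], schema, spec$divisors)
  dX_main <- X[i1, , drop = FALSE] - X[i2, , drop = FALSE]
  y <- ifelse(d$chosen[i1] == 1L, 1, -1)

  rid <- d$respondent_id[i1]
  resp_index <- match(rid, unique(rid))
  N <- max(resp_index)
  first <- match(seq_len(N), resp_index)
  rmeta <- d[i1, , drop = FALSE][first, , drop = FALSE]

  blocks <- list(dX_main)
  if (length(spec$sample_interactions)) {
    pubrow <- as.numeric(d$group[i1] == "public")
    Xi <- dX_main[, spec$sample_interactions, drop = FALSE] * pubrow
    colnames(Xi) <- paste0("pub_x_", spec$sample_interactions)
    blocks <- c(blocks, list(Xi))
  }
  for (cv in names(spec$covariate_interactions)) {
    cv_val <- as.numeric(d[[cv]][i1])
    tgt <- spec$covariate_interactions[[cv]]
    Xi <- dX_main[, tgt, drop = FALSE] * cv_val
    colnames(Xi) <- paste0("cov_", cv, "_x_", tgt)
    blocks <- c(blocks, list(Xi))
  }
  dX <- do.call(cbind, blocks)

  scale_names <- switch(spec$scale,
    gp_public_arm = c("log_lambda_pub", "log_lambda_arm"),
    arm_only = "log_lambda_arm",
    none = character(0))
  scale_load <- matrix(0, N, length(scale_names),
                       dimnames = list(NULL, scale_names))
  if (spec$scale == "gp_public_arm") {
    scale_load[, 1L] <- as.numeric(rmeta$group == "public")
    scale_load[, 2L] <- as.numeric(rmeta$group == "public" & rmeta$arm == "npv")
  } else if (spec$scale == "arm_only") {
    scale_load[, 1L] <- as.numeric(rmeta$arm == "npv")
  }

  if (spec$weights) {
    ng <- table(rmeta$group)
    w <- as.numeric(0.5 * N / ng[rmeta$group])
    if (length(ng) == 1L) w <- rep(1, N)
  } else w <- rep(1, N)

  Z <- matrix(0, N, 0)
  if (!is.null(latent)) {
    Z <- as.matrix(rmeta[latent$covariates])
    colnames(Z) <- latent$covariates
    storage.mode(Z) <- "double"
  }
  B <- matrix(0, N, 0); Sord <- rep(NA_integer_, N); L <- 0L
  if (!is.null(measurement)) {
    if (length(measurement$binary)) {
      B <- as.matrix(rmeta[measurement$binary])
      colnames(B) <- measurement$binary
      storage.mode(B) <- "double"
    }
    if (length(measurement$ordered)) {
      Sord <- as.integer(rmeta[[measurement$ordered]])
      L <- measurement$n_levels - 1L
      if (any(Sord < 0L | Sord > L, na.rm = TRUE))
        stop("ordered indicator outside 0..", L)
    }
  }

  resp_start <- c(0L, cumsum(as.integer(table(factor(resp_index, levels = seq_len(N))))))
  structure(list(
    dX = dX, y = y, resp_start = resp_start, w = w,
    scale_load = scale_load,
    rand_cols = match(spec$random, colnames(dX)),
    tau_cols = match(spec$latent_terms, colnames(dX)),
    Z = Z, B = B, Sord = Sord, L = L,
    respondent_id = rmeta$respondent_id, group = rmeta$group, arm = rmeta$arm,
    spec = spec, latent = latent, measurement = measurement,
    n_obs = length(y), n_respondents = N), class = "dce_bundle")
}

#' @export
print.dce_bundle <- function(x, ...) {
  cat("Estimation bundle:", x$n_respondents, "respondents,", x$n_obs,
      "choice tasks,", ncol(x$dX), "utility columns\n")
  invisible(x)
}

# parameter template: named start vector + block layout for the C++ engine
param_template <- function(bundle) {
  nm <- c(colnames(bundle$dX),
          if (length(bundle$rand_cols)) paste0("sd_", colnames(bundle$dX)[bundle$rand_cols]),
          colnames(bundle$scale_load),
          if (length(bundle$tau_cols)) paste0("lv_x_", colnames(bundle$dX)[bundle$tau_cols]),
          if (ncol(bundle$Z)) paste0("gamma_", colnames(bundle$Z)),
          if (ncol(bundle$B)) paste0("alpha_", colnames(bundle$B)),
          if (ncol(bundle$B)) paste0("zeta_", colnames(bundle$B)),
          if (bundle$L > 0L) "zeta_symptoms",
          if (bundle$L > 0L) paste0("cut_raw_", seq_len(bundle$L)))
  stats::setNames(numeric(length(nm)), nm)
}
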