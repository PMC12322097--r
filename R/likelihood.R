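#' Log-likelihood functions
#'
#' @description
#' `mnl_loglik()` evaluates the weighted multinomial (here binary) logit
#' log-likelihood `sum_n w_n sum_t log P_nt` with the respondent's scale
#' multiplier applied to utilities, and attaches the analytic gradient as the
#' `"gradient"` attribute.
#'
#' `mixed_panel_loglik()` evaluates the panel mixed-logit simulated
#' log-likelihood `sum_n w_n log[(1/R) sum_r prod_t P_nt(beta + sigma*xi_nr)]`
#' (the within-respondent product sits inside the draw average). With all
#' spreads zero it equals `mnl_loglik` for any draws.
#'
#' `iclv_loglik()` evaluates the joint simulated likelihood of choices and
#' indicators, `sum_n w_n log[(1/R) sum_r prod_t P_nt(beta + tau*LV_nr) *
#' prod_k m_k(I_nk | LV_nr)]` with `LV_nr = gamma' z_n + eta_nr`. With
#' `tau = 0` and all loadings zero it separates exactly into the choice and
#' measurement log-likelihoods.
#'
#' @param params Named parameter vector as laid out by the bundle (use
#'   [estimate()] / [estimate_iclv()] for packing; order: utility
#'   coefficients, random-coefficient spreads `sd_*`, log scale parameters,
#'   latent utility terms `lv_x_*`, structural `gamma_*`, measurement
#'   `alpha_*`/`zeta_*`, symptom loading and raw cut-points).
#' @param bundle A `dce_bundle` from [encode()].
#' @param draws Draw set from the internal Halton generator (or a list with
#'   elements `xi` (N x Krand x R array), `eta` (N x R), `R`).
#' @param want_scores If `TRUE`, attach the per-respondent score matrix.
#' @return Scalar log-likelihood with attribute `"gradient"` (and optionally
#'   `"scores"`).
#' @export
mnl_loglik <- function(params, bundle, want_scores = FALSE) {
  eval_loglik(params, bundle, draws = list(xi = NULL, eta = NULL, R = 1L),
              want_scores = want_scores)
}

#' @rdname mnl_loglik
#' @export
mixed_panel_loglik <- function(params, bundle, draws, want_scores = FALSE) {
  if (draws$R < 1L) stop("number of draws must be >= 1")
  eval_loglik(params, bundle, draws, want_scores = want_scores)
}

#' @rdname mnl_loglik
#' @export
iclv_loglik <- function(params, bundle, draws, want_scores = FALSE) {
  if (ncol(bundle$Z) == 0L && bundle$L == 0L && ncol(bundle$B) == 0L)
    stop("bundle carries no latent/measurement structure; encode() with latent and measurement specs")
  if (is.null(draws$eta)) stop("ICLV likelihood needs latent-disturbance draws (eta)")
  eval_loglik(params, bundle, draws, want_scores = want_scores)
}

eval_loglik <- function(params, bundle, draws, want_scores = FALSE) {
  tmpl <- param_template(bundle)
  if (length(params) != length(tmpl))
    stop("expected ", length(tmpl), " parameters, got ", length(params))
  R <- draws$R
  N <- bundle$n_respondents
  Krand <- length(bundle$rand_cols)
  xi <- draws$xi
  if (Krand > 0L && is.null(xi)) {
    if (R == 1L) xi <- array(0, c(N, Krand, 1L))  # spreads inert at R = 1
    else stop("random coefficients need xi draws")
  }
  if (Krand == 0L) xi <- numeric(0)
  eta <- draws$eta
  has_latent <- ncol(bundle$Z) > 0L || ncol(bundle$B) > 0L || bundle$L > 0L ||
    length(bundle$tau_cols) > 0L
  if (is.null(eta)) {
    eta <- matrix(0, N, if (has_latent) R else 0L)
  }
  res <- dce_loglik_cpp(unname(params), bundle$dX, bundle$y, bundle$resp_start,
                        bundle$w, bundle$scale_load,
                        as.integer(bundle$rand_cols) - 1L,
                        as.integer(bundle$tau_cols) - 1L,
                        bundle$Z, bundle$B,
                        ifelse(is.na(bundle$Sord), NA_integer_, as.integer(bundle$Sord)),
                        bundle$L, as.numeric(xi), eta, as.integer(R),
                        want_scores)
  out <- res$ll
  g <- res$grad
  names(g) <- names(tmpl)
  attr(out, "gradient") <- g
  if (want_scores) {
    colnames(res$scores) <- names(tmpl)
    attr(out, "scores") <- res$scores
  }
  out
}

# log-likelihood of the null (all coefficients zero) model: every binary
# choice has probability 1/2
null_loglik <- function(bundle) {
  Tn <- diff(bundle$resp_start)
  meas <- 0
  sum(bundle$w * Tn * log(0.5)) + meas
}
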