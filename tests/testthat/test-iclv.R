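test_that("principal-factor analysis handles rank-1, null and generated data", {
  # two perfectly correlated indicators: equal loadings, full first-factor share
  set.seed(51)
  x <- rbinom(200, 1, 0.5)
  fa <- factor_loadings(cbind(a = x, b = x))
  expect_equal(unname(fa$loadings[1]), unname(fa$loadings[2]))
  expect_equal(fa$prop_var, 1.0, tolerance = 1e-6)

  # independent indicators: loadings at the pure-noise scale. The leading
  # eigenvalue of a p x p correlation noise matrix is ~ 2 sqrt(p/n), so null
  # loadings scale like (4p/n)^(1/4) ~ 0.2 at p = 4, n = 10000; they must
  # stay below that and explain almost no variance
  ind <- matrix(rbinom(10000 * 4, 1, 0.4), ncol = 4,
                dimnames = list(NULL, paste0("i", 1:4)))
  fa0 <- factor_loadings(ind)
  expect_true(all(abs(fa0$loadings) < 0.2))
  expect_lt(fa0$prop_var, 0.02)

  # a one-factor truth: implied correlations l_j l_k match the data within
  # .05, and the loadings agree with maximum-likelihood factor analysis
  lv <- rnorm(10000)
  gen <- sapply(c(0.9, 0.7, 0.5), function(z) z * lv + rnorm(10000))
  colnames(gen) <- c("a", "b", "c")
  fa1 <- factor_loadings(gen)
  R <- cor(gen)
  for (j in 1:2) for (k in (j + 1):3)
    expect_lt(abs(fa1$loadings[j] * fa1$loadings[k] - R[j, k]), 0.05)
  # iterated to its fixed point, the solution matches ML factor analysis
  fa_it <- factor_loadings(gen, max_iter = 100)
  ml <- stats::factanal(covmat = R, factors = 1, n.obs = 10000)
  expect_lt(max(abs(abs(fa_it$loadings) - abs(drop(ml$loadings)))), 0.02)

  expect_error(factor_loadings(cbind(a = x, b = rep(1, 200))), "constant.*b")
  expect_error(factor_loadings(cbind(a = x)), "at least 2")
})

test_that("ICLV likelihood separates exactly when tau and loadings vanish", {
  des <- cached_design()
  tr <- true_parameters(sigma = 0, covariate = 0)
  resp <- generate_respondents(0, 50, tr, seed = 52)
  ch <- simulate_choices(des, resp, tr, seed = 53)
  spec <- utility_spec(mct_schema(), latent_terms = c("early_yes"),
                       scale = "arm_only", weights = FALSE)
  b <- encode(ch, spec, latent = latent_spec(), measurement = measurement_spec())
  tmpl <- mctchoice:::param_template(b)
  set.seed(54); p <- setNames(rnorm(length(tmpl)) * 0.3, names(tmpl))
  p[grep("^(lv_x_|zeta_)", names(p))] <- 0
  dr <- mctchoice:::make_draws(b$n_respondents, 30, 0, latent = TRUE, seed = 6)
  ll_joint <- as.numeric(iclv_loglik(p, b, dr))

  spec0 <- spec; spec0$latent_terms <- character(0)
  b0 <- encode(ch, spec0)
  ll_choice <- as.numeric(mnl_loglik(p[names(mctchoice:::param_template(b0))], b0))
  # closed-form measurement block at zero loadings
  ll_meas <- 0
  for (k in seq_len(ncol(b$B))) {
    a <- p[[paste0("alpha_", colnames(b$B)[k])]]
    ll_meas <- ll_meas + sum(ifelse(b$B[, k] > 0.5,
                                    plogis(a, log.p = TRUE),
                                    plogis(-a, log.p = TRUE)))
  }
  kap <- cumsum(c(p[["cut_raw_1"]], exp(p[paste0("cut_raw_", 2:16)])))
  s <- b$Sord
  Fhi <- ifelse(s < 16, plogis(kap[pmin(s + 1, 16)]), 1)
  Flo <- ifelse(s > 0, plogis(kap[pmax(s, 1)]), 0)
  ll_meas <- ll_meas + sum(log(Fhi - Flo))
  expect_equal(ll_joint, ll_choice + ll_meas, tolerance = 1e-8)
})

test_that("simulated measurement mixture matches Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  # one respondent, one binary indicator, no informative choice data:
  # P(I = 1) = E_eta plogis(alpha + zeta * eta)
  sch <- binary_schema()
  data <- data.frame(respondent_id = 1L, group = "public", arm = "full",
                     block = 1L, task_id = 1L, alternative = 1:2,
                     chosen = c(1L, 0L), site = c("yes", "yes"),
                     female = 0, screened = 1)
  spec <- utility_spec(sch, scale = "none", weights = FALSE,
                       divisors = numeric(0))
  b <- encode(data, spec, latent = latent_spec("female"),
              measurement = measurement_spec(binary = "screened",
                                             ordered = character(0)))
  p <- c(site_yes = 0, gamma_female = 0, alpha_screened = -0.4,
         zeta_screened = 1.1)
  dr <- mctchoice:::make_draws(1L, 10000L, 0L, latent = TRUE, seed = 7)
  # choice part contributes exactly log(1/2) (identical alternatives)
  p_sim <- exp(as.numeric(iclv_loglik(p, b, dr)) - log(0.5))
  gh <- pracma::gaussHermite(50)
  p_quad <- sum(gh$w / sqrt(pi) * plogis(-0.4 + 1.1 * sqrt(2) * gh$x))
  expect_lt(abs(p_sim - p_quad), 1e-3)
})

test_that("latent location shifts are absorbed by intercept adjustments", {
  des <- cached_design()
  tr <- true_parameters(sigma = 0, covariate = 0)
  resp <- generate_respondents(0, 40, tr, seed = 55)
  ch <- simulate_choices(des, resp, tr, seed = 56)
  spec <- utility_spec(mct_schema(), latent_terms = c("early_yes", "site_yes"),
                       scale = "arm_only", weights = FALSE)
  b <- encode(ch, spec, latent = latent_spec(), measurement = measurement_spec())
  tmpl <- mctchoice:::param_template(b)
  set.seed(57); p <- setNames(rnorm(length(tmpl)) * 0.3, names(tmpl))
  dr <- mctchoice:::make_draws(b$n_respondents, 25, 0, latent = TRUE, seed = 8)
  ll1 <- as.numeric(iclv_loglik(p, b, dr))
  # shift LV by c: add c to every draw; compensate alpha_k by -zeta_k c,
  # cut-points by +zeta_s c (through the first raw cut), and beta_j by
  # -tau_j c on the latent utility terms
  cc <- 0.7
  dr2 <- dr; dr2$eta <- dr$eta + cc
  p2 <- p
  for (k in c("screened", "had_cancer", "tested"))
    p2[paste0("alpha_", k)] <- p2[paste0("alpha_", k)] - p2[paste0("zeta_", k)] * cc
  p2["cut_raw_1"] <- p2["cut_raw_1"] + p2["zeta_symptoms"] * cc
  p2["early_yes"] <- p2["early_yes"] - p2["lv_x_early_yes"] * cc
  p2["site_yes"] <- p2["site_yes"] - p2["lv_x_site_yes"] * cc
  ll2 <- as.numeric(iclv_loglik(p2, b, dr2))
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("the latent sign convention fixes the first loading positive", {
  est <- c(a = 1, zeta_screened = -0.5, zeta_tested = 0.2, gamma_female = 0.3,
           lv_x_early_yes = -0.1, zeta_symptoms = 0.4)
  bundle <- list(B = matrix(0, 1, 2, dimnames = list(NULL, c("screened", "tested"))),
                 L = 16L)
  out <- mctchoice:::normalize_latent_sign(est, bundle)
  expect_equal(unname(out[["zeta_screened"]]), 0.5)
  expect_equal(unname(out[["zeta_tested"]]), -0.2)
  expect_equal(unname(out[["gamma_female"]]), -0.3)
  expect_equal(unname(out[["lv_x_early_yes"]]), 0.1)
  expect_equal(unname(out[["a"]]), 1)
})
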