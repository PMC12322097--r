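test_that("dummy encoding follows the reference-level scheme", {
  sch <- mct_schema()
  all_ref <- data.frame(ppv = 80, npv = 99.9, wait = "1wk", cancers = 1,
                        site = "no", form = "blood", early = "no")
  X <- encode_profiles(all_ref, sch)
  expect_equal(ncol(X), 13L)  # sum(levels - 1) over dummies + 1 continuous
  expect_equal(unname(X[1, "cancers_per10"]), 0.1)
  expect_true(all(X[1, colnames(X) != "cancers_per10"] == 0))
  X25 <- encode_profiles(transform(all_ref, cancers = 25), sch)
  expect_equal(unname(X25[1, "cancers_per10"]), 2.5)
  bad <- transform(all_ref, ppv = 70)
  expect_error(encode_profiles(bad, sch), "row 1.*70.*ppv")
  # off-grid permitted for prediction
  expect_silent(encode_profiles(bad, sch, off_grid = TRUE))
})

test_that("MNL log-likelihood matches uniform, linearity and brute force", {
  des <- cached_design()
  tr <- pooled_truth()
  resp <- generate_respondents(3, 0, tr, seed = 21)
  ch <- simulate_choices(des, resp, tr, seed = 22)
  ch <- ch[ch$task_id %in% unique(ch$task_id)[1:2] | ch$respondent_id > 1, ]
  spec <- utility_spec(mct_schema(), scale = "none", weights = FALSE)
  b <- encode(ch, spec)
  tmpl <- mctchoice:::param_template(b)

  # all parameters zero: LL = -N log 2
  ll0 <- as.numeric(mnl_loglik(tmpl, b))
  expect_equal(ll0, -b$n_obs * log(2))

  # doubling all weights doubles the LL exactly
  set.seed(23); p <- setNames(rnorm(length(tmpl)) * 0.3, names(tmpl))
  b2 <- b; b2$w <- 2 * b$w
  expect_equal(as.numeric(mnl_loglik(p, b2)), 2 * as.numeric(mnl_loglik(p, b)))

  # brute-force log-softmax sum over enumerated rows
  brute <- 0
  for (n in seq_len(b$n_respondents)) {
    rows <- (b$resp_start[n] + 1):b$resp_start[n + 1]
    for (m in rows) {
      dv <- sum(b$dX[m, ] * p[colnames(b$dX)])
      v1 <- dv; v2 <- 0  # utility difference vs alternative 2
      pick <- if (b$y[m] > 0) v1 else v2
      brute <- brute + (pick - log(exp(v1) + exp(v2)))
    }
  }
  expect_equal(as.numeric(mnl_loglik(p, b)), brute, tolerance = 1e-10)
})

test_that("analytic gradients match central finite differences", {
  des <- cached_design()
  tr <- pooled_truth()
  resp <- generate_respondents(8, 20, tr, seed = 24)
  ch <- simulate_choices(des, resp, tr, seed = 25)
  b <- encode(ch, canonical_pooled_spec())
  tmpl <- mctchoice:::param_template(b)
  dr <- mctchoice:::make_draws(b$n_respondents, 15, length(b$rand_cols), seed = 2)
  set.seed(26)
  for (rep in 1:3) {
    p <- setNames(rnorm(length(tmpl)) * 0.3, names(tmpl))
    g <- attr(mixed_panel_loglik(p, b, dr), "gradient")
    fd <- vapply(seq_along(p), function(j) {
      h <- 1e-4 * max(1, abs(p[j]))
      pp <- p; pp[j] <- pp[j] + h; pm <- p; pm[j] <- pm[j] - h
      (as.numeric(mixed_panel_loglik(pp, b, dr)) -
         as.numeric(mixed_panel_loglik(pm, b, dr))) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(g - fd) / pmax(1, abs(fd))), 1e-6)
  }
})

test_that("mixed logit reduces to MNL at zero spreads and is draw-exchangeable", {
  des <- cached_design()
  tr <- pooled_truth()
  resp <- generate_respondents(10, 24, tr, seed = 27)
  ch <- simulate_choices(des, resp, tr, seed = 28)
  b <- encode(ch, canonical_pooled_spec())
  tmpl <- mctchoice:::param_template(b)
  set.seed(29); p <- setNames(rnorm(length(tmpl)) * 0.3, names(tmpl))
  p[grep("^sd_", names(p))] <- 0
  dr <- mctchoice:::make_draws(b$n_respondents, 40, length(b$rand_cols), seed = 3)
  expect_equal(as.numeric(mixed_panel_loglik(p, b, dr)),
               as.numeric(mnl_loglik(p, b)), tolerance = 1e-12)
  # permuting the draw order leaves the simulated LL unchanged
  p[grep("^sd_", names(p))] <- 0.4
  perm <- sample(40)
  dr2 <- dr; dr2$xi <- dr$xi[, , perm, drop = FALSE]
  expect_equal(as.numeric(mixed_panel_loglik(p, b, dr)),
               as.numeric(mixed_panel_loglik(p, b, dr2)), tolerance = 1e-10)
  expect_error(mixed_panel_loglik(p, b, list(xi = NULL, eta = NULL, R = 0L)),
               ">= 1")
})

test_that("simulated mixing probability matches Gauss-Hermite quadrature", {
  skip_if_not_installed("pracma")
  # one respondent, one task, one random coefficient: P = E_z plogis(x(b + s z))
  sch <- binary_schema()
  data <- data.frame(respondent_id = 1L, group = "gp", arm = "full", block = 1L,
                     task_id = 1L, alternative = 1:2, chosen = c(1L, 0L),
                     site = c("yes", "no"))
  spec <- utility_spec(sch, random = "site_yes", scale = "none",
                       weights = FALSE, divisors = numeric(0))
  b <- encode(data, spec)
  p <- c(site_yes = 0.8, sd_site_yes = 1.3)
  dr <- mctchoice:::make_draws(1L, 10000L, 1L, seed = 5)
  p_sim <- exp(as.numeric(mixed_panel_loglik(p, b, dr)))
  gh <- pracma::gaussHermite(50)
  p_quad <- sum(gh$w / sqrt(pi) * plogis(p[1] + p[2] * sqrt(2) * gh$x))
  expect_lt(abs(p_sim - p_quad), 1e-3)
})

test_that("closed-form MLE is recovered on a single-regressor toy", {
  # regressor +1/-1 (difference 2); balanced design; MLE = (1/2) log(n+/n-)
  sch <- attribute_schema(attribute("dose", c(-1, 1), "continuous"))
  n_pos <- 30L; n_neg <- 10L
  mk <- function(i, chosen1) data.frame(
    respondent_id = i, group = "gp", arm = "full", block = 1L, task_id = 1L,
    alternative = 1:2, chosen = if (chosen1) c(1L, 0L) else c(0L, 1L),
    dose = c(1, -1))
  data <- do.call(rbind, c(lapply(seq_len(n_pos), mk, chosen1 = TRUE),
                           lapply(n_pos + seq_len(n_neg), mk, chosen1 = FALSE)))
  spec <- utility_spec(sch, scale = "none", weights = FALSE, divisors = numeric(0))
  fit <- estimate(data, spec, estimation_options(hessian = FALSE))
  expect_equal(unname(fit$estimates[["dose"]]), 0.5 * log(n_pos / n_neg),
               tolerance = 1e-5)
})

test_that("fixed-coefficient parameters are recovered within 3 SE", {
  des <- cached_design()
  tr <- pooled_truth(sigma = 0)
  resp <- generate_respondents(800, 0, tr, seed = 31)
  ch <- simulate_choices(des, resp, tr, seed = 32)
  spec <- utility_spec(mct_schema(), scale = "none", weights = FALSE)
  fit <- estimate(ch, spec, estimation_options(seed = 33))
  z <- (fit$estimates[names(tr$beta)] - tr$beta) / fit$se[names(tr$beta)]
  expect_true(all(abs(z) < 3))
  expect_true(fit$convergence$converged)
  expect_gt(fit$ll_final, fit$ll_zero)
})

test_that("the arm scale parameter is recovered within 3 SE", {
  des <- cached_design()
  tr <- pooled_truth(sigma = 0, lambda_pub = 1, lambda_arm = 0.5)
  resp <- generate_respondents(0, 900, tr, seed = 34)
  ch <- simulate_choices(des, resp, tr, seed = 35)
  spec <- utility_spec(mct_schema(), scale = "arm_only", weights = FALSE)
  fit <- estimate(ch, spec, estimation_options(seed = 36))
  z <- (fit$estimates[["log_lambda_arm"]] - log(0.5)) / fit$se[["log_lambda_arm"]]
  expect_lt(abs(z), 3)
})

test_that("weights: equal groups with unit weights match the unweighted LL", {
  des <- cached_design()
  tr <- pooled_truth()
  resp <- generate_respondents(40, 40, tr, seed = 37)
  ch <- simulate_choices(des, resp, tr, seed = 38)
  spec_w <- canonical_pooled_spec()
  spec_u <- spec_w; spec_u$weights <- FALSE
  bw <- encode(ch, spec_w); bu <- encode(ch, spec_u)
  expect_equal(bw$w, bu$w)  # equal groups: balancing weights are exactly 1
  tmpl <- mctchoice:::param_template(bw)
  set.seed(39); p <- setNames(rnorm(length(tmpl)) * 0.2, names(tmpl))
  expect_equal(as.numeric(mnl_loglik(p, bw)), as.numeric(mnl_loglik(p, bu)))
})

test_that("refinement with threshold zero returns the full model", {
  des <- cached_design()
  tr <- pooled_truth(sigma = 0)
  resp <- generate_respondents(60, 0, tr, seed = 40)
  ch <- simulate_choices(des, resp, tr, seed = 41)
  spec <- utility_spec(mct_schema(), scale = "none", weights = FALSE,
                       covariate_interactions = list(age65 = "site_yes",
                                                     female = "early_yes"))
  fit <- refine_interactions(ch, spec, alpha_t = 0,
                             options = estimation_options(seed = 42))
  expect_length(fit$removal_trail, 0L)
  expect_true(all(c("cov_age65_x_site_yes", "cov_female_x_early_yes") %in%
                    names(fit$estimates)))
})
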