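test_that("respondent generation reproduces the study structure", {
  tr <- true_parameters()
  resp <- generate_respondents(251, 1005, tr, seed = 5)
  expect_equal(nrow(resp), 1256L)
  expect_true(all(resp$arm[resp$group == "gp"] == "full"))
  n_ppv <- sum(resp$arm == "ppv")
  # central 99% range of Binomial(1005, .5)
  expect_true(n_ppv >= qbinom(0.005, 1005, 0.5) && n_ppv <= qbinom(0.995, 1005, 0.5))
  expect_true(all(resp$symptom_count >= 0 & resp$symptom_count <= 16))
  expect_true(all(resp$weight > 0))
  # each group carries half the effective sample
  expect_equal(sum(resp$weight[resp$group == "gp"]), 1256 / 2)
  expect_equal(sum(resp$weight[resp$group == "public"]), 1256 / 2)
  expect_error(generate_respondents(-1, 10), "nonnegative")

  # all prevalences zero: every covariate zero, score = intercept + noise
  r0 <- generate_respondents(0, 200, tr, prevalences = c(age65 = 0, female = 0,
    ethnic_minority = 0, degree = 0, rural = 0, suburban = 0), seed = 6)
  expect_true(all(r0[c("age65", "female", "ethnic_minority", "degree",
                       "rural", "suburban")] == 0))
  expect_equal(mean(r0$latent_score), tr$gamma[["intercept"]], tolerance = 0.3)
})

test_that("zero loadings give closed-form marginal indicator prevalences", {
  tr <- true_parameters(zeta = c(screened = 0, had_cancer = 0, tested = 0),
                        zeta_symptoms = 0)
  resp <- generate_respondents(0, 50000, tr, seed = 7)
  for (k in c("screened", "had_cancer", "tested")) {
    p_hat <- mean(resp[[k]])
    p_true <- plogis(tr$alpha[[k]])
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / 50000) + 1e-3)
  }
  # ordered count: P(count <= j) = plogis(cut_{j+1}) when the loading is 0
  expect_lt(abs(mean(resp$symptom_count <= 8) - plogis(tr$cuts[9])), 0.01)
})

test_that("simulated choices follow the choice model", {
  des <- cached_design()
  # all coefficients zero: uniform choices
  tr0 <- true_parameters(beta = setNames(rep(0, 13), names(true_parameters()$beta)),
                         sigma = 0, delta = 0, covariate = 0, tau = 0)
  resp <- generate_respondents(100, 300, tr0, seed = 8)
  ch <- simulate_choices(des, resp, tr0, seed = 9)
  n_tasks <- nrow(ch) / 2
  share <- mean(ch$chosen[ch$alternative == 1])
  expect_lt(abs(share - 0.5), 3 * sqrt(0.25 / n_tasks))
  # exactly one chosen per respondent-task, two rows each
  agg <- aggregate(chosen ~ respondent_id + task_id, ch, sum)
  expect_true(all(agg$chosen == 1L))
  expect_equal(nrow(ch), 2 * nrow(agg))
  # arm structure: hidden attribute rows are NA, GP rows complete
  expect_true(all(is.na(ch$npv[ch$arm == "ppv"])))
  expect_true(all(is.na(ch$ppv[ch$arm == "npv"])))
  expect_false(anyNA(ch[ch$arm == "full", names(mct_schema())]))

  # dominance limit: a huge site coefficient forces the site alternative
  trb <- true_parameters(beta = c(tr0$beta[names(tr0$beta) != "site_yes"],
                                  site_yes = 20),
                         sigma = 0, delta = 0, covariate = 0, tau = 0)
  chb <- simulate_choices(des, resp, trb, seed = 10)
  a1 <- chb[chb$alternative == 1, ]; a2 <- chb[chb$alternative == 2, ]
  onesite <- which(a1$site != a2$site)
  won <- ifelse(a1$site[onesite] == "yes", a1$chosen[onesite], a2$chosen[onesite])
  expect_gt(mean(won), 0.999)
})

test_that("choice shares match closed-form logit probabilities at sigma = 0", {
  des <- cached_design()
  tr <- pooled_truth(sigma = 0)
  resp <- generate_respondents(10000, 0, tr, seed = 11)
  ch <- simulate_choices(des, resp, tr, seed = 12)
  X <- encode_profiles(des$tasks[names(mct_schema())], mct_schema())
  V <- drop(X %*% tr$beta[colnames(X)])
  for (t in c(1, 7, 24)) {
    rows <- which(des$tasks$task_id == t)
    p_true <- plogis(V[rows[1]] - V[rows[2]])
    sel <- ch$task_id == t & ch$alternative == 1
    n <- sum(sel)
    p_hat <- mean(ch$chosen[sel])
    expect_lt(abs(p_hat - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  }
})

test_that("scale-coefficient confound: doubling lambda, halving beta is invariant", {
  des <- cached_design()
  tr1 <- pooled_truth()
  tr2 <- pooled_truth(beta = tr1$beta / 2, sigma = tr1$sigma / 2,
                      delta = tr1$delta / 2,
                      lambda_pub = 2 * tr1$lambda_pub,
                      lambda_arm = tr1$lambda_arm)
  resp <- generate_respondents(60, 140, tr1, seed = 13)
  ch1 <- simulate_choices(des, resp, tr1, seed = 14)
  ch2 <- simulate_choices(des, resp, tr2, seed = 14)
  # same seed, same utilities for the public: identical public choices; for
  # GPs (scale 1, halved coefficients) the distribution differs
  expect_identical(ch1$chosen[ch1$group == "public"],
                   ch2$chosen[ch2$group == "public"])
})

test_that("choice data round-trips through CSV", {
  des <- cached_design()
  tr <- pooled_truth()
  resp <- generate_respondents(5, 10, tr, seed = 15)
  ch <- simulate_choices(des, resp, tr, seed = 16)
  f <- tempfile(fileext = ".csv")
  write_choice_data(ch, f)
  back <- read_choice_data(f, mct_schema())
  expect_equal(back$chosen, ch$chosen)
  expect_equal(back$npv, ch$npv)
  expect_equal(back$form, ch$form)
})

test_that("truth fixtures round-trip through JSON", {
  tr <- true_parameters()
  f <- tempfile(fileext = ".json")
  write_truth(tr, f)
  back <- read_truth(f)
  expect_equal(back$beta, tr$beta)
  expect_equal(back$cuts, tr$cuts)
  expect_equal(back$covariate, tr$covariate)
  expect_equal(back$lambda_pub, tr$lambda_pub)
})
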