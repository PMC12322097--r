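#' Generate a synthetic respondent population
#'
#' Draws GP and public respondents with demographic indicators, a latent
#' cancer-knowledge/experience score, and the survey indicators generated
#' from its measurement model. Public respondents are randomised 50/50 to the
#' PPV or NPV arm; all respondents are randomised 50/50 to one of two design
#' blocks. Age, gender, ethnicity and education are independent Bernoulli
#' draws at the stated prevalences; urbanicity is a single three-way draw
#' (rural/suburban/urban) since its indicators are mutually exclusive.
#'
#' The latent score is `gamma' z + eta` with standard-normal disturbance;
#' binary indicators follow logit measurement equations and the 0-16
#' symptom-recognition count an ordered logit with 16 cut-points. Group
#' weights are `0.5 * N_total / N_group`, so each sample contributes half of
#' the effective pooled sample.
#'
#' @param n_gp,n_public Sample sizes (the emulated study: 251 GPs, 1005
#'   members of the public).
#' @param truth A [true_parameters()] object.
#' @param prevalences Named vector: `age65`, `female`, `ethnic_minority`,
#'   `degree` Bernoulli prevalences and `rural`, `suburban` shares of the
#'   urbanicity draw (urban is the remainder).
#' @param seed Integer master seed (substreams are derived internally).
#' @return Data frame of class `dce_respondents`, one row per respondent.
#' @export
generate_respondents <- function(n_gp, n_public, truth = true_parameters(),
                                 prevalences = c(age65 = 0.25, female = 0.51,
                                                 ethnic_minority = 0.20, degree = 0.43,
                                                 rural = 0.23, suburban = 0.46),
                                 seed = 1L) {
  if (n_gp < 0 || n_public < 0) stop("sample sizes must be nonnegative")
  if (any(prevalences < 0 | prevalences > 1)) stop("prevalences must lie in [0, 1]")
  n <- n_gp + n_public
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  group <- rep(c("gp", "public"), c(n_gp, n_public))
  arm <- ifelse(group == "gp", "full",
                ifelse(stats::runif(n) < 0.5, "ppv", "npv"))
  block <- sample(1:2, n, replace = TRUE)
  urb <- stats::runif(n)
  rural <- as.integer(urb < prevalences[["rural"]])
  suburban <- as.integer(urb >= prevalences[["rural"]] &
                           urb < prevalences[["rural"]] + prevalences[["suburban"]])
  z <- data.frame(
    age65 = stats::rbinom(n, 1, prevalences[["age65"]]),
    female = stats::rbinom(n, 1, prevalences[["female"]]),
    ethnic_minority = stats::rbinom(n, 1, prevalences[["ethnic_minority"]]),
    degree = stats::rbinom(n, 1, prevalences[["degree"]]),
    rural = rural, suburban = suburban)

  g <- truth$gamma
  lv <- g[["intercept"]] +
    as.matrix(z) %*% g[setdiff(names(g), "intercept")][colnames(z)] +
    stats::rnorm(n)
  lv <- drop(lv)

  draw_bin <- function(ind) {
    s <- truth$alpha[[ind]] + truth$zeta[[ind]] * lv
    stats::rbinom(n, 1, stats::plogis(s))
  }
  m <- truth$zeta_symptoms * lv + stats::rlogis(n)
  symptom_count <- vapply(m, function(mi) sum(mi > truth$cuts), integer(1))

  w <- ifelse(group == "gp", 0.5 * n / max(n_gp, 1L), 0.5 * n / max(n_public, 1L))
  out <- data.frame(
    respondent_id = seq_len(n), group = group, arm = arm, block = block,
    weight = w, z,
    latent_score = lv,
    screened = draw_bin("screened"), had_cancer = draw_bin("had_cancer"),
    tested = draw_bin("tested"), symptom_count = symptom_count,
    stringsAsFactors = FALSE)
  class(out) <- c("dce_respondents", "data.frame")
  out
}

#' Simulate stated choices for a respondent population
#'
#' For each respondent, individual coefficients are built as
#' `beta_n = beta + public shift + covariate shifts + tau * latent score +
#' sigma * xi_n` with one standard-normal draw `xi_n` per respondent (panel
#' structure: common across that respondent's tasks). Utilities are
#' `lambda_n * (x' beta_n)` plus independent standard Gumbel noise per
#' alternative (inverse-CDF of uniforms); the argmax is recorded as the
#' choice. Respondents see their own arm's view of their block's 12 tasks.
#'
#' @param design A `dce_design` (full view; arm views are derived here).
#' @param respondents Output of [generate_respondents()].
#' @param truth A [true_parameters()] object.
#' @param seed Integer seed (substream independent of the respondent draws).
#' @param divisors Continuous-attribute divisors.
#' @return Long-format data frame of class `dce_choices`: one row per
#'   respondent x task x alternative with attribute levels, `chosen` flag,
#'   group/arm/block/weight metadata, covariates and indicators.
#' @export
simulate_choices <- function(design, respondents, truth = true_parameters(),
                             seed = 1L, divisors = c(cancers = 10)) {
  schema <- design$schema
  cols <- main_effect_columns(schema, divisors)
  need_arms <- unique(respondents$arm)
  views <- lapply(stats::setNames(nm = need_arms), function(a) split_arm_view(design, a))
  blocks_in <- sort(unique(design$tasks$block))
  if (!all(unique(respondents$block) %in% blocks_in))
    stop("respondent block missing from design")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed + 1L)

  n <- nrow(respondents)
  # individual coefficients
  Bn <- matrix(rep(truth$beta[cols], each = n), n, length(cols),
               dimnames = list(NULL, cols))
  pub <- respondents$group == "public"
  for (j in names(truth$delta)) Bn[pub, j] <- Bn[pub, j] + truth$delta[[j]]
  for (cv in names(truth$covariate))
    for (j in names(truth$covariate[[cv]]))
      Bn[, j] <- Bn[, j] + truth$covariate[[cv]][[j]] * respondents[[cv]]
  for (j in names(truth$tau)) Bn[, j] <- Bn[, j] + truth$tau[[j]] * respondents$latent_score
  for (j in names(truth$sigma))
    if (truth$sigma[[j]] != 0)
      Bn[, j] <- Bn[, j] + truth$sigma[[j]] * stats::rnorm(n)
  lam <- ifelse(pub, truth$lambda_pub, 1) *
    ifelse(respondents$arm == "npv", truth$lambda_arm, 1)

  out <- vector("list", n)
  Xv <- lapply(views, function(v) encode_profiles(v$tasks[names(schema)], schema, divisors))
  for (i in seq_len(n)) {
    v <- views[[respondents$arm[i]]]
    sel <- v$tasks$block == respondents$block[i]
    X <- Xv[[respondents$arm[i]]][sel, , drop = FALSE]
    tv <- v$tasks[sel, , drop = FALSE]
    u <- lam[i] * drop(X %*% Bn[i, ]) - log(-log(stats::runif(nrow(X))))
    chosen <- stats::ave(u, tv$task_id, FUN = function(x) as.integer(x == max(x)))
    res <- data.frame(respondent_id = respondents$respondent_id[i],
                      group = respondents$group[i], arm = respondents$arm[i],
                      block = respondents$block[i], task_id = tv$task_id,
                      alternative = tv$alt, chosen = as.integer(chosen),
                      stringsAsFactors = FALSE)
    out[[i]] <- cbind(res, tv[names(schema)])
  }
  long <- do.call(rbind, out)
  meta_cols <- c("weight", "age65", "female", "ethnic_minority", "degree",
                 "rural", "suburban", "latent_score", "screened", "had_cancer",
                 "tested", "symptom_count")
  idx <- match(long$respondent_id, respondents$respondent_id)
  long <- cbind(long, respondents[idx, meta_cols])
  rownames(long) <- NULL
  class(long) <- c("dce_choices", "data.frame")
  long
}

#' Read / write long-format choice data
#'
#' @param data A `dce_choices` data frame.
#' @param path CSV file path.
#' @export
write_choice_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_choice_data
#' @param schema Schema used to restore numeric attribute types.
#' @export
read_choice_data <- function(path, schema) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (a in schema)
    if (is.numeric(a$levels)) d[[a$name]] <- as.numeric(d[[a$name]])
  class(d) <- c("dce_choices", "data.frame")
  d
}
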