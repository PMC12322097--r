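#' Deterministic utility of a test profile for a stakeholder group
#'
#' Evaluates the profile at the group's effective coefficient means with the
#' group's scale applied (GP reference scale 1; public: `lambda_pub`).
#' Off-grid numeric values of dummy-coded attributes (e.g. a PPV of 76%) are
#' evaluated by piecewise-linear interpolation between the adjacent level
#' coefficients, with the reference level contributing zero; values outside
#' the level range are clamped to the nearest level with a warning (or, with
#' `clamp = FALSE`, raise an error). An all-reference profile has utility 0.
#'
#' @param profile Named list or one-row data frame with a value for every
#'   schema attribute.
#' @param fit A `dce_fit`.
#' @param group `"gp"` or `"public"`.
#' @param clamp Clamp out-of-range numeric values (default) or error.
#' @return Scalar utility.
#' @export
profile_utility <- function(profile, fit, group = "gp", clamp = TRUE) {
  schema <- fit$spec$schema
  gc <- group_coefficients(fit, group)
  b <- gc$est
  profile <- as.list(profile)
  u <- 0
  for (a in schema) {
    v <- profile[[a$name]]
    if (is.null(v) || is.na(v)) stop("profile lacks attribute '", a$name, "'")
    if (a$coding == "continuous") {
      d <- if (a$name %in% names(fit$spec$divisors)) fit$spec$divisors[[a$name]] else 1
      cn <- paste0(a$name, if (d != 1) paste0("_per", d) else "")
      u <- u + as.numeric(v) / d * b[[cn]]
    } else if (is.numeric(a$levels)) {
      u <- u + interp_level_coef(as.numeric(v), a, b, clamp)
    } else {
      if (!v %in% a$levels)
        stop("'", v, "' is not a level of attribute '", a$name, "'")
      if (v != a$reference)
        u <- u + b[[paste0(a$name, "_", sanitize_level(v))]]
    }
  }
  unname(u)
}

# coefficient at a numeric level: exact at grid points (reference -> 0),
# linear between adjacent grid points otherwise
interp_level_coef <- function(v, attr, b, clamp) {
  lv <- sort(attr$levels)
  coef_at <- vapply(lv, function(l) {
    if (l == attr$reference) 0 else b[[paste0(attr$name, "_", sanitize_level(l))]]
  }, numeric(1))
  if (v < min(lv) || v > max(lv)) {
    if (!clamp) stop("value ", v, " of '", attr$name, "' outside level range")
    warning("'", attr$name, "' value ", v, " clamped to level range")
    v <- min(max(v, min(lv)), max(lv))
  }
  stats::approx(lv, coef_at, xout = v)$y
}

#' Probability that profile `a` is chosen over profile `b`
#'
#' Binary logit preference probability at the group's scaled deterministic
#' utilities: `exp(V_a) / (exp(V_a) + exp(V_b))`. Identical profiles give
#' exactly 0.5, and `pairwise_preference(a, b) + pairwise_preference(b, a)`
#' is exactly 1.
#'
#' @param a,b Profiles (named lists / one-row data frames).
#' @inheritParams profile_utility
#' @return Probability in (0, 1).
#' @export
pairwise_preference <- function(a, b, fit, group = "gp", clamp = TRUE) {
  stats::plogis(profile_utility(a, fit, group, clamp) -
                  profile_utility(b, fit, group, clamp))
}

#' Rank every profile in the design space against a benchmark
#'
#' Enumerates all attribute-level combinations, computes each profile's
#' probability of being chosen over the benchmark, and sorts descending. The
#' summary fraction is the share of enumerated profiles over which the
#' benchmark is preferred (pairwise probability strictly below 0.5; exact
#' ties count as not preferred by the benchmark).
#'
#' @param schema A `dce_schema`.
#' @param benchmark Benchmark profile (off-grid numeric values allowed).
#' @param fit A `dce_fit`.
#' @param group Stakeholder group.
#' @return List of class `ranking_result`: `table` (profiles with utility,
#'   probability vs benchmark and rank), `fraction_benchmark_preferred`,
#'   `benchmark_utility`, `n_ties`, `group`.
#' @export
rank_against_benchmark <- function(schema, benchmark, fit, group = "gp") {
  profs <- enumerate_profiles(schema)
  gc <- group_coefficients(fit, group)
  X <- encode_profiles(profs, schema, fit$spec$divisors)
  V <- drop(X %*% gc$est[colnames(X)])
  Vb <- profile_utility(benchmark, fit, group)
  p <- stats::plogis(V - Vb)
  ord <- order(p, decreasing = TRUE)
  tab <- cbind(profs, utility = V, prob_vs_benchmark = p)[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  n_ties <- sum(p == 0.5)
  structure(list(table = tab,
                 fraction_benchmark_preferred = mean(p < 0.5),
                 benchmark_utility = Vb, n_ties = n_ties, group = group),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("Ranking (%s): benchmark preferred over %.1f%% of %d profiles%s\n",
              x$group, 100 * x$fraction_benchmark_preferred, nrow(x$table),
              if (x$n_ties) paste0(" (", x$n_ties, " ties, counted against the benchmark)") else ""))
  invisible(x)
}

#' Compare clinical tests to the benchmark
#'
#' Probability of choosing each comparator profile (e.g. FIT, PSA, CA125)
#' over the benchmark, per stakeholder group: one row per comparator.
#'
#' @param comparators Named list of profiles.
#' @param benchmark Benchmark profile.
#' @param fit A `dce_fit`.
#' @param groups Stakeholder groups to evaluate.
#' @return Data frame: group, comparator, probability chosen over benchmark.
#' @export
compare_clinical_tests <- function(comparators, benchmark, fit,
                                   groups = "gp") {
  rows <- list()
  for (g in groups) for (nm in names(comparators)) {
    rows[[paste(g, nm)]] <- data.frame(
      group = g, comparator = nm,
      prob_vs_benchmark = pairwise_preference(comparators[[nm]], benchmark, fit, g),
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benchmark and comparator profiles
#'
#' Reads profiles from a YAML config (default: the packaged file with an
#' MCT benchmark shaped like the blood-based multi-cancer test evaluated in
#' the SYMPLIFY study — PPV 76%, NPV 98%, results in 1-2 weeks, identifies
#' the cancer site, detects early-stage disease, number of cancers clamped to
#' the design maximum of 25 — and illustrative FIT / PSA / CA125 profiles;
#' their accuracy values are synthetic placeholders, configurable in the
#' YAML, since the originally used values are not republished here).
#'
#' @param path YAML file; defaults to the packaged `benchmarks.yaml`.
#' @return List with `benchmark` (profile) and `comparators` (named list).
#' @export
read_benchmarks <- function(path = system.file("extdata", "benchmarks.yaml",
                                               package = "mctchoice")) {
  y <- yaml::read_yaml(path)
  list(benchmark = y$benchmark, comparators = y$comparators)
}
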