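#' @name design
#' @title Blocked Bayesian D-efficient choice designs
#'
#' @description Tools to build experimental designs for binary choice tasks:
#' exactly level-balanced random starts, a Bayesian D-error criterion averaged
#' over prior draws (and, for split designs, over respondent arms), and a
#' balance-preserving pairwise-swap search. A design holds `n_tasks` tasks of
#' two profiles each, split into blocks.
NULL

# A-priori preference orderings used to screen dominated tasks: a task is
# rejected when one alternative is weakly better on every monotone attribute
# and strictly better on at least one. Form of the test is non-monotone.
canonical_monotone <- function() {
  list(ppv = "increasing", npv = "increasing", cancers = "increasing",
       wait = c("1-2wk", "1wk"), site = c("no", "yes"), early = c("no", "yes"))
}

# numeric "better-ness" score per attribute column; NA for non-monotone
dominance_scores <- function(profiles, schema, monotone) {
  sc <- matrix(NA_real_, nrow(profiles), length(schema),
               dimnames = list(NULL, names(schema)))
  for (a in schema) {
    rule <- monotone[[a$name]]
    if (is.null(rule)) next
    v <- profiles[[a$name]]
    sc[, a$name] <-
      if (identical(rule, "increasing")) as.numeric(v)
      else if (identical(rule, "decreasing")) -as.numeric(v)
      else match(as.character(v), rule)  # worst..best order
  }
  sc
}

# TRUE if either alternative of the 2-row score matrix weakly dominates
task_dominated <- function(sc2) {
  d <- sc2[1L, ] - sc2[2L, ]
  d <- d[!is.na(d)]
  if (!length(d)) return(FALSE)
  (all(d >= 0) && any(d > 0)) || (all(d <= 0) && any(d < 0))
}

task_identical <- function(p2) {
  all(vapply(p2, function(col) {
    (is.na(col[1L]) && is.na(col[2L])) ||
      (!is.na(col[1L]) && !is.na(col[2L]) && col[1L] == col[2L])
  }, logical(1)))
}

new_design <- function(schema, tasks, n_blocks, prior_spec = NULL,
                       d_error = NA_real_, seed = NA_integer_, arm = "full") {
  structure(list(schema = schema, tasks = tasks, n_blocks = n_blocks,
                 prior_spec = prior_spec, d_error = d_error, seed = seed,
                 arm = arm),
            class = "dce_design")
}

#' @export
print.dce_design <- function(x, ...) {
  cat("Choice design:", max(x$tasks$task_id), "tasks,", x$n_blocks,
      "block(s), arm:", x$arm, "\n")
  if (is.finite(x$d_error)) cat("  Bayesian D-error:", signif(x$d_error, 5), "\n")
  invisible(x)
}

# level-balanced random design: each level of each attribute appears exactly
# slots / n_levels times across the 2 * n_tasks alternative slots; repaired by
# balance-preserving swaps until no task is identical or dominated
random_balanced_design <- function(schema, n_tasks, n_blocks = 1L,
                                   monotone = canonical_monotone(),
                                   max_repair = 5000L) {
  slots <- 2L * n_tasks
  counts <- schema_level_counts(schema)
  bad <- names(schema)[slots %% counts != 0L]
  if (length(bad))
    stop("infeasible design: ", slots, " alternative slots cannot balance attribute '",
         bad[1L], "' (", counts[[bad[1L]]], " levels)")
  if (n_tasks %% n_blocks != 0L) stop("n_tasks must be divisible by n_blocks")
  prof <- as.data.frame(lapply(schema, function(a)
    sample(rep(a$levels, slots / length(a$levels)))))
  names(prof) <- names(schema)
  task_of <- rep(seq_len(n_tasks), each = 2L)
  bad_task <- function(t) {
    idx <- which(task_of == t)
    task_identical(prof[idx, , drop = FALSE]) ||
      task_dominated(dominance_scores(prof[idx, , drop = FALSE], schema, monotone))
  }
  viol <- which(vapply(seq_len(n_tasks), bad_task, logical(1)))
  tries <- 0L
  while (length(viol) && tries < max_repair) {
    tries <- tries + 1L
    t1 <- viol[sample.int(length(viol), 1L)]
    a <- sample(names(schema), 1L)
    s1 <- which(task_of == t1)[sample.int(2L, 1L)]
    s2 <- sample.int(slots, 1L)
    t2 <- task_of[s2]
    if (t2 == t1 || prof[[a]][s1] == prof[[a]][s2]) next
    old1 <- bad_task(t1); old2 <- bad_task(t2)
    tmp <- prof[[a]][s1]; prof[[a]][s1] <- prof[[a]][s2]; prof[[a]][s2] <- tmp
    new1 <- bad_task(t1); new2 <- bad_task(t2)
    if ((new1 + new2) > (old1 + old2)) {  # revert if worse
      tmp <- prof[[a]][s1]; prof[[a]][s1] <- prof[[a]][s2]; prof[[a]][s2] <- tmp
    } else {
      viol <- which(vapply(seq_len(n_tasks), bad_task, logical(1)))
    }
  }
  if (length(viol))
    stop("could not repair random design to meet non-dominance constraints")
  tasks <- data.frame(task_id = task_of,
                      block = rep(rep(seq_len(n_blocks), each = n_tasks / n_blocks), each = 2L),
                      alt = rep(1:2, n_tasks))
  tasks <- cbind(tasks, prof)
  new_design(schema, tasks, n_blocks)
}

#' Bayesian D-error of a design
#'
#' Computes the mean over prior parameter draws of `det(I(beta))^(-1/K)`,
#' where `I` is the per-task-normalised information matrix of the binary-logit
#' design and `K` the number of identified parameters. For split designs the
#' criterion is the arm-weighted average of the per-arm D-errors, each arm
#' evaluated with the hidden attribute's columns dropped (its own utility
#' function). A singular information matrix yields `+Inf` (flagged via the
#' `"singular"` attribute, not an error).
#'
#' @param design A `dce_design`.
#' @param prior_draws Matrix of prior parameter draws (rows = draws, columns
#'   named by the full set of main-effect columns).
#' @param arm_weights Named weights over arms (`full`, `ppv`, `npv`); default
#'   is the design's own arms or `c(full = 1)`.
#' @param divisors Continuous-attribute divisors.
#' @return Scalar Bayesian D-error with attribute `per_arm`.
#' @export
bayesian_d_error <- function(design, prior_draws,
                             arm_weights = NULL, divisors = c(cancers = 10)) {
  if (is.null(arm_weights)) arm_weights <- c(full = 1)
  arm_weights <- arm_weights / sum(arm_weights)
  per_arm <- vapply(names(arm_weights), function(arm) {
    arm_d_error(design, prior_draws, arm, divisors)
  }, numeric(1))
  out <- sum(arm_weights * per_arm)
  attr(out, "per_arm") <- per_arm
  attr(out, "singular") <- !is.finite(out)
  out
}

arm_d_error <- function(design, prior_draws, arm, divisors) {
  tasks <- design$tasks
  hidden <- hidden_attribute(design$schema, arm)
  prof <- tasks[names(design$schema)]
  if (length(hidden)) prof[[hidden]] <- NA
  X <- encode_profiles(prof, design$schema, divisors)
  if (length(hidden)) {
    drop_cols <- grep(paste0("^", hidden, "_"), colnames(X))
    X <- X[, -drop_cols, drop = FALSE]
  }
  keep <- colnames(X)
  if (!all(keep %in% colnames(prior_draws)))
    stop("prior draws lack columns: ",
         paste(setdiff(keep, colnames(prior_draws)), collapse = ", "))
  Bm <- prior_draws[, keep, drop = FALSE]
  ord <- order(tasks$task_id, tasks$alt)
  X <- X[ord, , drop = FALSE]
  n <- nrow(X)
  dX <- X[seq(1L, n, 2L), , drop = FALSE] - X[seq(2L, n, 2L), , drop = FALSE]
  Tn <- nrow(dX); K <- ncol(dX)
  vals <- apply(Bm, 1L, function(b) {
    pr <- stats::plogis(drop(dX %*% b))
    I <- crossprod(dX * (pr * (1 - pr)), dX) / Tn
    dt <- suppressWarnings(det(I))
    if (!is.finite(dt) || dt <= 0) return(Inf)
    dt^(-1 / K)
  })
  mean(vals)
}

#' Generate a blocked Bayesian D-efficient design
#'
#' Builds an exactly level-balanced random start and improves it by
#' coordinate exchange with balance-preserving pairwise level swaps,
#' minimising the Bayesian D-error subject to the non-identical and
#' non-dominance constraints. Reproducible given the seed; the achieved
#' D-error never exceeds the D-error of the random start.
#'
#' @param schema A `dce_schema`.
#' @param priors List with `mean` (named vector over main-effect columns) and
#'   `cov` (covariance matrix, or a scalar variance applied to all columns).
#' @param n_tasks,n_blocks Task count and number of blocks (`n_tasks`
#'   divisible by `n_blocks`).
#' @param seed Integer seed controlling the start, the swap proposals and the
#'   quasi-random prior draws.
#' @param n_sweeps Number of search sweeps (each sweep proposes one swap per
#'   attribute per task).
#' @param n_prior_draws Quasi-random draws from the prior for the Bayesian
#'   criterion.
#' @param arm_weights Arms over which the criterion is averaged; defaults to
#'   `c(ppv = .5, npv = .5)` when the schema has arm-specific attributes
#'   (matching a 50/50 randomisation) and `c(full = 1)` otherwise.
#' @param monotone Dominance-screening orderings (see package vignette).
#' @param divisors Continuous-attribute divisors.
#' @return A `dce_design` with the achieved `d_error`, the `prior_spec` and
#'   the seed recorded.
#' @export
generate_design <- function(schema, priors, n_tasks = 24L, n_blocks = 2L,
                            seed = 1L, n_sweeps = 200L, n_prior_draws = 100L,
                            arm_weights = NULL,
                            monotone = canonical_monotone(),
                            divisors = c(cancers = 10)) {
  if (is.null(arm_weights)) {
    vis <- vapply(schema, `[[`, character(1), "arm_visibility")
    arm_weights <- if (any(vis != "all")) c(ppv = .5, npv = .5) else c(full = 1)
  }
  cols <- main_effect_columns(schema, divisors)
  pm <- priors$mean[cols]
  if (anyNA(pm)) stop("priors$mean must name every column: ",
                      paste(cols[is.na(pm)], collapse = ", "))
  pc <- priors$cov
  if (is.null(pc)) pc <- diag(0, length(cols))
  if (length(pc) == 1L) pc <- diag(as.numeric(pc), length(cols))
  draws <- halton_normal(n_prior_draws, length(cols), seed = seed + 7L)
  prior_draws <- sweep(draws %*% chol(pc), 2L, pm, `+`)
  colnames(prior_draws) <- cols

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  des <- random_balanced_design(schema, n_tasks, n_blocks, monotone)
  cur <- bayesian_d_error(des, prior_draws, arm_weights, divisors)
  task_of <- des$tasks$task_id
  slots <- nrow(des$tasks)
  bad_task <- function(prof, t) {
    idx <- which(task_of == t)
    task_identical(prof[idx, , drop = FALSE]) ||
      task_dominated(dominance_scores(prof[idx, , drop = FALSE], schema, monotone))
  }
  for (sweep_i in seq_len(n_sweeps)) {
    for (a in names(schema)) {
      for (prop in seq_len(n_tasks)) {
        s1 <- sample.int(slots, 1L); s2 <- sample.int(slots, 1L)
        if (task_of[s1] == task_of[s2]) next
        if (des$tasks[[a]][s1] == des$tasks[[a]][s2]) next
        cand <- des$tasks
        tmp <- cand[[a]][s1]; cand[[a]][s1] <- cand[[a]][s2]; cand[[a]][s2] <- tmp
        if (bad_task(cand[names(schema)], task_of[s1]) ||
            bad_task(cand[names(schema)], task_of[s2])) next
        cand_des <- des; cand_des$tasks <- cand
        val <- bayesian_d_error(cand_des, prior_draws, arm_weights, divisors)
        if (is.finite(val) && val < cur) {
          des <- cand_des
          cur <- val
        }
      }
    }
  }
  des$prior_spec <- list(mean = pm, cov = pc, n_draws = n_prior_draws)
  des$d_error <- as.numeric(cur)
  des$seed <- seed
  des
}

#' Restrict a design to a respondent arm's view
#'
#' `arm = "full"` returns the design unchanged; `"ppv"` removes the NPV
#' attribute from every profile (its levels become `NA`); `"npv"` removes the
#' PPV attribute. Task ids and blocks are preserved.
#'
#' @param design A `dce_design`.
#' @param arm One of `"full"`, `"ppv"`, `"npv"`.
#' @return A `dce_design` with `arm` recorded.
#' @export
split_arm_view <- function(design, arm = c("full", "ppv", "npv")) {
  if (!is.character(arm) || length(arm) != 1L || !arm %in% c("full", "ppv", "npv"))
    stop("unknown arm label: must be one of 'full', 'ppv', 'npv'")
  out <- design
  hidden <- hidden_attribute(design$schema, arm)
  if (length(hidden)) out$tasks[[hidden]] <- out$tasks[[hidden]][NA]
  out$arm <- arm
  out
}

#' Export / import a design
#'
#' Writes `design.csv` (one row per task x alternative: `task_id`, `block`,
#' `alt`, then one column per attribute) plus a `design.json` sidecar holding
#' the achieved D-error, the seed and the prior specification.
#'
#' @param design A `dce_design`.
#' @param dir Directory to write into (created if missing).
#' @param schema Schema used to re-attach types on read.
#' @return `write_design` returns `dir` invisibly; `read_design` a
#'   `dce_design`.
#' @export
write_design <- function(design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(design$tasks, file.path(dir, "design.csv"), row.names = FALSE)
  meta <- list(n_blocks = design$n_blocks, d_error = design$d_error,
               seed = design$seed, arm = design$arm,
               prior_mean = as.list(design$prior_spec$mean))
  jsonlite::write_json(meta, file.path(dir, "design.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_design
#' @export
read_design <- function(dir, schema) {
  tasks <- utils::read.csv(file.path(dir, "design.csv"), stringsAsFactors = FALSE,
                           check.names = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "design.json"), simplifyVector = TRUE)
  for (a in schema)
    if (is.numeric(a$levels)) tasks[[a$name]] <- as.numeric(tasks[[a$name]])
  new_design(schema, tasks, meta$n_blocks,
             prior_spec = list(mean = unlist(meta$prior_mean)),
             d_error = meta$d_error, seed = meta$seed,
             arm = if (is.null(meta$arm)) "full" else meta$arm)
}

# exact level-balance check per arm view: each level of each visible
# attribute must appear slots / n_levels times; returns max absolute deviation
level_balance_deviation <- function(design, arms = c("full")) {
  max(vapply(arms, function(arm) {
    hidden <- hidden_attribute(design$schema, arm)
    devs <- vapply(setdiff(names(design$schema), hidden), function(a) {
      tab <- table(factor(design$tasks[[a]], levels = design$schema[[a]]$levels))
      max(abs(tab - nrow(design$tasks) / length(design$schema[[a]]$levels)))
    }, numeric(1))
    max(devs)
  }, numeric(1)))
}

#' Read design priors from YAML
#'
#' @param path YAML file with `mean` (named log-odds per encoded column) and
#'   either `cov` (matrix) or `variance` (scalar); defaults to the packaged
#'   pilot-scale priors.
#' @return List with `mean` and `cov` ready for [generate_design()].
#' @export
read_priors <- function(path = system.file("extdata", "design_priors.yaml",
                                           package = "mctchoice")) {
  y <- yaml::read_yaml(path)
  m <- unlist(y$mean)
  cv <- if (!is.null(y$cov)) as.matrix(y$cov) else
    diag(as.numeric(y$variance), length(m))
  list(mean = m, cov = cv)
}
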