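test_that("profile enumeration covers the full Cartesian product", {
  profs <- enumerate_profiles(mct_schema())
  expect_equal(nrow(profs), 2048L)
  expect_equal(nrow(unique(profs)), 2048L)

  expect_equal(nrow(enumerate_profiles(binary_schema())), 2L)

  # independent recursive counter over random sub-schemas
  count_recursive <- function(counts) {
    if (length(counts) == 0L) return(1L)
    counts[1L] * count_recursive(counts[-1L])
  }
  set.seed(42)
  for (i in 1:5) {
    n_attr <- sample(2:4, 1)
    attrs <- lapply(seq_len(n_attr), function(j)
      attribute(paste0("a", j), seq_len(sample(2:4, 1)), "categorical"))
    sch <- attribute_schema(attrs)
    expect_equal(nrow(enumerate_profiles(sch)),
                 unname(count_recursive(vapply(sch, function(a) length(a$levels), integer(1)))))
  }
})

test_that("enumeration order is deterministic and lexicographic", {
  sch <- small_schema()
  p1 <- enumerate_profiles(sch)
  p2 <- enumerate_profiles(sch)
  expect_identical(p1, p2)
  # first attribute varies slowest
  expect_equal(p1$ppv, c(40, 40, 40, 40, 80, 80, 80, 80))
  expect_equal(p1$form[1:2], c("blood", "faecal"))
  expect_error(enumerate_profiles(list()), "invalid schema")
})

test_that("attribute and schema invariants are enforced", {
  expect_error(attribute("x", 1), "at least 2 levels")
  expect_error(attribute("x", c(1, 1, 2)), "duplicate")
  expect_error(attribute("x", c("a", "b"), reference = "c"), "reference")
  expect_error(attribute_schema(attribute("x", 1:2), attribute("x", 1:3)), "unique")
  expect_error(attribute_schema(
    attribute("a", 1:2, arm_visibility = "ppv_arm"),
    attribute("b", 1:2, arm_visibility = "ppv_arm")), "at most one")
})

test_that("Bayesian D-error matches the closed-form single-parameter case", {
  # one binary attribute, one task with differing levels, prior mass at 0:
  # information p(1-p) dx^2 = 0.25, D-error = 4 / dx^2 = 4
  sch <- binary_schema()
  tasks <- data.frame(task_id = c(1L, 1L), block = 1L, alt = 1:2,
                      site = c("yes", "no"))
  des <- mctchoice:::new_design(sch, tasks, 1L)
  pd <- matrix(0, 1, 1, dimnames = list(NULL, "site_yes"))
  expect_equal(as.numeric(bayesian_d_error(des, pd)), 4)

  # identical alternatives in every task: zero information, flagged +Inf
  tasks2 <- data.frame(task_id = c(1L, 1L), block = 1L, alt = 1:2,
                       site = c("yes", "yes"))
  des2 <- mctchoice:::new_design(sch, tasks2, 1L)
  d2 <- bayesian_d_error(des2, pd)
  expect_true(is.infinite(as.numeric(d2)))
  expect_true(attr(d2, "singular"))

  # duplicating every task leaves the per-task-normalised criterion unchanged
  tasks3 <- rbind(tasks, transform(tasks, task_id = 2L))
  des3 <- mctchoice:::new_design(sch, tasks3, 1L)
  expect_equal(as.numeric(bayesian_d_error(des3, pd)),
               as.numeric(bayesian_d_error(des, pd)))
})

test_that("generated designs are balanced, reproducible and feasible-checked", {
  des <- cached_design()
  expect_equal(max(des$tasks$task_id), 24L)
  expect_equal(des$n_blocks, 2L)
  expect_equal(as.integer(table(des$tasks$block)), c(24L, 24L))
  # exact level balance in every arm view: 4-level attributes appear 12 times
  # across the 48 slots, 2-level 24 times
  expect_equal(level_balance <- mctchoice:::level_balance_deviation(des, c("full", "ppv", "npv")), 0)
  tab <- table(des$tasks$ppv)
  expect_true(all(tab == 12L))
  # deterministic given the seed
  pri <- read_priors()
  des2 <- generate_design(mct_schema(), pri, 24, 2, seed = 11, n_sweeps = 10,
                          n_prior_draws = 50)
  expect_identical(des$tasks, des2$tasks)
  expect_equal(des$d_error, des2$d_error)
  # no task identical or dominated
  mono <- mctchoice:::canonical_monotone()
  for (t in 1:24) {
    rows <- des$tasks[des$tasks$task_id == t, ]
    expect_false(mctchoice:::task_identical(rows[names(mct_schema())]))
    expect_false(mctchoice:::task_dominated(
      mctchoice:::dominance_scores(rows, mct_schema(), mono)))
  }
  # 14 slots cannot balance a 4-level attribute
  expect_error(generate_design(mct_schema(), pri, n_tasks = 7, n_blocks = 1,
                               seed = 1, n_sweeps = 1),
               "infeasible design.*ppv")
})

test_that("arm views drop exactly the hidden attribute", {
  des <- cached_design()
  expect_identical(split_arm_view(des, "full")$tasks, des$tasks)
  pv <- split_arm_view(des, "ppv")
  expect_true(all(is.na(pv$tasks$npv)))
  expect_false(anyNA(pv$tasks$ppv))
  nv <- split_arm_view(des, "npv")
  expect_true(all(is.na(nv$tasks$ppv)))
  # every profile shows 6 of the 7 attributes in a public arm
  visible <- function(tasks) sum(!vapply(tasks[names(mct_schema())],
                                         function(c) anyNA(c), logical(1)))
  expect_equal(visible(pv$tasks), 6L)
  expect_equal(visible(nv$tasks), 6L)
  expect_equal(visible(des$tasks), 7L)
  expect_error(split_arm_view(des, "both"), "unknown arm")
})

test_that("design round-trips through CSV + JSON", {
  des <- cached_design()
  dir <- tempfile("design")
  write_design(des, dir)
  back <- read_design(dir, mct_schema())
  expect_equal(back$tasks$ppv, des$tasks$ppv)
  expect_equal(back$tasks$form, des$tasks$form)
  expect_equal(back$d_error, des$d_error)
  expect_equal(back$n_blocks, des$n_blocks)
})
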