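#' Define a choice-experiment attribute
#'
#' An attribute is one characteristic of a hypothetical test (e.g. positive
#' predictive value) together with the levels it can take in the experiment.
#'
#' @param name Identifier, unique within a schema.
#' @param levels Ordered vector of level values. Numeric where the level is
#'   meaningfully numeric (PPV in percent, number of cancers as a count),
#'   character otherwise.
#' @param coding `"categorical"` (entered as level-vs-reference dummies) or
#'   `"continuous"` (entered as a single numeric term).
#' @param reference Reference level (categorical attributes only); must be a
#'   member of `levels`.
#' @param arm_visibility `"all"` if every respondent sees the attribute,
#'   `"ppv_arm"`/`"npv_arm"` if only the corresponding public arm sees it.
#' @param wording Optional named list of audience-specific display labels
#'   (metadata only; never used in computation).
#'
#' @return An object of class `dce_attribute`.
#' @export
attribute <- function(name, levels, coding = c("categorical", "continuous"),
                      reference = NULL, arm_visibility = c("all", "ppv_arm", "npv_arm"),
                      wording = NULL) {
  coding <- match.arg(coding)
  arm_visibility <- match.arg(arm_visibility)
  if (length(levels) < 2L) stop("attribute '", name, "' needs at least 2 levels")
  if (anyDuplicated(levels)) stop("attribute '", name, "' has duplicate levels")
  if (coding == "continuous" && !is.numeric(levels))
    stop("continuous attribute '", name, "' must have numeric levels")
  if (coding == "categorical") {
    if (is.null(reference)) reference <- levels[length(levels)]
    if (!reference %in% levels)
      stop("reference level of '", name, "' is not one of its levels")
  } else {
    reference <- NULL
  }
  structure(list(name = name, coding = coding, levels = levels,
                 reference = reference, arm_visibility = arm_visibility,
                 wording = wording),
            class = "dce_attribute")
}

#' Assemble an attribute schema
#'
#' @param ... `dce_attribute` objects (or a single list of them).
#' @return An object of class `dce_schema`: an ordered list of attributes.
#' @export
attribute_schema <- function(...) {
  attrs <- list(...)
  if (length(attrs) == 1L && !inherits(attrs[[1L]], "dce_attribute")) attrs <- attrs[[1L]]
  if (length(attrs) == 0L) stop("invalid schema: no attributes")
  if (!all(vapply(attrs, inherits, logical(1), "dce_attribute")))
    stop("all schema elements must be dce_attribute objects")
  nms <- vapply(attrs, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("attribute names must be unique")
  for (arm in c("ppv_arm", "npv_arm")) {
    n_arm <- sum(vapply(attrs, function(a) a$arm_visibility == arm, logical(1)))
    if (n_arm > 1L) stop("at most one attribute may have arm_visibility = '", arm, "'")
  }
  names(attrs) <- nms
  structure(attrs, class = "dce_schema")
}

#' @export
print.dce_schema <- function(x, ...) {
  cat("Choice-experiment schema:", length(x), "attributes,",
      prod(schema_level_counts(x)), "profiles\n")
  for (a in x) {
    cat(sprintf("  %-10s [%s%s] %s\n", a$name, a$coding,
                if (a$arm_visibility != "all") paste0(", ", a$arm_visibility) else "",
                paste(a$levels, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname attribute_schema
#' @param x Object to test.
#' @export
is_dce_schema <- function(x) inherits(x, "dce_schema")

schema_level_counts <- function(schema) {
  vapply(schema, function(a) length(a$levels), integer(1))
}

#' The canonical multi-cancer-test schema
#'
#' Seven attributes describing a hypothetical multi-cancer test (MCT):
#' positive predictive value (20/40/60/80%, reference 80), negative predictive
#' value (96/99/99.5/99.9%, reference 99.9; presented to GPs as risk of cancer
#' after a negative test, 4/1/0.5/0.1%), waiting time for results (1 week vs
#' 1-2 weeks), number of cancers tested for (1/5/10/25, continuous, entered
#' per 10 cancers at estimation), whether the test identifies the cancer site,
#' the form of the test (blood/faecal/urine/breath) and whether it detects
#' cancer at an early stage. PPV is visible only to the public PPV arm and NPV
#' only to the NPV arm; GPs see all seven. Level counts (4,4,2,4,2,4,2) give
#' 2048 distinct profiles.
#'
#' @return A `dce_schema`.
#' @export
mct_schema <- function() {
  attribute_schema(
    attribute("ppv", c(20, 40, 60, 80), "categorical", reference = 80,
              arm_visibility = "ppv_arm",
              wording = list(gp = "Risk of cancer after a positive test",
                             public = "Test gets it wrong when it tells us there is a cancer")),
    attribute("npv", c(96, 99, 99.5, 99.9), "categorical", reference = 99.9,
              arm_visibility = "npv_arm",
              wording = list(gp = "Risk of cancer after a negative test",
                             public = "Test gets it wrong when it tells us there is not a cancer")),
    attribute("wait", c("1wk", "1-2wk"), "categorical", reference = "1wk",
              wording = list(gp = "Waiting time for test results",
                             public = "Waiting time for test results")),
    attribute("cancers", c(1, 5, 10, 25), "continuous",
              wording = list(gp = "Number of cancer sites tested",
                             public = "Number of cancers tested for")),
    attribute("site", c("yes", "no"), "categorical", reference = "no",
              wording = list(gp = "Can the test identify the site?",
                             public = "Test detects type of cancer?")),
    attribute("form", c("blood", "faecal", "urine", "breath"), "categorical",
              reference = "blood",
              wording = list(gp = "Form of the test", public = "Form of the test")),
    attribute("early", c("yes", "no"), "categorical", reference = "no",
              wording = list(gp = "Can the test detect the stage of cancer?",
                             public = "Test can detect cancer at an early stage?"))
  )
}

#' Enumerate every profile in a schema
#'
#' Returns the full Cartesian product of attribute levels, one row per
#' profile, in lexicographic order of the schema's attribute ordering with the
#' last attribute varying fastest.
#'
#' @param schema A `dce_schema`.
#' @return A data frame with one column per attribute and
#'   `prod(level counts)` rows.
#' @export
enumerate_profiles <- function(schema) {
  if (!is_dce_schema(schema) || length(schema) == 0L) stop("invalid schema")
  counts <- schema_level_counts(schema)
  n <- prod(counts)
  out <- vector("list", length(schema))
  rep_inner <- n  # times each level repeats: lexicographic, last varies fastest
  for (i in seq_along(schema)) {
    rep_inner <- rep_inner / counts[i]
    out[[i]] <- rep(schema[[i]]$levels,
                    each = rep_inner, times = n / (rep_inner * counts[i]))
  }
  names(out) <- names(schema)
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read / write a schema as YAML
#'
#' @param path File path.
#' @return `read_schema` returns a `dce_schema`; `write_schema` returns
#'   `path` invisibly.
#' @export
read_schema <- function(path) {
  spec <- yaml::read_yaml(path)
  attribute_schema(lapply(spec$attributes, function(a) {
    lv <- unlist(a$levels)
    if (!is.null(a$numeric) && isTRUE(a$numeric)) lv <- as.numeric(lv)
    attribute(a$name, lv, a$coding,
              reference = if (is.null(a$reference)) NULL else
                if (is.numeric(lv)) as.numeric(a$reference) else a$reference,
              arm_visibility = if (is.null(a$arm_visibility)) "all" else a$arm_visibility,
              wording = a$wording)
  }))
}

#' @rdname read_schema
#' @param schema A `dce_schema`.
#' @export
write_schema <- function(schema, path) {
  yaml::write_yaml(list(attributes = lapply(schema, function(a) {
    list(name = a$name, coding = a$coding, numeric = is.numeric(a$levels),
         levels = as.list(a$levels),
         reference = a$reference,
         arm_visibility = a$arm_visibility, wording = a$wording)
  })), path)
  invisible(path)
}

# Name of the attribute hidden from a given arm ("full" hides nothing;
# the ppv arm never sees the npv attribute and vice versa).
hidden_attribute <- function(schema, arm) {
  vis <- vapply(schema, `[[`, character(1), "arm_visibility")
  switch(arm,
         full = character(0),
         ppv  = names(schema)[vis == "npv_arm"],
         npv  = names(schema)[vis == "ppv_arm"],
         stop("unknown arm '", arm, "'"))
}
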