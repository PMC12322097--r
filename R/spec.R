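#' Specify the systematic utility of a choice model
#'
#' Describes how attribute levels enter utility (dummy coding against the
#' schema's reference levels, continuous terms with a divisor), which terms
#' carry normally distributed random coefficients, which are interacted with
#' the public-sample dummy or with respondent covariates, which are shifted by
#' the latent cancer-knowledge variable, and how data-source scale parameters
#' are attached to respondent groups.
#'
#' @param schema A `dce_schema`.
#' @param random Character vector of encoded main-effect column names whose
#'   coefficients are random (normal, one draw per respondent, common across
#'   that respondent's tasks).
#' @param sample_interactions Encoded main-effect columns interacted with the
#'   public-sample dummy (additive coefficient shifts for the public).
#' @param covariate_interactions Named list: covariate name -> character
#'   vector of encoded main-effect columns it shifts.
#' @param latent_terms Encoded main-effect columns shifted by the latent
#'   variable (ICLV models only).
#' @param scale Scale-parameter structure. `"gp_public_arm"`: GP utilities are
#'   the reference (scale 1), public utilities carry `lambda_pub`, and the
#'   public NPV arm additionally carries `lambda_arm` (so its scale is
#'   `lambda_pub * lambda_arm`). `"arm_only"`: for public-only data, the PPV
#'   arm is the reference and the NPV arm carries `lambda_arm`. `"none"`: no
#'   scale parameters.
#' @param weights If `TRUE`, respondents are weighted `0.5 * N_total /
#'   N_group` so the GP and public samples contribute equally to the
#'   likelihood regardless of their sizes.
#' @param divisors Named numeric vector of divisors for continuous attributes
#'   (default: number of cancers entered per 10 cancers).
#'
#' @return An object of class `utility_spec`.
#' @export
utility_spec <- function(schema, random = character(),
                         sample_interactions = character(),
                         covariate_interactions = list(),
                         latent_terms = character(),
                         scale = c("gp_public_arm", "arm_only", "none"),
                         weights = TRUE,
                         divisors = c(cancers = 10)) {
  scale <- match.arg(scale)
  cols <- main_effect_columns(schema, divisors)
  for (v in list(random, sample_interactions, latent_terms, unlist(covariate_interactions))) {
    bad <- setdiff(v, cols)
    if (length(bad)) stop("unknown utility term(s): ", paste(bad, collapse = ", "))
  }
  structure(list(schema = schema, random = random,
                 sample_interactions = sample_interactions,
                 covariate_interactions = covariate_interactions,
                 latent_terms = latent_terms, scale = scale,
                 weights = weights, divisors = divisors),
            class = "utility_spec")
}

#' Canonical pooled-model specification
#'
#' The pooled GP + public mixed logit: PPV and NPV level coefficients random;
#' public-sample interactions on the NPV, number-of-cancers, site, early-stage
#' and form terms (PPV and waiting-time terms are shared across samples, which
#' identifies the GP-vs-public scale parameter); GP scale fixed at 1, public
#' scale `lambda_pub`, NPV-arm scale `lambda_pub * lambda_arm`; group-balancing
#' weights on.
#'
#' @param schema A `dce_schema`, by default the canonical MCT schema.
#' @param random,sample_interactions Override the defaults described above.
#' @return A `utility_spec`.
#' @export
canonical_pooled_spec <- function(schema = mct_schema(),
                                  random = c("ppv_20", "ppv_40", "ppv_60",
                                             "npv_96", "npv_99", "npv_99.5"),
                                  sample_interactions = c("npv_96", "npv_99", "npv_99.5",
                                                          "cancers_per10", "site_yes",
                                                          "early_yes", "form_faecal",
                                                          "form_urine", "form_breath")) {
  utility_spec(schema, random = random,
               sample_interactions = sample_interactions,
               scale = "gp_public_arm", weights = TRUE)
}

#' @export
print.utility_spec <- function(x, ...) {
  cols <- main_effect_columns(x$schema, x$divisors)
  cat("Utility specification:", length(cols), "main-effect terms\n")
  if (length(x$random)) cat("  random coefficients:", paste(x$random, collapse = ", "), "\n")
  if (length(x$sample_interactions))
    cat("  sample interactions:", paste(x$sample_interactions, collapse = ", "), "\n")
  if (length(x$covariate_interactions))
    cat("  covariate interactions:", length(unlist(x$covariate_interactions)), "terms\n")
  if (length(x$latent_terms))
    cat("  latent-variable terms:", paste(x$latent_terms, collapse = ", "), "\n")
  cat("  scale structure:", x$scale, "| group weights:", x$weights, "\n")
  invisible(x)
}

# Canonical encoded column names for the main effects: dummy columns
# "<attr>_<level>" for each non-reference level (level order), and
# "<attr>_per<divisor>" for continuous attributes.
main_effect_columns <- function(schema, divisors = c(cancers = 10)) {
  unlist(lapply(schema, function(a) {
    if (a$coding == "continuous") {
      d <- if (a$name %in% names(divisors)) divisors[[a$name]] else 1
      paste0(a$name, if (d != 1) paste0("_per", d) else "")
    } else {
      lv <- setdiff(a$levels, a$reference)
      paste0(a$name, "_", sanitize_level(lv))
    }
  }), use.names = FALSE)
}

sanitize_level <- function(x) gsub("[^0-9A-Za-z.]", "_", as.character(x))

#' Dummy-code a table of profiles
#'
#' Encodes attribute levels into the canonical main-effect columns: for each
#' categorical attribute one indicator per non-reference level, and each
#' continuous attribute divided by its divisor. `NA` levels (attributes hidden
#' from a respondent's arm) encode as zero in every column of that attribute;
#' the arm-specific likelihood drops their contribution because both
#' alternatives encode identically.
#'
#' @param profiles Data frame with one column per schema attribute.
#' @param schema A `dce_schema`.
#' @param divisors Continuous-attribute divisors (see [utility_spec()]).
#' @param off_grid If `TRUE`, numeric levels between grid points are allowed
#'   (prediction only; see [profile_utility()] for interpolation). If `FALSE`
#'   an unknown level raises an error naming the offending row.
#' @return Numeric matrix, `nrow(profiles)` x number of main-effect columns.
#' @export
encode_profiles <- function(profiles, schema, divisors = c(cancers = 10),
                            off_grid = FALSE) {
  cols <- main_effect_columns(schema, divisors)
  X <- matrix(0, nrow(profiles), length(cols), dimnames = list(NULL, cols))
  for (a in schema) {
    v <- profiles[[a$name]]
    if (is.null(v)) stop("profiles lack attribute '", a$name, "'")
    if (a$coding == "continuous") {
      d <- if (a$name %in% names(divisors)) divisors[[a$name]] else 1
      cn <- paste0(a$name, if (d != 1) paste0("_per", d) else "")
      X[, cn] <- ifelse(is.na(v), 0, as.numeric(v) / d)
    } else {
      if (!off_grid) {
        ok <- is.na(v) | v %in% a$levels
        if (!all(ok))
          stop("row ", which(!ok)[1L], ": level '", v[which(!ok)[1L]],
               "' is not a level of attribute '", a$name, "'")
      }
      for (lv in setdiff(a$levels, a$reference)) {
        cn <- paste0(a$name, "_", sanitize_level(lv))
        X[, cn] <- as.numeric(!is.na(v) & v == lv)
      }
    }
  }
  X
}
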