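# Seeded synthetic survey generator.
#
# Mechanism: each informant independently cites species s with probability
# p_s (the citation probability). Conditional on citing, the informant
# mentions category u independently with probability w_su (the category
# weight); every species has at least one anchor category with w_su = 1, so
# a citing informant always contributes >= 1 use report. This is the
# simplest mechanism that reproduces the empirical pattern that every
# species has one category with fidelity level 100.
#
# Closed-form expectations under this model:
#   E[FC_s]  = N * p_s
#   E[UR_s]  = N * p_s * sum_u w_su
#   E[Nur_u] = N * sum_s p_s * w_su
# with E[CI] and E[RFC] scaling by 1/N, and NU attained almost surely at
# large N as #{u : w_su > 0}.

#' Parameters for the synthetic survey generator
#'
#' @param n_informants Number of respondents N (positive integer).
#' @param categories Character vector of use-category labels (the design).
#' @param citation_prob Named numeric vector, one probability in (0, 1\] per
#'   species: the chance an informant cites the species at all.
#' @param category_weights Numeric matrix, species x categories (dimnames
#'   must match `names(citation_prob)` and `categories`), entries in
#'   \[0, 1\]: conditional probability that a citing informant mentions the
#'   category. Every row must contain at least one weight equal to 1 (the
#'   anchor category).
#' @param seed Integer seed for the pseudorandom stream.
#' @return An object of class `survey_params`.
#' @export
survey_params <- function(n_informants, categories, citation_prob,
                          category_weights, seed = 1L) {
  design <- study_design(n_informants, categories)
  if (is.null(names(citation_prob)) || any(!nzchar(names(citation_prob)))) {
    rlang::abort("`citation_prob` must be named by species.",
                 class = "ethnosurvey_parameter_error")
  }
  names(citation_prob) <- normalize_label(names(citation_prob))
  if (any(citation_prob <= 0) || any(citation_prob > 1)) {
    rlang::abort("`citation_prob` entries must lie in (0, 1].",
                 class = "ethnosurvey_parameter_error")
  }
  category_weights <- as.matrix(category_weights)
  rownames(category_weights) <- normalize_label(rownames(category_weights))
  colnames(category_weights) <- normalize_label(colnames(category_weights))
  if (!identical(dim(category_weights),
                 c(length(citation_prob), length(design$categories)))) {
    rlang::abort("`category_weights` must be species x categories.",
                 class = "ethnosurvey_parameter_error")
  }
  if (!identical(rownames(category_weights), names(citation_prob)) ||
      !identical(colnames(category_weights), design$categories)) {
    rlang::abort("`category_weights` dimnames must match species/categories.",
                 class = "ethnosurvey_parameter_error")
  }
  if (any(category_weights < 0) || any(category_weights > 1)) {
    rlang::abort("`category_weights` entries must lie in [0, 1].",
                 class = "ethnosurvey_parameter_error")
  }
  if (any(apply(category_weights, 1L, max) < 1)) {
    rlang::abort("Every species needs an anchor category with weight 1.",
                 class = "ethnosurvey_parameter_error")
  }
  structure(list(design = design, citation_prob = citation_prob,
                 category_weights = category_weights,
                 seed = as.integer(seed)),
            class = "survey_params")
}

#' @export
print.survey_params <- function(x, ...) {
  cat("<survey_params> N =", x$design$n_informants, "informants,",
      length(x$citation_prob), "species,",
      length(x$design$categories), "categories, seed =", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic use-report table
#'
#' Fully reproducible for a given `params$seed`: the pseudorandom stream is
#' consumed in a fixed order (citation draws informant-major species-minor,
#' then category draws informant-major, species-minor, category-innermost),
#' so the same seed yields a byte-identical serialized table.
#'
#' @param params A [survey_params()] object.
#' @return A [use_report_table()] whose design is `params$design`.
#' @export
generate_survey <- function(params) {
  stopifnot(inherits(params, "survey_params"))
  n  <- params$design$n_informants
  sp <- names(params$citation_prob)
  cats <- params$design$categories
  s <- length(sp)
  k <- length(cats)

  set.seed(params$seed)
  # draws 1..n*s: (informant 1, species 1), (informant 1, species 2), ...
  u_cite <- matrix(stats::runif(n * s), nrow = n, ncol = s, byrow = TRUE)
  # draws in (informant, species, category) nesting, category innermost
  u_cat <- aperm(array(stats::runif(n * s * k), dim = c(k, s, n)), c(3L, 2L, 1L))

  cited <- u_cite <= matrix(params$citation_prob, nrow = n, ncol = s,
                            byrow = TRUE)
  w <- array(rep(params$category_weights, each = n), dim = c(n, s, k))
  mention <- (w >= 1) | (u_cat <= w & w > 0)
  mention <- mention & array(cited, dim = c(n, s, k))

  idx <- which(mention, arr.ind = TRUE)
  digits <- max(3L, nchar(as.character(n)))
  records <- tibble::tibble(
    informant    = sprintf("inf%0*d", digits, idx[, 1L]),
    species      = sp[idx[, 2L]],
    use_category = cats[idx[, 3L]])
  use_report_table(records, design = params$design)
}

#' Closed-form expected indices under the generator model
#'
#' @param params A [survey_params()] object.
#' @return List of two tibbles: `species` with columns `species`, `e_ur`,
#'   `e_fc`, `nu`, `e_ci`, `e_rfc` (expectations; `nu` is the almost-sure
#'   large-N value `#{u : w_su > 0}`), and `categories` with `use_category`,
#'   `e_nur`.
#' @export
expected_indices <- function(params) {
  stopifnot(inherits(params, "survey_params"))
  n <- params$design$n_informants
  p <- params$citation_prob
  w <- params$category_weights
  e_fc <- n * p
  e_ur <- n * p * rowSums(w)
  species <- tibble::tibble(
    species = names(p),
    e_ur = unname(e_ur),
    e_fc = unname(e_fc),
    nu = unname(rowSums(w > 0)),
    e_ci = unname(e_ur / n),
    e_rfc = unname(p))
  categories <- tibble::tibble(
    use_category = params$design$categories,
    e_nur = unname(n * colSums(p * w)))
  list(species = species, categories = categories)
}
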