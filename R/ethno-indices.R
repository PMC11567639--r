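# Per-species ethnobotanical indices.
#
# With N the number of respondents surveyed and NC the number of designed use
# categories, the indices for a species s are:
#
#   UR_s  = number of distinct (informant, category) pairs citing s
#   FC_s  = number of distinct informants citing s for any use
#   NU_s  = number of distinct categories in which s is cited
#   CI_s  = UR_s / N          (cultural importance; > 1 possible)
#   RFC_s = FC_s / N          (relative frequency of citation; <= 1)
#   RI_s  = ((RFC_s / max RFC) + (NU_s / max NU)) / 2, maxima over the table
#   CVe_s = (NU_s / NC) * RFC_s * CI_s   (cultural value)
#
# All arithmetic is kept at full precision; rounding is presentation-only
# (see render_table()).

assert_known_species <- function(x, species) {
  stopifnot(inherits(x, "use_report_table"))
  species <- normalize_label(species)
  if (!species %in% x$records$species) {
    rlang::abort(paste0("Species '", species, "' not present in the table."),
                 class = "ethnosurvey_lookup_error")
  }
  species
}

#' Per-species count operations
#'
#' `use_report_count()` gives UR: the number of use reports for a species,
#' i.e. the count of distinct informants per use category, summed over
#' categories. `frequency_of_citation()` gives FC: the number of distinct
#' informants citing the species for any use (an informant citing several
#' categories counts once). `number_of_uses()` gives NU: the number of
#' distinct use categories in which the species is cited.
#'
#' @param x A [use_report_table()].
#' @param species Species identifier (normalized before lookup).
#' @return An integer count.
#' @name species_counts
NULL

#' @rdname species_counts
#' @export
use_report_count <- function(x, species) {
  species <- assert_known_species(x, species)
  sum(x$records$species == species)
}

#' @rdname species_counts
#' @export
frequency_of_citation <- function(x, species) {
  species <- assert_known_species(x, species)
  dplyr::n_distinct(x$records$informant[x$records$species == species])
}

#' @rdname species_counts
#' @export
number_of_uses <- function(x, species) {
  species <- assert_known_species(x, species)
  dplyr::n_distinct(x$records$use_category[x$records$species == species])
}

#' Cultural importance index
#'
#' CI = UR / N: total use reports for the species divided by the number of
#' respondents surveyed. Exceeds 1 for species cited by many informants in
#' several categories. Vectorized over `ur`.
#'
#' @param ur Use-report count(s), non-negative.
#' @param n Total respondents surveyed (N), positive.
#' @return Numeric, full precision.
#' @export
cultural_importance <- function(ur, n) {
  if (any(n < 1)) {
    rlang::abort("`n` (respondents surveyed) must be >= 1.",
                 class = "ethnosurvey_domain_error")
  }
  if (any(ur < 0)) {
    rlang::abort("`ur` must be non-negative.",
                 class = "ethnosurvey_domain_error")
  }
  ur / n
}

#' Relative frequency of citation
#'
#' RFC = FC / N, in \[0, 1\]. Vectorized over `fc`.
#'
#' @param fc Citation count(s), 0 <= fc <= n.
#' @param n Total respondents surveyed (N), positive.
#' @return Numeric proportion(s).
#' @export
relative_frequency_of_citation <- function(fc, n) {
  if (any(n < 1)) {
    rlang::abort("`n` (respondents surveyed) must be >= 1.",
                 class = "ethnosurvey_domain_error")
  }
  if (any(fc < 0) || any(fc > n)) {
    rlang::abort("`fc` must satisfy 0 <= fc <= n.",
                 class = "ethnosurvey_consistency_error")
  }
  fc / n
}

#' Relative importance index
#'
#' RI = ((RFC / max RFC) + (NU / max NU)) / 2, where both maxima are taken
#' over all species in the analyzed table (not an external reference list).
#' Equals 1 only for a species attaining both maxima. Vectorized over `rfc`
#' and `nu`.
#'
#' @param rfc Species RFC value(s).
#' @param nu Species NU count(s).
#' @param max_rfc Largest RFC in the table, > 0.
#' @param max_nu Largest NU in the table, >= 1.
#' @return Numeric in (0, 1\].
#' @export
relative_importance <- function(rfc, nu, max_rfc, max_nu) {
  if (max_rfc <= 0 || max_nu < 1) {
    rlang::abort("Table maxima must be positive (empty table?).",
                 class = "ethnosurvey_domain_error")
  }
  if (any(rfc > max_rfc) || any(nu > max_nu)) {
    rlang::abort("`rfc`/`nu` exceed the supplied table maxima.",
                 class = "ethnosurvey_consistency_error")
  }
  ((rfc / max_rfc) + (nu / max_nu)) / 2
}

#' Cultural value index
#'
#' CVe = (NU / NC) * (FC / N) * (UR / N): the fraction of designed use
#' categories the species occupies, times its relative frequency of
#' citation, times its cultural importance. NC is the number of *designed*
#' categories, not the number populated in a particular dataset. Vectorized
#' over `nu`, `fc`, `ur`.
#'
#' @param nu Number-of-uses count(s).
#' @param nc Number of designed use categories (NC), >= 1.
#' @param fc Citation count(s).
#' @param ur Use-report count(s).
#' @param n Total respondents surveyed (N), >= 1.
#' @return Numeric, full precision.
#' @export
cultural_value <- function(nu, nc, fc, ur, n) {
  if (any(nc < 1) || any(n < 1)) {
    rlang::abort("`nc` and `n` must be >= 1.",
                 class = "ethnosurvey_domain_error")
  }
  (nu / nc) * (fc / n) * (ur / n)
}

#' Species index table
#'
#' Computes all per-species indices and assembles the ranked table: one row
#' per species, sorted by UR descending with ties broken by species id
#' ascending. All values are full precision; use [render_table()] for the
#' 3-decimal presentation.
#'
#' @param x A non-empty [use_report_table()].
#' @return Tibble with columns `species`, `ur`, `fc`, `nu`, `ci`, `rfc`,
#'   `ri`, `cve` (plus any `species_meta` columns, joined by species).
#' @export
species_index_table <- function(x) {
  stopifnot(inherits(x, "use_report_table"))
  if (nrow(x$records) == 0L) {
    rlang::abort("The use-report table is empty.",
                 class = "ethnosurvey_empty_input_error")
  }
  n  <- x$design$n_informants
  nc <- length(x$design$categories)

  tab <- dplyr::summarise(
    dplyr::group_by(x$records, .data$species),
    ur = dplyr::n(),
    fc = dplyr::n_distinct(.data$informant),
    nu = dplyr::n_distinct(.data$use_category),
    .groups = "drop")

  tab$ci  <- cultural_importance(tab$ur, n)
  tab$rfc <- relative_frequency_of_citation(tab$fc, n)
  tab$ri  <- relative_importance(tab$rfc, tab$nu,
                                 max_rfc = max(tab$rfc), max_nu = max(tab$nu))
  tab$cve <- cultural_value(tab$nu, nc, tab$fc, tab$ur, n)

  tab <- dplyr::arrange(tab, dplyr::desc(.data$ur), .data$species)
  if (!is.null(x$species_meta)) {
    tab <- dplyr::left_join(tab, x$species_meta, by = "species")
  }
  tab
}
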