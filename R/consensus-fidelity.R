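# Consensus and fidelity statistics.
#
# IAR (Trotter-Logan informant agreement ratio) summarizes, for one use
# category, how concentrated the Nur use reports are on few species:
#   IAR = (Nur - Ns) / (Nur - 1)
# 1 = every report names the same species, 0 = every report names a
# different species. Undefined for Nur <= 1 (reported as NA with a warning).
#
# FL (fidelity level) identifies a species' preferred purpose:
#   FL_su = 100 * UR_su / FC_s
# where UR_su counts informants citing species s for category u and FC_s
# counts informants citing s for any use. The denominator is FC, not UR, so
# a species' FL values across categories sum to 100 * UR_s / FC_s, which
# exceeds 100 for multi-use species.

#' Informant agreement ratio
#'
#' @param nur Total use reports for the category, non-negative. Vectorized.
#' @param ns Number of distinct species cited for the category, `0 <= ns <=
#'   nur`.
#' @return `(nur - ns) / (nur - 1)` where `nur >= 2`; `NA` (with a warning)
#'   where `nur <= 1`, since agreement among fewer than two reports is
#'   undefined.
#' @examples
#' informant_agreement_ratio(339, 2) # wall laths: 0.997...
#' @export
informant_agreement_ratio <- function(nur, ns) {
  if (any(ns > nur)) {
    rlang::abort("`ns` cannot exceed `nur`.",
                 class = "ethnosurvey_consistency_error")
  }
  if (any(ns < 0) || any(nur < 0)) {
    rlang::abort("`nur` and `ns` must be non-negative.",
                 class = "ethnosurvey_domain_error")
  }
  out <- rep(NA_real_, length(nur))
  ok <- nur >= 2
  out[ok] <- (nur[ok] - ns[ok]) / (nur[ok] - 1)
  if (any(!ok)) {
    rlang::warn(paste0("IAR undefined for ", sum(!ok),
                       " categor(y/ies) with fewer than 2 use reports; ",
                       "reported as NA."))
  }
  out
}

#' Per-category consensus table
#'
#' One row per *designed* use category, in design order; designed categories
#' without records carry `nur = 0`, `ns = 0` and an undefined (`NA`) IAR.
#' The helper columns `nur_minus_ns` and `nur_minus_1` mirror the
#' conventional presentation of the ratio.
#'
#' @param x A non-empty [use_report_table()].
#' @return Tibble with columns `use_category`, `nur`, `ns`, `nur_minus_ns`,
#'   `nur_minus_1`, `iar`. `sum(nur)` equals the total record count.
#' @export
consensus_table <- function(x) {
  stopifnot(inherits(x, "use_report_table"))
  if (nrow(x$records) == 0L) {
    rlang::abort("The use-report table is empty.",
                 class = "ethnosurvey_empty_input_error")
  }
  counts <- dplyr::summarise(
    dplyr::group_by(x$records, .data$use_category),
    nur = dplyr::n(),
    ns = dplyr::n_distinct(.data$species),
    .groups = "drop")
  tab <- dplyr::left_join(
    tibble::tibble(use_category = x$design$categories), counts,
    by = "use_category")
  tab$nur <- ifelse(is.na(tab$nur), 0L, tab$nur)
  tab$ns  <- ifelse(is.na(tab$ns), 0L, tab$ns)
  tab$nur_minus_ns <- tab$nur - tab$ns
  tab$nur_minus_1  <- tab$nur - 1L
  tab$iar <- informant_agreement_ratio(tab$nur, tab$ns)
  tab
}

#' Fidelity level
#'
#' @param ur_su Informants citing the species for the focal category,
#'   `0 <= ur_su <= fc_s`. Vectorized.
#' @param fc_s Informants citing the species for any use, >= 1.
#' @return Percentage `100 * ur_su / fc_s`, full precision (render at 2
#'   decimals for reporting).
#' @examples
#' fidelity_level(73, 103) # 70.87...
#' @export
fidelity_level <- function(ur_su, fc_s) {
  if (any(fc_s < 1)) {
    rlang::abort("`fc_s` must be >= 1.", class = "ethnosurvey_domain_error")
  }
  if (any(ur_su < 0) || any(ur_su > fc_s)) {
    rlang::abort("`ur_su` must satisfy 0 <= ur_su <= fc_s.",
                 class = "ethnosurvey_consistency_error")
  }
  100 * ur_su / fc_s
}

#' Species-by-category fidelity table
#'
#' Rows only for (species, category) pairs with at least one use report.
#' Categories appear in design order; within a category rows are sorted by
#' FL descending, species ascending. For each species the FL rows sum to
#' `100 * UR_s / FC_s`.
#'
#' @param x A non-empty [use_report_table()].
#' @return Tibble with columns `use_category`, `species`, `ur_su`,
#'   `fl` (percent, full precision).
#' @export
fidelity_table <- function(x) {
  stopifnot(inherits(x, "use_report_table"))
  if (nrow(x$records) == 0L) {
    rlang::abort("The use-report table is empty.",
                 class = "ethnosurvey_empty_input_error")
  }
  ur_su <- dplyr::summarise(
    dplyr::group_by(x$records, .data$species, .data$use_category),
    ur_su = dplyr::n_distinct(.data$informant),
    .groups = "drop")
  fc <- dplyr::summarise(
    dplyr::group_by(x$records, .data$species),
    fc = dplyr::n_distinct(.data$informant),
    .groups = "drop")
  tab <- dplyr::left_join(ur_su, fc, by = "species")
  tab$fl <- fidelity_level(tab$ur_su, tab$fc)
  tab$use_category <- factor(tab$use_category,
                             levels = x$design$categories)
  tab <- dplyr::arrange(tab, .data$use_category, dplyr::desc(.data$fl),
                        .data$species)
  tibble::tibble(use_category = as.character(tab$use_category),
                 species = tab$species, ur_su = tab$ur_su, fl = tab$fl)
}
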