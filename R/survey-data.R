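# Data model for informant use-report surveys.
#
# The atomic datum is a "use report": one informant citing one plant species
# for one use category. A survey is a set (not multiset) of such triples plus
# the study frame: the total number of respondents N and the designed list of
# use categories (NC of them). N and NC are properties of the survey design,
# not of the records — a respondent may contribute no records and a designed
# category may go uncited, yet both still enter the index denominators.

#' Normalize an identifier label
#'
#' Default normalization for hand-entered survey identifiers: trims leading
#' and trailing whitespace, collapses internal whitespace runs to a single
#' space, and (optionally) case-folds. Species and use-category names are
#' case-folded by default; informant codes are kept case-sensitive because
#' survey informant codes are often case-significant.
#'
#' @param x Character vector of labels.
#' @param casefold Lower-case the result? Default `TRUE`.
#' @return Character vector of normalized labels. Idempotent:
#'   `normalize_label(normalize_label(x)) == normalize_label(x)`.
#' @examples
#' normalize_label(c(" Bambusa  vulgaris ", "bambusa vulgaris"))
#' @export
normalize_label <- function(x, casefold = TRUE) {
  x <- gsub("[[:space:]]+", " ", trimws(as.character(x)))
  if (casefold) x <- tolower(x)
  x
}

#' Define the survey frame
#'
#' The study design fixes the two denominators every relative index uses:
#' `n_informants` (N, the total number of respondents surveyed, whether or
#' not each contributed records) and the ordered set of designed use
#' categories (NC = `length(categories)`). Category labels are normalized
#' with [normalize_label()]; their order is preserved and used for reporting.
#'
#' @param n_informants Positive integer, total respondents surveyed.
#' @param categories Character vector of use-category labels, no duplicates
#'   after normalization.
#' @return An object of class `study_design`.
#' @examples
#' study_design(258, c("main pole", "main beam", "wall lath",
#'                     "roof lath", "binding material", "thatch material"))
#' @export
study_design <- function(n_informants, categories) {
  n_informants <- as.integer(n_informants)
  if (length(n_informants) != 1L || is.na(n_informants) || n_informants < 1L) {
    rlang::abort("`n_informants` must be a single positive integer.",
                 class = "ethnosurvey_domain_error")
  }
  categories <- normalize_label(categories)
  if (length(categories) < 1L) {
    rlang::abort("`categories` must contain at least one use category.",
                 class = "ethnosurvey_domain_error")
  }
  if (anyDuplicated(categories)) {
    rlang::abort("`categories` contains duplicates after normalization.",
                 class = "ethnosurvey_validation_error")
  }
  if (any(!nzchar(categories))) {
    rlang::abort("`categories` contains empty labels after normalization.",
                 class = "ethnosurvey_validation_error")
  }
  structure(list(n_informants = n_informants, categories = categories),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design> N =", x$n_informants, "informants,",
      length(x$categories), "use categories:\n ",
      paste(x$categories, collapse = ", "), "\n")
  invisible(x)
}

#' Build a use-report table
#'
#' Constructs the central container from a data frame with columns
#' `informant`, `species` and `use_category` (one row per mention).
#' Identifiers are normalized, exact duplicate triples are collapsed
#' (set semantics: a use report is a *distinct* informant-species-category
#' triple, so repeated mentions within one interview cannot inflate UR),
#' and rows are stored in sorted order so that the same set of mentions
#' always yields an identical object regardless of input row order.
#'
#' @param records Data frame with character columns `informant`, `species`,
#'   `use_category`.
#' @param design A [study_design()], or `NULL` to derive one from the data
#'   (N = number of distinct informants observed; categories = sorted
#'   distinct categories observed).
#' @param species_meta Optional data frame of per-species passthrough
#'   metadata (must contain a `species` column); carried, never interpreted.
#' @param normalize Apply [normalize_label()] to identifiers? Default `TRUE`.
#' @return An object of class `use_report_table`: a list with elements
#'   `records` (tibble of distinct, sorted triples), `design`, and
#'   `species_meta`.
#' @export
use_report_table <- function(records, design = NULL, species_meta = NULL,
                             normalize = TRUE) {
  records <- tibble::as_tibble(records)
  needed <- c("informant", "species", "use_category")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    rlang::abort(
      paste0("`records` is missing column(s): ",
             paste(missing_cols, collapse = ", ")),
      class = "ethnosurvey_schema_error")
  }
  records <- records[needed]
  if (normalize) {
    records$informant    <- normalize_label(records$informant, casefold = FALSE)
    records$species      <- normalize_label(records$species)
    records$use_category <- normalize_label(records$use_category)
  } else {
    records[] <- lapply(records, as.character)
  }
  bad <- !nzchar(records$informant) | !nzchar(records$species) |
    !nzchar(records$use_category)
  if (any(bad)) {
    rlang::abort(
      paste0(sum(bad), " record(s) have empty identifiers after ",
             "normalization (rows ",
             paste(utils::head(which(bad), 5L), collapse = ", "), " ...)"),
      class = "ethnosurvey_validation_error")
  }
  records <- dplyr::distinct(records)
  records <- dplyr::arrange(records, .data$informant, .data$species,
                            .data$use_category)

  if (is.null(design)) {
    design <- study_design(
      n_informants = max(1L, dplyr::n_distinct(records$informant)),
      categories   = sort(unique(records$use_category)))
  } else {
    if (!inherits(design, "study_design")) {
      rlang::abort("`design` must be a study_design object.",
                   class = "ethnosurvey_domain_error")
    }
    stray <- setdiff(unique(records$use_category), design$categories)
    if (length(stray) > 0L) {
      rlang::abort(
        paste0("Categories in records absent from the supplied design: ",
               paste(stray, collapse = ", ")),
        class = "ethnosurvey_validation_error")
    }
    n_obs <- dplyr::n_distinct(records$informant)
    if (design$n_informants < n_obs) {
      rlang::abort(
        paste0("Design declares N = ", design$n_informants, " informants but ",
               n_obs, " distinct informant ids appear in the records."),
        class = "ethnosurvey_validation_error")
    }
  }

  if (!is.null(species_meta)) {
    species_meta <- tibble::as_tibble(species_meta)
    if (!"species" %in% names(species_meta)) {
      rlang::abort("`species_meta` must contain a `species` column.",
                   class = "ethnosurvey_schema_error")
    }
  }

  structure(list(records = records, design = design,
                 species_meta = species_meta),
            class = "use_report_table")
}

#' @export
print.use_report_table <- function(x, ...) {
  cat("<use_report_table>\n",
      " ", nrow(x$records), "use reports |",
      dplyr::n_distinct(x$records$species), "species |",
      dplyr::n_distinct(x$records$informant), "informants observed",
      "(N =", x$design$n_informants, "surveyed) |",
      length(x$design$categories), "designed categories\n")
  invisible(x)
}

#' @rdname use_report_table
#' @param x A `use_report_table`.
#' @export
n_use_reports <- function(x) {
  stopifnot(inherits(x, "use_report_table"))
  nrow(x$records)
}

#' @rdname use_report_table
#' @export
survey_species <- function(x) {
  stopifnot(inherits(x, "use_report_table"))
  sort(unique(x$records$species))
}

#' Read a use-report table from a delimited text file
#'
#' @param file Path to a delimited text file with a header row.
#' @param informant_col,species_col,category_col Names of the columns holding
#'   the informant, species and use-category identifiers. Defaults
#'   `informant`, `species`, `use_category`.
#' @param design Optional [study_design()]; if absent, derived from the data.
#' @param delim Field delimiter, default `","`.
#' @inheritParams use_report_table
#' @return A [use_report_table()].
#' @export
read_use_reports <- function(file,
                             informant_col = "informant",
                             species_col = "species",
                             category_col = "use_category",
                             design = NULL, delim = ",", normalize = TRUE) {
  raw <- tryCatch(
    readr::read_delim(file, delim = delim, show_col_types = FALSE,
                      progress = FALSE,
                      col_types = readr::cols(.default = readr::col_character())),
    error = function(e) {
      rlang::abort(paste0("Could not read '", file, "': ", conditionMessage(e)),
                   class = "ethnosurvey_empty_input_error")
    })
  if (nrow(raw) == 0L) {
    rlang::abort(paste0("Input file '", file, "' contains no records."),
                 class = "ethnosurvey_empty_input_error")
  }
  wanted <- c(informant = informant_col, species = species_col,
              use_category = category_col)
  missing_cols <- wanted[!wanted %in% names(raw)]
  if (length(missing_cols) > 0L) {
    rlang::abort(
      paste0("Mapped column(s) not found in '", file, "': ",
             paste(missing_cols, collapse = ", ")),
      class = "ethnosurvey_schema_error")
  }
  records <- tibble::tibble(informant    = raw[[informant_col]],
                            species      = raw[[species_col]],
                            use_category = raw[[category_col]])
  use_report_table(records, design = design, normalize = normalize)
}

#' Write the canonical deduplicated CSV form of a use-report table
#'
#' Columns `informant,species,use_category`, rows sorted lexicographically.
#' Reading the output back with [read_use_reports()] reproduces the table
#' exactly (round-trip identity).
#'
#' @param x A [use_report_table()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_use_reports <- function(x, file) {
  stopifnot(inherits(x, "use_report_table"))
  readr::write_csv(x$records, file, progress = FALSE)
  invisible(file)
}

#' Diagnose a use-report table
#'
#' Reporting-only checks; never errors and never mutates the table.
#' Findings: informants in the design contributing no records, species cited
#' by a single informant, and designed categories with no records.
#'
#' @param x A [use_report_table()].
#' @return Tibble with columns `check`, `item`, `message`; zero rows when
#'   there is nothing to report.
#' @export
validate_use_reports <- function(x) {
  stopifnot(inherits(x, "use_report_table"))
  out <- list()

  n_obs <- dplyr::n_distinct(x$records$informant)
  n_silent <- x$design$n_informants - n_obs
  if (n_silent > 0L) {
    out[[length(out) + 1L]] <- tibble::tibble(
      check = "informants_without_records", item = NA_character_,
      message = paste(n_silent, "informants contribute no records"))
  }

  fc <- dplyr::summarise(dplyr::group_by(x$records, .data$species),
                         fc = dplyr::n_distinct(.data$informant))
  singles <- fc$species[fc$fc == 1L]
  if (length(singles) > 0L) {
    out[[length(out) + 1L]] <- tibble::tibble(
      check = "single_informant_species", item = singles,
      message = paste0("species '", singles, "' cited by a single informant"))
  }

  empty <- setdiff(x$design$categories, unique(x$records$use_category))
  if (length(empty) > 0L) {
    out[[length(out) + 1L]] <- tibble::tibble(
      check = "empty_category", item = empty,
      message = paste0("designed category '", empty, "' has no records"))
  }

  if (length(out) == 0L) {
    tibble::tibble(check = character(), item = character(),
                   message = character())
  } else {
    dplyr::bind_rows(out)
  }
}
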