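# Report rendering and the end-to-end pipeline.
#
# Rounding is presentation-only and half-even, matching the conventional
# printing of these indices: 3 decimals for CI/RFC/RI/CVe, 2 for FL. All
# upstream arithmetic stays at full precision.

format_numeric_column <- function(x, digits) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (all(abs(x[ok] - round(x[ok])) < 1e-9)) {
    out[ok] <- format(round(x[ok]), scientific = FALSE, trim = TRUE)
  } else {
    out[ok] <- sprintf("%.*f", digits, round(x[ok], digits))
  }
  out
}

#' Render a report table as text
#'
#' Numeric columns whose values are all whole numbers are printed as
#' integers; other numeric columns are printed at `digits` decimals with
#' half-even rounding applied at render time only. CSV output is
#' RFC-4180-quoted; markdown output is a pipe table with a header row.
#'
#' @param rows Data frame of homogeneous report rows.
#' @param format `"csv"` or `"markdown"`.
#' @param digits Decimals for non-integer numeric columns (default 3).
#' @return A single string (with trailing newline).
#' @examples
#' render_table(data.frame(species = "x", ci = 1.70542), "csv", 3)
#' @export
render_table <- function(rows, format = c("csv", "markdown"), digits = 3) {
  format <- match.arg(format)
  if (digits < 0) {
    rlang::abort("`digits` must be >= 0.",
                 class = "ethnosurvey_parameter_error")
  }
  rows <- tibble::as_tibble(rows)
  chr <- rows
  for (j in seq_along(chr)) {
    if (is.numeric(chr[[j]])) {
      chr[[j]] <- format_numeric_column(chr[[j]], digits)
    } else {
      chr[[j]] <- as.character(chr[[j]])
    }
  }
  if (format == "csv") {
    readr::format_csv(chr, na = "NA")
  } else {
    cells <- as.matrix(chr)
    cells[is.na(cells)] <- "NA"
    header <- paste0("| ", paste(names(chr), collapse = " | "), " |")
    rule <- paste0("|", paste(rep(" --- |", ncol(chr)), collapse = ""))
    body <- apply(cells, 1L, function(r)
      paste0("| ", paste(r, collapse = " | "), " |"))
    paste0(paste(c(header, rule, body), collapse = "\n"), "\n")
  }
}

#' Run the full analysis pipeline
#'
#' Reads a use-report CSV, validates it (diagnostics go to standard error),
#' computes the species index, consensus and fidelity tables, and writes
#' them to `out_dir` together with a machine-readable run manifest
#' (`manifest.json`: input checksum, configuration echo, and record /
#' species / category counts). Outputs are deterministic: the same input
#' and configuration always produce byte-identical files.
#'
#' @param input Path to the input use-report CSV.
#' @param out_dir Output directory (created if needed).
#' @param n_informants Optional total-respondents override (N); default:
#'   distinct informants observed.
#' @param categories Optional character vector fixing the designed use
#'   categories and their reporting order; default: categories observed.
#' @param formats Output formats, subset of `c("csv", "markdown")`.
#' @param digits_indices Decimals for index rendering (default 3).
#' @param digits_fl Decimals for fidelity-level rendering (default 2).
#' @inheritParams read_use_reports
#' @param quiet Suppress progress messages? Default `FALSE`.
#' @return Invisibly, a list with the three computed tables (full
#'   precision) and the paths written.
#' @export
run_pipeline <- function(input, out_dir,
                         n_informants = NULL, categories = NULL,
                         formats = c("csv", "markdown"),
                         digits_indices = 3, digits_fl = 2,
                         informant_col = "informant",
                         species_col = "species",
                         category_col = "use_category",
                         delim = ",", normalize = TRUE, quiet = FALSE) {
  formats <- match.arg(formats, several.ok = TRUE)
  design <- NULL
  if (!is.null(categories)) {
    if (is.null(n_informants)) {
      rlang::abort("`categories` requires `n_informants` as well.",
                   class = "ethnosurvey_parameter_error")
    }
    design <- study_design(n_informants, categories)
  }
  tab <- read_use_reports(input, informant_col = informant_col,
                          species_col = species_col,
                          category_col = category_col,
                          design = design, delim = delim,
                          normalize = normalize)
  if (is.null(design) && !is.null(n_informants)) {
    tab <- use_report_table(tab$records,
                            design = study_design(n_informants,
                                                  tab$design$categories),
                            normalize = FALSE)
  }
  say <- function(...) if (!quiet) message(...)
  say("ethnosurvey: ", nrow(tab$records), " use reports, ",
      dplyr::n_distinct(tab$records$species), " species, N = ",
      tab$design$n_informants)
  diag <- validate_use_reports(tab)
  for (m in diag$message) say("ethnosurvey: note: ", m)

  species <- species_index_table(tab)
  consensus <- withCallingHandlers(
    consensus_table(tab),
    warning = function(w) {
      say("ethnosurvey: warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  fidelity <- fidelity_table(tab)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ext <- c(csv = "csv", markdown = "md")
  paths <- character()
  tables <- list(species_indices = list(rows = species, digits = digits_indices),
                 consensus = list(rows = consensus, digits = digits_indices),
                 fidelity = list(rows = fidelity, digits = digits_fl))
  for (name in names(tables)) {
    for (fmt in formats) {
      p <- file.path(out_dir, paste0(name, ".", ext[[fmt]]))
      writeLines(render_table(tables[[name]]$rows, fmt,
                              tables[[name]]$digits),
                 p, sep = "")
      paths <- c(paths, p)
    }
  }

  manifest <- list(
    tool = "ethnosurvey",
    version = as.character(utils::packageVersion("ethnosurvey")),
    input = input,
    input_md5 = unname(tools::md5sum(input)),
    config = list(n_informants = tab$design$n_informants,
                  categories = tab$design$categories,
                  informant_col = informant_col, species_col = species_col,
                  category_col = category_col, delim = delim,
                  normalize = normalize, formats = formats,
                  digits_indices = digits_indices, digits_fl = digits_fl),
    counts = list(use_reports = nrow(tab$records),
                  species = dplyr::n_distinct(tab$records$species),
                  informants_observed =
                    dplyr::n_distinct(tab$records$informant),
                  categories_observed =
                    dplyr::n_distinct(tab$records$use_category)),
    diagnostics = diag$message)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths <- c(paths, mp)
  say("ethnosurvey: wrote ", length(paths), " files to ", out_dir)

  invisible(list(table = tab, species_indices = species,
                 consensus = consensus, fidelity = fidelity, paths = paths))
}
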