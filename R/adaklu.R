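# Reference data: a 2023 ethnobotanical survey of vernacular-building
# artisans in the Adaklu district, Volta region, Ghana. 258 respondents were
# asked which plant species they use for six building elements (main pole,
# main beam, wall lath, roof lath, binding material, thatch material),
# yielding 4109 use reports over 26 species.
#
# The package ships the three published summary tables (per-species indices,
# per-element consensus, fidelity levels). The record-level table can be
# reconstructed exactly from them: inverting each fidelity level against the
# species' citation count recovers the integer per-cell counts
# UR_su = round(FL * FC / 100), which sum to every species' printed UR and
# to every element's printed Nur — the summaries determine the full
# contingency structure.

#' The six building-element use categories of the Adaklu survey, in design
#' order.
#' @export
adaklu_categories <- function() {
  c("main pole", "main beam", "wall lath", "roof lath",
    "binding material", "thatch material")
}

#' Published summary tables of the Adaklu vernacular-building survey
#'
#' @return List with elements `indices` (26 species: family, local name,
#'   voucher, IUCN status passthrough, and the printed UR/CI/FC/NU/RFC/RI/CVe
#'   values), `consensus` (6 elements: Nur, Ns, IAR), `fidelity` (36
#'   species-by-element rows with FL percentages), `n_informants` (258) and
#'   `categories`. Species names are normalized to match record-level ids; a
#'   `scientific_name` column keeps the display form.
#' @export
adaklu_reference <- function() {
  path <- function(f) system.file("extdata", f, package = "ethnosurvey",
                                  mustWork = TRUE)
  ct <- readr::cols(.default = readr::col_character())
  idx <- readr::read_csv(path("adaklu_species_indices.csv"),
                         show_col_types = FALSE, progress = FALSE)
  fid <- readr::read_csv(path("adaklu_fidelity.csv"),
                         show_col_types = FALSE, progress = FALSE)
  con <- readr::read_csv(path("adaklu_consensus.csv"),
                         show_col_types = FALSE, progress = FALSE)
  idx$scientific_name <- idx$species
  idx$species <- normalize_label(idx$species)
  fid$species <- normalize_label(fid$species)
  fid$use_category <- normalize_label(fid$use_category)
  con$use_category <- normalize_label(con$use_category)
  list(indices = idx, consensus = con, fidelity = fid,
       n_informants = 258L, categories = adaklu_categories())
}

#' Reconstruct the Adaklu survey at use-report level
#'
#' Builds a [use_report_table()] whose per-species and per-category margins
#' equal the published Adaklu summaries exactly. For each species the
#' integer cell counts `ur_su = round(fl * fc / 100)` are recovered from the
#' fidelity table; informant ids `inf001..inf258` are then assigned
#' deterministically — the species' anchor category (FL = 100) takes all
#' `fc` citing informants, every other category the first `ur_su` of them —
#' so every citing informant holds at least one record and all margins (UR,
#' FC, NU per species; Nur, Ns per element) are reproduced. Informant
#' identities are synthetic: the published summaries fix the margins, not
#' which respondent said what, so informant-level structure beyond FC/UR_su
#' is a construction, not data.
#'
#' @return A [use_report_table()] with 4109 records, N = 258, NC = 6, and
#'   the reference metadata attached as `species_meta`.
#' @export
reconstruct_adaklu_survey <- function() {
  ref <- adaklu_reference()
  fid <- dplyr::left_join(ref$fidelity,
                          ref$indices[, c("species", "fc")],
                          by = "species")
  fid$ur_su <- as.integer(round(fid$fl * fid$fc / 100))

  recs <- vector("list", nrow(fid))
  for (i in seq_len(nrow(fid))) {
    n_i <- fid$ur_su[i]
    recs[[i]] <- tibble::tibble(
      informant    = sprintf("inf%03d", seq_len(n_i)),
      species      = fid$species[i],
      use_category = fid$use_category[i])
  }
  records <- dplyr::bind_rows(recs)

  meta_cols <- c("species", "scientific_name", "family", "local_name",
                 "voucher_id", "conservation_status")
  use_report_table(
    records,
    design = study_design(ref$n_informants, ref$categories),
    species_meta = ref$indices[, meta_cols])
}

#' Generator parameters calibrated to the Adaklu survey
#'
#' Citation probabilities are the published FC/258 per species; category
#' weights are the published fidelity levels divided by 100 (so each
#' species' FL-100 element is its anchor category). Sampling from these
#' parameters emulates the marginal structure of the survey.
#'
#' @param seed Integer seed for [generate_survey()].
#' @return A [survey_params()] object with N = 258, 26 species, 6
#'   categories.
#' @export
adaklu_survey_params <- function(seed = 1L) {
  ref <- adaklu_reference()
  sp <- ref$indices$species
  p <- as.numeric(ref$indices$fc) / ref$n_informants
  names(p) <- sp
  w <- matrix(0, nrow = length(sp), ncol = length(ref$categories),
              dimnames = list(sp, ref$categories))
  for (i in seq_len(nrow(ref$fidelity))) {
    w[ref$fidelity$species[i], ref$fidelity$use_category[i]] <-
      ref$fidelity$fl[i] / 100
  }
  survey_params(ref$n_informants, ref$categories, p, w, seed = seed)
}
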