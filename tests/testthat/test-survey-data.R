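test_that("duplicate triples collapse and the design is derived when absent", {
  records <- data.frame(
    informant = c("i1", "i1", "i2"),
    species = c("s1", "s1", "s1"),
    use_category = c("poles", "poles", "beam"))
  tab <- use_report_table(records)
  expect_equal(n_use_reports(tab), 2L)
  expect_equal(tab$design$n_informants, 2L)
  expect_equal(length(tab$design$categories), 2L)
})

test_that("default normalization unifies whitespace and case variants", {
  records <- data.frame(
    informant = c("i1", "i2"),
    species = c(" Bambusa  vulgaris ", "bambusa vulgaris"),
    use_category = c("Main  Pole", "main pole"))
  tab <- use_report_table(records)
  expect_equal(survey_species(tab), "bambusa vulgaris")
  expect_equal(tab$design$categories, "main pole")
  # idempotence
  expect_identical(normalize_label(normalize_label(" A  b ")),
                   normalize_label(" A  b "))
})

test_that("informant ids stay case-sensitive while species case-fold", {
  records <- data.frame(
    informant = c("A1", "a1"),
    species = c("Sp One", "sp one"),
    use_category = c("c", "c"))
  tab <- use_report_table(records)
  expect_equal(n_use_reports(tab), 2L)
  expect_equal(length(survey_species(tab)), 1L)
})

test_that("loading is order-independent and round-trips through the writer", {
  set.seed(101)
  tab <- random_survey(60)
  shuffled <- tab$records[sample(nrow(tab$records)), ]
  tab2 <- use_report_table(shuffled, design = tab$design)
  expect_identical(tab$records, tab2$records)

  f <- withr::local_tempfile(fileext = ".csv")
  write_use_reports(tab, f)
  tab3 <- read_use_reports(f, design = tab$design)
  expect_identical(tab$records, tab3$records)
  # writer is deterministic byte-for-byte
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_use_reports(tab3, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("schema, empty-input and design violations raise classed errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("who,plant,purpose\ni1,s1,poles", f)
  expect_error(read_use_reports(f),
               class = "ethnosurvey_schema_error")
  expect_error(read_use_reports(f, informant_col = "who",
                                species_col = "plant",
                                category_col = "missing"),
               class = "ethnosurvey_schema_error")
  tab <- read_use_reports(f, informant_col = "who", species_col = "plant",
                          category_col = "purpose")
  expect_equal(n_use_reports(tab), 1L)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("informant,species,use_category", empty)
  expect_error(read_use_reports(empty),
               class = "ethnosurvey_empty_input_error")

  records <- data.frame(informant = "i1", species = "s1",
                        use_category = "rogue")
  expect_error(
    use_report_table(records, design = study_design(5, c("a", "b"))),
    class = "ethnosurvey_validation_error")
  expect_error(
    use_report_table(
      data.frame(informant = c("i1", "i2"), species = "s1",
                 use_category = "a"),
      design = study_design(1, "a")),
    class = "ethnosurvey_validation_error")
  expect_error(
    use_report_table(data.frame(informant = "", species = "s1",
                                use_category = "a")),
    class = "ethnosurvey_validation_error")
})

test_that("validation reports findings without mutating or failing", {
  records <- data.frame(
    informant = paste0("i", 1:251),
    species = "s1",
    use_category = "main pole")
  tab <- use_report_table(records,
                          design = study_design(258, c("main pole",
                                                       "wall lath")))
  diag <- validate_use_reports(tab)
  expect_true("7 informants contribute no records" %in% diag$message)
  expect_true(any(diag$check == "empty_category" & diag$item == "wall lath"))
  expect_equal(n_use_reports(tab), 251L)

  single <- use_report_table(
    data.frame(informant = c("i1", "i1", "i2"),
               species = c("lone", "shared", "shared"),
               use_category = "c"))
  d2 <- validate_use_reports(single)
  expect_true("lone" %in% d2$item[d2$check == "single_informant_species"])

  full <- use_report_table(
    data.frame(informant = c("i1", "i2"), species = "s",
               use_category = c("a", "b")),
    design = study_design(2, c("a", "b")))
  expect_equal(nrow(validate_use_reports(full)), 0L)
})

test_that("record totals are conserved across both groupings", {
  set.seed(7)
  for (rep in 1:10) {
    tab <- random_survey(n_rows = sample(10:80, 1))
    idx <- species_index_table(tab)
    suppressWarnings(con <- consensus_table(tab))
    expect_equal(sum(idx$ur), n_use_reports(tab))
    expect_equal(sum(con$nur), n_use_reports(tab))
  }
})
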