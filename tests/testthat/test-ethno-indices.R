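test_that("count operations match hand enumeration on tiny tables", {
  # 3 informants each citing species X in 2 categories: 6 triples
  records <- expand.grid(informant = c("i1", "i2", "i3"),
                         species = "x",
                         use_category = c("a", "b"),
                         stringsAsFactors = FALSE)
  tab <- use_report_table(records)
  expect_equal(use_report_count(tab, "x"), 6L)
  expect_equal(frequency_of_citation(tab, "x"), 3L)
  expect_equal(number_of_uses(tab, "x"), 2L)

  # one informant citing 2 uses, another citing 1: FC = 2, UR = 3
  tab2 <- use_report_table(data.frame(
    informant = c("i1", "i1", "i2"),
    species = "x",
    use_category = c("a", "b", "a")))
  expect_equal(frequency_of_citation(tab2, "x"), 2L)
  expect_equal(use_report_count(tab2, "x"), 3L)

  # single mention
  tab3 <- use_report_table(data.frame(informant = "i1", species = "x",
                                      use_category = "a"))
  expect_equal(use_report_count(tab3, "x"), 1L)
  expect_error(use_report_count(tab3, "unknown"),
               class = "ethnosurvey_lookup_error")
})

test_that("index formulas handle boundaries and reject bad denominators", {
  expect_equal(cultural_importance(0, 258), 0)
  expect_error(cultural_importance(5, 0), class = "ethnosurvey_domain_error")
  expect_equal(relative_frequency_of_citation(10, 10), 1)
  expect_error(relative_frequency_of_citation(11, 10),
               class = "ethnosurvey_consistency_error")
  # species attaining both maxima
  expect_equal(relative_importance(0.9, 4, 0.9, 4), 1)
  expect_error(relative_importance(0.5, 1, 0, 1),
               class = "ethnosurvey_domain_error")
  expect_equal(cultural_value(2, 6, 10, 0, 258), 0)
  expect_error(cultural_value(1, 0, 1, 1, 10),
               class = "ethnosurvey_domain_error")
})

test_that("all indices match direct enumeration on random small tables", {
  set.seed(42)
  for (rep in 1:20) {
    tab <- random_survey(n_rows = sample(5:80, 1),
                         n_inf = sample(2:10, 1),
                         n_sp = sample(1:5, 1),
                         n_cat = sample(1:4, 1))
    got <- species_index_table(tab)
    got <- got[order(got$species), ]
    want <- oracle_species_indices(as.data.frame(tab$records),
                                   n = tab$design$n_informants,
                                   nc = length(tab$design$categories))
    expect_equal(got$ur, want$ur)
    expect_equal(got$fc, want$fc)
    expect_equal(got$nu, want$nu)
    expect_equal(got$ci, want$ci)
    expect_equal(got$rfc, want$rfc)
    expect_equal(got$ri, want$ri)
    expect_equal(got$cve, want$cve)
  }
})

test_that("per-species invariants hold on random tables", {
  set.seed(99)
  for (rep in 1:10) {
    tab <- random_survey(n_rows = sample(10:80, 1))
    idx <- species_index_table(tab)
    nc <- length(tab$design$categories)
    expect_true(all(idx$fc <= idx$ur))
    expect_true(all(idx$ur <= idx$fc * idx$nu))
    expect_true(all(idx$nu <= nc))
    expect_true(all(idx$fc <= tab$design$n_informants))
    expect_true(all(idx$rfc <= idx$ci + 1e-12))
    expect_equal(idx$cve, (idx$nu / nc) * idx$rfc * idx$ci)
  }
})

test_that("adding a new record never decreases a species' counts or ratios", {
  set.seed(5)
  for (rep in 1:10) {
    tab <- random_survey(n_rows = 30)
    before <- species_index_table(tab)
    # a genuinely new triple for an existing species
    new <- data.frame(informant = "i_new", species = before$species[1],
                      use_category = tab$design$categories[1])
    grown <- use_report_table(
      rbind(as.data.frame(tab$records), new),
      design = study_design(tab$design$n_informants + 1L,
                            tab$design$categories))
    after <- species_index_table(grown)
    b <- before[before$species == new$species, ]
    a <- after[after$species == new$species, ]
    expect_true(a$ur >= b$ur)
    expect_true(a$fc >= b$fc)
    expect_true(a$nu >= b$nu)
  }
})

test_that("RI is invariant to duplicating every informant under fresh ids", {
  set.seed(11)
  tab <- random_survey(n_rows = 50)
  doubled <- as.data.frame(tab$records)
  doubled$informant <- paste0(doubled$informant, "_copy")
  big <- use_report_table(
    rbind(as.data.frame(tab$records), doubled),
    design = study_design(2L * tab$design$n_informants,
                          tab$design$categories))
  ri1 <- species_index_table(tab)[, c("species", "ri")]
  ri2 <- species_index_table(big)[, c("species", "ri")]
  expect_equal(ri1, ri2)
})

test_that("the index table is ranked by UR with deterministic tie-breaks", {
  tab <- use_report_table(data.frame(
    informant = c("i1", "i2", "i1", "i2", "i3"),
    species = c("b", "b", "a", "a", "c"),
    use_category = "u"))
  idx <- species_index_table(tab)
  expect_equal(idx$species, c("a", "b", "c"))  # ur 2,2,1; tie a before b
  single <- species_index_table(use_report_table(
    data.frame(informant = "i", species = "s", use_category = "u")))
  expect_equal(single$ur, 1L)
  expect_equal(single$fc, 1L)
  expect_equal(single$nu, 1L)
  expect_equal(single$ri, 1)
  empty <- use_report_table(data.frame(informant = "i", species = "s",
                                       use_category = "u"))
  empty$records <- empty$records[0, ]
  expect_error(species_index_table(empty),
               class = "ethnosurvey_empty_input_error")
})
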