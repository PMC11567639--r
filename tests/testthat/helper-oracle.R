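# Independent oracle: direct base-R enumeration over the triple set,
# deliberately avoiding the package's grouped/dplyr implementation paths.

oracle_species_indices <- function(records, n, nc) {
  sp <- sort(unique(records$species))
  ur <- fc <- nu <- integer(length(sp))
  for (i in seq_along(sp)) {
    sub <- records[records$species == sp[i], , drop = FALSE]
    ur[i] <- nrow(unique(sub[, c("informant", "use_category")]))
    fc[i] <- length(unique(sub$informant))
    nu[i] <- length(unique(sub$use_category))
  }
  ci <- ur / n
  rfc <- fc / n
  ri <- ((rfc / max(rfc)) + (nu / max(nu))) / 2
  cve <- (nu / nc) * rfc * ci
  data.frame(species = sp, ur = ur, fc = fc, nu = nu,
             ci = ci, rfc = rfc, ri = ri, cve = cve,
             stringsAsFactors = FALSE)
}

oracle_consensus <- function(records, categories) {
  nur <- ns <- integer(length(categories))
  for (i in seq_along(categories)) {
    sub <- records[records$use_category == categories[i], , drop = FALSE]
    nur[i] <- nrow(sub)
    ns[i] <- length(unique(sub$species))
  }
  iar <- ifelse(nur >= 2, (nur - ns) / (nur - 1), NA_real_)
  data.frame(use_category = categories, nur = nur, ns = ns, iar = iar,
             stringsAsFactors = FALSE)
}

oracle_fidelity <- function(records) {
  pairs <- unique(records[, c("species", "use_category")])
  out <- data.frame()
  for (i in seq_len(nrow(pairs))) {
    s <- pairs$species[i]
    u <- pairs$use_category[i]
    ur_su <- length(unique(
      records$informant[records$species == s & records$use_category == u]))
    fc_s <- length(unique(records$informant[records$species == s]))
    out <- rbind(out, data.frame(species = s, use_category = u,
                                 ur_su = ur_su, fl = 100 * ur_su / fc_s,
                                 stringsAsFactors = FALSE))
  }
  out
}

# Random small survey over a fixed frame (<= 10 informants, 5 species,
# 4 categories) with the design supplied explicitly.
random_survey <- function(n_rows = 40, n_inf = 10, n_sp = 5, n_cat = 4) {
  cats <- paste0("cat", seq_len(n_cat))
  records <- data.frame(
    informant = sample(paste0("i", seq_len(n_inf)), n_rows, replace = TRUE),
    species = sample(paste0("sp", seq_len(n_sp)), n_rows, replace = TRUE),
    use_category = sample(cats, n_rows, replace = TRUE),
    stringsAsFactors = FALSE)
  use_report_table(records, design = study_design(n_inf, cats))
}
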