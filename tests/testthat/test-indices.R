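kinmen_totals <- function() {
  readr::read_csv(system.file("extdata", "kinmen_species_citations.csv",
                              package = "ethnoconsensus"),
                  show_col_types = FALSE)
}

kinmen_consensus <- function() {
  readr::read_csv(system.file("extdata", "kinmen_category_consensus.csv",
                              package = "ethnoconsensus"),
                  show_col_types = FALSE)
}

test_that("UV and RFC reproduce the published per-species index rows", {
  totals <- kinmen_totals()
  ds <- survey_from_citation_totals(totals, n_informants = 80, n_excluded = 8)
  idx <- compute_species_indices(ds)
  merged <- dplyr::inner_join(totals, idx, by = "canonical_name")
  expect_equal(nrow(merged), 24)

  # one documented tie-rounding exception: Phyla nodiflora's UV 18/80 = 0.225
  # is printed 0.22 in the index table but 0.23 in the running text; half-up
  # gives 0.23, so that row is compared against the text value
  expected_uv <- ifelse(merged$canonical_name == "Phyla nodiflora",
                        0.23, merged$uv_printed)
  expect_equal(merged$uv, expected_uv)
  expect_equal(merged$rfc, merged$rfc_printed)
  expect_equal(merged$sum_ui.y, merged$sum_ui.x)
  expect_equal(merged$fc.y, merged$fc.x)
})

test_that("most-cited species row gives UV 0.93 and RFC 0.90 at N = 80", {
  ds <- survey_from_citation_totals(
    tibble::tibble(canonical_name = "Justicia procumbens", sum_ui = 74, fc = 72),
    n_informants = 80)
  idx <- compute_species_indices(ds)
  expect_equal(idx$uv, 0.93)
  expect_equal(idx$rfc, 0.90)
  ds2 <- survey_from_citation_totals(
    tibble::tibble(canonical_name = "Glycine tomentella", sum_ui = 36, fc = 33),
    n_informants = 80)
  idx2 <- compute_species_indices(ds2)
  expect_equal(idx2$uv, 0.45)
  expect_equal(idx2$rfc, 0.41)
})

test_that("species indices match a brute-force recount on random datasets", {
  for (seed in c(201, 202, 203, 204, 205)) {
    ds <- random_survey(seed)
    idx <- compute_species_indices(ds, include_uncited = TRUE)
    oracle <- oracle_species_indices(ds)
    merged <- merge(idx, oracle, by = "species_id")
    expect_equal(merged$sum_ui.x, merged$sum_ui.y)
    expect_equal(merged$fc.x, merged$fc.y)
    expect_equal(merged$uv_raw.x, merged$uv_raw.y)
    expect_equal(merged$rfc_raw.x, merged$rfc_raw.y)
  }
})

test_that("index computation refuses a zero denominator", {
  ds <- survey_dataset(make_informants(0, n_excluded = 2),
                       make_species("Morus alba"),
                       make_report(character(0), character(0)))
  expect_error(compute_species_indices(ds), "denominator")
})

test_that("Fic reproduces the published category consensus table", {
  counts <- kinmen_consensus()
  ds <- survey_from_category_counts(counts, n_informants = 136)
  fic <- compute_fic(ds)
  merged <- dplyr::inner_join(counts, fic, by = "icpc_category")
  expect_equal(nrow(merged), 12)
  expect_equal(merged$nur.y, merged$nur.x)
  expect_equal(merged$nt.y, merged$nt.x)
  expect_equal(merged$fic, merged$fic_printed)
})

test_that("Fic handles the degenerate single-report category and exact-zero case", {
  ds <- survey_from_category_counts(
    tibble::tibble(icpc_category = "cardiovascular", nur = 1, nt = 1))
  expect_equal(compute_fic(ds)$fic, 0)
  expect_equal(compute_fic(ds, fic_degenerate_value = NA_real_)$fic, NA_real_)

  # Nur = Nt = k > 1 must give exactly zero
  ds2 <- survey_from_category_counts(
    tibble::tibble(icpc_category = "digestive", nur = 5, nt = 5))
  expect_identical(compute_fic(ds2)$fic_raw, 0)
})

test_that("Fic matches the oracle and conserves the mapped report count", {
  for (seed in c(301, 302, 303)) {
    ds <- random_survey(seed)
    fic <- compute_fic(ds)
    oracle <- oracle_fic(ds)
    merged <- merge(fic, oracle, by = "icpc_category")
    expect_equal(merged$nur.x, merged$nur.y)
    expect_equal(merged$nt.x, merged$nt.y)
    expect_equal(merged$fic_raw.x, merged$fic_raw.y)
    expect_equal(sum(fic$nur), nrow(ds$reports))
  }
})

test_that("Fic is strictly monotone in Nt (Nur fixed) and Nur (Nt fixed)", {
  for (nur in c(5, 20, 63, 136)) {
    fics <- vapply(2:min(nur, 12), function(nt) {
      ds <- survey_from_category_counts(
        tibble::tibble(icpc_category = "respiratory", nur = nur, nt = nt))
      compute_fic(ds)$fic_raw
    }, numeric(1))
    expect_true(all(diff(fics) < 0))
  }
  for (nt in c(2, 5, 10)) {
    fics <- vapply(nt + c(1, 5, 20, 60), function(nur) {
      ds <- survey_from_category_counts(
        tibble::tibble(icpc_category = "digestive", nur = nur, nt = nt))
      compute_fic(ds)$fic_raw
    }, numeric(1))
    expect_true(all(diff(fics) > 0))
  }
})

test_that("family tabulation reproduces published percentages", {
  # 83 species with 5 Lamiaceae: the unique count in 0..83 printing as 6.02%
  fams <- c(rep("Lamiaceae", 5), paste0("Fam", sprintf("%02d", 1:78)))
  ds <- survey_dataset(make_informants(2), make_species(
    sprintf("Genus species%02d", 1:83), family = fams),
    make_report("I01", "S01"))
  tab <- tabulate_attribute(ds, "family")
  expect_equal(attr(tab, "denominator"), 83)
  expect_equal(tab$pct[tab$value == "Lamiaceae"], 6.02)
})

test_that("part tabulation multi-counts distinct values per species", {
  informants <- make_informants(3)
  species <- make_species(c("A alba", "B alba", "C alba"))
  reports <- dplyr::bind_rows(
    make_report("I01", "S01", part = "Wp;Le"),
    make_report("I02", "S01", "other", part = "Wp"),
    make_report("I01", "S02", part = "Le"),
    make_report("I02", "S03", part = "Ro"))
  ds <- survey_dataset(informants, species, reports)
  tab <- tabulate_attribute(ds, "part")
  expect_equal(attr(tab, "denominator"), 4)  # S01 has two parts
  expect_equal(sum(tab$count), 4)

  # 33 whole-plant entries of 91 total counted parts print as 36.26%
  expect_equal(round_half_up(100 * 33 / 91, 2), 36.26)
  expect_error(tabulate_attribute(ds, "nonsense"))
})

test_that("demographic summary recovers the gender knowledge ratio", {
  # 2 women citing 6 distinct species each, 2 men citing 4 each -> ratio 1.5
  informants <- make_informants(4, gender = c("female", "female", "male", "male"))
  species <- make_species(sprintf("Genus species%02d", 1:6))
  reports <- dplyr::bind_rows(
    make_report(rep(c("I01", "I02"), each = 6), rep(sprintf("S%02d", 1:6), 2)),
    make_report(rep(c("I03", "I04"), each = 4), rep(sprintf("S%02d", 1:4), 2)))
  ds <- survey_dataset(informants, species, reports)
  summ <- demographic_summary(ds)
  expect_equal(summ$female_male_ratio, 1.5)
  expect_equal(sort(summ$knowledge_by_gender$mean_distinct_species), c(4, 6))

  # identical citation sets across genders -> ratio exactly 1
  reports_eq <- make_report(rep(c("I01", "I02", "I03", "I04"), each = 2),
                            rep(c("S01", "S02"), 4))
  expect_equal(demographic_summary(
    survey_dataset(informants, species, reports_eq))$female_male_ratio, 1)

  # single informant: one gender present, the other absent from the table
  solo <- survey_dataset(make_informants(1, gender = "male"), species,
                         make_report(rep("I01", 3), c("S01", "S02", "S03")))
  s <- demographic_summary(solo)
  expect_equal(s$knowledge_by_gender$gender, "male")
  expect_equal(s$knowledge_by_gender$mean_distinct_species, 3)
  expect_true(is.na(s$female_male_ratio))
})
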