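test_that("overlap percentages reproduce the published cross-reference", {
  fx <- crossref_fixture()
  sp <- fx$ds$species$canonical_name
  expect_equal(flora_overlap(sp, fx$taiwan)$pct, 93.98)
  expect_equal(flora_overlap(sp, fx$fujian)$pct, 65.06)
  expect_equal(flora_overlap(sp, fx$kinmen_flora)$pct, 60.24)
})

test_that("shared-use agreement across both catalogues gives 46.99%", {
  fx <- crossref_fixture()
  res <- shared_use(fx$ds, list(fx$taiwan, fx$fujian))
  expect_equal(res$n_shared, 39)
  expect_equal(res$pct, 46.99)
})

test_that("overlap handles disjoint and superset references", {
  sp <- c("Justicia procumbens", "Morus alba")
  expect_equal(flora_overlap(sp, reference_flora("r", "Senna tora"))$pct, 0)
  expect_equal(flora_overlap(
    sp, reference_flora("r", c(sp, "Senna tora")))$pct, 100)
  expect_error(flora_overlap(character(0), reference_flora("r", "Morus alba")),
               "empty")
})

test_that("overlap is monotone under reference growth", {
  set.seed(77)
  survey <- paste("Genus", paste0("species", letters[1:20]))
  ref_members <- character(0)
  last <- -1
  for (step in 1:10) {
    ref_members <- union(ref_members, sample(survey, 3))
    res <- flora_overlap(survey, reference_flora("r", ref_members))
    expect_gte(res$pct, last)
    last <- res$pct
  }
})

test_that("shared_use requires use maps and matches a brute-force recount", {
  fx <- crossref_fixture()
  expect_error(shared_use(fx$ds, list(fx$kinmen_flora)), "no use map")

  ds <- random_survey(501)
  survey_uses <- local({
    m <- merge(merge(ds$reports, ds$ailment_map, by = "ailment_text"),
               ds$species[, c("species_id", "canonical_name")],
               by = "species_id")
    split(m$icpc_category, m$canonical_name)
  })
  set.seed(502)
  refs <- lapply(1:2, function(i) {
    members <- sample(ds$species$canonical_name,
                      ceiling(nrow(ds$species) * 0.7))
    uses <- stats::setNames(lapply(members, function(sp) {
      if (runif(1) < 0.5 && !is.null(survey_uses[[sp]])) {
        unique(survey_uses[[sp]])
      } else "unrelated-use"
    }), members)
    reference_flora(paste0("ref", i), members, uses = uses)
  })
  res <- shared_use(ds, refs)
  # oracle: explicit double loop over species and references
  expected <- 0L
  for (sp in names(survey_uses)) {
    ok <- TRUE
    for (ref in refs) {
      if (is.null(ref$uses[[sp]]) ||
          length(intersect(unique(survey_uses[[sp]]), ref$uses[[sp]])) == 0) {
        ok <- FALSE
      }
    }
    if (ok) expected <- expected + 1L
  }
  expect_equal(res$n_shared, expected)
})

test_that("novelty splits the survey into matched and novel species", {
  informants <- make_informants(3)
  species <- make_species(c("Vernonia amygdalina", "Senna occidentalis",
                            "Mimosa pudica"))
  reports <- dplyr::bind_rows(
    make_report("I01", "S01", "liver complaint"),
    make_report("I02", "S02", "eye strain"),
    make_report("I03", "S03", "cough"))
  ailment_map <- tibble::tibble(
    ailment_text = c("liver complaint", "eye strain", "cough"),
    icpc_category = c("digestive", "eye", "respiratory"))
  ds <- survey_dataset(informants, species, reports, ailment_map = ailment_map)
  ref <- reference_flora(
    "flora", c("Senna occidentalis", "Mimosa pudica"),
    uses = list("Senna occidentalis" = "digestive",   # disagrees with survey
                "Mimosa pudica" = "respiratory"))     # agrees
  nov <- detect_novelty(ds, list(ref))
  expect_equal(nov$novel_species, "Vernonia amygdalina")
  expect_equal(nov$n_novel_uses, 2)  # V. amygdalina digestive + S. occidentalis eye
  expect_equal(sum(nov$novel_uses$is_novel_species), 1)
  # matched and novel species partition the survey set
  expect_setequal(c(nov$novel_species,
                    intersect(ds$species$canonical_name, ref$species)),
                  ds$species$canonical_name)

  # references covering everything -> nothing novel
  full <- reference_flora("full", ds$species$canonical_name,
                          uses = list("Vernonia amygdalina" = "digestive",
                                      "Senna occidentalis" = "eye",
                                      "Mimosa pudica" = "respiratory"))
  nov2 <- detect_novelty(ds, list(full))
  expect_equal(nov2$n_novel_species, 0)
  expect_equal(nov2$n_novel_uses, 0)
})

test_that("novelty counts follow the published pattern on a shaped fixture", {
  # 18 survey species each with one use unknown to the references, 4 of them
  # absent from every reference list
  informants <- make_informants(20)
  species <- make_species(paste("Novelia", paste0("species", letters[1:20])))
  reports <- make_report(sprintf("I%02d", 1:20), sprintf("S%02d", 1:20),
                         ailment = rep(c("cough", "eye strain"), 10))
  ailment_map <- tibble::tibble(ailment_text = c("cough", "eye strain"),
                                icpc_category = c("respiratory", "eye"))
  ds <- survey_dataset(informants, species, reports, ailment_map = ailment_map)
  members <- ds$species$canonical_name[1:16]   # species 17..20 novel
  uses <- stats::setNames(as.list(rep("unrelated-use", 16)), members)
  uses[[members[1]]] <- "respiratory"          # species 1 agrees
  uses[[members[2]]] <- "eye"                  # species 2 agrees
  ref <- reference_flora("flora", members, uses = uses)
  nov <- detect_novelty(ds, list(ref))
  expect_equal(nov$n_novel_uses, 18)
  expect_equal(nov$n_novel_species, 4)
  expect_equal(sum(nov$novel_uses$is_novel_species), 4)
})

test_that("annotation tallies bucket unannotated species explicitly", {
  statuses <- c(rep("EN", 1), rep("VU", 2), rep("NT", 1), rep("LC", 13),
                rep("DD", 1), rep("NA", 16), rep(NA_character_, 49))
  species <- make_species(sprintf("Genus species%02d", 1:83))
  species$red_list_status <- statuses
  ds <- survey_dataset(make_informants(2), species,
                       make_report("I01", "S01"))
  tab <- annotation_counts(ds)
  expect_equal(sum(tab$count), 83)
  expect_equal(sum(tab$count[tab$value != "unannotated"]), 34)
  expect_equal(tab$count[tab$value == "EN"], 1)
  expect_equal(tab$count[tab$value == "VU"], 2)
  expect_equal(tab$count[tab$value == "unannotated"], 49)
  expect_error(annotation_counts(ds, "no-such-field"), "unknown annotation")

  species$red_list_status <- NA_character_
  ds2 <- survey_dataset(make_informants(2), species, make_report("I01", "S01"))
  tab2 <- annotation_counts(ds2)
  expect_equal(tab2$value, "unannotated")
  expect_equal(tab2$count, 83)
})
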