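test_that("baskets deduplicate species and keep empty informants", {
  informants <- make_informants(3)
  species <- make_species(c("A alba", "B alba"))
  reports <- dplyr::bind_rows(
    make_report("I01", "S01", "cough"),
    make_report("I01", "S01", "fever"),
    make_report("I01", "S02", "cough"))
  ds <- survey_dataset(informants, species, reports)
  baskets <- build_baskets(ds)
  expect_equal(nrow(baskets), 3)
  expect_equal(baskets$species[[1]], c("S01", "S02"))
  expect_equal(lengths(baskets$species), c(2, 0, 0))
  # sum of basket sizes = distinct (informant, species) pairs
  expect_equal(sum(lengths(baskets$species)),
               nrow(unique(ds$reports[, c("informant_id", "species_id")])))
})

test_that("a single co-citing informant yields both unit rules", {
  baskets <- tibble::tibble(informant_id = "I01", species = list(c("A", "B")))
  rules <- mine_rules(baskets, min_support = 1, min_confidence = 0)
  expect_equal(nrow(rules), 2)
  expect_equal(rules$support_count, c(1, 1))
  expect_equal(rules$confidence, c(1, 1))
  expect_setequal(rules$antecedent, c("A", "B"))

  expect_equal(nrow(mine_rules(baskets, min_support = 2, min_confidence = 0)), 0)
})

test_that("rule mining equals exhaustive pair enumeration on random baskets", {
  for (seed in 601:640) {
    baskets <- random_baskets(seed)
    min_support <- sample(1:3, 1)
    min_confidence <- runif(1)
    rules <- mine_rules(baskets, min_support, min_confidence)
    oracle <- oracle_rules(baskets, min_support, min_confidence)
    expect_equal(nrow(rules), nrow(oracle))
    if (nrow(rules) > 0) {
      expect_equal(rules$antecedent, oracle$antecedent)
      expect_equal(rules$consequent, oracle$consequent)
      expect_equal(rules$support_count, oracle$support_count)
      expect_equal(rules$confidence, oracle$confidence)
    }
  }
})

test_that("support is symmetric, anti-monotone in the threshold, and ties to counts", {
  baskets <- random_baskets(650)
  rules <- mine_rules(baskets, min_support = 1, min_confidence = 0)
  # symmetry of support and the exact integer identity
  counts <- table(unlist(lapply(baskets$species, unique)))
  for (i in seq_len(nrow(rules))) {
    rev <- rules[rules$antecedent == rules$consequent[i] &
                 rules$consequent == rules$antecedent[i], ]
    expect_equal(rev$support_count, rules$support_count[i])
    expect_equal(rules$confidence[i] * counts[[rules$antecedent[i]]],
                 rules$support_count[i])
  }
  # raising min_support never adds rules
  n_prev <- Inf
  for (ms in 1:4) {
    n_now <- nrow(mine_rules(baskets, min_support = ms, min_confidence = 0))
    expect_lte(n_now, n_prev)
    n_prev <- n_now
  }
})

test_that("the network collapses symmetric rules into undirected edges", {
  baskets <- tibble::tibble(
    informant_id = c("I01", "I02", "I03"),
    species = list(c("S01", "S02"), c("S01", "S02"), c("S02", "S03")))
  idx <- tibble::tibble(species_id = c("S01", "S02", "S03"),
                        canonical_name = c("A alba", "B alba", "C alba"),
                        fc = c(2L, 3L, 1L))
  rules <- mine_rules(baskets, min_support = 1, min_confidence = 0)
  net <- to_network(rules, idx)
  expect_equal(igraph::vcount(net), 3)
  expect_equal(igraph::ecount(net), 2)   # S01-S02 and S02-S03
  e <- igraph::as_data_frame(net, what = "edges")
  s12 <- e[(e$from == "S01" & e$to == "S02") | (e$from == "S02" & e$to == "S01"), ]
  expect_equal(s12$support_count, 2)
  expect_equal(sort(igraph::V(net)$fc), c(1, 2, 3))

  # empty rule set -> edgeless network over the indexed species
  empty_net <- to_network(mine_rules(baskets, min_support = 5), idx)
  expect_equal(igraph::ecount(empty_net), 0)
  expect_equal(igraph::vcount(empty_net), 3)

  # rules naming species missing from the index are rejected
  bad <- rules
  bad$antecedent[1] <- "S99"
  expect_error(to_network(bad, idx), "S99")
})

test_that("network export round-trips through GraphML and edge CSV", {
  ds <- random_survey(701)
  idx <- compute_species_indices(ds, include_uncited = TRUE)
  rules <- mine_rules(build_baskets(ds), min_support = 1, min_confidence = 0)
  net <- to_network(rules, idx)
  for (fmt in c("graphml", "edge-csv")) {
    path <- file.path(withr::local_tempdir(), paste0("net.", fmt))
    export_network(net, path, format = fmt)
    back <- import_network(path, format = fmt)
    expect_equal(igraph::vcount(back), igraph::vcount(net))
    expect_equal(igraph::ecount(back), igraph::ecount(net))
    expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
    e_old <- igraph::as_data_frame(net, what = "edges")
    e_new <- igraph::as_data_frame(back, what = "edges")
    key <- function(e) paste(pmin(e$from, e$to), pmax(e$from, e$to))
    e_new <- e_new[match(key(e_old), key(e_new)), ]
    expect_equal(e_new$support_count, e_old$support_count)
    expect_equal(e_new$confidence_fwd, e_old$confidence_fwd)
  }

  # empty network still exports a valid, re-importable file
  empty_net <- to_network(mine_rules(build_baskets(ds), min_support = 999), idx)
  path <- file.path(withr::local_tempdir(), "empty.graphml")
  export_network(empty_net, path)
  expect_equal(igraph::ecount(import_network(path)), 0)
})
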