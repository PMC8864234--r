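# Shared fixtures and independent brute-force oracles. The oracles recount
# everything with plain loops over raw rows, deliberately avoiding the
# package's dplyr pipelines.

make_informants <- function(n_included, n_excluded = 0,
                            gender = rep(c("female", "male"),
                                         length.out = n_included + n_excluded)) {
  n <- n_included + n_excluded
  tibble::tibble(
    informant_id = sprintf("I%02d", seq_len(n)),
    gender = gender,
    age_band = ">60", township = "T1", education = "elementary",
    knowledge_sources = "oral-transmission",
    included = rep(c(TRUE, FALSE), c(n_included, n_excluded)))
}

make_species <- function(names, family = "Testaceae") {
  tibble::tibble(
    species_id = sprintf("S%02d", seq_along(names)),
    canonical_name = names,
    family = rep_len(family, length(names)),
    local_names = NA_character_, voucher_id = NA_character_,
    source = "wild", red_list_status = NA_character_)
}

make_report <- function(informant, species, ailment = "cough",
                        part = "Wp", preparation = "decoction-fresh",
                        route = "oral") {
  tibble::tibble(informant_id = informant, species_id = species,
                 ailment_text = ailment, part = part,
                 preparation = preparation, route = route)
}

# a tiny consistent survey: 4 included informants, 3 species
tiny_survey <- function() {
  informants <- make_informants(4)
  species <- make_species(c("Justicia procumbens", "Lycium chinense",
                            "Morus alba"))
  reports <- dplyr::bind_rows(
    make_report("I01", "S01", "cough"),
    make_report("I01", "S01", "sore throat"),
    make_report("I02", "S01", "cough"),
    make_report("I02", "S02", "eye strain"),
    make_report("I03", "S02", "eye strain"),
    make_report("I03", "S03", "anemia"))
  ailment_map <- tibble::tibble(
    ailment_text = c("cough", "sore throat", "eye strain", "anemia"),
    icpc_category = c("respiratory", "respiratory", "eye",
                      "blood-blood-forming-lymph-spleen"))
  survey_dataset(informants, species, reports, ailment_map = ailment_map)
}

# random small survey for oracle-equivalence tests
random_survey <- function(seed, max_informants = 10, max_species = 8) {
  set.seed(seed)
  n_inf <- sample(2:max_informants, 1)
  n_sp <- sample(2:max_species, 1)
  n_rep <- sample(1:(3 * n_inf), 1)
  informants <- make_informants(n_inf)
  species <- make_species(paste("Genus", paste0("species", letters[seq_len(n_sp)])))
  cats <- icpc_categories()[1:3]
  ailments <- paste0(rep(cats, each = 2), "-a", 1:2)
  reports <- tibble::tibble(
    informant_id = sample(informants$informant_id, n_rep, replace = TRUE),
    species_id = sample(species$species_id, n_rep, replace = TRUE),
    ailment_text = sample(ailments, n_rep, replace = TRUE),
    part = sample(part_vocabulary(), n_rep, replace = TRUE),
    preparation = sample(preparation_vocabulary(), n_rep, replace = TRUE),
    route = sample(route_vocabulary(), n_rep, replace = TRUE))
  # keep one record per (informant, species, ailment) triple
  reports <- dplyr::distinct(reports, informant_id, species_id,
                             ailment_text, .keep_all = TRUE)
  ailment_map <- tibble::tibble(ailment_text = ailments,
                                icpc_category = rep(cats, each = 2))
  survey_dataset(informants, species, reports, ailment_map = ailment_map)
}

# --- oracles -------------------------------------------------------------

oracle_species_indices <- function(ds) {
  n <- sum(ds$informants$included)
  out <- list()
  for (i in seq_len(nrow(ds$species))) {
    sid <- ds$species$species_id[i]
    sum_ui <- 0L
    informants <- character(0)
    for (r in seq_len(nrow(ds$reports))) {
      if (ds$reports$species_id[r] == sid) {
        sum_ui <- sum_ui + 1L
        informants <- union(informants, ds$reports$informant_id[r])
      }
    }
    out[[i]] <- data.frame(species_id = sid, sum_ui = sum_ui,
                           fc = length(informants),
                           uv_raw = sum_ui / n, rfc_raw = length(informants) / n)
  }
  do.call(rbind, out)
}

oracle_fic <- function(ds, degenerate = 0) {
  map <- stats::setNames(ds$ailment_map$icpc_category, ds$ailment_map$ailment_text)
  cats <- unique(unname(map[ds$reports$ailment_text]))
  out <- list()
  for (cat in cats) {
    nur <- 0L
    taxa <- character(0)
    for (r in seq_len(nrow(ds$reports))) {
      if (map[[ds$reports$ailment_text[r]]] == cat) {
        nur <- nur + 1L
        taxa <- union(taxa, ds$reports$species_id[r])
      }
    }
    fic <- if (nur > 1) (nur - length(taxa)) / (nur - 1) else degenerate
    out[[cat]] <- data.frame(icpc_category = cat, nur = nur,
                             nt = length(taxa), fic_raw = fic)
  }
  do.call(rbind, out)
}

# exhaustive enumeration over all ordered species pairs
oracle_rules <- function(baskets, min_support, min_confidence) {
  species <- sort(unique(unlist(baskets$species)))
  n <- nrow(baskets)
  rows <- list()
  for (a in species) {
    for (b in species) {
      if (a == b) next
      n_a <- 0L; n_both <- 0L
      for (i in seq_len(n)) {
        has_a <- a %in% baskets$species[[i]]
        has_b <- b %in% baskets$species[[i]]
        if (has_a) n_a <- n_a + 1L
        if (has_a && has_b) n_both <- n_both + 1L
      }
      if (n_both >= min_support && n_both / n_a >= min_confidence) {
        rows[[length(rows) + 1]] <- data.frame(
          antecedent = a, consequent = b, support_count = n_both,
          support_frac = n_both / n, confidence = n_both / n_a)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(antecedent = character(), consequent = character(),
                      support_count = integer(), support_frac = numeric(),
                      confidence = numeric()))
  }
  df <- do.call(rbind, rows)
  df[order(-df$support_count, df$antecedent, df$consequent), , drop = FALSE]
}

# an 83-species survey and reference lists shaped like the published
# comparison: 78/83 and 54/83 covered with 39 use-consistent in both, plus a
# 50/83 membership-only flora
crossref_fixture <- function() {
  sim <- generate_survey(kinmen_sim_config(seed = 20260921))
  ds <- sim$dataset
  all_sp <- sort(unique(ds$species$canonical_name))
  cited <- ds$reports |>
    dplyr::left_join(dplyr::select(ds$species, species_id, canonical_name),
                     by = "species_id") |>
    dplyr::pull(canonical_name) |>
    unique() |>
    sort()
  stopifnot(length(cited) >= 39)
  agree <- cited[1:39]

  survey_uses <- local({
    m <- ds$reports |>
      dplyr::inner_join(ds$ailment_map, by = "ailment_text") |>
      dplyr::left_join(dplyr::select(ds$species, species_id, canonical_name),
                       by = "species_id")
    split(m$icpc_category, m$canonical_name)
  })
  use_list <- function(members) {
    stats::setNames(lapply(members, function(sp) {
      if (sp %in% agree) unique(survey_uses[[sp]]) else "unrelated-use"
    }), members)
  }
  taiwan_members <- unique(c(agree, setdiff(all_sp, agree)))[1:78]
  fujian_members <- unique(c(agree, setdiff(all_sp, agree)[1:15]))
  stopifnot(length(fujian_members) == 54)
  list(
    ds = ds,
    taiwan = reference_flora("taiwan-catalogue", taiwan_members,
                             uses = use_list(taiwan_members)),
    fujian = reference_flora("fujian-record", fujian_members,
                             uses = use_list(fujian_members)),
    kinmen_flora = reference_flora("kinmen-flora", all_sp[1:50]))
}

random_baskets <- function(seed, max_informants = 10, max_species = 8) {
  set.seed(seed)
  n_inf <- sample(2:max_informants, 1)
  n_sp <- sample(2:max_species, 1)
  species <- sprintf("S%02d", seq_len(n_sp))
  tibble::tibble(
    informant_id = sprintf("I%02d", seq_len(n_inf)),
    species = lapply(seq_len(n_inf), function(i) {
      k <- sample(0:n_sp, 1)
      sort(sample(species, k))
    }))
}
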