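#' Simulation configuration for synthetic surveys
#'
#' Parameterizes the generative model behind [generate_survey()]. The
#' defaults reproduce the shape of the Kinmen medicinal-plant survey: 80
#' included informants (plus 8 excluded respondents who completed no
#' interview), a female-majority panel (45/80), 83 species in 48 families,
#' twelve ICPC ailment categories with report mass distributed like the
#' published consensus table, and per-gender knowledge rates of 6 (women)
#' and 4 (men) distinct species on average.
#'
#' The consensus dial is `concentration`: within each category, species are
#' drawn from a symmetric Dirichlet-multinomial with this concentration
#' parameter per species slot. A low value makes a few taxa dominate the
#' category (high Fic); a high value spreads reports across the category's
#' taxon pool (low Fic).
#'
#' @param seed Integer seed; fixes the entire output.
#' @param n_informants Number of included informants.
#' @param n_excluded Respondents approached but excluded (no reports).
#' @param gender_split Fraction of included informants who are female.
#' @param knowledge_rate Named vector `c(female=, male=)`: target mean
#'   number of distinct species cited per informant of that gender.
#' @param n_species,n_families Species-pool dimensions.
#' @param family_size_law `"skewed"` (Zipf-like, a few large families) or
#'   `"uniform"`.
#' @param n_categories Number of ICPC categories used (first `n` of
#'   [icpc_categories()]).
#' @param category_weights Report-mass weights across categories (recycled /
#'   normalized); default follows the Kinmen consensus-table profile.
#' @param taxa_weights Relative sizes of the per-category taxon pools the
#'   species set is partitioned into; default follows the taxa profile of
#'   the same table.
#' @param concentration Dirichlet concentration per category (recycled);
#'   the default gradient runs from strong to weak consensus.
#' @param reports_per_citation Mean use reports per (informant, species)
#'   citation; >= 1. Values above 1 make \eqn{\Sigma U_i} exceed FC, as
#'   observed when informants cite one plant for several ailments.
#' @param multi_attr_rate Probability that a species carries two part /
#'   preparation / route values rather than one.
#' @param age_band_weights,education_weights,township_weights,knowledge_source_probs
#'   Demographic sampling laws (named vectors).
#' @param red_list_weights Named weights over red-list statuses for the
#'   annotated fraction of species; `annotated_fraction` controls how many
#'   species carry a status at all.
#' @param annotated_fraction Fraction of species with a red-list record.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_informants = 80L,
                       n_excluded = 8L,
                       gender_split = 45 / 80,
                       knowledge_rate = c(female = 6, male = 4),
                       n_species = 83L,
                       n_families = 48L,
                       family_size_law = c("skewed", "uniform"),
                       n_categories = 12L,
                       category_weights = NULL,
                       taxa_weights = NULL,
                       concentration = NULL,
                       reports_per_citation = 1.1,
                       multi_attr_rate = 0.1,
                       age_band_weights = c("20-30" = 0.05, "31-40" = 0.08,
                                            "41-50" = 0.15, "51-60" = 0.27,
                                            ">60" = 0.45),
                       education_weights = c(none = 0.15, elementary = 0.40,
                                             "junior-high" = 0.17,
                                             "senior-high" = 0.18,
                                             "university+" = 0.10),
                       township_weights = c("Jincheng" = 16, "Kinhu" = 22,
                                            "Kinsha" = 19, "Jinning" = 13,
                                            "Lieyu" = 8),
                       knowledge_source_probs = c("oral-transmission" = 0.90,
                                                  "books" = 0.15,
                                                  "media" = 0.08),
                       red_list_weights = c(EN = 1, VU = 2, NT = 1, LC = 13,
                                            DD = 1, "NA" = 16),
                       annotated_fraction = 34 / 83) {
  family_size_law <- match.arg(family_size_law)
  if (is.null(category_weights)) {
    # report-mass profile of the twelve categories, most-cited being
    # respiratory / general / musculoskeletal as in the field data
    category_weights <- c(63, 31, 136, 50, 102, 58, 18, 3, 18, 4, 1, 1)
  }
  if (is.null(taxa_weights)) {
    # taxon-pool profile: how many taxa compete within each category
    taxa_weights <- c(5, 4, 18, 10, 21, 16, 7, 2, 10, 3, 1, 1)
  }
  if (is.null(concentration)) {
    # spans strong consensus (few dominant taxa, low alpha) to weak; ordered
    # as icpc_categories(), mirroring the consensus gradient of field data
    concentration <- c(0.15, 0.2, 0.35, 0.4, 0.5, 0.8, 1.2, 1.5, 2, 2.5, 1, 1)
  }
  n_categories <- as.integer(n_categories)
  category_weights <- rep_len(category_weights, n_categories)
  taxa_weights <- rep_len(taxa_weights, n_categories)
  concentration <- rep_len(concentration, n_categories)
  stopifnot(
    n_informants > 0, n_excluded >= 0,
    gender_split >= 0, gender_split <= 1,
    all(knowledge_rate > 1), !is.null(names(knowledge_rate)),
    all(c("female", "male") %in% names(knowledge_rate)),
    n_species >= 1, n_families >= 1, n_families <= n_species,
    n_categories >= 1, n_categories <= length(icpc_categories()),
    n_species >= n_categories,
    all(category_weights >= 0), sum(category_weights) > 0,
    all(taxa_weights > 0), all(concentration > 0),
    reports_per_citation >= 1,
    multi_attr_rate >= 0, multi_attr_rate <= 1,
    annotated_fraction >= 0, annotated_fraction <= 1
  )
  structure(
    list(seed = as.integer(seed), n_informants = as.integer(n_informants),
         n_excluded = as.integer(n_excluded), gender_split = gender_split,
         knowledge_rate = knowledge_rate, n_species = as.integer(n_species),
         n_families = as.integer(n_families),
         family_size_law = family_size_law, n_categories = n_categories,
         category_weights = category_weights / sum(category_weights),
         taxa_weights = taxa_weights / sum(taxa_weights),
         concentration = concentration,
         reports_per_citation = reports_per_citation,
         multi_attr_rate = multi_attr_rate,
         age_band_weights = age_band_weights,
         education_weights = education_weights,
         township_weights = township_weights,
         knowledge_source_probs = knowledge_source_probs,
         red_list_weights = red_list_weights,
         annotated_fraction = annotated_fraction),
    class = "sim_config"
  )
}

#' Kinmen-shaped preset
#'
#' [sim_config()] with all defaults, i.e. the dimensions of the Kinmen
#' survey (80 included informants, 83 species, 48 families, 12 categories).
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
kinmen_sim_config <- function(seed = 42L) {
  sim_config(seed = seed)
}

# deterministic pseudo-Latin word from an index (no RNG involved)
latin_word <- function(i, n_syllables = 3) {
  syl <- c("al", "be", "ca", "do", "er", "fi", "go", "hu", "in", "ju",
           "ka", "lo", "mi", "nu", "or", "pe", "qui", "ra", "so", "ta",
           "ve", "wi", "xe", "yo", "zu")
  i <- as.integer(i) - 1L
  out <- character(n_syllables)
  for (k in seq_len(n_syllables)) {
    out[k] <- syl[(i %% length(syl)) + 1L]
    i <- i %/% length(syl)
  }
  paste(out, collapse = "")
}

capitalize <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

# zero-truncated Poisson sampler parameterized by its *mean*: the rate is
# solved from target = lambda / (1 - exp(-lambda)) so the realized mean of
# distinct-species counts is unbiased for the configured knowledge rate
ztp_rate_for_mean <- function(target_mean) {
  stopifnot(target_mean > 1)
  stats::uniroot(function(l) l / (1 - exp(-l)) - target_mean,
                 lower = 1e-8, upper = target_mean + 10,
                 tol = 1e-10)$root
}

rztpois <- function(n, lambda) {
  lambda <- rep_len(lambda, n)
  out <- stats::rpois(n, lambda)
  while (any(out == 0)) {
    zero <- which(out == 0)
    out[zero] <- stats::rpois(length(zero), lambda[zero])
  }
  out
}

sample_weighted <- function(n, weights) {
  sample(names(weights), n, replace = TRUE, prob = weights)
}

#' Generate a synthetic ethnobotanical survey
#'
#' Draws a complete survey dataset from the generative model described in
#' [sim_config()] together with the latent ground truth used for
#' parameter-recovery tests:
#' 1. Included informants get demographics from the configured categorical
#'    laws, and a distinct-species count from a zero-truncated Poisson whose
#'    mean is the gender's knowledge rate. Excluded respondents are emitted
#'    with `included = FALSE` and no reports.
#' 2. Species are partitioned into families (Zipf-like sizes by default) and
#'    into category pools; each category draws a species-choice probability
#'    vector from a symmetric Dirichlet with its concentration parameter —
#'    shared by all informants, which is what creates (or destroys)
#'    consensus.
#' 3. Each citation picks a category by the category weights, then a species
#'    from that category's Dirichlet draw, until the informant's distinct
#'    count is reached; each citation expands into `1 + Poisson` use reports
#'    for distinct ailments of that category.
#' 4. Parts, preparations and routes are fixed per species (occasionally
#'    multi-valued) and echoed by its reports, matching the per-species
#'    multi-count convention of the descriptive tabulations.
#'
#' All randomness flows from `cfg$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param cfg A [sim_config()].
#' @return A list: `dataset` (a [survey_dataset()] including the ailment
#'   map) and `ground_truth` (category probabilities and pools, per-gender
#'   rates, per-species attributes).
#' @export
generate_survey <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cfg$seed)

  categories <- icpc_categories()[seq_len(cfg$n_categories)]

  ## species table ----------------------------------------------------------
  sp_idx <- seq_len(cfg$n_species)
  canonical <- paste(capitalize(vapply(sp_idx * 2L - 1L, latin_word, character(1))),
                     vapply(sp_idx * 2L, latin_word, character(1)))
  fam_names <- paste0(capitalize(vapply(seq_len(cfg$n_families) + 7000L,
                                        latin_word, character(1))), "aceae")
  fam_w <- if (cfg$family_size_law == "skewed") 1 / seq_len(cfg$n_families) else
    rep(1, cfg$n_families)
  # every family gets one species, the rest are distributed by the size law
  fam_assign <- c(seq_len(cfg$n_families),
                  sample(cfg$n_families, cfg$n_species - cfg$n_families,
                         replace = TRUE, prob = fam_w))
  fam_assign <- sample(fam_assign)      # decouple family from species index

  n_annot <- round(cfg$annotated_fraction * cfg$n_species)
  red_list <- rep(NA_character_, cfg$n_species)
  if (n_annot > 0) {
    annotated <- sample(sp_idx, n_annot)
    red_list[annotated] <- sample_weighted(n_annot, cfg$red_list_weights)
  }

  part_w <- c(Wp = 0.36, Le = 0.31, Fr = 0.10, Ro = 0.08, St = 0.06,
              Se = 0.05, Fl = 0.02, Cx = 0.02)
  prep_w <- c("decoction-fresh" = 0.43, "decoction-dried" = 0.15,
              "crush" = 0.16, "soak" = 0.09, "raw" = 0.05, "fry" = 0.03,
              "juice" = 0.03, "burn" = 0.02, "cook-with-meat" = 0.02,
              "honey-maceration" = 0.02)
  route_w <- c("oral" = 0.74, "apply-to-injuries" = 0.13,
               "apply-to-skin" = 0.06, "fomentation" = 0.02, "chew" = 0.0125,
               "bath" = 0.0125, "fumigation" = 0.0125, "fill-teeth" = 0.0125)
  draw_attr <- function(weights) {
    vapply(sp_idx, function(i) {
      k <- 1 + stats::rbinom(1, 1, cfg$multi_attr_rate)
      paste(sample(names(weights), k, prob = weights), collapse = MULTI_SEP)
    }, character(1))
  }
  species <- tibble::tibble(
    species_id = sprintf("SP%03d", sp_idx),
    canonical_name = canonical,
    family = fam_names[fam_assign],
    local_names = paste0("local-", vapply(sp_idx + 9000L, latin_word, character(1))),
    voucher_id = sprintf("SYN%03d", sp_idx),
    source = sample(c("wild", "cultivated/institute"), cfg$n_species,
                    replace = TRUE, prob = c(0.8, 0.2)),
    red_list_status = red_list)
  sp_part <- draw_attr(part_w)
  sp_prep <- draw_attr(prep_w)
  sp_route <- draw_attr(route_w)

  ## category pools and Dirichlet species-choice laws ------------------------
  # pool sizes proportional to the taxa profile, every category >= 1 taxon
  pool_sizes <- pmax(1L, round(cfg$taxa_weights * cfg$n_species))
  while (sum(pool_sizes) > cfg$n_species) {
    big <- which(pool_sizes > 1L)
    i <- big[which.max(pool_sizes[big])]
    pool_sizes[i] <- pool_sizes[i] - 1L
  }
  while (sum(pool_sizes) < cfg$n_species) {
    i <- which.min(pool_sizes); pool_sizes[i] <- pool_sizes[i] + 1L
  }
  shuffled <- sample(sp_idx)
  pools <- split(shuffled, rep(seq_len(cfg$n_categories), times = pool_sizes))
  category_probs <- lapply(seq_len(cfg$n_categories), function(c) {
    g <- stats::rgamma(length(pools[[c]]), shape = cfg$concentration[c])
    if (sum(g) == 0) g <- rep(1, length(g))
    stats::setNames(g / sum(g), species$species_id[pools[[c]]])
  })

  ## ailment vocabulary ------------------------------------------------------
  ailments_per_cat <- 3L
  ailment_map <- tibble::tibble(
    ailment_text = as.vector(t(outer(categories, seq_len(ailments_per_cat),
                                     function(c, j) paste0(c, "-complaint-", j)))),
    icpc_category = rep(categories, each = ailments_per_cat))

  ## informants --------------------------------------------------------------
  n_inc <- cfg$n_informants
  gender <- sample(c("female", "male"), n_inc, replace = TRUE,
                   prob = c(cfg$gender_split, 1 - cfg$gender_split))
  lambda <- c(female = ztp_rate_for_mean(cfg$knowledge_rate[["female"]]),
              male = ztp_rate_for_mean(cfg$knowledge_rate[["male"]]))
  k_draw <- pmin(rztpois(n_inc, lambda[gender]), cfg$n_species)

  ks <- lapply(seq_len(n_inc), function(i) {
    srcs <- names(cfg$knowledge_source_probs)[
      stats::runif(length(cfg$knowledge_source_probs)) < cfg$knowledge_source_probs]
    if (length(srcs) == 0) srcs <- names(cfg$knowledge_source_probs)[1]
    srcs
  })
  informants <- tibble::tibble(
    informant_id = sprintf("INF%03d", seq_len(n_inc + cfg$n_excluded)),
    gender = c(gender, sample(c("female", "male"), cfg$n_excluded,
                              replace = TRUE)),
    age_band = sample_weighted(n_inc + cfg$n_excluded, cfg$age_band_weights),
    township = sample_weighted(n_inc + cfg$n_excluded, cfg$township_weights),
    education = c(sample_weighted(n_inc, cfg$education_weights),
                  rep("university+", cfg$n_excluded)),
    knowledge_sources = c(vapply(ks, paste, character(1), collapse = MULTI_SEP),
                          rep(NA_character_, cfg$n_excluded)),
    included = rep(c(TRUE, FALSE), c(n_inc, cfg$n_excluded)))

  ## use reports -------------------------------------------------------------
  cat_ail <- split(ailment_map$ailment_text, ailment_map$icpc_category)
  report_rows <- vector("list", n_inc)
  for (i in seq_len(n_inc)) {
    k <- k_draw[i]
    chosen_sp <- character(0)
    chosen_cat <- integer(0)
    attempts <- 0L
    while (length(chosen_sp) < k && attempts < 60L * k) {
      attempts <- attempts + 1L
      cat_i <- sample.int(cfg$n_categories, 1, prob = cfg$category_weights)
      p <- category_probs[[cat_i]]
      sp <- if (length(p) == 1) names(p) else sample(names(p), 1, prob = p)
      if (!(sp %in% chosen_sp)) {
        chosen_sp <- c(chosen_sp, sp)
        chosen_cat <- c(chosen_cat, cat_i)
      }
    }
    if (length(chosen_sp) == 0) next
    n_rep <- pmin(1L + stats::rpois(length(chosen_sp),
                                    cfg$reports_per_citation - 1),
                  ailments_per_cat)
    ail <- unlist(lapply(seq_along(chosen_sp), function(j) {
      sample(cat_ail[[categories[chosen_cat[j]]]], n_rep[j])
    }))
    sp_rep <- rep(chosen_sp, n_rep)
    report_rows[[i]] <- tibble::tibble(
      informant_id = informants$informant_id[i],
      species_id = sp_rep,
      ailment_text = ail)
  }
  reports <- dplyr::bind_rows(report_rows)
  sp_lookup <- match(reports$species_id, species$species_id)
  reports$part <- sp_part[sp_lookup]
  reports$preparation <- sp_prep[sp_lookup]
  reports$route <- sp_route[sp_lookup]

  ds <- survey_dataset(informants, species, reports, ailment_map = ailment_map)
  ground_truth <- list(
    config = cfg,
    category_probs = stats::setNames(category_probs, categories),
    category_pools = stats::setNames(
      lapply(pools, function(p) species$species_id[p]), categories),
    knowledge_lambda = lambda,
    knowledge_rate = cfg$knowledge_rate,
    species_attributes = tibble::tibble(species_id = species$species_id,
                                        part = sp_part, preparation = sp_prep,
                                        route = sp_route))
  list(dataset = ds, ground_truth = ground_truth)
}

#' Derive a synthetic reference flora from a survey
#'
#' Builds a reference catalogue covering a configurable fraction of the
#' survey's species, with a configurable fraction of the covered species
#' carrying a use term that matches their surveyed use — the construction
#' needed to exercise overlap, shared-use and novelty detection with known
#' expected answers.
#'
#' @param ds A [survey_dataset()].
#' @param coverage Fraction of survey species included in the reference;
#'   the reference holds `round(coverage * n_species)` of them.
#' @param agreement Fraction of the *covered* species whose reference use
#'   term matches a surveyed use; the rest receive a disjoint term.
#' @param seed Integer seed for the sampling.
#' @param name Reference label.
#' @param use_map Ailment -> use-term map; defaults to the dataset's map.
#' @return A [reference_flora()].
#' @export
make_reference_flora <- function(ds, coverage, agreement = 0, seed = 1L,
                                 name = "synthetic-reference",
                                 use_map = ds$ailment_map) {
  stopifnot(inherits(ds, "survey_dataset"),
            coverage >= 0, coverage <= 1, agreement >= 0, agreement <= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  all_sp <- unique(ds$species$canonical_name)
  n_cov <- round(coverage * length(all_sp))
  covered <- sample(all_sp, n_cov)
  uses <- NULL
  if (n_cov > 0 && !is.null(use_map)) {
    survey_uses <- survey_use_sets(ds, use_map)
    n_agree <- round(agreement * n_cov)
    agree_sp <- utils::head(covered[covered %in% names(survey_uses)], n_agree)
    uses <- stats::setNames(lapply(covered, function(sp) {
      if (sp %in% agree_sp) survey_uses[[sp]] else "unrelated-use"
    }), covered)
  }
  reference_flora(name, covered, uses = uses)
}
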