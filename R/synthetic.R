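# Synthetic scenarios: structurally faithful random inputs so every stage
# of the pipeline is testable without any external download.

#' Specify a synthetic planning scenario
#'
#' Defaults mirror the scale of the reference assessment: a ~200-million
#' state inside a country with ~950,000 annual new cancer cases, ten
#' cities of 0.5-2.8 million inhabitants whose combined population is well
#' under the state's.
#'
#' @param seed Integer seed governing all randomness in the scenario.
#' @param n_cities Number of cities to generate.
#' @param state_population State population (persons).
#' @param city_population_range `c(min, max)` city population (persons).
#' @param national_total_cases Annual national new cancer cases.
#' @param site_share_concentration Shape parameter for the symmetric
#'   Dirichlet draw of per-site proportions (1 = uniform over the simplex;
#'   larger = more even sites).
#' @param sex_split_range `c(min, max)` fraction of a site's cases that
#'   are male, drawn uniformly per site.
#' @param availability_sparsity Probability that any availability category
#'   is entirely absent (count 0) in a geography.
#' @param fraction_table Treatment-fraction table the scenario uses;
#'   defaults to the packaged canonical transcription.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(seed,
                          n_cities = 10,
                          state_population = 2e8,
                          city_population_range = c(5e5, 2.8e6),
                          national_total_cases = 948858,
                          site_share_concentration = 1,
                          sex_split_range = c(0.35, 0.65),
                          availability_sparsity = 0.3,
                          fraction_table = oncocap_fractions()) {
  if (length(city_population_range) != 2L ||
      city_population_range[1] > city_population_range[2]) {
    stop_config("city_population_range must be c(min, max) with min <= max")
  }
  if (length(sex_split_range) != 2L ||
      sex_split_range[1] > sex_split_range[2] ||
      sex_split_range[1] < 0 || sex_split_range[2] > 1) {
    stop_config("sex_split_range must be c(min, max) within [0, 1]")
  }
  if (availability_sparsity < 0 || availability_sparsity > 1) {
    stop_config("availability_sparsity must lie in [0, 1]")
  }
  if (site_share_concentration <= 0) {
    stop_config("site_share_concentration must be > 0")
  }
  if (n_cities * city_population_range[2] >= state_population) {
    stop_config("cities could exceed the state population; shrink n_cities ",
                "or the population range")
  }
  validate_fractions(fraction_table)
  structure(
    list(seed = as.integer(seed), n_cities = n_cities,
         state_population = state_population,
         city_population_range = city_population_range,
         national_total_cases = national_total_cases,
         site_share_concentration = site_share_concentration,
         sex_split_range = sex_split_range,
         availability_sparsity = availability_sparsity,
         fraction_table = fraction_table),
    class = "scenario_spec"
  )
}

#' Largest-remainder apportionment
#'
#' Allocates an integer `total` across categories proportionally to
#' `weights`, assigning each category the floor of its exact quota and
#' distributing the leftover units to the largest fractional remainders.
#' The result always sums to `total` exactly.
#'
#' @param total Non-negative integer to allocate.
#' @param weights Non-negative weights, not all zero.
#' @return Integer vector of the same length as `weights`, summing to
#'   `total`.
#' @export
apportion_largest_remainder <- function(total, weights) {
  if (!is_count(total)) stop_domain("total must be >= 0")
  if (any(weights < 0) || sum(weights) == 0) {
    stop_domain("weights must be >= 0 and not all zero")
  }
  quota <- total * weights / sum(weights)
  base <- floor(quota)
  leftover <- round(total - sum(base))
  if (leftover > 0) {
    top <- order(quota - base, decreasing = TRUE)[seq_len(leftover)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

# all categories an inventory can carry, for the generator
all_staff_categories <- function() {
  c("radiation_clinical_oncologists", "pathologists",
    "palliative_care_specialists", "surgical_oncologists",
    names(subspecialty_sites), "oncology_nurses", "oncopharmacists",
    "pharmacy_technicians", "rt_technicians", "medical_physicists",
    "linac_engineers", "rt_nurses")
}

all_equipment_categories <- function() {
  c("teletherapy", "brachytherapy", "ct_simulator", "tps", "dosimetry_qa")
}

#' Generate a synthetic scenario
#'
#' Produces a country/state/city geography set, a national incidence table
#' and per-geography availability inventories, deterministically for a
#' given seed. Site proportions come from a symmetric Dirichlet draw;
#' listed sites carry 85% of the national total (the rest is "other"
#' cancers, as in real planning tables that list only the most common
#' sites); counts are reconciled to integers by largest-remainder
#' apportionment, and sex splits are reconciled so men + women equals the
#' both-sexes count exactly. The country population is fixed at six times
#' the state's.
#'
#' @param spec A [scenario_spec()].
#' @return List with `spec`, `country`, `state`, `cities` (list of
#'   [geography()]), `national` (an [incidence_table()]), and
#'   `inventories` (named list of [availability_inventory()], one for the
#'   state and each city).
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  country <- geography("synthetic-country", 6 * spec$state_population,
                       "country")
  state <- geography("synthetic-state", spec$state_population, "state",
                     parent = country$name)
  cities <- lapply(seq_len(spec$n_cities), function(i) {
    pop <- round(stats::runif(1, spec$city_population_range[1],
                              spec$city_population_range[2]))
    geography(sprintf("city-%02d", i), pop, "city", parent = state$name)
  })
  names(cities) <- vapply(cities, `[[`, character(1), "name")

  sites <- spec$fraction_table$site[spec$fraction_table$level == "group"]
  k <- length(sites)
  props <- stats::rgamma(k, shape = spec$site_share_concentration)
  listed_total <- round_half_up(0.85 * spec$national_total_cases)
  both <- apportion_largest_remainder(listed_total, props)
  frac_male <- stats::runif(k, spec$sex_split_range[1],
                            spec$sex_split_range[2])
  men <- round_half_up(both * frac_male)
  women <- both - men
  national <- incidence_table(
    country, 2008,
    data.frame(site = sites, cases_both = both, cases_men = men,
               cases_women = women, stringsAsFactors = FALSE),
    total_all_cancers = spec$national_total_cases
  )

  geos <- c(list(state), cities)
  inventories <- lapply(geos, function(g) {
    scale <- if (g$level == "state") 30 else 3
    draw <- function(nm) {
      counts <- ifelse(
        stats::runif(length(nm)) < spec$availability_sparsity, 0,
        stats::rpois(length(nm), scale))
      stats::setNames(counts, nm)
    }
    availability_inventory(
      g$name,
      staff = draw(all_staff_categories()),
      beds = if (stats::runif(1) < spec$availability_sparsity) 0 else
        stats::rpois(1, 10 * scale),
      equipment = draw(all_equipment_categories())
    )
  })
  names(inventories) <- vapply(geos, `[[`, character(1), "name")

  list(spec = spec, country = country, state = state, cities = cities,
       national = national, inventories = inventories)
}

#' Perturb capacity norms for sensitivity analysis
#'
#' Multiplies every norm by an independent uniform factor in
#' `[1 - relative_range, 1 + relative_range]`; perturbed values are
#' re-rounded to integers of at least 1 (all norms are whole-unit rates).
#' `relative_range = 0` is an exact identity.
#'
#' @param norms A [capacity_norms()] object.
#' @param relative_range Fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return A perturbed `capacity_norms` object.
#' @export
perturb_norms <- function(norms, relative_range, seed) {
  stopifnot(inherits(norms, "capacity_norms"))
  if (relative_range < 0 || relative_range >= 1) {
    stop_domain("relative_range must lie in [0, 1)")
  }
  if (relative_range == 0) return(norms)
  set.seed(as.integer(seed))
  vals <- lapply(unclass(norms), function(v) {
    max(1, round(v * stats::runif(1, 1 - relative_range,
                                  1 + relative_range)))
  })
  do.call(capacity_norms, vals)
}

#' Write a generated scenario to a directory
#'
#' Emits a geography config (JSON), a national incidence CSV and a long
#' availability CSV, each with the generating seed in a comment header,
#' consumable unchanged by [read_geographies()], [read_incidence()] and
#' [read_inventory()].
#'
#' @param scenario Output of [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seed <- scenario$spec$seed
  geo_path <- file.path(dir, "geographies.json")
  geos <- c(list(scenario$country, scenario$state), scenario$cities)
  jsonlite::write_json(
    lapply(geos, function(g) {
      out <- list(name = g$name, population = g$population, level = g$level)
      if (!is.null(g$parent)) out$parent <- g$parent
      out
    }),
    geo_path, auto_unbox = TRUE, pretty = TRUE)

  inc_path <- file.path(dir, "incidence.csv")
  write_incidence(scenario$national, inc_path,
                  comment = paste0("synthetic scenario, seed ", seed))

  inv_path <- file.path(dir, "availability.csv")
  rows <- do.call(rbind, lapply(scenario$inventories, function(inv) {
    data.frame(
      geography = inv$geography,
      category = c(names(inv$staff), "beds", names(inv$equipment)),
      count = c(inv$staff, inv$beds, inv$equipment),
      flag = "",
      stringsAsFactors = FALSE
    )
  }))
  con <- file(inv_path, "w")
  writeLines(paste0("# synthetic scenario, seed ", seed), con)
  utils::write.csv(rows, con, row.names = FALSE)
  close(con)
  invisible(c(geo_path, inc_path, inv_path))
}
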