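# Packaged reference tables: a complete, plain-text transcription of the
# published Uttar Pradesh (UP) needs assessment, so the whole pipeline runs
# out of the box and the published state-level results can be reproduced.

oncocap_file <- function(...) {
  system.file("extdata", ..., package = "oncocap", mustWork = TRUE)
}

#' Packaged geographies: India, Uttar Pradesh and its ten radiotherapy
#' cities
#'
#' Populations are 2011 Indian census figures, included for illustration
#' and for population-share extrapolation when the user supplies no
#' explicit share. (The reference assessment derived its UP/India share
#' from case totals, not from these figures.)
#'
#' @return Named list of [geography()] objects.
#' @export
oncocap_geographies <- function() {
  read_geographies(oncocap_file("geographies_up.json"))
}

#' Packaged incidence table: most common cancers in Uttar Pradesh, 2008
#'
#' Annual new cases by site and sex, extrapolated from GLOBOCAN 2008
#' national estimates by population share. The all-cancers total (160,296)
#' exceeds the sum of the 14 listed sites; the remainder is less common
#' cancers.
#'
#' @return An [incidence_table()] for Uttar Pradesh.
#' @export
oncocap_incidence_up <- function() {
  read_incidence(oncocap_file("up_incidence_2008.csv"),
                 oncocap_geographies()[["Uttar Pradesh"]], 2008)
}

#' Packaged treatment-fraction table
#'
#' Percentage of patients requiring surgery, chemotherapy and radiotherapy
#' and the average length of stay (ALOS, days) per modality, at site-group
#' and subtype level. Includes Kaposi's sarcoma, which carries treatment
#' fractions although it is not among the listed incidence sites.
#'
#' @return Data frame of fraction records (see [read_fractions()]).
#' @export
oncocap_fractions <- function() {
  read_fractions(oncocap_file("treatment_fractions.csv"))
}

#' Packaged subtype-to-group site mapping
#'
#' Explicit, user-editable mapping from subtype labels (cervix uteri,
#' larynx, ...) to their site group (gynecological, head and neck, ...).
#' Nothing is inferred from label text.
#'
#' @return Data frame with columns `subtype`, `group`.
#' @export
oncocap_site_groups <- function() {
  utils::read.csv(oncocap_file("site_groups.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Packaged availability inventories for UP and its ten cities
#'
#' Survey-based counts of specialists, beds and radiotherapy equipment.
#' Oncopharmacists, pharmacy technicians, RT nurses and linac engineers
#' are flagged as specializations that do not exist in UP (available 0).
#' Gastro-surgeons appear as their own category; the reference assessment
#' pooled them with surgical oncologists via
#' [merge_available_categories()].
#'
#' @return Named list of [availability_inventory()] objects.
#' @export
oncocap_availability <- function() {
  read_inventory(oncocap_file("up_availability.csv"))
}

#' Packaged state-level planning figures
#'
#' The published state-level driving quantities: total cases, the
#' published modality totals (which were computed from finer-grained
#' inputs than the published site-group tables and therefore do not equal
#' their group-level recomputation), and the published bed requirement.
#' Used as explicit overrides for the capacity stage.
#'
#' @return Named numeric vector: `total_cases`, `requiring_surgery`,
#'   `requiring_chemotherapy`, `requiring_radiotherapy`, `beds_needed`,
#'   `national_cases_2008`, `national_cases_2016`.
#' @export
oncocap_reference <- function() {
  df <- utils::read.csv(oncocap_file("up_reference.csv"),
                        comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(df$value, df$quantity)
}

#' Reproduce the state-level UP needs assessment
#'
#' Runs the full pipeline on the packaged tables: demand from incidence
#' and treatment fractions, capacity requirements from the driving
#' totals, gap analysis against the surveyed inventory (with
#' gastro-surgeons pooled into surgical oncologists).
#'
#' With `use_published_totals = TRUE` (default) the published modality
#' totals and bed requirement drive the capacity stage, reproducing the
#' published staffing and equipment results; with `FALSE` the group-level
#' recomputation drives it, which yields lower totals (the published
#' figures were computed from unpublished subtype-level inputs).
#'
#' @param use_published_totals Drive capacity from the published totals
#'   (`TRUE`) or from the group-level recomputation (`FALSE`).
#' @param norms A [capacity_norms()] object.
#' @return A `gap_report` for Uttar Pradesh.
#' @examples
#' rep <- up_state_assessment()
#' subset(rep$rows, category == "radiation_clinical_oncologists")
#' @export
up_state_assessment <- function(use_published_totals = TRUE,
                                norms = capacity_norms()) {
  inc <- oncocap_incidence_up()
  demand <- compute_demand(inc, oncocap_fractions(), level = "group")
  if (use_published_totals) {
    ref <- oncocap_reference()
    demand <- override_totals(demand,
                              surgery = ref[["requiring_surgery"]],
                              chemo = ref[["requiring_chemotherapy"]],
                              rt = ref[["requiring_radiotherapy"]])
    beds <- ref[["beds_needed"]]
  } else {
    beds <- beds_needed(demand)
  }
  req <- compute_requirements(
    geography_name = inc$geography$name, level = "state",
    total_cases = inc$total_all_cancers,
    site_cases = stats::setNames(inc$records$cases_both, inc$records$site),
    surgical_patients = demand$totals[["surgery"]],
    rt_patients = demand$totals[["rt"]],
    beds = beds, nonstop_allowed = FALSE, norms = norms
  )
  inv <- oncocap_availability()[[inc$geography$name]]
  inv <- merge_available_categories(
    inv, list(list(from = "gastro_surgeons", to = "surgical_oncologists")))
  compute_gaps(req, inv)
}
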