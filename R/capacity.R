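# Capacity model: demand -> staff, wards, equipment, with ceiling rounding
# throughout. Ceiling (not half-up) is the one rounding rule consistent with
# whole-unit planning: a fraction of a specialist's workload still needs a
# specialist.

#' Capacity-planning norms
#'
#' All staffing ratios, ward constants, surgical throughput constants,
#' radiotherapy staffing/equipment ratios and the per-city minimum, as a
#' single overridable object. Defaults encode a needs assessment built on
#' IAEA-style recommendations for low and middle income countries:
#' combined radiation/clinical oncologists at 5 per 1000 new cancer
#' patients; pathologists and palliative care specialists at 2 per 1000;
#' organ-system subspecialists at 2 per 1000 site-specific cases; surgical
#' oncologists sized by annual theatre throughput (2 surgeries/day, 5
#' days/week, 48 weeks/year); a 24-bed oncology ward staffed by 15 nurses,
#' 4 oncopharmacists and 6 pharmacy technicians; per 1000 radiotherapy
#' patients 12 RT technicians, 4 medical physicists, 1 linac engineer,
#' 4 RT nurses and one of each major equipment item (two megavoltage
#' teletherapy units unless near-non-stop operation of a single unit is
#' acceptable); and at least two professionals of each kind per city, so a
#' single departure does not interrupt coverage.
#'
#' @param ... Named overrides of any default (see `formals(capacity_norms)`).
#' @return An object of class `capacity_norms` (named list).
#' @seealso [read_norms()] for file-based overrides.
#' @export
capacity_norms <- function(rco_per_1000_cases = 5,
                           pathologists_per_1000_cases = 2,
                           palliative_per_1000_cases = 2,
                           subspecialists_per_1000_site_cases = 2,
                           surgeries_per_day = 2,
                           days_per_week = 5,
                           weeks_per_year = 48,
                           ward_size_beds = 24,
                           nurses_per_ward = 15,
                           oncopharmacists_per_ward = 4,
                           pharmacy_techs_per_ward = 6,
                           rt_techs_per_1000_rt = 12,
                           physicists_per_1000_rt = 4,
                           linac_engineers_per_1000_rt = 1,
                           rt_nurses_per_1000_rt = 4,
                           equipment_per_1000_rt = 1,
                           teletherapy_units_if_not_nonstop = 2,
                           city_minimum = 2) {
  norms <- as.list(environment())
  for (nm in names(norms)) {
    v <- norms[[nm]]
    if (!is_scalar_number(v) || v <= 0) {
      stop_domain("norm '", nm, "' must be a single number > 0")
    }
  }
  structure(norms, class = "capacity_norms")
}

#' Read capacity norms from a YAML or JSON file
#'
#' Fields omitted from the file take the package defaults; unknown fields
#' are an error (typically a typo in a norm name).
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file of norm overrides.
#' @return A `capacity_norms` object.
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop_config("norms file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(formals(capacity_norms)))
  if (length(unknown)) {
    stop_config("unknown norm field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(capacity_norms, raw)
}

#' @export
print.capacity_norms <- function(x, ...) {
  cat("<capacity_norms>\n")
  for (nm in names(x)) cat(sprintf("  %s: %s\n", nm, x[[nm]]))
  invisible(x)
}

#' Ratio-based staff need
#'
#' `ceiling(patients * per_1000 / 1000)`: any started block of 1000
#' patients requires the full ratio complement.
#'
#' @param patients Annual patient count (>= 0).
#' @param per_1000 Staffing rate per 1000 patients (> 0).
#' @return Required specialist count (integer).
#' @examples
#' ratio_staff_need(160296, 5)  # 802 radiation/clinical oncologists
#' ratio_staff_need(12026, 2)   # 25 hematologist-oncologists
#' @export
ratio_staff_need <- function(patients, per_1000) {
  if (!is_count(patients)) stop_domain("patients must be >= 0")
  if (!is_scalar_number(per_1000) || per_1000 <= 0) {
    stop_domain("per_1000 must be > 0")
  }
  ceiling(patients * per_1000 / 1000)
}

#' Surgical oncologists needed
#'
#' Annual throughput per surgeon is `surgeries_per_day * days_per_week *
#' weeks_per_year` (default 2 x 5 x 48 = 480 operations); the need is the
#' ceiling of surgical patients over that throughput.
#'
#' @param surgical_patients Patients requiring surgery annually (>= 0).
#' @param norms A [capacity_norms()] object.
#' @return Required surgeon count (integer).
#' @export
surgeon_need <- function(surgical_patients, norms = capacity_norms()) {
  if (!is_count(surgical_patients)) stop_domain("surgical_patients must be >= 0")
  throughput <- norms$surgeries_per_day * norms$days_per_week *
    norms$weeks_per_year
  if (throughput <= 0) stop_config("surgeon annual throughput must be > 0")
  ceiling(surgical_patients / throughput)
}

#' Ward count and ward-based staffing
#'
#' Wards are fixed-size in-patient units; staffing scales in exact
#' multiples of the ward count.
#'
#' @param beds Oncology beds needed (>= 0).
#' @param norms A [capacity_norms()] object.
#' @return List with `wards`, `nurses`, `oncopharmacists`,
#'   `pharmacy_techs`.
#' @examples
#' ward_staffing(2892)  # 121 wards -> 1815 nurses, 484 + 726 pharmacy staff
#' @export
ward_staffing <- function(beds, norms = capacity_norms()) {
  if (!is_count(beds)) stop_domain("beds must be >= 0")
  wards <- ceiling(beds / norms$ward_size_beds)
  list(
    wards = wards,
    nurses = wards * norms$nurses_per_ward,
    oncopharmacists = wards * norms$oncopharmacists_per_ward,
    pharmacy_techs = wards * norms$pharmacy_techs_per_ward
  )
}

#' Radiotherapy staff needed
#'
#' Each profession scales as `ceiling(rt_patients * rate / 1000)`.
#'
#' @param rt_patients Patients requiring radiotherapy annually (>= 0).
#' @param norms A [capacity_norms()] object.
#' @return Named vector: `rt_technicians`, `medical_physicists`,
#'   `linac_engineers`, `rt_nurses`.
#' @examples
#' rt_staff_need(94808)  # 1138, 380, 95, 380
#' @export
rt_staff_need <- function(rt_patients, norms = capacity_norms()) {
  if (!is_count(rt_patients)) stop_domain("rt_patients must be >= 0")
  c(
    rt_technicians = ratio_or_zero(rt_patients, norms$rt_techs_per_1000_rt),
    medical_physicists = ratio_or_zero(rt_patients, norms$physicists_per_1000_rt),
    linac_engineers = ratio_or_zero(rt_patients,
                                    norms$linac_engineers_per_1000_rt),
    rt_nurses = ratio_or_zero(rt_patients, norms$rt_nurses_per_1000_rt)
  )
}

# ratio_staff_need but tolerating patients = 0 without special-casing callers
ratio_or_zero <- function(patients, per_1000) {
  if (patients == 0) 0 else ratio_staff_need(patients, per_1000)
}

#' Radiotherapy equipment needed
#'
#' Equipment scales in blocks of 1000 radiotherapy patients: one
#' brachytherapy unit, CT simulator, treatment planning system and
#' dosimetry/QA package per block. Megavoltage teletherapy is one unit per
#' block only if that unit may run nearly non-stop; otherwise two units
#' per block, so maintenance and downtime do not interrupt treatment.
#'
#' @param rt_patients Patients requiring radiotherapy annually (>= 0).
#' @param nonstop_allowed Is near-non-stop operation of a single
#'   teletherapy unit acceptable? Default `FALSE` (two units per block).
#' @param norms A [capacity_norms()] object.
#' @return Named vector: `teletherapy`, `brachytherapy`, `ct_simulator`,
#'   `tps`, `dosimetry_qa`.
#' @examples
#' rt_equipment_need(94808)  # teletherapy 190, all others 95
#' @export
rt_equipment_need <- function(rt_patients, nonstop_allowed = FALSE,
                              norms = capacity_norms()) {
  if (!is_count(rt_patients)) stop_domain("rt_patients must be >= 0")
  blocks <- ceiling(rt_patients / 1000) * norms$equipment_per_1000_rt
  tele <- if (nonstop_allowed) blocks else
    blocks * norms$teletherapy_units_if_not_nonstop
  c(teletherapy = tele, brachytherapy = blocks, ct_simulator = blocks,
    tps = blocks, dosimetry_qa = blocks)
}

# site labels whose case counts drive organ-system subspecialists
subspecialty_sites <- c(
  gynecologic_oncologists = "gynecological",
  urologic_oncologists = "urological",
  neurologic_oncologists = "brain and nervous system",
  hematologist_oncologists = "hematological"
)

#' Full requirement summary for one geography
#'
#' Assembles every staffing, bed, ward and equipment requirement from the
#' driving quantities. Ratio-based specialists are driven by total cancer
#' cases; organ-system subspecialists by their site's cases; surgical
#' oncologists by surgical patients; ward staff by beds; radiotherapy
#' staff and equipment by radiotherapy patients. The radiation/clinical
#' oncologist need is driven by total cancer cases (they prescribe both
#' chemotherapy and radiotherapy), not by radiotherapy patients alone.
#'
#' @param geography_name Label for the geography.
#' @param level `"country"`, `"state"` or `"city"`.
#' @param total_cases Annual new cancer cases, all sites.
#' @param site_cases Named numeric vector of per-site cases; sites named in
#'   `gynecological`, `urological`, `brain and nervous system`,
#'   `hematological` drive subspecialists (missing sites contribute 0).
#' @param surgical_patients,rt_patients Patients requiring surgery /
#'   radiotherapy annually.
#' @param beds Oncology beds needed.
#' @param nonstop_allowed Passed to [rt_equipment_need()].
#' @param norms A [capacity_norms()] object.
#' @return An object of class `requirement_summary`: `geography`, `level`,
#'   `staff` (named vector), `beds`, `wards`, `equipment` (named vector),
#'   `floored` (categories raised by the city minimum; empty here, see
#'   [apply_city_minimum()]).
#' @export
compute_requirements <- function(geography_name, level, total_cases,
                                 site_cases = numeric(0),
                                 surgical_patients, rt_patients, beds,
                                 nonstop_allowed = FALSE,
                                 norms = capacity_norms()) {
  if (!is_count(total_cases)) stop_domain("total_cases must be >= 0")
  ward <- ward_staffing(beds, norms)
  sub <- vapply(subspecialty_sites, function(site) {
    n <- if (site %in% names(site_cases)) site_cases[[site]] else 0
    ratio_or_zero(n, norms$subspecialists_per_1000_site_cases)
  }, numeric(1))
  staff <- c(
    radiation_clinical_oncologists =
      ratio_or_zero(total_cases, norms$rco_per_1000_cases),
    pathologists = ratio_or_zero(total_cases,
                                 norms$pathologists_per_1000_cases),
    palliative_care_specialists =
      ratio_or_zero(total_cases, norms$palliative_per_1000_cases),
    surgical_oncologists = surgeon_need(surgical_patients, norms),
    sub,
    oncology_nurses = ward$nurses,
    oncopharmacists = ward$oncopharmacists,
    pharmacy_technicians = ward$pharmacy_techs,
    rt_staff_need(rt_patients, norms)
  )
  structure(
    list(geography = geography_name, level = level, staff = staff,
         beds = beds, wards = ward$wards,
         equipment = rt_equipment_need(rt_patients, nonstop_allowed, norms),
         floored = character(0)),
    class = "requirement_summary"
  )
}

#' @export
print.requirement_summary <- function(x, ...) {
  cat(sprintf("<requirement_summary> %s (%s): %d beds in %d wards\n",
              x$geography, x$level, x$beds, x$wards))
  print(x$staff)
  print(x$equipment)
  invisible(x)
}

#' Apply the per-city staffing floor
#'
#' Every staff category in a city is raised to at least the city minimum
#' (default two), so that coverage survives one person leaving or taking
#' leave. Beds, wards and equipment are unaffected (teletherapy redundancy
#' is governed by its own two-unit rule). The floor applies to cities
#' only; state and country needs are computed directly from their own
#' totals, never as sums of floored city values.
#'
#' @param requirements A `requirement_summary` with `level = "city"`.
#' @param norms A [capacity_norms()] object.
#' @return The summary with floored staff counts; `floored` lists the
#'   categories that were raised (used for report footnotes).
#' @export
apply_city_minimum <- function(requirements, norms = capacity_norms()) {
  stopifnot(inherits(requirements, "requirement_summary"))
  if (!identical(requirements$level, "city")) {
    stop_domain("the city minimum applies only to city-level summaries, got ",
                requirements$level)
  }
  low <- requirements$staff < norms$city_minimum
  requirements$floored <- names(requirements$staff)[low]
  requirements$staff[low] <- norms$city_minimum
  requirements
}
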