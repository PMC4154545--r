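#' Patients requiring a treatment modality at one site
#'
#' Whole-patient demand: `round_half_up(cases * pct / 100)`. Vectorised over
#' both arguments.
#'
#' @param cases Annual new cases at the site (>= 0).
#' @param pct Percentage of those cases requiring the modality, in
#'   \[0, 100\].
#' @return Number of patients (integer-valued).
#' @examples
#' site_modality_demand(3689, 100)  # every brain-tumour patient has surgery
#' site_modality_demand(28934, 40)  # 11574
#' @export
site_modality_demand <- function(cases, pct) {
  if (any(is.na(cases)) || any(cases < 0)) {
    stop_domain("cases must be >= 0")
  }
  if (any(is.na(pct)) || any(pct < 0 | pct > 100)) {
    stop_domain("pct must lie in [0, 100]")
  }
  round_half_up(cases * pct / 100)
}

#' Read a treatment-fraction table
#'
#' Columns: `site`, `level` (`group` or `subtype`), `pct_surgery`,
#' `alos_surgery`, `pct_chemo`, `alos_chemo`, `pct_rt`, `alos_rt`.
#' Percentages in \[0, 100\]; average lengths of stay (ALOS) in days. A
#' modality a site never uses has `pct = 0` and `alos = 0`.
#'
#' @param path CSV file path. Lines starting with `#` are ignored.
#' @return Data frame of fraction records.
#' @seealso [oncocap_fractions()] for the packaged canonical table.
#' @export
read_fractions <- function(path) {
  if (!file.exists(path)) stop_config("fractions file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("site", "level", "pct_surgery", "alos_surgery", "pct_chemo",
              "alos_chemo", "pct_rt", "alos_rt")
  if (!all(needed %in% names(df))) {
    stop_config("fractions file must have columns: ",
                paste(needed, collapse = ", "))
  }
  validate_fractions(df)
  df
}

validate_fractions <- function(df) {
  for (col in c("pct_surgery", "pct_chemo", "pct_rt")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0 | df[[col]] > 100)
    if (length(bad)) {
      stop_domain(col, " outside [0, 100] for site(s): ",
                  paste(df$site[bad], collapse = ", "))
    }
  }
  for (col in c("alos_surgery", "alos_chemo", "alos_rt")) {
    bad <- which(is.na(df[[col]]) | df[[col]] < 0)
    if (length(bad)) {
      stop_domain(col, " must be >= 0 for site(s): ",
                  paste(df$site[bad], collapse = ", "))
    }
  }
  invisible(df)
}

#' Compute per-modality treatment demand and bed-days
#'
#' Applies per-site treatment fractions to an incidence table. Every
#' incident site with cases must have a fraction record at the chosen
#' level; missing records are a configuration error, named explicitly,
#' never silently imputed. Bed-days per modality are
#' `sum over sites of demand * ALOS`.
#'
#' @param incidence An [incidence_table()] whose sites use labels of the
#'   chosen level.
#' @param fractions Fraction data frame (see [read_fractions()]).
#' @param level `"group"` or `"subtype"`; selects fraction records.
#' @return An object of class `modality_demand` with elements `geography`,
#'   `per_site` (data frame: site, cases, surgery, chemo, rt), `totals`
#'   and `bed_days` (named vectors over surgery/chemo/rt),
#'   `totals_source` (`"computed"`).
#' @seealso [override_totals()] to substitute externally supplied totals,
#'   [beds_needed()].
#' @export
compute_demand <- function(incidence, fractions, level = c("group", "subtype")) {
  stopifnot(inherits(incidence, "incidence_table"))
  level <- match.arg(level)
  validate_fractions(fractions)
  fr <- fractions[fractions$level == level, , drop = FALSE]
  rec <- incidence$records
  missing <- setdiff(rec$site[rec$cases_both > 0], fr$site)
  if (length(missing)) {
    stop_config("no ", level, "-level fraction record for site(s): ",
                paste(missing, collapse = ", "))
  }
  fr <- fr[match(rec$site, fr$site), , drop = FALSE]
  # zero-case sites may lack a fraction record; they contribute nothing
  blank <- is.na(fr$site)
  fr[blank, c("pct_surgery", "alos_surgery", "pct_chemo", "alos_chemo",
              "pct_rt", "alos_rt")] <- 0
  per_site <- data.frame(
    site = rec$site,
    cases = rec$cases_both,
    surgery = site_modality_demand(rec$cases_both, fr$pct_surgery),
    chemo = site_modality_demand(rec$cases_both, fr$pct_chemo),
    rt = site_modality_demand(rec$cases_both, fr$pct_rt),
    stringsAsFactors = FALSE
  )
  totals <- c(surgery = sum(per_site$surgery), chemo = sum(per_site$chemo),
              rt = sum(per_site$rt))
  bed_days <- c(
    surgery = sum(per_site$surgery * fr$alos_surgery),
    chemo = sum(per_site$chemo * fr$alos_chemo),
    rt = sum(per_site$rt * fr$alos_rt)
  )
  structure(
    list(geography = incidence$geography$name, level = level,
         per_site = per_site, totals = totals, bed_days = bed_days,
         computed_totals = totals, totals_source = "computed"),
    class = "modality_demand"
  )
}

#' @export
print.modality_demand <- function(x, ...) {
  cat(sprintf("<modality_demand> %s (%s level, totals %s)\n", x$geography,
              x$level, x$totals_source))
  cat(sprintf("  surgery %s, chemotherapy %s, radiotherapy %s patients\n",
              format(x$totals[["surgery"]], big.mark = ","),
              format(x$totals[["chemo"]], big.mark = ","),
              format(x$totals[["rt"]], big.mark = ",")))
  invisible(x)
}

#' Replace computed modality totals with externally supplied ones
#'
#' Planning documents sometimes publish modality totals that cannot be
#' recomputed from their own published site-level inputs (for example when
#' the original computation used unpublished subtype counts). This keeps
#' both numbers: the computed totals stay in `computed_totals`, the
#' supplied ones drive downstream capacity stages, and `totals_source`
#' records the substitution.
#'
#' @param demand A `modality_demand` object.
#' @param surgery,chemo,rt Replacement totals (patients); `NULL` keeps the
#'   computed value for that modality.
#' @return The modified `modality_demand`.
#' @export
override_totals <- function(demand, surgery = NULL, chemo = NULL, rt = NULL) {
  stopifnot(inherits(demand, "modality_demand"))
  repl <- list(surgery = surgery, chemo = chemo, rt = rt)
  for (m in names(repl)) {
    v <- repl[[m]]
    if (!is.null(v)) {
      if (!is_count(v)) stop_domain("override for ", m, " must be >= 0")
      demand$totals[[m]] <- v
    }
  }
  if (!identical(demand$totals, demand$computed_totals)) {
    demand$totals_source <- "override"
  }
  demand
}

#' Oncology beds needed per day
#'
#' Total annual in-patient bed-days over the three modalities, divided by
#' 365 and rounded up: the steady-state daily bed requirement.
#'
#' @param demand A `modality_demand` object with `bed_days` populated.
#' @return Number of beds (integer).
#' @export
beds_needed <- function(demand) {
  stopifnot(inherits(demand, "modality_demand"))
  ceiling(sum(demand$bed_days) / 365)
}
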