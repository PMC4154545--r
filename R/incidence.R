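#' Construct an incidence table
#'
#' Holds annual new cancer case counts by site (and optionally by sex) for
#' one geography and year, plus an all-cancers total. The total may exceed
#' the sum of listed sites because a table typically lists only the most
#' common sites; the remainder is "other" cancers.
#'
#' @param geography A [geography()] object.
#' @param year Calendar year the counts refer to.
#' @param records Data frame with columns `site` (character), `cases_both`
#'   (numeric, required), `cases_men`, `cases_women` (numeric, `NA` when not
#'   reported -- distinct from 0).
#' @param total_all_cancers Annual new cases over all sites, listed or not.
#' @return An object of class `incidence_table`.
#' @seealso [validate_incidence()], [extrapolate_incidence()]
#' @export
incidence_table <- function(geography, year, records, total_all_cancers) {
  if (!inherits(geography, "geography")) {
    stop_config("geography must be a geography object")
  }
  if (!is.data.frame(records)) stop_config("records must be a data frame")
  needed <- c("site", "cases_both")
  if (!all(needed %in% names(records))) {
    stop_config("records must have columns: ", paste(needed, collapse = ", "))
  }
  for (col in c("cases_men", "cases_women")) {
    if (!col %in% names(records)) records[[col]] <- NA_real_
  }
  if (anyNA(records$site) || any(!nzchar(records$site))) {
    stop_config("every record needs a site label")
  }
  if (anyDuplicated(records$site)) {
    stop_config("duplicate site labels: ",
                paste(unique(records$site[duplicated(records$site)]),
                      collapse = ", "))
  }
  if (!is_count(total_all_cancers)) {
    stop_domain("total_all_cancers must be a single non-negative number")
  }
  structure(
    list(geography = geography, year = as.integer(year),
         records = records[, c("site", "cases_both", "cases_men",
                               "cases_women")],
         total_all_cancers = as.numeric(total_all_cancers)),
    class = "incidence_table"
  )
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("<incidence_table> %s, %d: %d sites, %s cases in all\n",
              x$geography$name, x$year, nrow(x$records),
              format(x$total_all_cancers, big.mark = ",")))
  print(utils::head(x$records, 20))
  invisible(x)
}

#' Validate an incidence table
#'
#' Checks, per record: non-negative counts; when both sex-specific counts
#' are reported, men + women must equal the both-sexes count. Checks, per
#' table: the all-cancers total must be at least the sum of listed sites.
#' Violations are data, not errors: an empty character vector means the
#' table is clean.
#'
#' @param table An [incidence_table()].
#' @return Character vector of human-readable violation descriptions
#'   (empty when valid).
#' @examples
#' g <- geography("toy", 1e6, "state")
#' tab <- incidence_table(g, 2008,
#'   data.frame(site = "lung", cases_both = 9894,
#'              cases_men = 7942, cases_women = 1952),
#'   total_all_cancers = 10000)
#' validate_incidence(tab)  # character(0)
#' @export
validate_incidence <- function(table) {
  stopifnot(inherits(table, "incidence_table"))
  r <- table$records
  out <- character(0)
  for (i in seq_len(nrow(r))) {
    site <- r$site[i]
    for (col in c("cases_both", "cases_men", "cases_women")) {
      v <- r[[col]][i]
      if (!is.na(v) && v < 0) {
        out <- c(out, sprintf("%s: %s is negative (%s)", site, col, v))
      }
    }
    m <- r$cases_men[i]; w <- r$cases_women[i]; b <- r$cases_both[i]
    if (!is.na(m) && !is.na(w) && !is.na(b) && m + w != b) {
      out <- c(out, sprintf(
        "%s: men (%s) + women (%s) = %s, but both-sexes count is %s",
        site, m, w, m + w, b))
    }
  }
  listed <- sum(r$cases_both, na.rm = TRUE)
  if (table$total_all_cancers < listed) {
    out <- c(out, sprintf(
      "all-cancers total (%s) is below the sum of listed sites (%s)",
      table$total_all_cancers, listed))
  }
  out
}

#' Extrapolate national incidence to a sub-national geography
#'
#' Scales every per-site count and the all-cancers total by a population
#' share. The share is either given explicitly or derived as
#' `target$population / national$geography$population`. Per-site counts are
#' rounded half-up to whole cases; the all-cancers total is scaled and
#' rounded independently (not as the sum of rounded sites) because it
#' covers unlisted sites.
#'
#' @param national An [incidence_table()] for the reference geography.
#' @param target A [geography()] the counts are scaled to.
#' @param share Optional explicit share in (0, 1]; when `NULL`, derived
#'   from the two populations.
#' @return An [incidence_table()] for `target`.
#' @examples
#' # halving a toy table
#' g <- geography("country", 2e6, "country")
#' tab <- incidence_table(g, 2008,
#'   data.frame(site = c("siteA", "siteB"), cases_both = c(100, 50)),
#'   total_all_cancers = 200)
#' half <- extrapolate_incidence(tab, geography("state", 1e6, "state"))
#' half$records$cases_both  # 50 25
#' @export
extrapolate_incidence <- function(national, target, share = NULL) {
  stopifnot(inherits(national, "incidence_table"),
            inherits(target, "geography"))
  if (is.null(share)) {
    np <- national$geography$population
    tp <- target$population
    if (is.na(np) || is.na(tp) || np <= 0) {
      stop_config("populations unavailable; supply an explicit share")
    }
    share <- tp / np
  }
  if (!is_scalar_number(share) || share <= 0 || share > 1) {
    stop_domain("share must lie in (0, 1], got ", share)
  }
  if (national$total_all_cancers <= 0) {
    stop_domain("national all-cancers total must be > 0")
  }
  r <- national$records
  scale_col <- function(x) ifelse(is.na(x), NA_real_, round_half_up(x * share))
  r$cases_both <- scale_col(r$cases_both)
  r$cases_men <- scale_col(r$cases_men)
  r$cases_women <- scale_col(r$cases_women)
  incidence_table(target, national$year, r,
                  round_half_up(national$total_all_cancers * share))
}

#' Define a case-count growth projection
#'
#' @param base_year,horizon_year Calendar years, `horizon_year > base_year`.
#' @param base_total,horizon_total National case counts in those years
#'   (both > 0).
#' @return An object of class `growth_projection`.
#' @export
growth_projection <- function(base_year, base_total, horizon_year,
                              horizon_total) {
  if (horizon_year <= base_year) {
    stop_domain("horizon_year must be after base_year")
  }
  if (base_total <= 0 || horizon_total <= 0) {
    stop_domain("both totals must be > 0")
  }
  structure(
    list(base_year = as.integer(base_year), base_total = base_total,
         horizon_year = as.integer(horizon_year),
         horizon_total = horizon_total),
    class = "growth_projection"
  )
}

#' Growth factor for a query year
#'
#' Returns the dimensionless multiplier to apply to base-year resource
#' estimates: 1 at the base year, `horizon_total / base_total` at the
#' horizon year, linearly interpolated in the factor between. Queries
#' outside the projection window are refused rather than extrapolated.
#'
#' @param projection A [growth_projection()].
#' @param query_year Year in `[base_year, horizon_year]`.
#' @return A single number >= 0.
#' @examples
#' p <- growth_projection(2008, 948858, 2016, 1220000)
#' growth_factor(p, 2008)   # 1
#' growth_factor(p, 2016)   # ~1.2858
#' @export
growth_factor <- function(projection, query_year) {
  stopifnot(inherits(projection, "growth_projection"))
  if (query_year < projection$base_year ||
      query_year > projection$horizon_year) {
    stop_domain("query_year ", query_year, " outside projection window [",
                projection$base_year, ", ", projection$horizon_year, "]")
  }
  end_factor <- projection$horizon_total / projection$base_total
  frac <- (query_year - projection$base_year) /
    (projection$horizon_year - projection$base_year)
  1 + frac * (end_factor - 1)
}
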