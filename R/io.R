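# Reading and writing incidence tables.

#' Read an incidence table from CSV
#'
#' Columns `site`, `cases_both`, and optionally `cases_men`,
#' `cases_women`. An empty cell means "not reported", which is distinct
#' from 0. A row whose site matches `total_site` supplies the all-cancers
#' total; without one, the total defaults to the sum of listed sites.
#'
#' @param path CSV path. Lines starting with `#` are ignored.
#' @param geography A [geography()] the counts belong to.
#' @param year Calendar year of the counts.
#' @param total_site Site label of the all-cancers row (default
#'   `"all cancers"`).
#' @return An [incidence_table()].
#' @export
read_incidence <- function(path, geography, year,
                           total_site = "all cancers") {
  if (!file.exists(path)) stop_config("incidence file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("site", "cases_both") %in% names(df))) {
    stop_config("incidence file needs columns site, cases_both")
  }
  for (col in c("cases_men", "cases_women")) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
  }
  is_total <- df$site == total_site
  if (sum(is_total) > 1) stop_config("multiple all-cancers rows")
  total <- if (any(is_total)) df$cases_both[is_total] else
    sum(df$cases_both, na.rm = TRUE)
  incidence_table(geography, year, df[!is_total, , drop = FALSE], total)
}

#' Write an incidence table to CSV
#'
#' Inverse of [read_incidence()]: the all-cancers total becomes a leading
#' row labelled `total_site`; unreported sex-specific counts become empty
#' cells.
#'
#' @param table An [incidence_table()].
#' @param path Output path.
#' @param total_site Label for the all-cancers row.
#' @param comment Optional comment line (without the leading `#`) written
#'   as a header, e.g. generation provenance.
#' @return Invisibly, `path`.
#' @export
write_incidence <- function(table, path, total_site = "all cancers",
                            comment = NULL) {
  stopifnot(inherits(table, "incidence_table"))
  df <- rbind(
    data.frame(site = total_site, cases_both = table$total_all_cancers,
               cases_men = NA_real_, cases_women = NA_real_,
               stringsAsFactors = FALSE),
    table$records
  )
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}
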