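# Gap analysis: needed vs available vs shortage/surplus per category.

#' Construct an availability inventory
#'
#' Counts of professionals, beds and equipment actually present in a
#' geography, typically assembled by survey. Categories with no local
#' specialization at all (for example oncology pharmacy in a region where
#' that track does not exist) are listed in `nonexistent` and reported as
#' zero with an explanatory flag rather than silently.
#'
#' @param geography Geography name the counts refer to.
#' @param staff Named numeric vector, profession -> available count.
#' @param beds Available oncology beds (or `NA` if not surveyed).
#' @param equipment Named numeric vector, equipment type -> count.
#' @param nonexistent Character vector of categories with no local
#'   specialization.
#' @return An object of class `availability_inventory`.
#' @export
availability_inventory <- function(geography, staff = numeric(0),
                                   beds = NA_real_, equipment = numeric(0),
                                   nonexistent = character(0)) {
  staff <- unlist(staff); equipment <- unlist(equipment)
  if (length(staff) && (is.null(names(staff)) || any(!nzchar(names(staff))))) {
    stop_config("staff counts must be named by profession")
  }
  if (length(equipment) &&
      (is.null(names(equipment)) || any(!nzchar(names(equipment))))) {
    stop_config("equipment counts must be named by type")
  }
  if (any(staff < 0) || any(equipment < 0) || (!is.na(beds) && beds < 0)) {
    stop_domain("availability counts must be >= 0")
  }
  for (cat in nonexistent) {
    if (!cat %in% names(staff)) staff[[cat]] <- 0
    if (staff[[cat]] != 0) {
      stop_domain("category '", cat, "' flagged nonexistent but has count ",
                  staff[[cat]])
    }
  }
  structure(
    list(geography = geography, staff = staff, beds = beds,
         equipment = equipment, nonexistent = nonexistent,
         merges = character(0)),
    class = "availability_inventory"
  )
}

#' Read availability inventories from CSV
#'
#' Long format, columns `geography`, `category`, `count` and optional
#' `flag` (`nonexistent`, or `merged-from:<label>` on an already-merged
#' row). The special categories `beds` and the known equipment types go to
#' the `beds`/`equipment` slots; everything else is staff.
#'
#' @param path CSV path. Lines starting with `#` are ignored.
#' @return Named list of [availability_inventory()] objects, one per
#'   geography in the file.
#' @export
read_inventory <- function(path) {
  if (!file.exists(path)) stop_config("inventory file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("geography", "category", "count") %in% names(df))) {
    stop_config("inventory file needs columns geography, category, count")
  }
  if (!"flag" %in% names(df)) df$flag <- ""
  df$flag[is.na(df$flag)] <- ""
  equipment_types <- c("teletherapy", "brachytherapy", "ct_simulator", "tps",
                       "dosimetry_qa")
  out <- lapply(split(df, df$geography), function(g) {
    beds <- NA_real_
    staff <- numeric(0); equipment <- numeric(0)
    nonexistent <- character(0)
    for (i in seq_len(nrow(g))) {
      cat <- g$category[i]; n <- g$count[i]
      if (cat == "beds") {
        beds <- n
      } else if (cat %in% equipment_types) {
        equipment[[cat]] <- n
      } else {
        staff[[cat]] <- n
        if (identical(g$flag[i], "nonexistent")) {
          nonexistent <- c(nonexistent, cat)
        }
      }
    }
    availability_inventory(g$geography[1], staff, beds, equipment,
                           nonexistent)
  })
  out[order(names(out))]
}

#' Merge availability categories
#'
#' Pools the counts of several surveyed categories under one target label,
#' e.g. when an adjacent specialty does the same clinical work (regional
#' gastro-surgeons counted with surgical oncologists). The merge is
#' recorded and surfaces as a report footnote; it never happens silently.
#'
#' @param inventory An [availability_inventory()].
#' @param merges List of `list(from = <character vector>, to = <label>)`.
#'   Merging into a label not yet present creates it (and is logged).
#' @return The modified inventory.
#' @examples
#' inv <- availability_inventory("UP",
#'   staff = c(surgical_oncologists = 21, gastro_surgeons = 21))
#' inv <- merge_available_categories(inv,
#'   list(list(from = "gastro_surgeons", to = "surgical_oncologists")))
#' inv$staff[["surgical_oncologists"]]  # 42
#' @export
merge_available_categories <- function(inventory, merges) {
  stopifnot(inherits(inventory, "availability_inventory"))
  for (m in merges) {
    from <- m$from; to <- m$to
    missing <- setdiff(from, names(inventory$staff))
    if (length(missing)) {
      stop_config("cannot merge unknown category(ies): ",
                  paste(missing, collapse = ", "))
    }
    if (!to %in% names(inventory$staff)) {
      inventory$staff[[to]] <- 0
      message("merge target '", to, "' did not exist; created with count 0")
    }
    moved <- sum(inventory$staff[from])
    inventory$staff[[to]] <- inventory$staff[[to]] + moved
    inventory$staff <- inventory$staff[setdiff(names(inventory$staff), from)]
    inventory$merges <- c(
      inventory$merges,
      stats::setNames(paste(from, collapse = "+"), to)
    )
  }
  inventory
}

#' Compare requirements with availability
#'
#' Produces one row per category with `shortage = max(0, needed -
#' available)` and `surplus = max(0, available - needed)`; exactly one of
#' the two is nonzero. A surplus in one category (or one city) never
#' offsets a deficit elsewhere. Categories present on only one side appear
#' with the other side taken as 0 and a warning. Beds are compared when
#' the inventory surveyed them; wards are a derived unit and are not
#' compared.
#'
#' @param required A `requirement_summary` (see [compute_requirements()]).
#' @param available An [availability_inventory()] for the same geography.
#' @return An object of class `gap_report`: `geography`, `level`, `rows`
#'   (data frame: category, needed, available, shortage, surplus, note).
#' @examples
#' req <- compute_requirements("UP", "state", total_cases = 160296,
#'   surgical_patients = 74860, rt_patients = 94808, beds = 2892)
#' inv <- availability_inventory("UP",
#'   staff = c(radiation_clinical_oncologists = 87))
#' rep <- compute_gaps(req, inv)
#' subset(rep$rows, category == "radiation_clinical_oncologists")
#' @export
compute_gaps <- function(required, available) {
  stopifnot(inherits(required, "requirement_summary"),
            inherits(available, "availability_inventory"))
  if (!identical(required$geography, available$geography)) {
    stop_domain("geography mismatch: requirements for '", required$geography,
                "', availability for '", available$geography, "'")
  }
  needed <- c(required$staff, required$equipment)
  if (!is.na(available$beds)) needed <- c(needed, beds = required$beds)
  avail <- c(available$staff, available$equipment)
  if (!is.na(available$beds)) avail <- c(avail, beds = available$beds)

  only_avail <- setdiff(names(avail), names(needed))
  only_needed <- setdiff(names(needed), names(avail))
  if (length(only_avail)) {
    warning("categories only in the availability inventory (needed taken ",
            "as 0): ", paste(only_avail, collapse = ", "))
  }
  cats <- c(names(needed), only_avail)
  n <- ifelse(cats %in% names(needed), needed[cats], 0)
  a <- ifelse(cats %in% names(avail), avail[cats], 0)
  note <- character(length(cats))
  note[cats %in% only_needed] <- "not surveyed"
  note[cats %in% available$nonexistent] <- "no local specialization"
  note[cats %in% required$floored] <- "city minimum applied"
  note[cats %in% names(available$merges)] <- paste0(
    "includes merged: ",
    available$merges[cats[cats %in% names(available$merges)]])
  rows <- data.frame(
    category = cats,
    needed = as.numeric(n),
    available = as.numeric(a),
    shortage = pmax(0, n - a),
    surplus = pmax(0, a - n),
    note = note,
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(list(geography = required$geography, level = required$level,
                 rows = rows),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("<gap_report> %s (%s)\n", x$geography, x$level))
  print(x$rows, row.names = FALSE)
  invisible(x)
}

#' Render gap reports
#'
#' Serializes one or more gap reports deterministically (fixed column
#' order, no timestamps): `csv` for machine consumption, `json` for APIs,
#' `text` for terminal-readable tables. City reports should be listed
#' after their state so grouped reading works; rows carry their notes
#' (city-minimum floors, nonexistent specializations, category merges) as
#' a final column / footnote markers.
#'
#' @param reports A `gap_report` or list of them.
#' @param format `"csv"`, `"json"` or `"text"`.
#' @return A single string (the serialized report).
#' @export
render_report <- function(reports, format = c("csv", "json", "text")) {
  format <- match.arg(format)
  if (inherits(reports, "gap_report")) reports <- list(reports)
  if (!length(reports)) stop_config("no reports to render")
  stopifnot(all(vapply(reports, inherits, logical(1), "gap_report")))
  combined <- do.call(rbind, lapply(reports, function(r) {
    cbind(data.frame(geography = r$geography, stringsAsFactors = FALSE),
          r$rows)
  }))
  rownames(combined) <- NULL
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(combined, con, row.names = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  if (format == "json") {
    return(as.character(jsonlite::toJSON(combined, dataframe = "rows",
                                         pretty = TRUE, digits = NA)))
  }
  # text: one block per report, footnote markers for noted rows
  blocks <- vapply(reports, function(r) {
    rows <- r$rows
    marker <- ifelse(nzchar(rows$note), "*", "")
    body <- sprintf("  %-34s %8s %10s %9s %8s%s",
                    rows$category, format(rows$needed, big.mark = ","),
                    format(rows$available, big.mark = ","),
                    format(rows$shortage, big.mark = ","),
                    format(rows$surplus, big.mark = ","), marker)
    head <- sprintf("%s (%s)\n  %-34s %8s %10s %9s %8s", r$geography,
                    r$level, "category", "needed", "available", "shortage",
                    "surplus")
    foot <- rows$note[nzchar(rows$note)]
    footnotes <- if (length(foot)) {
      paste0("  * ", paste(unique(paste0(rows$category[nzchar(rows$note)],
                                         ": ", foot)), collapse = "\n  * "))
    } else character(0)
    paste(c(head, body, footnotes), collapse = "\n")
  }, character(1))
  paste0(paste(blocks, collapse = "\n\n"), "\n")
}

#' Parse a CSV gap report back into gap_report objects
#'
#' Inverse of `render_report(format = "csv")`; shortages and surpluses are
#' recomputed from needed/available, so a round trip also re-verifies the
#' gap identities.
#'
#' @param text CSV text as produced by [render_report()].
#' @return Named list of `gap_report` objects.
#' @export
read_gap_report <- function(text) {
  df <- utils::read.csv(text = text, stringsAsFactors = FALSE)
  if (!"note" %in% names(df)) df$note <- ""
  df$note[is.na(df$note)] <- ""
  lapply(split(df, df$geography)[unique(df$geography)], function(g) {
    rows <- data.frame(
      category = g$category, needed = g$needed, available = g$available,
      shortage = pmax(0, g$needed - g$available),
      surplus = pmax(0, g$available - g$needed),
      note = g$note, stringsAsFactors = FALSE, row.names = NULL
    )
    structure(list(geography = g$geography[1], level = NA_character_,
                   rows = rows),
              class = "gap_report")
  })
}
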