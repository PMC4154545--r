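#' Define a geography
#'
#' A geography is a named population unit at one of three administrative
#' levels. Cities carry a `parent` pointer to their state so that
#' population-consistency checks and grouped reporting work.
#'
#' @param name Text label, e.g. `"Uttar Pradesh"`.
#' @param population Number of persons (non-negative). May be `NA` when the
#'   population is unknown and incidence shares are supplied explicitly.
#' @param level One of `"country"`, `"state"`, `"city"`.
#' @param parent Name of the enclosing geography, or `NULL` for a country.
#' @return An object of class `geography`.
#' @examples
#' geography("Uttar Pradesh", 199812341, "state", parent = "India")
#' @export
geography <- function(name, population, level = c("country", "state", "city"),
                      parent = NULL) {
  level <- match.arg(level)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_config("geography name must be a non-empty string")
  }
  if (length(population) != 1L) {
    stop_config("population must be a single number (or NA)")
  }
  if (!is.na(population) && (!is.numeric(population) || population < 0)) {
    stop_domain("population must be >= 0, got ", population)
  }
  if (!is.null(parent) && (!is.character(parent) || length(parent) != 1L)) {
    stop_config("parent must be NULL or a single geography name")
  }
  structure(
    list(name = name, population = as.numeric(population), level = level,
         parent = parent),
    class = "geography"
  )
}

#' @export
print.geography <- function(x, ...) {
  cat(sprintf("<geography> %s (%s), population %s%s\n", x$name, x$level,
              ifelse(is.na(x$population), "unknown",
                     format(x$population, big.mark = ",")),
              if (!is.null(x$parent)) paste0(", in ", x$parent) else ""))
  invisible(x)
}

#' Check population consistency between a city and its parent state
#'
#' @param city,state `geography` objects.
#' @return `TRUE` invisibly; errors if the city's population exceeds the
#'   state's.
#' @keywords internal
check_city_in_state <- function(city, state) {
  if (!is.na(city$population) && !is.na(state$population) &&
      city$population > state$population) {
    stop_domain("city '", city$name, "' population exceeds parent state '",
                state$name, "'")
  }
  invisible(TRUE)
}

#' Read geographies from a JSON or YAML config
#'
#' The config is a list of records with fields `name`, `population`,
#' `level` and optional `parent`.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return Named list of `geography` objects (names are geography names).
#' @export
read_geographies <- function(path) {
  if (!file.exists(path)) stop_config("geography config not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  geos <- lapply(raw, function(g) {
    geography(g$name, if (is.null(g$population)) NA_real_ else g$population,
              g$level, parent = g$parent)
  })
  names(geos) <- vapply(geos, `[[`, character(1), "name")
  # validate city/state containment where both populations are known
  for (g in geos) {
    if (g$level == "city" && !is.null(g$parent) && g$parent %in% names(geos)) {
      check_city_in_state(g, geos[[g$parent]])
    }
  }
  geos
}
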