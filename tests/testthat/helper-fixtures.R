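# Small in-code fixtures shared across test files.

toy_geography <- function(name = "toyland", population = 1e6,
                          level = "state", parent = NULL) {
  geography(name, population, level, parent)
}

# two-site table used for arithmetic-identity tests
toy_incidence <- function(population = 2e6) {
  incidence_table(
    geography("toy-country", population, "country"), 2008,
    data.frame(site = c("siteA", "siteB"), cases_both = c(100, 50),
               cases_men = c(60, NA), cases_women = c(40, NA),
               stringsAsFactors = FALSE),
    total_all_cancers = 200
  )
}

toy_fractions <- function() {
  data.frame(
    site = c("siteA", "siteB"),
    level = "group",
    pct_surgery = c(50, 0), alos_surgery = c(4, 0),
    pct_chemo = c(100, 80), alos_chemo = c(3, 2),
    pct_rt = c(25, 50), alos_rt = c(5, 5),
    stringsAsFactors = FALSE
  )
}

# reference projection: 948,858 national cases in 2008 -> 1,220,000 by 2016
reference_projection <- function() {
  growth_projection(2008, 948858, 2016, 1220000)
}
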