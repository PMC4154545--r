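#!/usr/bin/env Rscript
# Thin command-line wrapper over the oncocap package.
#
#   Rscript scripts/oncocap.R <subcommand> [options]
#
# Subcommands:
#   validate     check an incidence CSV          (--incidence, --geography)
#   extrapolate  scale national incidence        (--incidence, --share, --out)
#   demand       per-modality treatment demand   (--incidence, --fractions)
#   capacity     requirement summary             (--incidence, --norms, ...)
#   gaps|report  needed-vs-available gap tables  (... --inventory, --format)
#   simulate     write a synthetic scenario      (--seed, --out)
#
# With no --incidence/--fractions/--inventory the packaged reference
# tables for Uttar Pradesh are used.

suppressMessages({
  library(oncocap)
  library(optparse)
})

parser <- OptionParser(
  usage = "usage: %prog <validate|extrapolate|demand|capacity|gaps|report|simulate> [options]",
  option_list = list(
    make_option("--incidence", type = "character", default = NULL,
                help = "incidence CSV (default: packaged reference table)"),
    make_option("--geography", type = "character", default = "Uttar Pradesh",
                help = "geography name [default %default]"),
    make_option("--year", type = "integer", default = 2008L),
    make_option("--share", type = "double", default = NULL,
                help = "explicit population share for extrapolation"),
    make_option("--fractions", type = "character", default = NULL,
                help = "treatment-fractions CSV"),
    make_option("--inventory", type = "character", default = NULL,
                help = "availability inventory CSV"),
    make_option("--norms", type = "character", default = NULL,
                help = "capacity-norms YAML/JSON"),
    make_option("--format", type = "character", default = "text",
                help = "report format: csv|json|text [default %default]"),
    make_option("--seed", type = "integer", default = 1L),
    make_option("--out", type = "character", default = NULL,
                help = "output file (reports) or directory (simulate)")
  )
)
parsed <- parse_args(parser, positional_arguments = 1)
cmd <- parsed$args
opt <- parsed$options

emit <- function(text) {
  if (is.null(opt$out)) cat(text) else writeLines(text, opt$out)
}

load_incidence <- function() {
  if (is.null(opt$incidence)) return(oncocap_incidence_up())
  geos <- oncocap_geographies()
  g <- if (opt$geography %in% names(geos)) geos[[opt$geography]] else
    geography(opt$geography, NA, "state")
  read_incidence(opt$incidence, g, opt$year)
}
load_fractions <- function() {
  if (is.null(opt$fractions)) oncocap_fractions() else
    read_fractions(opt$fractions)
}
load_norms <- function() {
  if (is.null(opt$norms)) capacity_norms() else read_norms(opt$norms)
}

run_pipeline <- function() {
  inc <- load_incidence()
  d <- compute_demand(inc, load_fractions(), "group")
  req <- compute_requirements(
    inc$geography$name, inc$geography$level, inc$total_all_cancers,
    setNames(inc$records$cases_both, inc$records$site),
    surgical_patients = d$totals[["surgery"]],
    rt_patients = d$totals[["rt"]], beds = beds_needed(d),
    norms = load_norms())
  if (inc$geography$level == "city") req <- apply_city_minimum(req, load_norms())
  list(incidence = inc, demand = d, requirements = req)
}

switch(cmd,
  validate = {
    v <- validate_incidence(load_incidence())
    if (length(v)) { writeLines(v); quit(status = 1) }
    message("incidence table valid")
  },
  extrapolate = {
    inc <- load_incidence()
    target <- geography(paste0(opt$geography, " (scaled)"),
                        NA, inc$geography$level)
    out <- extrapolate_incidence(inc, target, share = opt$share)
    path <- if (is.null(opt$out)) stdout() else opt$out
    write_incidence(out, if (is.character(path)) path else tempfile())
    if (is.null(opt$out)) print(out) else message("wrote ", opt$out)
  },
  demand = {
    print(compute_demand(load_incidence(), load_fractions(), "group"))
  },
  capacity = {
    print(run_pipeline()$requirements)
  },
  gaps = ,
  report = {
    stage <- run_pipeline()
    invs <- if (is.null(opt$inventory)) oncocap_availability() else
      read_inventory(opt$inventory)
    if (!stage$incidence$geography$name %in% names(invs)) {
      stop("no inventory for geography '",
           stage$incidence$geography$name, "'")
    }
    rep <- compute_gaps(stage$requirements,
                        invs[[stage$incidence$geography$name]])
    emit(render_report(rep, opt$format))
  },
  simulate = {
    dir <- if (is.null(opt$out)) "scenario" else opt$out
    sc <- generate_scenario(scenario_spec(seed = opt$seed))
    write_scenario(sc, dir)
    message("wrote scenario (seed ", opt$seed, ") to ", dir)
  },
  stop("unknown subcommand: ", cmd)
)
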