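#' Validate a pipeline configuration
#'
#' Fills defaults and reports schema violations with field paths before
#' any computation.
#' @param config list or path to a JSON config file
#' @return validated config list
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(seed = 1L, scale = 100, survey_n = 10000,
                   start_year = 2018, end_year = 2030,
                   smoothing_window = 5,
                   marginals_file = NULL, findrisc_file = NULL,
                   mortality_file = NULL,
                   psa = list(enabled = FALSE, n_runs = 100,
                              sample_fraction = 0.01),
                   inequality_axis = "education")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in names(defaults$psa)) {
    if (is.null(config$psa[[nm]])) config$psa[[nm]] <- defaults$psa[[nm]]
  }
  checks <- list(
    c("seed", is.numeric(config$seed) && config$seed == round(config$seed)),
    c("scale", is.numeric(config$scale) && config$scale > 0),
    c("survey_n", is.numeric(config$survey_n) && config$survey_n >= 100),
    c("start_year", is.numeric(config$start_year)),
    c("end_year", is.numeric(config$end_year) &&
        config$end_year >= config$start_year),
    c("psa.n_runs", is.numeric(config$psa$n_runs) && config$psa$n_runs >= 2),
    c("psa.sample_fraction", config$psa$sample_fraction > 0 &&
        config$psa$sample_fraction <= 1),
    c("inequality_axis",
      config$inequality_axis %in% c("education", "income"))
  )
  bad <- vapply(checks, function(ch) !as.logical(ch[2]), TRUE)
  if (any(bad)) {
    stop("invalid config field(s): ",
         paste(vapply(checks[bad], `[`, "", 1), collapse = ", "))
  }
  config
}

#' Run the end-to-end pipeline
#'
#' Executes synthetic population generation, transition calibration, the
#' simulation, burden accounting, inequality indices, and (optionally)
#' the probabilistic sensitivity analysis, writing tidy CSV outputs and a
#' run manifest (seeds, config hash, file checksums, per-stage runtimes)
#' to `out_dir`. Re-running the same config and seeds reproduces
#' identical outputs.
#'
#' @param config list or JSON path (see [validate_config()])
#' @param out_dir output directory (created if missing)
#' @return the manifest list, invisibly
#' @export
run_pipeline <- function(config, out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  runtimes <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    runtimes[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    message(sprintf("[t2dsim] %-12s %8.2fs", stage, runtimes[[stage]]))
    val
  }

  spec <- tick("marginals", {
    if (is.null(config$marginals_file)) {
      default_marginals(scale = config$scale,
                        baseline_year = config$start_year)
    } else {
      read_marginals(config$marginals_file, scale = config$scale,
                     baseline_year = config$start_year)
    }
  })
  survey <- tick("synthpop", generate_survey_fixture(
    spec, n = config$survey_n, seed = config$seed))
  pop <- tick("expand", expand_population(survey, spec,
                                          seed = config$seed + 1L))
  tables <- tick("calibrate", {
    tb <- default_tables(spec, window = config$smoothing_window)
    if (!is.null(config$findrisc_file)) {
      tb$findrisc <- read_findrisc_params(config$findrisc_file)
    }
    if (!is.null(config$mortality_file)) {
      tb$mortality <- read_mortality_table(config$mortality_file)
    }
    tb
  })
  cfg <- sim_config(start_year = config$start_year,
                    end_year = config$end_year, seed = config$seed + 2L)
  sim <- tick("run", run_simulation(pop, cfg, tables))
  burden <- tick("burden", compute_dalys(compute_rates(sim)))
  ineq <- tick("inequality", {
    axis <- config$inequality_axis
    bstrat <- compute_rates(sim, by = "education")
    last <- bstrat[year == max(year)]
    shares <- last$midyear / sum(last$midyear)
    ord <- match(c("high", "intermediate", "low"), last$education)
    data.table(axis = axis, year = max(last$year),
               rii = rii_sii(data.frame(group = last$education[ord],
                                        rate = last$prevalence_rate[ord],
                                        share = shares[ord]))$rii,
               sii = rii_sii(data.frame(group = last$education[ord],
                                        rate = last$prevalence_rate[ord],
                                        share = shares[ord]))$sii)
  })

  fwrite(sim$events, file.path(out_dir, "events.csv"))
  fwrite(burden, file.path(out_dir, "burden.csv"))
  fwrite(ineq, file.path(out_dir, "inequality.csv"))
  if (isTRUE(config$psa$enabled)) {
    psa <- tick("psa", run_psa(
      pop, psa_config(n_runs = config$psa$n_runs,
                      sample_fraction = config$psa$sample_fraction,
                      seed = config$seed + 3L),
      tables, cfg))
    fwrite(psa, file.path(out_dir, "psa.csv"))
  }

  outputs <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("t2dsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_hash = .hash_object(config),
    seeds = list(survey = config$seed, expand = config$seed + 1L,
                 simulation = config$seed + 2L, psa = config$seed + 3L),
    checksums = as.list(tools::md5sum(outputs)),
    runtimes = runtimes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# md5 of the canonical JSON serialisation
.hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
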