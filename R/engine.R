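#' Simulation configuration
#'
#' @param start_year baseline calendar year (default 2018)
#' @param end_year last simulated year (default 2030)
#' @param seed integer RNG seed for the run's single stream
#' @param births_enabled append an annual birth cohort (default TRUE; open
#'   cohort with births and deaths, migration excluded)
#' @param annual_birth_cohort newborns per year; `NULL` uses the baseline
#'   age-0 count
#' @param incidence_age_floor youngest age at which T2D incidence is
#'   simulated (default 35; annual probability is 0 below it)
#' @param mortality_first if TRUE the death draw precedes the incidence
#'   draw within a cycle (default FALSE: risk factors, then incidence,
#'   then death, so same-year onsets face RR-adjusted mortality)
#' @return a `sim_config` list
#' @export
sim_config <- function(start_year = 2018, end_year = 2030, seed = 1L,
                       births_enabled = TRUE, annual_birth_cohort = NULL,
                       incidence_age_floor = 35, mortality_first = FALSE) {
  stopifnot(start_year <= end_year)
  structure(list(start_year = start_year, end_year = end_year,
                 seed = as.integer(seed), births_enabled = births_enabled,
                 annual_birth_cohort = annual_birth_cohort,
                 incidence_age_floor = incidence_age_floor,
                 mortality_first = mortality_first),
            class = "sim_config")
}

#' Bundled default model tables
#'
#' Convenience constructor for the table set consumed by the engine:
#' risk-factor transition tables calibrated from the default prevalence
#' curves, the synthetic mortality and relative-risk tables, and the
#' FINDRISC parameters.
#'
#' @param spec marginal spec used to anchor the prevalence curves
#' @param window smoothing window for the curves
#' @return list with `transitions`, `mortality`, `rr`, `findrisc`
#' @export
default_tables <- function(spec = default_marginals(), window = 5) {
  list(transitions = build_transition_tables(
         default_prevalence_curves(spec), window = window),
       mortality = default_mortality_table(),
       rr = default_rr_table(),
       findrisc = read_findrisc_params())
}

# one annual cycle over the whole population; pop must be keyed/ordered by
# id so the single RNG stream is consumed in id order
.step_core <- function(pop, year, tables, config) {
  alive0 <- which(pop$alive)
  if (length(alive0) > 0L) {
    set(pop, alive0, "age", pop$age[alive0] + 1L)
  }
  pop <- .update_risk_factors(pop, tables$transitions)
  events <- list()

  draw_incidence <- function(pop) {
    cand <- which(pop$alive & !pop$t2d &
                    pop$age >= config$incidence_age_floor)
    if (length(cand) == 0L) return(NULL)
    p10 <- ten_year_risk(pop[cand], tables$findrisc)
    p1 <- annual_probability(pmin(p10, 1 - 1e-12))
    onset <- cand[runif(length(cand)) < p1]
    if (length(onset) > 0L) {
      set(pop, onset, "t2d", TRUE)
      set(pop, onset, "t2d_onset_year", as.integer(year))
      return(data.table(id = pop$id[onset], year = as.integer(year),
                        event = "t2d_onset", cause = NA_character_,
                        age = pop$age[onset], sex = pop$sex[onset],
                        region = pop$region[onset],
                        education = pop$education[onset]))
    }
    NULL
  }

  draw_death <- function(pop) {
    alive <- which(pop$alive)
    if (length(alive) == 0L) return(NULL)
    dp <- death_probability(pop[alive], tables$mortality, tables$rr)
    u <- runif(length(alive))
    dies <- u < dp$prob
    if (!any(dies)) return(NULL)
    idx <- alive[dies]
    attributed <- runif(length(idx)) < dp$attribution[dies]
    set(pop, idx, "alive", FALSE)
    set(pop, idx, "death_year", as.integer(year))
    set(pop, idx, "death_cause",
        ifelse(attributed, "t2d_attributable", "other"))
    data.table(id = pop$id[idx], year = as.integer(year), event = "death",
               cause = ifelse(attributed, "t2d_attributable", "other"),
               age = pop$age[idx], sex = pop$sex[idx],
               region = pop$region[idx], education = pop$education[idx])
  }

  if (isTRUE(config$mortality_first)) {
    events$death <- draw_death(pop)
    events$onset <- draw_incidence(pop)
  } else {
    events$onset <- draw_incidence(pop)
    events$death <- draw_death(pop)
  }
  list(pop = pop, events = rbindlist(events, use.names = TRUE))
}

#' Advance the population by one simulated year
#'
#' Per alive individual, in order: (1) age increases by one; (2) the
#' modifiable risk factors are updated by net-transition draws; (3) if
#' healthy and at or above the incidence age floor, a Bernoulli draw at
#' the FINDRISC-derived annual probability may set T2D onset; (4) a
#' Bernoulli death draw at the state-appropriate probability may set death
#' (with probabilistic T2D attribution). An individual can experience both
#' onset and death in the same year; the dead are never touched again, and
#' demographics other than age never change.
#'
#' @param pop population data.table (modified by reference and returned)
#' @param year calendar year being simulated
#' @param tables list as from [default_tables()]
#' @param config a [sim_config()]
#' @return list `pop`, `events` (columns `id, year, event, cause, age,
#'   sex, region, education`)
#' @export
step_year <- function(pop, year, tables, config = sim_config()) {
  stopifnot(is.data.table(pop))
  .step_core(pop, year, tables, config)
}

# newborn rows drawn from the baseline age-0 demographic pool
.make_births <- function(pool, n, next_id, year) {
  if (n <= 0L) return(NULL)
  rows <- pool[sample.int(nrow(pool), n, replace = TRUE)]
  rows[, `:=`(id = next_id + seq_len(n) - 1L, age = 0L,
              bmi_class = "lt25", waist_class = "low",
              bp_medication = FALSE, high_glucose_history = FALSE,
              t2d = FALSE, alive = TRUE, baseline_prevalent = FALSE,
              t2d_onset_year = NA_integer_, death_year = NA_integer_,
              death_cause = NA_character_, weight = 1)]
  rows
}

# per-year accounting inputs for the burden module, at single-year-of-age
# granularity so any reporting age window can be applied downstream
.yearly_snapshot <- function(pop, year, ev) {
  strata <- c("sex", "region", "education", "age")
  snap <- pop[alive == TRUE, .(alive = .N, prev = sum(t2d)), by = strata]
  if (!is.null(ev) && nrow(ev) > 0 && any(ev$event == "death")) {
    dw <- ev[event == "death",
             .(deaths = .N,
               deaths_attr = sum(cause == "t2d_attributable")),
             by = strata]
    snap <- merge(snap, dw, by = strata, all = TRUE)
  }
  for (cc in c("alive", "prev", "deaths", "deaths_attr")) {
    if (!cc %in% names(snap)) set(snap, j = cc, value = 0L)
  }
  setnafill(snap, fill = 0L,
            cols = c("alive", "prev", "deaths", "deaths_attr"))
  snap[, year := as.integer(year)]
  snap[]
}

#' Run the full annual-cycle simulation
#'
#' Iterates [step_year()] from the year after baseline through the
#' horizon, optionally appending a constant birth cohort each year, and
#' accumulates the event log plus per-year stratified accounting inputs.
#' A single seeded RNG stream drives every draw, so identical seed and
#' inputs give identical output.
#'
#' @param pop0 baseline population (from [expand_population()])
#' @param config a [sim_config()]
#' @param tables list as from [default_tables()]
#' @return a `t2d_sim` object: list with `events`, `yearly` (per year x
#'   sex x region x education counts; window = ages 35-80), `final_pop`,
#'   `config`
#' @export
run_simulation <- function(pop0, config = sim_config(),
                           tables = default_tables()) {
  pop <- as.data.table(copy(pop0))
  setorder(pop, id)
  set.seed(config$seed)
  birth_pool <- pop[age == 0L]
  if (nrow(birth_pool) == 0L) birth_pool <- pop[age <= 17L]
  if (nrow(birth_pool) == 0L) birth_pool <- copy(pop)
  n_births <- if (!config$births_enabled) 0L else
    if (is.null(config$annual_birth_cohort)) nrow(pop[age == 0L]) else
      as.integer(config$annual_birth_cohort)

  yearly <- list(.yearly_snapshot(pop, config$start_year, NULL))
  births <- list(data.table(year = as.integer(config$start_year),
                            births = 0L))
  events <- list()
  years <- if (config$end_year > config$start_year) {
    (config$start_year + 1L):config$end_year
  } else integer(0)
  for (y in years) {
    st <- .step_core(pop, y, tables, config)
    pop <- st$pop
    if (n_births > 0L) {
      nb <- .make_births(birth_pool, n_births, max(pop$id) + 1L, y)
      pop <- rbind(pop, nb, use.names = TRUE)
    }
    events[[as.character(y)]] <- st$events
    yearly[[as.character(y)]] <- .yearly_snapshot(pop, y, st$events)
    births[[as.character(y)]] <- data.table(year = as.integer(y),
                                            births = n_births)
  }
  ev <- rbindlist(events, use.names = TRUE)
  if (nrow(ev) == 0L) {
    ev <- data.table(id = integer(), year = integer(), event = character(),
                     cause = character(), age = integer(),
                     sex = character(), region = character(),
                     education = character())
  }
  structure(list(events = ev, yearly = rbindlist(yearly),
                 births = rbindlist(births), final_pop = pop,
                 config = config),
            class = "t2d_sim")
}

#' @export
print.t2d_sim <- function(x, ...) {
  cat("<t2d_sim>", x$config$start_year, "-", x$config$end_year,
      "| events:", nrow(x$events),
      "| final alive:", sum(x$final_pop$alive), "\n")
  invisible(x)
}
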