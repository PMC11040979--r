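#' Burden accounting parameters
#'
#' @param dw disability weight for prevalent T2D, in \[0,1); the default
#'   0.049 is the uncomplicated-diabetes convention (0 gives a pure-YLL
#'   accounting)
#' @param life_table reference remaining-life-expectancy table
#'   (`age`, `le`), decreasing in age; default derived from the package's
#'   mortality table via [life_expectancy_table()]
#' @return a `burden_params` list
#' @export
burden_params <- function(dw = 0.049, life_table = NULL) {
  stopifnot(dw >= 0, dw < 1)
  if (is.null(life_table)) life_table <- life_expectancy_table()
  stopifnot(all(diff(life_table$le) < 0))
  structure(list(dw = dw, life_table = as.data.table(life_table)),
            class = "burden_params")
}

#' Per-year incidence, prevalence and mortality rates
#'
#' Converts a simulation's event log and yearly accounting inputs into
#' counts and rates per 100,000, restricted to a reporting age window
#' (default 35-80). The denominator is the mid-year alive population in
#' the window (end-of-year alive plus half the year's in-window deaths).
#'
#' @param sim a `t2d_sim` from [run_simulation()]
#' @param by stratifiers, subset of `c("sex", "region", "education")`
#'   (empty = overall)
#' @param ages reporting age window `c(lo, hi)`
#' @return data.table (class `yearly_burden`) with counts and
#'   `incidence_rate`, `prevalence_rate`, `mortality_rate` per 100,000;
#'   carries the inputs needed by [compute_dalys()] as an attribute
#' @export
compute_rates <- function(sim, by = character(), ages = c(35, 80)) {
  stopifnot(inherits(sim, "t2d_sim"),
            all(by %in% c("sex", "region", "education")))
  lo <- ages[1]; hi <- ages[2]
  y <- sim$yearly[age >= lo & age <= hi]
  agg <- y[, .(alive_end = sum(alive), prev_end = sum(prev),
               deaths = sum(deaths), deaths_attr = sum(deaths_attr)),
           by = c("year", by)]
  ev <- sim$events
  if (nrow(ev) > 0) {
    inc <- ev[event == "t2d_onset" & age >= lo & age <= hi,
              .(incident = .N), by = c("year", by)]
    agg <- merge(agg, inc, by = c("year", by), all.x = TRUE)
  } else {
    agg[, incident := 0L]
  }
  setnafill(agg, fill = 0L, cols = "incident")
  agg[, midyear := alive_end + 0.5 * deaths]
  per <- function(cnt, den) ifelse(den > 0, cnt / den * 1e5, NA_real_)
  agg[, `:=`(
    incidence_rate = per(incident, midyear),
    prevalence_rate = per(prev_end, midyear),
    mortality_rate = per(deaths, midyear)
  )]
  setorderv(agg, c(by, "year"))
  out <- agg[]
  setattr(out, "class", c("yearly_burden", class(out)))
  setattr(out, "daly_inputs",
          list(deaths_by_age = y[, .(deaths_attr = sum(deaths_attr)),
                                 by = c("year", by, "age")],
               by = by, ages = ages))
  out
}

#' Fill YLL, YLD and DALY columns of a burden series
#'
#' `YLL(y) = sum over T2D-attributed deaths of remaining life expectancy
#' at the age of death`; `YLD(y) = prevalent person-years x disability
#' weight`, with person-years taken as the trapezoid of the end-of-year
#' prevalent counts over `[y-1, y]`; `DALY = YLL + YLD` exactly. The first
#' (baseline) year has no person-year interval and gets NA. Death ages
#' beyond the life table use its last row.
#'
#' @param burden output of [compute_rates()]
#' @param params a [burden_params()]
#' @return the burden series with `yll`, `yld`, `daly` and
#'   `daly_rate` (per 100,000 mid-year population) columns added
#' @export
compute_dalys <- function(burden, params = burden_params()) {
  inputs <- attr(burden, "daly_inputs")
  if (is.null(inputs)) stop("burden series must come from compute_rates()")
  by <- inputs$by
  lt <- params$life_table
  max_lt <- max(lt$age)
  d <- copy(inputs$deaths_by_age)
  d[, le := lt$le[match(pmin(age, max_lt), lt$age)]]
  if (any(d$age > max_lt & d$deaths_attr > 0)) {
    warning("death ages beyond life table; last row used")
  }
  yll <- d[, .(yll = sum(deaths_attr * le)), by = c("year", by)]
  out <- copy(burden)
  out <- merge(out, yll, by = c("year", by), all.x = TRUE)
  setnafill(out, fill = 0, cols = "yll")
  setorderv(out, c(by, "year"))
  # prevalent person-years: trapezoid of consecutive end-of-year counts
  if (length(by) > 0) {
    out[, py := (shift(prev_end) + prev_end) / 2, by = by]
  } else {
    out[, py := (shift(prev_end) + prev_end) / 2]
  }
  out[, yld := py * params$dw]
  first_year <- min(out$year)
  out[year == first_year, `:=`(yll = NA_real_, yld = NA_real_)]
  out[, daly := yll + yld]
  out[, daly_rate := ifelse(midyear > 0, daly / midyear * 1e5, NA_real_)]
  out[, py := NULL]
  setattr(out, "class", c("yearly_burden", class(out)))
  setattr(out, "daly_inputs", inputs)
  out[]
}

#' Percent change between two rates
#'
#' `100 * (rate_b - rate_a) / rate_a`, reported to one decimal. Undefined
#' (NA) when the reference rate is zero.
#'
#' @param rate_a reference rate (> 0 for a defined result)
#' @param rate_b comparison rate
#' @return percent change, rounded to one decimal; NA where `rate_a == 0`
#' @export
percent_change <- function(rate_a, rate_b) {
  out <- ifelse(rate_a > 0, round(100 * (rate_b - rate_a) / rate_a, 1),
                NA_real_)
  out
}
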