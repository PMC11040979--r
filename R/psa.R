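#' Probabilistic sensitivity analysis configuration
#'
#' @param n_runs number of parameter-draw simulations (default 100)
#' @param sample_fraction fraction of the population simulated per run
#'   (default 0.01), subsampled with stratification by age group x sex x
#'   region so structure is preserved at 1%
#' @param seed integer master seed; per-run seeds are derived from it
#' @param redraw_sample draw a fresh subsample each run (default TRUE)
#' @return a `psa_config` list
#' @export
psa_config <- function(n_runs = 100, sample_fraction = 0.01, seed = 1L,
                       redraw_sample = TRUE) {
  stopifnot(n_runs >= 2, sample_fraction > 0, sample_fraction <= 1)
  structure(list(n_runs = as.integer(n_runs),
                 sample_fraction = sample_fraction,
                 seed = as.integer(seed),
                 redraw_sample = isTRUE(redraw_sample)),
            class = "psa_config")
}

# stratified subsample preserving age group x sex x region structure
.psa_subsample <- function(pop, fraction) {
  if (fraction >= 1) return(copy(pop))
  pop <- copy(pop)
  pop[, age_group := age_group_of(age)]
  idx <- pop[, {
    m <- max(1L, round(.N * fraction))
    .I[sample.int(.N, m)]
  }, by = .(age_group, sex, region)]$V1
  out <- pop[sort(idx)]
  out[, age_group := NULL]
  out[, id := seq_len(.N)]
  out[]
}

# lognormal draw of each RR from its 95% CI
.perturb_rr <- function(rr_table) {
  out <- copy(rr_table)
  sdlog <- (log(out$rr_hi) - log(out$rr_lo)) / (2 * 1.96)
  out[, rr := rlnorm(.N, log(rr), sdlog)]
  out[]
}

# headline outputs of one simulated run, per 100,000
.psa_outputs <- function(sim, ages = c(35, 80)) {
  b <- compute_dalys(compute_rates(sim, ages = ages))
  y0 <- min(b$year); y1 <- max(b$year)
  after <- b[year > y0]
  c(incidence_avg = mean(after$incidence_rate),
    incidence_total = sum(after$incidence_rate),
    prevalence_start = b[year == y0, prevalence_rate],
    prevalence_end = b[year == y1, prevalence_rate],
    prevalence_change = percent_change(b[year == y0, prevalence_rate],
                                       b[year == y1, prevalence_rate]),
    daly_first = after[1, daly_rate],
    daly_end = b[year == y1, daly_rate],
    daly_change = percent_change(after[1, daly_rate],
                                 b[year == y1, daly_rate]))
}

#' Run the probabilistic sensitivity analysis
#'
#' The point estimate comes from one all-parameters-at-point run on the
#' full population. Each uncertainty run draws FINDRISC coefficients
#' (normal, point/SE) and mortality relative risks (lognormal from the
#' 95% CI), subsamples the population, runs the full simulation and
#' scales the outputs to per-100,000. The 95% uncertainty interval is the
#' 2.5th-97.5th empirical percentile across runs. Because the point run
#' uses the full population, it is not guaranteed to lie inside the
#' subsample-based interval.
#'
#' @param pop baseline population
#' @param config a [psa_config()]
#' @param tables model tables as from [default_tables()]
#' @param sim_cfg simulation configuration applied to every run
#' @param ages reporting age window
#' @return data.table `outcome, point, lo95, hi95` (class `t2d_psa`,
#'   with the run-level draws in attribute `runs`)
#' @export
run_psa <- function(pop, config = psa_config(), tables = default_tables(),
                    sim_cfg = sim_config(), ages = c(35, 80)) {
  stopifnot(inherits(config, "psa_config"))
  point_cfg <- sim_cfg
  point_cfg$seed <- config$seed
  point <- .psa_outputs(run_simulation(pop, point_cfg, tables), ages)

  fixed_sample <- NULL
  if (!config$redraw_sample) {
    set.seed(config$seed)
    fixed_sample <- .psa_subsample(pop, config$sample_fraction)
  }
  runs <- matrix(NA_real_, config$n_runs, length(point),
                 dimnames = list(NULL, names(point)))
  for (r in seq_len(config$n_runs)) {
    run_seed <- (config$seed + 104729L * r) %% .Machine$integer.max
    res <- tryCatch({
      set.seed(run_seed)
      sub <- if (config$redraw_sample) {
        .psa_subsample(pop, config$sample_fraction)
      } else fixed_sample
      tb <- tables
      tb$findrisc <- perturb_findrisc(tables$findrisc)
      tb$rr <- .perturb_rr(tables$rr)
      # common random numbers: every run re-uses the master simulation
      # seed, so run-to-run spread reflects parameter draws and
      # subsampling only (and collapses under degenerate distributions)
      cfg <- sim_cfg
      cfg$seed <- config$seed
      if (!is.null(cfg$annual_birth_cohort)) {
        cfg$annual_birth_cohort <-
          max(1L, round(cfg$annual_birth_cohort * config$sample_fraction))
      }
      .psa_outputs(run_simulation(sub, cfg, tb), ages)
    }, error = function(e) {
      stop("PSA run with seed ", run_seed, " failed: ",
           conditionMessage(e))
    })
    runs[r, ] <- res
  }
  out <- data.table(
    outcome = names(point),
    point = unname(point),
    lo95 = apply(runs, 2, quantile, 0.025, na.rm = TRUE),
    hi95 = apply(runs, 2, quantile, 0.975, na.rm = TRUE))
  setattr(out, "class", c("t2d_psa", class(out)))
  setattr(out, "runs", runs)
  out[]
}

#' Format a point (lo; hi) presentation string
#'
#' @param point,lo,hi numeric scalars
#' @param digits rounding digits (default 0)
#' @return character like `"560 (285; 962)"`
#' @export
format_ui <- function(point, lo, hi, digits = 0) {
  f <- function(z) formatC(round(z, digits), format = "f",
                           digits = digits, big.mark = ",")
  paste0(f(point), " (", f(lo), "; ", f(hi), ")")
}
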