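#' Load concise FINDRISC logistic parameters
#'
#' Reads the intercept and category coefficients (point estimate and
#' standard error) of the concise FINDRISC model: age band (45-54, 55-64
#' vs <45), BMI class (25-30, >30 vs <25), waist class (mid, high vs low),
#' blood-pressure medication and history of high blood glucose. Reference
#' categories carry coefficient 0 implicitly. The bundled default carries
#' the published point estimates; its SEs are synthetic plausible values
#' used only for probabilistic sensitivity analysis.
#'
#' @param path JSON parameter file; default is the bundled file
#' @return a `findrisc_params` list with `intercept` and a named
#'   `coefficients` data.table (`term`, `estimate`, `se`)
#' @export
read_findrisc_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "findrisc_params.json",
                        package = "t2dsim")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- raw$coefficients
  dt <- data.table(term = names(co),
                   estimate = vapply(co, function(x) x$estimate, 0),
                   se = vapply(co, function(x) x$se, 0))
  if (any(dt$se < 0) || raw$intercept$se < 0) {
    stop("FINDRISC standard errors must be >= 0")
  }
  structure(list(intercept = raw$intercept$estimate,
                 intercept_se = raw$intercept$se,
                 coefficients = dt),
            class = "findrisc_params")
}

.findrisc_terms <- c("age_45_54", "age_55_64", "bmi_25to30", "bmi_gt30",
                     "waist_mid", "waist_high", "bp_medication",
                     "high_glucose_history")

# coefficient lookup with an explicit error naming any missing term
.findrisc_coef <- function(params, terms_needed) {
  co <- setNames(params$coefficients$estimate, params$coefficients$term)
  missing <- setdiff(terms_needed, names(co))
  if (length(missing) > 0) {
    stop("missing FINDRISC coefficient for: ",
         paste(missing, collapse = ", "))
  }
  co
}

#' Ten-year T2D risk from the concise FINDRISC model
#'
#' Vectorised logistic prediction over individuals: `plogis(intercept +
#' sum of applicable coefficients)`. The top age coefficient (55-64) is
#' carried forward for ages 65+ (documented extrapolation); ages below 45
#' are the age reference. Predictors outside the concise model (education,
#' income, region) never enter.
#'
#' @param ind data.table (or 1-row data.frame) of individuals with `age`,
#'   `bmi_class`, `waist_class`, `bp_medication`, `high_glucose_history`
#' @param params a `findrisc_params` object
#' @return numeric vector of 10-year risks in (0,1)
#' @export
ten_year_risk <- function(ind, params = read_findrisc_params()) {
  ind <- as.data.table(ind)
  co <- .findrisc_coef(params, .findrisc_terms)
  lp <- rep(params$intercept, nrow(ind))
  lp <- lp + fifelse(ind$age >= 45 & ind$age < 55, co["age_45_54"],
                     fifelse(ind$age >= 55, co["age_55_64"], 0))
  lp <- lp + fifelse(ind$bmi_class == "25to30", co["bmi_25to30"],
                     fifelse(ind$bmi_class == "gt30", co["bmi_gt30"], 0))
  lp <- lp + fifelse(ind$waist_class == "mid", co["waist_mid"],
                     fifelse(ind$waist_class == "high", co["waist_high"], 0))
  lp <- lp + fifelse(as.logical(ind$bp_medication), co["bp_medication"], 0)
  lp <- lp + fifelse(as.logical(ind$high_glucose_history),
                     co["high_glucose_history"], 0)
  unname(plogis(lp))
}

#' Convert a 10-year risk to a one-year probability
#'
#' Constant-hazard conversion over the 10-year horizon:
#' `1 - (1 - p10)^(1/10)`. Exact round trip: ten independent annual
#' Bernoulli trials at the returned probability have cumulative incidence
#' `p10`.
#'
#' @param p10 ten-year risk(s) in \[0, 1)
#' @return one-year probability, same length
#' @export
annual_probability <- function(p10) {
  if (any(p10 < 0 | p10 >= 1)) {
    stop("10-year risk must lie in [0, 1): got ",
         paste(utils::head(p10[p10 < 0 | p10 >= 1], 3), collapse = ", "))
  }
  1 - (1 - p10)^(1 / 10)
}

#' Draw a perturbed FINDRISC parameter set
#'
#' Normal draws around each point estimate with its SE; used by the
#' probabilistic sensitivity analysis.
#' @param params a `findrisc_params`
#' @return a `findrisc_params` with perturbed estimates (SEs kept)
#' @export
perturb_findrisc <- function(params) {
  out <- params
  out$intercept <- rnorm(1, params$intercept, params$intercept_se)
  out$coefficients <- copy(params$coefficients)
  out$coefficients[, estimate := rnorm(.N, estimate, se)]
  out
}
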