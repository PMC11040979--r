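#' Convert an annual event rate to an annual probability
#'
#' Constant-hazard-within-the-year actuarial conversion
#' `p = 1 - exp(-rate)`.
#'
#' @param rate event rate(s) per person-year, >= 0
#' @return probability in \[0, 1)
#' @export
rate_to_probability <- function(rate) {
  if (any(rate < 0)) stop("rates must be >= 0")
  1 - exp(-rate)
}

#' Synthetic default mortality table
#'
#' Gompertz-Makeham all-cause rates `C + A * exp(B * age)` with sex and
#' region multipliers, plus a T2D-cause component as an age-increasing
#' fraction of the all-cause rate. These are synthetic stand-ins for
#' national vital-statistics extracts (which are not redistributable);
#' supply a real table via [read_mortality_table()] for applied use.
#'
#' @param max_age last tabulated age (open interval beyond it)
#' @return data.table `age, sex, region, all_cause_rate, t2d_cause_rate`
#' @export
default_mortality_table <- function(max_age = 110) {
  A <- 2e-5; B <- 0.095; C <- 2e-4
  sex_mult <- c(male = 1.30, female = 0.78)
  region_mult <- c(Brussels = 1.02, Flanders = 0.93, Wallonia = 1.12)
  dt <- CJ(age = 0:max_age, sex = t2d_levels$sex,
           region = t2d_levels$region, sorted = FALSE)
  dt[, all_cause_rate := (C + A * exp(B * pmin(age, max_age))) *
       sex_mult[sex] * region_mult[region]]
  # T2D-attributed share of total mortality rises from ~0.5% to ~4%
  dt[, t2d_cause_rate := all_cause_rate *
       (0.005 + 0.035 * plogis((age - 65) / 8))]
  dt[]
}

#' Read a mortality table from CSV
#'
#' Columns: `age, sex, region, all_cause_rate, t2d_cause_rate` (rates per
#' person-year). Validates `0 <= t2d_cause_rate <= all_cause_rate`.
#' @param path CSV path
#' @return data.table mortality table
#' @export
read_mortality_table <- function(path) {
  mt <- as.data.table(read.csv(path, stringsAsFactors = FALSE))
  need <- c("age", "sex", "region", "all_cause_rate", "t2d_cause_rate")
  if (!all(need %in% names(mt))) {
    stop("mortality CSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(mt$all_cause_rate)) ||
      any(mt$t2d_cause_rate < 0 | mt$t2d_cause_rate > mt$all_cause_rate)) {
    stop("require 0 <= t2d_cause_rate <= all_cause_rate, finite")
  }
  mt[]
}

#' Synthetic default relative risks of all-cause mortality for T2D
#'
#' Age-band- and sex-specific relative risks emulating the pattern of
#' large European cohort collaborations: RR declines with age and is
#' higher in women. Synthetic values (the source estimates are not
#' redistributable); 95% CIs are used for lognormal parameter draws in the
#' probabilistic sensitivity analysis.
#'
#' @return data.table `age_lo, age_hi, sex, rr, rr_lo, rr_hi`
#' @export
default_rr_table <- function() {
  dt <- data.table(
    age_lo = rep(c(0L, 50L, 60L, 70L, 80L), each = 2),
    age_hi = rep(c(49L, 59L, 69L, 79L, 199L), each = 2),
    sex = rep(c("male", "female"), 5),
    rr = c(2.5, 3.0, 2.2, 2.6, 1.9, 2.2, 1.6, 1.8, 1.3, 1.4)
  )
  dt[, `:=`(rr_lo = round(rr * 0.8, 2), rr_hi = round(rr * 1.25, 2))]
  stopifnot(all(dt$rr >= 1), all(dt$rr_lo <= dt$rr & dt$rr <= dt$rr_hi))
  dt[]
}

# RR lookup for a vector of (age, sex)
.rr_lookup <- function(age, sex, rr_table) {
  out <- rep(NA_real_, length(age))
  for (i in seq_len(nrow(rr_table))) {
    sel <- sex == rr_table$sex[i] & age >= rr_table$age_lo[i] &
      age <= rr_table$age_hi[i]
    out[sel] <- rr_table$rr[i]
  }
  if (any(is.na(out))) {
    bad <- which(is.na(out))[1]
    stop("no relative risk for age ", age[bad], ", sex ", sex[bad])
  }
  out
}

#' Annual death probability and T2D attribution weight
#'
#' Healthy individuals face the cause-deleted rate (all-cause minus
#' T2D-cause); individuals with T2D face the all-cause rate multiplied by
#' the age-sex relative risk (hazard capped so the probability stays
#' <= 0.999), and their deaths are T2D-attributable with probability equal
#' to the excess fraction `(RR*r_ac - (r_ac - r_t2d)) / (RR*r_ac)`,
#' clipped to \[0, 1\].
#'
#' @param ind data.table of alive individuals with `age, sex, region, t2d`
#' @param mt mortality table (see [default_mortality_table()])
#' @param rr_table relative-risk table (see [default_rr_table()])
#' @return list of numeric vectors `prob` and `attribution`
#' @export
death_probability <- function(ind, mt = default_mortality_table(),
                              rr_table = default_rr_table()) {
  ind <- as.data.table(ind)
  max_age <- max(mt$age)
  lookup <- data.table(age = pmin(ind$age, max_age), sex = ind$sex,
                       region = ind$region)
  hit <- mt[lookup, on = c("age", "sex", "region")]
  if (any(is.na(hit$all_cause_rate))) {
    bad <- which(is.na(hit$all_cause_rate))[1]
    stop("mortality table missing stratum: age ", lookup$age[bad], ", ",
         lookup$sex[bad], ", ", lookup$region[bad])
  }
  r_ac <- hit$all_cause_rate
  r_t2d <- hit$t2d_cause_rate
  has_t2d <- as.logical(ind$t2d)
  prob <- numeric(nrow(ind))
  attribution <- numeric(nrow(ind))
  # healthy: cause-deleted
  prob[!has_t2d] <- rate_to_probability(pmax(r_ac - r_t2d, 0)[!has_t2d])
  if (any(has_t2d)) {
    rr <- .rr_lookup(ind$age[has_t2d], ind$sex[has_t2d], rr_table)
    r_adj <- pmin(rr * r_ac[has_t2d], -log(1 - 0.999))
    prob[has_t2d] <- rate_to_probability(r_adj)
    excess <- (rr * r_ac[has_t2d] - (r_ac[has_t2d] - r_t2d[has_t2d])) /
      (rr * r_ac[has_t2d])
    attribution[has_t2d] <- pmin(pmax(excess, 0), 1)
  }
  list(prob = prob, attribution = attribution)
}

#' Remaining life expectancy table from a mortality table
#'
#' Period life-table closure of the (sex- and region-averaged) all-cause
#' rates: remaining expectancy at age a is the sum over x >= a of survival
#' from a to x plus a half-year correction. Used as the default reference
#' table for years of life lost.
#'
#' @param mt mortality table
#' @return data.table `age, le` with `le` strictly decreasing
#' @export
life_expectancy_table <- function(mt = default_mortality_table()) {
  avg <- mt[, .(rate = mean(all_cause_rate)), by = age][order(age)]
  q <- rate_to_probability(avg$rate)
  surv <- cumprod(1 - q)
  n <- length(q)
  le <- numeric(n)
  for (a in seq_len(n)) {
    s <- c(1, cumprod(1 - q[a:n]))
    le[a] <- sum((utils::head(s, -1) + utils::tail(s, -1)) / 2)
  }
  data.table(age = avg$age, le = le)
}
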