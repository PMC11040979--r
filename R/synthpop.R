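#' Default monotone association structure for the survey fixture
#'
#' Pairwise adjacent-category odds multipliers linking ordered variables:
#' values > 1 mean the two variables increase together, < 1 that they move
#' in opposite directions. Applied as log-linear tilts before iterative
#' proportional fitting, so the configured marginals are preserved while
#' the local (adjacent-category) odds ratio of each listed pair equals the
#' multiplier.
#'
#' @return data.table with columns `var1`, `var2`, `odds`
#' @export
default_correlation <- function() {
  data.table(
    var1 = c("education", "bmi_class", "bmi_class", "bmi_class",
             "high_glucose_history", "bp_medication"),
    var2 = c("bmi_class", "waist_class", "bp_medication",
             "high_glucose_history", "t2d", "t2d"),
    odds = c(0.6, 3.0, 1.6, 1.5, 4.0, 1.5)
  )
}

# Joint distribution over categorical variables: product of the target
# marginals, tilted by odds^((i-1)*(j-1)) for each configured pair, then
# iterative proportional fitting back onto the marginals.
.ipf_joint <- function(margins, tilts = NULL, tol = 1e-12, maxit = 2000) {
  vars <- names(margins)
  idx <- do.call(CJ, c(lapply(margins, function(m) seq_along(m)),
                       list(sorted = FALSE)))
  setnames(idx, vars)
  w <- rep(1, nrow(idx))
  for (v in vars) w <- w * margins[[v]][idx[[v]]]
  if (!is.null(tilts) && nrow(tilts) > 0) {
    for (r in seq_len(nrow(tilts))) {
      v1 <- tilts$var1[r]; v2 <- tilts$var2[r]; odds <- tilts$odds[r]
      if (!v1 %in% vars || !v2 %in% vars) next
      if (!is.finite(odds) || odds <= 0) {
        stop("odds multiplier for ", v1, " x ", v2, " must be finite and > 0")
      }
      w <- w * odds^((idx[[v1]] - 1) * (idx[[v2]] - 1))
    }
  }
  if (any(!is.finite(w))) {
    bad <- which(!is.finite(w))[1]
    cell <- paste(vars, "=", vapply(vars, function(v) {
      names(margins[[v]])[idx[[v]][bad]]
    }, ""), collapse = ", ")
    stop("infeasible correlation config: non-finite weight in cell {",
         cell, "}")
  }
  w <- w / sum(w)
  for (it in seq_len(maxit)) {
    dev <- 0
    for (v in vars) {
      cur <- vapply(seq_along(margins[[v]]),
                    function(k) sum(w[idx[[v]] == k]), 0)
      f <- ifelse(cur > 0, margins[[v]] / cur, 0)
      w <- w * f[idx[[v]]]
      dev <- max(dev, max(abs(cur - margins[[v]])))
    }
    w <- w / sum(w)
    if (dev < tol) break
  }
  list(index = idx, prob = w, vars = vars, margins = margins)
}

#' Theoretical joint distribution of the survey fixture's risk variables
#'
#' Exposes the exact cell probabilities the fixture generator samples from
#' for one age group, so associations can be verified against brute-force
#' cell-count computation.
#'
#' @param spec a `marginal_spec`
#' @param correlation_config pair/odds table as in [default_correlation()]
#' @param age_group age-group label present in `spec`
#' @return data.table of category combinations with a `prob` column
#' @export
survey_joint_distribution <- function(spec, correlation_config,
                                      age_group) {
  stopifnot(inherits(spec, "marginal_spec"))
  prev <- spec$prevalence[[age_group]]
  if (is.null(prev)) stop("unknown age group: ", age_group)
  minor <- .age_group_bounds(age_group)$hi < 18
  vars <- if (minor) .marginal_vars_minor else .marginal_vars_adult
  vars <- intersect(vars, names(prev))
  joint <- .ipf_joint(prev[vars], correlation_config)
  out <- copy(joint$index)
  for (v in joint$vars) {
    set(out, j = v, value = names(joint$margins[[v]])[out[[v]]])
  }
  set(out, j = "prob", value = joint$prob)
  out[]
}

#' Generate a complete survey-like individual sample
#'
#' Synthetic stand-in for a fully imputed national health-interview /
#' examination sample: `n` complete individuals whose category frequencies
#' match the marginal spec in expectation and whose pairwise associations
#' follow `correlation_config`. Minors (<18) carry the lowest-risk state
#' for waist, blood-pressure medication, glucose history and T2D.
#'
#' @param spec a `marginal_spec`
#' @param correlation_config pair/odds table ([default_correlation()] by
#'   default)
#' @param n sample size (>= 100)
#' @param seed integer RNG seed
#' @return data.table of individuals with a `weight` column (all 1: the
#'   fixture emulates a self-weighting sample)
#' @export
generate_survey_fixture <- function(spec,
                                    correlation_config = default_correlation(),
                                    n = 10000, seed = 1L) {
  stopifnot(inherits(spec, "marginal_spec"), n >= 100)
  set.seed(as.integer(seed))
  groups <- spec$age_groups
  share <- groups$count / sum(groups$count)
  n_g <- floor(n * share)
  rem <- n - sum(n_g)
  if (rem > 0) {
    o <- order(n * share - n_g, decreasing = TRUE)[seq_len(rem)]
    n_g[o] <- n_g[o] + 1
  }
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    g <- groups$age_group[i]
    ng <- n_g[i]
    if (ng == 0L) next
    ages <- sample(groups$lo[i]:groups$hi[i], ng, replace = TRUE)
    # sex x province drawn jointly from the stratum targets so every
    # expansion stratum has donors
    st <- spec$strata[age_group == g & count > 0]
    si <- sample.int(nrow(st), ng, replace = TRUE, prob = st$count)
    # coverage fix-up: guarantee >= 1 donor per non-empty stratum
    missing <- setdiff(seq_len(nrow(st)), unique(si))
    if (length(missing) > 0 && ng >= nrow(st)) {
      tab <- tabulate(si, nrow(st))
      for (m in missing) {
        donorable <- which(si == which.max(tab))[1]
        tab[si[donorable]] <- tab[si[donorable]] - 1L
        si[donorable] <- m
        tab[m] <- tab[m] + 1L
      }
    }
    joint <- .ipf_joint(spec$prevalence[[g]][
      intersect(if (groups$hi[i] < 18) .marginal_vars_minor else
        .marginal_vars_adult, names(spec$prevalence[[g]]))],
      correlation_config)
    ci <- sample.int(nrow(joint$index), ng, replace = TRUE,
                     prob = joint$prob)
    dt <- data.table(age = ages, sex = st$sex[si], region = st$region[si],
                     province = st$province[si])
    for (v in joint$vars) {
      set(dt, j = v, value = names(joint$margins[[v]])[joint$index[[v]][ci]])
    }
    if (groups$hi[i] < 18) {
      dt[, `:=`(waist_class = "low", bp_medication = "no",
                high_glucose_history = "no", t2d = "no")]
    }
    out[[i]] <- dt
  }
  pop <- rbindlist(out, use.names = TRUE)
  pop[, `:=`(
    bp_medication = bp_medication == "yes",
    high_glucose_history = high_glucose_history == "yes",
    t2d = t2d == "yes"
  )]
  pop[, `:=`(
    id = seq_len(.N),
    weight = 1,
    alive = TRUE,
    baseline_prevalent = t2d,
    t2d_onset_year = NA_integer_,
    death_year = NA_integer_,
    death_cause = NA_character_
  )]
  setcolorder(pop, c("id", "age", "sex", "region", "province", "education",
                     "income", "bmi_class", "waist_class", "bp_medication",
                     "high_glucose_history", "t2d", "alive"))
  pop[]
}

#' Expand a survey sample to population marginals
#'
#' Weighted sampling with replacement of individuals within each
#' age group x sex x province stratum until the stratum's target count is
#' reached exactly. Education, income and risk factors ride along with the
#' sampled donor, preserving the survey correlation structure.
#'
#' @param sample data.table of individuals with a positive `weight` column
#' @param spec a `marginal_spec` providing the stratum targets
#' @param seed integer RNG seed
#' @return data.table of individuals with fresh unique `id`s
#' @export
expand_population <- function(sample, spec, seed = 1L) {
  stopifnot(inherits(spec, "marginal_spec"))
  sample <- as.data.table(sample)
  if (!"weight" %in% names(sample)) sample[, weight := 1]
  if (any(sample$weight <= 0)) stop("sampling weights must be > 0")
  set.seed(as.integer(seed))
  groups <- spec$age_groups$age_group
  sample_ag <- age_group_of(sample$age, groups)
  targets <- spec$strata[count > 0]
  picks <- vector("list", nrow(targets))
  for (i in seq_len(nrow(targets))) {
    rows <- which(sample_ag == targets$age_group[i] &
                    sample$sex == targets$sex[i] &
                    sample$province == targets$province[i])
    if (length(rows) == 0L) {
      stop("no survey donors for stratum ", targets$age_group[i], " / ",
           targets$sex[i], " / ", targets$province[i])
    }
    picks[[i]] <- if (length(rows) == 1L) {
      rep(rows, targets$count[i])
    } else {
      sample(rows, targets$count[i], replace = TRUE,
             prob = sample$weight[rows])
    }
  }
  pop <- sample[unlist(picks)]
  pop[, `:=`(id = seq_len(.N), weight = 1)]
  pop[]
}

#' Per-stratum category prevalence summary
#'
#' Weighted category fractions per stratum, emulating a descriptive
#' baseline table. Fractions within a variable sum to 1 in every stratum;
#' empty strata are simply absent from the output.
#'
#' @param pop data.table of individuals
#' @param grouping character vector of stratifiers, a subset of
#'   `c("age_group", "sex", "region", "province", "education")`; empty for
#'   an overall summary
#' @param variables variables to summarise (default: the risk-factor and
#'   socio-demographic categoricals present in `pop`)
#' @return data.table with grouping columns, `variable`, `category`,
#'   `share` and the stratum weight total `n`
#' @export
population_summary <- function(pop, grouping = character(),
                               variables = NULL) {
  pop <- as.data.table(pop)
  allowed <- c("age_group", "sex", "region", "province", "education")
  bad <- setdiff(grouping, allowed)
  if (length(bad) > 0) stop("unknown grouping variable: ",
                            paste(bad, collapse = ", "))
  work <- copy(pop)
  if ("age_group" %in% grouping && !"age_group" %in% names(work)) {
    work[, age_group := age_group_of(age)]
  }
  if (!"weight" %in% names(work)) work[, weight := 1]
  if (is.null(variables)) {
    variables <- intersect(names(t2d_levels), names(work))
    variables <- setdiff(variables, grouping)
  }
  out <- list()
  for (v in variables) {
    x <- work[, .(variable = v,
                  category = as.character(get(v)), weight)]
    if (is.logical(work[[v]])) {
      x[, category := ifelse(category == "TRUE", "yes", "no")]
    }
    if (length(grouping) > 0) x <- cbind(work[, ..grouping], x)
    agg <- x[, .(w = sum(weight)), by = c(grouping, "variable", "category")]
    agg[, `:=`(n = sum(w), share = w / sum(w)), by = grouping]
    if (length(grouping) == 0) agg[, `:=`(n = sum(w), share = w / sum(w))]
    agg[, w := NULL]
    out[[v]] <- agg
  }
  rbindlist(out)[]
}
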