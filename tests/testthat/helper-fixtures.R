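library(data.table)

# Write a long-format marginals CSV and read it back through the public
# loader, so test specs exercise the same path as user data.
make_spec <- function(counts,
                      prev,
                      scale = 1,
                      sex_split = c(male = 0.5, female = 0.5),
                      region_split = c(Brussels = 0.2, Flanders = 0.5,
                                       Wallonia = 0.3)) {
  rows <- list()
  for (g in names(counts)) {
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "population", age_group = g, category = "count",
      value = counts[[g]])
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "sex", age_group = g, category = names(sex_split),
      value = 100 * sex_split)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "region", age_group = g, category = names(region_split),
      value = 100 * region_split)
    for (v in names(prev[[g]])) {
      pv <- prev[[g]][[v]]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, age_group = g, category = names(pv),
        value = 100 * pv)
    }
  }
  path <- tempfile(fileext = ".csv")
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  read_marginals(path, scale = scale)
}

# single adult stratum (plus the mandatory 0-17 group) for focused tests
adult_spec <- function(n_adult = 10000, n_minor = 100,
                       t2d_prev = 0.062,
                       bmi = c(lt25 = 0.5, `25to30` = 0.3, gt30 = 0.2),
                       waist = c(low = 0.4, mid = 0.3, high = 0.3)) {
  make_spec(
    counts = list(`0-17` = n_minor, `18-80` = n_adult),
    prev = list(
      `0-17` = list(
        education = c(low = 0.2, intermediate = 0.3, high = 0.5),
        income = c(Q1 = 0.2, Q2 = 0.2, Q3 = 0.2, Q4 = 0.2, Q5 = 0.2),
        bmi_class = c(lt25 = 0.8, `25to30` = 0.15, gt30 = 0.05)),
      `18-80` = list(
        education = c(low = 0.2, intermediate = 0.3, high = 0.5),
        income = c(Q1 = 0.2, Q2 = 0.2, Q3 = 0.2, Q4 = 0.2, Q5 = 0.2),
        bmi_class = bmi,
        waist_class = waist,
        bp_medication = c(no = 0.85, yes = 0.15),
        high_glucose_history = c(no = 0.95, yes = 0.05),
        t2d = c(no = 1 - t2d_prev, yes = t2d_prev))))
}

# flat prevalence curves (no age trend) => empty transition tables
flat_curves <- function(ages = 18:80) {
  curves <- CJ(risk_factor = "bmi_class", sex = c("male", "female"),
               region = c("Brussels", "Flanders", "Wallonia"),
               education = c("low", "intermediate", "high"),
               age = ages, sorted = FALSE)
  out <- rbindlist(list(
    copy(curves)[, `:=`(state = "lt25", p = 0.5)],
    copy(curves)[, `:=`(state = "25to30", p = 0.3)],
    copy(curves)[, `:=`(state = "gt30", p = 0.2)]))
  out[]
}

# FINDRISC parameter set with a known constant 10-year risk
const_findrisc <- function(p10) {
  params <- read_findrisc_params()
  params$intercept <- qlogis(p10)
  params$intercept_se <- 0
  params$coefficients[, `:=`(estimate = 0, se = 0)]
  params
}

# mortality table with uniform configurable rates
flat_mortality <- function(all_cause = 0, t2d_cause = 0, max_age = 130) {
  dt <- CJ(age = 0:max_age, sex = c("male", "female"),
           region = c("Brussels", "Flanders", "Wallonia"), sorted = FALSE)
  dt[, `:=`(all_cause_rate = all_cause, t2d_cause_rate = t2d_cause)]
  dt[]
}

flat_rr <- function(rr = 1) {
  data.table(age_lo = 0L, age_hi = 199L, sex = c("male", "female"),
             rr = rr, rr_lo = rr, rr_hi = rr)
}

# empty transition table in the engine's schema
no_transitions <- function() {
  data.table(risk_factor = character(), sex = character(),
             region = character(), education = character(),
             age = integer(), from_state = character(),
             to_state = character(), p_move = numeric())
}

# minimal homogeneous adult cohort for engine tests
make_cohort <- function(n, age = 40, sex = "male", region = "Flanders",
                        education = "high", t2d = FALSE,
                        province = "Antwerp") {
  data.table(
    id = seq_len(n), age = as.integer(age), sex = sex, region = region,
    province = province, education = education, income = "Q3",
    bmi_class = "lt25", waist_class = "low", bp_medication = FALSE,
    high_glucose_history = FALSE, t2d = t2d, alive = TRUE, weight = 1,
    baseline_prevalent = t2d, t2d_onset_year = NA_integer_,
    death_year = NA_integer_, death_cause = NA_character_)
}

# tables bundle with everything switched off
null_tables <- function() {
  list(transitions = no_transitions(),
       mortality = flat_mortality(0, 0),
       rr = flat_rr(1),
       findrisc = const_findrisc(1e-12))
}

# independent brute-force IPF oracle, written with plain loops over a
# 2-variable contingency table (kept deliberately naive)
oracle_ipf_2var <- function(m1, m2, odds, iters = 10000) {
  k1 <- length(m1); k2 <- length(m2)
  cells <- matrix(0, k1, k2)
  for (i in 1:k1) for (j in 1:k2) {
    cells[i, j] <- m1[i] * m2[j] * odds^((i - 1) * (j - 1))
  }
  cells <- cells / sum(cells)
  for (it in 1:iters) {
    for (i in 1:k1) {
      rs <- sum(cells[i, ])
      if (rs > 0) cells[i, ] <- cells[i, ] * m1[i] / rs
    }
    for (j in 1:k2) {
      cs <- sum(cells[, j])
      if (cs > 0) cells[, j] <- cells[, j] * m2[j] / cs
    }
    cells <- cells / sum(cells)
    if (max(abs(rowSums(cells) - m1)) < 1e-13 &&
        max(abs(colSums(cells) - m2)) < 1e-13) break
  }
  cells
}

# grid-search oracle for K=3 net-transition calibration: coarse grid then
# local refinement at 1e-4 resolution, independent of Nelder-Mead
oracle_grid_k3 <- function(p_from, p_to) {
  dirs <- ifelse(abs(cumsum(p_from)[1:2] - cumsum(p_to)[1:2]) <= 1e-12, 0,
                 ifelse(cumsum(p_from)[1:2] > cumsum(p_to)[1:2], 1, -1))
  qmat <- function(f1, f2) {
    Q <- diag(3)
    if (dirs[1] > 0) { Q[1, 2] <- f1; Q[1, 1] <- Q[1, 1] - f1 }
    if (dirs[1] < 0) { Q[2, 1] <- f1; Q[2, 2] <- Q[2, 2] - f1 }
    if (dirs[2] > 0) { Q[2, 3] <- f2; Q[2, 2] <- Q[2, 2] - f2 }
    if (dirs[2] < 0) { Q[3, 2] <- f2; Q[3, 3] <- Q[3, 3] - f2 }
    Q
  }
  objective <- function(f1, f2) {
    Q <- qmat(f1, f2)
    if (any(diag(Q) < 0)) return(Inf)
    sum((p_to - as.vector(p_from %*% Q))^2)
  }
  best <- c(0, 0); best_obj <- objective(0, 0)
  search <- function(f1s, f2s) {
    for (f1 in f1s) for (f2 in f2s) {
      o <- objective(f1, f2)
      if (o < best_obj) { best_obj <<- o; best <<- c(f1, f2) }
    }
  }
  search(seq(0, 1, by = 1e-3), seq(0, 1, by = 1e-3))
  search(seq(max(0, best[1] - 2e-3), min(1, best[1] + 2e-3), by = 1e-4),
         seq(max(0, best[2] - 2e-3), min(1, best[2] + 2e-3), by = 1e-4))
  list(flows = best, objective = best_obj)
}
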