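test_that("null hazards: only age changes", {
  pop <- make_cohort(100, age = 40)
  before <- copy(pop)
  st <- step_year(pop, 2019, null_tables(), sim_config())
  expect_equal(st$pop$age, before$age + 1L)
  expect_equal(nrow(st$events), 0)
  same <- setdiff(names(before), "age")
  expect_identical(st$pop[, ..same], before[, ..same])
})

test_that("onset and death can share a year; dead are never touched", {
  tables <- null_tables()
  tables$findrisc <- const_findrisc(1 - 1e-12)    # annual prob ~ 0.94
  tables$mortality <- flat_mortality(all_cause = 50, t2d_cause = 5)
  pop <- make_cohort(300, age = 50)
  set.seed(1)
  st <- step_year(pop, 2019, tables, sim_config())
  ev <- st$events
  both <- intersect(ev[event == "t2d_onset", id], ev[event == "death", id])
  expect_gt(length(both), 0)
  expect_true(all(ev[id %in% both, year] == 2019))
  # a second step must not mutate the dead
  dead_before <- st$pop[alive == FALSE]
  st2 <- step_year(st$pop, 2020, tables, sim_config())
  expect_identical(st2$pop[alive == FALSE & id %in% dead_before$id],
                   dead_before)
})

test_that("onset counts follow the binomial oracle", {
  p10 <- 0.651
  tables <- null_tables()
  tables$findrisc <- const_findrisc(p10)
  pop <- make_cohort(1e5, age = 50)
  set.seed(2)
  st <- step_year(pop, 2019, tables, sim_config())
  p1 <- annual_probability(p10)
  onsets <- nrow(st$events[event == "t2d_onset"])
  expect_lt(abs(onsets - 1e5 * p1), 3 * sqrt(1e5 * p1 * (1 - p1)))
})

test_that("incidence respects the age floor", {
  tables <- null_tables()
  tables$findrisc <- const_findrisc(0.9)
  pop <- rbind(make_cohort(200, age = 30), make_cohort(200, age = 50)[
    , id := id + 200L])
  set.seed(3)
  st <- step_year(pop, 2019, tables, sim_config(incidence_age_floor = 35))
  expect_true(all(st$events[event == "t2d_onset", age] >= 35))
  expect_false(any(st$pop[age <= 31, t2d]))
})

test_that("run_simulation: trivial horizons, conservation, determinism", {
  pop <- make_cohort(200, age = 40)
  cfg0 <- sim_config(start_year = 2018, end_year = 2018, seed = 1)
  sim0 <- run_simulation(pop, cfg0, null_tables())
  expect_equal(nrow(sim0$events), 0)
  expect_equal(sort(unique(sim0$yearly$year)), 2018)

  # zero hazards: counts conserved plus births
  cfg <- sim_config(start_year = 2018, end_year = 2023, seed = 1,
                    births_enabled = TRUE, annual_birth_cohort = 10)
  sim <- run_simulation(pop, cfg, null_tables())
  alive_by_year <- sim$yearly[, .(alive = sum(alive)), by = year][order(year)]
  expect_equal(alive_by_year$alive, 200 + 10 * (0:5))

  sim_a <- run_simulation(pop, sim_config(end_year = 2022, seed = 42),
                          null_tables())
  sim_b <- run_simulation(pop, sim_config(end_year = 2022, seed = 42),
                          null_tables())
  expect_identical(sim_a$events, sim_b$events)
  expect_identical(sim_a$yearly, sim_b$yearly)
})

test_that("state machine admits only the legal transitions", {
  spec <- default_marginals(scale = 2000)
  s <- generate_survey_fixture(spec, n = 1500, seed = 4)
  pop <- expand_population(s, spec, seed = 5)
  tables <- default_tables(spec)
  sim <- run_simulation(pop, sim_config(seed = 6), tables)
  ev <- sim$events
  # at most one onset and one death per individual
  expect_true(all(ev[event == "t2d_onset", .N, by = id]$N == 1))
  expect_true(all(ev[event == "death", .N, by = id]$N == 1))
  # no event after death
  last_death <- ev[event == "death", .(dy = year), by = id]
  merged <- merge(ev, last_death, by = "id")
  expect_true(all(merged$year <= merged$dy))
  # onset never after death year; final state flags consistent
  fp <- sim$final_pop
  expect_true(all(fp[alive == FALSE, !is.na(death_year)]))
  expect_true(all(fp[t2d & !baseline_prevalent & alive,
                     !is.na(t2d_onset_year)]))
  both <- fp[!is.na(t2d_onset_year) & !is.na(death_year)]
  expect_true(all(both$t2d_onset_year <= both$death_year))
})

test_that("yearly accounting identity holds", {
  spec <- default_marginals(scale = 2000)
  s <- generate_survey_fixture(spec, n = 1500, seed = 7)
  pop <- expand_population(s, spec, seed = 8)
  sim <- run_simulation(pop, sim_config(seed = 9), default_tables(spec))
  tot <- sim$yearly[, .(alive = sum(alive), deaths = sum(deaths)),
                    by = year][order(year)]
  tot <- merge(tot, sim$births, by = "year")
  for (i in 2:nrow(tot)) {
    expect_equal(tot$alive[i],
                 tot$alive[i - 1] - tot$deaths[i] + tot$births[i])
  }
})

test_that("constant hazard, no mortality: analytic prevalence limit", {
  h10 <- 0.3
  tables <- null_tables()
  tables$findrisc <- const_findrisc(h10)
  h <- annual_probability(h10)
  k <- 5
  pop <- make_cohort(5e4, age = 40)
  sim <- run_simulation(pop, sim_config(start_year = 2018,
                                        end_year = 2018 + k, seed = 10,
                                        births_enabled = FALSE), tables)
  prev <- sim$final_pop[, mean(t2d)]
  expected <- 1 - (1 - h)^k
  expect_lt(abs(prev - expected), 3 * sqrt(expected * (1 - expected) / 5e4))
})

test_that("demographics other than age never change", {
  spec <- default_marginals(scale = 5000)
  s <- generate_survey_fixture(spec, n = 1000, seed = 11)
  pop <- expand_population(s, spec, seed = 12)
  sim <- run_simulation(pop, sim_config(seed = 13, end_year = 2021,
                                        births_enabled = FALSE),
                        default_tables(spec))
  cols <- c("id", "sex", "region", "province", "education", "income")
  expect_equal(as.data.frame(sim$final_pop[order(id), ..cols]),
               as.data.frame(pop[order(id), ..cols]))
  # survivors age one year per cycle; the dead stop ageing
  fp <- sim$final_pop[order(id)]
  p0 <- pop[order(id)]
  expect_equal(fp[alive == TRUE, age],
               p0[fp$alive == TRUE, age] + 3L)
  expect_true(all(fp[alive == FALSE, age] - p0[fp$alive == FALSE, age] <= 3L))
})
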