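test_that("survey fixture recovers configured marginals", {
  spec <- adult_spec(n_adult = 10000, t2d_prev = 0.062)
  s <- generate_survey_fixture(spec, n = 10000, seed = 42)
  adults <- s[age >= 18]
  # t2d fraction within 3 binomial SE of the configured 6.2%
  se <- sqrt(0.062 * (1 - 0.062) / nrow(adults))
  expect_lt(abs(mean(adults$t2d) - 0.062), 3 * se)
  # every other marginal, same tolerance
  for (v in c("bmi_class", "waist_class", "education")) {
    tgt <- spec$prevalence[["18-80"]][[v]]
    for (cat in names(tgt)) {
      phat <- mean(adults[[v]] == cat)
      se <- sqrt(tgt[[cat]] * (1 - tgt[[cat]]) / nrow(adults))
      expect_lt(abs(phat - tgt[[cat]]), 3 * se + 1e-12)
    }
  }
  expect_true(all(s$weight > 0))
  expect_false(anyNA(s[, .(age, sex, region, province, education, income,
                           bmi_class, waist_class)]))
})

test_that("degenerate prevalence vectors give identical individuals", {
  spec <- adult_spec(
    bmi = c(lt25 = 1, `25to30` = 0, gt30 = 0),
    waist = c(low = 0, mid = 0, high = 1))
  s <- generate_survey_fixture(spec, n = 500, seed = 1)
  adults <- s[age >= 18]
  expect_true(all(adults$bmi_class == "lt25"))
  expect_true(all(adults$waist_class == "high"))
})

test_that("configured associations match the brute-force IPF oracle", {
  spec <- adult_spec()
  config <- data.table(var1 = "bmi_class", var2 = "waist_class", odds = 3.0)
  joint <- survey_joint_distribution(spec, config, "18-80")
  # exhaustive cell-count oracle over the bmi x waist margin
  tab <- joint[, .(p = sum(prob)), by = .(bmi_class, waist_class)]
  oracle <- oracle_ipf_2var(spec$prevalence[["18-80"]]$bmi_class,
                            spec$prevalence[["18-80"]]$waist_class, 3.0)
  for (i in seq_along(t2d_levels$bmi_class)) {
    for (j in seq_along(t2d_levels$waist_class)) {
      got <- tab[bmi_class == t2d_levels$bmi_class[i] &
                   waist_class == t2d_levels$waist_class[j], p]
      expect_equal(got, oracle[i, j], tolerance = 1e-8)
    }
  }
  # marginals preserved exactly by the tilt + IPF
  expect_equal(as.vector(tapply(joint$prob, joint$bmi_class, sum)[
    t2d_levels$bmi_class]),
    unname(spec$prevalence[["18-80"]]$bmi_class), tolerance = 1e-9)
  # sampled odds ratio between extremes is positive and > 1
  s <- generate_survey_fixture(spec, config, n = 20000, seed = 3)
  a <- s[age >= 18]
  or <- (sum(a$bmi_class == "gt30" & a$waist_class == "high") *
           sum(a$bmi_class == "lt25" & a$waist_class == "low")) /
    (sum(a$bmi_class == "gt30" & a$waist_class == "low") *
       sum(a$bmi_class == "lt25" & a$waist_class == "high"))
  expect_gt(or, 1)
})

test_that("infeasible correlation config fails loudly", {
  spec <- adult_spec()
  bad <- data.table(var1 = "bmi_class", var2 = "waist_class", odds = -2)
  expect_error(generate_survey_fixture(spec, bad, n = 500, seed = 1),
               "finite and > 0")
  huge <- data.table(var1 = "bmi_class", var2 = "waist_class",
                     odds = 1e400)
  expect_error(survey_joint_distribution(spec, huge, "18-80"),
               "finite")
})

test_that("expansion hits stratum targets exactly and respects weights", {
  spec <- adult_spec(n_adult = 2000, n_minor = 200)
  s <- generate_survey_fixture(spec, n = 1000, seed = 5)
  pop <- expand_population(s, spec, seed = 6)
  got <- pop[, .N, by = .(age_group = age_group_of(age, c("0-17", "18-80")),
                          sex, province)]
  tgt <- spec$strata[count > 0]
  m <- merge(tgt, got,
             by.x = c("age_group", "sex", "province"),
             by.y = c("age_group", "sex", "province"), all = TRUE)
  expect_true(all(m$count == m$N))  # hard equality per stratum

  # two donors, weights 3:1 -> copy fraction near 0.75 (binomial oracle)
  donors <- make_cohort(2, age = 40, region = "Brussels",
                        province = "Brussels-Capital")
  donors[, weight := c(3, 1)]
  donors[, income := c("Q1", "Q2")]  # marks donor identity post-expansion
  one_spec <- make_spec(
    counts = list(`0-17` = 1, `18-80` = 10000),
    prev = list(`0-17` = list(), `18-80` = list()),
    sex_split = c(male = 1, female = 0),
    region_split = c(Brussels = 1, Flanders = 0, Wallonia = 0))
  minor_donor <- make_cohort(1, age = 5, region = "Brussels",
                             province = "Brussels-Capital")
  minor_donor[, id := 3L]
  big <- expand_population(rbind(donors, minor_donor), one_spec, seed = 1)
  frac <- mean(big[age == 40]$income == "Q1")
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(frac - 0.75), 3 * se)

  # single donor: weight irrelevant, copies exact
  solo <- expand_population(rbind(donors[1], minor_donor), one_spec,
                            seed = 2)
  expect_equal(sum(solo$age == 40), 10000)
})

test_that("empty donor stratum fails naming the stratum", {
  spec <- adult_spec(n_adult = 500, n_minor = 50)
  s <- generate_survey_fixture(spec, n = 500, seed = 5)
  s_no_minor <- s[age >= 18]
  expect_error(expand_population(s_no_minor, spec, seed = 1), "0-17")
})

test_that("population_summary fractions are coherent", {
  spec <- adult_spec(n_adult = 2000, n_minor = 200)
  s <- generate_survey_fixture(spec, n = 1000, seed = 8)
  pop <- expand_population(s, spec, seed = 9)
  ps <- population_summary(pop, grouping = c("sex", "region"))
  sums <- ps[, .(s = sum(share)), by = .(sex, region, variable)]
  expect_true(all(abs(sums$s - 1) < 1e-9))
  expect_error(population_summary(pop, grouping = "shoe_size"),
               "unknown grouping")
  one <- population_summary(pop[1], variables = "bmi_class")
  expect_true(all(one$share %in% c(0, 1)))
})

test_that("generation is deterministic under a fixed seed", {
  spec <- adult_spec(n_adult = 1000, n_minor = 100)
  a <- generate_survey_fixture(spec, n = 500, seed = 11)
  b <- generate_survey_fixture(spec, n = 500, seed = 11)
  expect_identical(a, b)
  pa <- expand_population(a, spec, seed = 3)
  pb <- expand_population(b, spec, seed = 3)
  expect_identical(pa, pb)
  expect_false(identical(
    generate_survey_fixture(spec, n = 500, seed = 12), a))
})

test_that("expanded prevalences converge to donor weighted prevalences", {
  spec <- adult_spec(n_adult = 100000, n_minor = 1000)
  s <- generate_survey_fixture(spec, n = 5000, seed = 21)
  pop <- expand_population(s, spec, seed = 22)
  # within-stratum resampling preserves the weighted donor distribution;
  # compare overall adult bmi prevalence at 3 binomial SE of n=100k
  donor_prev <- s[age >= 18, mean(bmi_class == "gt30")]
  pop_prev <- pop[age >= 18, mean(bmi_class == "gt30")]
  n <- pop[age >= 18, .N]
  expect_lt(abs(pop_prev - donor_prev),
            3 * sqrt(donor_prev * (1 - donor_prev) / n) + 0.01)
})
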