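#' Category levels used throughout the model
#'
#' Ordered category labels for every individual-level variable. Waist
#' classes use sex-specific cut meanings (men <94 / 94-102 / >=102 cm,
#' women <80 / 80-88 / >=88 cm) but share the low/mid/high labels.
#' @keywords internal
t2d_levels <- list(
  sex        = c("male", "female"),
  region     = c("Brussels", "Flanders", "Wallonia"),
  education  = c("low", "intermediate", "high"),
  income     = c("Q1", "Q2", "Q3", "Q4", "Q5"),
  bmi_class  = c("lt25", "25to30", "gt30"),
  waist_class = c("low", "mid", "high"),
  bp_medication = c("no", "yes"),
  high_glucose_history = c("no", "yes"),
  t2d        = c("no", "yes")
)

#' Provinces nested within regions (Brussels-Capital plus 5 + 5)
#' @keywords internal
t2d_provinces <- list(
  Brussels = "Brussels-Capital",
  Flanders = c("Antwerp", "East Flanders", "Flemish Brabant", "Limburg",
               "West Flanders"),
  Wallonia = c("Hainaut", "Liege", "Luxembourg", "Namur", "Walloon Brabant")
)

# variables with age-group prevalence vectors; adults only beyond bmi
.marginal_vars_minor <- c("education", "income", "bmi_class")
.marginal_vars_adult <- c("education", "income", "bmi_class", "waist_class",
                          "bp_medication", "high_glucose_history", "t2d")

.age_group_bounds <- function(age_group) {
  parts <- strsplit(age_group, "-", fixed = TRUE)
  lo <- as.integer(vapply(parts, `[`, "", 1L))
  hi <- as.integer(vapply(parts, `[`, "", 2L))
  list(lo = lo, hi = hi)
}

#' Assign individuals to the model's age groups
#'
#' @param age integer vector of ages in years
#' @param groups character vector of "lo-hi" group labels partitioning the
#'   modelled age range
#' @return character vector of group labels (NA outside the partition)
#' @export
age_group_of <- function(age, groups = c("0-17", "18-34", "35-64", "65-80")) {
  b <- .age_group_bounds(groups)
  out <- rep(NA_character_, length(age))
  for (i in seq_along(groups)) {
    out[age >= b$lo[i] & age <= b$hi[i]] <- groups[i]
  }
  # open-ended top group: ages past the last bound stay in the last group
  out[age > b$hi[length(groups)]] <- groups[length(groups)]
  out
}

#' Read a marginal specification from CSV
#'
#' The CSV is in long format with columns `variable, age_group, category,
#' value`. `variable == "population"` rows carry age-group population
#' counts; all other rows carry category percentages (renormalised to sum
#' to one within each variable x age group). Sex and region rows define the
#' expansion strata; province targets are obtained by splitting each
#' region's share uniformly across its provinces.
#'
#' @param path CSV file path
#' @param scale positive divisor applied to population counts so that
#'   desk-scale runs complete quickly (default 100)
#' @param baseline_year calendar year the marginals describe
#' @return a `marginal_spec` object
#' @export
read_marginals <- function(path, scale = 100, baseline_year = 2018) {
  stopifnot(scale > 0)
  raw <- as.data.table(read.csv(path, stringsAsFactors = FALSE))
  need <- c("variable", "age_group", "category", "value")
  if (!all(need %in% names(raw))) {
    stop("marginals CSV must have columns: ", paste(need, collapse = ", "))
  }
  counts <- raw[variable == "population"]
  age_groups <- counts$age_group
  b <- .age_group_bounds(age_groups)
  groups <- data.table(age_group = age_groups, lo = b$lo, hi = b$hi,
                       count = as.numeric(counts$value) / scale)

  prev <- list()
  for (g in age_groups) {
    vars <- list()
    sub <- raw[variable != "population" & age_group == g]
    for (v in unique(sub$variable)) {
      x <- sub[variable == v]
      pvec <- setNames(as.numeric(x$value), x$category)
      lev <- t2d_levels[[v]]
      if (!is.null(lev)) {
        if (!all(names(pvec) %in% lev)) {
          stop("unknown category for ", v, ": ",
               paste(setdiff(names(pvec), lev), collapse = ", "))
        }
        full <- setNames(numeric(length(lev)), lev)
        full[names(pvec)] <- pvec
        pvec <- full
      }
      s <- sum(pvec)
      if (s <= 0) stop("non-positive prevalence vector for ", v, " in ", g)
      vars[[v]] <- pvec / s
    }
    prev[[g]] <- vars
  }

  spec <- structure(list(
    age_groups = groups,
    prevalence = prev,
    baseline_year = baseline_year,
    scale = scale
  ), class = "marginal_spec")
  spec$strata <- .build_strata(spec)
  validate_marginals(spec)
  spec
}

# expansion strata: age group x sex x province, integer target counts
# (largest-remainder rounding keeps the age-group totals exact)
.build_strata <- function(spec) {
  out <- list()
  for (i in seq_len(nrow(spec$age_groups))) {
    g <- spec$age_groups$age_group[i]
    total <- spec$age_groups$count[i]
    sexp <- spec$prevalence[[g]][["sex"]]
    regp <- spec$prevalence[[g]][["region"]]
    if (is.null(sexp) || is.null(regp)) {
      stop("marginals must include sex and region rows for age group ", g)
    }
    cells <- CJ(sex = t2d_levels$sex, region = t2d_levels$region,
                sorted = FALSE)
    cells <- cells[, .(province = t2d_provinces[[region]]),
                   by = .(sex, region)]
    cells[, prob := sexp[sex] * regp[region] /
            vapply(region, function(r) length(t2d_provinces[[r]]), 1)]
    cells[, prob := prob / sum(prob)]
    raw <- cells$prob * total
    k <- floor(raw)
    rem <- round(total) - sum(k)
    if (rem > 0) {
      k[order(raw - k, decreasing = TRUE)[seq_len(rem)]] <-
        k[order(raw - k, decreasing = TRUE)[seq_len(rem)]] + 1
    }
    cells[, count := as.integer(k)]
    cells[, age_group := g]
    out[[g]] <- cells[, .(age_group, sex, region, province, count)]
  }
  rbindlist(out)
}

#' Validate a marginal specification
#'
#' Checks the invariants: positive counts, prevalence vectors summing to 1
#' within 1e-9, and age groups partitioning the modelled range.
#' @param spec a `marginal_spec`
#' @return the spec, invisibly; stops on violation
#' @export
validate_marginals <- function(spec) {
  stopifnot(inherits(spec, "marginal_spec"))
  if (any(spec$age_groups$count <= 0)) stop("age-group counts must be > 0")
  ag <- spec$age_groups[order(lo)]
  if (ag$lo[1] != 0) stop("age groups must start at 0")
  if (nrow(ag) > 1 && any(ag$lo[-1] != ag$hi[-nrow(ag)] + 1)) {
    stop("age groups must partition the age range contiguously")
  }
  for (g in names(spec$prevalence)) {
    for (v in names(spec$prevalence[[g]])) {
      s <- sum(spec$prevalence[[g]][[v]])
      if (abs(s - 1) > 1e-9) {
        stop("prevalence vector for ", v, " in ", g, " sums to ", s)
      }
    }
  }
  invisible(spec)
}

#' Bundled baseline marginal specification
#'
#' Loads the package's baseline (2018) marginal table: national age-group
#' population counts with per-age-group prevalence of sex, region,
#' education, income and the T2D risk factors. Province targets split each
#' region uniformly (the bundled table reports region only).
#'
#' @inheritParams read_marginals
#' @return a `marginal_spec`
#' @export
default_marginals <- function(scale = 100, baseline_year = 2018) {
  path <- system.file("extdata", "baseline_marginals.csv", package = "t2dsim")
  read_marginals(path, scale = scale, baseline_year = baseline_year)
}

#' @export
print.marginal_spec <- function(x, ...) {
  cat("<marginal_spec> baseline year", x$baseline_year,
      "| scale 1/", x$scale, "\n")
  cat("  age groups:", paste(x$age_groups$age_group, collapse = ", "), "\n")
  cat("  total population:", format(round(sum(x$age_groups$count)),
                                    big.mark = ","), "\n")
  invisible(x)
}
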