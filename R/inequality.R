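#' Relative and slope indices of inequality
#'
#' Regression-based inequality metrics across ordered socio-demographic
#' groups. Each group is placed at its ridit score (midpoint of its
#' cumulative population share, so the ordered spectrum spans 0-1). The
#' slope index of inequality (SII) is the slope of a share-weighted linear
#' regression of the rate on the ridit; the relative index of inequality
#' (RII) is the ratio of the predicted rate at ridit 1 versus ridit 0 from
#' a share-weighted log-linear (or Poisson, behind a flag) regression.
#' Uniform rates give RII = 1 and SII = 0; values above 1 / 0 indicate a
#' burden increasing towards the last-listed group.
#'
#' @param data data.frame with columns `group` (in spectrum order),
#'   `rate` (>= 0) and `share` (population shares summing to 1);
#'   optionally `cases` and `denom` counts for bootstrap CIs
#' @param method `"linear"` (WLS on log rate, default) or `"poisson"`
#'   (weighted quasi-Poisson GLM with log link) for the RII fit
#' @param n_boot bootstrap replicates for 95% CIs (0 = no CIs); requires
#'   `cases`/`denom` columns (parametric binomial resampling of counts)
#' @param epsilon floor applied to zero rates before the log fit (flagged
#'   in the result)
#' @return list `rii`, `sii`, `ridit`, `floored`, and with bootstrap:
#'   `rii_ci`, `sii_ci`
#' @export
rii_sii <- function(data, method = c("linear", "poisson"), n_boot = 0,
                    epsilon = 1e-6) {
  method <- match.arg(method)
  data <- as.data.frame(data)
  stopifnot(nrow(data) >= 2, all(data$rate >= 0),
            abs(sum(data$share) - 1) < 1e-9)
  ridit <- cumsum(data$share) - data$share / 2

  point <- .rii_sii_fit(data$rate, ridit, data$share, method, epsilon)
  out <- list(rii = point$rii, sii = point$sii, ridit = ridit,
              floored = point$floored)
  if (n_boot > 0) {
    if (!all(c("cases", "denom") %in% names(data))) {
      stop("bootstrap CIs require `cases` and `denom` columns")
    }
    scale_f <- data$rate / ifelse(data$cases > 0,
                                  data$cases / data$denom, 1)
    scale_f[!is.finite(scale_f) | scale_f == 0] <- 1e5
    reps <- vapply(seq_len(n_boot), function(b) {
      cs <- rbinom(nrow(data), data$denom,
                   pmin(pmax(data$cases / data$denom, 0), 1))
      r <- cs / data$denom * scale_f
      ft <- .rii_sii_fit(r, ridit, data$share, method, epsilon)
      c(ft$rii, ft$sii)
    }, numeric(2))
    out$rii_ci <- unname(quantile(reps[1, ], c(0.025, 0.975)))
    out$sii_ci <- unname(quantile(reps[2, ], c(0.025, 0.975)))
  }
  out
}

.rii_sii_fit <- function(rate, ridit, share, method, epsilon) {
  sii <- unname(coef(lm(rate ~ ridit, weights = share))[2])
  floored <- any(rate <= 0)
  if (method == "poisson") {
    fit <- suppressWarnings(glm(rate ~ ridit, family = stats::quasipoisson(),
                                weights = share))
    rii <- unname(exp(coef(fit)[2]))
  } else {
    r <- pmax(rate, epsilon)
    rii <- unname(exp(coef(lm(log(r) ~ ridit, weights = share))[2]))
  }
  list(rii = rii, sii = sii, floored = floored)
}

#' Intraclass correlation coefficient for absolute agreement
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC --
#' ICC(A,1) in the McGraw & Wong taxonomy -- with its F-based 95%
#' confidence interval. Used to validate generated per-stratum prevalences
#' against their targets.
#'
#' @param x,y paired per-stratum values (>= 5 pairs)
#' @param conf confidence level (default 0.95)
#' @return list `icc`, `ci` (length-2), `n`, and the mean squares
#' @export
icc_agreement <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x); k <- 2
  m <- cbind(x, y)
  if (var(x) == 0 && var(y) == 0) {
    stop("zero variance in both series: ICC undefined")
  }
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci = c(lo, hi), n = n,
       ms = c(rows = msr, cols = msc, error = mse))
}

#' Agreement between a generated population and its marginal targets
#'
#' Flattens target and realised per-age-group category prevalences into
#' paired vectors and returns their [icc_agreement()].
#'
#' @param pop generated population
#' @param spec the `marginal_spec` it was generated from
#' @param variables variables to compare (default: all prevalence
#'   variables in the spec)
#' @return list as from [icc_agreement()], plus the paired table
#' @export
population_agreement <- function(pop, spec, variables = NULL) {
  pop <- copy(as.data.table(pop))
  pop[, age_group := age_group_of(age, spec$age_groups$age_group)]
  got <- population_summary(pop, grouping = "age_group")
  pairs <- list()
  for (g in names(spec$prevalence)) {
    prev <- spec$prevalence[[g]]
    vars <- if (is.null(variables)) names(prev) else
      intersect(variables, names(prev))
    vars <- setdiff(vars, c("sex", "region"))
    for (v in vars) {
      tgt <- prev[[v]]
      for (cat in names(tgt)) {
        real <- got[age_group == g & variable == v & category == cat,
                    share]
        pairs[[length(pairs) + 1L]] <- data.table(
          age_group = g, variable = v, category = cat,
          target = tgt[[cat]],
          realised = if (length(real) == 1) real else 0)
      }
    }
  }
  tab <- rbindlist(pairs)
  res <- icc_agreement(tab$target, tab$realised)
  res$pairs <- tab
  res
}
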