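#' Age-smooth a prevalence curve
#'
#' Centered moving average over age of each state's prevalence series,
#' truncated at the boundaries, followed by joint renormalisation so the
#' state vector sums to 1 at every age.
#'
#' @param curve data.table with columns `risk_factor, sex, region,
#'   education, age, state, p` (long format; one probability per state per
#'   age per stratum)
#' @param window odd integer moving-average width in years (default 5)
#' @return smoothed curve in the same format
#' @export
smooth_prevalence <- function(curve, window = 5) {
  stopifnot(window >= 1, window %% 2 == 1)
  curve <- as.data.table(curve)
  key <- intersect(c("risk_factor", "sex", "region", "education", "state"),
                   names(curve))
  out <- copy(curve)
  setorderv(out, c(key, "age"))
  half <- (window - 1L) / 2L
  out[, {
    if (window > .N) stop("smoothing window larger than age range")
    NULL
  }, by = key]
  out[, p := {
    n <- .N
    sm <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      sm[i] <- mean(p[lo:hi])
    }
    sm
  }, by = key]
  norm_key <- setdiff(key, "state")
  out[, p := p / sum(p), by = c(norm_key, "age")]
  out[]
}

# directions of net flow across each adjacent-state boundary implied by the
# change in the cumulative distribution; +1 = up (k -> k+1), -1 = down, 0 none
.net_flow_directions <- function(p_from, p_to, tol = 1e-12) {
  d <- cumsum(p_from)[-length(p_from)] - cumsum(p_to)[-length(p_to)]
  ifelse(abs(d) <= tol, 0L, ifelse(d > 0, 1L, -1L))
}

# assemble the one-year transition matrix from boundary flows
.flows_to_matrix <- function(flows, dirs, K) {
  Q <- diag(K)
  for (k in seq_len(K - 1L)) {
    if (dirs[k] > 0) {
      Q[k, k + 1L] <- flows[k]
      Q[k, k] <- Q[k, k] - flows[k]
    } else if (dirs[k] < 0) {
      Q[k + 1L, k] <- flows[k]
      Q[k + 1L, k + 1L] <- Q[k + 1L, k + 1L] - flows[k]
    }
  }
  Q
}

#' Calibrate net annual transition probabilities between ordered states
#'
#' Finds one-directional flows between adjacent states such that applying
#' the resulting one-year matrix to `p_from` reproduces `p_to`, using
#' Nelder-Mead simplex minimisation of the squared error with flows
#' logit-transformed to stay in (0,1). The direction of each net flow is
#' fixed by the sign of the cumulative prevalence change it must produce,
#' so full bidirectional matrices (unidentifiable from two cross-sections)
#' are never attempted.
#'
#' @param p_from,p_to state-probability vectors (same length K in 2..3+,
#'   each summing to 1)
#' @param max_iter Nelder-Mead iteration cap (default 2000)
#' @param tol objective tolerance declaring an exact solution (default 1e-10)
#' @return list with `Q` (K x K matrix, rows sum to 1), `objective`,
#'   `flows`, `directions`, and `warning` (TRUE when no feasible exact
#'   solution was found and `Q` is the best fit)
#' @export
calibrate_net_transitions <- function(p_from, p_to, max_iter = 2000,
                                      tol = 1e-10) {
  K <- length(p_from)
  stopifnot(K >= 2, length(p_to) == K,
            abs(sum(p_from) - 1) < 1e-9, abs(sum(p_to) - 1) < 1e-9)
  dirs <- .net_flow_directions(p_from, p_to)
  active <- which(dirs != 0L)
  if (length(active) == 0L) {
    return(list(Q = diag(K), objective = 0, flows = numeric(K - 1L),
                directions = dirs, warning = FALSE))
  }
  obj <- function(theta) {
    flows <- numeric(K - 1L)
    flows[active] <- plogis(theta)
    Q <- .flows_to_matrix(flows, dirs, K)
    pen <- sum(pmax(-diag(Q), 0)^2) * 1e3
    sum((p_to - as.vector(p_from %*% Q))^2) + pen
  }
  # closed-form boundary-crossing start point, clipped into (0,1)
  d <- abs(cumsum(p_from)[-K] - cumsum(p_to)[-K])
  src <- ifelse(dirs > 0, seq_len(K - 1L), seq_len(K - 1L) + 1L)
  f0 <- pmin(pmax(ifelse(p_from[src] > 0, d / p_from[src], 0.5),
                  1e-6), 1 - 1e-6)
  theta0 <- qlogis(f0[active])
  fit <- suppressWarnings(optim(theta0, obj, method = "Nelder-Mead",
                                control = list(maxit = max_iter,
                                               reltol = 1e-14)))
  flows <- numeric(K - 1L)
  flows[active] <- plogis(fit$par)
  Q <- .flows_to_matrix(flows, dirs, K)
  # clamp tiny numerical negatives on the diagonal
  infeasible <- any(diag(Q) < -1e-9)
  Q[Q < 0 & Q > -1e-9] <- 0
  Q <- Q / rowSums(Q)
  objective <- sum((p_to - as.vector(p_from %*% Q))^2)
  list(Q = Q, objective = objective, flows = flows, directions = dirs,
       warning = infeasible || objective > tol)
}

#' Sample one annual state transition
#'
#' Draws the next state from one row of a transition matrix.
#'
#' @param state current 1-based state index
#' @param q_row probability vector over destination states (sums to 1)
#' @return next state index
#' @export
apply_transition <- function(state, q_row) {
  stopifnot(state >= 1, state <= length(q_row),
            abs(sum(q_row) - 1) < 1e-9, all(q_row >= 0))
  sample.int(length(q_row), 1L, prob = q_row)
}

#' Build per-age transition tables from prevalence curves
#'
#' For every stratum and single year of age, calibrates the net annual
#' transitions that carry the smoothed prevalence at age `a` to the
#' prevalence at `a + 1` (a period-as-cohort approximation). Identical
#' (p_from, p_to) pairs are calibrated once and reused. The result is a
#' compact table with one row per possible move: since flows are net,
#' each `from_state` has at most one destination.
#'
#' @param curves prevalence curves as accepted by [smooth_prevalence()]
#' @param window smoothing window (odd; default 5); use 1 to skip smoothing
#' @return data.table `risk_factor, sex, region, education, age,
#'   from_state, to_state, p_move` where `age` is the age at the start of
#'   the one-year interval
#' @export
build_transition_tables <- function(curves, window = 5) {
  sm <- smooth_prevalence(curves, window = window)
  key <- c("risk_factor", "sex", "region", "education")
  setorderv(sm, c(key, "age", "state"))
  wide <- dcast(sm, risk_factor + sex + region + education + age ~ state,
                value.var = "p")
  states_of <- sm[, .(states = list(unique(state))), by = risk_factor]
  out <- list()
  cache <- new.env(parent = emptyenv())
  for (rf in states_of$risk_factor) {
    sts <- states_of[risk_factor == rf, states][[1]]
    # preserve the model's canonical state order
    lev <- t2d_levels[[rf]]
    if (!is.null(lev)) sts <- lev[lev %in% sts]
    sub <- wide[risk_factor == rf]
    setorderv(sub, c("sex", "region", "education", "age"))
    gcols <- c("sex", "region", "education")
    rows <- sub[, {
      pm <- as.matrix(.SD[, sts, with = FALSE])
      res <- list()
      for (i in seq_len(.N - 1L)) {
        p_from <- pm[i, ]; p_to <- pm[i + 1L, ]
        ck <- paste(signif(c(p_from, p_to), 12), collapse = ",")
        cal <- cache[[ck]]
        if (is.null(cal)) {
          cal <- calibrate_net_transitions(p_from, p_to)
          cache[[ck]] <- cal
        }
        Q <- cal$Q
        mv <- which(Q - diag(length(sts)) > 1e-12, arr.ind = TRUE)
        if (nrow(mv) > 0) {
          res[[length(res) + 1L]] <- data.table(
            age = age[i], from_state = sts[mv[, 1]],
            to_state = sts[mv[, 2]],
            p_move = Q[mv])
        }
      }
      rbindlist(res)
    }, by = gcols]
    if (nrow(rows) > 0) {
      rows[, risk_factor := rf]
      out[[rf]] <- rows
    }
  }
  res <- rbindlist(out, use.names = TRUE)
  setcolorder(res, c("risk_factor", "sex", "region", "education", "age",
                     "from_state", "to_state", "p_move"))
  setkeyv(res, c("risk_factor", "sex", "region", "education", "age",
                 "from_state"))
  res[]
}

#' Synthetic default age-prevalence curves for the modifiable risk factors
#'
#' Anchors each factor's state prevalences at the baseline marginal table's
#' age-group values (placed at group midpoints) and interpolates linearly
#' on the logit scale over single years of age, constant beyond the outer
#' midpoints. Curves are replicated across sex x region x education (the
#' bundled baseline table does not stratify risk-factor prevalence further);
#' supply your own curves for stratum-specific dynamics.
#'
#' @param spec a `marginal_spec` (default [default_marginals()])
#' @param ages integer age grid (default 18:80; BMI extends to minors)
#' @return prevalence curves in [smooth_prevalence()] long format
#' @export
default_prevalence_curves <- function(spec = default_marginals(),
                                      ages = 18:80) {
  factors <- c("bmi_class", "waist_class", "bp_medication",
               "high_glucose_history")
  groups <- spec$age_groups
  mid <- (groups$lo + groups$hi) / 2
  out <- list()
  for (rf in factors) {
    lev <- t2d_levels[[rf]]
    have <- vapply(groups$age_group,
                   function(g) !is.null(spec$prevalence[[g]][[rf]]), TRUE)
    anchor_age <- mid[have]
    anchors <- do.call(rbind, lapply(groups$age_group[have], function(g) {
      spec$prevalence[[g]][[rf]][lev]
    }))
    grid_ages <- if (rf == "bmi_class") min(0, ages):max(ages) else ages
    pm <- matrix(0, length(grid_ages), length(lev))
    for (j in seq_along(lev)) {
      lp <- qlogis(pmin(pmax(anchors[, j], 1e-6), 1 - 1e-6))
      pm[, j] <- plogis(stats::approx(anchor_age, lp, xout = grid_ages,
                                      rule = 2)$y)
    }
    pm <- pm / rowSums(pm)
    cj <- CJ(sex = t2d_levels$sex, region = t2d_levels$region,
             education = t2d_levels$education, sorted = FALSE)
    per <- data.table(age = rep(grid_ages, each = length(lev)),
                      state = rep(lev, length(grid_ages)),
                      p = as.vector(t(pm)))
    per[, risk_factor := rf]
    out[[rf]] <- cbind(
      cj[rep(seq_len(nrow(cj)), each = nrow(per))],
      per[rep(seq_len(nrow(per)), times = nrow(cj))])
  }
  res <- rbindlist(out, use.names = TRUE)
  setcolorder(res, c("risk_factor", "sex", "region", "education", "age",
                     "state", "p"))
  res[]
}

# Vectorised annual risk-factor update used by the engine. `pop` has
# already been aged by one year; transitions keyed on the age at the start
# of the interval, i.e. current age - 1. A middle state may carry net
# flows in both directions (towards each neighbour), so up to two move
# rows per (stratum, age, from_state) are resolved with one uniform draw.
.update_risk_factors <- function(pop, transitions) {
  factors <- unique(transitions$risk_factor)
  alive_idx <- which(pop$alive)
  if (length(alive_idx) == 0L) return(pop)
  keycols <- c("risk_factor", "sex", "region", "education", "age",
               "from_state")
  for (rf in factors) {
    tr <- transitions[risk_factor == rf]
    tr[, slot := seq_len(.N), by = keycols]
    cur <- as.character(pop[[rf]][alive_idx])
    if (is.logical(pop[[rf]])) cur <- ifelse(pop[[rf]][alive_idx], "yes", "no")
    lookup <- data.table(
      sex = pop$sex[alive_idx], region = pop$region[alive_idx],
      education = pop$education[alive_idx],
      age = pop$age[alive_idx] - 1L, from_state = cur)
    lookup[, risk_factor := rf]
    hit1 <- tr[slot == 1L][lookup, on = keycols]
    p1 <- fifelse(is.na(hit1$p_move), 0, hit1$p_move)
    u <- runif(length(alive_idx))
    dest <- rep(NA_character_, length(alive_idx))
    dest[u < p1] <- hit1$to_state[u < p1]
    if (any(tr$slot == 2L)) {
      hit2 <- tr[slot == 2L][lookup, on = keycols]
      p2 <- fifelse(is.na(hit2$p_move), 0, hit2$p_move)
      sel <- u >= p1 & u < p1 + p2
      dest[sel] <- hit2$to_state[sel]
    }
    move <- !is.na(dest)
    if (any(move)) {
      rows <- alive_idx[move]
      if (is.logical(pop[[rf]])) {
        set(pop, rows, rf, dest[move] == "yes")
      } else {
        set(pop, rows, rf, dest[move])
      }
    }
  }
  pop
}
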