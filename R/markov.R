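#' Discrete annual discount factor
#'
#' @param t Cycle index (years from model start), `t >= 0`.
#' @param r Annual discount rate, `r >= 0`.
#' @return `(1 + r)^(-t)` (vectorized over `t`).
#' @export
discount_factor <- function(t, r) {
  if (any(t < 0)) stop("cycle index t must be nonnegative")
  if (r < 0) stop("discount rate must be nonnegative")
  (1 + r)^(-t)
}

#' Combine disease transitions with background mortality into a cycle matrix
#'
#' Death competes with severity transitions: each alive row's severity
#' entries are the disease probabilities scaled by survival `(1 - p_death)`,
#' its dead entry is `p_death`, and the dead row is absorbing.
#'
#' @param disease 3x3 disease transition matrix (see [disease_matrix()]).
#' @param p_death Annual death probability in `[0, 1]`.
#' @return 4x4 annual transition matrix over (mild, moderate, severe, dead);
#'   every row sums to 1 within 1e-12.
#' @export
build_cycle_matrix <- function(disease, p_death) {
  validate_disease_matrix(unclass(disease), attr(disease, "strategy") %||% "unnamed")
  if (!is.finite(p_death) || p_death < 0 || p_death > 1) {
    stop("p_death must lie in [0, 1]")
  }
  m <- matrix(0, 4, 4, dimnames = list(health_states(), health_states()))
  m[1:3, 1:3] <- unclass(disease) * (1 - p_death)
  m[1:3, 4] <- p_death
  m[4, 4] <- 1
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer-age strata (ages, weights) discretizing a truncated normal age
# distribution; sd 0 collapses to a single stratum at the rounded mean.
age_strata <- function(cohort) {
  if (cohort$sd_age == 0) {
    return(list(ages = as.integer(round(cohort$mean_age)), weights = 1))
  }
  ages <- seq(cohort$age_bounds[1], cohort$age_bounds[2])
  w <- stats::pnorm(ages + 0.5, cohort$mean_age, cohort$sd_age) -
    stats::pnorm(ages - 0.5, cohort$mean_age, cohort$sd_age)
  list(ages = ages, weights = w / sum(w))
}

#' Run the Markov cohort model for one strategy
#'
#' Propagates the cohort through annual cycles. The cohort is modeled as
#' weighted integer-age strata that each age by one year per cycle; each
#' stratum faces its own sex-mixed background mortality, and results are
#' aggregated by stratum weight. Death probability is forced to 1 once a
#' stratum reaches `config$max_age`. The run stops at the first cycle where
#' the aggregate alive fraction falls to `config$extinction_epsilon` or
#' below (the lifetime horizon), or after exactly `config$max_cycles` cycles
#' when a fixed horizon is set.
#'
#' @param disease 3x3 [disease_matrix()] for the strategy.
#' @param cohort A [cohort_spec()].
#' @param lt A [life_table()].
#' @param config A [model_config()].
#' @return A `cohort_trace`: list with `occupancy` ((T+1) x 4 matrix of
#'   state fractions at cycle starts t = 0..T), `effective_occupancy`
#'   (T x 3 matrix of alive-state person-year weights for cycles 0..T-1;
#'   trapezoidal half-cycle corrected when `config$half_cycle`), and
#'   `cycles_run` (T).
#' @export
run_cohort <- function(disease, cohort, lt, config = model_config()) {
  validate_disease_matrix(unclass(disease), attr(disease, "strategy") %||% "unnamed")
  if (!inherits(lt, "life_table")) lt <- life_table(lt)
  D <- unclass(disease)[1:3, 1:3]
  st <- age_strata(cohort)
  n <- length(st$ages)
  hard_cap <- 200L
  fixed_T <- if (is.finite(config$max_cycles)) as.integer(config$max_cycles) else NA_integer_
  cap <- if (!is.na(fixed_T)) fixed_T else hard_cap

  # precompute sex-mixed qx for every age a stratum can reach
  a0 <- min(st$ages)
  qmix <- mortality_probability(seq(a0, config$max_age), cohort$prop_female, lt)

  init <- c(0, cohort$initial_split, 0)
  # alive fractions per stratum: (mild = 0, moderate, severe)
  S <- cbind(0, matrix(rep(cohort$initial_split, each = n), n, 2))
  dead <- numeric(n)
  occ <- matrix(NA_real_, cap + 1L, 4L,
                dimnames = list(0:cap, health_states()))
  occ[1L, ] <- init

  T_run <- NA_integer_
  for (t in seq_len(cap)) {
    age_now <- st$ages + (t - 1L)
    pd <- qmix[pmin(age_now, config$max_age) - a0 + 1L]
    pd[age_now >= config$max_age] <- 1
    alive_mass <- rowSums(S)
    dead <- dead + alive_mass * pd
    S <- (S * (1 - pd)) %*% D
    occ[t + 1L, ] <- c(colSums(S * st$weights), sum(dead * st$weights))
    alive_frac <- 1 - occ[t + 1L, 4L]
    if (!is.na(fixed_T)) {
      if (t == fixed_T) { T_run <- t; break }
    } else if (alive_frac <= config$extinction_epsilon) {
      T_run <- t
      break
    }
  }
  if (is.na(T_run)) {
    stop(sprintf(
      "cohort did not fall below extinction_epsilon = %g within %d cycles; non-terminating configuration",
      config$extinction_epsilon, hard_cap
    ))
  }
  occ <- occ[seq_len(T_run + 1L), , drop = FALSE]
  eff <- if (config$half_cycle) {
    (occ[seq_len(T_run), 1:3, drop = FALSE] +
       occ[seq_len(T_run) + 1L, 1:3, drop = FALSE]) / 2
  } else {
    occ[seq_len(T_run), 1:3, drop = FALSE]
  }
  rownames(eff) <- seq_len(T_run) - 1L
  structure(list(
    occupancy = occ,
    effective_occupancy = eff,
    cycles_run = T_run,
    strategy = attr(disease, "strategy") %||% "unnamed"
  ), class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf(
    "<cohort_trace> strategy '%s': %d cycles, final dead fraction %.6f\n",
    x$strategy, x$cycles_run, x$occupancy[nrow(x$occupancy), "dead"]
  ))
  invisible(x)
}
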