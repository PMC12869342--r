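#' Health states of the fibromyalgia Markov model
#'
#' The model has four states: three alive severity states defined on the
#' 11-point numeric pain rating scale -- mild (0-3), moderate (4-6) and
#' severe (7-10) -- plus an absorbing dead state.
#'
#' @return Character vector of the four state labels, in model order.
#' @export
health_states <- function() c("mild", "moderate", "severe", "dead")

#' Alive severity states
#' @return Character vector \code{c("mild", "moderate", "severe")}.
#' @export
alive_states <- function() c("mild", "moderate", "severe")

#' Pain-scale ranges defining the severity states
#'
#' @return Named list of inclusive integer intervals on the 0-10 pain scale.
#' @export
pain_ranges <- function() {
  list(mild = c(0L, 3L), moderate = c(4L, 6L), severe = c(7L, 10L))
}

#' Construct a per-strategy disease transition matrix
#'
#' Annual transition probabilities among the alive severity states,
#' conditional on surviving the cycle. Background mortality is layered on
#' separately by [build_cycle_matrix()].
#'
#' @param probs 3x3 numeric matrix; rows and columns ordered
#'   mild, moderate, severe. Each row must sum to 1 within 1e-9.
#' @param strategy Strategy name (single string).
#' @return A `disease_matrix` object (a named 3x3 matrix with a
#'   `strategy` attribute).
#' @export
disease_matrix <- function(probs, strategy = "unnamed") {
  probs <- as.matrix(probs)
  if (!identical(dim(probs), c(3L, 3L))) {
    stop("disease transition matrix must be 3x3 (mild, moderate, severe)")
  }
  dimnames(probs) <- list(alive_states(), alive_states())
  validate_disease_matrix(probs, strategy)
  structure(probs, strategy = strategy, class = c("disease_matrix", "matrix", "array"))
}

validate_disease_matrix <- function(probs, strategy = "unnamed", tol = 1e-9) {
  if (any(!is.finite(probs)) || any(probs < -tol) || any(probs > 1 + tol)) {
    stop(sprintf("strategy '%s': transition probabilities must lie in [0, 1]", strategy))
  }
  rs <- rowSums(probs)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0) {
    stop(sprintf(
      "strategy '%s': transition row '%s' sums to %.10f, not 1",
      strategy, alive_states()[bad[1]], rs[bad[1]]
    ))
  }
  invisible(probs)
}

#' Cohort specification
#'
#' Demographics of the modeled cohort. The age distribution is normal with
#' the given mean and SD, discretized to integer-age strata truncated to
#' `age_bounds`; sex enters only through the mortality mix. Everyone enters
#' alive, split between the moderate and severe states.
#'
#' @param mean_age Mean age at entry (years). Default 48.4.
#' @param sd_age SD of age at entry (years). Default 10.4. `sd_age = 0`
#'   collapses the cohort to a single stratum at `round(mean_age)`.
#' @param prop_female Proportion female, in `[0, 1]`. Default 0.944.
#' @param initial_split Length-2 numeric `(prop_moderate, prop_severe)`,
#'   summing to 1. Default `c(0.5, 0.5)`.
#' @param age_bounds Integer `(min, max)` truncation bounds for the age
#'   distribution. Default `c(18, 90)`.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(mean_age = 48.4, sd_age = 10.4, prop_female = 0.944,
                        initial_split = c(0.5, 0.5), age_bounds = c(18L, 90L)) {
  stopifnot(length(initial_split) == 2, length(age_bounds) == 2)
  if (prop_female < 0 || prop_female > 1) stop("prop_female must lie in [0, 1]")
  if (abs(sum(initial_split) - 1) > 1e-9 || any(initial_split < 0)) {
    stop("initial_split (moderate, severe) must be nonnegative and sum to 1")
  }
  if (sd_age < 0) stop("sd_age must be nonnegative")
  age_bounds <- as.integer(round(age_bounds))
  if (mean_age < age_bounds[1] || mean_age > age_bounds[2]) {
    stop("mean_age must lie within age_bounds")
  }
  structure(list(
    mean_age = mean_age, sd_age = sd_age, prop_female = prop_female,
    initial_split = as.numeric(initial_split), age_bounds = age_bounds
  ), class = "cohort_spec")
}

#' Model run configuration
#'
#' @param discount_rate Annual discount rate applied to both costs and QALYs.
#'   Default 0.03.
#' @param wtp_thresholds Ascending willingness-to-pay thresholds ($/QALY).
#'   Default `c(50000, 100000, 150000)`.
#' @param perspective `"payer"` (direct medical + nonmedical costs) or
#'   `"societal"` (adds indirect costs).
#' @param extinction_epsilon Alive-fraction threshold at which the lifetime
#'   horizon is considered exhausted. Must lie in `(0, 1e-3]`. Default 1e-7.
#' @param max_age Age at which death probability is forced to 1 for every
#'   stratum. Default 100.
#' @param half_cycle Apply the trapezoidal half-cycle correction. Default TRUE.
#' @param max_cycles Optional fixed horizon (cycles). When `NA` (default) the
#'   model runs to cohort extinction, with an internal hard cap of 200 cycles
#'   beyond which a non-terminating configuration is an error.
#' @param reference_strategy Reference for iNMB reporting; `NULL` means the
#'   lowest-cost strategy.
#' @return A `model_config` list. Cycle length is fixed at 1 year.
#' @export
model_config <- function(discount_rate = 0.03,
                         wtp_thresholds = c(50000, 100000, 150000),
                         perspective = c("payer", "societal"),
                         extinction_epsilon = 1e-7,
                         max_age = 100L,
                         half_cycle = TRUE,
                         max_cycles = NA_integer_,
                         reference_strategy = NULL) {
  perspective <- match.arg(perspective)
  if (discount_rate < 0) stop("discount_rate must be nonnegative")
  if (any(wtp_thresholds <= 0) || is.unsorted(wtp_thresholds, strictly = TRUE)) {
    stop("wtp_thresholds must be positive and strictly ascending")
  }
  if (extinction_epsilon <= 0 || extinction_epsilon > 1e-3) {
    stop("extinction_epsilon must lie in (0, 1e-3]")
  }
  structure(list(
    discount_rate = discount_rate, cycle_length = 1L,
    wtp_thresholds = as.numeric(wtp_thresholds), perspective = perspective,
    extinction_epsilon = extinction_epsilon, max_age = as.integer(max_age),
    half_cycle = isTRUE(half_cycle), max_cycles = max_cycles,
    reference_strategy = reference_strategy
  ), class = "model_config")
}
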