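#' Per-state utilities and annual cost components
#'
#' Annual values per alive severity state. Utilities are QALY weights in
#' `[0, 1]`. Cost components are direct medical (hospitalizations, outpatient
#' and emergency care, diagnostics, out-of-pocket), direct nonmedical, and
#' indirect (productivity losses, work absence, unpaid caregiving; counted
#' only under the societal perspective).
#'
#' @param df data.frame with columns `state` (mild/moderate/severe),
#'   `utility`, `direct_medical`, `direct_nonmedical`, `indirect` -- all
#'   annual dollar values except `utility`.
#' @return A `state_economics` data.frame ordered mild, moderate, severe.
#' @export
state_economics <- function(df) {
  req <- c("state", "utility", "direct_medical", "direct_nonmedical", "indirect")
  if (!all(req %in% names(df))) {
    stop("state economics must have columns ", paste(req, collapse = ", "))
  }
  df <- df[, req]
  if (!setequal(df$state, alive_states()) || nrow(df) != 3) {
    stop("state economics must have exactly one row per alive state")
  }
  df <- df[match(alive_states(), df$state), , drop = FALSE]
  if (any(df$utility < 0 | df$utility > 1)) stop("utilities must lie in [0, 1]")
  costs <- as.matrix(df[, c("direct_medical", "direct_nonmedical", "indirect")])
  if (any(costs < 0)) stop("cost components must be nonnegative")
  rownames(df) <- NULL
  structure(df, class = c("state_economics", "data.frame"))
}

#' Accrue lifetime discounted costs and QALYs from a cohort trace
#'
#' Each cycle's (half-cycle-corrected) alive-state person-year weights are
#' multiplied by the per-state utility and annual cost, then discounted at
#' `(1 + r)^(-t)`. The payer perspective counts direct medical + direct
#' nonmedical + drug acquisition cost; the societal perspective adds
#' indirect costs. Drug cost accrues for every alive person-year.
#'
#' @param trace A `cohort_trace` from [run_cohort()].
#' @param econ A [state_economics()].
#' @param drug_cost Annual drug acquisition cost ($/year while alive).
#' @param perspective `"payer"` or `"societal"`; defaults to the config's.
#' @param config A [model_config()] (supplies the discount rate).
#' @return A one-row `strategy_outcome` data.frame with columns `strategy`,
#'   `cost`, `qaly`, `perspective`.
#' @export
accrue_outcomes <- function(trace, econ, drug_cost = 0,
                            perspective = NULL, config = model_config()) {
  stopifnot(inherits(trace, "cohort_trace"))
  econ <- state_economics(econ)
  perspective <- perspective %||% config$perspective
  if (!perspective %in% c("payer", "societal")) {
    stop("perspective must be 'payer' or 'societal'")
  }
  if (drug_cost < 0) stop("drug_cost must be nonnegative")
  eff <- trace$effective_occupancy
  tt <- seq_len(nrow(eff)) - 1L
  disc <- discount_factor(tt, config$discount_rate)
  u <- econ$utility
  cost_state <- econ$direct_medical + econ$direct_nonmedical + drug_cost
  if (perspective == "societal") cost_state <- cost_state + econ$indirect
  qaly <- sum(disc * (eff %*% u))
  cost <- sum(disc * (eff %*% cost_state))
  structure(data.frame(
    strategy = trace$strategy, cost = cost, qaly = qaly,
    perspective = perspective, stringsAsFactors = FALSE
  ), class = c("strategy_outcome", "data.frame"))
}

#' Construct strategy outcomes directly from cost/QALY values
#'
#' Used to feed externally supplied lifetime (cost, QALY) pairs straight
#' into the economics layer, bypassing the Markov engine.
#'
#' @param strategy Character vector of strategy names.
#' @param cost,qaly Numeric vectors of discounted lifetime values.
#' @param perspective `"payer"` or `"societal"`.
#' @return A `strategy_outcome` data.frame, one row per strategy.
#' @export
strategy_outcomes <- function(strategy, cost, qaly, perspective = "payer") {
  stopifnot(length(strategy) == length(cost), length(cost) == length(qaly))
  if (any(cost < 0) || any(qaly < 0)) stop("costs and QALYs must be nonnegative")
  structure(data.frame(
    strategy = as.character(strategy), cost = as.numeric(cost),
    qaly = as.numeric(qaly), perspective = perspective,
    stringsAsFactors = FALSE
  ), class = c("strategy_outcome", "data.frame"))
}

outcome_row <- function(outcomes, strategy) {
  i <- match(strategy, outcomes$strategy)
  if (is.na(i)) stop(sprintf("strategy '%s' not found in outcomes", strategy))
  outcomes[i, , drop = FALSE]
}

#' Incremental cost-effectiveness ratio
#'
#' `(cost_c - cost_r) / (qaly_c - qaly_r)` between a candidate and a
#' reference outcome. Undefined when the QALYs are equal; dominance logic
#' must handle that case instead.
#'
#' @param candidate,reference One-row `strategy_outcome`s with the same
#'   perspective.
#' @return ICER in $/QALY, unrounded (round only for reporting).
#' @export
icer <- function(candidate, reference) {
  check_same_perspective(candidate, reference)
  dq <- candidate$qaly - reference$qaly
  if (dq == 0) {
    stop(sprintf(
      "ICER undefined: '%s' and '%s' have equal QALYs; handle via dominance",
      candidate$strategy, reference$strategy
    ))
  }
  (candidate$cost - reference$cost) / dq
}

#' Incremental net monetary benefit
#'
#' `wtp * (qaly_c - qaly_r) - (cost_c - cost_r)` -- positive when the health
#' gain is worth more than the added spending at the given willingness to pay.
#'
#' @param candidate,reference One-row `strategy_outcome`s with the same
#'   perspective.
#' @param wtp Willingness-to-pay threshold(s) in $/QALY, nonnegative.
#' @return Data.frame with columns `strategy`, `reference`, `wtp`, `inmb`
#'   (unrounded; round only for reporting), one row per threshold.
#' @export
inmb <- function(candidate, reference, wtp) {
  check_same_perspective(candidate, reference)
  if (any(wtp < 0)) stop("willingness-to-pay must be nonnegative")
  data.frame(
    strategy = candidate$strategy, reference = reference$strategy,
    wtp = as.numeric(wtp),
    inmb = wtp * (candidate$qaly - reference$qaly) - (candidate$cost - reference$cost),
    stringsAsFactors = FALSE
  )
}

check_same_perspective <- function(candidate, reference) {
  stopifnot(
    inherits(candidate, "strategy_outcome"), nrow(candidate) == 1,
    inherits(reference, "strategy_outcome"), nrow(reference) == 1
  )
  if (!identical(candidate$perspective, reference$perspective)) {
    stop("candidate and reference outcomes are from different perspectives")
  }
  invisible(TRUE)
}
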