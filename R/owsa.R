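#' Deterministic one-way sensitivity analysis (tornado)
#'
#' Varies each listed parameter independently across its plausible range
#' while holding all others at base case, each time re-running the
#' deterministic pipeline for the candidate and reference strategies and
#' recording the incremental net monetary benefit of the pair at the given
#' willingness-to-pay threshold.
#'
#' @param inputs Base-case [cea_inputs()].
#' @param cohort A [cohort_spec()].
#' @param config A [model_config()].
#' @param ranges data.frame with columns `parameter`, `low`, `high`; each
#'   range must bracket the base value and respect the parameter's domain.
#'   See [default_dsa_ranges()].
#' @param candidate,reference Strategy names for the compared pair.
#' @param wtp Willingness-to-pay threshold ($/QALY).
#' @return A `tornado` data.frame with columns `parameter`, `low`, `high`,
#'   `inmb_low`, `inmb_high`, `width` (= `|inmb_high - inmb_low|`), sorted
#'   descending by `width`.
#' @export
one_way_sensitivity <- function(inputs, cohort, config = model_config(),
                                ranges, candidate, reference, wtp) {
  stopifnot(all(c("parameter", "low", "high") %in% names(ranges)))
  if (length(wtp) != 1 || wtp < 0) stop("wtp must be a single nonnegative value")
  base <- list_parameters(inputs)
  pair_inmb <- function(inp) {
    oc <- pipeline_pair(inp, cohort, config, c(candidate, reference))
    inmb(outcome_row(oc, candidate), outcome_row(oc, reference), wtp)$inmb
  }
  rows <- lapply(seq_len(nrow(ranges)), function(i) {
    nm <- ranges$parameter[i]
    lo <- ranges$low[i]; hi <- ranges$high[i]
    if (!nm %in% names(base)) stop(sprintf("unknown parameter '%s' in ranges", nm))
    if (lo > base[[nm]] || hi < base[[nm]]) {
      stop(sprintf("range for '%s' must bracket its base value %g", nm, base[[nm]]))
    }
    i_low <- pair_inmb(set_parameter(inputs, nm, lo))
    i_high <- pair_inmb(set_parameter(inputs, nm, hi))
    data.frame(parameter = nm, low = lo, high = hi,
               inmb_low = i_low, inmb_high = i_high,
               width = abs(i_high - i_low), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$width, out$parameter), ]
  rownames(out) <- NULL
  structure(out, candidate = candidate, reference = reference, wtp = wtp,
            class = c("tornado", "data.frame"))
}

# outcomes for a subset of strategies only (cheaper than the full pipeline)
pipeline_pair <- function(inputs, cohort, config, keep) {
  inputs$transitions <- inputs$transitions[unique(keep)]
  inputs$drug_costs <- inputs$drug_costs[unique(keep)]
  compute_outcomes(inputs, cohort, config)
}

#' Default plausible ranges for the one-way sensitivity analysis
#'
#' Each parameter is varied by +/- a fixed fraction of its base value,
#' clipped to the parameter's domain (probabilities and utilities to
#' `[0, 1]`, costs to nonnegative values).
#'
#' @param inputs A [cea_inputs()].
#' @param frac Fractional half-width. Default 0.2.
#' @param parameters Optional subset of parameter ids; default all.
#' @return data.frame with columns `parameter`, `low`, `high`.
#' @export
default_dsa_ranges <- function(inputs, frac = 0.2, parameters = NULL) {
  base <- list_parameters(inputs)
  if (!is.null(parameters)) {
    missing <- setdiff(parameters, names(base))
    if (length(missing) > 0) stop(sprintf("unknown parameter '%s'", missing[1]))
    base <- base[parameters]
  }
  kind <- vapply(strsplit(names(base), ":", fixed = TRUE), `[`, "", 1)
  lo <- base * (1 - frac)
  hi <- base * (1 + frac)
  cap1 <- kind %in% c("tp", "utility")
  hi[cap1] <- pmin(1, hi[cap1])
  data.frame(parameter = names(base), low = as.numeric(lo),
             high = as.numeric(hi), stringsAsFactors = FALSE)
}
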