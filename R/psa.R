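#' Build moment-matched distribution specs for every model parameter
#'
#' Transition probabilities get beta distributions, cost parameters (state
#' cost components and drug costs) get gamma, and utilities get lognormal
#' (samples capped at 1 at draw time). The standard error defaults to a
#' fixed fraction of each mean; parameters with mean 0 (and probabilities
#' at 0 or 1) are held fixed.
#'
#' @param inputs A [cea_inputs()].
#' @param se_frac Standard error as a fraction of the mean. Default 0.2.
#' @param overrides Optional named list of `dist_spec`s replacing the
#'   defaults for specific parameter ids.
#' @return Named list of `dist_spec`s covering every parameter of `inputs`.
#' @export
build_distribution_specs <- function(inputs, se_frac = 0.2, overrides = list()) {
  base <- list_parameters(inputs)
  specs <- vector("list", length(base))
  names(specs) <- names(base)
  for (nm in names(base)) {
    v <- base[[nm]]
    kind <- strsplit(nm, ":", fixed = TRUE)[[1]][1]
    specs[[nm]] <- if (kind == "tp") {
      if (v <= 0 || v >= 1) fixed_dist(v) else beta_from_moments(v, se_frac * v)
    } else if (kind == "utility") {
      lognormal_from_moments(v, se_frac * v)
    } else {
      if (v == 0) fixed_dist(0) else gamma_from_moments(v, se_frac * v)
    }
  }
  for (nm in names(overrides)) {
    if (!nm %in% names(specs)) stop(sprintf("override for unknown parameter '%s'", nm))
    specs[[nm]] <- overrides[[nm]]
  }
  specs
}

#' Sample one complete parameter realization
#'
#' Every parameter is drawn from its spec. Transition-matrix rows are
#' sampled entrywise from their beta specs and then renormalized to sum to
#' 1 (an approximation to a Dirichlet); utility draws are capped at 1;
#' gamma cost draws are nonnegative by construction.
#'
#' @param inputs Base-case [cea_inputs()] (supplies structure and any value
#'   a `fixed` spec pins down).
#' @param specs Named list of `dist_spec`s from [build_distribution_specs()];
#'   every parameter of `inputs` must have one.
#' @param seed Optional integer; when given, `set.seed(seed)` is called
#'   first so the realization is reproducible in isolation. Leave `NULL`
#'   inside a PSA loop, which manages one stream via its own seed.
#' @return A new `cea_inputs` realization.
#' @export
sample_parameter_set <- function(inputs, specs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- list_parameters(inputs)
  missing <- setdiff(names(base), names(specs))
  if (length(missing) > 0) {
    stop(sprintf("missing distribution spec for parameter '%s'", missing[1]))
  }
  draws <- vapply(names(base), function(nm) draw_dist(specs[[nm]], 1), 0)

  out <- inputs
  for (s in strategies(inputs)) {
    m <- matrix(0, 3, 3, dimnames = list(alive_states(), alive_states()))
    for (fr in alive_states()) {
      row <- vapply(alive_states(), function(to) {
        draws[[paste("tp", s, fr, to, sep = ":")]]
      }, 0)
      if (sum(row) <= 0) stop(sprintf("sampled transition row '%s' for '%s' is all zero", fr, s))
      m[fr, ] <- row / sum(row)
    }
    out$transitions[[s]] <- disease_matrix(m, strategy = s)
  }
  for (st in alive_states()) {
    i <- which(out$econ$state == st)
    out$econ$utility[i] <- min(1, draws[[paste("utility", st, sep = ":")]])
    out$econ$direct_medical[i] <- draws[[paste("cost", "direct_medical", st, sep = ":")]]
    out$econ$direct_nonmedical[i] <- draws[[paste("cost", "direct_nonmedical", st, sep = ":")]]
    out$econ$indirect[i] <- draws[[paste("cost", "indirect", st, sep = ":")]]
  }
  for (s in strategies(inputs)) {
    out$drug_costs[[s]] <- draws[[paste("drug", s, sep = ":")]]
  }
  out
}

#' Probabilistic sensitivity analysis (second-order Monte Carlo)
#'
#' For each draw, samples a complete parameter set and runs the full Markov
#' + accrual pipeline for every strategy, recording discounted lifetime
#' (cost, QALY) under the configured perspective.
#'
#' @param inputs Base-case [cea_inputs()].
#' @param cohort A [cohort_spec()].
#' @param config A [model_config()].
#' @param specs Distribution specs from [build_distribution_specs()].
#' @param n_draws Number of second-order draws. Default 1000.
#' @param seed RNG seed; recorded on the result. Default 20240101.
#' @return A `psa_result` data.frame with columns `draw`, `strategy`,
#'   `cost`, `qaly` and attributes `n_draws`, `seed`, `perspective`.
#' @export
run_psa <- function(inputs, cohort, config = model_config(), specs,
                    n_draws = 1000, seed = 20240101) {
  if (n_draws < 1) stop("n_draws must be at least 1")
  set.seed(seed)
  strat <- strategies(inputs)
  res <- vector("list", n_draws)
  for (d in seq_len(n_draws)) {
    par_d <- tryCatch(
      sample_parameter_set(inputs, specs),
      error = function(e) stop(sprintf("PSA draw %d: %s", d, conditionMessage(e)))
    )
    rows <- tryCatch(
      compute_outcomes(par_d, cohort, config),
      error = function(e) stop(sprintf("PSA draw %d: %s", d, conditionMessage(e)))
    )
    rows$draw <- d
    res[[d]] <- rows
  }
  out <- do.call(rbind, res)
  out <- out[, c("draw", "strategy", "cost", "qaly")]
  rownames(out) <- NULL
  structure(out, n_draws = as.integer(n_draws), seed = seed,
            perspective = config$perspective,
            class = c("psa_result", "data.frame"))
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay value, the probability a strategy is
#' cost-effective is the fraction of PSA draws in which it attains the
#' maximum net monetary benefit `wtp * qaly - cost`; exact ties split the
#' draw's probability mass equally.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Ascending, nonempty grid of WTP values.
#' @return A `ceac_curve` data.frame with columns `strategy`, `wtp`,
#'   `probability` (long format, plot-ready). Probabilities sum to 1 over
#'   strategies at each WTP.
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0) stop("wtp_grid must be nonempty")
  if (is.unsorted(wtp_grid)) stop("wtp_grid must be ascending")
  strat <- unique(psa$strategy)
  Q <- matrix(psa$qaly, ncol = length(strat), byrow = TRUE,
              dimnames = list(NULL, strat))
  C <- matrix(psa$cost, ncol = length(strat), byrow = TRUE)
  out <- lapply(as.numeric(wtp_grid), function(w) {
    nmb <- w * Q - C
    mx <- do.call(pmax, as.data.frame(nmb))
    win <- nmb == mx
    mass <- win / rowSums(win)
    data.frame(strategy = strat, wtp = w, probability = colMeans(mass),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("ceac_curve", "data.frame"))
}
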