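# CSV dialect: UTF-8, comma-separated, "." decimal, mandatory headers.
# Numbers are serialized with %.17g so write -> read round-trips doubles
# bit-exactly; display rounding lives only in cea_report().

write_csv_exact <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_checked_csv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
  }
  df
}

#' Read and write per-strategy transition matrices
#'
#' Long CSV with header `strategy,from_state,to_state,prob`; states named
#' mild/moderate/severe. Every (strategy, from_state) row must sum to 1.
#'
#' @param path CSV file path.
#' @return `read_transition_matrices()`: named list of [disease_matrix()].
#' @export
read_transition_matrices <- function(path) {
  df <- read_checked_csv(path, c("strategy", "from_state", "to_state", "prob"))
  bad <- !df$from_state %in% alive_states() | !df$to_state %in% alive_states()
  if (any(bad)) {
    stop(sprintf("%s: unknown state in row %d", path, which(bad)[1] + 1L))
  }
  out <- lapply(split(df, df$strategy), function(d) {
    m <- matrix(NA_real_, 3, 3, dimnames = list(alive_states(), alive_states()))
    m[cbind(d$from_state, d$to_state)] <- d$prob
    if (anyNA(m)) {
      stop(sprintf("%s: incomplete matrix for strategy '%s'", path, d$strategy[1]))
    }
    disease_matrix(m, strategy = d$strategy[1])
  })
  out[unique(df$strategy)]
}

#' @rdname read_transition_matrices
#' @param transitions Named list of [disease_matrix()].
#' @export
write_transition_matrices <- function(transitions, path) {
  rows <- lapply(names(transitions), function(s) {
    m <- unclass(transitions[[s]])
    expand <- expand.grid(to_state = alive_states(), from_state = alive_states(),
                          stringsAsFactors = FALSE)
    data.frame(strategy = s, from_state = expand$from_state,
               to_state = expand$to_state,
               prob = m[cbind(expand$from_state, expand$to_state)],
               stringsAsFactors = FALSE)
  })
  write_csv_exact(do.call(rbind, rows), path)
}

#' Read and write a life table
#'
#' CSV with header `age,sex,qx`, one row per (age, sex).
#'
#' @param path CSV file path.
#' @return `read_life_table()`: a [life_table()].
#' @export
read_life_table <- function(path) {
  life_table(read_checked_csv(path, c("age", "sex", "qx")))
}

#' @rdname read_life_table
#' @param lt A [life_table()].
#' @export
write_life_table <- function(lt, path) {
  write_csv_exact(as.data.frame(lt), path)
}

#' Read and write per-state economics
#'
#' CSV with header `state,utility,direct_medical,direct_nonmedical,indirect`.
#' The `indirect` column carries 3-month indirect cost estimates, as mapped
#' from burden-of-illness sources; it is annualized (x4) at ingestion, and
#' divided back by 4 on write so the file round-trips exactly.
#'
#' @param path CSV file path.
#' @return `read_state_economics()`: a [state_economics()] with annualized
#'   indirect costs.
#' @export
read_state_economics <- function(path) {
  df <- read_checked_csv(path, c("state", "utility", "direct_medical",
                                 "direct_nonmedical", "indirect"))
  num <- c("utility", "direct_medical", "direct_nonmedical", "indirect")
  df[num] <- lapply(df[num], as.numeric)
  df$indirect <- df$indirect * 4
  state_economics(df)
}

#' @rdname read_state_economics
#' @param econ A [state_economics()] (annual values).
#' @export
write_state_economics <- function(econ, path) {
  df <- as.data.frame(econ)
  df$indirect <- df$indirect / 4
  write_csv_exact(df, path)
}

#' Read and write annual drug acquisition costs
#'
#' CSV with header `strategy,drug_cost_annual`.
#'
#' @param path CSV file path.
#' @return `read_drug_costs()`: named numeric vector.
#' @export
read_drug_costs <- function(path) {
  df <- read_checked_csv(path, c("strategy", "drug_cost_annual"))
  stats::setNames(as.numeric(df$drug_cost_annual), df$strategy)
}

#' @rdname read_drug_costs
#' @param drug_costs Named numeric vector.
#' @export
write_drug_costs <- function(drug_costs, path) {
  write_csv_exact(data.frame(strategy = names(drug_costs),
                             drug_cost_annual = as.numeric(drug_costs),
                             stringsAsFactors = FALSE), path)
}

#' Read and write distribution specs
#'
#' CSV with header `parameter,family,mean,se`; families beta, gamma,
#' lognormal or fixed, moment-matched on read.
#'
#' @param path CSV file path.
#' @return `read_distribution_specs()`: named list of `dist_spec`s.
#' @export
read_distribution_specs <- function(path) {
  df <- read_checked_csv(path, c("parameter", "family", "mean", "se"))
  specs <- lapply(seq_len(nrow(df)), function(i) {
    switch(df$family[i],
      beta = beta_from_moments(df$mean[i], df$se[i]),
      gamma = gamma_from_moments(df$mean[i], df$se[i]),
      lognormal = lognormal_from_moments(df$mean[i], df$se[i]),
      fixed = fixed_dist(df$mean[i]),
      stop(sprintf("%s: unknown family '%s' for parameter '%s'",
                   path, df$family[i], df$parameter[i]))
    )
  })
  stats::setNames(specs, df$parameter)
}

#' @rdname read_distribution_specs
#' @param specs Named list of `dist_spec`s.
#' @export
write_distribution_specs <- function(specs, path) {
  write_csv_exact(data.frame(
    parameter = names(specs),
    family = vapply(specs, `[[`, "", "family"),
    mean = vapply(specs, `[[`, 0, "target_mean"),
    se = vapply(specs, `[[`, 0, "target_se"),
    stringsAsFactors = FALSE
  ), path)
}

#' Read one-way sensitivity ranges
#'
#' CSV with header `parameter,low,high`.
#'
#' @param path CSV file path.
#' @return data.frame with columns parameter, low, high.
#' @export
read_dsa_ranges <- function(path) {
  read_checked_csv(path, c("parameter", "low", "high"))
}

#' Read a run configuration file
#'
#' Flat YAML key-value file; recognized keys mirror [model_config()]
#' (`discount_rate`, `wtp_thresholds`, `perspective`, `extinction_epsilon`,
#' `max_age`, `half_cycle`, `max_cycles`, `reference_strategy`) and
#' [cohort_spec()] (`mean_age`, `sd_age`, `prop_female`, `prop_moderate`,
#' `prop_severe`, `age_min`, `age_max`). Absent keys keep their defaults.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return List with elements `config` and `cohort`.
#' @export
read_run_config <- function(path = NULL) {
  vals <- if (is.null(path)) list() else yaml::read_yaml(path)
  known <- c("discount_rate", "wtp_thresholds", "perspective",
             "extinction_epsilon", "max_age", "half_cycle", "max_cycles",
             "reference_strategy", "mean_age", "sd_age", "prop_female",
             "prop_moderate", "prop_severe", "age_min", "age_max")
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key '%s'", unknown[1]))
  }
  pick <- function(key, default) if (!is.null(vals[[key]])) vals[[key]] else default
  cfg <- model_config(
    discount_rate = pick("discount_rate", 0.03),
    wtp_thresholds = unlist(pick("wtp_thresholds", c(50000, 100000, 150000))),
    perspective = pick("perspective", "payer"),
    extinction_epsilon = pick("extinction_epsilon", 1e-7),
    max_age = pick("max_age", 100L),
    half_cycle = pick("half_cycle", TRUE),
    max_cycles = pick("max_cycles", NA_integer_),
    reference_strategy = vals[["reference_strategy"]]
  )
  coh <- cohort_spec(
    mean_age = pick("mean_age", 48.4),
    sd_age = pick("sd_age", 10.4),
    prop_female = pick("prop_female", 0.944),
    initial_split = c(pick("prop_moderate", 0.5), pick("prop_severe", 0.5)),
    age_bounds = c(pick("age_min", 18L), pick("age_max", 90L))
  )
  list(config = cfg, cohort = coh)
}

#' Write a complete runnable synthetic input directory
#'
#' Emits every CSV the pipeline consumes (transitions, economics, drug
#' costs, life table, distribution specs) plus a `config.yaml`, generated
#' from one scenario.
#'
#' @param scenario A [synthetic_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the generated parameter set.
#' @export
write_synthetic_inputs <- function(scenario, dir) {
  ps <- generate_parameter_set(scenario)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_transition_matrices(ps$inputs$transitions, file.path(dir, "transitions.csv"))
  write_state_economics(ps$inputs$econ, file.path(dir, "economics.csv"))
  write_drug_costs(ps$inputs$drug_costs, file.path(dir, "drug_costs.csv"))
  write_life_table(ps$inputs$life_table, file.path(dir, "life_table.csv"))
  write_distribution_specs(ps$specs, file.path(dir, "distribution_specs.csv"))
  yaml::write_yaml(list(discount_rate = 0.03, perspective = "payer",
                        wtp_thresholds = c(50000, 100000, 150000)),
                   file.path(dir, "config.yaml"))
  invisible(ps)
}

#' Read a full input directory into a [cea_inputs()] bundle
#'
#' @param dir Directory holding `transitions.csv`, `economics.csv`,
#'   `drug_costs.csv`, `life_table.csv`.
#' @return A [cea_inputs()].
#' @export
read_input_dir <- function(dir) {
  cea_inputs(
    transitions = read_transition_matrices(file.path(dir, "transitions.csv")),
    econ = read_state_economics(file.path(dir, "economics.csv")),
    drug_costs = read_drug_costs(file.path(dir, "drug_costs.csv")),
    lt = read_life_table(file.path(dir, "life_table.csv"))
  )
}
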