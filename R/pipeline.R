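#' Deterministic outcomes for every strategy
#'
#' Runs the Markov cohort engine and accrues discounted lifetime cost and
#' QALYs for each strategy in the input bundle, under the configured
#' perspective.
#'
#' @param inputs A [cea_inputs()].
#' @param cohort A [cohort_spec()].
#' @param config A [model_config()].
#' @return A `strategy_outcome` data.frame, one row per strategy.
#' @export
compute_outcomes <- function(inputs, cohort, config = model_config()) {
  rows <- lapply(strategies(inputs), function(s) {
    trace <- run_cohort(inputs$transitions[[s]], cohort, inputs$life_table, config)
    accrue_outcomes(trace, inputs$econ, drug_cost = inputs$drug_costs[[s]],
                    perspective = config$perspective, config = config)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("strategy_outcome", "data.frame"))
}

#' Full deterministic cost-effectiveness analysis
#'
#' Computes (or accepts) per-strategy outcomes, classifies them on the
#' efficiency frontier, and evaluates incremental net monetary benefit of
#' every strategy against the reference at each configured
#' willingness-to-pay threshold.
#'
#' @param inputs A [cea_inputs()]; ignored when `outcomes` is supplied.
#' @param cohort A [cohort_spec()].
#' @param config A [model_config()].
#' @param outcomes Optional precomputed `strategy_outcome` data.frame
#'   (bypasses the Markov engine, e.g. for externally supplied lifetime
#'   values).
#' @return A `cea_result`: list with `outcomes`, `frontier` (a
#'   `frontier_result`), `inmb` (one row per strategy, one `inmb_<wtp>`
#'   column per threshold), `reference`, `config`.
#' @export
run_cea <- function(inputs = NULL, cohort = cohort_spec(),
                    config = model_config(), outcomes = NULL) {
  if (is.null(outcomes)) {
    if (is.null(inputs)) stop("either inputs or outcomes must be supplied")
    outcomes <- compute_outcomes(inputs, cohort, config)
  }
  fr <- build_frontier(outcomes)
  reference <- config$reference_strategy %||%
    outcomes$strategy[which.min(outcomes$cost)]
  ref_row <- outcome_row(outcomes, reference)
  nmb <- do.call(rbind, lapply(seq_len(nrow(outcomes)), function(i) {
    rec <- inmb(outcomes[i, , drop = FALSE], ref_row, config$wtp_thresholds)
    wide <- as.data.frame(as.list(stats::setNames(
      rec$inmb, paste0("inmb_", format(rec$wtp, scientific = FALSE, trim = TRUE))
    )))
    cbind(data.frame(strategy = outcomes$strategy[i], stringsAsFactors = FALSE), wide)
  }))
  structure(list(outcomes = outcomes, frontier = fr, inmb = nmb,
                 reference = reference, config = config),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("<cea_result> %d strategies, perspective '%s', reference '%s'\n",
              nrow(x$outcomes), x$config$perspective, x$reference))
  print(cea_report(x))
  invisible(x)
}

#' Render a display table with the field's rounding conventions
#'
#' Costs and iNMB round to the nearest dollar and QALYs to a fixed number
#' of decimals; internal arithmetic is never rounded, only this rendering.
#' Frontier members show their pairwise ICER (the cheapest shows
#' "reference" when it is the iNMB reference), dominated strategies their
#' dominance class.
#'
#' @param result A `cea_result`.
#' @param qaly_digits Decimals for QALY display. Default 3.
#' @return data.frame with columns `strategy`, `expected_cost`,
#'   `expected_qaly`, `icer_or_status`, and one `inmb_<wtp>` column per
#'   threshold, ordered by increasing cost.
#' @export
cea_report <- function(result, qaly_digits = 3) {
  cls <- result$frontier$classification
  fr <- result$frontier$frontier
  status <- vapply(cls$strategy, function(s) {
    st <- cls$status[cls$strategy == s]
    if (st == "strongly_dominated") return("dominated")
    if (st == "extendedly_dominated") return("extendedly dominated")
    ic <- fr$icer[fr$strategy == s]
    if (is.na(ic)) {
      if (identical(s, result$reference)) "reference" else "least costly"
    } else {
      format(round(ic), scientific = FALSE, trim = TRUE)
    }
  }, "")
  out <- data.frame(
    strategy = cls$strategy,
    expected_cost = round(cls$cost),
    expected_qaly = round(cls$qaly, qaly_digits),
    icer_or_status = status,
    stringsAsFactors = FALSE
  )
  nmb <- result$inmb
  nmb_num <- nmb[match(out$strategy, nmb$strategy), -1, drop = FALSE]
  nmb_num[] <- lapply(nmb_num, round)
  out <- cbind(out, nmb_num)
  rownames(out) <- NULL
  out
}

#' Run manifest for reproducibility
#'
#' Records the configuration echo, md5 checksums of every input file, the
#' seed(s), package version and a timestamp; every emitted result directory
#' carries the manifest that produced it.
#'
#' @param input_files Character vector of input file paths.
#' @param config A [model_config()].
#' @param seed Seed(s) used, if any.
#' @return A `run_manifest` list.
#' @export
run_manifest <- function(input_files, config, seed = NULL) {
  files <- input_files[file.exists(input_files)]
  structure(list(
    package = "fmcea",
    version = as.character(utils::packageVersion("fmcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    inputs = as.list(tools::md5sum(files))
  ), class = "run_manifest")
}

write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Pipeline entry points: deterministic run, PSA, one-way sensitivity
#'
#' Thin orchestration over the package's functions: read a configuration
#' and an input directory, run the stage, and write plot-ready CSV results
#' plus a `manifest.json` to the output directory. Validation failures
#' raise errors naming the offending file and row, so a wrapping script
#' exits nonzero.
#'
#' @param config_path YAML run configuration (or `NULL` for defaults).
#' @param input_dir Directory of input CSVs (see [read_input_dir()]).
#' @param output_dir Output directory (created if needed).
#' @param fixture Optional `"payer"`/`"societal"`: bypass the Markov engine
#'   and feed the stored reference cost/QALY pairs directly to the
#'   economics layer ([reference_outcomes()]).
#' @return `cea_run()`: the `cea_result`, invisibly.
#' @export
cea_run <- function(config_path = NULL, input_dir = NULL, output_dir,
                    fixture = NULL) {
  rc <- read_run_config(config_path)
  if (!is.null(fixture)) {
    outcomes <- reference_outcomes(fixture)
    rc$config$perspective <- fixture
    if (is.null(rc$config$reference_strategy)) {
      rc$config$reference_strategy <- "amitriptyline"
    }
    inputs <- NULL
    in_files <- character(0)
  } else {
    inputs <- read_input_dir(input_dir)
    outcomes <- NULL
    in_files <- file.path(input_dir, c("transitions.csv", "economics.csv",
                                       "drug_costs.csv", "life_table.csv"))
  }
  res <- run_cea(inputs, rc$cohort, rc$config, outcomes = outcomes)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_exact(res$outcomes, file.path(output_dir, "outcomes.csv"))
  write_csv_exact(res$frontier$classification, file.path(output_dir, "frontier.csv"))
  write_csv_exact(merge(res$frontier$classification[, c("strategy", "status")],
                        res$inmb, by = "strategy"),
                  file.path(output_dir, "inmb.csv"))
  utils::write.csv(cea_report(res), file.path(output_dir, "report.csv"),
                   row.names = FALSE)
  write_manifest(run_manifest(c(config_path %||% character(0), in_files), rc$config),
                 file.path(output_dir, "manifest.json"))
  invisible(res)
}

#' @rdname cea_run
#' @param n_draws PSA draw count. Default 1000.
#' @param seed PSA seed. Default 20240101.
#' @param wtp_grid WTP grid for the acceptability curves; default 0 to the
#'   largest configured threshold in $5000 steps.
#' @return `cea_psa()`: list with the `psa_result` and `ceac_curve`,
#'   invisibly.
#' @export
cea_psa <- function(config_path = NULL, input_dir, output_dir,
                    n_draws = 1000, seed = 20240101, wtp_grid = NULL) {
  rc <- read_run_config(config_path)
  inputs <- read_input_dir(input_dir)
  spec_path <- file.path(input_dir, "distribution_specs.csv")
  specs <- if (file.exists(spec_path)) {
    read_distribution_specs(spec_path)
  } else {
    build_distribution_specs(inputs)
  }
  psa <- run_psa(inputs, rc$cohort, rc$config, specs, n_draws = n_draws, seed = seed)
  grid <- wtp_grid %||% seq(0, max(rc$config$wtp_thresholds), by = 5000)
  cc <- ceac(psa, grid)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_exact(as.data.frame(psa), file.path(output_dir, "psa_draws.csv"))
  write_csv_exact(as.data.frame(cc), file.path(output_dir, "ceac.csv"))
  write_manifest(run_manifest(c(config_path %||% character(0),
                                file.path(input_dir, c("transitions.csv",
                                                       "economics.csv",
                                                       "drug_costs.csv",
                                                       "life_table.csv")),
                                spec_path),
                              rc$config, seed = seed),
                 file.path(output_dir, "manifest.json"))
  invisible(list(psa = psa, ceac = cc))
}

#' @rdname cea_run
#' @param ranges_path CSV of DSA ranges (see [read_dsa_ranges()]); `NULL`
#'   uses [default_dsa_ranges()].
#' @param candidate,reference Strategy pair for the tornado iNMB.
#' @param wtp WTP threshold for the tornado; default the middle configured
#'   threshold.
#' @return `cea_owsa()`: the `tornado` data.frame, invisibly.
#' @export
cea_owsa <- function(config_path = NULL, input_dir, output_dir,
                     ranges_path = NULL, candidate, reference, wtp = NULL) {
  rc <- read_run_config(config_path)
  inputs <- read_input_dir(input_dir)
  ranges <- if (is.null(ranges_path)) {
    default_dsa_ranges(inputs)
  } else {
    read_dsa_ranges(ranges_path)
  }
  wtp <- wtp %||% stats::median(rc$config$wtp_thresholds)
  tor <- one_way_sensitivity(inputs, rc$cohort, rc$config, ranges,
                             candidate, reference, wtp)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- as.data.frame(tor)
  names(out) <- c("parameter", "low", "high", "inmb_low", "inmb_high", "width")
  write_csv_exact(out, file.path(output_dir, "tornado.csv"))
  write_manifest(run_manifest(c(config_path %||% character(0),
                                ranges_path %||% character(0)),
                              rc$config),
                 file.path(output_dir, "manifest.json"))
  invisible(tor)
}
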