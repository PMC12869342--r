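#' Bundle complete model inputs
#'
#' Collects everything one deterministic model evaluation needs: a disease
#' transition matrix and an annual drug acquisition cost per strategy, the
#' per-state utilities and cost components, and a life table.
#'
#' @param transitions Named list of [disease_matrix()] objects, one per
#'   strategy.
#' @param econ A [state_economics()] data.frame.
#' @param drug_costs Named numeric vector of annual drug costs ($/year),
#'   names matching `transitions`.
#' @param lt A [life_table()].
#' @return A `cea_inputs` list.
#' @export
cea_inputs <- function(transitions, econ, drug_costs, lt) {
  stopifnot(is.list(transitions), length(transitions) >= 1)
  if (is.null(names(transitions)) || anyDuplicated(names(transitions))) {
    stop("transitions must be a uniquely named list of strategies")
  }
  transitions <- lapply(names(transitions), function(s) {
    disease_matrix(unclass(transitions[[s]]), strategy = s)
  })
  names(transitions) <- vapply(transitions, attr, "", "strategy")
  econ <- state_economics(econ)
  if (!setequal(names(drug_costs), names(transitions))) {
    stop("drug_costs names must match transition strategy names")
  }
  if (any(drug_costs < 0)) stop("drug costs must be nonnegative")
  drug_costs <- drug_costs[names(transitions)]
  if (!inherits(lt, "life_table")) lt <- life_table(lt)
  structure(list(transitions = transitions, econ = econ,
                 drug_costs = drug_costs, life_table = lt),
            class = "cea_inputs")
}

#' Strategy names in an input bundle
#' @param inputs A [cea_inputs()].
#' @return Character vector of strategy names.
#' @export
strategies <- function(inputs) names(inputs$transitions)

# Flat parameter ids: "tp:<strategy>:<from>:<to>", "utility:<state>",
# "cost:<component>:<state>", "drug:<strategy>".

#' Enumerate the model's flat parameter vector
#'
#' @param inputs A [cea_inputs()].
#' @return Named numeric vector of base-case values; names are parameter
#'   ids of the form `tp:<strategy>:<from>:<to>`, `utility:<state>`,
#'   `cost:<component>:<state>`, `drug:<strategy>`.
#' @export
list_parameters <- function(inputs) {
  out <- c()
  for (s in strategies(inputs)) {
    m <- inputs$transitions[[s]]
    for (fr in alive_states()) for (to in alive_states()) {
      out[paste("tp", s, fr, to, sep = ":")] <- m[fr, to]
    }
  }
  for (st in alive_states()) {
    row <- inputs$econ[inputs$econ$state == st, ]
    out[paste("utility", st, sep = ":")] <- row$utility
    out[paste("cost", "direct_medical", st, sep = ":")] <- row$direct_medical
    out[paste("cost", "direct_nonmedical", st, sep = ":")] <- row$direct_nonmedical
    out[paste("cost", "indirect", st, sep = ":")] <- row$indirect
  }
  for (s in strategies(inputs)) {
    out[paste("drug", s, sep = ":")] <- inputs$drug_costs[[s]]
  }
  out
}

parse_parameter <- function(name) {
  parts <- strsplit(name, ":", fixed = TRUE)[[1]]
  kind <- parts[1]
  ok <- switch(kind,
    tp = length(parts) == 4 &&
      all(parts[3:4] %in% alive_states()),
    utility = length(parts) == 2 && parts[2] %in% alive_states(),
    cost = length(parts) == 3 &&
      parts[2] %in% c("direct_medical", "direct_nonmedical", "indirect") &&
      parts[3] %in% alive_states(),
    drug = length(parts) == 2,
    FALSE
  )
  if (!isTRUE(ok)) stop(sprintf("malformed parameter id '%s'", name))
  parts
}

#' Set one model parameter, respecting its domain
#'
#' For a transition probability the varied entry is held exactly at the set
#' value and the remaining entries of its row are rescaled to the
#' complement, keeping the row a probability vector (used by the one-way
#' sensitivity analysis; probabilistic sampling instead redraws whole rows
#' and renormalizes, see [sample_parameter_set()]).
#'
#' @param inputs A [cea_inputs()].
#' @param name Parameter id (see [list_parameters()]).
#' @param value New value; probabilities and utilities must lie in `[0, 1]`,
#'   costs must be nonnegative.
#' @return A modified `cea_inputs`.
#' @export
set_parameter <- function(inputs, name, value) {
  parts <- parse_parameter(name)
  kind <- parts[1]
  if (kind %in% c("tp", "utility") && (value < 0 || value > 1)) {
    stop(sprintf("parameter '%s' must lie in [0, 1], got %g", name, value))
  }
  if (kind %in% c("cost", "drug") && value < 0) {
    stop(sprintf("parameter '%s' must be nonnegative, got %g", name, value))
  }
  if (kind == "tp") {
    s <- parts[2]
    if (!s %in% strategies(inputs)) stop(sprintf("unknown strategy '%s' in '%s'", s, name))
    m <- unclass(inputs$transitions[[s]])
    fr <- parts[3]; to <- parts[4]
    others <- setdiff(alive_states(), to)
    rest <- m[fr, others]
    if (sum(rest) > 0) {
      m[fr, others] <- rest * (1 - value) / sum(rest)
    } else {
      m[fr, others] <- (1 - value) / length(others)
    }
    m[fr, to] <- value
    inputs$transitions[[s]] <- disease_matrix(m, strategy = s)
  } else if (kind == "utility") {
    inputs$econ$utility[inputs$econ$state == parts[2]] <- value
  } else if (kind == "cost") {
    col <- parts[2]
    inputs$econ[[col]][inputs$econ$state == parts[3]] <- value
  } else {
    s <- parts[2]
    if (!s %in% strategies(inputs)) stop(sprintf("unknown strategy '%s' in '%s'", s, name))
    inputs$drug_costs[[s]] <- value
  }
  inputs
}

#' @export
print.cea_inputs <- function(x, ...) {
  cat(sprintf("<cea_inputs> %d strategies: %s\n",
              length(x$transitions), paste(strategies(x), collapse = ", ")))
  invisible(x)
}
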