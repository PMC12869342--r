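#' Classify strategies and build the efficiency frontier
#'
#' Strategies are ordered by increasing cost. A strategy is strongly
#' dominated when another offers at least as many QALYs at no greater cost,
#' with at least one inequality strict (an exact cost-and-QALY tie dominates
#' neither). Among survivors, ICERs are computed for adjacent pairs and any
#' strategy whose ICER exceeds (or equals, for collinear points) that of the
#' next more effective, more costly survivor is removed as extendedly
#' dominated; removal repeats until the remaining pairwise ICERs are
#' strictly increasing. Survivors form the efficiency frontier.
#'
#' @param outcomes A `strategy_outcome` data.frame (>= 1 row, one
#'   perspective, unique strategy names).
#' @return A `frontier_result`: list with `classification` (strategy, cost,
#'   qaly, status in {on_frontier, strongly_dominated, extendedly_dominated})
#'   and `frontier` (cost-ordered on-frontier strategies with the pairwise
#'   `icer` vs the previous member; NA for the cheapest).
#' @export
build_frontier <- function(outcomes) {
  stopifnot(inherits(outcomes, "data.frame"), nrow(outcomes) >= 1)
  if (length(unique(outcomes$perspective)) > 1) {
    stop("all outcomes must share one perspective")
  }
  if (anyDuplicated(outcomes$strategy)) {
    stop("duplicate strategy names in outcomes")
  }
  n <- nrow(outcomes)
  cost <- outcomes$cost
  qaly <- outcomes$qaly
  status <- rep("on_frontier", n)

  for (i in seq_len(n)) {
    dominated <- any(
      cost <= cost[i] & qaly >= qaly[i] & (cost < cost[i] | qaly > qaly[i])
    )
    if (dominated) status[i] <- "strongly_dominated"
  }

  surv <- which(status == "on_frontier")
  ord <- surv[order(cost[surv], qaly[surv], outcomes$strategy[surv])]
  # collapse exact (cost, qaly) ties into single frontier points
  key <- paste(cost[ord], qaly[ord])
  groups <- split(ord, factor(key, levels = unique(key)))
  pts <- data.frame(
    cost = vapply(groups, function(g) cost[g[1]], 0),
    qaly = vapply(groups, function(g) qaly[g[1]], 0)
  )
  members <- groups

  repeat {
    np <- nrow(pts)
    if (np <= 2) break
    icers <- (pts$cost[-1] - pts$cost[-np]) / (pts$qaly[-1] - pts$qaly[-np])
    bad <- which(icers[-length(icers)] >= icers[-1])
    if (length(bad) == 0) break
    k <- bad[1] + 1L # point whose incoming ICER is not strictly below the next
    for (i in members[[k]]) status[i] <- "extendedly_dominated"
    pts <- pts[-k, , drop = FALSE]
    members <- members[-k]
  }

  np <- nrow(pts)
  icers <- if (np >= 2) {
    c(NA_real_, (pts$cost[-1] - pts$cost[-np]) / (pts$qaly[-1] - pts$qaly[-np]))
  } else {
    NA_real_
  }
  frontier <- do.call(rbind, lapply(seq_len(np), function(k) {
    data.frame(
      strategy = outcomes$strategy[members[[k]]],
      cost = pts$cost[k], qaly = pts$qaly[k], icer = icers[k],
      stringsAsFactors = FALSE
    )
  }))
  rownames(frontier) <- NULL

  classification <- data.frame(
    strategy = outcomes$strategy, cost = cost, qaly = qaly,
    status = status, stringsAsFactors = FALSE
  )
  classification <- classification[order(classification$cost, classification$qaly,
                                         classification$strategy), ]
  rownames(classification) <- NULL
  structure(list(classification = classification, frontier = frontier),
            class = "frontier_result")
}

#' @export
print.frontier_result <- function(x, ...) {
  cat("<frontier_result>\n")
  print(x$classification)
  invisible(x)
}

#' Brute-force net-monetary-benefit verifier for the frontier
#'
#' At each willingness-to-pay value, returns the strategy maximizing
#' `wtp * qaly - cost` (ties broken toward the lower cost, then
#' lexicographically). Every strategy optimal at some WTP must sit on the
#' efficiency frontier, making this an independent check of
#' [build_frontier()].
#'
#' @param outcomes A `strategy_outcome` data.frame.
#' @param wtp_grid Dense ascending grid of WTP values (>= 0).
#' @return Data.frame with columns `wtp`, `strategy`.
#' @export
frontier_nmb_oracle <- function(outcomes, wtp_grid) {
  stopifnot(nrow(outcomes) >= 1, length(wtp_grid) >= 1)
  if (is.unsorted(wtp_grid)) stop("wtp_grid must be ascending")
  winners <- vapply(wtp_grid, function(w) {
    nmb <- w * outcomes$qaly - outcomes$cost
    best <- which(nmb == max(nmb))
    best <- best[order(outcomes$cost[best], outcomes$strategy[best])]
    outcomes$strategy[best[1]]
  }, character(1))
  data.frame(wtp = as.numeric(wtp_grid), strategy = winners,
             stringsAsFactors = FALSE)
}
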