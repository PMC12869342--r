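#' Moment-matched sampling distributions for probabilistic sensitivity analysis
#'
#' Beta distributions are used for transition probabilities, gamma for
#' (right-skewed) cost parameters, and lognormal for utility values. Each
#' constructor solves the family's parameters so the analytic mean and
#' variance reproduce the target mean and standard error exactly. A standard
#' error of zero degenerates to the `fixed` family, which always returns the
#' mean.
#'
#' @param mean Target mean.
#' @param se Target standard error (>= 0).
#' @return A `dist_spec` list: `family`, family-specific `pars`,
#'   `target_mean`, `target_se`.
#' @name moment_matching
NULL

dist_spec <- function(family, pars, mean, se) {
  structure(list(family = family, pars = pars,
                 target_mean = mean, target_se = se),
            class = "dist_spec")
}

#' @rdname moment_matching
#' @export
beta_from_moments <- function(mean, se) {
  if (se == 0) return(dist_spec("fixed", list(value = mean), mean, 0))
  if (mean <= 0 || mean >= 1) stop("beta moment matching requires 0 < mean < 1")
  v <- se^2
  if (v >= mean * (1 - mean)) {
    stop(sprintf(
      "infeasible moments for beta: se^2 = %g must be below mean(1-mean) = %g",
      v, mean * (1 - mean)
    ))
  }
  nu <- mean * (1 - mean) / v - 1
  dist_spec("beta", list(shape1 = mean * nu, shape2 = (1 - mean) * nu), mean, se)
}

#' @rdname moment_matching
#' @export
gamma_from_moments <- function(mean, se) {
  if (se == 0) return(dist_spec("fixed", list(value = mean), mean, 0))
  if (mean <= 0 || se < 0) stop("gamma moment matching requires mean > 0 and se > 0")
  dist_spec("gamma", list(shape = mean^2 / se^2, scale = se^2 / mean), mean, se)
}

#' @rdname moment_matching
#' @export
lognormal_from_moments <- function(mean, se) {
  if (mean <= 0) stop("lognormal moment matching requires mean > 0")
  if (se < 0) stop("se must be nonnegative")
  if (se == 0) return(dist_spec("fixed", list(value = mean), mean, 0))
  sigma2 <- log(1 + se^2 / mean^2)
  dist_spec("lognormal",
            list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2)),
            mean, se)
}

#' Fixed (degenerate) distribution
#' @param value The constant value returned by every draw.
#' @return A `dist_spec` of family `fixed`.
#' @export
fixed_dist <- function(value) dist_spec("fixed", list(value = value), value, 0)

#' Draw from a moment-matched distribution
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Uses the session RNG stream.
#' @export
draw_dist <- function(spec, n = 1) {
  switch(spec$family,
    fixed = rep(spec$pars$value, n),
    beta = stats::rbeta(n, spec$pars$shape1, spec$pars$shape2),
    gamma = stats::rgamma(n, shape = spec$pars$shape, scale = spec$pars$scale),
    lognormal = stats::rlnorm(n, spec$pars$meanlog, spec$pars$sdlog),
    stop(sprintf("unknown distribution family '%s'", spec$family))
  )
}

#' Analytic mean and variance of a `dist_spec`
#' @param spec A `dist_spec`.
#' @return Named numeric vector `c(mean, var)`.
#' @export
dist_moments <- function(spec) {
  with(spec$pars, switch(spec$family,
    fixed = c(mean = value, var = 0),
    beta = {
      m <- shape1 / (shape1 + shape2)
      c(mean = m, var = m * (1 - m) / (shape1 + shape2 + 1))
    },
    gamma = c(mean = shape * scale, var = shape * scale^2),
    lognormal = {
      m <- exp(meanlog + sdlog^2 / 2)
      c(mean = m, var = (exp(sdlog^2) - 1) * m^2)
    }
  ))
}
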