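#' Construct and validate a life table
#'
#' Age- and sex-specific annual death probabilities (qx). Ages must be
#' contiguous for each sex from a minimum of at most 18 up to a terminal age
#' at which qx = 1; ages requested beyond the terminal row are clamped to it.
#'
#' @param df data.frame with columns `age` (integer years), `sex`
#'   (`"female"`/`"male"`) and `qx` (annual death probability in `[0, 1]`).
#' @return A `life_table` data.frame, sorted by sex then age.
#' @export
life_table <- function(df) {
  req <- c("age", "sex", "qx")
  if (!all(req %in% names(df))) {
    stop("life table must have columns age, sex, qx")
  }
  df <- df[, req]
  df$age <- as.integer(df$age)
  df$sex <- as.character(df$sex)
  df$qx <- as.numeric(df$qx)
  if (!all(df$sex %in% c("female", "male"))) {
    stop("life table sex must be 'female' or 'male'")
  }
  if (any(!is.finite(df$qx)) || any(df$qx < 0 | df$qx > 1)) {
    stop("life table qx values must lie in [0, 1]")
  }
  df <- df[order(df$sex, df$age), , drop = FALSE]
  for (s in c("female", "male")) {
    a <- df$age[df$sex == s]
    if (length(a) == 0) stop(sprintf("life table is missing sex '%s'", s))
    if (anyDuplicated(a)) stop(sprintf("duplicate ages for sex '%s'", s))
    if (!identical(a, seq(min(a), max(a)))) {
      stop(sprintf("life table ages for sex '%s' must be contiguous", s))
    }
    if (min(a) > 18L) {
      stop(sprintf("life table for sex '%s' must start at age <= 18", s))
    }
    q_last <- df$qx[df$sex == s & df$age == max(a)]
    if (q_last < 1) {
      stop(sprintf("terminal qx for sex '%s' must equal 1", s))
    }
  }
  rownames(df) <- NULL
  structure(df, class = c("life_table", "data.frame"))
}

#' Sex-mixed annual background mortality probability
#'
#' Mixes the female and male qx at a given age by the cohort's proportion
#' female: `prop_female * qx(age, female) + (1 - prop_female) * qx(age, male)`.
#' Ages beyond the table's terminal age are clamped to the terminal row.
#'
#' @param age Age in integer years (vectorized).
#' @param prop_female Proportion female in `[0, 1]`.
#' @param lt A [life_table()].
#' @return Death probability (or vector of) in `[0, 1]`.
#' @export
mortality_probability <- function(age, prop_female, lt) {
  if (!inherits(lt, "life_table")) lt <- life_table(lt)
  if (prop_female < 0 || prop_female > 1) stop("prop_female must lie in [0, 1]")
  qf <- lt$qx[lt$sex == "female"]
  qm <- lt$qx[lt$sex == "male"]
  af <- lt$age[lt$sex == "female"]
  am <- lt$age[lt$sex == "male"]
  age <- as.integer(round(age))
  if (any(age < min(af)) || any(age < min(am))) {
    stop(sprintf("age %d is below the life-table minimum", min(age)))
  }
  i_f <- pmin(age - min(af) + 1L, length(qf))
  i_m <- pmin(age - min(am) + 1L, length(qm))
  prop_female * qf[i_f] + (1 - prop_female) * qm[i_m]
}

#' Generate a synthetic Gompertz-type life table
#'
#' Stand-in for national vital statistics life tables:
#' `qx(age, sex) = min(1, a * s_sex * exp(b * age))`, with the female scale
#' below the male scale, and qx forced to 1 at `max_age`.
#'
#' @param a Baseline annual hazard scale (> 0). Default 2e-5.
#' @param b Age slope on the log scale (>= 0). Default 0.095.
#' @param max_age Terminal age; qx = 1 there. Default 100.
#' @param min_age First tabulated age. Default 0.
#' @param sex_scale Named multipliers for the two sexes; female must be below
#'   male. Default `c(female = 0.75, male = 1.25)`.
#' @return A [life_table()].
#' @export
generate_life_table <- function(a = 2e-5, b = 0.095, max_age = 100L,
                                min_age = 0L,
                                sex_scale = c(female = 0.75, male = 1.25)) {
  if (a <= 0) stop("baseline hazard 'a' must be positive")
  if (b < 0) stop("age slope 'b' must be nonnegative")
  if (sex_scale[["female"]] >= sex_scale[["male"]]) {
    stop("female scale must be below male scale")
  }
  ages <- seq(as.integer(min_age), as.integer(max_age))
  rows <- lapply(c("female", "male"), function(s) {
    qx <- pmin(1, a * sex_scale[[s]] * exp(b * ages))
    qx[length(qx)] <- 1
    data.frame(age = ages, sex = s, qx = qx)
  })
  life_table(do.call(rbind, rows))
}
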