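# Shared in-code fixtures: tiny life tables, economics blocks, and random
# instance generators used by the property-style tests.

# flat life table: constant qx for both sexes up to a terminal age with qx 1
lt_const <- function(q, max_age = 200L) {
  ages <- 0:max_age
  qx <- c(rep(q, max_age), 1)
  life_table(data.frame(
    age = rep(ages, 2),
    sex = rep(c("female", "male"), each = max_age + 1L),
    qx = rep(qx, 2)
  ))
}

lt_zero <- function(max_age = 200L) lt_const(0, max_age)

# stub table with distinct female/male hazards
lt_stub <- function(qf, qm, max_age = 60L) {
  ages <- 0:max_age
  life_table(data.frame(
    age = rep(ages, 2),
    sex = rep(c("female", "male"), each = max_age + 1L),
    qx = c(c(rep(qf, max_age), 1), c(rep(qm, max_age), 1))
  ))
}

# single-stratum cohort, everyone enters moderate
single_cohort <- function(age = 30, split = c(1, 0), prop_female = 1) {
  cohort_spec(mean_age = age, sd_age = 0, prop_female = prop_female,
              initial_split = split, age_bounds = c(18L, 90L))
}

identity_matrix <- function(strategy = "stay") {
  disease_matrix(diag(3), strategy = strategy)
}

econ_df <- function(utility = c(0.8, 0.65, 0.45),
                    direct_medical = c(0, 0, 0),
                    direct_nonmedical = c(0, 0, 0),
                    indirect = c(0, 0, 0)) {
  state_economics(data.frame(
    state = alive_states(), utility = utility,
    direct_medical = direct_medical, direct_nonmedical = direct_nonmedical,
    indirect = indirect
  ))
}

random_disease_matrix <- function(strategy = "random") {
  m <- matrix(stats::rgamma(9, shape = 1), 3, 3)
  disease_matrix(m / rowSums(m), strategy = strategy)
}

random_outcomes <- function(n) {
  strategy_outcomes(
    strategy = paste0("s", seq_len(n)),
    cost = stats::runif(n, 0, 1e5),
    qaly = stats::runif(n, 0, 15),
    perspective = "payer"
  )
}

# three-strategy scenario where "dominant" has much better transitions and
# the lowest drug cost; distributions tightly concentrated
dominant_scenario <- function(seed = 7, se_frac = 0.02) {
  synthetic_scenario(
    seed = seed,
    gradients = c(weak = 0, mid = 0.05, dominant = 0.5),
    drug_costs = c(weak = 500, mid = 400, dominant = 50),
    se_frac = se_frac
  )
}
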