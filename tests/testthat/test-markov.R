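test_that("sex-mixed background mortality combines the life-table rows", {
  expect_equal(mortality_probability(50, 0.5, lt_zero()), 0)
  lt <- lt_stub(0.003, 0.005)
  expect_identical(mortality_probability(50, 1, lt), 0.003)
  expect_equal(mortality_probability(50, 0.944, lt),
               0.944 * 0.003 + 0.056 * 0.005) # = 0.003112
  # ages beyond the table clamp to the terminal row
  expect_equal(mortality_probability(500, 0.5, lt), 1)
  expect_error(mortality_probability(-3, 0.5, lt), "below the life-table minimum")
  expect_error(life_table(data.frame(age = 0:10, sex = "female", qx = 0.1)),
               "missing sex|terminal")
})

test_that("cycle matrix layers death onto the disease transitions", {
  d <- random_disease_matrix()
  m0 <- build_cycle_matrix(d, 0)
  expect_equal(m0[1:3, 1:3], unclass(d), ignore_attr = TRUE)
  expect_equal(m0[1:3, 4], rep(0, 3), ignore_attr = TRUE)
  m1 <- build_cycle_matrix(d, 1)
  expect_equal(unname(m1[1:3, ]), matrix(rep(c(0, 0, 0, 1), 3), 3, byrow = TRUE))
  mi <- build_cycle_matrix(identity_matrix(), 0.1)
  expect_equal(unname(diag(mi)[1:3]), rep(0.9, 3))
  expect_equal(unname(mi[1:3, 4]), rep(0.1, 3))
  expect_equal(unname(mi[4, ]), c(0, 0, 0, 1))
  expect_true(all(abs(rowSums(build_cycle_matrix(d, 0.37)) - 1) < 1e-12))
  bad <- diag(3) * 0.9
  expect_error(build_cycle_matrix(bad, 0.1), "row 'mild'")
})

test_that("cohort propagation honors its initialization and stopping contracts", {
  cfg10 <- model_config(max_cycles = 10)
  tr <- run_cohort(identity_matrix(), single_cohort(split = c(0.5, 0.5)),
                   lt_zero(), cfg10)
  expect_equal(unname(tr$occupancy[1, ]), c(0, 0.5, 0.5, 0))
  # no mortality, no flow: occupancy constant at the initial vector
  for (t in seq_len(nrow(tr$occupancy))) {
    expect_equal(unname(tr$occupancy[t, ]), c(0, 0.5, 0.5, 0))
  }
  expect_equal(tr$cycles_run, 10)
  # an extinction criterion that can never be met errors at the hard cap
  expect_error(
    run_cohort(identity_matrix(), single_cohort(), lt_zero(max_age = 400L),
               model_config(max_age = 500L)),
    "non-terminating"
  )
})

test_that("half-cycle corrected person-years match the geometric closed form", {
  stay_moderate <- disease_matrix(
    matrix(c(1, 0, 0, 0, 1, 0, 0, 0, 1), 3, 3), "stay"
  )
  tr <- run_cohort(stay_moderate, single_cohort(), lt_const(0.5), model_config())
  eff_moderate <- tr$effective_occupancy[, "moderate"]
  expect_equal(eff_moderate, 0.75 * 0.5^(seq_along(eff_moderate) - 1),
               ignore_attr = TRUE)
  expect_equal(sum(tr$effective_occupancy), 1.5, tolerance = 1e-6)
  # general closed form (1 - q/2)/q, via independent geometric summation
  for (q in c(0.2, 0.7)) {
    trq <- run_cohort(stay_moderate, single_cohort(), lt_const(q), model_config())
    expect_equal(sum(trq$effective_occupancy), (1 - q / 2) / q, tolerance = 1e-6)
    oracle <- sum((1 - q / 2) * (1 - q)^(0:500))
    expect_equal(sum(trq$effective_occupancy), oracle, tolerance = 1e-6)
  }
})

test_that("discounting uses the discrete annual factor", {
  expect_equal(discount_factor(0, 0.07), 1)
  expect_equal(discount_factor(5, 0), 1)
  expect_equal(discount_factor(2, 0.03), 1 / 1.0609)
  expect_error(discount_factor(-1, 0.03), "nonnegative")
})

test_that("occupancy is conserved and death is absorbing on random instances", {
  set.seed(42)
  lt <- generate_life_table()
  for (i in 1:100) {
    d <- random_disease_matrix()
    coh <- cohort_spec(mean_age = runif(1, 30, 70), sd_age = runif(1, 0, 8),
                       prop_female = runif(1),
                       initial_split = local({
                         p <- runif(1); c(p, 1 - p)
                       }))
    tr <- run_cohort(d, coh, lt, model_config(max_cycles = 15))
    expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-9))
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-12))
  }
})

test_that("the engine matches explicit matrix-vector propagation", {
  set.seed(11)
  lt <- generate_life_table(a = 5e-4, b = 0.05)
  for (i in 1:20) {
    d <- random_disease_matrix()
    age0 <- sample(25:80, 1)
    coh <- single_cohort(age = age0, split = c(0.3, 0.7), prop_female = 0.944)
    cfg <- model_config(max_cycles = 5)
    tr <- run_cohort(d, coh, lt, cfg)
    # independent brute-force trace
    v <- c(0, 0.3, 0.7, 0)
    expect_equal(unname(tr$occupancy[1, ]), v, tolerance = 1e-12)
    for (t in 0:4) {
      pd <- mortality_probability(min(age0 + t, 100), 0.944, lt)
      if (age0 + t >= 100) pd <- 1
      M <- rbind(cbind(unclass(d) * (1 - pd), rep(pd, 3)), c(0, 0, 0, 1))
      v <- as.numeric(v %*% M)
      expect_equal(unname(tr$occupancy[t + 2, ]), v, tolerance = 1e-12)
    }
  }
})

test_that("age strata aggregate as the weighted mixture of stratum runs", {
  lt <- generate_life_table(a = 1e-3, b = 0.03)
  d <- random_disease_matrix()
  coh <- cohort_spec(mean_age = 50, sd_age = 4, prop_female = 0.8,
                     initial_split = c(0.5, 0.5), age_bounds = c(49L, 51L))
  cfg <- model_config(max_cycles = 8)
  tr <- run_cohort(d, coh, lt, cfg)
  w <- stats::pnorm(49:51 + 0.5, 50, 4) - stats::pnorm(49:51 - 0.5, 50, 4)
  w <- w / sum(w)
  parts <- lapply(49:51, function(a) {
    run_cohort(d, single_cohort(age = a, split = c(0.5, 0.5), prop_female = 0.8),
               lt, cfg)$occupancy
  })
  agg <- w[1] * parts[[1]] + w[2] * parts[[2]] + w[3] * parts[[3]]
  expect_equal(tr$occupancy, agg, tolerance = 1e-12)
})

test_that("undiscounted person-years reproduce life-table life expectancy", {
  lt <- generate_life_table(a = 1e-4, b = 0.09)
  coh <- single_cohort(age = 40, split = c(1, 0), prop_female = 0.944)
  cfg <- model_config(discount_rate = 0)
  tr <- run_cohort(identity_matrix(), coh, lt, cfg)
  # independent survival curve and trapezoidal life expectancy
  qx <- vapply(40:100, function(a) mortality_probability(a, 0.944, lt), 0)
  qx[length(qx)] <- 1
  lx <- cumprod(c(1, 1 - qx))
  ex <- sum((lx[-length(lx)] + lx[-1]) / 2)
  expect_equal(sum(tr$effective_occupancy), ex, tolerance = 0.5)
})
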