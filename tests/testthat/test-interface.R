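test_that("every CSV format round-trips bit-exactly", {
  ps <- generate_parameter_set(synthetic_scenario(seed = 55))
  dir <- withr::local_tempdir()

  write_transition_matrices(ps$inputs$transitions, file.path(dir, "t.csv"))
  tr2 <- read_transition_matrices(file.path(dir, "t.csv"))
  for (s in strategies(ps$inputs)) {
    expect_identical(unclass(tr2[[s]])[,], unclass(ps$inputs$transitions[[s]])[,])
  }

  write_life_table(ps$inputs$life_table, file.path(dir, "lt.csv"))
  expect_identical(read_life_table(file.path(dir, "lt.csv"))$qx,
                   ps$inputs$life_table$qx)

  write_state_economics(ps$inputs$econ, file.path(dir, "e.csv"))
  e2 <- read_state_economics(file.path(dir, "e.csv"))
  expect_identical(as.data.frame(e2), as.data.frame(ps$inputs$econ))

  write_drug_costs(ps$inputs$drug_costs, file.path(dir, "d.csv"))
  expect_identical(read_drug_costs(file.path(dir, "d.csv")), ps$inputs$drug_costs)

  write_distribution_specs(ps$specs, file.path(dir, "s.csv"))
  s2 <- read_distribution_specs(file.path(dir, "s.csv"))
  expect_identical(names(s2), names(ps$specs))
  for (nm in names(s2)) expect_equal(s2[[nm]], ps$specs[[nm]])
})

test_that("run configuration files override defaults and reject junk", {
  rc <- read_run_config(NULL)
  expect_equal(rc$config$discount_rate, 0.03)
  expect_equal(rc$config$wtp_thresholds, c(50000, 100000, 150000))
  expect_equal(rc$cohort$mean_age, 48.4)
  expect_equal(rc$cohort$prop_female, 0.944)

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("discount_rate: 0.05", "perspective: societal",
               "sd_age: 0", "mean_age: 60"), path)
  rc2 <- read_run_config(path)
  expect_equal(rc2$config$discount_rate, 0.05)
  expect_equal(rc2$config$perspective, "societal")
  expect_equal(rc2$cohort$sd_age, 0)

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines("discont_rate: 0.05", bad)
  expect_error(read_run_config(bad), "unknown configuration key")
})

test_that("a synthesized input directory runs end to end with a manifest", {
  dir <- withr::local_tempdir()
  indir <- file.path(dir, "in"); outdir <- file.path(dir, "out")
  write_synthetic_inputs(synthetic_scenario(seed = 9), indir)
  cfg <- file.path(dir, "config.yaml")
  writeLines(c("sd_age: 0", "mean_age: 55"), cfg) # single stratum: fast

  res <- cea_run(cfg, indir, outdir)
  for (f in c("outcomes.csv", "frontier.csv", "inmb.csv", "report.csv",
              "manifest.json")) {
    expect_true(file.exists(file.path(outdir, f)))
  }
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  for (f in names(man$inputs)) {
    expect_equal(unname(tools::md5sum(f)), man$inputs[[f]])
  }
  oc <- read.csv(file.path(outdir, "outcomes.csv"))
  expect_equal(sort(oc$strategy), sort(strategies(read_input_dir(indir))))
  expect_equal(oc$cost, res$outcomes$cost[match(oc$strategy, res$outcomes$strategy)])
})

test_that("corrupt transition inputs fail loudly, naming the offender", {
  dir <- withr::local_tempdir()
  indir <- file.path(dir, "in")
  write_synthetic_inputs(synthetic_scenario(seed = 9), indir)
  tpath <- file.path(indir, "transitions.csv")
  df <- read.csv(tpath)
  i <- which(df$strategy == "amitriptyline" & df$from_state == "moderate" &
               df$to_state == "moderate")[1]
  df$prob[i] <- df$prob[i] - 0.1 # row now sums to 0.9
  write.csv(df, tpath, row.names = FALSE)
  expect_error(cea_run(NULL, indir, file.path(dir, "out")),
               "amitriptyline.*row 'moderate'")
})

test_that("the fixture bypass reproduces the published iNMB columns", {
  dir <- withr::local_tempdir()
  res <- cea_run(NULL, NULL, file.path(dir, "out"), fixture = "payer")
  rep <- cea_report(res)
  dulox <- rep[rep$strategy == "duloxetine 120 mg", ]
  expect_equal(dulox$icer_or_status, "1536")
  expect_equal(unlist(dulox[c("inmb_50000", "inmb_100000", "inmb_150000")],
                      use.names = FALSE),
               c(19725, 40075, 60425))
  ami <- rep[rep$strategy == "amitriptyline", ]
  expect_equal(ami$icer_or_status, "reference")

  res_s <- cea_run(NULL, NULL, file.path(dir, "out2"), fixture = "societal")
  rep_s <- cea_report(res_s)
  preg <- rep_s[rep_s$strategy == "pregabalin 450 mg", ]
  expect_equal(unname(unlist(preg[grep("^inmb", names(preg))])),
               c(28190, 40190, 52190))
})

test_that("the PSA and tornado entry points are deterministic end to end", {
  dir <- withr::local_tempdir()
  indir <- file.path(dir, "in")
  write_synthetic_inputs(dominant_scenario(seed = 4), indir)
  cfg <- file.path(dir, "config.yaml")
  writeLines(c("sd_age: 0", "mean_age: 55"), cfg)

  r1 <- cea_psa(cfg, indir, file.path(dir, "p1"), n_draws = 5, seed = 42)
  r2 <- cea_psa(cfg, indir, file.path(dir, "p2"), n_draws = 5, seed = 42)
  expect_identical(readLines(file.path(dir, "p1", "ceac.csv")),
                   readLines(file.path(dir, "p2", "ceac.csv")))
  expect_identical(readLines(file.path(dir, "p1", "psa_draws.csv")),
                   readLines(file.path(dir, "p2", "psa_draws.csv")))
  sums <- tapply(r1$ceac$probability, r1$ceac$wtp, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  tor <- cea_owsa(cfg, indir, file.path(dir, "t"),
                  candidate = "dominant", reference = "weak")
  expect_true(file.exists(file.path(dir, "t", "tornado.csv")))
  got <- read.csv(file.path(dir, "t", "tornado.csv"))
  expect_equal(got$width, as.numeric(tor$width))

  expect_error(cea_owsa(cfg, indir, file.path(dir, "t2"),
                        ranges_path = file.path(dir, "nope.csv"),
                        candidate = "dominant", reference = "weak"),
               "not found")
})
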