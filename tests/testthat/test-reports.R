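test_that("cmd_run writes a complete, byte-reproducible artifact set", {
  yaml_path <- system.file("extdata", "basecase", "basecase.yaml",
                           package = "mcpcea")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  r1 <- cmd_run(yaml_path, d1, n_runs = 25, seed = 1, wtp = seq(0, 5000, 500),
                quiet = TRUE)
  r2 <- cmd_run(yaml_path, d2, n_runs = 25, seed = 1, wtp = seq(0, 5000, 500),
                quiet = TRUE)
  for (f in c("deterministic.csv", "psa_samples.csv", "quadrants.csv",
              "ceac.csv", "summary.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # machine-readable summary round-trips the headline numbers
  js <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_equal(js$psa$means$d_dalys, mean(r1$samples$d_dalys))
  expect_equal(js$n_runs, 25)
})

test_that("a collapsed-distribution run's PSA equals its deterministic report", {
  p <- degenerate_params()
  d <- withr::local_tempdir()
  res <- cmd_run(p, d, n_runs = 3, seed = 2, wtp = c(0, 1000), quiet = TRUE)
  expect_identical(unique(res$samples$d_cost_hc),
                   res$deterministic$incremental$d_cost_hc)
  expect_identical(unique(res$samples$d_dalys),
                   res$deterministic$incremental$d_dalys_averted)
})

test_that("cmd_run rejects invalid configuration", {
  d <- withr::local_tempdir()
  expect_error(cmd_run(file.path(d, "missing.yaml"), d, quiet = TRUE),
               "not found")
  expect_error(cmd_run(base_params(), d, n_runs = 5, wtp = c(5, 1),
                       quiet = TRUE), "increasing")
})

test_that("cmd_validate reports passes for the shipped file and names failures", {
  yaml_path <- system.file("extdata", "basecase", "basecase.yaml",
                           package = "mcpcea")
  checks <- cmd_validate(yaml_path, quiet = TRUE)
  expect_true(all(checks$pass))

  # break the recovery curve with an increasing step
  src <- dirname(yaml_path)
  d <- withr::local_tempdir()
  file.copy(list.files(src, full.names = TRUE), d)
  curve <- utils::read.csv(file.path(d, "recovery_curve.csv"))
  curve$probability[5] <- curve$probability[4] + 0.1
  utils::write.csv(curve, file.path(d, "recovery_curve.csv"),
                   row.names = FALSE, quote = FALSE)
  checks_bad <- cmd_validate(file.path(d, "basecase.yaml"), quiet = TRUE)
  bad <- checks_bad[!checks_bad$pass, ]
  expect_true("transitions$recovery_curve_monotone" %in% bad$check)
  expect_match(bad$detail[bad$check == "transitions$recovery_curve_monotone"],
               "cycle 5")
})
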