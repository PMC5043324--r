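test_that("class detection matches the published structures", {
  cl <- detect_classes(make_uniform(g100))
  expect_identical(cl$class_count, 1L)
  expect_equal(cl$levels, 0.5)

  cl <- detect_classes(two_step(0.3))
  expect_identical(cl$class_count, 2L)
  expect_equal(sort(cl$levels), c(0.35, 0.65), tolerance = 1e-9)

  cl <- detect_classes(make_fermi(g100, 0.05))
  expect_gte(cl$class_count, 25)
})

test_that("a scan reproduces the cascade of class counts", {
  cfg <- run_config(t_values = c(5, 3.9, 1.4, 0.1), M = 100,
                    metropolis = metropolis_config(n_iter = 1e5),
                    seed = 1)
  res <- run_scan(cfg)
  expect_equal(res$summary$t, c(0.1, 1.4, 3.9, 5))
  counts <- res$summary$class_count
  expect_gte(counts[res$summary$t == 0.1], 25)
  expect_identical(counts[res$summary$t == 1.4], 3L)
  expect_identical(counts[res$summary$t == 3.9], 2L)
  expect_identical(counts[res$summary$t == 5], 1L)
  # class count is non-increasing as t grows
  expect_true(all(diff(counts) <= 0))
  # n = 1/2 above the transition
  expect_lt(abs(res$summary$n[res$summary$t == 5] - 0.5), 0.01)
})

test_that("scans are reproducible and write inspectable artifacts", {
  dir1 <- tempfile("scan1_")
  dir2 <- tempfile("scan2_")
  base <- run_config(t_values = c(5, 2), M = 100,
                     metropolis = metropolis_config(n_iter = 2e4),
                     seed = 7)
  cfg1 <- base; cfg1$out_dir <- dir1
  cfg2 <- base; cfg2$out_dir <- dir2
  run_scan(cfg1)
  run_scan(cfg2)
  expect_identical(readLines(file.path(dir1, "scan.json")),
                   readLines(file.path(dir2, "scan.json")))
  d <- read_trait_dist(file.path(dir1, "dist_t2.tsv"))
  expect_s3_class(d, "trait_dist")
})

test_that("fixture generation round-trips and conserves proportions", {
  b <- generate_fixture("binned_survey",
                        list(Ttilde = 0.09, n_respondents = 1e6, noise = 0),
                        seed = 2)
  expect_equal(sum(b$proportion), 1, tolerance = 1e-12)
  expect_lt(abs(fit_ttilde(b)$Ttilde_hat - 0.09), 0.005)

  path <- tempfile(fileext = ".tsv")
  d <- generate_fixture("distribution", list(profile = "two_step", c = 0.5),
                        seed = 1, path = path)
  expect_equal(read_trait_dist(path)$p, two_step(0.5)$p)
  expect_error(generate_fixture("binned_survey", list(Ttilde = -1)),
               "invalid 'Ttilde'")
})
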