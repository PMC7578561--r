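make_power_input <- function(seed = 26, n_pre = 84, n_post = 24,
                             base_mean = 150, sigma = 0.1) {
  set.seed(seed)
  s <- generate_series(fixture_spec(n_months = n_pre, base_mean = base_mean,
                                    sigma = sigma))
  assemble(s, rep(0, n_post), replicate_id = 0)$series
}

test_that("the experiment is bit-reproducible under the master seed", {
  series <- make_power_input()
  w <- analysis_window("2010-01", "2011-12")
  cfg <- power_config(irr_grid = 0.8, n_sim = 15, master_seed = 42)
  r1 <- run_power(series, w, cfg)
  r2 <- run_power(series, w, cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_identical(power_replicates(r1), power_replicates(r2))
})

test_that("cells cover the effect-by-drop grid and counts add up", {
  series <- make_power_input()
  w <- analysis_window("2010-01", "2010-12")
  cfg <- power_config(irr_grid = c(0.6, 0.9), n_sim = 8, master_seed = 5,
                      baseline_drops = c(0, 2))
  res <- run_power(series, w, cfg)
  expect_equal(nrow(res), 4)
  expect_setequal(res$baseline_drop, c(0, 2))
  expect_true(all(res$n_converged + res$n_failed == 8))
  expect_true(all(res$power >= 0 & res$power <= 1, na.rm = TRUE))
  expect_true(all(res$coverage >= 0 & res$coverage <= 1, na.rm = TRUE))
  # truncated cells refit on a shorter baseline with its own characteristics
  expect_equal(unique(round(res$mean_count[res$baseline_drop == 2], 6)),
               round(mean(truncate_baseline(split_periods(series, w)$pre, 2)$outcome), 6))
  reps <- power_replicates(res)
  expect_equal(nrow(reps), 4 * 8)
})

test_that("power_vs_baseline_length with a single zero drop equals run_power", {
  series <- make_power_input()
  w <- analysis_window("2010-01", "2010-12")
  cfg <- power_config(irr_grid = 0.8, n_sim = 10, master_seed = 9)
  a <- run_power(series, w, cfg)
  b <- power_vs_baseline_length(series, w, cfg, baseline_drops = 0)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("control series flow through the covariate pipeline", {
  set.seed(27)
  ach <- rpois(84, 900)
  s <- monthly_series(months_from("2003-01", 84), rpois(84, 150),
                      controls = list(ach = ach))
  full <- assemble(s, rep(0, 12),
                   controls_post = extend_controls(s, 12),
                   replicate_id = 0)$series
  w <- analysis_window("2010-01", "2010-12")
  res <- run_power(full, w, power_config(irr_grid = 0.8, n_sim = 6, master_seed = 3),
                   control_mode = "covariate")
  expect_equal(nrow(res), 1)
  expect_true(res$n_converged + res$n_failed == 6)
})

test_that("summarize_report writes the cells, replicates and plots", {
  series <- make_power_input()
  w <- analysis_window("2010-01", "2010-12")
  res <- run_power(series, w, power_config(irr_grid = 0.8, n_sim = 10,
                                           master_seed = 2, keep_series = 5))
  out <- withr::local_tempdir()
  paths <- summarize_report(res, out)
  expect_true(all(file.exists(paths)))
  cells <- readr::read_csv(paths["cells"], show_col_types = FALSE)
  expect_equal(nrow(cells), 1)
  reps <- readr::read_csv(paths["replicates"], show_col_types = FALSE)
  expect_equal(nrow(reps), 10)
  expect_error(summarize_report(res[0, ], out), class = "itspower_error_domain")
})

test_that("plot builders return ggplot objects", {
  series <- make_power_input()
  w <- analysis_window("2010-01", "2010-12")
  res <- run_power(series, w, power_config(irr_grid = 0.8, n_sim = 6,
                                           master_seed = 8, keep_series = 3))
  expect_s3_class(plot_simulated_series(res), "ggplot")
  expect_s3_class(plot_estimates(res), "ggplot")
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res, x = "mean_count"), "ggplot")
})
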