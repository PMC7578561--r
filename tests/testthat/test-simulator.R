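test_that("vaccine ramp is the clamped log-linear decline", {
  eff <- vaccine_effect(0.8, 24)
  v <- vaccine_ramp(36, eff)
  expect_length(v, 36)
  expect_equal(v[1], 0)                      # introduction month
  expect_equal(v[13], 0.5 * log(0.8))        # midpoint t = 12
  expect_equal(v[25], log(0.8))              # ramp end t = 24
  expect_equal(v[26:36], rep(log(0.8), 11))  # plateau
  expect_equal(vaccine_ramp(18, vaccine_effect(1)), rep(0, 18))
  # step change via ramp_months = 1
  expect_equal(vaccine_ramp(4, vaccine_effect(0.5, 1)),
               c(0, rep(log(0.5), 3)))
  expect_error(vaccine_effect(0), class = "itspower_error_domain")
  expect_error(vaccine_effect(1.2), class = "itspower_error_domain")
})

test_that("parameter draws have the requested mean and covariance", {
  beta <- c(a = 1, b = -0.5)
  # degenerate: zero covariance returns beta exactly
  expect_equal(draw_parameters(fake_fit(beta, matrix(0, 2, 2))), beta)
  V <- matrix(c(1, 0.3, 0.3, 0.5), 2, 2)
  set.seed(17)
  draws <- draw_parameters(fake_fit(beta, V), n = 10000)
  expect_equal(unname(colMeans(draws)), unname(beta), tolerance = 0.03)
  emp <- stats::cov(draws)
  expect_true(all(abs(emp - V) <= 0.05 * max(abs(V))))
  # determinism under a fixed seed
  set.seed(99); d1 <- draw_parameters(fake_fit(beta, V), n = 5)
  set.seed(99); d2 <- draw_parameters(fake_fit(beta, V), n = 5)
  expect_identical(d1, d2)
  # a genuinely indefinite covariance is refused
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(draw_parameters(fake_fit(beta, bad)),
               class = "itspower_error_numerical")
})

test_that("with no noise sources simulated counts are plain Poisson", {
  s <- make_series(rep(100, 48))
  fit <- fit_baseline(s)
  fit$vcov[] <- 0
  fit$sigma <- 0
  post <- make_series(rep(0, 12), start = "2007-01")
  pd <- build_design(post, origin = s$date[1])
  mu <- drop(pd$X %*% fit$beta)
  set.seed(18)
  sims <- replicate(5000, simulate_post(fit, pd, vaccine_effect(1)))
  expect_true(all(abs(rowMeans(sims) - exp(mu)) / exp(mu) < 0.02))
  # variance consistent with Poisson (index of dispersion near 1)
  iod <- apply(sims, 1, var) / rowMeans(sims)
  expect_true(all(iod > 0.9 & iod < 1.1))
})

test_that("the injected effect scales post-ramp counts by the rate ratio", {
  set.seed(19)
  s <- generate_series(fixture_spec(n_months = 84, base_mean = 500, sigma = 0.05))
  fit <- fit_baseline(s)
  post <- make_series(rep(0, 30), start = "2010-01")
  pd <- build_design(post, origin = s$date[1])
  R <- 400
  lr <- numeric(R)
  for (r in seq_len(R)) {
    bd <- draw_parameters(fit)
    set.seed(1000 + r); y_eff <- simulate_post(fit, pd, vaccine_effect(0.5), beta_draw = bd)
    set.seed(1000 + r); y_null <- simulate_post(fit, pd, vaccine_effect(1), beta_draw = bd)
    # common random numbers: the beta draw and phi sequence are shared, so
    # the post-ramp log-ratio of totals isolates the injected effect
    lr[r] <- log(sum(y_eff[25:30]) / sum(y_null[25:30]))
  }
  expect_lt(abs(mean(lr) - log(0.5)), 3 * sd(lr) / sqrt(R))
})

test_that("identical seeds give identical simulations", {
  set.seed(20)
  s <- generate_series(fixture_spec(n_months = 60, base_mean = 150, sigma = 0.1))
  fit <- fit_baseline(s)
  pd <- build_design(make_series(rep(0, 12), start = "2008-01"), origin = s$date[1])
  set.seed(7); y1 <- simulate_post(fit, pd, vaccine_effect(0.8))
  set.seed(7); y2 <- simulate_post(fit, pd, vaccine_effect(0.8))
  expect_identical(y1, y2)
})

test_that("assemble concatenates and preserves the baseline bit-exactly", {
  set.seed(21)
  s <- make_series(rpois(84, 150))
  y_post <- rpois(36, 120)
  ds <- assemble(s, y_post, truth = vaccine_effect(0.8), replicate_id = 3)
  expect_equal(nrow(ds$series), 120)
  expect_identical(ds$series$outcome[1:84], s$outcome)
  expect_identical(ds$series$outcome[85:120], as.numeric(y_post))
  expect_equal(ds$series$date[85], as.Date("2010-01-01"))
  expect_equal(ds$replicate_id, 3)

  # controls must abut exactly
  sc <- make_series(rpois(84, 150), controls = list(ach = rpois(84, 900)))
  good <- tibble::tibble(date = months_from("2010-01", 36), ach = rpois(36, 900))
  ds2 <- assemble(sc, y_post, controls_post = good)
  expect_identical(ds2$series$ach[85:120], as.numeric(good$ach))
  shifted <- good
  shifted$date <- shifted$date + 31
  expect_error(assemble(sc, y_post, controls_post = shifted),
               class = "itspower_error_contiguity")
  expect_error(assemble(sc, y_post), class = "itspower_error_config")
})

test_that("extend_controls repeats the recent seasonal profile", {
  set.seed(22)
  ach <- rep(c(900, 950, 1000, 980, 940, 910, 890, 920, 960, 990, 970, 930), 7)
  s <- make_series(rpois(84, 150), controls = list(ach = ach))
  ext <- extend_controls(s, 24)
  expect_equal(nrow(ext), 24)
  expect_equal(ext$date[1], as.Date("2010-01-01"))
  # deterministic seasonal profile: carried forward unchanged
  expect_equal(ext$ach, rep(ach[1:12], 2))
})

test_that("replicates export in long format", {
  set.seed(23)
  s <- make_series(rpois(24, 80))
  d1 <- assemble(s, rpois(6, 70), replicate_id = 1)
  d2 <- assemble(s, rpois(6, 70), replicate_id = 2)
  long <- replicates_long(list(d1, d2))
  expect_equal(nrow(long), 2 * 30)
  expect_equal(unique(long$replicate), c(1, 2))
  expect_equal(sum(long$period == "pre"), 48)
})
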