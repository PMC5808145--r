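test_that("rmse: trivial cases and the direct-loop oracle", {
  t <- toy_forecasts()
  perfect <- t$fc
  perfect$mean <- t$obs$richness
  expect_equal(rmse(perfect, t$obs), 0)
  pm1 <- perfect
  pm1$mean <- pm1$mean + c(1, -1, 1, -1)
  expect_equal(rmse(pm1, t$obs), 1)
  # random instance vs brute-force loop
  set.seed(4)
  fc <- new_gaussian_forecast(sample(letters[1:5], 30, TRUE),
                              sample(1:6, 30, TRUE), 1, rnorm(30, 50),
                              runif(30), "m")
  fc <- fc[!duplicated(paste(fc$site_id, fc$year)), ]
  obs <- data.frame(site_id = fc$site_id, year = fc$year,
                    richness = rnorm(nrow(fc), 50))
  acc <- 0
  for (i in seq_len(nrow(fc))) acc <- acc + (fc$mean[i] - obs$richness[i])^2
  expect_equal(rmse(fc, obs), sqrt(acc / nrow(fc)))
  expect_error(rmse(fc, data.frame(site_id = "zz", year = 1,
                                   richness = 1)), "no forecasts match")
})

test_that("coverage: limits, sd = 0 rule, and calibration of a
           well-specified Gaussian forecaster", {
  t <- toy_forecasts()
  huge <- t$fc; huge$sd <- 1e6
  expect_equal(coverage(huge, t$obs), 1)
  zero <- t$fc; zero$sd <- 0; zero$mean <- t$obs$richness + 1
  expect_equal(coverage(zero, t$obs), 0)
  zero$mean <- t$obs$richness
  expect_equal(coverage(zero, t$obs), 1)   # exact hits count as covered
  set.seed(12)
  n <- 4000
  mu <- rnorm(n, 50, 5)
  fc <- new_gaussian_forecast(sprintf("s%05d", 1:n), 2004L, 1, mu,
                              rep(2, n), "m")
  obs <- data.frame(site_id = fc$site_id, year = 2004L,
                    richness = rnorm(n, mu, 2))
  se <- sqrt(0.95 * 0.05 / n)
  expect_lt(abs(coverage(fc, obs, 0.95) - 0.95), 3 * se + 1e-9)
})

test_that("deviance: closed form, monotonicity, oracle, and its minimum
           at sd^2 = MSE", {
  obs <- data.frame(site_id = "a", year = 1:4, richness = c(5, 6, 7, 8))
  fc <- new_gaussian_forecast("a", 1:4, 1:4, c(5, 6, 7, 8), 1, "m")
  expect_equal(mean_deviance(fc, obs), log(2 * pi))
  fc2 <- fc; fc2$sd <- 3
  expect_gt(mean_deviance(fc2, obs), mean_deviance(fc, obs))
  # direct Gaussian log-density oracle on a random instance
  set.seed(31)
  fc3 <- fc; fc3$mean <- rnorm(4, 6); fc3$sd <- runif(4, 0.5, 2)
  oracle <- -2 * mean(dnorm(obs$richness, fc3$mean, fc3$sd, log = TRUE))
  expect_equal(mean_deviance(fc3, obs), oracle)
  # sd = 0 handling
  fc0 <- fc; fc0$sd <- 0
  expect_error(mean_deviance(fc0, obs, var_floor = 0), "variance floor|floor")
  expect_message(mean_deviance(fc0, obs), "variance floor")
  # numeric 1-D scan: fixed predictions, deviance minimized at sd^2 = MSE
  set.seed(32)
  y <- rnorm(200, 50, 3); m <- rnorm(200, 50, 1)
  obs2 <- data.frame(site_id = sprintf("s%03d", 1:200), year = 1L,
                     richness = y)
  dev_at <- function(s) {
    f <- new_gaussian_forecast(obs2$site_id, 1L, 1, m, rep(s, 200), "m")
    mean_deviance(f, obs2)
  }
  mse <- mean((m - y)^2)
  grid <- seq(sqrt(mse) * 0.5, sqrt(mse) * 2, length.out = 60)
  expect_equal(grid[which.min(vapply(grid, dev_at, 0))], sqrt(mse),
               tolerance = 0.05)
})

test_that("skill vs baseline: zero against itself, signed differences,
           mean-difference identity, and key mismatch errors", {
  t <- toy_forecasts()
  self <- skill_vs_baseline(t$fc, t$fc, t$obs)
  expect_true(all(self$table$d_abs_error == 0))
  expect_true(all(self$table$d_deviance == 0))
  worse <- t$fc
  worse$mean <- worse$mean + c(1, 1, -1, -1)   # abs error 3 vs baseline 2 etc.
  sk <- skill_vs_baseline(worse, t$fc, t$obs)
  expect_equal(sk$table$d_abs_error,
               abs(worse$mean - t$obs$richness) -
                 abs(t$fc$mean - t$obs$richness))
  expect_equal(sk$mean_d_abs_error, mean(sk$table$d_abs_error))
  other <- t$fc; other$year <- other$year + 10
  expect_error(skill_vs_baseline(other, t$fc, t$obs), "keys differ")
})

test_that("MSE decomposition: hand example, constant bias, perfection,
           and exact additivity on random instances", {
  # 1 site, obs (50, 52), pred (53, 53): site 4, annual 1, total 5
  fc <- new_gaussian_forecast("a", 1:2, 1:2, c(53, 53), c(1, 1), "m")
  obs <- data.frame(site_id = "a", year = 1:2, richness = c(50, 52))
  d <- decompose_mse(fc, obs)
  expect_equal(d$site_component, 4)
  expect_equal(d$annual_component, 1)
  expect_equal(d$total, 5)

  # constant bias b everywhere: site b^2, annual 0
  set.seed(41)
  obs2 <- data.frame(site_id = rep(letters[1:4], each = 5),
                     year = rep(1:5, 4), richness = rnorm(20, 50, 3))
  fcb <- new_gaussian_forecast(obs2$site_id, obs2$year, obs2$year,
                               obs2$richness + 2.5, 1, "m")
  db <- decompose_mse(fcb, obs2)
  expect_equal(db$site_component, 6.25, tolerance = 1e-12)
  expect_equal(db$annual_component, 0, tolerance = 1e-12)

  # perfect forecasts: all zero
  fcp <- new_gaussian_forecast(obs2$site_id, obs2$year, obs2$year,
                               obs2$richness, 1, "m")
  dp <- decompose_mse(fcp, obs2)
  expect_equal(c(dp$site_component, dp$annual_component, dp$total),
               c(0, 0, 0))

  # additivity to 1e-9 relative on random unbalanced instances
  for (seed in 1:5) {
    set.seed(seed)
    ns <- sample(2:6, 8, replace = TRUE)
    obs3 <- do.call(rbind, lapply(seq_along(ns), function(i)
      data.frame(site_id = paste0("s", i), year = seq_len(ns[i]),
                 richness = rnorm(ns[i], 50, 5))))
    fc3 <- new_gaussian_forecast(obs3$site_id, obs3$year, obs3$year,
                                 rnorm(nrow(obs3), 50, 5), 1, "m")
    d3 <- decompose_mse(fc3, obs3)
    expect_equal(d3$site_component + d3$annual_component, d3$total,
                 tolerance = 1e-9)
  }
})

test_that("horizon-stratified metrics partition the pooled table and the
           naive model's coverage grows with horizon on stationary data", {
  set.seed(51)
  sim <- simulate_richness_panel(sim_config(n_sites = 60, sigma_obs = 0,
                                            resid_ar1 = 0, obs_prob = 1,
                                            seed = 51))
  parts <- split_train_test(sim$panel, 2003)
  fcs <- do.call(rbind, lapply(split(parts$train, parts$train$site_id),
    function(d) forecast_naive(suppressWarnings(
      fit_naive(d$richness, d$year)), 1:10, d$site_id[1], 2003)))
  mh <- metrics_by_horizon(fcs, parts$test)
  expect_equal(sum(mh$n), nrow(parts$test))
  # intervals expand with sqrt(h): late-horizon coverage beats early
  expect_gt(mean(mh$coverage95[mh$horizon >= 8]),
            mean(mh$coverage95[mh$horizon <= 2]))
  # single-horizon input equals the pooled table
  f1 <- fcs[fcs$horizon == 1, ]
  m1 <- metrics_by_horizon(f1, parts$test)
  mp <- metrics_table(f1, parts$test)
  expect_equal(m1$rmse, mp$rmse)
  expect_equal(m1$coverage95, mp$coverage95)
  expect_equal(m1$n, mp$n)
})
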