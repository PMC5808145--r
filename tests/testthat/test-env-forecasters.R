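# Environmental-model tests use small synthetic benchmarks with known
# signal so fits stay fast.

step_data <- function(n, seed = 3) {
  set.seed(seed)
  cov <- data.frame(site_id = sprintf("s%04d", seq_len(n)), year = 2000L,
                    env1 = runif(n), env2 = runif(n))
  list(cov = cov, y = ifelse(cov$env1 > 0.5, 60, 40) + rnorm(n, 0, 1))
}

test_that("boosted trees learn a step function (holdout R^2 > 0.95) and
           stay honest on pure noise", {
  d <- step_data(600)
  g <- fit_richness_gbm(d$cov[1:400, ], d$y[1:400], max_trees = 1500,
                        seed = 1)
  fc <- predict_richness_gbm(g, d$cov[401:600, ])
  r2 <- 1 - mean((fc$mean - d$y[401:600])^2) / var(d$y[401:600])
  expect_gt(r2, 0.95)
  expect_true(all(fc$sd == g$sigma))    # homoscedastic SD

  set.seed(9)
  ynoise <- rnorm(600, 50, 5)
  gn <- fit_richness_gbm(d$cov[1:400, ], ynoise[1:400], max_trees = 1500,
                         seed = 1)
  fcn <- predict_richness_gbm(gn, d$cov[401:600, ])
  r2n <- 1 - mean((fcn$mean - ynoise[401:600])^2) / var(ynoise[401:600])
  expect_lt(gn$n_trees, 200)            # early stopping on pure noise
  expect_lt(abs(r2n), 0.25)
})

test_that("identical covariate rows receive identical predictions from
           every environmental model", {
  d <- step_data(200)
  twin <- d$cov[c(1, 1), ]
  twin$site_id <- c("twin_a", "twin_b")
  g <- fit_richness_gbm(d$cov, d$y, max_trees = 300, seed = 2)
  pg <- predict_richness_gbm(g, twin)
  expect_equal(pg$mean[1], pg$mean[2])

  cfg <- tiny_config(n_species = 6)
  cv <- simulate_covariates(cfg)
  cs <- simulate_community_panel(cfg, cv)
  sf <- fit_stacked_sdm(cs$community, cv, n_trees = 30, seed = 4)
  twin2 <- cv[c(3, 3), ]
  ps <- predict_species_probs(sf, twin2)
  expect_equal(ps[1, ], ps[2, ])
  jf <- fit_jsdm(cs$community, cv, n_latent = 0, seed = 4)
  pj <- predict_jsdm_richness(jf, twin2, n_samples = 200, seed = 11)
  expect_equal(pj$mean[1], pj$mean[2], tolerance = 0.3)
})

test_that("constant response returns a constant predictor with warning", {
  d <- step_data(50)
  expect_warning(g <- fit_richness_gbm(d$cov, rep(42, 50)), "constant")
  expect_equal(predict_richness_gbm(g, d$cov)$mean, rep(42, 50))
})

test_that("per-species forests separate a deterministic threshold species", {
  set.seed(6)
  n <- 300
  cov <- data.frame(site_id = sprintf("s%04d", 1:n), year = 2000L,
                    env1 = runif(n), env2 = runif(n))
  comm <- data.frame(site_id = rep(cov$site_id, 2),
                     year = 2000L,
                     species_id = rep(c("thresh", "coin"), each = n),
                     detected = c(as.integer(cov$env1 > 0.5),
                                  rbinom(n, 1, 0.5)))
  sf <- fit_stacked_sdm(comm, cov, n_trees = 100, seed = 3)
  p <- predict_species_probs(sf, cov)
  clear <- abs(cov$env1 - 0.5) > 0.1
  expect_gt(mean(p[clear & cov$env1 > 0.5, "thresh"]), 0.9)
  expect_lt(mean(p[clear & cov$env1 < 0.5, "thresh"]), 0.1)
})

test_that("single-class species yield flagged constant probabilities and
           n_trees = 1 reduces to one tree's 0/1 vote", {
  set.seed(8)
  n <- 60
  cov <- data.frame(site_id = sprintf("s%03d", 1:n), year = 2000L,
                    env1 = runif(n), env2 = runif(n))
  comm <- data.frame(site_id = rep(cov$site_id, 2), year = 2000L,
                     species_id = rep(c("always", "var"), each = n),
                     detected = c(rep(1L, n), as.integer(cov$env1 > 0.4)))
  sf <- fit_stacked_sdm(comm, cov, n_trees = 1, seed = 5)
  expect_named(sf$constant_species, "always")
  p <- predict_species_probs(sf, cov)
  expect_true(all(p[, "always"] == 1))
  expect_true(all(p[, "var"] %in% c(0, 1)))   # single-tree vote
})

test_that("stacked richness follows the independent-Bernoulli closed form
           and its Monte-Carlo oracle", {
  cov <- data.frame(site_id = "s1", year = 2004L)
  p <- matrix(c(1, 0, 0.5), 1, dimnames = list(NULL, c("a", "b", "c")))
  fc <- predict_stacked_richness(p, cov, last_year = 2003L)
  expect_equal(fc$mean, 1.5)
  expect_equal(fc$sd^2, 0.25)
  # all p in {0, 1}: zero variance
  p01 <- matrix(c(1, 0, 1), 1)
  expect_equal(predict_stacked_richness(p01, cov)$sd, 0)
  # Monte-Carlo oracle: variance of independent Bernoulli draws
  set.seed(2)
  pr <- matrix(runif(12), 1)
  fc2 <- predict_stacked_richness(pr, cov)
  sims <- replicate(30000, sum(rbinom(12, 1, pr)))
  expect_equal(fc2$mean, mean(sims), tolerance = 0.05)
  expect_equal(fc2$sd^2, var(sims), tolerance = 0.1)
})

test_that("corrected-mode forests agree with uncorrected in expectation
           when observer effects are zero", {
  cfg <- tiny_config(n_species = 5, sigma_obs = 0)
  cv <- simulate_covariates(cfg)
  cs <- simulate_community_panel(cfg, cv)
  zero_draws <- matrix(0, nrow(cv), 10)
  sf_u <- fit_stacked_sdm(cs$community, cv, n_trees = 60, seed = 9)
  sf_c <- fit_stacked_sdm(cs$community, cv, observer_draws = zero_draws,
                          n_trees = 60, seed = 9)
  pu <- predict_species_probs(sf_u, cv)
  pc <- predict_species_probs(sf_c, cv, obs_effect = 0)
  expect_lt(mean(abs(pu - pc)), 0.12)   # tolerance set by forest noise
})

test_that("JSDM with n_latent = 0 matches independent logistic fits", {
  cfg <- tiny_config(n_species = 4, n_latent = 0)
  cv <- simulate_covariates(cfg)
  cs <- simulate_community_panel(cfg, cv)
  jf <- fit_jsdm(cs$community, cv, n_latent = 0, seed = 3)
  xs <- scale(as.matrix(cv[, c("env1", "env2", "elevation")]))
  for (sp in jf$species) {
    y <- cs$community$detected[cs$community$species_id == sp]
    gl <- suppressWarnings(glm(y ~ xs, family = binomial))
    expect_equal(unname(jf$alpha[sp]), unname(coef(gl)[1]),
                 tolerance = 1e-5)
    expect_equal(unname(jf$beta[sp, ]), unname(coef(gl)[-1]),
                 tolerance = 1e-5)
  }
})

test_that("JSDM recovers a strong latent loading vector up to sign", {
  cfg <- sim_config(n_sites = 50, years = 2000:2009, n_species = 10,
                    n_latent = 1, latent_scale = 1.5, obs_prob = 1,
                    seed = 9)
  cv <- simulate_covariates(cfg)
  cs <- simulate_community_panel(cfg, cv)
  jf <- suppressWarnings(fit_jsdm(cs$community, cv, n_latent = 1,
                                  n_particles = 80, max_iter = 8,
                                  seed = 3))
  r <- cor(jf$loadings[, 1], cs$truth$loadings[, 1])
  expect_gt(abs(r), 0.7)
})

test_that("permuting species order permutes JSDM parameters identically", {
  cfg <- tiny_config(n_species = 4, n_latent = 0)
  cv <- simulate_covariates(cfg)
  cs <- simulate_community_panel(cfg, cv)
  comm_rev <- cs$community[order(cs$community$species_id,
                                 decreasing = TRUE), ]
  j1 <- fit_jsdm(cs$community, cv, n_latent = 0, seed = 3)
  j2 <- fit_jsdm(comm_rev, cv, n_latent = 0, seed = 3)
  expect_equal(j1$alpha, j2$alpha)
  expect_equal(j1$beta, j2$beta)
})

test_that("JSDM predictions: zero loadings reduce to the stacked formula;
           a shared factor widens intervals; large samples stabilize", {
  cfg <- tiny_config(n_species = 8, n_latent = 0)
  cv <- simulate_covariates(cfg)
  cs <- simulate_community_panel(cfg, cv)
  jf <- fit_jsdm(cs$community, cv, n_latent = 0, seed = 3)
  rows <- cv[1:6, ]
  fc <- predict_jsdm_richness(jf, rows, n_samples = 4000, seed = 8)
  # closed-form p from the fitted coefficients
  xs <- sweep(sweep(as.matrix(rows[, c("env1", "env2", "elevation")]),
                    2, jf$center), 2, jf$scale, "/")
  eta <- matrix(jf$alpha, 6, 8, byrow = TRUE) + xs %*% t(jf$beta)
  p <- plogis(eta)
  expect_equal(fc$mean, unname(rowSums(p)), tolerance = 0.15)
  expect_equal(fc$sd^2, unname(rowSums(p * (1 - p))), tolerance = 0.15)

  # nonzero loadings: predictive SD strictly exceeds independent SD
  jf2 <- jf
  jf2$n_latent <- 1L
  jf2$loadings <- matrix(2, 8, 1)
  fc2 <- predict_jsdm_richness(jf2, rows, n_samples = 4000, seed = 8)
  expect_true(all(fc2$sd > fc$sd))

  # stability: two large-sample runs agree closely (SE of mean < 0.1)
  fc3 <- predict_jsdm_richness(jf, rows, n_samples = 4000, seed = 9)
  expect_lt(max(abs(fc3$mean - fc$mean)), 0.2)
})
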