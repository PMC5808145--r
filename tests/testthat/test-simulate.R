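test_that("invalid configurations are rejected", {
  expect_error(sim_config(sigma_site = -1), "sigma_site")
  expect_error(sim_config(resid_ar1 = 1), "resid_ar1")
  expect_error(sim_config(n_sites = 0), "n_sites")
  expect_error(sim_config(years = 1990), "years")
})

test_that("identical configs give byte-identical panels", {
  cfg <- tiny_config()
  s1 <- simulate_richness_panel(cfg)
  s2 <- simulate_richness_panel(cfg)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$true_effects, s2$true_effects)
  w1 <- simulate_monthly_weather(cfg)
  w2 <- simulate_monthly_weather(cfg)
  expect_identical(w1, w2)
})

test_that("noise-free limit gives constant site series at mu + a_s", {
  cfg <- tiny_config(sigma_obs = 0, sigma_resid = 0, resid_ar1 = 0)
  sim <- simulate_richness_panel(cfg)
  per_site <- split(sim$panel$richness, sim$panel$site_id)
  expect_true(all(vapply(per_site, function(x) diff(range(x)), 0) < 1e-12))
  means <- vapply(per_site, mean, 0)
  truth <- cfg$global_mean_richness +
    sim$true_effects$site_effects[names(means)]
  expect_equal(unname(means), unname(truth), tolerance = 1e-12)
})

test_that("panel structure: unique keys, observers in consecutive stints", {
  sim <- simulate_richness_panel(tiny_config())
  expect_false(anyDuplicated(paste(sim$panel$site_id, sim$panel$year)) > 0)
  expect_true(all(sim$panel$richness >= 0))
  expect_true(all(nzchar(sim$panel$observer_id)))
  # stints are consecutive: each observer's years form one unbroken run
  runs <- tapply(sim$panel$year, sim$panel$observer_id,
                 function(y) all(diff(sort(y)) == 1))
  expect_true(all(runs))
  # observers are never shared across sites
  xsite <- tapply(sim$panel$site_id, sim$panel$observer_id,
                  function(s) length(unique(s)))
  expect_true(all(xsite == 1))
})

test_that("default variance components are recovered by direct ANOVA-style
           decomposition of the generated effect arrays", {
  cfg <- sim_config(n_sites = 600, seed = 21, obs_prob = 1)
  sim <- simulate_richness_panel(cfg)
  v_site <- var(sim$true_effects$site_effects)
  v_obs <- var(sim$true_effects$observer_effects)
  v_res <- var(as.vector(sim$true_effects$residuals))
  tot <- v_site + v_obs + v_res
  fr <- c(v_site, v_obs, v_res) / tot
  # Monte-Carlo SE of a variance fraction at these n is well under 0.03;
  # 3 SEs around the generating 70/21/9 partition
  expect_equal(fr[1], 0.70, tolerance = 0.09)
  expect_equal(fr[2], 0.21, tolerance = 0.06)
  expect_equal(fr[3], 0.09, tolerance = 0.03)
  expect_equal(sqrt(v_res), 3.6, tolerance = 0.2)
})

test_that("lag-1 residual dependence matches the generating AR(1)", {
  cfg <- sim_config(n_sites = 1500, years = 1982:2013, seed = 3)
  sim <- simulate_richness_panel(cfg)
  eps <- sim$true_effects$residuals
  r <- cor(as.vector(eps[, -ncol(eps)]), as.vector(eps[, -1]))
  # oracle: squared sample autocorrelation ~ resid_ar1^2 = 0.114^2 ~ 0.013
  expect_lt(abs(r^2 - 0.013), 0.006)
})

test_that("missing-visit process thins the panel at the configured rate", {
  cfg <- sim_config(n_sites = 200, years = 1982:2013, obs_prob = 0.9,
                    seed = 5)
  sim <- simulate_richness_panel(cfg)
  frac <- nrow(sim$panel) / (200 * 32)
  expect_gt(frac, 0.87)
  expect_lt(frac, 0.93)
})

test_that("community richness equals detection row sums", {
  cfg <- tiny_config(n_species = 12)
  cov <- simulate_covariates(cfg)
  cs <- simulate_community_panel(cfg, cov)
  sums <- tapply(cs$community$detected,
                 paste(cs$community$site_id, cs$community$year), sum)
  expect_equal(as.vector(sums[paste(cs$panel$site_id, cs$panel$year)]),
               cs$panel$richness)
  expect_true(all(cs$community$detected %in% 0:1))
  expect_type(cs$panel$richness, "integer")
})

test_that("saturating logit gives detected = 1 everywhere, richness 1", {
  cfg <- tiny_config(n_species = 1, sigma_obs = 0, n_latent = 0,
                     env_effect_scale = 0)
  cov <- simulate_covariates(cfg)
  cs <- simulate_community_panel(cfg, cov, alpha = 50)
  expect_true(all(cs$community$detected == 1L))
  expect_true(all(cs$panel$richness == 1L))
})

test_that("mismatched covariate keys raise a key error", {
  cfg <- tiny_config(n_species = 3)
  expect_error(simulate_community_panel(cfg, data.frame(x = 1)), "site_id")
})

test_that("n_latent = 0 leaves species conditionally independent;
           a strong shared factor inflates richness variance beyond the
           independent-Bernoulli formula", {
  # conditional independence: many years at one site, fixed covariates
  cfg0 <- sim_config(n_sites = 2, years = 1001:1800, n_species = 6,
                     n_latent = 0, env_effect_scale = 0, sigma_obs = 0,
                     obs_prob = 1, mean_stint_years = 1e6, seed = 11)
  cov0 <- simulate_covariates(cfg0)
  cov0$env1 <- 0.5; cov0$env2 <- 0.5   # identical covariates throughout
  cs0 <- simulate_community_panel(cfg0, cov0)
  det <- matrix(cs0$community$detected, ncol = 6)
  cors <- cor(det)[upper.tri(diag(6))]
  expect_lt(max(abs(cors)), 0.12)  # ~0 within sampling error at n=1600

  # over-dispersion: Monte-Carlo richness variance vs sum p(1-p)
  cfg1 <- sim_config(n_sites = 400, years = 2000:2001, n_species = 20,
                     n_latent = 1, latent_scale = 2, sigma_obs = 0,
                     obs_prob = 1, seed = 12)
  cov1 <- simulate_covariates(cfg1)
  cs1 <- simulate_community_panel(cfg1, cov1)
  p <- cs1$truth$prob
  v_indep <- mean(rowSums(p * (1 - p)))
  v_mc <- var(cs1$panel$richness)
  expect_gt(v_mc, v_indep)
})

test_that("weather generator: bounds hold and zero amplitude passes a
           constant diurnal range through to bio2", {
  cfg <- tiny_config()
  w <- simulate_monthly_weather(cfg)
  expect_true(all(w$tmax >= w$tmin))
  expect_true(all(w$prec >= 0))
  # noise 0, amplitude 0: constant climate per site, bio2 = tmax - tmin
  w0 <- simulate_monthly_weather(cfg, amplitude = 0, noise_sd = 0)
  bc <- compute_bioclim(w0, survey_year = 2005)
  one <- w0[w0$site_id == bc$site_id[1], ]
  expect_equal(bc$bio2[1], one$tmax[1] - one$tmin[1], tolerance = 1e-9)
})
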