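# Shared fixtures: everything is generated in code at test time.

# small, fast config for structural tests
tiny_config <- function(...) {
  sim_config(n_sites = 8, years = 2000:2009, obs_prob = 1, seed = 7, ...)
}

# constant-climate weather table for closed-form bioclim checks
constant_weather <- function(tmax = 20, tmin = 10, prec = 100,
                             sites = "s1", years = 1999:2001) {
  grid <- expand.grid(month = 1:12, year = years, site_id = sites,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  data.frame(grid[, c("site_id", "year", "month")],
             tmax = tmax, tmin = tmin, prec = prec, ndvi = 0.5)
}

# random weather for oracle comparisons
random_weather <- function(seed, sites = c("a", "b"), years = 1999:2001) {
  set.seed(seed)
  grid <- expand.grid(month = 1:12, year = years, site_id = sites,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  tmax <- rnorm(n, 18, 8)
  data.frame(grid[, c("site_id", "year", "month")],
             tmax = tmax, tmin = tmax - runif(n, 2, 12),
             prec = rgamma(n, 2, 1 / 40), ndvi = runif(n))
}

# independent oracle for the quarter-based bioclim values: brute-force
# scan over the 10 non-wrapping 3-month windows of the July-June series
oracle_quarters <- function(tmax, tmin, prec) {
  mid <- (tmax + tmin) / 2
  stats <- t(sapply(1:10, function(i)
    c(psum = sum(prec[i:(i + 2)]), tmean = mean(mid[i:(i + 2)]))))
  list(bio16 = unname(max(stats[, "psum"])),
       bio8 = unname(stats[which.max(stats[, "psum"]), "tmean"]),
       bio9 = unname(stats[which.min(stats[, "psum"]), "tmean"]),
       bio18 = unname(stats[which.max(stats[, "tmean"]), "psum"]))
}

# July-June month vectors for one site/survey-year from a weather table
window_series <- function(weather, site, survey_year) {
  sel <- weather$site_id == site &
    ((weather$year == survey_year - 1 & weather$month >= 7) |
       (weather$year == survey_year & weather$month <= 6))
  w <- weather[sel, ]
  w <- w[order(w$year, w$month), ]
  w
}

# deterministic tiny forecast/observation pair
toy_forecasts <- function() {
  list(
    fc = new_gaussian_forecast(rep(c("a", "b"), each = 2),
                               rep(1:2, 2), rep(1:2, 2),
                               c(50, 51, 40, 41), c(1, 1, 2, 2), "toy"),
    obs = data.frame(site_id = rep(c("a", "b"), each = 2),
                     year = rep(1:2, 2),
                     richness = c(50.5, 50, 42, 40))
  )
}
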