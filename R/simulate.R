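# Site-level setup shared by the generators: two environmental gradients
# per site, an elevation value, and the site effect a_s decomposed into a
# smooth nonlinear function of the gradients plus an unmeasured term.
site_frame <- function(config) {
  g1 <- stats::runif(config$n_sites)
  g2 <- stats::runif(config$n_sites)
  w <- config$env_effect_scale
  # standardized smooth surface: var(sin(2*pi*U)) = 1/2, var(2(U-1/2)) = 1/3
  f <- (sin(2 * pi * g1) + 2 * (g2 - 0.5)) / sqrt(1 / 2 + 1 / 3)
  z <- stats::rnorm(config$n_sites)
  a <- config$sigma_site * (sqrt(w) * f + sqrt(1 - w) * z)
  data.frame(
    site_id = sprintf("site_%04d", seq_len(config$n_sites)),
    g1 = g1, g2 = g2,
    elevation = round(200 + 1500 * g2 + stats::rnorm(config$n_sites, 0, 50)),
    site_effect = a,
    stringsAsFactors = FALSE
  )
}

# Observer schedule for one site: consecutive stints with geometric
# durations (mean = mean_stint_years), a fresh observer id per stint,
# observers never shared across sites.
observer_schedule <- function(site_id, n_years, mean_stint) {
  out <- integer(0)
  stint <- 0L
  while (length(out) < n_years) {
    stint <- stint + 1L
    len <- 1L + stats::rgeom(1L, 1 / mean_stint)
    out <- c(out, rep(stint, len))
  }
  paste0(site_id, "_obs_", sprintf("%02d", out[seq_len(n_years)]))
}

#' Simulate a site-year richness panel with observer structure
#'
#' Generates richness as \eqn{y_{s,t} = \mu + a_s + b_{o(s,t)} +
#' \epsilon_{s,t}} where \eqn{a_s} is a site effect (partly driven by two
#' environmental gradients), \eqn{b_o} is an observer effect, and
#' \eqn{\epsilon} is an AR(1) residual with lag-1 correlation
#' \code{config$resid_ar1} and marginal SD \code{config$sigma_resid}.
#' Observers work consecutive multi-year stints at a single site. Each
#' scheduled site-year is surveyed with probability \code{config$obs_prob}.
#'
#' @param config A [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{panel}{data.frame with columns \code{site_id}, \code{year},
#'       \code{observer_id}, \code{richness} (class
#'       \code{richness_panel}); unique on (site_id, year).}
#'     \item{true_effects}{list with \code{mu}, named vectors
#'       \code{site_effects} and \code{observer_effects}, the residual
#'       matrix \code{residuals} (sites x years), and the per-site
#'       covariate gradients in \code{sites}.}
#'   }
#' @export
#' @examples
#' sim <- simulate_richness_panel(sim_config(n_sites = 5, seed = 42))
#' head(sim$panel)
simulate_richness_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sites <- site_frame(config)
  ny <- length(config$years)

  obs_id <- unlist(lapply(sites$site_id, observer_schedule,
                          n_years = ny, mean_stint = config$mean_stint_years))
  obs_levels <- unique(obs_id)
  b <- stats::setNames(stats::rnorm(length(obs_levels), 0, config$sigma_obs),
                       obs_levels)

  # AR(1) residuals, marginal SD sigma_resid, one series per site
  phi <- config$resid_ar1
  eps <- matrix(0, config$n_sites, ny)
  innov_sd <- config$sigma_resid * sqrt(1 - phi^2)
  eps[, 1] <- stats::rnorm(config$n_sites, 0, config$sigma_resid)
  if (ny > 1) for (t in 2:ny)
    eps[, t] <- phi * eps[, t - 1] + stats::rnorm(config$n_sites, 0, innov_sd)

  panel <- data.frame(
    site_id = rep(sites$site_id, each = ny),
    year = rep(config$years, config$n_sites),
    observer_id = obs_id,
    stringsAsFactors = FALSE
  )
  panel$richness <- pmax(0, config$global_mean_richness +
    rep(sites$site_effect, each = ny) +
    unname(b[panel$observer_id]) +
    as.vector(t(eps)))

  if (config$obs_prob < 1)
    panel <- panel[stats::runif(nrow(panel)) < config$obs_prob, , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("richness_panel", "data.frame")

  list(panel = panel,
       true_effects = list(
         mu = config$global_mean_richness,
         site_effects = stats::setNames(sites$site_effect, sites$site_id),
         observer_effects = b,
         residuals = eps,
         sites = sites))
}

#' Simulate a simple site-year covariate table
#'
#' Exposes the two synthetic environmental gradients (plus elevation and a
#' small year-to-year wiggle) as a covariate table keyed on (site_id,
#' year). Convenient for community-mode simulation and fast model tests;
#' for the full bioclim feature set use [simulate_monthly_weather()] and
#' [build_covariates()].
#'
#' @param config A [sim_config()].
#' @param sites Optional site frame from a previous
#'   [simulate_richness_panel()] call (element `true_effects$sites`), so
#'   covariates align with an existing panel. When `NULL` a fresh site
#'   frame is drawn from `config$seed`.
#' @return data.frame with columns site_id, year, env1, env2, elevation.
#' @export
simulate_covariates <- function(config, sites = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sites)) {
    set.seed(config$seed)
    sites <- site_frame(config)
  }
  set.seed(config$seed + 1L)
  ny <- length(config$years)
  n <- nrow(sites)
  data.frame(
    site_id = rep(sites$site_id, each = ny),
    year = rep(config$years, n),
    env1 = rep(sites$g1, each = ny) + stats::rnorm(n * ny, 0, 0.02),
    env2 = rep(sites$g2, each = ny) + stats::rnorm(n * ny, 0, 0.02),
    elevation = rep(sites$elevation, each = ny),
    stringsAsFactors = FALSE
  )
}

#' Simulate a site-year-species community panel
#'
#' Species-level detections are Bernoulli with occupancy logit
#' \eqn{\alpha_i + \beta_i' x_{s,t} + \lambda_i' u_s}, where \eqn{x} are
#' the standardized numeric covariates, \eqn{u_s} are site-level latent
#' community factors (standard normal, shared by all species), and the
#' detection logit is additionally shifted by the surveying observer's
#' effect scaled by `config$obs_logit_scale`. Richness in the returned
#' panel equals the detection row sum at every site-year exactly.
#'
#' @param config A [sim_config()]; `n_species`, `n_latent`,
#'   `latent_scale` and `obs_logit_scale` control the community layer.
#' @param covariates Site-year covariate table covering every site-year
#'   to simulate (e.g. from [simulate_covariates()]).
#' @param alpha Optional vector of species occupancy intercepts (logit
#'   scale, length `n_species`), overriding the default draw centered on
#'   the richness target.
#' @return list with `community` (data.frame site_id, year, species_id,
#'   detected, observer_id; class \code{community_panel}), `panel` (the
#'   paired integer-richness \code{richness_panel}), and `truth` (alpha,
#'   beta, loadings, site factors, observer effects, and the marginal
#'   probability matrix `prob`).
#' @export
simulate_community_panel <- function(config, covariates, alpha = NULL) {
  stopifnot(inherits(config, "sim_config"))
  need <- c("site_id", "year")
  if (!all(need %in% names(covariates)))
    stop("`covariates` must have site_id and year columns", call. = FALSE)
  set.seed(config$seed)
  site_ids <- unique(covariates$site_id)
  ns <- length(site_ids)
  nsp <- config$n_species
  k <- config$n_latent

  # expected per-species occupancy tuned so mean richness is near target
  if (is.null(alpha)) {
    pbar <- min(0.95, max(0.05, config$global_mean_richness / nsp))
    alpha <- stats::rnorm(nsp, stats::qlogis(pbar), 1)
  } else stopifnot(length(alpha) == nsp)
  xcols <- setdiff(names(covariates)[vapply(covariates, is.numeric, TRUE)],
                   "year")
  x <- scale(as.matrix(covariates[, xcols, drop = FALSE]))
  x[is.nan(x)] <- 0
  beta <- matrix(stats::rnorm(nsp * ncol(x),
                              0, config$env_effect_scale / sqrt(ncol(x))),
                 nsp, ncol(x))
  loadings <- if (k > 0)
    matrix(stats::rnorm(nsp * k, 0, config$latent_scale), nsp, k)
  else matrix(0, nsp, 0)
  u <- matrix(stats::rnorm(ns * max(k, 1)), ns, max(k, 1))[, seq_len(k),
                                                           drop = FALSE]
  rownames(u) <- site_ids

  # observer schedule aligned per site-year (same mechanism as richness mode)
  yr_by_site <- split(covariates$year, covariates$site_id)
  obs_id <- character(nrow(covariates))
  idx <- split(seq_len(nrow(covariates)), covariates$site_id)
  for (s in site_ids) {
    yrs <- sort(unique(yr_by_site[[s]]))
    sched <- stats::setNames(
      observer_schedule(s, length(yrs), config$mean_stint_years), yrs)
    obs_id[idx[[s]]] <- sched[as.character(covariates$year[idx[[s]]])]
  }
  obs_levels <- unique(obs_id)
  b <- stats::setNames(stats::rnorm(length(obs_levels), 0, config$sigma_obs),
                       obs_levels)

  eta <- matrix(alpha, nrow(covariates), nsp, byrow = TRUE) +
    x %*% t(beta)
  if (k > 0)
    eta <- eta + u[covariates$site_id, , drop = FALSE] %*% t(loadings)
  eta <- eta + config$obs_logit_scale * unname(b[obs_id])
  prob <- stats::plogis(eta)
  det <- matrix(stats::rbinom(length(prob), 1L, prob), nrow(prob), ncol(prob))

  species <- sprintf("sp_%03d", seq_len(nsp))
  community <- data.frame(
    site_id = rep(covariates$site_id, times = nsp),
    year = rep(covariates$year, times = nsp),
    species_id = rep(species, each = nrow(covariates)),
    detected = as.integer(det),
    observer_id = rep(obs_id, times = nsp),
    stringsAsFactors = FALSE
  )
  class(community) <- c("community_panel", "data.frame")

  panel <- data.frame(
    site_id = covariates$site_id,
    year = covariates$year,
    observer_id = obs_id,
    richness = as.integer(rowSums(det)),
    stringsAsFactors = FALSE
  )
  class(panel) <- c("richness_panel", "data.frame")

  list(community = community, panel = panel,
       truth = list(alpha = alpha, beta = beta, loadings = loadings,
                    site_factors = u, observer_effects = b, prob = prob))
}

#' Simulate monthly site weather (and NDVI) series
#'
#' Each site gets a seasonal sinusoid for temperature (colder at high
#' `g2`, i.e. high elevation), a wet-season sinusoid for precipitation,
#' and Gaussian noise. `tmax >= tmin` and `prec >= 0` are enforced. A
#' monthly NDVI column tracking the growing season is included for
#' [seasonal_ndvi()]. Months cover January of the year before
#' `config$years` starts (so the July-June window of the first survey
#' year is complete) through December of the final year.
#'
#' @param config A [sim_config()].
#' @param sites Optional site frame (see [simulate_covariates()]).
#' @param amplitude Seasonal temperature amplitude, deg C.
#' @param noise_sd Weather noise SD (deg C for temperatures; mm for
#'   precipitation it is scaled by 10).
#' @return data.frame site_id, year, month, tmax, tmin, prec, ndvi
#'   (class \code{monthly_weather}).
#' @export
simulate_monthly_weather <- function(config, sites = NULL,
                                     amplitude = 12, noise_sd = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(sites)) {
    set.seed(config$seed)
    sites <- site_frame(config)
  }
  set.seed(config$seed + 2L)
  years <- (min(config$years) - 1L):max(config$years)
  grid <- expand.grid(month = 1:12, year = years,
                      site_id = sites$site_id, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  g1 <- stats::setNames(sites$g1, sites$site_id)[grid$site_id]
  g2 <- stats::setNames(sites$g2, sites$site_id)[grid$site_id]
  base_t <- 25 - 18 * g2          # warm lowlands, cool highlands
  season <- cos(2 * pi * (grid$month - 7) / 12)
  n <- nrow(grid)
  tmax <- base_t + amplitude * season + stats::rnorm(n, 0, noise_sd)
  drange <- 8 + 4 * g1            # diurnal range widens along gradient 1
  tmin <- tmax - pmax(0.5, drange + stats::rnorm(n, 0, noise_sd))
  prec <- pmax(0, 60 + 80 * g1 +
                 40 * sin(2 * pi * (grid$month - 4) / 12) +
                 stats::rnorm(n, 0, 10 * noise_sd))
  ndvi <- pmax(0, pmin(1, 0.25 + 0.35 * (0.5 + 0.5 * season) *
                         (0.5 + g1 / 2) + stats::rnorm(n, 0, 0.02 * noise_sd)))
  out <- data.frame(site_id = grid$site_id, year = grid$year,
                    month = grid$month, tmax = tmax, tmin = tmin,
                    prec = prec, ndvi = ndvi, stringsAsFactors = FALSE)
  class(out) <- c("monthly_weather", "data.frame")
  out
}
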