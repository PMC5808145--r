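# Environmental forecasters trained across sites with no site identity:
# a boosted-tree richness model, stacked per-species random forests, and
# a latent-factor logistic JSDM. All are pure functions of covariates
# (plus, in corrected mode, observer-effect estimates): identical
# covariate rows always receive identical predictions.

covariate_matrix <- function(covariates, cols = NULL) {
  drop <- c("site_id", "year", "observer_id", "richness")
  if (is.null(cols))
    cols <- setdiff(names(covariates)[vapply(covariates, is.numeric, TRUE)],
                    drop)
  as.matrix(covariates[, cols, drop = FALSE])
}

#' Boosted regression trees for richness ("macroecological" model)
#'
#' Gradient-boosted trees with squared-error loss, interaction depth 5,
#' shrinkage 0.015 and up to `max_trees` trees, fit to richness as a
#' function of environmental covariates only. The tree count is selected
#' by 5-fold cross-validation at the same settings; the predictive SD is
#' homoscedastic, the SD of training residuals at the selected size.
#'
#' @param covariates Training covariate table (site_id/year columns are
#'   ignored as predictors).
#' @param richness Training richness vector aligned with `covariates`.
#' @param max_depth,shrinkage,max_trees Boosting hyperparameters.
#' @param subsample Row subsampling rate per tree.
#' @param seed Integer seed.
#' @return Object of class \code{richness_gbm}: list(booster, n_trees,
#'   sigma, feature_names, constant).
#' @export
fit_richness_gbm <- function(covariates, richness, max_depth = 5,
                             shrinkage = 0.015, max_trees = 10000,
                             subsample = 0.5, seed = 1L) {
  x <- covariate_matrix(covariates)
  if (ncol(x) < 1) stop("need >= 1 covariate column", call. = FALSE)
  if (stats::sd(richness) == 0) {
    warning("constant response: returning a constant predictor",
            call. = FALSE)
    return(structure(list(booster = NULL, n_trees = 0L, sigma = 0,
                          feature_names = colnames(x),
                          constant = richness[1]),
                     class = "richness_gbm"))
  }
  set.seed(seed)
  params <- list(max_depth = max_depth, eta = shrinkage,
                 subsample = subsample, objective = "reg:squarederror",
                 nthread = 1)
  cv <- xgboost::xgb.cv(params = params,
                        data = xgboost::xgb.DMatrix(x, label = richness),
                        nrounds = max_trees, nfold = 5,
                        early_stopping_rounds = 50, verbose = 0)
  n_trees <- cv$early_stop$best_iteration
  if (is.null(n_trees)) n_trees <- which.min(cv$evaluation_log$test_rmse_mean)
  set.seed(seed)
  booster <- xgboost::xgb.train(params = params,
                                data = xgboost::xgb.DMatrix(x, label = richness),
                                nrounds = n_trees, verbose = 0)
  resid <- richness - stats::predict(booster, xgboost::xgb.DMatrix(x))
  structure(list(booster = booster, n_trees = as.integer(n_trees),
                 sigma = stats::sd(resid), feature_names = colnames(x),
                 constant = NULL),
            class = "richness_gbm")
}

#' @rdname fit_richness_gbm
#' @param fit A \code{richness_gbm}.
#' @param model,corrected Forecast labelling.
#' @param last_year Final training year, used to compute horizons.
#' @export
predict_richness_gbm <- function(fit, covariates, last_year = NULL,
                                 model = "gbm", corrected = FALSE) {
  if (is.null(last_year)) last_year <- min(covariates$year) - 1L
  mu <- if (is.null(fit$booster)) rep(fit$constant, nrow(covariates))
  else stats::predict(fit$booster, xgboost::xgb.DMatrix(
    covariate_matrix(covariates, fit$feature_names)))
  new_gaussian_forecast(covariates$site_id, covariates$year,
                        pmax(1L, covariates$year - last_year), mu,
                        rep(fit$sigma, nrow(covariates)), model, corrected)
}

# ---- stacked per-species random forests ------------------------------

#' Stacked species distribution models (per-species random forests)
#'
#' Fits one classification random forest per species on the covariates;
#' occupancy probability is the fraction of trees voting presence.
#' In corrected mode each tree is fit with a different Monte Carlo
#' draw of the observer effects as an extra predictor (one single-tree
#' forest per draw, cycled over `observer_draws` columns). Species with
#' a single observed class get a constant probability and are flagged in
#' `constant_species`.
#'
#' @param community Long community panel (site_id, year, species_id,
#'   detected).
#' @param covariates Covariate table covering every training site-year.
#' @param observer_draws Optional matrix of observer-effect values
#'   (rows = site-years in `covariates` order, columns = posterior
#'   draws); supplying it switches on corrected mode.
#' @param n_trees Trees per species (default 500).
#' @param min_node_size Minimum terminal node size (default 5).
#' @param seed Integer seed.
#' @return Object of class \code{stacked_sdm}: list(forests,
#'   constant_species, species, feature_names, corrected).
#' @export
fit_stacked_sdm <- function(community, covariates, observer_draws = NULL,
                            n_trees = 500, min_node_size = 5, seed = 1L) {
  key_c <- paste(covariates$site_id, covariates$year)
  key_m <- paste(community$site_id, community$year)
  if (!all(key_m %in% key_c))
    stop("community site-years missing from covariates: ",
         paste(utils::head(setdiff(key_m, key_c), 3), collapse = ", "),
         call. = FALSE)
  x <- covariate_matrix(covariates)
  corrected <- !is.null(observer_draws)
  if (corrected) {
    observer_draws <- as.matrix(observer_draws)
    stopifnot(nrow(observer_draws) == nrow(covariates))
  }
  species <- sort(unique(community$species_id))
  set.seed(seed)
  forests <- vector("list", length(species))
  names(forests) <- species
  constant_species <- stats::setNames(rep(NA_real_, length(species)), species)
  row_of <- match(key_m, key_c)
  for (i in seq_along(species)) {
    sp <- species[i]
    sel <- community$species_id == sp
    y <- community$detected[sel]
    rows <- row_of[sel]
    if (length(unique(y)) < 2) {
      constant_species[sp] <- mean(y)
      next
    }
    df <- as.data.frame(x[rows, , drop = FALSE])
    df$.y <- factor(y, levels = c(0, 1))
    if (!corrected) {
      forests[[sp]] <- ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = n_trees, min.node.size = min_node_size,
        seed = seed + i, num.threads = 1)
    } else {
      # tree t sees observer-effect draw t as a predictor
      dcols <- rep_len(seq_len(ncol(observer_draws)), n_trees)
      forests[[sp]] <- lapply(seq_len(n_trees), function(t) {
        dft <- df
        dft$obs_effect <- observer_draws[rows, dcols[t]]
        ranger::ranger(dependent.variable.name = ".y", data = dft,
                       num.trees = 1, min.node.size = min_node_size,
                       seed = seed + i * 1000L + t, num.threads = 1)
      })
    }
  }
  structure(list(forests = forests,
                 constant_species = constant_species[!is.na(constant_species)],
                 species = species, feature_names = colnames(x),
                 corrected = corrected, n_trees = n_trees),
            class = "stacked_sdm")
}

#' Per-species occupancy probabilities from a stacked SDM
#'
#' @param fit A \code{stacked_sdm}.
#' @param covariates Covariate rows to predict.
#' @param obs_effect Observer-effect value(s) used for prediction in
#'   corrected mode (default 0: the typical-observer convention for
#'   future or unseen observers).
#' @return Matrix (rows = covariate rows, cols = species) of
#'   probabilities in [0, 1]: the fraction of trees voting presence.
#' @export
predict_species_probs <- function(fit, covariates, obs_effect = 0) {
  x <- covariate_matrix(covariates, fit$feature_names)
  df <- as.data.frame(x)
  p <- matrix(0, nrow(df), length(fit$species),
              dimnames = list(NULL, fit$species))
  for (sp in fit$species) {
    if (sp %in% names(fit$constant_species)) {
      p[, sp] <- fit$constant_species[sp]
    } else if (!fit$corrected) {
      pr <- stats::predict(fit$forests[[sp]], data = df,
                           predict.all = TRUE, num.threads = 1)
      votes <- pr$predictions - 1       # factor levels 1/2 -> 0/1
      p[, sp] <- rowMeans(votes)
    } else {
      dft <- df
      dft$obs_effect <- rep_len(obs_effect, nrow(df))
      votes <- vapply(fit$forests[[sp]], function(tr)
        as.numeric(stats::predict(tr, data = dft,
                                  num.threads = 1)$predictions) - 1,
        numeric(nrow(dft)))
      p[, sp] <- rowMeans(matrix(votes, nrow = nrow(dft)))
    }
  }
  p
}

#' Richness forecast from stacked species probabilities
#'
#' Treats richness as a sum of independent Bernoulli variables: the
#' point estimate is \eqn{\sum_i p_i} and the variance is
#' \eqn{\sigma^2_{richness} = \sum_i p_i (1 - p_i)}.
#'
#' @param fit A \code{stacked_sdm}, or a probability matrix as returned
#'   by [predict_species_probs()].
#' @param covariates Covariate rows (with site_id, year) to predict.
#' @param last_year Final training year for horizon labelling.
#' @param obs_effect Observer effect used at prediction (corrected mode).
#' @param model,corrected Forecast labelling.
#' @return A \code{gaussian_forecast}.
#' @export
#' @examples
#' p <- matrix(c(1, 0, 0.5), 1)
#' sum(p * (1 - p))  # the variance the forecast reports
predict_stacked_richness <- function(fit, covariates, last_year = NULL,
                                     obs_effect = 0, model = "stacked_sdm",
                                     corrected = FALSE) {
  p <- if (is.matrix(fit)) fit
  else predict_species_probs(fit, covariates, obs_effect)
  stopifnot(all(p >= 0 & p <= 1))
  if (is.null(last_year)) last_year <- min(covariates$year) - 1L
  new_gaussian_forecast(covariates$site_id, covariates$year,
                        pmax(1L, covariates$year - last_year),
                        rowSums(p), sqrt(rowSums(p * (1 - p))),
                        model, corrected)
}

# ---- latent-factor JSDM ---------------------------------------------

#' Latent-factor joint species distribution model
#'
#' Logistic occupancy model with species-specific covariate coefficients
#' and `n_latent` shared site-level latent factors:
#' \eqn{logit\, p_{i,s,t} = \alpha_i + \beta_i' x_{s,t} + \lambda_i' u_s},
#' \eqn{u_s \sim N(0, I)}. Shared factors induce inter-species
#' dependence and hence over-dispersed richness relative to the
#' independent-Bernoulli sum. Fit by Monte-Carlo EM: latent factors are
#' sampled from their N(0, I) prior and importance-weighted by each
#' site's likelihood (E-step); species-wise weighted logistic
#' regressions update the coefficients and loadings (M-step). With
#' `n_latent = 0` the fit reduces to independent per-species logistic
#' regressions. In corrected mode `observer_effect` enters as an extra
#' predictor column.
#'
#' @param community Long community panel.
#' @param covariates Covariate table covering the community site-years.
#' @param n_latent Number of latent factors (>= 0; default 2).
#' @param observer_effect Optional per-site-year observer-effect vector
#'   (aligned with `covariates` rows) used as a predictor.
#' @param n_particles Importance-sample size per site (E-step).
#' @param max_iter Maximum EM iterations.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param seed Integer seed.
#' @return Object of class \code{jsdm_fit}: list(alpha, beta, loadings,
#'   n_latent, feature_names, site_scores, converged, loglik).
#' @export
fit_jsdm <- function(community, covariates, n_latent = 2,
                     observer_effect = NULL, n_particles = 100,
                     max_iter = 15, tol = 1e-4, seed = 1L) {
  stopifnot(n_latent >= 0)
  x <- covariate_matrix(covariates)
  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  if (!is.null(observer_effect))
    xs <- cbind(xs, obs_effect = rep_len(observer_effect, nrow(xs)))
  key_c <- paste(covariates$site_id, covariates$year)
  key_m <- paste(community$site_id, community$year)
  if (!all(key_m %in% key_c))
    stop("community site-years missing from covariates", call. = FALSE)
  species <- sort(unique(community$species_id))
  # detection matrix, rows aligned with covariates
  y <- matrix(NA_real_, nrow(covariates), length(species),
              dimnames = list(NULL, species))
  y[cbind(match(key_m, key_c), match(community$species_id, species))] <-
    community$detected
  if (anyNA(y))
    stop("community panel must cover every species at every site-year",
         call. = FALSE)

  set.seed(seed)
  nsp <- length(species); k <- n_latent
  site <- factor(covariates$site_id)
  s_idx <- as.integer(site); S <- nlevels(site)

  # init: independent logistic fits, small random loadings
  alpha <- numeric(nsp)
  beta <- matrix(0, nsp, ncol(xs), dimnames = list(species, colnames(xs)))
  for (i in seq_len(nsp)) {
    g <- suppressWarnings(stats::glm.fit(cbind(1, xs), y[, i],
                                         family = stats::binomial()))
    cf <- g$coefficients; cf[!is.finite(cf)] <- 0
    alpha[i] <- cf[1]; beta[i, ] <- cf[-1]
  }
  if (k == 0)
    return(structure(list(alpha = stats::setNames(alpha, species),
                          beta = beta, loadings = matrix(0, nsp, 0),
                          n_latent = 0L, feature_names = colnames(xs),
                          center = ctr, scale = scl,
                          site_scores = matrix(0, S, 0,
                                               dimnames = list(levels(site), NULL)),
                          converged = TRUE, loglik = NA_real_,
                          species = species),
                     class = "jsdm_fit"))

  lambda <- matrix(stats::rnorm(nsp * k, 0, 0.1), nsp, k)
  u_part <- matrix(stats::rnorm(n_particles * k), n_particles, k)
  ll_old <- -Inf; converged <- FALSE
  w_site <- matrix(1 / n_particles, S, n_particles)
  for (iter in seq_len(max_iter)) {
    # E-step: importance weights per site over shared particles
    eta_fix <- matrix(alpha, nrow(xs), nsp, byrow = TRUE) + xs %*% t(beta)
    ll_part <- matrix(0, S, n_particles)
    for (m in seq_len(n_particles)) {
      eta <- eta_fix + matrix(u_part[m, ] %*% t(lambda),
                              nrow(xs), nsp, byrow = TRUE)
      lp <- stats::dbinom(y, 1, stats::plogis(eta), log = TRUE)
      ll_part[, m] <- as.vector(rowsum(rowSums(lp), s_idx, reorder = TRUE))
    }
    mx <- apply(ll_part, 1, max)
    w_site <- exp(ll_part - mx)
    w_site <- w_site / rowSums(w_site)
    ll <- sum(mx + log(rowMeans(exp(ll_part - mx))))

    # M-step: weighted logistic regression per species on expanded data
    w_rows <- w_site[s_idx, , drop = FALSE]            # n x M
    keep <- which(w_rows > 1e-8, arr.ind = TRUE)
    Xbig <- cbind(1, xs[keep[, 1], , drop = FALSE],
                  u_part[keep[, 2], , drop = FALSE])
    wbig <- w_rows[keep]
    for (i in seq_len(nsp)) {
      g <- suppressWarnings(stats::glm.fit(Xbig, y[keep[, 1], i],
                                           weights = wbig,
                                           family = stats::binomial()))
      cf <- g$coefficients; cf[!is.finite(cf)] <- 0
      alpha[i] <- cf[1]
      beta[i, ] <- cf[2:(1 + ncol(xs))]
      lambda[i, ] <- cf[(2 + ncol(xs)):(1 + ncol(xs) + k)]
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll_old)) {
      converged <- TRUE; ll_old <- ll; break
    }
    ll_old <- ll
  }
  if (!converged)
    warning("Monte-Carlo EM did not converge in ", max_iter,
            " iterations; returning last iterate", call. = FALSE)
  site_scores <- w_site %*% u_part
  rownames(site_scores) <- levels(site)
  structure(list(alpha = stats::setNames(alpha, species), beta = beta,
                 loadings = lambda, n_latent = as.integer(k),
                 feature_names = colnames(xs), center = ctr, scale = scl,
                 site_scores = site_scores, converged = converged,
                 loglik = ll_old, species = species),
            class = "jsdm_fit")
}

#' Richness forecast from a latent-factor JSDM
#'
#' Samples latent factors from their N(0, I) prior, draws per-species
#' Bernoulli occupancies for each sample, and reports the sample mean
#' and SD of the summed richness as a Gaussian forecast. With zero
#' loadings this reproduces the independent-Bernoulli mean
#' \eqn{\sum p_i} and variance \eqn{\sum p_i(1-p_i)} up to Monte-Carlo
#' error; shared factors widen the predictive distribution.
#'
#' @param fit A \code{jsdm_fit}.
#' @param covariates Covariate rows to predict (site_id, year needed).
#' @param n_samples Monte-Carlo community samples (>= 100).
#' @param observer_effect Observer-effect predictor value (default 0).
#' @param last_year Final training year for horizon labelling.
#' @param model,corrected Forecast labelling.
#' @param seed Integer seed.
#' @return A \code{gaussian_forecast}.
#' @export
predict_jsdm_richness <- function(fit, covariates, n_samples = 1000,
                                  observer_effect = 0, last_year = NULL,
                                  model = "jsdm", corrected = FALSE,
                                  seed = 1L) {
  stopifnot(inherits(fit, "jsdm_fit"), n_samples >= 100)
  x <- covariate_matrix(covariates,
                        setdiff(fit$feature_names, "obs_effect"))
  xs <- sweep(sweep(x, 2, fit$center), 2, fit$scale, "/")
  if ("obs_effect" %in% fit$feature_names)
    xs <- cbind(xs, obs_effect = rep_len(observer_effect, nrow(xs)))
  eta_fix <- matrix(fit$alpha, nrow(xs), length(fit$alpha), byrow = TRUE) +
    xs %*% t(fit$beta)
  k <- fit$n_latent
  set.seed(seed)
  n <- nrow(xs)
  rich <- matrix(0, n, n_samples)
  for (m in seq_len(n_samples)) {
    eta <- eta_fix
    if (k > 0) {
      u <- stats::rnorm(k)
      eta <- eta + matrix(u %*% t(fit$loadings), n, length(fit$alpha),
                          byrow = TRUE)
    }
    p <- stats::plogis(eta)
    rich[, m] <- rowSums(matrix(stats::rbinom(length(p), 1, p), n))
  }
  if (is.null(last_year)) last_year <- min(covariates$year) - 1L
  new_gaussian_forecast(covariates$site_id, covariates$year,
                        pmax(1L, covariates$year - last_year),
                        rowMeans(rich), apply(rich, 1, stats::sd),
                        model, corrected)
}
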