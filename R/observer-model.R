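# Hierarchical site + observer model for survey richness:
#
#   y_i = mu + a_{s(i)} + b_{o(i)} + eps_i,   eps_i ~ N(0, sigma_resid^2)
#   a_s ~ N(0, sigma_site^2),  b_o ~ N(0, sigma_obs^2)
#
# fit by a blocked Gibbs sampler in the centered parameterization:
# conjugate normal updates for mu, a and b; slice-sampled updates for
# sigma_site and sigma_obs under half-Normal(0, 25^2) priors; a
# conjugate inverse-gamma(0.01, 0.01) update for the residual variance.
# Two location-interweaving moves per sweep (shifting mass between mu
# and the mean of a, resp. b, along the flat likelihood direction)
# remove the grand-mean/effect-mean ridge that otherwise slows mixing.

# univariate slice sampler (stepping out + shrinkage), Neal (2003)
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50) {
  y <- logf(x0) - stats::rexp(1)
  lo <- x0 - stats::runif(1) * w
  hi <- lo + w
  k <- max_steps
  while (k > 0 && logf(lo) > y) { lo <- lo - w; k <- k - 1 }
  k <- max_steps
  while (k > 0 && logf(hi) > y) { hi <- hi + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# sigma | effects under a half-Normal(0, c^2) prior:
#   p(sigma) propto sigma^-S exp(-ss / (2 sigma^2)) exp(-sigma^2 / (2 c^2))
draw_scale <- function(sigma0, ss, S, c2) {
  logf <- function(s)
    if (s <= 0) -Inf else -S * log(s) - ss / (2 * s^2) - s^2 / (2 * c2)
  slice_sample1(sigma0, logf, w = max(sigma0 / 4, 0.05))
}

#' Fit the hierarchical observer model by Gibbs sampling
#'
#' Partitions richness variation into site, observer and residual
#' components and returns posterior draws of the global mean, every site
#' and observer effect, and the three standard deviations. Site-level
#' random effects ensure that inferred observer deviations are not just
#' relabelled site differences; that identification requires observer
#' turnover within sites (a design where each site has exactly one
#' observer and vice versa is flagged as confounded, and the fit is
#' still returned).
#'
#' @param train A richness panel (site_id, year, observer_id, richness).
#' @param n_draws Number of retained posterior draws (default 500).
#' @param seed Integer seed for the sampler.
#' @param warmup Burn-in iterations discarded before retention.
#' @param prior_sd Scale of the half-Normal priors on `sigma_site` and
#'   `sigma_obs` (species units).
#' @return An object of class \code{observer_posterior}: list with
#'   \code{mu} (vector, n_draws), \code{site_effects} and
#'   \code{observer_effects} (n_draws x levels matrices),
#'   \code{sigma_site}, \code{sigma_obs}, \code{sigma_resid} (vectors),
#'   and \code{rhat} (split-chain scale reduction for the three SDs).
#' @export
#' @examples
#' sim <- simulate_richness_panel(sim_config(n_sites = 20, seed = 7))
#' post <- fit_observer_model(sim$panel, n_draws = 50, warmup = 50)
#' variance_partition(post)
fit_observer_model <- function(train, n_draws = 500, seed = 1L,
                               warmup = 500, prior_sd = 25) {
  stopifnot(is.data.frame(train), n_draws >= 1, warmup >= 0)
  need <- c("site_id", "observer_id", "richness")
  if (!all(need %in% names(train)))
    stop("panel must have site_id, observer_id, richness", call. = FALSE)
  if (length(unique(train$site_id)) < 2)
    stop("need >= 2 sites to separate site and observer variance",
         call. = FALSE)

  xt <- table(train$site_id, train$observer_id)
  if (all(rowSums(xt > 0) == 1) && all(colSums(xt > 0) == 1))
    warning("every site has a single dedicated observer: site and ",
            "observer effects are confounded; interpret the partition ",
            "with caution", call. = FALSE)

  y <- train$richness
  site <- factor(train$site_id)
  obs <- factor(train$observer_id)
  s_idx <- as.integer(site)
  o_idx <- as.integer(obs)
  S <- nlevels(site); O <- nlevels(obs); n <- length(y)
  n_s <- tabulate(s_idx, S); n_o <- tabulate(o_idx, O)

  set.seed(seed)
  mu <- mean(y)
  a <- stats::rnorm(S, 0, 1); b <- stats::rnorm(O, 0, 1)
  sig_a <- max(stats::sd(y) / 2, 0.5)
  sig_b <- max(stats::sd(y) / 4, 0.5)
  sig2 <- stats::var(y) / 4
  a0 <- b0 <- 0.01                      # IG prior on residual variance
  c2 <- prior_sd^2

  total <- warmup + n_draws
  out_mu <- numeric(n_draws)
  out_ss <- numeric(n_draws); out_so <- numeric(n_draws)
  out_sr <- numeric(n_draws)
  out_a <- matrix(0, n_draws, S, dimnames = list(NULL, levels(site)))
  out_b <- matrix(0, n_draws, O, dimnames = list(NULL, levels(obs)))

  for (it in seq_len(total)) {
    # site effects a_s | .
    r <- y - mu - b[o_idx]
    prec <- n_s / sig2 + 1 / sig_a^2
    m <- as.vector(rowsum(r, s_idx, reorder = TRUE)) / sig2 / prec
    a <- stats::rnorm(S, m, sqrt(1 / prec))

    # observer effects b_o | .
    r <- y - mu - a[s_idx]
    prec <- n_o / sig2 + 1 / sig_b^2
    m <- as.vector(rowsum(r, o_idx, reorder = TRUE)) / sig2 / prec
    b <- stats::rnorm(O, m, sqrt(1 / prec))

    # grand mean mu | . (flat prior)
    r <- y - a[s_idx] - b[o_idx]
    mu <- stats::rnorm(1, mean(r), sqrt(sig2 / n))

    # interweave: shift mass between mu and mean(a), then mean(b);
    # the likelihood is flat along these directions, the priors are not
    delta <- stats::rnorm(1, -mean(a), sig_a / sqrt(S))
    a <- a + delta; mu <- mu - delta
    delta <- stats::rnorm(1, -mean(b), sig_b / sqrt(O))
    b <- b + delta; mu <- mu - delta

    # scales | effects, half-Normal(0, prior_sd^2) priors
    sig_a <- draw_scale(sig_a, sum(a^2), S, c2)
    sig_b <- draw_scale(sig_b, sum(b^2), O, c2)

    # residual variance | .
    r <- y - mu - a[s_idx] - b[o_idx]
    sig2 <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(r^2) / 2)

    if (it > warmup) {
      d <- it - warmup
      out_mu[d] <- mu
      out_ss[d] <- sig_a
      out_so[d] <- sig_b
      out_sr[d] <- sqrt(sig2)
      out_a[d, ] <- a
      out_b[d, ] <- b
    }
  }

  rhat <- c(sigma_site = split_rhat(out_ss),
            sigma_obs = split_rhat(out_so),
            sigma_resid = split_rhat(out_sr))

  structure(list(mu = out_mu, site_effects = out_a, observer_effects = out_b,
                 sigma_site = out_ss, sigma_obs = out_so,
                 sigma_resid = out_sr, rhat = rhat,
                 n_draws = n_draws, warmup = warmup, seed = seed),
            class = "observer_posterior")
}

# split-chain potential scale reduction from a single chain cut in half
split_rhat <- function(x) {
  n <- length(x) %/% 2
  if (n < 2) return(NA_real_)
  halves <- list(x[seq_len(n)], x[(length(x) - n + 1):length(x)])
  m <- vapply(halves, mean, 0); v <- vapply(halves, stats::var, 0)
  w <- mean(v)
  b <- n * stats::var(m)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' @export
print.observer_posterior <- function(x, ...) {
  cat("<observer_posterior>\n")
  cat(sprintf("  %d draws (%d warmup), %d sites, %d observers\n",
              x$n_draws, x$warmup, ncol(x$site_effects),
              ncol(x$observer_effects)))
  cat(sprintf("  posterior mean SDs: site %.2f, observer %.2f, residual %.2f\n",
              mean(x$sigma_site), mean(x$sigma_obs), mean(x$sigma_resid)))
  cat(sprintf("  split-Rhat: %s\n",
              paste(names(x$rhat), round(x$rhat, 3), collapse = ", ")))
  invisible(x)
}

#' Posterior variance partition of observed richness
#'
#' For each posterior draw the three variance fractions
#' \eqn{\sigma_k^2 / (\sigma_{site}^2 + \sigma_{obs}^2 +
#' \sigma_{resid}^2)} are computed, then averaged over draws; they sum to
#' one by construction. `sd_resid` is the posterior mean residual SD.
#'
#' @param post An \code{observer_posterior}.
#' @return Object of class \code{variance_partition}: list(frac_site,
#'   frac_obs, frac_resid, sd_resid).
#' @export
variance_partition <- function(post) {
  stopifnot(inherits(post, "observer_posterior"))
  tot <- post$sigma_site^2 + post$sigma_obs^2 + post$sigma_resid^2
  out <- list(frac_site = mean(post$sigma_site^2 / tot),
              frac_obs = mean(post$sigma_obs^2 / tot),
              frac_resid = mean(post$sigma_resid^2 / tot),
              sd_resid = mean(post$sigma_resid))
  class(out) <- "variance_partition"
  out
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf(
    "Variance partition: site %.1f%%, observer %.1f%%, residual %.1f%% (residual SD %.2f species)\n",
    100 * x$frac_site, 100 * x$frac_obs, 100 * x$frac_resid, x$sd_resid))
  invisible(x)
}

#' Observer-corrected richness under each posterior draw
#'
#' For draw \eqn{d} the corrected value is \eqn{y - b_{o}^{(d)}}: the
#' richness a typical (zero-effect) observer would have recorded.
#' Observers absent from the posterior (e.g. test-period newcomers) get
#' effect 0 and are listed in the `unseen_observers` attribute.
#'
#' @param panel A richness panel.
#' @param post An \code{observer_posterior}.
#' @param draws Indices of draws to use (default all).
#' @return Object of class \code{corrected_draws}: list with `panel`
#'   (the input keys) and `corrected`, an nrow(panel) x length(draws)
#'   matrix of corrected richness.
#' @export
corrected_richness_draws <- function(panel, post, draws = NULL) {
  stopifnot(inherits(post, "observer_posterior"))
  if (is.null(draws)) draws <- seq_len(post$n_draws)
  known <- colnames(post$observer_effects)
  unseen <- setdiff(unique(panel$observer_id), known)
  b <- t(post$observer_effects[draws, , drop = FALSE])   # obs x draws
  idx <- match(panel$observer_id, known)
  eff <- matrix(0, nrow(panel), length(draws))
  seen <- !is.na(idx)
  eff[seen, ] <- b[idx[seen], , drop = FALSE]
  out <- list(panel = panel[, c("site_id", "year", "observer_id")],
              corrected = panel$richness - eff, draws = draws)
  attr(out, "unseen_observers") <- unseen
  if (length(unseen) > 0)
    message(length(unseen),
            " observer(s) not in the posterior; effect 0 used")
  class(out) <- "corrected_draws"
  out
}
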