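# Single-site forecasters: the "average" and "naive" baselines and an
# AICc-selected ARIMA. All emit Gaussian predictive distributions as
# gaussian_forecast data.frames (site_id, year, horizon, mean, sd,
# model, corrected).

#' Construct a Gaussian forecast table
#'
#' The common container for all forecasters: one row per predicted
#' site-year carrying the Gaussian predictive mean and SD, the forecast
#' horizon, a model tag, and the observer-correction flag.
#'
#' @param site_id,year,horizon,mean,sd,model,corrected Column values
#'   (recycled per data.frame rules); `sd >= 0` and `horizon >= 1` are
#'   enforced.
#' @return A \code{gaussian_forecast} data.frame.
#' @export
new_gaussian_forecast <- function(site_id, year, horizon, mean, sd,
                                  model, corrected = FALSE) {
  stopifnot(all(sd >= 0), all(horizon >= 1))
  out <- data.frame(site_id = site_id, year = as.integer(year),
                    horizon = as.integer(horizon), mean = mean, sd = sd,
                    model = model, corrected = corrected,
                    stringsAsFactors = FALSE)
  class(out) <- c("gaussian_forecast", "data.frame")
  out
}

#' The "average" baseline: constant richness with constant uncertainty
#'
#' Models richness as uncorrelated noise around a site-level constant,
#' \eqn{y_t = \mu + \epsilon_t}. Forecasts are centered on the training
#' mean with a horizon-invariant SD (the training sample SD, or a
#' supplied residual SD such as the observer model's `sigma_resid` in
#' corrected mode).
#'
#' @param series Numeric vector of yearly richness values (>= 2).
#' @param sigma Optional predictive SD overriding the sample SD.
#' @return Object of class \code{average_fit}: list(mu, sigma, n).
#' @export
#' @examples
#' fit_average(c(50, 52, 54))
fit_average <- function(series, sigma = NULL) {
  series <- series[!is.na(series)]
  if (length(series) < 2)
    stop("need >= 2 observations to fit the average model", call. = FALSE)
  s <- if (is.null(sigma)) stats::sd(series) else sigma
  structure(list(mu = mean(series), sigma = s, n = length(series)),
            class = "average_fit")
}

#' @rdname fit_average
#' @param fit An \code{average_fit}.
#' @param horizons Integer horizons (years ahead).
#' @param site_id,last_year,model,corrected Forecast labelling.
#' @export
forecast_average <- function(fit, horizons, site_id = "site",
                             last_year = 0L, model = "average",
                             corrected = FALSE) {
  new_gaussian_forecast(site_id, last_year + horizons, horizons,
                        rep(fit$mu, length(horizons)),
                        rep(fit$sigma, length(horizons)), model, corrected)
}

#' The "naive" baseline: random walk from the last observation
#'
#' An ARIMA(0,1,0) model \eqn{y_t = y_{t-1} + \epsilon_t}: the point
#' forecast at every horizon is the final observed value, and because
#' the step errors accumulate the predictive SD grows as
#' \eqn{\sigma_{step}\sqrt{h}}. `sigma_step` is the sample SD of first
#' differences, taken only across consecutive observed years; gaps in
#' the series are flagged via the `n_gaps` element.
#'
#' @param series Numeric vector of yearly richness (>= 2 values; >= 3
#'   for a nonzero step SD).
#' @param years Optional observation years (default consecutive); used
#'   to restrict differences to adjacent years.
#' @return Object of class \code{naive_fit}: list(last_value,
#'   sigma_step, n_diffs, n_gaps).
#' @export
fit_naive <- function(series, years = seq_along(series)) {
  ok <- !is.na(series)
  series <- series[ok]; years <- years[ok]
  if (length(series) < 2)
    stop("need >= 2 observations to fit the naive model", call. = FALSE)
  o <- order(years); series <- series[o]; years <- years[o]
  adj <- diff(years) == 1
  d <- diff(series)[adj]
  n_gaps <- sum(!adj)
  if (n_gaps > 0)
    warning(n_gaps, " gap(s) in series; differences taken only across ",
            "consecutive years", call. = FALSE)
  sigma_step <- if (length(d) >= 2) stats::sd(d) else 0
  structure(list(last_value = series[length(series)],
                 sigma_step = sigma_step, n_diffs = length(d),
                 n_gaps = n_gaps),
            class = "naive_fit")
}

#' @rdname fit_naive
#' @param fit A \code{naive_fit}.
#' @param horizons Integer horizons.
#' @param site_id,last_year,model,corrected Forecast labelling.
#' @export
forecast_naive <- function(fit, horizons, site_id = "site",
                           last_year = 0L, model = "naive",
                           corrected = FALSE) {
  new_gaussian_forecast(site_id, last_year + horizons, horizons,
                        rep(fit$last_value, length(horizons)),
                        fit$sigma_step * sqrt(horizons), model, corrected)
}

# ---- auto-ARIMA ------------------------------------------------------

# KPSS level-stationarity statistic with a Bartlett-kernel long-run
# variance, truncation l = trunc(4 (n/100)^{1/4}); 5% critical value
# 0.463 (Kwiatkowski et al. 1992, Table 1, eta_mu).
kpss_stat <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  e <- x - mean(x)
  s <- cumsum(e)
  l <- trunc(4 * (n / 100)^0.25)
  lrv <- sum(e^2) / n
  if (l > 0) for (j in seq_len(l)) {
    w <- 1 - j / (l + 1)
    lrv <- lrv + 2 * w * sum(e[1:(n - j)] * e[(j + 1):n]) / n
  }
  sum(s^2) / (n^2 * lrv)
}

# number of differences needed for level stationarity by repeated KPSS
ndiffs_kpss <- function(x, max_d = 2, alpha_crit = 0.463) {
  d <- 0
  while (d < max_d && length(x) > 6 && kpss_stat(x) > alpha_crit) {
    x <- diff(x)
    d <- d + 1
  }
  d
}

fit_arima_candidate <- function(series, p, d, q, constant) {
  n <- length(series)
  out <- tryCatch({
    if (d == 1 && constant) {
      # drift term via a linear trend regressor; do.call embeds the
      # matrix by value so predict() can re-evaluate the stored call
      drift <- matrix(seq_len(n), ncol = 1,
                      dimnames = list(NULL, "drift"))
      m <- do.call(stats::arima,
                   list(series, order = c(p, d, q), xreg = drift,
                        method = "CSS-ML"))
    } else {
      m <- stats::arima(series, order = c(p, d, q),
                        include.mean = constant && d == 0,
                        method = "CSS-ML")
    }
    k <- length(m$coef) + 1          # + innovation variance
    nstar <- n - d
    aicc <- m$aic + 2 * k * (k + 1) / max(nstar - k - 1, 1e-8)
    list(model = m, p = p, d = d, q = q, constant = constant, aicc = aicc)
  }, error = function(e) NULL)
  if (!is.null(out) && !is.finite(out$aicc)) out <- NULL
  out
}

#' Stepwise AICc selection of an ARIMA model
#'
#' Chooses the differencing order by repeated KPSS tests, then runs a
#' Hyndman--Khandakar style stepwise search over (p, q) and the
#' constant/drift term, keeping the candidate with the lowest AICc. No
#' seasonal component is considered. The search is deterministic given
#' the series. Series shorter than `min_obs` fall back to the average
#' model with a warning.
#'
#' @param series Numeric yearly richness values.
#' @param max_p,max_q,max_d Search bounds (defaults 5, 5, 2).
#' @param min_obs Minimum series length for an ARIMA fit (default 10).
#' @return Object of class \code{arima_fit}: list(order = c(p, d, q),
#'   constant, coef, sigma (innovation SD), aicc, model, fallback,
#'   candidates (data.frame of every evaluated (p, d, q, constant,
#'   AICc))). When falling back, `fallback` is the \code{average_fit}.
#' @export
select_arima <- function(series, max_p = 5, max_q = 5, max_d = 2,
                         min_obs = 10) {
  series <- as.numeric(series)
  n <- length(series[!is.na(series)])
  if (n < min_obs) {
    warning("series has ", n, " observations (< ", min_obs,
            "); falling back to the average model", call. = FALSE)
    fb <- fit_average(series)
    return(structure(list(order = c(0L, 0L, 0L), constant = TRUE,
                          coef = c(intercept = fb$mu), sigma = fb$sigma,
                          aicc = NA_real_, model = NULL, fallback = fb,
                          candidates = NULL),
                     class = "arima_fit"))
  }
  d <- ndiffs_kpss(series, max_d)
  tried <- new.env()
  seen <- character(0)
  cands <- list()
  try_fit <- function(p, q, constant) {
    if (p < 0 || q < 0 || p > max_p || q > max_q) return(NULL)
    key <- paste(p, d, q, constant)
    if (key %in% seen) return(NULL)
    seen <<- c(seen, key)
    fit <- fit_arima_candidate(series, p, d, q, constant)
    if (!is.null(fit)) cands[[length(cands) + 1]] <<- fit
    fit
  }
  const0 <- d < 2
  best <- NULL
  for (pq in list(c(2, 2), c(0, 0), c(1, 0), c(0, 1))) {
    f <- try_fit(pq[1], pq[2], const0)
    if (!is.null(f) && (is.null(best) || f$aicc < best$aicc)) best <- f
  }
  if (is.null(best))
    stop("no ARIMA candidate converged", call. = FALSE)
  repeat {
    improved <- FALSE
    p <- best$p; q <- best$q; cst <- best$constant
    moves <- list(c(p - 1, q), c(p + 1, q), c(p, q - 1), c(p, q + 1),
                  c(p - 1, q - 1), c(p + 1, q + 1))
    for (mv in moves) {
      f <- try_fit(mv[1], mv[2], cst)
      if (!is.null(f) && f$aicc < best$aicc) { best <- f; improved <- TRUE }
    }
    if (d < 2) {
      f <- try_fit(best$p, best$q, !best$constant)
      if (!is.null(f) && f$aicc < best$aicc) { best <- f; improved <- TRUE }
    }
    if (!improved) break
  }
  cand_df <- do.call(rbind, lapply(cands, function(f)
    data.frame(p = f$p, d = f$d, q = f$q, constant = f$constant,
               aicc = f$aicc)))
  structure(list(order = as.integer(c(best$p, d, best$q)),
                 constant = best$constant,
                 coef = best$model$coef,
                 sigma = sqrt(best$model$sigma2), aicc = best$aicc,
                 model = best$model, fallback = NULL,
                 candidates = cand_df),
            class = "arima_fit")
}

#' @rdname select_arima
#' @param fit An \code{arima_fit}.
#' @param horizons Integer horizons 1..H (must be consecutive from 1).
#' @param site_id,last_year,model,corrected Forecast labelling.
#' @export
forecast_arima <- function(fit, horizons, site_id = "site",
                           last_year = 0L, model = "auto_arima",
                           corrected = FALSE) {
  h <- max(horizons)
  if (!is.null(fit$fallback)) {
    fc <- forecast_average(fit$fallback, seq_len(h), site_id, last_year,
                           model, corrected)
  } else {
    m <- fit$model
    if (fit$order[2] == 1 && fit$constant) {
      # the fitted drift regressor was 1..n; extend it to n+1..n+h
      newx <- matrix(length(m$residuals) + seq_len(h), ncol = 1,
                     dimnames = list(NULL, "drift"))
      pr <- stats::predict(m, n.ahead = h, newxreg = newx)
    } else {
      pr <- stats::predict(m, n.ahead = h)
    }
    fc <- new_gaussian_forecast(site_id, last_year + seq_len(h),
                                seq_len(h), as.numeric(pr$pred),
                                as.numeric(pr$se), model, corrected)
  }
  fc[fc$horizon %in% horizons, , drop = FALSE]
}

#' @export
print.arima_fit <- function(x, ...) {
  if (!is.null(x$fallback)) {
    cat("<arima_fit> fallback to average model (short series)\n")
  } else {
    cat(sprintf("<arima_fit> ARIMA(%d,%d,%d)%s, AICc %.2f, sigma %.3f\n",
                x$order[1], x$order[2], x$order[3],
                if (x$constant) " with constant" else "", x$aicc, x$sigma))
  }
  invisible(x)
}

#' Combine per-draw forecasts by the law of total variance
#'
#' Given one Gaussian forecast per posterior draw for the same
#' site-years, the combined point estimate is the mean of the draw means
#' and the combined variance is the (unbiased) variance of the draw
#' means plus the average of the draw variances:
#' \eqn{Var(\bar y) + E[Var(y)]}.
#'
#' @param forecasts List of \code{gaussian_forecast} data.frames with
#'   identical (site_id, year) rows, one per draw.
#' @return A single \code{gaussian_forecast}.
#' @export
#' @examples
#' f1 <- forecast_average(fit_average(c(1, 1)), 1)
#' f2 <- forecast_average(fit_average(c(3, 3)), 1)
#' combine_draw_forecasts(list(f1, f2))$sd^2  # var of means + mean var
combine_draw_forecasts <- function(forecasts) {
  stopifnot(length(forecasts) >= 1)
  base <- forecasts[[1]]
  means <- vapply(forecasts, function(f) f$mean, numeric(nrow(base)))
  vars <- vapply(forecasts, function(f) f$sd^2, numeric(nrow(base)))
  means <- matrix(means, nrow = nrow(base))
  vars <- matrix(vars, nrow = nrow(base))
  m <- rowMeans(means)
  v_between <- if (ncol(means) > 1) apply(means, 1, stats::var) else 0
  v <- v_between + rowMeans(vars)
  out <- base
  out$mean <- m
  out$sd <- sqrt(v)
  out
}
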