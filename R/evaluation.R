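# Forecast verification: RMSE, central-interval coverage, Gaussian
# deviance, per-forecast skill against a baseline, horizon-stratified
# metrics, and the exact site/annual squared-error decomposition.

join_forecasts <- function(forecasts, observed, quiet = FALSE) {
  key_f <- paste(forecasts$site_id, forecasts$year)
  key_o <- paste(observed$site_id, observed$year)
  m <- match(key_f, key_o)
  dropped <- sum(is.na(m))
  if (dropped > 0 && !quiet)
    message(dropped, " forecast row(s) without a matching observation dropped")
  keep <- !is.na(m)
  if (!any(keep))
    stop("no forecasts match the observations on (site_id, year)",
         call. = FALSE)
  cbind(forecasts[keep, , drop = FALSE],
        observed = observed$richness[m[keep]])
}

#' Root-mean-square forecast error
#'
#' @param forecasts A \code{gaussian_forecast} (site_id, year, mean, sd).
#' @param observed A richness panel with the realized values.
#' @return \eqn{\sqrt{mean((mean - y)^2)}} over the joined rows.
#' @export
rmse <- function(forecasts, observed) {
  j <- join_forecasts(forecasts, observed)
  sqrt(mean((j$mean - j$observed)^2))
}

#' Prediction-interval coverage
#'
#' Fraction of observations inside the central Gaussian interval
#' \eqn{mean \pm z \cdot sd} at the given level. Rows with `sd == 0`
#' count as covered only when the observation equals the mean exactly.
#'
#' @param forecasts A \code{gaussian_forecast}.
#' @param observed Realized richness panel.
#' @param level Interval level (default 0.95).
#' @return Proportion in [0, 1].
#' @export
coverage <- function(forecasts, observed, level = 0.95) {
  stopifnot(level > 0, level < 1)
  j <- join_forecasts(forecasts, observed)
  if (any(j$sd < 0)) stop("negative forecast sd", call. = FALSE)
  z <- stats::qnorm(1 - (1 - level) / 2)
  inside <- abs(j$observed - j$mean) <= z * j$sd
  exact <- j$sd == 0 & j$observed == j$mean
  mean(inside | exact)
}

#' Mean Gaussian deviance of forecasts
#'
#' Deviance is \eqn{-2} times the Gaussian log-likelihood; per row
#' \eqn{\log(2\pi\,sd^2) + (y - mean)^2 / sd^2}, averaged over rows. A
#' variance floor guards degenerate `sd = 0` forecasts; with
#' `var_floor = 0` such rows are an error.
#'
#' @param forecasts A \code{gaussian_forecast}.
#' @param observed Realized richness panel.
#' @param var_floor Minimum predictive variance (default 1e-6); a
#'   message reports how many rows it lifted.
#' @return Mean deviance (unitless).
#' @export
mean_deviance <- function(forecasts, observed, var_floor = 1e-6) {
  j <- join_forecasts(forecasts, observed)
  v <- j$sd^2
  if (var_floor > 0 && any(v < var_floor)) {
    message(sum(v < var_floor), " row(s) lifted to the variance floor ",
            var_floor)
    v <- pmax(v, var_floor)
  }
  if (any(v <= 0))
    stop("forecast sd of 0 gives infinite deviance; set `var_floor` ",
         "to a small positive variance", call. = FALSE)
  mean(log(2 * pi * v) + (j$observed - j$mean)^2 / v)
}

#' Per-forecast skill relative to a baseline
#'
#' Joins model and baseline forecasts on identical (site_id, year) keys
#' and returns, for every forecast, the model-minus-baseline difference
#' in absolute error and in Gaussian deviance, so errors for the same
#' site and testing year are directly compared. A baseline compared
#' against itself gives exactly zero everywhere.
#'
#' @param model_fc,baseline_fc \code{gaussian_forecast}s on the same
#'   keys (a key mismatch is an error listing offenders).
#' @param observed Realized richness panel.
#' @param var_floor Variance floor for the deviance terms.
#' @return list(table = per-row data.frame with `d_abs_error`,
#'   `d_deviance`, mean_d_abs_error, mean_d_deviance).
#' @export
skill_vs_baseline <- function(model_fc, baseline_fc, observed,
                              var_floor = 1e-6) {
  key_m <- paste(model_fc$site_id, model_fc$year)
  key_b <- paste(baseline_fc$site_id, baseline_fc$year)
  bad <- c(setdiff(key_m, key_b), setdiff(key_b, key_m))
  if (length(bad) > 0)
    stop("model and baseline keys differ: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  jm <- join_forecasts(model_fc, observed, quiet = TRUE)
  jb <- join_forecasts(baseline_fc, observed, quiet = TRUE)
  jb <- jb[match(paste(jm$site_id, jm$year), paste(jb$site_id, jb$year)), ]
  dev_row <- function(j) {
    v <- pmax(j$sd^2, var_floor)
    log(2 * pi * v) + (j$observed - j$mean)^2 / v
  }
  tab <- data.frame(site_id = jm$site_id, year = jm$year,
                    d_abs_error = abs(jm$mean - jm$observed) -
                      abs(jb$mean - jb$observed),
                    d_deviance = dev_row(jm) - dev_row(jb),
                    stringsAsFactors = FALSE)
  list(table = tab,
       mean_d_abs_error = mean(tab$d_abs_error),
       mean_d_deviance = mean(tab$d_deviance))
}

#' Decompose mean squared error into site and annual components
#'
#' Within each site the squared error splits exactly into a site-level
#' term — the squared difference between the site's mean prediction and
#' its mean observation over the test years — and an annual term, the
#' mean squared error of the within-site anomalies. The cross term
#' cancels within sites, so with sites weighted by their number of test
#' years the two components add to the pooled MSE to machine precision.
#'
#' @param forecasts A \code{gaussian_forecast}.
#' @param observed Realized richness panel.
#' @return Object of class \code{error_decomposition}: list(
#'   site_component, annual_component, total, by_site data.frame).
#' @export
#' @examples
#' fc <- new_gaussian_forecast("a", 1:2, 1:2, c(53, 53), c(1, 1), "m")
#' obs <- data.frame(site_id = "a", year = 1:2, richness = c(50, 52))
#' decompose_mse(fc, obs)  # site 4, annual 1, total 5
decompose_mse <- function(forecasts, observed) {
  j <- join_forecasts(forecasts, observed)
  by_site <- do.call(rbind, lapply(split(j, j$site_id), function(d) {
    pb <- mean(d$mean); yb <- mean(d$observed)
    data.frame(site_id = d$site_id[1], n = nrow(d),
               site = (pb - yb)^2,
               annual = mean(((d$mean - pb) - (d$observed - yb))^2),
               stringsAsFactors = FALSE)
  }))
  w <- by_site$n / sum(by_site$n)
  out <- list(site_component = sum(w * by_site$site),
              annual_component = sum(w * by_site$annual),
              total = mean((j$mean - j$observed)^2),
              by_site = by_site)
  class(out) <- "error_decomposition"
  out
}

#' @export
print.error_decomposition <- function(x, ...) {
  cat(sprintf(
    "MSE %.3f = site %.3f + annual %.3f (squared species)\n",
    x$total, x$site_component, x$annual_component))
  invisible(x)
}

#' Pooled verification metrics for a set of forecasts
#'
#' @param forecasts A \code{gaussian_forecast} (may mix models and
#'   correction modes; metrics are computed per group).
#' @param observed Realized richness panel.
#' @param level Coverage level.
#' @param var_floor Variance floor for deviance.
#' @return A \code{metrics_table} data.frame: model, corrected, rmse,
#'   coverage95, mean_deviance, n.
#' @export
metrics_table <- function(forecasts, observed, level = 0.95,
                          var_floor = 1e-6) {
  groups <- split(forecasts,
                  list(forecasts$model, forecasts$corrected), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(f) {
    j <- join_forecasts(f, observed, quiet = TRUE)
    data.frame(model = f$model[1], corrected = f$corrected[1],
               rmse = rmse(f, observed),
               coverage95 = coverage(f, observed, level),
               mean_deviance = suppressMessages(
                 mean_deviance(f, observed, var_floor)),
               n = nrow(j), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  out
}

#' Verification metrics stratified by forecast horizon
#'
#' Computes the pooled metrics within each horizon stratum 1..H; empty
#' strata are skipped with a message. Stratum sizes sum to the pooled n.
#'
#' @inheritParams metrics_table
#' @return A \code{metrics_table} with an extra `horizon` column.
#' @export
metrics_by_horizon <- function(forecasts, observed, level = 0.95,
                               var_floor = 1e-6) {
  out <- do.call(rbind, lapply(sort(unique(forecasts$horizon)), function(h) {
    f <- forecasts[forecasts$horizon == h, , drop = FALSE]
    j <- tryCatch(join_forecasts(f, observed, quiet = TRUE),
                  error = function(e) NULL)
    if (is.null(j)) {
      message("horizon ", h, " has no matched forecasts; skipped")
      return(NULL)
    }
    cbind(horizon = h, metrics_table(f, observed, level, var_floor))
  }))
  rownames(out) <- NULL
  class(out) <- c("metrics_table", "data.frame")
  out
}
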