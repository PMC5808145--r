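# Environmental feature construction: bioclim variables on the July-June
# pre-survey window, seasonal NDVI means, completeness filtering, and the
# train/test split.

# months of the July-June window preceding a survey year, as (year, month)
july_june_window <- function(survey_year) {
  data.frame(year = c(rep(survey_year - 1L, 6L), rep(survey_year, 6L)),
             month = c(7:12, 1:6))
}

bioclim_one <- function(tmax, tmin, prec) {
  # inputs ordered July ... June; quarters are the 10 non-wrapping
  # 3-month windows, ties broken by the earliest window
  mid <- (tmax + tmin) / 2
  q <- vapply(1:10, function(i) {
    idx <- i:(i + 2)
    c(prec = sum(prec[idx]), temp = mean(mid[idx]))
  }, c(prec = 0, temp = 0))
  wettest <- which.max(q["prec", ])
  driest <- which.min(q["prec", ])
  warmest <- which.max(q["temp", ])
  bio2 <- mean(tmax - tmin)
  bio5 <- max(tmax)
  rng <- bio5 - min(tmin)
  c(bio2 = bio2,
    bio3 = if (rng > 0) 100 * bio2 / rng else 100,
    bio5 = bio5,
    bio8 = q["temp", wettest],
    bio9 = q["temp", driest],
    bio15 = 100 * stats::sd(prec) / (1 + mean(prec)),
    bio16 = q["prec", wettest],
    bio18 = q["prec", warmest])
}

#' Bioclim variables for the 12 months preceding each survey
#'
#' Computes eight bioclim-style summaries from monthly weather over the
#' July--June window ending just before the survey season of
#' `survey_year` (July of the previous calendar year through June of the
#' survey year, not the calendar year):
#' \describe{
#'   \item{bio2}{mean diurnal range, mean monthly (tmax - tmin), deg C}
#'   \item{bio3}{isothermality, 100 * bio2 / (bio5 - min monthly tmin)}
#'   \item{bio5}{max temperature of the warmest month, deg C}
#'   \item{bio8}{mean temperature of the wettest quarter, deg C}
#'   \item{bio9}{mean temperature of the driest quarter, deg C}
#'   \item{bio15}{precipitation seasonality,
#'     100 * SD(monthly prec) / (1 + mean monthly prec)}
#'   \item{bio16}{precipitation of the wettest quarter, mm}
#'   \item{bio18}{precipitation of the warmest quarter, mm}
#' }
#' Quarters are the 10 non-wrapping 3-month windows of the July--June
#' sequence; monthly mean temperature is the midpoint (tmax + tmin) / 2;
#' ties between quarters go to the earliest window. The `+1` in the
#' bio15 denominator guards zero-precipitation climates.
#'
#' @param weather A \code{monthly_weather} data.frame (site_id, year,
#'   month, tmax, tmin, prec).
#' @param survey_year Integer survey year (one value).
#' @return data.frame: site_id, year, bio2, bio3, bio5, bio8, bio9,
#'   bio15, bio16, bio18 — one row per site.
#' @export
compute_bioclim <- function(weather, survey_year) {
  survey_year <- as.integer(survey_year)
  win <- july_june_window(survey_year)
  key <- paste(win$year, win$month)
  wkey <- paste(weather$year, weather$month)
  rows <- weather[wkey %in% key, , drop = FALSE]
  out <- lapply(split(rows, rows$site_id), function(d) {
    have <- paste(d$year, d$month)
    miss <- setdiff(key, have)
    if (length(miss) > 0)
      stop("missing weather for site ", d$site_id[1], ": ",
           paste(gsub(" ", "-", miss), collapse = ", "),
           " (need July ", survey_year - 1L, " through June ",
           survey_year, ")", call. = FALSE)
    d <- d[match(key, have), ]
    bioclim_one(d$tmax, d$tmin, d$prec)
  })
  if (length(out) == 0)
    stop("no weather rows found for the July-June window of ",
         survey_year, call. = FALSE)
  res <- as.data.frame(do.call(rbind, out))
  names(res) <- c("bio2", "bio3", "bio5", "bio8", "bio9", "bio15",
                  "bio16", "bio18")
  data.frame(site_id = names(out), year = survey_year, res,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Seasonal NDVI means for a survey year
#'
#' Summer NDVI is the mean of April, May and June of the survey year;
#' winter NDVI is the mean of December of the *previous* calendar year
#' plus January and February of the survey year.
#'
#' @param monthly_ndvi data.frame with site_id, year, month, ndvi.
#' @param survey_year Integer survey year.
#' @return data.frame: site_id, year, ndvi_summer, ndvi_winter.
#' @export
seasonal_ndvi <- function(monthly_ndvi, survey_year) {
  survey_year <- as.integer(survey_year)
  need <- data.frame(
    year = c(survey_year, survey_year, survey_year,
             survey_year - 1L, survey_year, survey_year),
    month = c(4L, 5L, 6L, 12L, 1L, 2L),
    season = c("summer", "summer", "summer", "winter", "winter", "winter"))
  key <- paste(need$year, need$month)
  rows <- monthly_ndvi[paste(monthly_ndvi$year, monthly_ndvi$month) %in% key,
                       , drop = FALSE]
  out <- lapply(split(rows, rows$site_id), function(d) {
    have <- paste(d$year, d$month)
    miss <- setdiff(key, have)
    if (length(miss) > 0)
      stop("missing NDVI for site ", d$site_id[1], ": ",
           paste(gsub(" ", "-", miss), collapse = ", "), call. = FALSE)
    d <- d[match(key, have), ]
    c(summer = mean(d$ndvi[need$season == "summer"]),
      winter = mean(d$ndvi[need$season == "winter"]))
  })
  if (length(out) == 0)
    stop("no NDVI rows found for survey year ", survey_year, call. = FALSE)
  m <- do.call(rbind, out)
  data.frame(site_id = rownames(m), year = survey_year,
             ndvi_summer = m[, "summer"], ndvi_winter = m[, "winter"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build the full site-year covariate table from monthly weather
#'
#' Joins [compute_bioclim()] and [seasonal_ndvi()] per survey year with
#' site-constant elevation.
#'
#' @param weather monthly weather including an `ndvi` column (e.g. from
#'   [simulate_monthly_weather()]).
#' @param survey_years Integer vector of survey years.
#' @param elevation Optional data.frame (site_id, elevation); when absent
#'   and `weather` lacks elevation, the column is omitted.
#' @return Covariate data.frame keyed on (site_id, year) with columns
#'   bio2, bio3, bio5, bio8, bio9, bio15, bio16, bio18, ndvi_summer,
#'   ndvi_winter and (if supplied) elevation.
#' @export
build_covariates <- function(weather, survey_years, elevation = NULL) {
  out <- do.call(rbind, lapply(as.integer(survey_years), function(y) {
    bc <- compute_bioclim(weather, y)
    nd <- seasonal_ndvi(weather, y)
    merge(bc, nd, by = c("site_id", "year"))
  }))
  if (!is.null(elevation))
    out <- merge(out, elevation[, c("site_id", "elevation")], by = "site_id")
  out[order(out$site_id, out$year), , drop = FALSE]
}

#' Drop sites with too few training-period observations
#'
#' Retains exactly the sites observed in at least
#' `ceiling(min_fraction * length(training_years))` distinct training
#' years (with the defaults of a 22-year training period and 0.7 this is
#' 16 annual observations). Test-period records of retained sites are
#' untouched. The filter is idempotent.
#'
#' @param panel A richness panel.
#' @param training_years Integer vector of training years.
#' @param min_fraction Required fraction of training years, in (0, 1].
#' @return The filtered panel; a warning (not an error) if nothing
#'   survives.
#' @export
filter_complete_sites <- function(panel, training_years, min_fraction = 0.7) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("`min_fraction` must be in (0, 1]", call. = FALSE)
  threshold <- ceiling(min_fraction * length(training_years))
  in_train <- panel$year %in% training_years
  counts <- tapply(panel$year[in_train], panel$site_id[in_train],
                   function(y) length(unique(y)))
  keep <- names(counts)[counts >= threshold]
  out <- panel[panel$site_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0)
    warning("no sites meet the completeness threshold of ", threshold,
            " training years", call. = FALSE)
  out
}

#' Split a panel into training and test periods
#'
#' @param panel A richness panel.
#' @param split_year Last training year; training = years <= split_year,
#'   test = years > split_year. The two parts are disjoint and exhaustive.
#' @return list(train, test).
#' @export
split_train_test <- function(panel, split_year) {
  if (split_year < min(panel$year) || split_year > max(panel$year))
    stop("`split_year` outside the panel's year span", call. = FALSE)
  is_train <- panel$year <= split_year
  train <- panel[is_train, , drop = FALSE]
  test <- panel[!is_train, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test)
}
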