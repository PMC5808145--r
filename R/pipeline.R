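# Orchestration: typed panel I/O, experiment configuration, the
# end-to-end simulate -> filter/split -> fit-observer -> forecast ->
# evaluate experiment, and the delimited-text forecast archive.

#' Read and write richness panels
#'
#' Panels are plain CSV with columns site_id, year, observer_id,
#' richness. Reading validates the schema, parses types, and rejects
#' duplicated (site_id, year) keys by name.
#'
#' @param path File path.
#' @return `read_richness_panel`: a \code{richness_panel} data.frame.
#' @export
read_richness_panel <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "year", "observer_id", "richness")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  for (col in c("year", "richness")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v))
      stop("unparseable ", col, " at line(s) ",
           paste(utils::head(which(is.na(v)) + 1L, 5), collapse = ", "),
           call. = FALSE)
    df[[col]] <- if (col == "year") as.integer(v) else v
  }
  key <- paste(df$site_id, df$year)
  if (anyDuplicated(key))
    stop("duplicated (site_id, year): ",
         paste(utils::head(unique(key[duplicated(key)]), 5),
               collapse = "; "), call. = FALSE)
  if (any(df$richness < 0))
    stop("negative richness values", call. = FALSE)
  df <- df[, need]
  class(df) <- c("richness_panel", "data.frame")
  df
}

#' @rdname read_richness_panel
#' @param panel A richness panel.
#' @export
write_richness_panel <- function(panel, path) {
  utils::write.csv(panel[, c("site_id", "year", "observer_id", "richness")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Experiment configuration
#'
#' Either `sim` (an embedded [sim_config()]) or `panel_path` must be
#' given. Community-dependent models (stacked_sdm, jsdm) require either
#' simulation or a `community_path`; the check happens here, before any
#' compute.
#'
#' @param models Subset of c("average", "naive", "auto_arima", "gbm",
#'   "stacked_sdm", "jsdm").
#' @param split_year Last training year.
#' @param n_draws Posterior draws used for observer correction (the
#'   full-scale convention is 500; smaller values speed exploration).
#' @param warmup Gibbs warmup iterations.
#' @param min_fraction Training completeness threshold for
#'   [filter_complete_sites()].
#' @param sim Optional [sim_config()] for synthetic input.
#' @param panel_path,covariate_path,community_path Optional input files.
#' @param seed Master seed for per-stage seeds.
#' @param future_covariates One of "observed" (hindcast convention: the
#'   test years' covariates are known) or "climatology" (substitute each
#'   site's training-period mean covariates, mimicking true forecasting).
#' @return An \code{experiment_config} list.
#' @export
experiment_config <- function(models = c("average", "naive"),
                              split_year = 2003, n_draws = 50,
                              warmup = 200, min_fraction = 0.7,
                              sim = NULL, panel_path = NULL,
                              covariate_path = NULL,
                              community_path = NULL, seed = 1L,
                              future_covariates = c("observed",
                                                    "climatology")) {
  all_models <- c("average", "naive", "auto_arima", "gbm",
                  "stacked_sdm", "jsdm")
  bad <- setdiff(models, all_models)
  if (length(bad) > 0)
    stop("unknown model(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (is.null(sim) && is.null(panel_path))
    stop("either `sim` or `panel_path` is required", call. = FALSE)
  needs_comm <- intersect(models, c("stacked_sdm", "jsdm"))
  if (length(needs_comm) > 0 && is.null(sim) && is.null(community_path))
    stop("model(s) ", paste(needs_comm, collapse = ", "),
         " need community data: supply `community_path` or simulate",
         call. = FALSE)
  needs_env <- intersect(models, c("gbm", "stacked_sdm", "jsdm"))
  if (length(needs_env) > 0 && is.null(sim) && is.null(covariate_path))
    stop("model(s) ", paste(needs_env, collapse = ", "),
         " need covariates: supply `covariate_path` or simulate",
         call. = FALSE)
  structure(list(models = models, split_year = as.integer(split_year),
                 n_draws = as.integer(n_draws), warmup = as.integer(warmup),
                 min_fraction = min_fraction, sim = sim,
                 panel_path = panel_path, covariate_path = covariate_path,
                 community_path = community_path, seed = as.integer(seed),
                 future_covariates = match.arg(future_covariates)),
            class = "experiment_config")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(config, f)
  unname(tools::md5sum(f))
}

site_series <- function(panel) {
  lapply(split(panel[, c("year", "richness")], panel$site_id),
         function(d) d[order(d$year), ])
}

# fit + forecast one single-site model for every site, one draw
single_site_forecasts <- function(series_list, model, horizons, last_year,
                                  corrected = FALSE, sigma_avg = NULL) {
  out <- lapply(names(series_list), function(s) {
    d <- series_list[[s]]
    fc <- switch(model,
      average = forecast_average(
        fit_average(d$richness, sigma = sigma_avg), horizons, s,
        last_year, "average", corrected),
      naive = forecast_naive(
        suppressWarnings(fit_naive(d$richness, d$year)), horizons, s,
        last_year, "naive", corrected),
      auto_arima = forecast_arima(
        suppressWarnings(select_arima(d$richness)), horizons, s,
        last_year, "auto_arima", corrected))
    fc
  })
  do.call(rbind, out)
}

#' Run the end-to-end hindcast experiment
#'
#' Simulates (or reads) a richness panel, applies the completeness
#' filter and train/test split, fits the observer model, runs every
#' requested forecaster both with and without observer correction
#' (paired, sharing seeds), and evaluates the hindcasts. No model ever
#' sees test-period richness; environmental models see test-period
#' covariates under the hindcast convention (configurable).
#'
#' Observer correction by model family: single-site models are refit on
#' each posterior draw's corrected series and combined by the law of
#' total variance (the "average" model uses each draw's residual SD as
#' its predictive SD); the boosted-tree model is refit per draw on
#' corrected richness; stacked SDMs give each tree a different
#' observer-effect draw as a predictor; the JSDM uses the posterior-mean
#' observer effect as a predictor. Future observers are assigned zero
#' effect.
#'
#' @param config An [experiment_config()].
#' @param progress Print per-stage progress lines.
#' @return list: `archive` (\code{forecast_archive}), `metrics`
#'   (pooled \code{metrics_table}), `by_horizon`, `decomposition`
#'   (per model), `skill` (vs the uncorrected average baseline),
#'   `partition` (observer [variance_partition()]), `log` (per-stage
#'   record counts), `test` (the held-out panel).
#' @export
run_experiment <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (progress) message("[richcast] ", ...)
  logs <- list()

  # ---- inputs
  needs_comm <- intersect(config$models, c("stacked_sdm", "jsdm"))
  if (!is.null(config$sim)) {
    say("simulating panel (", config$sim$n_sites, " sites)")
    if (length(needs_comm) > 0) {
      # community mode: richness is the integer detection row sum, so
      # every model trains and is scored on the same panel
      covariates <- simulate_covariates(config$sim)
      comm_sim <- simulate_community_panel(config$sim, covariates)
      panel <- comm_sim$panel
      community <- comm_sim$community
    } else {
      simr <- simulate_richness_panel(config$sim)
      panel <- simr$panel
      covariates <- simulate_covariates(config$sim, simr$true_effects$sites)
      community <- NULL
    }
  } else {
    panel <- read_richness_panel(config$panel_path)
    covariates <- if (!is.null(config$covariate_path))
      utils::read.csv(config$covariate_path, stringsAsFactors = FALSE)
    community <- if (!is.null(config$community_path))
      utils::read.csv(config$community_path, stringsAsFactors = FALSE)
  }
  logs$input_rows <- nrow(panel)

  years <- sort(unique(panel$year))
  training_years <- years[years <= config$split_year]
  n0 <- nrow(panel)
  panel <- filter_complete_sites(panel, training_years,
                                 config$min_fraction)
  logs$dropped_incomplete <- n0 - nrow(panel)
  say("completeness filter dropped ", logs$dropped_incomplete, " rows")

  parts <- split_train_test(panel, config$split_year)
  train <- parts$train; test <- parts$test
  logs$train_rows <- nrow(train); logs$test_rows <- nrow(test)
  last_year <- config$split_year
  horizons <- seq_len(max(years) - last_year)

  if (length(needs_comm) > 0 && is.null(community))
    stop("community data required for ",
         paste(needs_comm, collapse = ", "), call. = FALSE)

  # ---- observer model
  say("fitting observer model (", config$n_draws, " draws)")
  post <- fit_observer_model(train, n_draws = config$n_draws,
                             seed = config$seed + 1L,
                             warmup = config$warmup)
  partition <- variance_partition(post)
  corr <- suppressMessages(corrected_richness_draws(train, post))

  # training covariate rows aligned with the train panel, plus the
  # test-period covariate rows used for prediction
  if (!is.null(covariates)) {
    key_cov <- paste(covariates$site_id, covariates$year)
    cov_train <- covariates[match(paste(train$site_id, train$year), key_cov), ]
    cov_test <- covariates[match(paste(test$site_id, test$year), key_cov), ]
    if (config$future_covariates == "climatology") {
      num <- setdiff(names(covariates)[vapply(covariates, is.numeric, TRUE)],
                     "year")
      clim <- stats::aggregate(cov_train[num],
                               by = list(site_id = cov_train$site_id), mean)
      cov_test[num] <- clim[match(cov_test$site_id, clim$site_id), num]
    }
    # per-draw observer effects aligned with training covariate rows
    obs_draws <- panel_observer_effects(train, post)
  }

  # ---- forecasting
  say("forecasting: ", paste(config$models, collapse = ", "))
  fcs <- list()
  series_raw <- site_series(train)
  for (model in intersect(config$models,
                          c("average", "naive", "auto_arima"))) {
    fcs[[paste0(model, "_raw")]] <-
      single_site_forecasts(series_raw, model, horizons, last_year, FALSE)
    per_draw <- lapply(seq_along(corr$draws), function(d) {
      pan_d <- train
      pan_d$richness <- corr$corrected[, d]
      sig <- if (model == "average") post$sigma_resid[corr$draws[d]] else NULL
      single_site_forecasts(site_series(pan_d), model, horizons,
                            last_year, TRUE, sigma_avg = sig)
    })
    fcs[[paste0(model, "_corr")]] <- combine_draw_forecasts(per_draw)
  }

  if ("gbm" %in% config$models) {
    fcs$gbm_raw <- predict_richness_gbm(
      fit_richness_gbm(cov_train, train$richness,
                       max_trees = 1000, seed = config$seed + 2L),
      cov_test, last_year)
    per_draw <- lapply(seq_len(min(config$n_draws, 20)), function(d) {
      g <- fit_richness_gbm(cov_train, corr$corrected[, d],
                            max_trees = 1000, seed = config$seed + 2L)
      predict_richness_gbm(g, cov_test, last_year, corrected = TRUE)
    })
    fcs$gbm_corr <- combine_draw_forecasts(per_draw)
  }

  if (length(needs_comm) > 0) {
    comm_train <- community[paste(community$site_id, community$year) %in%
                              paste(train$site_id, train$year), ]
    if ("stacked_sdm" %in% config$models) {
      sf_raw <- fit_stacked_sdm(comm_train, cov_train, n_trees = 100,
                                seed = config$seed + 3L)
      fcs$sdm_raw <- predict_stacked_richness(sf_raw, cov_test, last_year)
      sf_cor <- fit_stacked_sdm(comm_train, cov_train,
                                observer_draws = obs_draws,
                                n_trees = min(100, config$n_draws),
                                seed = config$seed + 3L)
      fcs$sdm_corr <- predict_stacked_richness(
        sf_cor, cov_test, last_year, obs_effect = 0, corrected = TRUE)
    }
    if ("jsdm" %in% config$models) {
      jf_raw <- fit_jsdm(comm_train, cov_train, n_latent = 2,
                         seed = config$seed + 4L)
      fcs$jsdm_raw <- predict_jsdm_richness(jf_raw, cov_test,
                                            last_year = last_year,
                                            seed = config$seed + 5L)
      jf_cor <- fit_jsdm(comm_train, cov_train, n_latent = 2,
                         observer_effect = rowMeans(obs_draws),
                         seed = config$seed + 4L)
      fcs$jsdm_corr <- predict_jsdm_richness(
        jf_cor, cov_test, observer_effect = 0, last_year = last_year,
        corrected = TRUE, seed = config$seed + 5L)
    }
  }

  all_fc <- do.call(rbind, fcs)
  rownames(all_fc) <- NULL
  archive <- forecast_archive(all_fc, config, training_years)

  # ---- evaluation
  say("evaluating ", nrow(all_fc), " forecasts")
  metrics <- suppressMessages(metrics_table(all_fc, test))
  by_horizon <- suppressMessages(metrics_by_horizon(all_fc, test))
  groups <- split(all_fc, list(all_fc$model, all_fc$corrected), drop = TRUE)
  decomposition <- lapply(groups, decompose_mse, observed = test)
  skill <- NULL
  if ("average" %in% config$models) {
    base <- fcs$average_raw
    skill <- lapply(groups, function(f) {
      f <- f[paste(f$site_id, f$year) %in% paste(base$site_id, base$year), ]
      skill_vs_baseline(f, base, test)
    })
  }

  list(archive = archive, metrics = metrics, by_horizon = by_horizon,
       decomposition = decomposition, skill = skill,
       partition = partition, post = post, log = logs, test = test)
}

# matrix of per-draw observer effects aligned with panel rows
panel_observer_effects <- function(panel, post) {
  known <- colnames(post$observer_effects)
  idx <- match(panel$observer_id, known)
  eff <- matrix(0, nrow(panel), post$n_draws)
  seen <- !is.na(idx)
  eff[seen, ] <- t(post$observer_effects)[idx[seen], , drop = FALSE]
  eff
}

# ---- forecast archive ------------------------------------------------

#' The forecast archive
#'
#' A forecast table (site_id, year, model, corrected, mean, sd, lo68,
#' hi68, lo95, hi95) plus a metadata block (config hash, seed, code
#' version, training years), written as CSV with `#`-prefixed header
#' lines so archived forecasts can be re-evaluated when new observations
#' arrive.
#'
#' @param forecasts A \code{gaussian_forecast}.
#' @param config The generating [experiment_config()].
#' @param training_years Years the models were trained on (recorded so
#'   in-sample evaluation can be refused later).
#' @return Object of class \code{forecast_archive}.
#' @export
forecast_archive <- function(forecasts, config, training_years) {
  z68 <- stats::qnorm(0.84); z95 <- stats::qnorm(0.975)
  tab <- data.frame(site_id = forecasts$site_id, year = forecasts$year,
                    model = forecasts$model,
                    corrected = forecasts$corrected,
                    mean = forecasts$mean, sd = forecasts$sd,
                    lo68 = forecasts$mean - z68 * forecasts$sd,
                    hi68 = forecasts$mean + z68 * forecasts$sd,
                    lo95 = forecasts$mean - z95 * forecasts$sd,
                    hi95 = forecasts$mean + z95 * forecasts$sd,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 metadata = list(
                   config_hash = config_hash(config),
                   seed = config$seed,
                   version = as.character(utils::packageVersion("richcast")),
                   training_years = range(training_years))),
            class = "forecast_archive")
}

#' @rdname forecast_archive
#' @param archive A \code{forecast_archive}.
#' @param path File path.
#' @export
write_forecast_archive <- function(archive, path) {
  stopifnot(inherits(archive, "forecast_archive"))
  md <- archive$metadata
  hdr <- c(paste0("# config_hash: ", md$config_hash),
           paste0("# seed: ", md$seed),
           paste0("# version: ", md$version),
           paste0("# training_years: ", md$training_years[1], " ",
                  md$training_years[2]))
  tab <- archive$table
  num <- c("mean", "sd", "lo68", "hi68", "lo95", "hi95")
  for (col in num) tab[[col]] <- sprintf("%.6f", tab[[col]])
  lines <- c(hdr, paste(names(tab), collapse = ","),
             do.call(paste, c(tab, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname forecast_archive
#' @export
read_forecast_archive <- function(path) {
  lines <- readLines(path)
  is_md <- startsWith(lines, "# ")
  md_raw <- sub("^# ", "", lines[is_md])
  kv <- strsplit(md_raw, ": ", fixed = TRUE)
  md <- stats::setNames(lapply(kv, `[`, 2), vapply(kv, `[`, "", 1))
  md$seed <- as.integer(md$seed)
  md$training_years <- as.integer(strsplit(md$training_years, " ")[[1]])
  tab <- utils::read.csv(text = lines[!is_md], stringsAsFactors = FALSE)
  need <- c("site_id", "year", "model", "corrected", "mean", "sd",
            "lo68", "hi68", "lo95", "hi95")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("archive missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(tab$sd < 0) || any(tab$hi95 < tab$lo95) || any(tab$hi68 < tab$lo68))
    stop("archive violates interval invariants", call. = FALSE)
  structure(list(table = tab, metadata = md), class = "forecast_archive")
}

#' @export
print.forecast_archive <- function(x, ...) {
  cat(sprintf("<forecast_archive> %d forecasts, %d model(s), seed %s\n",
              nrow(x$table), length(unique(x$table$model)),
              x$metadata$seed))
  invisible(x)
}

#' Evaluate an archived forecast set against observations
#'
#' Joins the archive against a (possibly newly collected) richness
#' panel. Evaluation against years inside the archive's recorded
#' training period is refused unless `allow_insample = TRUE`.
#'
#' @param archive A \code{forecast_archive}.
#' @param observed Richness panel of realized values.
#' @param allow_insample Acknowledge in-sample evaluation explicitly.
#' @return A \code{metrics_table}.
#' @export
evaluate_archive <- function(archive, observed, allow_insample = FALSE) {
  stopifnot(inherits(archive, "forecast_archive"))
  ty <- archive$metadata$training_years
  insample <- observed$year >= ty[1] & observed$year <= ty[2]
  if (any(insample) && !allow_insample)
    stop("observations overlap the training period ", ty[1], "-", ty[2],
         "; pass allow_insample = TRUE to evaluate anyway", call. = FALSE)
  tab <- archive$table
  tab$horizon <- pmax(1L, tab$year - ty[2])
  class(tab) <- c("gaussian_forecast", "data.frame")
  metrics_table(tab, observed)
}

#' Serialize and restore fitted model objects
#'
#' Fitted forecaster objects (observer posteriors, forest sets, JSDM
#' fits, boosters) are wrapped with a format-version tag and the package
#' version, then written with R's native serialization.
#'
#' @param object Any fitted richcast model object.
#' @param path File path (conventionally `.rds`).
#' @return `save_model`: `path`, invisibly; `load_model`: the restored
#'   object.
#' @export
save_model <- function(object, path) {
  saveRDS(list(container_version = 1L,
               package_version =
                 as.character(utils::packageVersion("richcast")),
               class = class(object), object = object), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  wrap <- readRDS(path)
  if (!is.list(wrap) || is.null(wrap$container_version))
    stop("not a richcast model container", call. = FALSE)
  wrap$object
}
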