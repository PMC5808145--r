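# Simple base-graphics views of the verification output.

#' Plot verification metrics against forecast horizon
#'
#' One panel per metric (RMSE, 95% coverage, mean deviance), one line
#' per model/correction group, against horizon — the standard view of
#' how forecast quality decays with lead time.
#'
#' @param by_horizon A \code{metrics_table} from [metrics_by_horizon()].
#' @param file Optional PNG path; when `NULL`, draws on the active
#'   device.
#' @param width,height Device size in pixels.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_horizon_curves <- function(by_horizon, file = NULL,
                                width = 900, height = 360) {
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  grp <- interaction(by_horizon$model, by_horizon$corrected, drop = TRUE)
  cols <- stats::setNames(grDevices::hcl.colors(nlevels(grp), "Dark 3"),
                          levels(grp))
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  panels <- c(rmse = "RMSE (species)", coverage95 = "95% coverage",
              mean_deviance = "mean deviance")
  for (m in names(panels)) {
    graphics::plot(range(by_horizon$horizon), range(by_horizon[[m]]),
                   type = "n", xlab = "horizon (years)",
                   ylab = panels[m])
    if (m == "coverage95") graphics::abline(h = 0.95, lty = 2)
    for (g in levels(grp)) {
      d <- by_horizon[grp == g, ]
      graphics::lines(d$horizon, d[[m]], col = cols[g], lwd = 2)
    }
  }
  graphics::legend("bottomright", legend = levels(grp), col = cols,
                   lwd = 2, cex = 0.7, bty = "n")
  invisible(file)
}

#' Plot per-forecast skill distributions against the baseline
#'
#' Boxplots of the per-forecast error differences (model minus
#' baseline) from [skill_vs_baseline()]; the zero line is the
#' baseline's own error.
#'
#' @param skill Named list of [skill_vs_baseline()] results (one per
#'   model), as returned in `run_experiment()$skill`.
#' @param what Either "d_abs_error" or "d_deviance".
#' @param file Optional PNG path.
#' @param width,height Device size in pixels.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_skill_distributions <- function(skill, what = c("d_abs_error",
                                                     "d_deviance"),
                                     file = NULL, width = 700,
                                     height = 400) {
  what <- match.arg(what)
  if (!is.null(file)) {
    grDevices::png(file, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  vals <- lapply(skill, function(s) s$table[[what]])
  graphics::boxplot(vals, las = 2, cex.axis = 0.7,
                    ylab = paste("model - baseline,", what))
  graphics::abline(h = 0, lty = 2, col = "grey40")
  invisible(file)
}
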