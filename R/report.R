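# Summary tables and simple learning-curve rendering.

#' Summarize scenario results into impact tables and learning curves
#'
#' Writes one summary table per scenario kind present in `results` — an
#' experiment-by-AUROC table (baseline / drift / train-test group rows,
#' mean over replicate seeds) — plus `learning_curves.csv` for the
#' fraction-grid scenarios.
#'
#' @param results a [run_scenario()] result table (rows from several
#'   scenarios may be concatenated).
#' @param out_dir output directory.
#' @return invisibly, the list of written summary tables.
#' @export
report_results <- function(results, out_dir) {
  res <- data.table::as.data.table(results)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  for (kind in unique(res$scenario)) {
    r <- res[scenario == kind]
    if (kind %in% c("baseline", "drift", "population")) {
      tab <- r[, .(auroc = mean(auroc), sd = if (.N > 1) stats::sd(auroc)
                   else 0, n_test = round(mean(n_test))),
               by = .(experiment = ifelse(is.na(group), scenario, group))]
      f <- file.path(out_dir, sprintf("summary_%s.csv", kind))
      data.table::fwrite(tab, f)
      written[[kind]] <- tab
    } else {
      tab <- r[, .(mean_auroc = mean(auroc),
                   sd_auroc = if (.N > 1) stats::sd(auroc) else 0,
                   n_train = round(mean(n_train))),
               by = .(scenario, arm, fraction)][order(arm, fraction)]
      f <- file.path(out_dir, sprintf("learning_curves_%s.csv", kind))
      data.table::fwrite(tab, f)
      written[[kind]] <- tab
    }
  }
  invisible(written)
}

#' Plot a learning curve
#'
#' Base-graphics rendering of mean AUROC against training fraction with a
#' +/- 1 sd band.
#'
#' @param curve a [learning_curve()].
#' @param add draw into an existing plot?
#' @param col line colour.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot_learning_curve <- function(curve, add = FALSE, col = "steelblue",
                                ...) {
  x <- curve$fraction; y <- curve$mean_auroc; s <- curve$sd_auroc
  if (!add)
    graphics::plot(x, y, type = "n", xlab = "training fraction",
                   ylab = "AUROC", ylim = range(c(y - s, y + s)), ...)
  graphics::polygon(c(x, rev(x)), c(y - s, rev(y + s)), border = NA,
                    col = grDevices::adjustcolor(col, 0.2))
  graphics::lines(x, y, col = col, lwd = 2)
  graphics::points(x, y, col = col, pch = 16, cex = 0.7)
  invisible(curve)
}
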