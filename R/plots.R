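#' Plot Kaplan-Meier curves for score strata
#'
#' @param km_list named list of [km_estimate()] curves.
#' @param main plot title.
#' @export
plot_km <- function(km_list, main = "Progression-free survival") {
  cols <- c("firebrick", "steelblue", "darkgreen", "orange")
  xmax <- max(vapply(km_list, function(k) max(k$time), 0))
  plot(NA, xlim = c(0, xmax), ylim = c(0, 1), xlab = "Months",
       ylab = "Progression-free survival", main = main)
  for (i in seq_along(km_list)) {
    k <- km_list[[i]]
    graphics::lines(stats::stepfun(k$time, c(1, k$surv)),
                    col = cols[(i - 1L) %% length(cols) + 1L],
                    do.points = FALSE, lwd = 2)
  }
  graphics::legend("bottomleft", legend = names(km_list),
                   col = cols[seq_along(km_list)], lwd = 2, bty = "n")
  invisible(NULL)
}

#' Waterfall plot of per-sample activity scores
#'
#' Bars are sorted by decreasing score; optional group labels color the
#' bars.
#'
#' @param scores named numeric vector of per-sample scores for one set.
#' @param groups optional named group labels for coloring.
#' @param main plot title.
#' @export
plot_waterfall <- function(scores, groups = NULL,
                           main = "Activity score") {
  o <- order(scores, decreasing = TRUE)
  col <- "grey60"
  if (!is.null(groups)) {
    g <- factor(groups[names(scores)[o]])
    col <- c("firebrick", "steelblue", "darkgreen",
             "orange")[as.integer(g)]
  }
  graphics::barplot(scores[o], col = col, border = NA,
                    names.arg = rep("", length(scores)),
                    ylab = "Activity score", main = main)
  if (!is.null(groups))
    graphics::legend("topright", legend = levels(factor(groups)),
                     fill = c("firebrick", "steelblue", "darkgreen",
                              "orange")[seq_along(levels(factor(groups)))],
                     bty = "n")
  invisible(NULL)
}

# PNG renditions of the main figures for a pipeline run
render_plots <- function(res, config) {
  png_to <- function(name, expr) {
    grDevices::png(file.path(config$outdir, name), width = 900,
                   height = 600, res = 110)
    on.exit(grDevices::dev.off())
    expr
  }
  png_to("km.png", plot_km(res$survival$km))
  anchor_set <- res$scores$set[1L]
  s <- res$scores[res$scores$set == anchor_set, ]
  base <- res$survival$data
  sc <- stats::setNames(
    s$score[match(paste0(base$subject_id, "_",
                         res$cohort$sample_sheet$timepoint[1L]),
                  s$sample_id)], base$subject_id)
  png_to("waterfall.png",
         plot_waterfall(sc, stats::setNames(base$epigroup,
                                            base$subject_id),
                        main = paste("Activity score:", anchor_set)))
  if (!is.null(res$epigroups))
    png_to("pca.png", {
      plot(res$epigroups$pca[, 1:2],
           col = res$epigroups$labels, pch = 19,
           main = "PCA of DMG profiles")
    })
  invisible(NULL)
}
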