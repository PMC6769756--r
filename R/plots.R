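#' Plot ranked per-sample loads
#'
#' Horizontal bar chart of genome-wide loads sorted decreasingly,
#' colored by management group.
#'
#' @param loads Output of [compute_load()].
#' @param meta Sample metadata (`sample_id`, `group`).
#' @return Invisibly, the plotted order of sample ids.
#' @export
plot_loads <- function(loads, meta) {
  grp <- meta$group[match(loads$sample_id, meta$sample_id)]
  ord <- order(loads$load)
  cols <- setNames(seq_along(unique(grp)) + 1L, unique(grp))
  barplot(loads$load[ord], horiz = TRUE, border = NA,
          col = cols[grp[ord]], xlab = "mutational load",
          main = "per-genome mutational load")
  legend("bottomright", legend = names(cols), fill = cols, bty = "n")
  invisible(loads$sample_id[ord])
}

#' Plot frequency shifts per time interval
#'
#' Box plot of absolute allele-frequency changes between consecutive
#' non-overlapping bins, one box per interval (labelled by the younger
#' bin's center).
#'
#' @param delta Output of [delta_series()].
#' @return Invisibly, the per-interval medians.
#' @export
plot_delta <- function(delta) {
  if (nrow(delta) == 0L) stop("no frequency shifts to plot")
  delta$interval_center <- factor(delta$interval_center,
                                  levels = sort(unique(
                                    delta$interval_center),
                                    decreasing = TRUE))
  boxplot(delta_abs ~ interval_center, data = delta, outline = FALSE,
          xlab = "interval (younger bin center, years BP)",
          ylab = expression(abs(Delta ~ "frequency")),
          main = "allele-frequency shifts between time intervals")
  invisible(tapply(delta$delta_abs, delta$interval_center, median))
}
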