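#' @include AllClasses.R population.R
NULL

#' Shell histogram with SEM bars and significance markers
#'
#' Bar plot of a condition's mean normalized shell profile, shell 1 (nuclear
#' periphery) on the left through the innermost shell on the right, with SEM
#' error bars. If a shell-wise comparison is supplied, significant shells are
#' marked with a filled square above the bar.
#'
#' @param result a \code{\linkS4class{PopulationResult}}.
#' @param comparison optional \code{\link{compareShells}} table against a
#'   reference condition; its \code{significant} column drives the markers.
#' @param ylab y-axis label; the default names the plotted quantity (the
#'   mean probe/DAPI normalized proportion, a dimensionless ratio).
#' @param col bar colour.
#' @param ... passed to \code{\link[graphics]{barplot}}.
#' @return Invisibly, the bar midpoints.
#' @export
plotShellHistogram <- function(result, comparison = NULL,
                               ylab = "mean normalized proportion (probe/DAPI)",
                               col = "grey70", ...) {
  stopifnot(is(result, "PopulationResult"))
  m <- shellMeans(result)
  s <- shellSEM(result)
  ymax <- max(m + s) * 1.25
  mids <- graphics::barplot(m, names.arg = seq_along(m),
                            xlab = "shell (1 = nuclear periphery)",
                            ylab = ylab, ylim = c(0, ymax), col = col,
                            main = conditionName(result), ...)
  graphics::arrows(mids, m - s, mids, m + s, angle = 90, code = 3,
                   length = 0.04)
  if (!is.null(comparison)) {
    sig <- comparison$significant
    if (any(sig))
      graphics::points(mids[sig], (m + s)[sig] + 0.06 * ymax, pch = 15)
  }
  invisible(mids)
}

#' Overlay frequency-distribution curves
#'
#' Plots one \code{\link{frequencyCurve}} per condition on shared axes, the
#' conventional display for comparing territory-periphery distance
#' distributions across conditions.
#'
#' @param curves named list of \code{frequencyCurve} tables.
#' @param xlab,ylab axis labels.
#' @param col line colours, recycled.
#' @param ... passed to \code{\link[graphics]{matplot}} lines.
#' @return Invisibly \code{NULL}.
#' @export
plotFrequencyCurves <- function(curves,
                                xlab = "distance to nuclear periphery (um)",
                                ylab = "frequency",
                                col = seq_along(curves), ...) {
  stopifnot(length(curves) >= 1)
  xr <- range(unlist(lapply(curves, function(cv) cv$mid)))
  yr <- c(0, max(unlist(lapply(curves, function(cv) cv$frequency))))
  graphics::plot(NA, xlim = xr, ylim = yr, xlab = xlab, ylab = ylab)
  col <- rep_len(col, length(curves))
  for (i in seq_along(curves))
    graphics::lines(curves[[i]]$mid, curves[[i]]$frequency, col = col[i],
                    type = "o", pch = 16, cex = 0.6, ...)
  if (!is.null(names(curves)))
    graphics::legend("topright", legend = names(curves), col = col, lty = 1,
                     bty = "n")
  invisible(NULL)
}
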