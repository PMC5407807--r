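#' @include AllClasses.R AllGenerics.R
NULL

#' Forest plot of per-cohort estimates with a combined diamond
#'
#' @param studies `data.frame` with columns `study`, `beta`, `se`.
#' @param meta Optional [MetaResult-class] drawn as the combined row.
#' @param xlab X-axis label (units of the estimate).
#' @param main Plot title.
#' @return Invisibly, the plotted table with confidence limits.
#' @export
forestPlot <- function(studies, meta = NULL,
                       xlab = "Effect (SD per SD)", main = "") {
  stopifnot(all(c("study", "beta", "se") %in% colnames(studies)))
  df <- data.frame(study = as.character(studies$study),
                   beta = studies$beta, se = studies$se)
  df$lo <- df$beta - .Z95 * df$se
  df$hi <- df$beta + .Z95 * df$se
  k <- nrow(df)
  extra <- if (!is.null(meta)) 1 else 0
  ylim <- c(0.5, k + extra + 0.5)
  xlim <- range(c(df$lo, df$hi, 0,
                  if (!is.null(meta)) confInt(meta)))
  op <- graphics::par(mar = c(4, 9, if (nzchar(main)) 3 else 1, 2))
  on.exit(graphics::par(op))
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = xlab, ylab = "", main = main)
  graphics::abline(v = 0, lty = 2, col = "grey50")
  ys <- rev(seq_len(k)) + extra
  graphics::segments(df$lo, ys, df$hi, ys)
  graphics::points(df$beta, ys, pch = 15,
                   cex = 0.8 + 0.8 * (1 / df$se) / max(1 / df$se))
  graphics::axis(2, at = ys, labels = df$study, las = 1, tick = FALSE)
  if (!is.null(meta)) {
    ci <- confInt(meta)
    graphics::polygon(
      c(ci[1], estimate(meta), ci[2], estimate(meta)),
      c(1, 1.25, 1, 0.75), col = "grey30")
    graphics::axis(2, at = 1,
                   labels = sprintf("Combined (%s)", meta@model),
                   las = 1, tick = FALSE)
  }
  invisible(df)
}

#' Analytic IV power curve over a grid of true effects
#'
#' @param n Sample size.
#' @param r2 Instrument R-squared (may be a vector: one curve each).
#' @param betas Grid of true effects (SD per SD).
#' @param alpha Two-sided level.
#' @return Invisibly, the matrix of power values (betas x r2).
#' @export
powerCurve <- function(n, r2, betas = seq(0, 0.5, by = 0.01),
                       alpha = 0.05) {
  pw <- sapply(r2, function(r)
    vapply(betas, function(b) ivPower(n, r, b, alpha)@power, numeric(1)))
  pw <- matrix(pw, nrow = length(betas))
  graphics::matplot(betas, pw, type = "l", lty = 1, lwd = 2,
                    ylim = c(0, 1),
                    xlab = "True causal effect (SD per SD)",
                    ylab = "Power",
                    main = sprintf("Analytic IV power, n = %d", n))
  graphics::abline(h = 0.8, lty = 3, col = "grey50")
  graphics::legend("bottomright", lty = 1, lwd = 2,
                   col = seq_along(r2),
                   legend = sprintf("R² = %.1f%%", 100 * r2),
                   bty = "n")
  invisible(pw)
}
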