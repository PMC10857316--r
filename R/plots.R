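# Base-graphics displays: kappa-versus-duration sweep curves and the
# per-participant kappa distribution.

#' Plot an agreement sweep
#'
#' One panel per intensity set: kappa (median by default, matching the
#' usual presentation of these curves; or mean) against the required
#' active minutes m, with the stored confidence band as error bars.
#'
#' @param x an `agreement_sweep` data frame from [sweep_agreement()].
#' @param stat `"median"` (default) or `"mean"`.
#' @param ... further arguments passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.agreement_sweep <- function(x, stat = c("median", "mean"), ...) {
  stat <- match.arg(stat)
  ycol <- if (stat == "median") "median_kappa" else "mean_kappa"
  sets <- unique(x$intensity_set)
  old <- par(mfrow = c(1, length(sets)), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  ylim <- range(c(x$ci_low, x$ci_high, x[[ycol]]), na.rm = TRUE)
  for (s in sets) {
    d <- x[x$intensity_set == s, ]
    plot(d$m, d[[ycol]], type = "b", pch = 19, ylim = ylim,
         xlab = "required active minutes (m)",
         ylab = sprintf("%s kappa", stat), main = s, ...)
    ok <- !is.na(d$ci_low) & !is.na(d$ci_high) & d$ci_high > d$ci_low
    if (any(ok)) {
      arrows(d$m[ok], d$ci_low[ok], d$m[ok], d$ci_high[ok],
             angle = 90, code = 3, length = 0.03,
             col = adjustcolor("black", 0.5))
    }
  }
  invisible(x)
}

#' Plot the per-participant kappa distribution
#'
#' Histogram of defined per-participant kappas with the pooled kappa
#' marked.
#'
#' @param x an `ema_agreement` object.
#' @param ... passed to [hist()].
#' @return `x`, invisibly.
#' @export
plot.ema_agreement <- function(x, ...) {
  k <- x$per_participant$kappa
  k <- k[!is.na(k)]
  hist(k, breaks = "FD", xlab = "per-participant kappa",
       main = "Day-level agreement", ...)
  if (!x$pooled$undefined) {
    abline(v = x$pooled$kappa, lwd = 2, lty = 2)
    legend("topright", legend = sprintf("pooled = %.2f", x$pooled$kappa),
           lty = 2, lwd = 2, bty = "n")
  }
  invisible(x)
}
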