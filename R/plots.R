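# Diagnostic plots for evaluation reports.

#' Inferred-VAF spectrum with ground-truth overlay
#'
#' Histogram of the inferred allele frequencies of PASS calls with the
#' ground-truth frequency distribution overlaid, visualizing dispersion and
#' the conditional detection bias.
#'
#' @param matched a [match_calls()] result.
#' @param breaks histogram breaks (default semi-centiles over `[0, 1]`).
#' @param main plot title.
#' @return invisibly, the histogram object.
#' @export
plot_vaf_spectrum <- function(matched, breaks = seq(0, 1, by = 0.005),
                              main = "Inferred vs true VAF spectrum") {
  t <- matched$truth
  inf <- t$inferred_vaf[t$class == "TP" & !is.na(t$inferred_vaf)]
  truef <- t$true_f
  h_true <- hist(truef, breaks = breaks, plot = FALSE)
  h_inf <- if (length(inf)) hist(inf, breaks = breaks, plot = FALSE) else
    NULL
  ylim <- c(0, max(h_true$counts, if (!is.null(h_inf)) h_inf$counts else 0))
  plot(h_true, col = rgb(0.6, 0.6, 0.6, 0.5), border = NA, ylim = ylim,
       main = main, xlab = "allele frequency")
  if (!is.null(h_inf))
    plot(h_inf, col = rgb(0.8, 0.2, 0.2, 0.5), border = NA, add = TRUE)
  legend("topright", fill = c(rgb(0.6, 0.6, 0.6, 0.5),
                              rgb(0.8, 0.2, 0.2, 0.5)),
         legend = c("ground truth", "inferred (PASS)"), bty = "n")
  invisible(h_inf)
}

#' Detection-rate curve over true-frequency bins
#'
#' @param dm a [detection_matrix()] result.
#' @param n_bins number of bins used (for the x axis).
#' @param ... passed to [plot()].
#' @return invisibly, the per-bin rates.
#' @export
plot_detection_rate <- function(dm, n_bins = length(dm$rate), ...) {
  mid <- (seq_len(n_bins) - 0.5) * 0.5 / n_bins
  plot(mid, dm$rate, type = "b", pch = 16, xlab = "true allele frequency",
       ylab = "detection rate", ylim = c(0, 1), ...)
  invisible(dm$rate)
}
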