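# Ground-truth somatic allele-frequency spectra.
#
# The neutral-evolution subclonal spectrum has cumulative mutation count
# proportional to 1/f; restricted to [f_min, f_max] its CDF is
#   F(f) = (1/f_min - 1/f) / (1/f_min - 1/f_max),
# inverted as f(u) = 1 / (1/f_min - u * (1/f_min - 1/f_max)).

#' Sample subclonal allele frequencies under the neutral-evolution model
#'
#' Draws i.i.d. frequencies with density proportional to 1/f^2 on
#' `[f_min, f_max]` (cumulative count proportional to 1/f) by inverse-CDF
#' sampling.
#'
#' @param n number of draws.
#' @param f_min,f_max frequency bounds, `0 < f_min < f_max <= 1`.
#'   Defaults 0.01 and 0.25, the subclonal range of a diploid tumour at
#'   full purity.
#' @return numeric vector of length `n` in `[f_min, f_max]`.
#' @export
#' @examples
#' set.seed(1); summary(sample_neutral(1000))
sample_neutral <- function(n, f_min = 0.01, f_max = 0.25) {
  if (!(f_min > 0 && f_min < f_max && f_max <= 1))
    stopf("invalid neutral bounds: f_min=%g f_max=%g", f_min, f_max)
  if (n == 0) return(numeric(0))
  u <- runif(n)
  1 / (1 / f_min - u * (1 / f_min - 1 / f_max))
}

#' Analytic CDF of the truncated neutral spectrum
#' @inheritParams sample_neutral
#' @param f frequencies at which to evaluate.
#' @return CDF values in `[0, 1]`.
#' @export
neutral_cdf <- function(f, f_min = 0.01, f_max = 0.25) {
  pmin(1, pmax(0, (1 / f_min - 1 / f) / (1 / f_min - 1 / f_max)))
}

#' Specify a ground-truth somatic frequency spectrum
#'
#' @param kind `"neutral"` (1/f subclonal tail plus an optional clonal point
#'   mass at `clonal_f`), `"point_mass"` (all variants at `f0`) or
#'   `"uniform_bins"` (per-bin uniform draws, e.g. semi-centiles).
#' @param n_total total variant count (ignored for `uniform_bins`, where
#'   the per-bin counts decide).
#' @param f_min,f_max neutral subclonal bounds.
#' @param clonal_f,n_clonal clonal frequency (0.5 for a diploid tumour at
#'   100% purity) and clonal variant count.
#' @param f0 point-mass frequency.
#' @param bins data.frame with columns `lo`, `hi`, `n` (half-open
#'   `[lo, hi)` bins); see [semi_centile_bins()].
#' @param purity tumour purity in `[0, 1]`; scales all frequencies.
#' @return object of class `spectrum_spec`.
#' @export
spectrum_spec <- function(kind = c("neutral", "point_mass", "uniform_bins"),
                          n_total = 0L, f_min = 0.01, f_max = 0.25,
                          clonal_f = 0.5, n_clonal = 0L, f0 = 0.035,
                          bins = NULL, purity = 1) {
  kind <- match.arg(kind)
  stopifnot(purity >= 0, purity <= 1, n_total >= 0, n_clonal >= 0)
  if (kind == "neutral") {
    if (!(f_min > 0 && f_min < f_max && f_max <= 1))
      stopf("invalid neutral bounds")
    if (n_clonal > n_total) stopf("n_clonal exceeds n_total")
  }
  if (kind == "uniform_bins") {
    stopifnot(is.data.frame(bins), all(c("lo", "hi", "n") %in% names(bins)))
    if (any(bins$lo < 0 | bins$hi > 1 | bins$hi <= bins$lo | bins$n < 0))
      stopf("invalid uniform bins")
  }
  structure(list(kind = kind, n_total = as.integer(n_total), f_min = f_min,
                 f_max = f_max, clonal_f = clonal_f,
                 n_clonal = as.integer(n_clonal), f0 = f0, bins = bins,
                 purity = purity),
            class = "spectrum_spec")
}

#' Semi-centile frequency bins
#'
#' Partitions the lower half of the frequency range, `(0, 0.5]`, into 100
#' half-open bins `[(i-1)/200, i/200)`; the variant count `n` is per bin.
#'
#' @param i bin indices in 1..100 (default all).
#' @param n variants per bin.
#' @return data.frame with columns `lo`, `hi`, `n`.
#' @export
semi_centile_bins <- function(i = 1:100, n = 0L) {
  stopifnot(all(i >= 1 & i <= 100))
  data.frame(lo = (i - 1) / 200, hi = i / 200, n = as.integer(n))
}

#' Draw a ground-truth somatic burden from a spectrum specification
#'
#' @param spec a [spectrum_spec()].
#' @param seed optional RNG seed.
#' @return numeric vector of true allele frequencies (already scaled by
#'   purity).
#' @export
#' @examples
#' make_burden(spectrum_spec("point_mass", n_total = 5, f0 = 0.035))
make_burden <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "spectrum_spec"))
  maybe_seed(seed)
  f <- switch(spec$kind,
    neutral = c(rep(spec$clonal_f, spec$n_clonal),
                sample_neutral(spec$n_total - spec$n_clonal,
                               spec$f_min, spec$f_max)),
    point_mass = rep(spec$f0, spec$n_total),
    uniform_bins = {
      b <- spec$bins
      unlist(lapply(seq_len(nrow(b)), function(i) {
        # [lo, hi) half-open; a zero lower edge is nudged off 0
        runif(b$n[i], min = max(b$lo[i], 1e-12), max = b$hi[i])
      }), use.names = FALSE)
    })
  f * spec$purity
}

#' Ground-truth tumour mutation burden
#'
#' TMB is the number of somatic SNVs per megabase with frequency at or above
#' a threshold (0.05 by convention).
#'
#' @param frequencies vector of (true or inferred) allele frequencies.
#' @param threshold inclusion threshold on frequency; default 0.05.
#' @param target_mb target size in megabases; must be positive.
#' @return mutations per megabase (unrounded; the print convention is one
#'   decimal, see examples).
#' @export
#' @examples
#' round_half_up(true_tmb(rep(0.1, 645), target_mb = 76), 1)  # 8.5
true_tmb <- function(frequencies, threshold = 0.05, target_mb) {
  if (target_mb <= 0) stopf("target_mb must be positive")
  sum(frequencies >= threshold) / target_mb
}

#' @export
print.spectrum_spec <- function(x, ...) {
  cat("spectrum_spec:", x$kind)
  if (x$kind == "neutral")
    cat(sprintf(" (n=%d incl. %d clonal at %.3g, subclonal 1/f on [%g, %g])",
                x$n_total, x$n_clonal, x$clonal_f, x$f_min, x$f_max))
  if (x$kind == "point_mass")
    cat(sprintf(" (n=%d at f0=%g)", x$n_total, x$f0))
  if (x$kind == "uniform_bins")
    cat(sprintf(" (%d bins, %d variants)", nrow(x$bins), sum(x$bins$n)))
  cat(sprintf(", purity %g\n", x$purity))
  invisible(x)
}
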