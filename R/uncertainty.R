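#' @title Measurement-uncertainty budget
#' @name uncertainty
#' @description Combined complex measurement uncertainty from pre/post
#'   validation sweeps on a reference liquid, decomposed into random,
#'   systematic and drift components, each tracked separately for the real
#'   and imaginary permittivity parts; plus the non-overlapping-error-bar
#'   significance check used to compare measurements.
NULL

#' Combined complex uncertainty from a validation pair
#'
#' Standard root-sum-of-squares uncertainty budget at the permittivity level,
#' per frequency and separately for the real and imaginary parts:
#' * random: pooled sample standard deviation across all validation sweeps
#'   (pre and post together);
#' * systematic: absolute deviation of the grand mean of all validation
#'   sweeps from the reference-liquid model evaluation;
#' * drift: absolute difference between the post-run and pre-run means;
#' * combined: `sqrt(random^2 + systematic^2 + drift^2)`.
#'
#' @param pair A [validation_pair()]. A nonzero random component requires at
#'   least two sweeps in total.
#' @return An object of class `uncertainty_estimate`: a list with
#'   `frequencies` and data.frames `real`/`imag`, each holding per-frequency
#'   columns `random`, `systematic`, `drift`, `s_comb`.
#' @examples
#' ref <- cole_cole_model(5, 1, list(), "reference")
#' vp <- generate_validation_sweeps(ref, n_pre = 3, n_post = 3,
#'                                  noise_sd = 0, drift_offset = 0.3,
#'                                  frequencies = seq(1e9, 1e10, 1e8), seed = 1)
#' u <- combined_uncertainty(vp)
#' max(u$real$drift) # 0.3
#' @export
combined_uncertainty <- function(pair) {
  stopifnot(inherits(pair, "validation_pair"))
  f0 <- pair$pre_sweeps[[1]]$frequencies
  sweeps <- c(pair$pre_sweeps, pair$post_sweeps)
  n_pre <- length(pair$pre_sweeps)
  re_mat <- vapply(sweeps, `[[`, numeric(length(f0)), "eps_real")
  im_mat <- vapply(sweeps, `[[`, numeric(length(f0)), "eps_imag")
  re_mat <- matrix(re_mat, nrow = length(f0))
  im_mat <- matrix(im_mat, nrow = length(f0))
  ref <- evaluate_permittivity(pair$reference, f0)
  budget <- function(mat, ref_part) {
    random <- if (ncol(mat) >= 2L) apply(mat, 1, stats::sd) else rep(0, nrow(mat))
    systematic <- abs(rowMeans(mat) - ref_part)
    drift <- abs(rowMeans(mat[, n_pre + seq_len(ncol(mat) - n_pre), drop = FALSE]) -
                   rowMeans(mat[, seq_len(n_pre), drop = FALSE]))
    data.frame(random = random, systematic = systematic, drift = drift,
               s_comb = sqrt(random^2 + systematic^2 + drift^2))
  }
  structure(
    list(frequencies = f0,
         real = budget(re_mat, Re(ref)),
         imag = budget(im_mat, -Im(ref))),
    class = "uncertainty_estimate"
  )
}

#' @export
print.uncertainty_estimate <- function(x, ...) {
  cat(sprintf("Uncertainty budget over %d frequencies (%.3g-%.3g GHz)\n",
              length(x$frequencies), min(x$frequencies) / 1e9,
              max(x$frequencies) / 1e9))
  cat(sprintf("  s_comb (real): median %.3g, max %.3g\n",
              stats::median(x$real$s_comb), max(x$real$s_comb)))
  cat(sprintf("  s_comb (imag): median %.3g, max %.3g\n",
              stats::median(x$imag$s_comb), max(x$imag$s_comb)))
  invisible(x)
}

#' Per-frequency significance by non-overlapping error bars
#'
#' Two measurements with +/- 1 s_comb error bars are called significantly
#' different at a frequency when the bars do not overlap:
#' `|mean1 - mean2| > s1 + s2`. Touching bars do not count.
#'
#' @param mean1,mean2 Per-frequency means on a shared grid.
#' @param s1,s2 Corresponding uncertainty half-widths (>= 0).
#' @return Logical vector, `TRUE` where the difference is significant.
#' @export
significant_difference <- function(mean1, s1, mean2, s2) {
  n <- length(mean1)
  stopifnot(length(s1) == n, length(mean2) == n, length(s2) == n)
  abs(mean1 - mean2) > (s1 + s2)
}

#' Export an uncertainty estimate as CSV
#'
#' Columns: `frequency_Hz, random_re, random_im, systematic_re,
#' systematic_im, drift_re, drift_im, scomb_re, scomb_im`.
#'
#' @param estimate An `uncertainty_estimate`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_uncertainty_csv <- function(estimate, path) {
  stopifnot(inherits(estimate, "uncertainty_estimate"))
  tab <- data.frame(
    frequency_Hz = estimate$frequencies,
    random_re = estimate$real$random, random_im = estimate$imag$random,
    systematic_re = estimate$real$systematic,
    systematic_im = estimate$imag$systematic,
    drift_re = estimate$real$drift, drift_im = estimate$imag$drift,
    scomb_re = estimate$real$s_comb, scomb_im = estimate$imag$s_comb
  )
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
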