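#' Per-channel linear correlation of two electrodograms
#'
#' Computes the Pearson correlation between corresponding channels of two
#' electrodograms (inactive entries counted as zero stimulation) and the
#' arithmetic mean across channels, the standard global similarity measure
#' for comparing processing pipelines against a reference strategy.
#'
#' Zero-variance channels (e.g. electrodes never selected by N-of-M) have
#' no defined Pearson correlation: they are excluded from the mean and
#' reported as `NA`, with `n_defined` giving the count that entered the
#' mean. Two constant and equal channels are scored 1 (identical streams);
#' a constant channel against a varying one is undefined.
#'
#' @param Ea,Eb `electrodogram`s of identical shape and frame rate.
#' @return an object of class `lcc_result`: list with `per_channel`
#'   (length-M vector, `NA` = undefined), `mean`, and `n_defined`.
#' @export
lcc_per_channel <- function(Ea, Eb) {
  stopifnot(inherits(Ea, "electrodogram"), inherits(Eb, "electrodogram"))
  if (!all(dim(Ea$values) == dim(Eb$values))) stop("lcc_per_channel: shape mismatch")
  if (!isTRUE(all.equal(Ea$frame_rate, Eb$frame_rate, tolerance = 1e-6)))
    stop("lcc_per_channel: frame_rate mismatch")
  A <- Ea$values; A[is.na(A)] <- 0
  B <- Eb$values; B[is.na(B)] <- 0
  M <- ncol(A)
  r <- vapply(seq_len(M), function(m) {
    a <- A[, m]; b <- B[, m]
    va <- stats::var(a); vb <- stats::var(b)
    if (va == 0 && vb == 0) {
      if (isTRUE(all.equal(a, b))) 1 else NA_real_
    } else if (va == 0 || vb == 0) {
      NA_real_
    } else if (all(a == b)) {
      1                         # identical streams: exactly 1, no FP round-off
    } else {
      stats::cor(a, b)
    }
  }, numeric(1))
  defined <- !is.na(r)
  structure(list(per_channel = r,
                 mean = if (any(defined)) mean(r[defined]) else NA_real_,
                 n_defined = sum(defined)),
            class = "lcc_result")
}

#' @export
print.lcc_result <- function(x, ...) {
  cat(sprintf("<lcc_result> mean r = %.5f over %d defined channel(s) of %d\n",
              x$mean, x$n_defined, length(x$per_channel)))
  invisible(x)
}

#' Scale-invariant signal-to-noise ratio
#'
#' The projection-based separation quality measure used both as a training
#' loss and for evaluation. Both signals are made zero-mean; the estimate
#' is decomposed into its projection onto the reference (`s_target`) and
#' the residual (`e_noise`); the result is
#' `10 * log10(||s_target||^2 / ||e_noise||^2)`, invariant to positive
#' rescaling of the estimate, clamped at `ceiling_db` for (near-)exact
#' reconstructions.
#'
#' @param estimate,reference equally long `audio_track`s; the reference
#'   must have nonzero energy after mean removal.
#' @param ceiling_db clamp for perfect reconstruction (default 60 dB).
#' @return SI-SNR in dB (scalar).
#' @export
si_snr <- function(estimate, reference, ceiling_db = 60) {
  assert_track(estimate, "estimate"); assert_track(reference, "reference")
  if (length(estimate$samples) != length(reference$samples)) stop("si_snr: length mismatch")
  e <- estimate$samples - mean(estimate$samples)
  s <- reference$samples - mean(reference$samples)
  es <- sum(s^2)
  if (es == 0) stop("si_snr: reference has zero energy")
  alpha <- sum(e * s) / es
  st <- alpha * s
  en <- e - st
  num <- sum(st^2); den <- sum(en^2)
  if (den == 0 || num / den > 10^(ceiling_db / 10)) return(ceiling_db)
  10 * log10(num / den)
}
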