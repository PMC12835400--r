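#' Ratio report constructor (internal)
#'
#' Wraps a decibel energy ratio with its domain and the quantity it
#' instantiates (vocals-to-instruments or signal-to-interference
#' enhancement, front-end `-F` / end-to-end `-E`, or the cross-domain
#' equivalence ratio `VIR_eqi`). Degenerate zero-energy denominators are
#' flagged infinite rather than raising.
#'
#' @param value_db decibels (may be `Inf`).
#' @param domain_tag `"time"` or `"electrodogram"`.
#' @param equation_tag one of `"VIR_Enh-F"`, `"SIR_Enh-F"`, `"VIR_Enh-E"`,
#'   `"SIR_Enh-E"`, `"VIR_eqi"`, or `"ratio"`.
#' @return an object of class `ratio_report`.
#' @keywords internal
ratio_report <- function(value_db, domain_tag, equation_tag = "ratio") {
  tags <- c("VIR_Enh-F", "SIR_Enh-F", "VIR_Enh-E", "SIR_Enh-E", "VIR_eqi", "ratio")
  if (!equation_tag %in% tags) stop("ratio_report: unknown equation_tag")
  structure(list(value_db = value_db, domain_tag = domain_tag,
                 equation_tag = equation_tag, infinite = is.infinite(value_db)),
            class = "ratio_report")
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf("<%s, %s domain> %s dB\n", x$equation_tag, x$domain_tag,
              if (x$infinite) "Inf (zero-energy denominator)" else sprintf("%.4f", x$value_db)))
  invisible(x)
}

#' Time-domain energy ratio in dB
#'
#' `10 * log10(sum(a^2) / sum(b^2))` over the full tracks (no trimming or
#' weighting). With the separated vocals and instruments as arguments this
#' is the vocals-to-instruments enhancement; with target speech and
#' interferer it is the signal-to-interference enhancement.
#'
#' @param a,b equally long `audio_track`s (numerator, denominator).
#' @param tag equation tag recorded in the report (default `"ratio"`).
#' @return a `ratio_report` (time domain); infinite flag when `b` has zero
#'   energy.
#' @export
energy_ratio_db <- function(a, b, tag = "ratio") {
  assert_track(a, "a"); assert_track(b, "b")
  if (length(a$samples) != length(b$samples)) stop("energy_ratio_db: length mismatch")
  ea <- sum(a$samples^2); eb <- sum(b$samples^2)
  val <- if (eb == 0) Inf else 10 * log10(ea / eb)
  ratio_report(val, "time", tag)
}

#' Electrodogram-domain energy ratio in dB
#'
#' `10 * log10` of the ratio of summed squared stimulation magnitudes over
#' all frames and electrodes; inactive entries contribute zero energy.
#'
#' @param Ea,Eb `electrodogram`s with matching shape, frame rate and domain.
#' @param tag equation tag recorded in the report.
#' @return a `ratio_report` (electrodogram domain).
#' @export
electrodogram_ratio_db <- function(Ea, Eb, tag = "ratio") {
  stopifnot(inherits(Ea, "electrodogram"), inherits(Eb, "electrodogram"))
  if (!all(dim(Ea$values) == dim(Eb$values)))
    stop("electrodogram_ratio_db: shape mismatch")
  if (!isTRUE(all.equal(Ea$frame_rate, Eb$frame_rate, tolerance = 1e-6)) ||
      Ea$domain_tag != Eb$domain_tag)
    stop("electrodogram_ratio_db: frame_rate/domain_tag mismatch")
  ea <- sum(Ea$values^2, na.rm = TRUE)
  eb <- sum(Eb$values^2, na.rm = TRUE)
  val <- if (eb == 0) Inf else 10 * log10(ea / eb)
  ratio_report(val, "electrodogram", tag)
}

#' Equivalent end-to-end enhancement of a separated pair
#'
#' Encodes the separated vocals and instruments tracks independently with
#' the ACE strategy and returns the electrodogram-domain energy ratio of
#' the two electrodograms. Because the strategy is nonlinear (LGF,
#' N-of-M), this ratio is not equal to the time-domain ratio of the inputs;
#' it is the quantity that makes front-end and end-to-end enhancement
#' magnitudes comparable.
#'
#' @param v_sep,i_sep separated vocals / instruments `audio_track`s of
#'   equal length.
#' @param cfg an [ace_config()].
#' @return a `ratio_report` tagged `"VIR_eqi"`.
#' @export
vir_eqi <- function(v_sep, i_sep, cfg = ace_config()) {
  assert_track(v_sep, "v_sep"); assert_track(i_sep, "i_sep")
  if (length(v_sep$samples) != length(i_sep$samples)) stop("vir_eqi: length mismatch")
  Ev <- encode_ace(v_sep, cfg)
  Ei <- encode_ace(i_sep, cfg)
  r <- electrodogram_ratio_db(Ev, Ei, tag = "ratio")
  ratio_report(r$value_db, "electrodogram", "VIR_eqi")
}

#' Split a total dB gain symmetrically across target and interferer
#'
#' Applies `+total_db/2` to the target and `-total_db/2` to the interferer
#' (amplitude factors `10^(+-total_db/40)`), the convention under which a
#' 6 dB vocals-to-instruments enhancement is realized as a 3 dB gain on
#' the vocals and a 3 dB attenuation on the instruments, approximately
#' preserving overall mixture level. The pairwise energy ratio shifts by
#' exactly `total_db`.
#'
#' @param target,interferer `audio_track`s.
#' @param total_db total relative gain in dB (finite).
#' @return list with elements `target` and `interferer` (scaled tracks).
#' @export
apply_split_gain <- function(target, interferer, total_db) {
  assert_track(target, "target"); assert_track(interferer, "interferer")
  if (!is.finite(total_db)) stop("apply_split_gain: total_db must be finite")
  g <- 10^(total_db / 40)
  list(target = track_scale(target, g),
       interferer = track_scale(interferer, 1 / g))
}

# interferer rescaled so energy_ratio_db(target, out) == ratio_db
scale_to_ratio <- function(target, interferer, ratio_db) {
  et <- sum(target$samples^2); ei <- sum(interferer$samples^2)
  if (ei == 0) stop("mix_at_ratio: interferer has zero energy")
  s <- sqrt(et / ei) * 10^(-ratio_db / 20)
  track_scale(interferer, s)
}

#' Mix a target and interferer at a prescribed energy ratio
#'
#' Rescales the interferer so that the target-to-interferer energy ratio
#' equals `ratio_db`, then sums; the target is left unscaled. A `-Inf`
#' ratio is the degenerate "target alone" convention.
#'
#' @param target,interferer equally long `audio_track`s.
#' @param ratio_db desired ratio in dB (`-Inf` for target alone).
#' @return mixture `audio_track`; the scaled interferer is available as
#'   attribute `"components"` (list of target and scaled interferer).
#' @export
mix_at_ratio <- function(target, interferer, ratio_db) {
  assert_track(target, "target"); assert_track(interferer, "interferer")
  if (length(target$samples) != length(interferer$samples))
    stop("mix_at_ratio: length mismatch")
  if (identical(ratio_db, -Inf)) {
    mix <- audio_track(target$samples, target$rate, "mixture")
    attr(mix, "components") <- list(target = target,
                                    interferer = track_scale(interferer, 0))
    return(mix)
  }
  if (!is.finite(ratio_db)) stop("mix_at_ratio: ratio_db must be finite or -Inf")
  si <- scale_to_ratio(target, interferer, ratio_db)
  mix <- track_sum(target, si, "mixture")
  attr(mix, "components") <- list(target = target, interferer = si)
  mix
}

#' Front-end vs end-to-end enhancement equivalence table
#'
#' For each front-end gain step `g`, applies the split gain to the
#' separated pair and computes the equivalent end-to-end enhancement
#' ([vir_eqi()]) of the gained pair. Because the LGF compresses dynamics,
#' equal front-end increments map to smaller end-to-end increments when the
#' full nonlinear strategy is active; with the linear-bypass configuration
#' the end-to-end column equals the front-end steps plus a constant.
#'
#' @param v_sep,i_sep separated vocals / instruments `audio_track`s.
#' @param front_steps strictly increasing front-end gains in dB.
#' @param cfg an [ace_config()].
#' @return data frame of class `equivalence_table` with columns
#'   `front_end_db`, `end_to_end_db`.
#' @export
build_equivalence_table <- function(v_sep, i_sep, front_steps = 0:8,
                                    cfg = ace_config()) {
  if (is.unsorted(front_steps, strictly = TRUE))
    stop("build_equivalence_table: front_steps must be strictly increasing")
  ee <- vapply(front_steps, function(g) {
    pair <- apply_split_gain(v_sep, i_sep, g)
    vir_eqi(pair$target, pair$interferer, cfg)$value_db
  }, numeric(1))
  structure(data.frame(front_end_db = front_steps, end_to_end_db = ee),
            class = c("equivalence_table", "data.frame"))
}

#' @export
print.equivalence_table <- function(x, ...) {
  cat("Front-end vs equivalent end-to-end enhancement (dB):\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}
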