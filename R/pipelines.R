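stop_config <- function(...) {
  stop(structure(class = c("cisep_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("cisep_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Pipeline configuration
#'
#' Ties a sound-coding strategy, a separation stage and an enhancement
#' setting into a runnable processing pipeline.
#'
#' The separation stage is either
#' `list(type = "model", model = <tasnet_model>)` /
#' `list(type = "model", checkpoint = "<path>")`, or
#' `list(type = "oracle", sources = list(target, interferer))` where the
#' ground-truth sources are injected (used for pipeline-consistency
#' checks). The enhancement stage is
#' `list(tag = "VIR"|"SIR", gain_db = <dB>, domain = "time"|"electrodogram")`;
#' the front-end pipeline requires the `"time"` domain and the end-to-end
#' pipeline the `"electrodogram"` domain.
#'
#' @param strategy an [ace_config()].
#' @param separation separation stage descriptor (above).
#' @param enhancement enhancement descriptor (above).
#' @param seed integer seed recorded in manifests.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(strategy = ace_config(),
                            separation = list(type = "oracle", sources = NULL),
                            enhancement = list(tag = "VIR", gain_db = 0,
                                               domain = "time"),
                            seed = 1) {
  if (!inherits(strategy, "ace_config")) stop_config("strategy must be an ace_config")
  if (!separation$type %in% c("model", "oracle"))
    stop_config("separation$type must be 'model' or 'oracle'")
  if (separation$type == "model" && is.null(separation$model)) {
    if (is.null(separation$checkpoint))
      stop_config("model separation needs a 'model' or 'checkpoint'")
    if (!file.exists(separation$checkpoint))
      stop_config("separator checkpoint not found: ", separation$checkpoint)
  }
  if (!enhancement$domain %in% c("time", "electrodogram"))
    stop_config("enhancement$domain must be 'time' or 'electrodogram'")
  if (!enhancement$tag %in% c("VIR", "SIR"))
    stop_config("enhancement$tag must be 'VIR' or 'SIR'")
  if (!is.finite(enhancement$gain_db)) stop_config("enhancement$gain_db must be finite")
  structure(list(strategy = strategy, separation = separation,
                 enhancement = enhancement, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(x) fnv1a(serialize(x, NULL, version = 2))

pipeline_manifest <- function(cfg, extra = list()) {
  c(list(config_hash = config_hash(unclass(cfg)), seed = cfg$seed,
         package = "cisep",
         version = as.character(utils::packageVersion("cisep"))),
    extra)
}

resolve_time_sources <- function(mixture, cfg) {
  sep <- cfg$separation
  if (sep$type == "oracle") {
    if (is.null(sep$sources) || length(sep$sources) < 2L)
      stop_config("oracle separation needs two ground-truth sources")
    sep$sources[1:2]
  } else {
    model <- if (!is.null(sep$model)) sep$model else load_separator(sep$checkpoint)
    if (model$cfg$output_domain != "time")
      stop_config("front-end pipeline needs a time-domain separator")
    separate(model, mixture, rate = cfg$strategy$fs)$sources[1:2]
  }
}

#' Run the front-end (audio-domain) pipeline
#'
#' Separation at the most upstream stage: the mixture is split into target
#' and interferer tracks, the split gain is applied in the time domain,
#' the remix is summed and encoded with the ACE strategy. With an oracle
#' separator and 0 dB gain the output electrodogram equals that of the
#' plain strategy on the mixture.
#'
#' @param mixture an `audio_track`.
#' @param cfg a [pipeline_config()] with `enhancement$domain = "time"`.
#' @return list with `electrodogram`, `separated` (gained tracks),
#'   `remix`, `ratio` (time-domain `ratio_report` of the gained pair) and
#'   `manifest`.
#' @export
run_front_end_pipeline <- function(mixture, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  assert_track(mixture)
  if (cfg$enhancement$domain != "time")
    stop_config("front-end pipeline requires enhancement domain 'time'")
  src <- resolve_time_sources(mixture, cfg)
  gained <- apply_split_gain(src[[1L]], src[[2L]], cfg$enhancement$gain_db)
  remix <- track_sum(gained$target, gained$interferer, "remix")
  tag <- paste0(cfg$enhancement$tag, "_Enh-F")
  ratio <- energy_ratio_db(gained$target, gained$interferer, tag = tag)
  elec <- encode_ace(remix, cfg$strategy)
  list(electrodogram = elec, separated = gained, remix = remix, ratio = ratio,
       manifest = pipeline_manifest(cfg, list(pipeline = "front_end",
                                              gain_db = cfg$enhancement$gain_db)))
}

# Oracle LGF streams: split the mixture's LGF magnitudes between the two
# sources by their band-envelope energy fractions (root-Wiener weights),
# so the root-sum-square recombination reconstructs the mixture's LGF
# exactly.
oracle_lgf_streams <- function(mixture, sources, strategy) {
  enc_cfg <- strategy
  enc_cfg$bypass_nofm <- TRUE
  enc_cfg$output <- "lgf"
  Emix <- encode_ace(mixture, enc_cfg)
  env <- lapply(sources[1:2], function(s)
    band_envelopes(analysis_filterbank(apply_agc(s, strategy$agc), strategy), strategy))
  p1 <- env[[1L]]^2
  tot <- p1 + env[[2L]]^2
  w1 <- ifelse(tot > 0, p1 / tot, 0.5)
  mk <- function(w) {
    v <- Emix$values * sqrt(w)
    electrodogram(v, Emix$frame_rate, "lgf", N = strategy$M)
  }
  list(mk(w1), mk(1 - w1))
}

resolve_lgf_streams <- function(mixture, cfg) {
  sep <- cfg$separation
  if (sep$type == "oracle") {
    if (is.null(sep$sources) || length(sep$sources) < 2L)
      stop_config("oracle separation needs two ground-truth sources")
    oracle_lgf_streams(mixture, sep$sources, cfg$strategy)
  } else {
    model <- if (!is.null(sep$model)) sep$model else load_separator(sep$checkpoint)
    if (model$cfg$output_domain != "lgf")
      stop_config("end-to-end pipeline needs an lgf-domain separator")
    separate(model, mixture, rate = cfg$strategy$fs)$sources[1:2]
  }
}

# scale electrodogram magnitudes by an energy gain of g dB (amplitude
# factor 10^(g/40) on the ratio split convention used throughout)
scale_lgf_stream <- function(e, amp) {
  electrodogram(e$values * amp, e$frame_rate, e$domain_tag, e$N)
}

#' Run the end-to-end (electrodogram-domain) pipeline
#'
#' Separation at the most downstream stage: per-source LGF magnitude
#' streams are obtained (from an LGF-domain separator or the oracle), the
#' split gain is applied to the streams' magnitudes (`+-total/2` dB on
#' their energies), the streams are recombined by root-sum-square, clipped
#' to `[0, 1]`, and the strategy's N-of-M selection and optional subject
#' mapping are applied.
#'
#' @param mixture an `audio_track`.
#' @param cfg a [pipeline_config()] with
#'   `enhancement$domain = "electrodogram"`.
#' @return list with `electrodogram`, `streams` (gained per-source LGF
#'   streams), `ratio` (electrodogram-domain `ratio_report` of the gained
#'   streams) and `manifest`.
#' @export
run_end_to_end_pipeline <- function(mixture, cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  assert_track(mixture)
  if (cfg$enhancement$domain != "electrodogram")
    stop_config("end-to-end pipeline requires enhancement domain 'electrodogram'")
  streams <- resolve_lgf_streams(mixture, cfg)
  g <- cfg$enhancement$gain_db
  gained <- list(scale_lgf_stream(streams[[1L]], 10^(g / 40)),
                 scale_lgf_stream(streams[[2L]], 10^(-g / 40)))
  tag <- paste0(cfg$enhancement$tag, "_Enh-E")
  ratio <- electrodogram_ratio_db(gained[[1L]], gained[[2L]], tag = "ratio")
  ratio <- ratio_report(ratio$value_db, "electrodogram", tag)
  A <- gained[[1L]]$values; A[is.na(A)] <- 0
  B <- gained[[2L]]$values; B[is.na(B)] <- 0
  comb <- sqrt(A^2 + B^2)
  comb <- pmin(comb, 1)
  comb[comb == 0] <- NA_real_
  strat <- cfg$strategy
  if (!strat$bypass_nofm) comb <- select_n_of_m(comb, strat$N)
  if (strat$output == "current") comb <- map_to_current(comb, strat$map)
  elec <- electrodogram(comb, gained[[1L]]$frame_rate, strat$output,
                        N = if (strat$bypass_nofm) strat$M else strat$N)
  list(electrodogram = elec, streams = gained, ratio = ratio,
       manifest = pipeline_manifest(cfg, list(pipeline = "end_to_end",
                                              gain_db = g)))
}
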