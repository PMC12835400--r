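#' Separation network hyperparameters
#'
#' Configuration of the Conv-TasNet-style separator: an encoder of `N`
#' learned basis filters of length `L` samples (stride `L/2`), a temporal
#' convolutional network (TCN) of `R` repeats of `X` dilated blocks with
#' bottleneck width `B`, block width `H`, skip width `S` and kernel `P`,
#' and a decoder. Two output domains are supported: `"time"` (waveform
#' resynthesis, the front-end variant) and `"lgf"` (per-source normalized
#' LGF magnitude frames with `lgf_bands` channels, the end-to-end variant).
#'
#' The two variants share encoder and TCN structure and differ only in the
#' encoder activation (linear for the time variant, ReLU for the LGF
#' variant, both overridable), the training objective attached to the
#' output (SI-SNR vs MSE, see [train_separator()]), and the decoder head.
#'
#' For the two-source case with `S == N`, the mask head estimates a single
#' sigmoid mask on the skip accumulation and drives the second source with
#' the complementary mask; otherwise a 1x1 convolution produces
#' `num_sources` masks.
#'
#' @param N encoder basis count. @param L encoder window in samples (even).
#' @param B bottleneck channels. @param H block channels.
#' @param S skip-connection channels. @param P block kernel size (odd).
#' @param X blocks per repeat. @param R repeats.
#' @param num_sources number of output sources (default 2).
#' @param output_domain `"time"` or `"lgf"`.
#' @param lgf_bands number of LGF output bands (must equal the paired
#'   strategy's M when `output_domain = "lgf"`).
#' @param encoder_activation `"linear"` or `"relu"`; default depends on
#'   `output_domain`.
#' @param seed integer seed for parameter initialization.
#' @return an object of class `tasnet_config`.
#' @export
tasnet_config <- function(N = 128, L = 16, B = 64, H = 128, S = 128, P = 3,
                          X = 8, R = 3, num_sources = 2,
                          output_domain = c("time", "lgf"), lgf_bands = 22,
                          encoder_activation = NULL, seed = 1) {
  output_domain <- match.arg(output_domain)
  for (nm in c("N", "L", "B", "H", "S", "P", "X", "R", "num_sources")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v < 1 || v != round(v))
      stop("tasnet_config: ", nm, " must be a positive integer")
  }
  if (L %% 2 != 0) stop("tasnet_config: L must be even (stride L/2)")
  if (P %% 2 != 1) stop("tasnet_config: P must be odd")
  if (output_domain == "lgf" && (!is.numeric(lgf_bands) || lgf_bands < 1))
    stop("tasnet_config: output_domain 'lgf' requires lgf_bands >= 1")
  if (is.null(encoder_activation))
    encoder_activation <- if (output_domain == "time") "linear" else "relu"
  if (!encoder_activation %in% c("linear", "relu"))
    stop("tasnet_config: encoder_activation must be 'linear' or 'relu'")
  structure(list(N = as.integer(N), L = as.integer(L), B = as.integer(B),
                 H = as.integer(H), S = as.integer(S), P = as.integer(P),
                 X = as.integer(X), R = as.integer(R),
                 num_sources = as.integer(num_sources),
                 output_domain = output_domain,
                 lgf_bands = as.integer(lgf_bands),
                 encoder_activation = encoder_activation,
                 seed = as.integer(seed)),
            class = "tasnet_config")
}

#' Published separator presets
#'
#' The four hyperparameter columns used for the speech (female/male) and
#' singing-music (vocals/instruments) separation tasks, front-end
#' (time-domain) and end-to-end (LGF-domain) variants.
#'
#' @return named list of [tasnet_config()] objects.
#' @export
tasnet_presets <- function() {
  list(
    speech_front_end = tasnet_config(N = 128, L = 16, B = 64,  H = 128, S = 128,
                                     P = 3, X = 8, R = 3, output_domain = "time"),
    speech_end_to_end = tasnet_config(N = 128, L = 16, B = 64,  H = 128, S = 64,
                                      P = 3, X = 8, R = 3, output_domain = "lgf"),
    music_front_end = tasnet_config(N = 128, L = 16, B = 128, H = 256, S = 128,
                                    P = 3, X = 8, R = 3, output_domain = "time"),
    music_end_to_end = tasnet_config(N = 128, L = 16, B = 128, H = 256, S = 64,
                                     P = 3, X = 8, R = 3, output_domain = "lgf"))
}

uses_complementary_mask <- function(cfg) {
  cfg$num_sources == 2L && cfg$S == cfg$N
}

lgf_decoder_width <- function(cfg) max(1L, as.integer(ceiling(cfg$N / 2)))

# parameter shape table for a config; order is the canonical flattening
tasnet_param_shapes <- function(cfg) {
  shp <- list(enc.W = c(cfg$N, cfg$L),
              enc_norm.g = c(cfg$N, 1L), enc_norm.b = c(cfg$N, 1L),
              bn.W = c(cfg$B, cfg$N), bn.b = c(cfg$B, 1L))
  for (i in seq_len(cfg$R * cfg$X)) {
    p <- function(s) paste0("blk", i, ".", s)
    shp[[p("in.W")]] <- c(cfg$H, cfg$B); shp[[p("in.b")]] <- c(cfg$H, 1L)
    shp[[p("p1")]] <- c(1L, 1L)
    shp[[p("n1.g")]] <- c(cfg$H, 1L); shp[[p("n1.b")]] <- c(cfg$H, 1L)
    shp[[p("dw.W")]] <- c(cfg$H, cfg$P); shp[[p("dw.b")]] <- c(cfg$H, 1L)
    shp[[p("p2")]] <- c(1L, 1L)
    shp[[p("n2.g")]] <- c(cfg$H, 1L); shp[[p("n2.b")]] <- c(cfg$H, 1L)
    shp[[p("skip.W")]] <- c(cfg$S, cfg$H); shp[[p("skip.b")]] <- c(cfg$S, 1L)
    shp[[p("res.W")]] <- c(cfg$B, cfg$H); shp[[p("res.b")]] <- c(cfg$B, 1L)
  }
  shp[["mask.p"]] <- c(1L, 1L)
  if (!uses_complementary_mask(cfg)) {
    shp[["mask.W"]] <- c(cfg$num_sources * cfg$N, cfg$S)
    shp[["mask.b"]] <- c(cfg$num_sources * cfg$N, 1L)
  }
  if (cfg$output_domain == "time") {
    shp[["dec.W"]] <- c(cfg$L, cfg$N)
  } else {
    D <- lgf_decoder_width(cfg)
    shp[["dec1.W"]] <- c(D, cfg$N * cfg$P); shp[["dec1.b"]] <- c(D, 1L)
    shp[["dec2.W"]] <- c(cfg$lgf_bands, D); shp[["dec2.b"]] <- c(cfg$lgf_bands, 1L)
  }
  shp
}

#' Build a separator model
#'
#' Deterministically initializes all trainable parameters for the given
#' configuration (same config and seed give a bit-identical parameter
#' vector). Weight matrices use uniform Kaiming-style initialization
#' scaled by the fan-in; normalization gains start at 1, PReLU slopes at
#' 0.25, biases at 0.
#'
#' @param cfg a [tasnet_config()].
#' @return an object of class `tasnet_model`.
#' @export
build_separator <- function(cfg) {
  stopifnot(inherits(cfg, "tasnet_config"))
  shapes <- tasnet_param_shapes(cfg)
  params <- with_seed(cfg$seed, {
    lapply(names(shapes), function(nm) {
      d <- shapes[[nm]]
      if (grepl("\\.(g|p)$", nm) || grepl("\\.p[12]$", nm)) {
        v <- if (grepl("\\.g$", nm)) rep(1, d[1L]) else rep(0.25, prod(d))
        matrix(v, d[1L], d[2L])
      } else if (grepl("\\.b$", nm)) {
        matrix(0, d[1L], d[2L])
      } else {
        fan_in <- d[2L]
        s <- sqrt(1 / fan_in)
        matrix(stats::runif(prod(d), -s, s), d[1L], d[2L])
      }
    })
  })
  names(params) <- names(shapes)
  structure(list(cfg = cfg, params = params), class = "tasnet_model")
}

#' @export
print.tasnet_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(paste0("<tasnet_model> %s-domain, %d sources; N=%d L=%d B=%d H=%d ",
                     "S=%d P=%d X=%d R=%d; %s mask head; %s parameters\n"),
              cfg$output_domain, cfg$num_sources, cfg$N, cfg$L, cfg$B, cfg$H,
              cfg$S, cfg$P, cfg$X, cfg$R,
              if (uses_complementary_mask(cfg)) "complementary" else "conv",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#' @param model a `tasnet_model`.
#' @return total number of trainable scalar parameters (integer).
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "tasnet_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' Structural summary of a separator
#'
#' Returns the encoder activation, the decoder head type and the parameter
#' shape table of the shared encoder/TCN trunk, used to verify that the
#' time-domain and LGF-domain variants differ only in the declared aspects.
#'
#' @param model a `tasnet_model`.
#' @return list with `encoder_activation`, `head`, `trunk_shapes`.
#' @export
tasnet_structure <- function(model) {
  stopifnot(inherits(model, "tasnet_model"))
  shapes <- lapply(model$params, dim)
  trunk <- shapes[!grepl("^(dec|mask\\.[Wb])", names(shapes))]
  list(encoder_activation = model$cfg$encoder_activation,
       head = model$cfg$output_domain,
       trunk_shapes = trunk)
}

# ---- forward pass ---------------------------------------------------------

# Wrap current parameter values in tape nodes; returns list(nodes, env).
tasnet_param_nodes <- function(model) {
  lapply(model$params, tg_param)
}

# Forward through the network. x: numeric sample vector. Returns
# list(sources = list of output nodes, act_w, n_frames, pad_len, nodes).
tasnet_forward <- function(model, x, param_nodes = NULL) {
  cfg <- model$cfg
  stride <- cfg$L %/% 2L
  T0 <- length(x)
  len <- max(cfg$L, cfg$L + ceiling(max(0, T0 - cfg$L) / stride) * stride)
  if (len > T0) x <- c(x, numeric(len - T0))
  pn <- if (is.null(param_nodes)) tasnet_param_nodes(model) else param_nodes
  xin <- tg_val(matrix(x, 1L))
  w <- tg_conv1d(xin, pn$enc.W, K = cfg$L, stride = stride)
  act_w <- if (cfg$encoder_activation == "relu") tg_relu(w) else w
  h0 <- tg_gln(w, pn$enc_norm.g, pn$enc_norm.b)
  y <- tg_addbias(tg_matmul(pn$bn.W, h0), pn$bn.b)
  skip <- NULL
  i <- 0L
  for (r in seq_len(cfg$R)) {
    for (xb in seq_len(cfg$X)) {
      i <- i + 1L
      p <- function(s) pn[[paste0("blk", i, ".", s)]]
      h <- tg_addbias(tg_matmul(p("in.W"), y), p("in.b"))
      h <- tg_prelu(h, p("p1"))
      h <- tg_gln(h, p("n1.g"), p("n1.b"))
      h <- tg_dwconv1d(h, p("dw.W"), p("dw.b"), K = cfg$P,
                       dilation = 2L^(xb - 1L))
      h <- tg_prelu(h, p("p2"))
      h <- tg_gln(h, p("n2.g"), p("n2.b"))
      sk <- tg_addbias(tg_matmul(p("skip.W"), h), p("skip.b"))
      skip <- if (is.null(skip)) sk else tg_add(skip, sk)
      y <- tg_add(y, tg_addbias(tg_matmul(p("res.W"), h), p("res.b")))
    }
  }
  m <- tg_prelu(skip, pn$mask.p)
  masks <- if (uses_complementary_mask(cfg)) {
    m1 <- tg_sigmoid(m)
    list(m1, tg_one_minus(m1))
  } else {
    mm <- tg_sigmoid(tg_addbias(tg_matmul(pn$mask.W, m), pn$mask.b))
    lapply(seq_len(cfg$num_sources), function(c_)
      tg_rows(mm, (c_ - 1L) * cfg$N + seq_len(cfg$N)))
  }
  sources <- lapply(masks, function(mk) {
    feat <- tg_mul(act_w, mk)
    if (cfg$output_domain == "time") {
      yh <- tg_convtrans1d(feat, pn$dec.W, stride)
      tg_gather(yh, matrix(seq_len(T0), 1L), c(1L, T0))
    } else {
      z <- tg_conv1d(feat, pn$dec1.W, pn$dec1.b, K = cfg$P,
                     pad = (cfg$P - 1L) %/% 2L)
      z <- tg_relu(z)
      tg_sigmoid(tg_addbias(tg_matmul(pn$dec2.W, z), pn$dec2.b))
    }
  })
  list(sources = sources, nodes = pn, n_frames = ncol(w$v), T0 = T0)
}

#' Separate a mixture
#'
#' Runs the model at inference. Time-domain models return one
#' `audio_track` per source (length-matched to the input); LGF-domain
#' models return one `electrodogram` (domain `"lgf"`) per source at the
#' encoder frame rate (`rate / (L/2)` frames/s).
#'
#' @param model a `tasnet_model`.
#' @param mixture an `audio_track` (resampled with a warning if its rate
#'   differs from `rate`).
#' @param rate expected processing rate (default 16000).
#' @return an object of class `separated_sources`: list with `sources`,
#'   `domain`, `provenance`.
#' @export
separate <- function(model, mixture, rate = 16000) {
  stopifnot(inherits(model, "tasnet_model"))
  assert_track(mixture)
  if (mixture$rate != rate) {
    warning(sprintf("separate: resampling mixture from %g to %g Hz", mixture$rate, rate))
    mixture <- track_resample(mixture, rate)
  }
  fw <- tasnet_forward(model, mixture$samples)
  cfg <- model$cfg
  srcs <- if (cfg$output_domain == "time") {
    lapply(seq_along(fw$sources), function(c_)
      audio_track(as.vector(fw$sources[[c_]]$v), rate,
                  sprintf("separated_%d", c_)))
  } else {
    fr <- rate / (cfg$L / 2)
    lapply(fw$sources, function(s)
      electrodogram(t(s$v), frame_rate = fr, domain_tag = "lgf", N = cfg$lgf_bands))
  }
  structure(list(sources = srcs, domain = cfg$output_domain,
                 provenance = list(config = unclass(cfg),
                                   params_hash = params_hash(model))),
            class = "separated_sources")
}

#' @export
print.separated_sources <- function(x, ...) {
  cat(sprintf("<separated_sources> %d %s-domain source(s)\n",
              length(x$sources), x$domain))
  invisible(x)
}

#' LGF-domain training targets for clean sources
#'
#' Encodes each clean source with the ACE chain up to and including the
#' LGF (channel selection is by default applied afterwards when rendering
#' electrodograms, not in the target), returning dense `frames x M` target
#' matrices with inactive entries as 0.
#'
#' @param sources list of `audio_track`s.
#' @param cfg an [ace_config()]; its N-of-M stage is bypassed unless
#'   `include_selection`.
#' @param include_selection apply N-of-M inside the target as well.
#' @return list of numeric `frames x M` matrices.
#' @export
lgf_targets <- function(sources, cfg = ace_config(), include_selection = FALSE) {
  stopifnot(inherits(cfg, "ace_config"))
  tcfg <- cfg
  tcfg$bypass_nofm <- !include_selection
  tcfg$output <- "lgf"
  lapply(sources, function(s) {
    e <- encode_ace(s, tcfg)
    v <- e$values
    v[is.na(v)] <- 0
    v
  })
}

# checksum of the parameter values at text precision (stable across a
# JSON save/load round trip); manifest/reproducibility tag
params_hash <- function(model) {
  txt <- sprintf("%.15g", unlist(model$params, use.names = FALSE))
  fnv1a(charToRaw(paste(txt, collapse = ",")))
}

# vectorized polynomial checksum (content fingerprint, not cryptographic)
fnv1a <- function(bytes) {
  b <- as.numeric(bytes)
  n <- length(b)
  if (!n) return("00000000")
  p <- 2147483647
  w <- (seq_len(n) * 2654435761) %% p
  h <- 0
  for (i0 in seq.int(1L, n, by = 8192L)) {
    j <- i0:min(n, i0 + 8191L)
    h <- (h + sum(b[j] * w[j])) %% p
  }
  sprintf("%08x", h)
}

#' Save / load a separator as JSON text
#'
#' Checkpoints are plain JSON: the configuration, the flattened parameter
#' arrays with their dimensions, and the parameter hash.
#'
#' @param model a `tasnet_model`. @param path file path.
#' @return `path` invisibly / the restored `tasnet_model`.
#' @export
save_separator <- function(model, path) {
  stopifnot(inherits(model, "tasnet_model"))
  obj <- list(config = unclass(model$cfg),
              params = lapply(model$params, function(p)
                list(dim = dim(p), values = as.vector(p))),
              params_hash = params_hash(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_separator
#' @export
load_separator <- function(path) {
  if (!file.exists(path)) stop("load_separator: no such checkpoint: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(tasnet_config, obj$config[c("N", "L", "B", "H", "S", "P", "X", "R",
                                             "num_sources", "output_domain",
                                             "lgf_bands", "encoder_activation",
                                             "seed")])
  params <- lapply(obj$params, function(p) matrix(p$values, p$dim[1L], p$dim[2L]))
  model <- structure(list(cfg = cfg, params = params), class = "tasnet_model")
  if (!identical(params_hash(model), obj$params_hash))
    warning("load_separator: parameter hash mismatch")
  model
}
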