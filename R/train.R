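#' Training specification
#'
#' @param loss `"si-snr"` (time-domain models) or `"mse-lgf"` (LGF-domain
#'   models).
#' @param lr initial Adam learning rate (default 0.001).
#' @param max_epochs maximum number of passes over the data.
#' @param batch_size items per gradient step (default 1).
#' @param seed integer seed controlling shuffling.
#' @return an object of class `train_spec`.
#' @export
train_spec <- function(loss = c("si-snr", "mse-lgf"), lr = 1e-3,
                       max_epochs = 10, batch_size = 1, seed = 1) {
  loss <- match.arg(loss)
  if (!is.numeric(lr) || lr <= 0) stop("train_spec: lr must be > 0")
  if (max_epochs < 0) stop("train_spec: max_epochs must be >= 0")
  structure(list(loss = loss, lr = lr, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_spec")
}

# negative-log-ratio SI-SNR loss node for one estimated source (1 x T node)
# against a numeric reference; monotone in -SI-SNR.
si_snr_loss_node <- function(est, ref, eps = 1e-10) {
  Tn <- length(ref)
  s <- ref - mean(ref)
  es <- sum(s^2)
  if (es == 0) stop("si-snr loss: reference has zero energy")
  mu <- tg_scale(tg_ssum(est), 1 / Tn)
  e <- tg_addscalar(est, mu, sign = -1)
  sn <- tg_val(matrix(s, 1L))
  alpha <- tg_scale(tg_ssum(tg_mul(e, sn)), 1 / es)
  st <- tg_scale(sn, alpha)
  noise <- tg_sub(e, st)
  nn <- tg_sop(tg_ssum(tg_mul(noise, noise)), eps, "add")
  ss <- tg_sop(tg_ssum(tg_mul(st, st)), eps, "add")
  tg_sop(tg_slog(nn), tg_slog(ss), "sub")
}

mse_loss_node <- function(pred, target) {
  d <- tg_sub(pred, tg_val(target))
  tg_scale(tg_ssum(tg_mul(d, d)), 1 / length(target))
}

# one forward + loss for a dataset item; returns list(loss_node, nodes)
item_loss <- function(model, item, spec, param_nodes) {
  fw <- tasnet_forward(model, item$mixture$samples, param_nodes)
  C <- model$cfg$num_sources
  total <- NULL
  for (c_ in seq_len(C)) {
    lc <- if (spec$loss == "si-snr") {
      si_snr_loss_node(fw$sources[[c_]], item$sources[[c_]]$samples)
    } else {
      tgt <- t(item$targets[[c_]])                   # M x frames
      Tm <- min(ncol(tgt), ncol(fw$sources[[c_]]$v))
      pred <- tg_gather(fw$sources[[c_]],
                        matrix(seq_len(nrow(tgt) * Tm), nrow(tgt)),
                        c(nrow(tgt), Tm))
      mse_loss_node(pred, tgt[, seq_len(Tm), drop = FALSE])
    }
    total <- if (is.null(total)) lc else tg_sop(total, lc, "add")
  }
  tg_scale(total, 1 / C)
}

#' Train a separator
#'
#' Adam optimization of the model parameters on a list of items, each a
#' list with `mixture` (an `audio_track`) and `sources` (list of clean
#' `audio_track`s in fixed role order). For `"mse-lgf"` training, LGF
#' targets are computed once per item with [lgf_targets()] under
#' `strategy` (or taken from a pre-set `targets` element). Source roles
#' are fixed across the dataset, so no permutation search is performed.
#'
#' With `max_epochs = 0` the model is returned unchanged with an empty
#' history.
#'
#' @param model a `tasnet_model`.
#' @param dataset list of items (see above), e.g. from
#'   [make_mixture_dataset()].
#' @param spec a [train_spec()]; its loss must match the model's output
#'   domain (`"si-snr"` for time, `"mse-lgf"` for lgf).
#' @param strategy an [ace_config()] used to derive LGF targets; its frame
#'   timing should match the model (`hop == L/2`, `fft_size == L` give
#'   exact alignment; otherwise frames are truncated to the shorter).
#' @param clip_norm global gradient-norm clip (default 5).
#' @param verbose print per-epoch losses.
#' @return list with `model` (trained) and `history` (numeric vector of
#'   per-epoch mean training losses).
#' @export
train_separator <- function(model, dataset, spec = train_spec(),
                            strategy = NULL, clip_norm = 5, verbose = FALSE) {
  stopifnot(inherits(model, "tasnet_model"), inherits(spec, "train_spec"))
  dom <- model$cfg$output_domain
  if (spec$loss == "si-snr" && dom != "time")
    stop("train_separator: si-snr loss requires a time-domain model")
  if (spec$loss == "mse-lgf" && dom != "lgf")
    stop("train_separator: mse-lgf loss requires an lgf-domain model")
  if (spec$max_epochs == 0L) return(list(model = model, history = numeric(0)))
  if (spec$loss == "mse-lgf") {
    if (is.null(strategy)) strategy <- ace_config(fft_size = model$cfg$L,
                                                  hop = model$cfg$L %/% 2L,
                                                  M = model$cfg$lgf_bands)
    dataset <- lapply(dataset, function(it) {
      if (is.null(it$targets)) it$targets <- lgf_targets(it$sources, strategy)
      it
    })
  }
  pstate <- list(m = lapply(model$params, function(p) p * 0),
                 v = lapply(model$params, function(p) p * 0), t = 0L)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- numeric(spec$max_epochs)
  for (ep in seq_len(spec$max_epochs)) {
    ord <- with_seed(spec$seed + ep, sample.int(length(dataset)))
    losses <- numeric(0)
    bstart <- seq.int(1L, length(ord), by = spec$batch_size)
    for (bs in bstart) {
      items <- dataset[ord[bs:min(bs + spec$batch_size - 1L, length(ord))]]
      pn <- tasnet_param_nodes(model)
      total <- NULL
      for (it in items) {
        l <- item_loss(model, it, spec, pn)
        total <- if (is.null(total)) l else tg_sop(total, l, "add")
      }
      total <- tg_scale(total, 1 / length(items))
      tg_backward(total)
      losses <- c(losses, total$v[1L])
      grads <- lapply(pn, function(n) if (is.null(n$grad)) n$v * 0 else n$grad)
      gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
      if (is.finite(gn) && gn > clip_norm)
        grads <- lapply(grads, function(g) g * (clip_norm / gn))
      pstate$t <- pstate$t + 1L
      corr1 <- 1 - b1^pstate$t; corr2 <- 1 - b2^pstate$t
      for (nm in names(model$params)) {
        g <- grads[[nm]]
        pstate$m[[nm]] <- b1 * pstate$m[[nm]] + (1 - b1) * g
        pstate$v[[nm]] <- b2 * pstate$v[[nm]] + (1 - b2) * g^2
        mhat <- pstate$m[[nm]] / corr1
        vhat <- pstate$v[[nm]] / corr2
        model$params[[nm]] <- model$params[[nm]] - spec$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d: loss %.5f", ep, history[ep]))
  }
  list(model = model, history = history)
}
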