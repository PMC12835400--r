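# The autodiff engine is validated against central finite differences.

num_grad_check <- function(make_loss, P0, eps = 1e-6, probe = NULL) {
  tg <- asNamespace("cisep")
  p <- tg$tg_param(P0)
  l <- make_loss(p)
  tg$tg_backward(l)
  ga <- p$grad
  idx <- if (is.null(probe)) seq_along(P0) else probe
  worst <- 0
  for (j in idx) {
    P2 <- P0; P2[j] <- P2[j] + eps
    P3 <- P0; P3[j] <- P3[j] - eps
    gn <- (make_loss(tg$tg_param(P2))$v[1] - make_loss(tg$tg_param(P3))$v[1]) / (2 * eps)
    worst <- max(worst, abs(ga[j] - gn) / max(1e-4, abs(ga[j]) + abs(gn)))
  }
  worst
}

test_that("elementary op gradients match finite differences", {
  tg <- asNamespace("cisep")
  set.seed(5)
  P0 <- matrix(rnorm(12), 3, 4)
  X <- matrix(rnorm(8), 4, 2)
  cases <- list(
    matmul = function(p) tg$tg_ssum(tg$tg_mul(tg$tg_matmul(p, tg$tg_val(X)),
                                              tg$tg_matmul(p, tg$tg_val(X)))),
    sigmoid = function(p) tg$tg_ssum(tg$tg_sigmoid(p)),
    relu = function(p) tg$tg_ssum(tg$tg_mul(tg$tg_relu(p), p)),
    gln = local({
      gv <- matrix(c(0.7, 1.3, 2.1), 3, 1)
      function(p) {
        g <- tg$tg_param(gv)
        b <- tg$tg_param(matrix(0.1, 3, 1))
        y <- tg$tg_gln(p, g, b)
        tg$tg_ssum(tg$tg_mul(y, y))
      }
    }),
    scalar_chain = function(p) {
      s <- tg$tg_slog(tg$tg_sop(tg$tg_ssum(tg$tg_mul(p, p)), 1, "add"))
      tg$tg_sop(s, tg$tg_scale(tg$tg_ssum(p), 0.5), "sub")
    })
  for (nm in names(cases)) {
    expect_lt(num_grad_check(cases[[nm]], P0), 1e-5)
  }
})

test_that("gather, scatter and convolution gradients match finite differences", {
  tg <- asNamespace("cisep")
  set.seed(6)
  P0 <- matrix(rnorm(12), 3, 4)
  idxg <- matrix(c(1L, 0L, 5L, 7L, 2L, 2L), 2, 3)   # duplicates and zero-pad
  expect_lt(num_grad_check(function(p) {
    y <- tg$tg_gather(p, idxg, c(2L, 3L))
    tg$tg_ssum(tg$tg_mul(y, y))
  }, P0), 1e-5)
  idxs <- tg$fold_scatter_idx(4L, 3L, 2L)
  expect_lt(num_grad_check(function(p) {
    y <- tg$tg_scatter(p, idxs, 9L)
    tg$tg_ssum(tg$tg_mul(y, y))
  }, P0), 1e-5)
  W0 <- matrix(rnorm(8), 4, 2)
  X0 <- matrix(rnorm(10), 2, 5)
  expect_lt(num_grad_check(function(p) {
    y <- tg$tg_convtrans1d(tg$tg_val(X0), p, 2L)
    tg$tg_ssum(tg$tg_mul(y, y))
  }, W0), 1e-5)
  Wc <- matrix(rnorm(6), 3, 2)
  expect_lt(num_grad_check(function(p) {
    y <- tg$tg_conv1d(p, tg$tg_val(Wc), K = 1L)
    tg$tg_ssum(tg$tg_mul(y, y))
  }, X0), 1e-5)
})

test_that("transposed convolution forward equals manual overlap-add", {
  tg <- asNamespace("cisep")
  set.seed(7)
  W0 <- matrix(rnorm(8), 4, 2)
  X0 <- matrix(rnorm(10), 2, 5)
  y <- tg$tg_convtrans1d(tg$tg_val(X0), tg$tg_val(W0), 2L)
  man <- numeric(12)
  for (t in 1:5) {
    i0 <- (t - 1) * 2
    man[i0 + 1:4] <- man[i0 + 1:4] + as.vector(W0 %*% X0[, t])
  }
  expect_equal(as.vector(y$v), man, tolerance = 1e-12)
})

test_that("whole-model gradients for both variants match finite differences", {
  tg <- asNamespace("cisep")
  set.seed(1)
  x <- rnorm(40) * 0.1
  refs <- list(rnorm(40), rnorm(40))
  # time-domain model with SI-SNR loss
  model <- build_separator(tiny_time_cfg())
  lv <- function(m) {
    pn <- tg$tasnet_param_nodes(m)
    fw <- tg$tasnet_forward(m, x, pn)
    l <- tg$tg_sop(tg$si_snr_loss_node(fw$sources[[1]], refs[[1]]),
                   tg$si_snr_loss_node(fw$sources[[2]], refs[[2]]), "add")
    list(node = l, pn = pn)
  }
  r <- lv(model); tg$tg_backward(r$node)
  eps <- 1e-6; worst <- 0
  for (nm in names(model$params)) {
    g <- r$pn[[nm]]$grad
    if (is.null(g)) next   # the unused final residual conv has no gradient
    for (j in seq_len(min(2, length(model$params[[nm]])))) {
      m2 <- model; m2$params[[nm]][j] <- m2$params[[nm]][j] + eps
      m3 <- model; m3$params[[nm]][j] <- m3$params[[nm]][j] - eps
      gn <- (lv(m2)$node$v[1] - lv(m3)$node$v[1]) / (2 * eps)
      worst <- max(worst, abs(g[j] - gn) / max(1e-4, abs(g[j]) + abs(gn)))
    }
  }
  expect_lt(worst, 1e-4)
  # lgf-domain model with MSE loss
  model2 <- build_separator(tiny_lgf_cfg())
  set.seed(2)
  tgt <- lapply(1:2, function(i) matrix(runif(5 * 19), 19, 5))
  lv2 <- function(m) {
    pn <- tg$tasnet_param_nodes(m)
    fw <- tg$tasnet_forward(m, x, pn)
    l <- NULL
    for (c_ in 1:2) {
      tt <- t(tgt[[c_]])
      Tm <- min(ncol(tt), ncol(fw$sources[[c_]]$v))
      pred <- tg$tg_gather(fw$sources[[c_]],
                           matrix(seq_len(nrow(tt) * Tm), nrow(tt)), c(nrow(tt), Tm))
      lc <- tg$mse_loss_node(pred, tt[, seq_len(Tm), drop = FALSE])
      l <- if (is.null(l)) lc else tg$tg_sop(l, lc, "add")
    }
    list(node = l, pn = pn)
  }
  r2 <- lv2(model2); tg$tg_backward(r2$node)
  worst2 <- 0
  for (nm in names(model2$params)) {
    g <- r2$pn[[nm]]$grad
    if (is.null(g)) next
    j <- 1L
    m2 <- model2; m2$params[[nm]][j] <- m2$params[[nm]][j] + eps
    m3 <- model2; m3$params[[nm]][j] <- m3$params[[nm]][j] - eps
    gn <- (lv2(m2)$node$v[1] - lv2(m3)$node$v[1]) / (2 * eps)
    worst2 <- max(worst2, abs(g[j] - gn) / max(1e-4, abs(g[j]) + abs(gn)))
  }
  expect_lt(worst2, 1e-4)
})

test_that("node ids are a topological order even for inline construction", {
  tg <- asNamespace("cisep")
  W <- tg$tg_param(matrix(1:6 / 10, 2, 3))
  b <- tg$tg_param(matrix(c(0.1, 0.2), 2, 1))
  # matmul is constructed lazily inside the addbias call
  y <- tg$tg_addbias(tg$tg_matmul(W, tg$tg_val(matrix(1:6, 3, 2))), b)
  l <- tg$tg_ssum(tg$tg_mul(y, y))
  tg$tg_backward(l)
  expect_false(is.null(W$grad))
  X <- matrix(1:6, 3, 2)
  y_manual <- W$v %*% X + matrix(c(0.1, 0.2), 2, 2)
  expect_equal(W$grad, 2 * y_manual %*% t(X))
})
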