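# Reverse-mode automatic differentiation on a dynamic tape.
#
# Minimal engine supporting exactly the operations the separation networks
# need: matrix product, elementwise arithmetic, row-broadcast bias/scale,
# gather/scatter (for im2col convolution and overlap-add), PReLU / ReLU /
# sigmoid, global layer normalization, and scalar reductions for losses.
# Values are numeric matrices; scalars are 1x1 matrices. Gradients are
# checked against numerical differentiation in the test suite.

.tg <- new.env(parent = emptyenv())
.tg$id <- 0L

tg_node <- function(v, parents = list(), bw = NULL, req = FALSE) {
  # force parents (and any nodes their construction creates) and the value
  # BEFORE taking an id, so ids are a valid topological order of the graph
  req <- req || any(vapply(parents, function(p) p$req, logical(1)))
  n <- new.env(parent = emptyenv())
  n$v <- v
  n$grad <- NULL
  n$parents <- parents
  n$bw <- bw
  n$req <- req
  .tg$id <- .tg$id + 1L
  n$id <- .tg$id
  class(n) <- "tg_node"
  n
}

tg_val <- function(x) tg_node(as.matrix(x))
tg_param <- function(x) tg_node(as.matrix(x), req = TRUE)

as_node <- function(x) if (inherits(x, "tg_node")) x else tg_val(x)

# Accumulate d into node's grad
tg_acc <- function(n, d) {
  if (!n$req) return(invisible())
  n$grad <- if (is.null(n$grad)) d else n$grad + d
  invisible()
}

#' @export
print.tg_node <- function(x, ...) {
  cat(sprintf("<tg_node #%d> %dx%d%s\n", x$id, nrow(x$v), ncol(x$v),
              if (x$req) " (grad)" else ""))
  invisible(x)
}

# ---- elementwise and matrix ops ------------------------------------------

tg_add <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  tg_node(a$v + b$v, list(a, b), function(g) { tg_acc(a, g); tg_acc(b, g) })
}

tg_sub <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  tg_node(a$v - b$v, list(a, b), function(g) { tg_acc(a, g); tg_acc(b, -g) })
}

tg_mul <- function(a, b) {
  a <- as_node(a); b <- as_node(b)
  tg_node(a$v * b$v, list(a, b),
          function(g) { tg_acc(a, g * b$v); tg_acc(b, g * a$v) })
}

# bias: column vector (length nrow(x)) added to every column
tg_addbias <- function(x, b) {
  bx <- as.vector(b$v)
  tg_node(x$v + bx, list(x, b), function(g) {
    tg_acc(x, g); tg_acc(b, matrix(rowSums(g), ncol = 1))
  })
}

# per-row scale by column vector w
tg_rowscale <- function(x, w) {
  wv <- as.vector(w$v)
  tg_node(x$v * wv, list(x, w), function(g) {
    tg_acc(x, g * wv)
    tg_acc(w, matrix(rowSums(g * x$v), ncol = 1))
  })
}

tg_matmul <- function(A, B) {
  tg_node(A$v %*% B$v, list(A, B), function(g) {
    tg_acc(A, g %*% t(B$v))
    tg_acc(B, crossprod(A$v, g))
  })
}

# multiply by scalar (numeric or 1x1 node)
tg_scale <- function(x, s) {
  if (!inherits(s, "tg_node")) {
    sv <- s
    return(tg_node(x$v * sv, list(x), function(g) tg_acc(x, g * sv)))
  }
  sv <- s$v[1L]
  tg_node(x$v * sv, list(x, s), function(g) {
    tg_acc(x, g * sv)
    tg_acc(s, matrix(sum(g * x$v)))
  })
}

# add sign * scalar-node to every entry
tg_addscalar <- function(x, s, sign = 1) {
  sv <- s$v[1L]
  tg_node(x$v + sign * sv, list(x, s), function(g) {
    tg_acc(x, g)
    tg_acc(s, matrix(sign * sum(g)))
  })
}

# one minus x (for complementary masks)
tg_one_minus <- function(x) {
  tg_node(1 - x$v, list(x), function(g) tg_acc(x, -g))
}

# ---- gather / scatter -----------------------------------------------------
# idx is a flat index into x's value (column-major), 0 meaning "zero pad".
# Gather produces a matrix of dim out_dim; scatter accumulates x's entries
# into a zero vector of length out_len at positions idx (shape 1 x out_len).

tg_gather <- function(x, idx, out_dim) {
  aug <- c(0, as.vector(x$v))
  tg_node(matrix(aug[idx + 1L], out_dim[1L], out_dim[2L]), list(x), function(g) {
    gx <- numeric(length(x$v))
    nz <- idx != 0L
    if (any(nz)) {
      acc <- rowsum(as.vector(g)[nz], group = idx[nz], reorder = FALSE)
      gx[as.integer(rownames(acc))] <- acc[, 1L]
    }
    tg_acc(x, matrix(gx, nrow(x$v), ncol(x$v)))
  })
}

tg_scatter <- function(x, idx, out_len) {
  y <- numeric(out_len)
  acc <- rowsum(as.vector(x$v), group = as.vector(idx), reorder = FALSE)
  y[as.integer(rownames(acc))] <- acc[, 1L]
  tg_node(matrix(y, 1L), list(x), function(g) {
    gv <- as.vector(g)
    tg_acc(x, matrix(gv[idx], nrow(x$v), ncol(x$v)))
  })
}

# ---- nonlinearities -------------------------------------------------------

tg_relu <- function(x) {
  m <- x$v > 0
  tg_node(x$v * m, list(x), function(g) tg_acc(x, g * m))
}

tg_sigmoid <- function(x) {
  s <- 1 / (1 + exp(-x$v))
  tg_node(s, list(x), function(g) tg_acc(x, g * s * (1 - s)))
}

# PReLU with a single learned slope (1x1 param node)
tg_prelu <- function(x, a) {
  av <- a$v[1L]
  neg <- x$v < 0
  tg_node(ifelse(neg, av * x$v, x$v), list(x, a), function(g) {
    tg_acc(x, g * ifelse(neg, av, 1))
    tg_acc(a, matrix(sum(g[neg] * x$v[neg])))
  })
}

# global layer normalization: normalize over all entries of the C x T
# matrix, then per-row (channel) affine with gamma/beta column vectors.
tg_gln <- function(x, gamma, beta, eps = 1e-8) {
  n <- length(x$v)
  mu <- mean(x$v)
  va <- mean((x$v - mu)^2)
  sd_ <- sqrt(va + eps)
  xh <- (x$v - mu) / sd_
  gv <- as.vector(gamma$v); bv <- as.vector(beta$v)
  tg_node(xh * gv + bv, list(x, gamma, beta), function(g) {
    tg_acc(gamma, matrix(rowSums(g * xh), ncol = 1))
    tg_acc(beta, matrix(rowSums(g), ncol = 1))
    dxh <- g * gv
    dx <- (dxh - mean(dxh) - xh * mean(dxh * xh)) / sd_
    tg_acc(x, dx)
  })
}

# ---- reductions and scalar arithmetic ------------------------------------

tg_ssum <- function(x) {
  dims <- dim(x$v)
  tg_node(matrix(sum(x$v)), list(x),
          function(g) tg_acc(x, matrix(g[1L], dims[1L], dims[2L])))
}

tg_sop <- function(a, b, op) {
  a <- as_node(a); b <- as_node(b)
  av <- a$v[1L]; bv <- b$v[1L]
  switch(op,
    add = tg_node(matrix(av + bv), list(a, b), function(g) {
      tg_acc(a, g); tg_acc(b, g) }),
    sub = tg_node(matrix(av - bv), list(a, b), function(g) {
      tg_acc(a, g); tg_acc(b, -g) }),
    mul = tg_node(matrix(av * bv), list(a, b), function(g) {
      tg_acc(a, g * bv); tg_acc(b, g * av) }),
    div = tg_node(matrix(av / bv), list(a, b), function(g) {
      tg_acc(a, g / bv); tg_acc(b, -g * av / bv^2) }),
    stop("tg_sop: unknown op"))
}

tg_slog <- function(a) {
  av <- a$v[1L]
  tg_node(matrix(log(av)), list(a), function(g) tg_acc(a, g / av))
}

# ---- backward pass --------------------------------------------------------

# Seeds the loss gradient with 1 and propagates through all reachable
# gradient-requiring nodes in reverse creation order.
tg_backward <- function(loss) {
  stopifnot(inherits(loss, "tg_node"), length(loss$v) == 1L)
  # collect reachable subgraph (iterative DFS)
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    if (!n$req) next
    nodes[[length(nodes) + 1L]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  loss$grad <- matrix(1)
  for (n in nodes[ord]) {
    if (!is.null(n$bw) && !is.null(n$grad)) n$bw(n$grad)
  }
  invisible(loss)
}

# ---- convolution helpers --------------------------------------------------

# Flat (column-major) gather index for im2col 1-D convolution on a C x T
# input: output column j collects taps t0(j) + (k-1)*dilation for k=1..K,
# all C channels, rows ordered (k outer, c inner). Entries outside [1, T]
# become 0 (zero padding).
conv_gather_idx <- function(C, T_in, K, stride = 1L, dilation = 1L, pad = 0L) {
  span <- (K - 1L) * dilation + 1L
  starts <- seq.int(1L - pad, T_in + pad - span + 1L, by = stride)
  T_out <- length(starts)
  taps <- outer(seq.int(0L, K - 1L) * dilation, starts, `+`)  # K x T_out
  tap_ok <- taps >= 1L & taps <= T_in
  base <- (taps - 1L) * C
  idx <- matrix(0L, C * K, T_out)
  for (k in seq_len(K)) {
    rows <- (k - 1L) * C + seq_len(C)
    col_base <- ifelse(tap_ok[k, ], base[k, ], NA_integer_)
    blk <- outer(seq_len(C), col_base, `+`)
    blk[is.na(blk)] <- 0L
    idx[rows, ] <- blk
  }
  storage.mode(idx) <- "integer"
  idx
}

# Scatter index for transposed 1-D convolution (overlap-add) with a single
# output channel: input column t contributes K samples at (t-1)*stride + k.
fold_scatter_idx <- function(T_in, K, stride) {
  idx <- outer(seq_len(K), (seq_len(T_in) - 1L) * stride, `+`)
  storage.mode(idx) <- "integer"
  idx
}

# 1-D convolution as gather + matmul: x is C_in x T node, W a node of dim
# C_out x (C_in*K) with columns ordered (k outer, c_in inner), b optional
# C_out bias node.
tg_conv1d <- function(x, W, b = NULL, K, stride = 1L, dilation = 1L,
                      pad = 0L, idx = NULL) {
  C <- nrow(x$v); T_in <- ncol(x$v)
  if (is.null(idx)) idx <- conv_gather_idx(C, T_in, K, stride, dilation, pad)
  u <- tg_gather(x, idx, dim(idx))
  y <- tg_matmul(W, u)
  if (!is.null(b)) y <- tg_addbias(y, b)
  y
}

# depthwise 1-D convolution ("same" padding): W is C x K node, b a C bias.
tg_dwconv1d <- function(x, W, b = NULL, K, dilation = 1L) {
  C <- nrow(x$v); T_in <- ncol(x$v)
  pad <- ((K - 1L) * dilation) %/% 2L
  out <- NULL
  for (k in seq_len(K)) {
    off <- (k - 1L) * dilation - pad
    taps <- seq_len(T_in) + off
    ok <- taps >= 1L & taps <= T_in
    col_idx <- ifelse(ok, (taps - 1L) * C, NA_integer_)
    blk <- outer(seq_len(C), col_idx, `+`)
    blk[is.na(blk)] <- 0L
    storage.mode(blk) <- "integer"
    shifted <- tg_gather(x, blk, c(C, T_in))
    wk <- tg_col(W, k)
    term <- tg_rowscale(shifted, wk)
    out <- if (is.null(out)) term else tg_add(out, term)
  }
  if (!is.null(b)) out <- tg_addbias(out, b)
  out
}

# column extraction (view of one kernel tap of a C x K weight)
tg_col <- function(x, j) {
  C <- nrow(x$v); K <- ncol(x$v)
  tg_node(x$v[, j, drop = FALSE], list(x), function(g) {
    gx <- matrix(0, C, K)
    gx[, j] <- g
    tg_acc(x, gx)
  })
}

# transposed convolution to a single output channel: x is N x T, W an
# (K x N) node; returns 1 x ((T-1)*stride + K).
tg_convtrans1d <- function(x, W, stride) {
  T_in <- ncol(x$v); K <- nrow(W$v)
  P <- tg_matmul(W, x)                       # K x T frames of contributions
  idx <- fold_scatter_idx(T_in, K, stride)
  tg_scatter(P, idx, (T_in - 1L) * stride + K)
}

# row-block extraction (rows a..b), for splitting multi-source outputs
tg_rows <- function(x, rows) {
  nr <- nrow(x$v); nc <- ncol(x$v)
  tg_node(x$v[rows, , drop = FALSE], list(x), function(g) {
    gx <- matrix(0, nr, nc)
    gx[rows, ] <- g
    tg_acc(x, gx)
  })
}
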