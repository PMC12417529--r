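# Minimal reverse-mode automatic differentiation on dense arrays.
#
# Every op accepts either a plain array (treated as a constant: the op then
# simply computes and returns a plain array, which is the fast inference path)
# or an `adnode`.  When at least one argument is a node, the op records a
# backward closure; `ad_backward()` later traverses nodes in reverse creation
# order and accumulates gradients.  Feature maps are arrays [B, C, D, H, W];
# token sequences are [B, L, C]; matrices are used for per-item attention.

.ad <- new.env(parent = emptyenv())
.ad$id <- 0L

is_node <- function(x) inherits(x, "adnode")
nval <- function(x) if (is_node(x)) x$val else x

new_node <- function(val, parents, bw) {
  e <- new.env(parent = emptyenv())
  .ad$id <- .ad$id + 1L
  e$id <- .ad$id
  e$val <- val
  e$grad <- NULL
  e$parents <- parents[vapply(parents, is_node, logical(1))]
  e$bw <- bw
  class(e) <- "adnode"
  e
}

ad_leaf <- function(val) new_node(val, list(), NULL)

accum <- function(n, g) {
  if (is_node(n)) n$grad <- if (is.null(n$grad)) g else n$grad + g
  invisible(NULL)
}

any_node <- function(...) any(vapply(list(...), is_node, logical(1)))

#' @noRd
ad_backward <- function(root) {
  nodes <- vector("list", 64L)
  nn <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- list(root)
  while (length(stack)) {
    n <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(n$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nn <- nn + 1L
    if (nn > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[nn]] <- n
    for (p in n$parents) stack[[length(stack) + 1L]] <- p
  }
  nodes <- nodes[seq_len(nn)]
  ids <- vapply(nodes, function(n) n$id, integer(1))
  nodes <- nodes[order(ids, decreasing = TRUE)]
  root$grad <- if (is.null(dim(root$val))) rep(1, length(root$val)) else
    array(1, dim = dim(root$val))
  for (n in nodes) if (!is.null(n$bw) && !is.null(n$grad)) n$bw(n$grad)
  invisible(root)
}

# ---- elementwise ----

ad_add <- function(a, b) {
  v <- nval(a) + nval(b)
  if (!any_node(a, b)) return(v)
  new_node(v, list(a, b), function(g) { accum(a, g); accum(b, g) })
}

ad_mul <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  v <- av * bv
  if (!any_node(a, b)) return(v)
  new_node(v, list(a, b), function(g) { accum(a, g * bv); accum(b, g * av) })
}

ad_smul <- function(a, s) {  # s plain scalar
  v <- nval(a) * s
  if (!is_node(a)) return(v)
  new_node(v, list(a), function(g) accum(a, g * s))
}

ad_relu <- function(x) {
  xv <- nval(x)
  v <- pmax(xv, 0)
  if (!is.null(dim(xv))) dim(v) <- dim(xv)
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) accum(x, g * (xv > 0)))
}

ad_sigmoid <- function(x) {
  v <- 1 / (1 + exp(-nval(x)))
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) accum(x, g * v * (1 - v)))
}

ad_silu <- function(x) {
  xv <- nval(x)
  s <- 1 / (1 + exp(-xv))
  v <- xv * s
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) accum(x, g * (s + xv * s * (1 - s))))
}

ad_gelu <- function(x) {  # exact (erf) form: x * Phi(x)
  xv <- nval(x)
  ph <- stats::pnorm(xv)
  v <- xv * ph
  if (!is.null(dim(xv))) dim(v) <- dim(xv)
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) accum(x, g * (ph + xv * stats::dnorm(xv))))
}

# ---- shape ----

ad_reshape <- function(x, d) {
  v <- nval(x)
  od <- dim(v)
  dim(v) <- d
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) { dim(g) <- od; accum(x, g) })
}

ad_aperm <- function(x, perm) {
  v <- aperm(nval(x), perm)
  if (!is_node(x)) return(v)
  inv <- order(perm)
  new_node(v, list(x), function(g) accum(x, aperm(g, inv)))
}

ad_cbind <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  v <- cbind(av, bv)
  if (!any_node(a, b)) return(v)
  na <- ncol(av)
  new_node(v, list(a, b), function(g) {
    accum(a, g[, seq_len(na), drop = FALSE])
    accum(b, g[, na + seq_len(ncol(bv)), drop = FALSE])
  })
}

ad_rbind_list <- function(xs) {
  vs <- lapply(xs, nval)
  v <- do.call(rbind, vs)
  if (!any(vapply(xs, is_node, logical(1)))) return(v)
  rows <- vapply(vs, nrow, integer(1))
  ends <- cumsum(rows)
  starts <- ends - rows + 1L
  new_node(v, xs, function(g) {
    for (i in seq_along(xs))
      accum(xs[[i]], g[starts[i]:ends[i], , drop = FALSE])
  })
}

# rows i0..i1 of a matrix
ad_rows <- function(x, i0, i1) {
  xv <- nval(x)
  v <- xv[i0:i1, , drop = FALSE]
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) {
    full <- array(0, dim = dim(xv))
    full[i0:i1, ] <- g
    accum(x, full)
  })
}

ad_t <- function(x) {
  v <- t(nval(x))
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) accum(x, t(g)))
}

# extract item b of [B, L, C] as a [C, L] matrix
ad_item_mat <- function(x, b) {
  xv <- nval(x)
  d <- dim(xv)
  v <- t(array(xv[b, , ], dim = d[2:3]))
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) {
    full <- array(0, dim = d)
    full[b, , ] <- t(g)
    accum(x, full)
  })
}

# stack a list of B [C, L] matrices into [B, L, C]
ad_stack_items <- function(xs) {
  vs <- lapply(xs, nval)
  B <- length(vs); C <- nrow(vs[[1]]); L <- ncol(vs[[1]])
  v <- array(0, dim = c(B, L, C))
  for (b in seq_len(B)) v[b, , ] <- t(vs[[b]])
  if (!any(vapply(xs, is_node, logical(1)))) return(v)
  new_node(v, xs, function(g) {
    for (b in seq_len(B)) accum(xs[[b]], t(array(g[b, , ], dim = c(L, C))))
  })
}

# concatenate two [B, L, C] arrays along the channel (last) dim
ad_concat_last3 <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  da <- dim(av); db <- dim(bv)
  v <- array(0, dim = c(da[1], da[2], da[3] + db[3]))
  v[, , seq_len(da[3])] <- av
  v[, , da[3] + seq_len(db[3])] <- bv
  if (!any_node(a, b)) return(v)
  new_node(v, list(a, b), function(g) {
    accum(a, g[, , seq_len(da[3]), drop = FALSE])
    accum(b, g[, , da[3] + seq_len(db[3]), drop = FALSE])
  })
}

# concatenate two rank-5 arrays along the channel (2nd) dim
ad_concat_ch5 <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  da <- dim(av); db <- dim(bv)
  v <- array(0, dim = c(da[1], da[2] + db[2], da[3], da[4], da[5]))
  v[, seq_len(da[2]), , , ] <- av
  v[, da[2] + seq_len(db[2]), , , ] <- bv
  if (!any_node(a, b)) return(v)
  new_node(v, list(a, b), function(g) {
    accum(a, g[, seq_len(da[2]), , , , drop = FALSE])
    accum(b, g[, da[2] + seq_len(db[2]), , , , drop = FALSE])
  })
}

# ---- linear algebra ----

ad_matmul <- function(a, b) {
  av <- nval(a); bv <- nval(b)
  v <- av %*% bv
  if (!any_node(a, b)) return(v)
  new_node(v, list(a, b), function(g) {
    accum(a, g %*% t(bv))
    accum(b, t(av) %*% g)
  })
}

# x [N, din] %*% W [din, dout] + b
ad_linear <- function(x, W, b = NULL) {
  xv <- nval(x); Wv <- nval(W)
  v <- xv %*% Wv
  if (!is.null(b)) v <- v + rep(nval(b), each = nrow(v))
  if (!any_node(x, W, b)) return(v)
  new_node(v, list(x, W, b), function(g) {
    accum(x, g %*% t(Wv))
    accum(W, t(xv) %*% g)
    if (!is.null(b)) accum(b, colSums(g))
  })
}

# row-wise softmax with max subtraction, for square score matrices
ad_softmax_rows <- function(x) {
  xv <- nval(x)
  e <- exp(xv - apply(xv, 1, max))
  v <- e / rowSums(e)
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) accum(x, (g - rowSums(g * v)) * v))
}

# ---- reductions / broadcasts on [B, C, D, H, W] ----

ad_gap_spatial <- function(x) {  # -> [B, C]
  xv <- nval(x)
  d <- dim(xv)
  S <- prod(d[3:5])
  v <- matrix(rowMeans(matrix(xv, d[1] * d[2], S)), d[1], d[2])
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) {
    full <- array(as.vector(g) / S, dim = d)  # recycles over spatial dims
    accum(x, full)
  })
}

ad_gmp_spatial <- function(x) {  # -> [B, C], ties to first
  xv <- nval(x)
  d <- dim(xv)
  m <- matrix(xv, d[1] * d[2], prod(d[3:5]))
  idx <- max.col(m, ties.method = "first")
  v <- matrix(m[cbind(seq_len(nrow(m)), idx)], d[1], d[2])
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) {
    dm <- matrix(0, nrow(m), ncol(m))
    dm[cbind(seq_len(nrow(m)), idx)] <- as.vector(g)
    dim(dm) <- d
    accum(x, dm)
  })
}

# multiply each channel by a per-(batch, channel) gate s [B, C]
ad_scale_channels <- function(x, s) {
  xv <- nval(x); sv <- nval(s)
  d <- dim(xv)
  v <- xv * as.vector(sv)  # recycling: first two dims are (B, C)
  if (!any_node(x, s)) return(v)
  new_node(v, list(x, s), function(g) {
    accum(x, g * as.vector(sv))
    ds <- matrix(rowSums(matrix(g * xv, d[1] * d[2], prod(d[3:5]))), d[1], d[2])
    accum(s, ds)
  })
}

# multiply all channels by a spatial gate m [B, 1, D, H, W]
ad_scale_spatial <- function(x, m) {
  xv <- nval(x); mv <- nval(m)
  d <- dim(xv)
  mfull <- mv[, rep(1L, d[2]), , , , drop = FALSE]
  v <- xv * mfull
  if (!any_node(x, m)) return(v)
  new_node(v, list(x, m), function(g) {
    accum(x, g * mfull)
    gx <- g * xv
    dm <- array(0, dim = dim(mv))
    for (cc in seq_len(d[2])) dm <- dm + gx[, cc, , , , drop = FALSE]
    accum(m, dm)
  })
}

ad_channel_mean <- function(x) {  # [B,C,D,H,W] -> [B,1,D,H,W]
  xv <- nval(x)
  d <- dim(xv)
  v <- array(0, dim = c(d[1], 1, d[3], d[4], d[5]))
  for (cc in seq_len(d[2])) v <- v + xv[, cc, , , , drop = FALSE]
  v <- v / d[2]
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) {
    accum(x, g[, rep(1L, d[2]), , , , drop = FALSE] / d[2])
  })
}

ad_channel_max <- function(x) {  # [B,1,D,H,W], ties to first channel
  xv <- nval(x)
  d <- dim(xv)
  B <- d[1]; C <- d[2]; S <- prod(d[3:5])
  pm <- aperm(array(xv, dim = c(B, C, S)), c(2, 1, 3))   # [C, B*S]
  dim(pm) <- c(C, B * S)
  idx <- max.col(t(pm), ties.method = "first")           # length B*S
  vals <- pm[cbind(idx, seq_len(B * S))]
  v <- array(aperm(array(vals, dim = c(B, S)), c(1, 2)), dim = c(B, 1, d[3], d[4], d[5]))
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) {
    dmat <- matrix(0, C, B * S)
    dmat[cbind(idx, seq_len(B * S))] <- as.vector(g)
    dx <- aperm(array(dmat, dim = c(C, B, S)), c(2, 1, 3))
    dim(dx) <- d
    accum(x, dx)
  })
}

# ---- [B, L, C] token ops ----

ad_mean_tokens <- function(x) {  # -> [B, C]
  xv <- nval(x)
  d <- dim(xv)
  v <- matrix(0, d[1], d[3])
  for (l in seq_len(d[2])) v <- v + xv[, l, ]
  v <- v / d[2]
  if (d[1] == 1L) dim(v) <- c(1L, d[3])
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) {
    dx <- array(0, dim = d)
    for (l in seq_len(d[2])) dx[, l, ] <- g / d[2]
    accum(x, dx)
  })
}

# average pooling over the token axis, kernel 3, stride 1, same length,
# averaging only the neighbors that exist
avgpool_token_matrix <- function(T) {
  A <- matrix(0, T, T)
  for (t in seq_len(T)) {
    nb <- intersect((t - 1):(t + 1), seq_len(T))
    A[t, nb] <- 1 / length(nb)
  }
  A
}

ad_avgpool_tokens <- function(x) {
  xv <- nval(x)
  d <- dim(xv)
  A <- avgpool_token_matrix(d[2])
  xm <- matrix(aperm(xv, c(2, 1, 3)), d[2], d[1] * d[3])
  v <- aperm(array(A %*% xm, dim = c(d[2], d[1], d[3])), c(2, 1, 3))
  if (!is_node(x)) return(v)
  new_node(v, list(x), function(g) {
    gm <- matrix(aperm(g, c(2, 1, 3)), d[2], d[1] * d[3])
    accum(x, aperm(array(t(A) %*% gm, dim = c(d[2], d[1], d[3])), c(2, 1, 3)))
  })
}

# ---- normalizations ----

# LayerNorm over the LAST dimension of an array, learnable gamma/beta
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- nval(x)
  d <- if (is.null(dim(xv))) c(1L, length(xv)) else dim(xv)
  C <- d[length(d)]
  N <- prod(d) / C
  Xm <- matrix(xv, N, C)
  mu <- rowMeans(Xm)
  xc <- Xm - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xh <- xc * inv
  gv <- nval(gamma); bv <- nval(beta)
  v <- xh * rep(gv, each = N) + rep(bv, each = N)
  dim(v) <- d
  if (!any_node(x, gamma, beta)) return(v)
  new_node(v, list(x, gamma, beta), function(g) {
    Gm <- matrix(g, N, C)
    dxh <- Gm * rep(gv, each = N)
    dx <- inv * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
    dim(dx) <- d
    accum(x, dx)
    accum(gamma, colSums(Gm * xh))
    accum(beta, colSums(Gm))
  })
}

# Batch normalization for [B, C, D, H, W]; `state` is an environment holding
# running mean/var under keys <key>.mean / <key>.var, updated when training.
ad_batchnorm <- function(x, gamma, beta, state, key, training,
                         momentum = 0.1, eps = 1e-5) {
  xv <- nval(x)
  d <- dim(xv)
  B <- d[1]; C <- d[2]; S <- prod(d[3:5])
  n <- B * S
  km <- paste0(key, ".mean"); kv <- paste0(key, ".var")
  gv <- nval(gamma); bv <- nval(beta)
  per_ch <- function(a) colMeans(matrix(rowMeans(matrix(a, B * C, S)), B, C))
  if (training) {
    mu <- per_ch(xv)
    va <- per_ch(xv * xv) - mu * mu
    ub <- if (n > 1) va * n / (n - 1) else va
    state[[km]] <- (1 - momentum) * state[[km]] + momentum * mu
    state[[kv]] <- (1 - momentum) * state[[kv]] + momentum * ub
  } else {
    mu <- state[[km]]
    va <- state[[kv]]
  }
  inv <- 1 / sqrt(va + eps)
  mu_bc <- rep(mu, each = B)
  inv_bc <- rep(inv, each = B)
  xh <- (xv - mu_bc) * inv_bc  # recycles over spatial dims
  v <- xh * rep(gv, each = B) + rep(bv, each = B)
  if (!any_node(x, gamma, beta)) return(v)
  new_node(v, list(x, gamma, beta), function(g) {
    gxh <- g * xh
    dgamma <- per_ch(gxh) * n
    dbeta <- per_ch(g) * n
    dxh <- g * rep(gv, each = B)
    if (training) {
      m1 <- per_ch(dxh)
      m2 <- per_ch(dxh * xh)
      dx <- (dxh - rep(m1, each = B) - xh * rep(m2, each = B)) * inv_bc
    } else {
      dx <- dxh * inv_bc
    }
    accum(x, dx)
    accum(gamma, dgamma)
    accum(beta, dbeta)
  })
}

# ---- convolution / pooling (C++ kernels) ----

ad_conv3d <- function(x, w, b = NULL, stride = 1L, pad = 0L) {
  bv <- if (is.null(b)) numeric(0) else nval(b)
  v <- .conv3d_fwd_cpp(nval(x), nval(w), bv, as.integer(stride), as.integer(pad))
  if (!any_node(x, w, b)) return(v)
  new_node(v, list(x, w, b), function(g) {
    r <- .conv3d_bwd_cpp(nval(x), nval(w), g, as.integer(stride), as.integer(pad),
                         length(bv) > 0)
    accum(x, r$dx)
    accum(w, r$dw)
    if (!is.null(b) && length(bv)) accum(b, r$db)
  })
}

ad_maxpool3d <- function(x, k = 3L, stride = 2L, pad = 1L) {
  r <- .maxpool3d_fwd_cpp(nval(x), as.integer(k), as.integer(stride), as.integer(pad))
  if (!is_node(x)) return(r$out)
  d <- dim(nval(x))
  new_node(r$out, list(x), function(g) {
    accum(x, .maxpool3d_bwd_cpp(r$argmax, g, as.integer(d)))
  })
}

# ---- scalar reductions ----

ad_mean_all <- function(x) {
  xv <- nval(x)
  v <- mean(xv)
  if (!is_node(x)) return(v)
  n <- length(xv)
  new_node(v, list(x), function(g) {
    dx <- array(as.numeric(g) / n, dim = if (is.null(dim(xv))) NULL else dim(xv))
    if (is.null(dim(xv))) dx <- rep(as.numeric(g) / n, n)
    accum(x, dx)
  })
}
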