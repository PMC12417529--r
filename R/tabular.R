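# Clinical tabular encoder: a single Kolmogorov-Arnold (B-spline) layer that
# lifts the 7 standardized clinical features into a latent vector, followed by
# M PoolFormer blocks operating on a token view of that vector.

#' Define a uniform B-spline grid
#'
#' Knots are uniform over `range` with `order`-fold extension at both ends, so
#' there are `grid_size + order` basis functions. Inputs outside the range are
#' evaluated by the natural polynomial extension of the boundary pieces.
#'
#' @param order Polynomial degree of the spline pieces (k >= 1).
#' @param grid_size Number of intervals G over `range`.
#' @param range Length-2 numeric `(lo, hi)`, `hi > lo`.
#' @return An object of class `spline_grid`.
#' @export
spline_grid <- function(order = 3L, grid_size = 5L, range = c(-2, 2)) {
  order <- as.integer(order); grid_size <- as.integer(grid_size)
  if (order < 1L) stop("spline order must be >= 1")
  if (grid_size < 1L) stop("grid_size must be >= 1")
  if (!(range[2] > range[1])) stop("degenerate knot vector: hi must exceed lo")
  h <- (range[2] - range[1]) / grid_size
  knots <- range[1] + ((-order):(grid_size + order)) * h
  structure(list(order = order, grid_size = grid_size, range = range,
                 h = h, knots = knots, nbasis = grid_size + order),
            class = "spline_grid")
}

# de Boor evaluation on the clamped interval index; uniform knots make all
# denominators equal to d*h. Returns basis values and (optionally) first
# derivatives as [n, G+k] matrices.
.bspline_eval <- function(x, grid, deriv = FALSE) {
  k <- grid$order; G <- grid$grid_size
  lo <- grid$range[1]; h <- grid$h
  n <- length(x)
  j <- pmin(pmax(floor((x - lo) / h), 0), G - 1)
  u <- x - (lo + j * h)
  N <- matrix(1, n, 1)
  Nk1 <- if (k == 1L) N else NULL
  for (d in seq_len(k)) {
    saved <- numeric(n)
    Nn <- matrix(0, n, d + 1)
    for (r in 0:(d - 1)) {
      temp <- N[, r + 1] / (d * h)
      Nn[, r + 1] <- saved + ((r + 1) * h - u) * temp
      saved <- (u + (d - r - 1) * h) * temp
    }
    Nn[, d + 1] <- saved
    if (deriv && d == k - 1L) Nk1 <- Nn
    N <- Nn
  }
  cols <- as.vector(outer(j, 0:k, "+")) + 1
  idx <- cbind(rep(seq_len(n), k + 1), cols)
  B <- matrix(0, n, G + k)
  B[idx] <- as.vector(N)
  if (!deriv) return(list(B = B))
  P <- cbind(0, Nk1, 0)                     # degree k-1 values, zero padded
  dN <- (P[, 1:(k + 1), drop = FALSE] - P[, 2:(k + 2), drop = FALSE]) / h
  D <- matrix(0, n, G + k)
  D[idx] <- as.vector(dN)
  list(B = B, dB = D)
}

#' Evaluate the B-spline basis at points
#'
#' Inside the grid range the `G + k` basis values are nonnegative and sum to
#' one (partition of unity).
#'
#' @param x Numeric vector of evaluation points.
#' @param grid A [spline_grid()].
#' @return Matrix `[length(x), G + k]` of basis values (a plain vector for
#'   scalar `x`).
#' @export
bspline_basis <- function(x, grid) {
  stopifnot(inherits(grid, "spline_grid"))
  B <- .bspline_eval(x, grid)$B
  if (length(x) == 1L) drop(B) else B
}

#' Initialize parameters of a Kolmogorov-Arnold layer
#'
#' Each edge function is `w_b * SiLU(x) + w_s * sum_r c_r B_r(x)`, without a
#' bias term.
#'
#' @param in_dim,out_dim Layer dimensions.
#' @param grid A [spline_grid()].
#' @param coef_sd Standard deviation of the random spline coefficients.
#' @return A list with `w_b`, `w_s`, `coeffs` (`[out, in, G + k]`) and `grid`.
#' @export
kan_params <- function(in_dim, out_dim, grid = spline_grid(), coef_sd = 0.1) {
  R <- grid$nbasis
  sd_w <- sqrt(2 / in_dim)
  list(w_b = matrix(stats::rnorm(out_dim * in_dim, sd = sd_w), out_dim, in_dim),
       w_s = matrix(1, out_dim, in_dim),
       coeffs = array(stats::rnorm(out_dim * in_dim * R, sd = coef_sd),
                      dim = c(out_dim, in_dim, R)),
       grid = grid)
}

# autodiff-aware KAN forward; x [B, in] (plain or node), params entries may be
# nodes. Gradients flow to w_b, w_s, coeffs and to x (via basis derivatives).
ad_kan <- function(x, w_b, w_s, coeffs, grid) {
  xv <- nval(x); wbv <- nval(w_b); wsv <- nval(w_s); cv <- nval(coeffs)
  if (is.null(dim(xv))) xv <- matrix(xv, 1)
  B <- nrow(xv); p <- ncol(xv)
  out_dim <- nrow(wbv); R <- grid$nbasis
  need_dx <- is_node(x)
  ev <- .bspline_eval(as.vector(xv), grid, deriv = need_dx)
  Fm <- matrix(ev$B, B, p * R)              # [(b), (i fastest, r)] layout
  sg <- 1 / (1 + exp(-xv))
  S <- xv * sg
  ca <- aperm(cv, c(2, 3, 1)); dim(ca) <- c(p * R, out_dim)
  wsbig <- t(wsv)[rep(seq_len(p), times = R), , drop = FALSE]
  Ceff <- ca * wsbig
  v <- S %*% t(wbv) + Fm %*% Ceff
  if (!any_node(x, w_b, w_s, coeffs)) return(v)
  new_node(v, list(x, w_b, w_s, coeffs), function(g) {
    accum(w_b, t(g) %*% S)
    dCeff <- t(Fm) %*% g
    dca <- dCeff * wsbig
    dim(dca) <- c(p, R, out_dim)
    accum(coeffs, aperm(dca, c(3, 1, 2)))
    dwsm <- dCeff * ca
    dim(dwsm) <- c(p, R, out_dim)
    accum(w_s, t(apply(dwsm, c(1, 3), sum)))
    if (need_dx) {
      dS <- g %*% wbv
      dx_base <- dS * (sg + xv * sg * (1 - sg))
      dFm <- g %*% t(Ceff)
      dB <- matrix(ev$dB, B, p * R)
      dx_spl <- matrix(rowSums(array(dFm * dB, dim = c(B * p, R))), B, p)
      accum(x, dx_base + dx_spl)
    }
  })
}

#' Forward pass of a single Kolmogorov-Arnold layer
#'
#' Computes `out_j = sum_i w_b[j,i] SiLU(x_i) + w_s[j,i] sum_r c[j,i,r]
#' B_r(x_i)` (no bias).
#'
#' @param x Numeric vector `[in_dim]` or matrix `[B, in_dim]`.
#' @param params A [kan_params()] list.
#' @return Vector `[out_dim]` (or matrix `[B, out_dim]`).
#' @export
kan_layer_forward <- function(x, params) {
  vec <- is.null(dim(x))
  out <- ad_kan(if (vec) matrix(x, 1) else x, params$w_b, params$w_s,
                params$coeffs, params$grid)
  if (vec) drop(out) else out
}

#' Initialize a stack of PoolFormer blocks
#'
#' @param tokens,channels Token count and channel width of the token view.
#' @param blocks Number of blocks M.
#' @param expansion MLP expansion ratio.
#' @return A list of per-block parameter lists plus the geometry.
#' @export
poolformer_params <- function(tokens = 8L, channels = 8L, blocks = 2L,
                              expansion = 4L) {
  blk <- function() {
    hid <- channels * expansion
    list(ln1_g = rep(1, channels), ln1_b = rep(0, channels),
         ln2_g = rep(1, channels), ln2_b = rep(0, channels),
         w1 = matrix(stats::rnorm(channels * hid, sd = sqrt(2 / channels)),
                     channels, hid),
         b1 = rep(0, hid),
         w2 = matrix(stats::rnorm(hid * channels, sd = sqrt(2 / hid)),
                     hid, channels),
         b2 = rep(0, channels))
  }
  list(tokens = as.integer(tokens), channels = as.integer(channels),
       blocks = lapply(seq_len(blocks), function(i) blk()))
}

# one PoolFormer block on [B, T, C] (plain or nodes in `pb`)
ad_poolformer_block <- function(H, pb) {
  Hn <- ad_layernorm(H, pb$ln1_g, pb$ln1_b)
  H1 <- ad_add(H, ad_avgpool_tokens(Hn))
  H2n <- ad_layernorm(H1, pb$ln2_g, pb$ln2_b)
  d <- dim(nval(H2n))
  Xm <- ad_reshape(H2n, c(d[1] * d[2], d[3]))
  M <- ad_linear(ad_gelu(ad_linear(Xm, pb$w1, pb$b1)), pb$w2, pb$b2)
  ad_add(H1, ad_reshape(M, d))
}

#' Forward pass of one PoolFormer block
#'
#' The token mixer is `H' = H + AvgPool(LayerNorm(H))` (average pooling over
#' the token axis, kernel 3, stride 1, averaging only existing neighbors),
#' followed by `H = H' + MLP(LayerNorm(H'))` with a GELU MLP over channels.
#'
#' @param H Numeric `[T, C]` matrix or `[B, T, C]` array.
#' @param params One element of `poolformer_params()$blocks`.
#' @return Array of the same shape as `H`.
#' @export
poolformer_block_forward <- function(H, params) {
  two_d <- length(dim(H)) == 2L
  if (two_d) H <- array(H, dim = c(1L, dim(H)))
  out <- ad_poolformer_block(H, params)
  if (two_d) array(out[1, , ], dim = dim(out)[2:3]) else out
}

# full tabular branch with nodes allowed; x [B, 7]
ad_tabular_encode <- function(x, kan, pf) {
  H <- ad_kan(x, kan$w_b, kan$w_s, kan$coeffs, kan$grid)   # [B, D_tab]
  Bn <- nrow(nval(H))
  Tt <- pf$tokens; Ct <- pf$channels
  H <- ad_aperm(ad_reshape(H, c(Bn, Ct, Tt)), c(1, 3, 2))  # [B, T, C]
  for (pb in pf$blocks) H <- ad_poolformer_block(H, pb)
  ad_reshape(ad_aperm(H, c(1, 3, 2)), c(Bn, Tt * Ct))
}

#' Encode clinical feature vectors into latent tabular embeddings
#'
#' Runs the KAN layer, reshapes its `D_tab`-dimensional output into
#' `tokens x channels`, applies the PoolFormer stack and flattens back.
#'
#' @param x Numeric vector `[7]` or matrix `[B, 7]` of standardized features.
#' @param kan A [kan_params()] list whose output dimension equals
#'   `tokens * channels` of `pf`.
#' @param pf A [poolformer_params()] list.
#' @return Vector `[D_tab]` (or matrix `[B, D_tab]`).
#' @export
tabular_encode <- function(x, kan, pf) {
  if (nrow(kan$w_b) != pf$tokens * pf$channels)
    stop("KAN output dimension ", nrow(kan$w_b),
         " is not tokens * channels = ", pf$tokens * pf$channels)
  vec <- is.null(dim(x))
  out <- ad_tabular_encode(if (vec) matrix(x, 1) else x, kan, pf)
  if (vec) drop(out) else out
}

# MLP substitute for the KAN layer (ablation switch): SiLU(x W + b)
mlp_tabular_params <- function(in_dim, out_dim) {
  list(w = matrix(stats::rnorm(in_dim * out_dim, sd = sqrt(2 / in_dim)),
                  in_dim, out_dim),
       b = rep(0, out_dim))
}

ad_mlp_tabular <- function(x, p) ad_silu(ad_linear(x, p$w, p$b))
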