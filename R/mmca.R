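# MultiModal Cascaded Attention: the two HBAM-refined streams, viewed as
# token sequences, are split into N channel groups; within each group
# bidirectional cross-attention (queries from the opposite modality) with a
# learnable position bias is applied, and each modality's group input is the
# channel slice plus its own attended output from the previous group
# (cascade). Group outputs are concatenated and projected per modality, and
# the two projected streams are concatenated along channels.

#' Flatten a feature map into a token sequence
#'
#' Tokens are ordered row-major in `(d, h, w)`: the token for voxel
#' `(d, h, w)` (0-based) sits at flattened position `(d*H + h)*W + w`.
#'
#' @param f Feature map `[B, C, D, H, W]`.
#' @return Token array `[B, L, C]` with `L = D*H*W`.
#' @export
tokens_from_featuremap <- function(f) {
  d <- dim(nval(f))
  ad_reshape(ad_aperm(f, c(1, 5, 4, 3, 2)), c(d[1], d[3] * d[4] * d[5], d[2]))
}

#' Restore a feature map from a token sequence
#'
#' Inverse of [tokens_from_featuremap()].
#'
#' @param tok Token array `[B, L, C]`.
#' @param spatial Integer `(D, H, W)` with `prod(spatial) == L`.
#' @return Feature map `[B, C, D, H, W]`.
#' @export
featuremap_from_tokens <- function(tok, spatial) {
  d <- dim(nval(tok))
  if (prod(spatial) != d[2]) stop("token count does not match spatial shape")
  ad_aperm(ad_reshape(tok, c(d[1], spatial[3], spatial[2], spatial[1], d[3])),
           c(1, 5, 4, 3, 2))
}

#' Initialize MMCA parameters
#'
#' @param channels Channel width C of each token stream; divisible by
#'   `groups`.
#' @param tokens Token count L (the position bias is an L x L matrix, so the
#'   input spatial shape is fixed at build time).
#' @param groups Number of attention groups N.
#' @param bias_init Initial value of the position bias (0 by default).
#' @return Nested parameter list of class `mmca_params`.
#' @export
mmca_params <- function(channels, tokens, groups = 4L, bias_init = 0) {
  if (channels %% groups != 0L) stop("channels must be divisible by groups")
  d <- channels %/% groups
  pm <- function() matrix(stats::rnorm(d * d, sd = sqrt(1 / d)), d, d)
  grp <- function() list(qx = pm(), kx = pm(), vx = pm(),
                         qy = pm(), ky = pm(), vy = pm(),
                         bias = matrix(bias_init, tokens, tokens))
  structure(list(
    N = as.integer(groups), d = d, L = as.integer(tokens),
    C = as.integer(channels),
    groups = lapply(seq_len(groups), function(i) grp()),
    proj_x_w = matrix(stats::rnorm(channels^2, sd = sqrt(2 / channels)),
                      channels, channels),
    proj_x_b = rep(0, channels),
    proj_y_w = matrix(stats::rnorm(channels^2, sd = sqrt(2 / channels)),
                      channels, channels),
    proj_y_b = rep(0, channels)
  ), class = "mmca_params")
}

#' Scaled dot-product attention with a position bias
#'
#' `scores = t(q) k / sqrt(d_k) + bias`, rows softmax-normalized with max
#' subtraction, output `weights %*% t(v)`.
#'
#' @param q,k,v Matrices `[d_k, L]`.
#' @param bias Matrix `[L, L]`.
#' @return Matrix `[L, d_k]` of attended values.
#' @export
biased_attention <- function(q, k, v, bias) {
  dk <- nrow(nval(q))
  scores <- ad_add(ad_smul(ad_matmul(ad_t(q), k), 1 / sqrt(dk)), bias)
  ad_matmul(ad_softmax_rows(scores), ad_t(v))
}

# per-item cascaded grouped bidirectional cross-attention; Xi, Yi are [C, L]
.mmca_item <- function(Xi, Yi, params) {
  N <- params$N; d <- params$d
  prevx <- NULL; prevy <- NULL
  outx <- vector("list", N); outy <- vector("list", N)
  for (i in seq_len(N)) {
    g <- params$groups[[i]]
    i0 <- (i - 1L) * d + 1L; i1 <- i * d
    gx <- ad_rows(Xi, i0, i1)
    gy <- ad_rows(Yi, i0, i1)
    if (i > 1L) {
      gx <- ad_add(gx, prevx)
      gy <- ad_add(gy, prevy)
    }
    qx <- ad_matmul(g$qx, gx); kx <- ad_matmul(g$kx, gx); vx <- ad_matmul(g$vx, gx)
    qy <- ad_matmul(g$qy, gy); ky <- ad_matmul(g$ky, gy); vy <- ad_matmul(g$vy, gy)
    vhx <- biased_attention(qy, kx, vx, g$bias)  # [L, d]
    vhy <- biased_attention(qx, ky, vy, g$bias)
    prevx <- ad_t(vhx)
    prevy <- ad_t(vhy)
    outx[[i]] <- vhx
    outy[[i]] <- vhy
  }
  cx <- Reduce(ad_cbind, outx)                  # [L, C]
  cy <- Reduce(ad_cbind, outy)
  list(zx = ad_linear(cx, params$proj_x_w, params$proj_x_b),
       zy = ad_linear(cy, params$proj_y_w, params$proj_y_b))
}

#' MMCA forward pass
#'
#' @param X,Y Token arrays `[B, L, C]` from the two modality streams.
#' @param params An [mmca_params()] built for the same `L` and `C`.
#' @return Fused representation `[B, L, 2C]` (the X-stream channels first).
#' @export
mmca_forward <- function(X, Y, params) {
  dx <- dim(nval(X)); dy <- dim(nval(Y))
  if (!identical(dx, dy)) stop("X and Y must share [B, L, C]")
  if (dx[3] != params$C) stop("channel width does not match params")
  if (dx[2] != params$L) stop("token count does not match params (L is fixed at build time)")
  B <- dx[1]
  zx <- vector("list", B); zy <- vector("list", B)
  for (b in seq_len(B)) {
    r <- .mmca_item(ad_item_mat(X, b), ad_item_mat(Y, b), params)
    zx[[b]] <- ad_t(r$zx)                       # [C, L] for stacking
    zy[[b]] <- ad_t(r$zy)
  }
  ad_concat_last3(ad_stack_items(zx), ad_stack_items(zy))
}
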