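# Hybrid Block Attention Module: channel attention whose logits mix global
# average/max pooled image statistics with an embedded clinical vector,
# followed by CBAM-style spatial attention. Information flows from the
# clinical vector into the image stream only; both gates lie in (0, 1), so
# HBAM never increases feature magnitude and preserves sign patterns.

#' Initialize HBAM parameters
#'
#' @param c_img Image feature channels entering the module.
#' @param c_cli Length of the clinical embedding (`D_tab`).
#' @param reduction Bottleneck ratio r of the shared channel MLP; must divide
#'   `c_img`.
#' @param spatial_kernel Spatial attention convolution kernel (odd).
#' @return Nested parameter list of class `hbam_params`.
#' @export
hbam_params <- function(c_img, c_cli, reduction = 8L, spatial_kernel = 7L) {
  if (c_img %% reduction != 0L) stop("reduction must divide c_img")
  hid <- c_img %/% reduction
  k <- as.integer(spatial_kernel)
  if (k %% 2L != 1L) stop("spatial kernel must be odd")
  structure(list(
    embed_w = matrix(stats::rnorm(c_cli * c_img, sd = sqrt(2 / c_cli)),
                     c_cli, c_img),
    embed_b = rep(0, c_img),
    mlp_w1 = matrix(stats::rnorm(c_img * hid, sd = sqrt(2 / c_img)), c_img, hid),
    mlp_b1 = rep(0, hid),
    mlp_w2 = matrix(stats::rnorm(hid * c_img, sd = sqrt(2 / hid)), hid, c_img),
    spatial_w = .conv_init(k, 2L, 1L),
    spatial_b = rep(0, 1),
    kernel = k
  ), class = "hbam_params")
}

#' Embed a clinical feature vector into image channel space
#'
#' @param f_cli Clinical embedding vector `[c_cli]` or matrix `[B, c_cli]`.
#' @param params An [hbam_params()].
#' @return Vector `[c_img]` (or matrix `[B, c_img]`).
#' @export
embed_clinical <- function(f_cli, params) {
  vec <- is.null(dim(f_cli))
  out <- ad_linear(if (vec) matrix(f_cli, 1) else f_cli,
                   params$embed_w, params$embed_b)
  if (vec) drop(out) else out
}

# shared bottleneck MLP on pooled channel vectors [B, C]; no bias on the
# final layer so that zero weights give exactly zero logits
.hbam_mlp <- function(v, params) {
  ad_linear(ad_relu(ad_linear(v, params$mlp_w1, params$mlp_b1)),
            params$mlp_w2, NULL)
}

#' Hybrid channel attention
#'
#' Computes global average and max pooled channel descriptors, passes both
#' through a shared bottleneck MLP, adds the clinical embedding to the summed
#' logits, applies a sigmoid and rescales each channel:
#' `F_hc = sigmoid(M_avg + M_max + E_cli) (x) F_img`. With `E_cli = 0` this is
#' exactly CBAM channel attention.
#'
#' @param f_img Feature map `[B, C, D, H, W]`.
#' @param e_cli Clinical embedding `[B, C]` (or vector `[C]`, recycled).
#' @param params An [hbam_params()].
#' @return Gated feature map of the same shape.
#' @export
hybrid_channel_attention <- function(f_img, e_cli, params) {
  d <- dim(nval(f_img))
  if (is.null(dim(nval(e_cli))) && !is_node(e_cli))
    e_cli <- matrix(e_cli, d[1], length(e_cli), byrow = TRUE)
  f_avg <- ad_gap_spatial(f_img)
  f_max <- ad_gmp_spatial(f_img)
  logits <- ad_add(ad_add(.hbam_mlp(f_avg, params), .hbam_mlp(f_max, params)),
                   e_cli)
  ad_scale_channels(f_img, ad_sigmoid(logits))
}

#' Spatial attention
#'
#' Concatenates the channel-wise mean and max maps, convolves them (kernel
#' `params$kernel`, stride 1, zero padding preserving shape), applies a
#' sigmoid and rescales every channel by the resulting `[B, 1, D, H, W]` map.
#'
#' @param f_hc Feature map `[B, C, D, H, W]`.
#' @param params An [hbam_params()].
#' @return Gated feature map of the same shape.
#' @export
spatial_attention <- function(f_hc, params) {
  pooled <- ad_concat_ch5(ad_channel_mean(f_hc), ad_channel_max(f_hc))
  pad <- (params$kernel - 1L) %/% 2L
  m <- ad_sigmoid(ad_conv3d(pooled, params$spatial_w, params$spatial_b, 1L, pad))
  ad_scale_spatial(f_hc, m)
}

#' Full HBAM forward pass
#'
#' `spatial_attention(hybrid_channel_attention(F_img, Embed(F_cli)))`.
#'
#' @param f_img Feature map `[B, C, D, H, W]`.
#' @param f_cli Clinical embedding `[B, c_cli]` (or vector).
#' @param params An [hbam_params()].
#' @return Refined feature map `[B, C, D, H, W]`.
#' @export
hbam_forward <- function(f_img, f_cli, params) {
  if (is.null(dim(nval(f_cli))) && !is_node(f_cli))
    f_cli <- matrix(f_cli, 1)
  e <- ad_linear(f_cli, params$embed_w, params$embed_b)
  spatial_attention(hybrid_channel_attention(f_img, e, params), params)
}
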