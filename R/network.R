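# Full network assembly: tabular encoder -> two image encoders -> HBAM
# refinement of each imaging stream by the clinical embedding -> token
# flattening -> MMCA fusion -> mean-pooled classification head emitting a
# single pMCI logit. Focal loss handles the pMCI/sMCI class imbalance.

#' Configure the triple-modal fusion network
#'
#' @param preset Image-encoder preset, `"test"` (default; 24x32x24 inputs) or
#'   `"full"` (96x128x96 inputs).
#' @param input_shape Volume shape `(D, H, W)`; defaults to the preset's
#'   native shape.
#' @param d_tab Latent clinical embedding width (`tokens * channels`).
#' @param tab_tokens,tab_channels,tab_blocks Token view geometry and
#'   PoolFormer depth of the tabular branch.
#' @param use_kan Use the Kolmogorov-Arnold layer (`TRUE`) or a plain
#'   linear+SiLU layer (the MLP ablation).
#' @param grid_size,spline_order,spline_range B-spline grid of the KAN layer.
#' @param hbam_reduction,spatial_kernel HBAM bottleneck ratio and spatial
#'   kernel.
#' @param mmca_groups Number of cascaded attention groups N.
#' @param use_hbam,use_mmca Ablation switches; with `FALSE` the HBAM modules
#'   are skipped and/or MMCA is replaced by plain channel concatenation.
#' @param head_hidden Hidden width of the classification head.
#' @return An object of class `trifuse_config`.
#' @export
trifuse_config <- function(preset = c("test", "full"), input_shape = NULL,
                           d_tab = 64L, tab_tokens = 8L, tab_channels = 8L,
                           tab_blocks = 2L, use_kan = TRUE, grid_size = 5L,
                           spline_order = 3L, spline_range = c(-2, 2),
                           hbam_reduction = 8L, spatial_kernel = 7L,
                           mmca_groups = 4L, use_hbam = TRUE, use_mmca = TRUE,
                           head_hidden = 64L) {
  preset <- match.arg(preset)
  if (is.null(input_shape))
    input_shape <- if (preset == "full") c(96L, 128L, 96L) else c(24L, 32L, 24L)
  if (d_tab != tab_tokens * tab_channels)
    stop("d_tab must equal tab_tokens * tab_channels")
  enc <- encoder_config(preset)
  ds <- 4L * prod(enc$stage_strides)
  spatial <- as.integer(input_shape) %/% ds
  if (any(as.integer(input_shape) %% ds != 0L))
    stop("input_shape must be divisible by the encoder downsampling factor ", ds)
  structure(list(
    preset = preset, input_shape = as.integer(input_shape), encoder = enc,
    c_img = enc$widths[4], feat_spatial = spatial,
    tokens = prod(spatial),
    d_tab = as.integer(d_tab), tab_tokens = as.integer(tab_tokens),
    tab_channels = as.integer(tab_channels), tab_blocks = as.integer(tab_blocks),
    use_kan = isTRUE(use_kan), grid_size = as.integer(grid_size),
    spline_order = as.integer(spline_order), spline_range = spline_range,
    hbam_reduction = as.integer(hbam_reduction),
    spatial_kernel = as.integer(spatial_kernel),
    mmca_groups = as.integer(mmca_groups),
    use_hbam = isTRUE(use_hbam), use_mmca = isTRUE(use_mmca),
    head_hidden = as.integer(head_hidden)
  ), class = "trifuse_config")
}

#' Initialize all network parameters
#'
#' @param config A [trifuse_config()].
#' @param seed Integer seed for the random initialization.
#' @return List with `params` (nested trainable arrays) and `state` (an
#'   environment of batch-norm running statistics, keys prefixed `mri.` /
#'   `pet.`).
#' @export
trifuse_init <- function(config, seed = 1L) {
  with_seed(seed, {
    tab <- if (config$use_kan) {
      list(kan = kan_params(7L, config$d_tab,
                            spline_grid(config$spline_order, config$grid_size,
                                        config$spline_range)),
           pf = poolformer_params(config$tab_tokens, config$tab_channels,
                                  config$tab_blocks))
    } else {
      list(mlp = mlp_tabular_params(7L, config$d_tab),
           pf = poolformer_params(config$tab_tokens, config$tab_channels,
                                  config$tab_blocks))
    }
    enc_mri <- resnet3d_params(config$encoder)
    enc_pet <- resnet3d_params(config$encoder)
    C <- config$c_img
    p <- list(tab = tab, enc_mri = enc_mri$params, enc_pet = enc_pet$params)
    if (config$use_hbam) {
      p$hbam_mri <- hbam_params(C, config$d_tab, config$hbam_reduction,
                                config$spatial_kernel)
      p$hbam_pet <- hbam_params(C, config$d_tab, config$hbam_reduction,
                                config$spatial_kernel)
    }
    if (config$use_mmca)
      p$mmca <- mmca_params(C, config$tokens, config$mmca_groups)
    hid <- config$head_hidden
    p$head <- list(ln_g = rep(1, 2 * C), ln_b = rep(0, 2 * C),
                   w1 = matrix(stats::rnorm(2 * C * hid, sd = sqrt(2 / (2 * C))),
                               2 * C, hid),
                   b1 = rep(0, hid),
                   w2 = matrix(stats::rnorm(hid, sd = sqrt(2 / hid)), hid, 1),
                   b2 = rep(0, 1))
    state <- new.env(parent = emptyenv())
    for (nm in ls(enc_mri$state)) state[[paste0("mri.", nm)]] <- enc_mri$state[[nm]]
    for (nm in ls(enc_pet$state)) state[[paste0("pet.", nm)]] <- enc_pet$state[[nm]]
    list(params = p, state = state)
  })
}

# autodiff-aware full forward; returns logits [B, 1]
ad_trifuse <- function(mri, pet, cli, params, config, state,
                       training = FALSE) {
  f_cli <- if (config$use_kan)
    ad_tabular_encode(cli, params$tab$kan, params$tab$pf)
  else {
    h <- ad_mlp_tabular(cli, params$tab$mlp)
    Bn <- nrow(nval(h))
    h <- ad_aperm(ad_reshape(h, c(Bn, config$tab_channels, config$tab_tokens)),
                  c(1, 3, 2))
    for (pb in params$tab$pf$blocks) h <- ad_poolformer_block(h, pb)
    ad_reshape(ad_aperm(h, c(1, 3, 2)), c(Bn, config$d_tab))
  }
  f_mri <- ad_resnet3d(mri, config$encoder, params$enc_mri, state,
                       training = training, prefix = "mri.")
  f_pet <- ad_resnet3d(pet, config$encoder, params$enc_pet, state,
                       training = training, prefix = "pet.")
  if (config$use_hbam) {
    f_mri <- hbam_forward(f_mri, f_cli, params$hbam_mri)
    f_pet <- hbam_forward(f_pet, f_cli, params$hbam_pet)
  }
  tx <- tokens_from_featuremap(f_mri)
  ty <- tokens_from_featuremap(f_pet)
  z <- if (config$use_mmca) mmca_forward(tx, ty, params$mmca)
       else ad_concat_last3(tx, ty)
  h <- ad_mean_tokens(z)
  h <- ad_layernorm(h, params$head$ln_g, params$head$ln_b)
  h <- ad_gelu(ad_linear(h, params$head$w1, params$head$b1))
  ad_linear(h, params$head$w2, params$head$b2)
}

#' Run the assembled network on a batch of subjects
#'
#' @param model A fitted `trifuse` object (or a list with `params`, `state`,
#'   `config`).
#' @param mri,pet Volume batches: lists of [volume_grid()] or arrays
#'   `[B, 1, D, H, W]`.
#' @param clinical Standardized clinical matrix `[B, 7]`.
#' @param training Logical; evaluation mode (running batch-norm statistics)
#'   by default.
#' @return Data frame with columns `logit`, `probability` and `class`
#'   (the 0.5-threshold label, 1 = pMCI).
#' @export
trifuse_forward <- function(model, mri, pet, clinical, training = FALSE) {
  if (is.null(dim(clinical))) clinical <- matrix(clinical, 1)
  z <- ad_trifuse(volumes_to_batch(mri), volumes_to_batch(pet), clinical,
                  model$params, model$config, model$state, training = training)
  z <- as.vector(nval(z))
  p <- 1 / (1 + exp(-z))
  data.frame(logit = z, probability = p, class = as.integer(p >= 0.5))
}

#' Focal loss for binary classification
#'
#' The default form uses `p_t = p` if `y = 1` else `1 - p` and
#' `alpha_t = alpha` if `y = 1` else `1 - alpha`:
#' `loss = -alpha_t (1 - p_t)^gamma log(p_t)`; at `gamma = 0`, `alpha = 1`
#' it reduces to cross-entropy. `literal_form = TRUE` instead multiplies the
#' full cross-entropy by a single `alpha (1 - p)^gamma` factor.
#' Probabilities are clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param p Predicted positive-class probabilities in (0, 1).
#' @param y Labels in \{0, 1\}.
#' @param alpha Class-balance weight in `[0, 1]`.
#' @param gamma Focusing parameter (>= 0).
#' @param literal_form Use the single-factor variant.
#' @return Vector of per-sample losses.
#' @export
focal_loss <- function(p, y, alpha = 0.75, gamma = 2, literal_form = FALSE) {
  if (!all(y %in% c(0, 1))) stop("labels must be 0 or 1")
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  if (gamma < 0) stop("gamma must be nonnegative")
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  if (literal_form) {
    -alpha * (1 - p)^gamma * (y * log(p) + (1 - y) * log(1 - p))
  } else {
    pt <- ifelse(y == 1, p, 1 - p)
    at <- ifelse(y == 1, alpha, 1 - alpha)
    -at * (1 - pt)^gamma * log(pt)
  }
}

# focal loss on logits as an autodiff op (mean over the batch)
ad_focal_from_logits <- function(z, y, alpha = 0.75, gamma = 2,
                                 literal_form = FALSE) {
  zv <- as.vector(nval(z))
  p_raw <- 1 / (1 + exp(-zv))
  p <- pmin(pmax(p_raw, 1e-7), 1 - 1e-7)
  li <- focal_loss(p, y, alpha, gamma, literal_form)
  v <- mean(li)
  if (!is_node(z)) return(v)
  n <- length(zv)
  new_node(v, list(z), function(g) {
    if (literal_form) {
      core <- y * log(p) + (1 - y) * log(1 - p)
      mod_d <- if (gamma > 0) -gamma * (1 - p)^(gamma - 1) * core else rep(0, n)
      dLdp <- -alpha * (mod_d + (1 - p)^gamma * (y / p - (1 - y) / (1 - p)))
    } else {
      pt <- ifelse(y == 1, p, 1 - p)
      at <- ifelse(y == 1, alpha, 1 - alpha)
      mod_d <- if (gamma > 0) -gamma * (1 - pt)^(gamma - 1) * log(pt) else rep(0, n)
      dLdpt <- -at * (mod_d + (1 - pt)^gamma / pt)
      dLdp <- ifelse(y == 1, dLdpt, -dLdpt)
    }
    inside <- (p_raw > 1e-7) & (p_raw < 1 - 1e-7)
    dz <- ifelse(inside, dLdp * p_raw * (1 - p_raw), 0) * as.numeric(g) / n
    accum(z, matrix(dz, ncol = 1))
  })
}

#' Save a model checkpoint
#'
#' Stores parameters, batch-norm state, configuration and training history in
#' one archive, plus a human-readable JSON snapshot of the configuration next
#' to it.
#'
#' @param model A `trifuse` model object.
#' @param path Destination `.rds` path.
#' @return Invisibly, `path`.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(params = model$params, state = as.list(model$state),
              config = model$config, control = model$control,
              history = model$history, clinical_stats = model$clinical_stats)
  saveRDS(obj, path)
  cfg_path <- paste0(sub("\\.rds$", "", path), "_config.json")
  cfg <- model$config
  cfg$encoder <- unclass(cfg$encoder)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint saved by [save_checkpoint()]
#'
#' @param path Checkpoint `.rds` path.
#' @return A `trifuse` model object.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  state <- new.env(parent = emptyenv())
  for (nm in names(obj$state)) state[[nm]] <- obj$state[[nm]]
  structure(list(params = obj$params, state = state, config = obj$config,
                 control = obj$control, history = obj$history,
                 clinical_stats = obj$clinical_stats),
            class = "trifuse")
}
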