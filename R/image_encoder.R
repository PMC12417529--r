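# 3D residual image encoder ("ResNet-18 style" basic blocks in 3D). The full
# preset maps 96 x 128 x 96 volumes to a [256, 3, 4, 3] feature map (total
# downsampling x32); the test preset is a width/4, downsampling-x8 variant
# sized so a 24 x 32 x 24 volume yields the same 3 x 4 x 3 token grid, which
# keeps the whole pipeline runnable in seconds on a CPU.

#' Configure a 3D residual encoder
#'
#' @param preset `"full"` (widths 32/64/128/256, two blocks per stage, 7^3
#'   stem) or `"test"` (widths 8/16/32/64, one block per stage, 3^3 stem).
#' @param widths,blocks Optional overrides of the per-stage channel widths and
#'   block counts (length 4 each).
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(preset = c("full", "test"), widths = NULL,
                           blocks = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "full") {
    list(preset = preset, widths = c(32L, 64L, 128L, 256L),
         blocks = c(2L, 2L, 2L, 2L), stem_kernel = 7L, stem_stride = 2L,
         stage_strides = c(1L, 2L, 2L, 2L))
  } else {
    list(preset = preset, widths = c(8L, 16L, 32L, 64L),
         blocks = c(1L, 1L, 1L, 1L), stem_kernel = 3L, stem_stride = 2L,
         stage_strides = c(1L, 2L, 1L, 1L))
  }
  if (!is.null(widths)) cfg$widths <- as.integer(widths)
  if (!is.null(blocks)) cfg$blocks <- as.integer(blocks)
  if (any(diff(cfg$widths) <= 0)) stop("stage widths must be strictly increasing")
  structure(cfg, class = "encoder_config")
}

.conv_init <- function(k, cin, cout) {
  array(stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / (k^3 * cin))),
        dim = c(k, k, k, cin, cout))
}

.bn_init <- function(c) list(g = rep(1, c), b = rep(0, c))

#' Initialize encoder parameters and batch-norm state
#'
#' @param config An [encoder_config()].
#' @param in_channels Number of input channels (1 for a single volume).
#' @return List with `params` (nested trainable arrays) and `state` (an
#'   environment of batch-norm running statistics).
#' @export
resnet3d_params <- function(config, in_channels = 1L) {
  w <- config$widths
  state <- new.env(parent = emptyenv())
  add_bn <- function(key, c) {
    state[[paste0(key, ".mean")]] <- rep(0, c)
    state[[paste0(key, ".var")]] <- rep(1, c)
  }
  p <- list(stem = list(w = .conv_init(config$stem_kernel, in_channels, w[1]),
                        bn = .bn_init(w[1])))
  add_bn("stem.bn", w[1])
  stages <- list()
  cin <- w[1]
  for (s in 1:4) {
    blks <- list()
    for (b in seq_len(config$blocks[s])) {
      stride <- if (b == 1L) config$stage_strides[s] else 1L
      cout <- w[s]
      blk <- list(c1 = .conv_init(3L, cin, cout), bn1 = .bn_init(cout),
                  c2 = .conv_init(3L, cout, cout), bn2 = .bn_init(cout))
      key <- paste0("s", s, ".b", b)
      add_bn(paste0(key, ".bn1"), cout)
      add_bn(paste0(key, ".bn2"), cout)
      if (stride != 1L || cin != cout) {
        blk$sc <- .conv_init(1L, cin, cout)
        blk$scbn <- .bn_init(cout)
        add_bn(paste0(key, ".scbn"), cout)
      }
      blks[[b]] <- blk
      cin <- cout
    }
    stages[[s]] <- blks
  }
  p$stages <- stages
  list(params = p, state = state)
}

# autodiff-aware encoder forward; x is [B, Cin, D, H, W] (plain or node)
ad_resnet3d <- function(x, config, params, state, training = FALSE,
                        prefix = "") {
  key <- function(...) paste0(prefix, ...)
  pad <- (config$stem_kernel - 1L) %/% 2L
  y <- ad_conv3d(x, params$stem$w, NULL, config$stem_stride, pad)
  y <- ad_batchnorm(y, params$stem$bn$g, params$stem$bn$b, state,
                    key("stem.bn"), training)
  y <- ad_relu(y)
  y <- ad_maxpool3d(y, 3L, 2L, 1L)
  for (s in 1:4) {
    for (b in seq_along(params$stages[[s]])) {
      blk <- params$stages[[s]][[b]]
      stride <- if (b == 1L) config$stage_strides[s] else 1L
      bk <- key("s", s, ".b", b)
      z <- ad_conv3d(y, blk$c1, NULL, stride, 1L)
      z <- ad_batchnorm(z, blk$bn1$g, blk$bn1$b, state, paste0(bk, ".bn1"),
                        training)
      z <- ad_relu(z)
      z <- ad_conv3d(z, blk$c2, NULL, 1L, 1L)
      z <- ad_batchnorm(z, blk$bn2$g, blk$bn2$b, state, paste0(bk, ".bn2"),
                        training)
      sc <- if (!is.null(blk$sc)) {
        tmp <- ad_conv3d(y, blk$sc, NULL, stride, 0L)
        ad_batchnorm(tmp, blk$scbn$g, blk$scbn$b, state, paste0(bk, ".scbn"),
                     training)
      } else y
      y <- ad_relu(ad_add(z, sc))
    }
  }
  y
}

#' Extract feature maps from a batch of volumes
#'
#' @param volumes A list of [volume_grid()]s sharing one shape, or a numeric
#'   array `[B, 1, D, H, W]`.
#' @param config An [encoder_config()].
#' @param params,state From [resnet3d_params()].
#' @param training Logical; `FALSE` uses batch-norm running statistics
#'   (deterministic evaluation mode).
#' @return Feature map array `[B, C, D', H', W']`.
#' @export
resnet3d_forward <- function(volumes, config, params, state,
                             training = FALSE) {
  x <- volumes_to_batch(volumes)
  d <- dim(x)
  total_ds <- 4L * prod(config$stage_strides)
  if (any(d[3:5] < total_ds))
    stop("input spatial shape ", paste(d[3:5], collapse = "x"),
         " is smaller than the total downsampling factor ", total_ds)
  ad_resnet3d(x, config, params, state, training = training)
}

#' Stack volumes into a batch array
#'
#' @param volumes List of [volume_grid()]s with identical shapes, or an
#'   already-built `[B, 1, D, H, W]` array (returned unchanged).
#' @return Array `[B, 1, D, H, W]`.
#' @export
volumes_to_batch <- function(volumes) {
  if (is.array(volumes) && length(dim(volumes)) == 5L) return(volumes)
  if (inherits(volumes, "volume_grid")) volumes <- list(volumes)
  shapes <- vapply(volumes, function(v) dim(v$voxels), integer(3))
  if (ncol(shapes) > 1L && any(shapes != shapes[, 1]))
    stop("all volumes in a batch must share one shape")
  d <- shapes[, 1]
  x <- array(0, dim = c(length(volumes), 1L, d))
  for (b in seq_along(volumes)) x[b, 1, , , ] <- volumes[[b]]$voxels
  x
}
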