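# Integrated gradients: path-integral attribution from a baseline to the
# input, approximated with a midpoint Riemann sum. The attribution target is
# the pre-sigmoid logit; by the completeness axiom the attributions over all
# three input blocks sum to F(x) - F(x') up to the discretization gap, which
# is reported and shrinks as the step count grows.

#' Integrated gradients for a generic differentiable function
#'
#' Approximates `IG_i = (x_i - x'_i) * mean_s dF/dx_i` at the midpoints
#' `x' + (s - 1/2)/m * (x - x')`, `s = 1..m`.
#'
#' @param f_grad Function taking a numeric vector and returning a list with
#'   `value` (scalar) and `grad` (vector of the same length).
#' @param x Input vector.
#' @param baseline Baseline vector `x'` (defaults to zeros).
#' @param steps Number of path steps m (>= 1).
#' @return List with `attributions`, `completeness_gap`, `value` `F(x)` and
#'   `baseline_value` `F(x')`.
#' @export
integrated_gradients_fn <- function(f_grad, x, baseline = NULL, steps = 64L) {
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  if (is.null(baseline)) baseline <- x * 0
  diff <- x - baseline
  gsum <- x * 0
  for (s in seq_len(steps)) {
    a <- (s - 0.5) / steps
    g <- f_grad(baseline + a * diff)$grad
    if (any(!is.finite(g))) stop("non-finite gradients on the IG path")
    gsum <- gsum + g
  }
  attr_ <- diff * gsum / steps
  fx <- f_grad(x)$value
  f0 <- f_grad(baseline)$value
  list(attributions = attr_, completeness_gap = abs(sum(attr_) - (fx - f0)),
       value = fx, baseline_value = f0)
}

#' Integrated-gradients attribution for a fitted model
#'
#' Attributes the pMCI logit of one subject jointly over the MRI volume, the
#' PET volume and the 7 standardized clinical features, using a zero baseline
#' by default. Path points are evaluated in evaluation mode (running
#' batch-norm statistics), batched along the network's batch axis.
#'
#' @param model A fitted `trifuse` object (or list with `params`, `state`,
#'   `config`).
#' @param mri,pet Normalized input volumes: [volume_grid()]s or `[D, H, W]`
#'   arrays.
#' @param clinical Standardized clinical feature vector `[7]`.
#' @param steps Number of path steps m.
#' @param baseline Optional list with `mri`, `pet`, `clinical` baselines;
#'   zeros by default.
#' @param chunk Path points evaluated per forward pass.
#' @return An object of class `trifuse_attribution` with `mri_attr`,
#'   `pet_attr` (arrays matching the inputs), `clinical_attr` (length 7),
#'   `completeness_gap`, `value` and `baseline_value`.
#' @export
integrated_gradients <- function(model, mri, pet, clinical, steps = 64L,
                                 baseline = NULL, chunk = 8L) {
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be >= 1")
  vx <- function(v) if (inherits(v, "volume_grid")) v$voxels else v
  xm <- vx(mri); xp <- vx(pet); xc <- as.numeric(clinical)
  d <- dim(xm)
  bm <- if (is.null(baseline)) xm * 0 else vx(baseline$mri)
  bp <- if (is.null(baseline)) xp * 0 else vx(baseline$pet)
  bc <- if (is.null(baseline)) xc * 0 else as.numeric(baseline$clinical)
  dm <- xm - bm; dp <- xp - bp; dc <- xc - bc
  gm <- xm * 0; gp <- xp * 0; gc <- xc * 0
  logit_at <- function(am, ap, ac) {  # plain forward, batch of 1
    mb <- array(am, dim = c(1L, 1L, d)); pb <- array(ap, dim = c(1L, 1L, d))
    z <- ad_trifuse(mb, pb, matrix(ac, 1), model$params, model$config,
                    model$state, training = FALSE)
    as.numeric(nval(z))
  }
  s <- 1L
  while (s <= steps) {
    alphas <- ((s:min(s + chunk - 1L, steps)) - 0.5) / steps
    nb <- length(alphas)
    mb <- array(0, dim = c(nb, 1L, d)); pb <- array(0, dim = c(nb, 1L, d))
    cb <- matrix(0, nb, length(xc))
    for (i in seq_len(nb)) {
      mb[i, 1, , , ] <- bm + alphas[i] * dm
      pb[i, 1, , , ] <- bp + alphas[i] * dp
      cb[i, ] <- bc + alphas[i] * dc
    }
    nm <- ad_leaf(mb); np <- ad_leaf(pb); nc <- ad_leaf(cb)
    z <- ad_trifuse(nm, np, nc, model$params, model$config, model$state,
                    training = FALSE)
    tot <- ad_mean_all(ad_smul(z, nb))  # sum of the chunk's logits
    ad_backward(tot)
    if (any(!is.finite(nm$grad)) || any(!is.finite(nc$grad)))
      stop("non-finite gradients on the IG path")
    for (i in seq_len(nb)) {
      gm <- gm + array(nm$grad[i, 1, , , ], dim = d)
      gp <- gp + array(np$grad[i, 1, , , ], dim = d)
      gc <- gc + nc$grad[i, ]
    }
    s <- s + nb
  }
  am <- dm * gm / steps
  ap <- dp * gp / steps
  ac <- unname(dc * gc / steps)
  fx <- logit_at(xm, xp, xc)
  f0 <- logit_at(bm, bp, bc)
  structure(list(mri_attr = am, pet_attr = ap, clinical_attr = ac,
                 completeness_gap = abs(sum(am) + sum(ap) + sum(ac) - (fx - f0)),
                 value = fx, baseline_value = f0, steps = steps),
            class = "trifuse_attribution")
}

#' @export
print.trifuse_attribution <- function(x, ...) {
  cat(sprintf(
    "<trifuse_attribution> m=%d  F(x)=%.4f  F(x')=%.4f  completeness gap=%.3g\n",
    x$steps, x$value, x$baseline_value, x$completeness_gap))
  cat("clinical attributions:\n")
  print(stats::setNames(round(x$clinical_attr, 5), .clinical_order))
  invisible(x)
}

#' Export an attribution map as a NIfTI overlay
#'
#' Writes the voxel attributions for one modality into the reference
#' volume's grid and affine, optionally rescaled by the maximum absolute
#' value to `[-1, 1]` for display (signs and magnitude ranks are preserved).
#'
#' @param attr A `trifuse_attribution` (or a plain attribution array).
#' @param reference The [volume_grid()] the attributions align to.
#' @param path Output NIfTI path.
#' @param modality `"mri"` or `"pet"` when `attr` is an attribution object.
#' @param normalize Rescale to `[-1, 1]`.
#' @return Invisibly, `path`.
#' @export
export_overlay <- function(attr, reference, path, modality = c("mri", "pet"),
                           normalize = TRUE) {
  a <- if (inherits(attr, "trifuse_attribution")) {
    modality <- match.arg(modality)
    if (modality == "mri") attr$mri_attr else attr$pet_attr
  } else attr
  if (!identical(dim(a), dim(reference$voxels)))
    stop("attribution shape does not match the reference volume")
  if (normalize) {
    mx <- max(abs(a))
    if (mx > 0) a <- a / mx
  }
  write_volume(volume_grid(a, reference$affine, reference$subject_id), path)
}
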