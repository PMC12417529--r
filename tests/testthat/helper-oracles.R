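# Independent reference implementations used as oracles. These are written
# from the defining formulas with plain loops and never call the package's
# own computational path.

# textbook Cox-de Boor recursion on the extended knot vector (valid strictly
# inside the grid range, away from the right boundary knot)
naive_bspline <- function(x, grid) {
  tt <- grid$knots
  k <- grid$order
  rec <- function(i, d) {
    if (d == 0) return(as.numeric(x >= tt[i] & x < tt[i + 1]))
    a <- if (tt[i + d] > tt[i])
      (x - tt[i]) / (tt[i + d] - tt[i]) * rec(i, d - 1) else 0
    b <- if (tt[i + d + 1] > tt[i + 1])
      (tt[i + d + 1] - x) / (tt[i + d + 1] - tt[i + 1]) * rec(i + 1, d - 1) else 0
    a + b
  }
  vapply(seq_len(grid$nbasis), function(i) rec(i, k), numeric(length(x)))
}

# literal double-loop evaluation of the KAN edge functions
naive_kan <- function(x, params) {
  grid <- params$grid
  out_dim <- nrow(params$w_b); in_dim <- ncol(params$w_b)
  silu <- function(v) v / (1 + exp(-v))
  out <- numeric(out_dim)
  for (j in seq_len(out_dim)) {
    acc <- 0
    for (i in seq_len(in_dim)) {
      Bi <- naive_bspline(x[i], grid)
      acc <- acc + params$w_b[j, i] * silu(x[i]) +
        params$w_s[j, i] * sum(params$coeffs[j, i, ] * Bi)
    }
    out[j] <- acc
  }
  out
}

# step-by-step PoolFormer block on a [T, C] matrix
naive_poolformer_block <- function(H, pb, eps = 1e-5) {
  ln <- function(M, g, b) {
    t(apply(M, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps))) *
      rep(g, each = nrow(M)) + rep(b, each = nrow(M))
  }
  Tt <- nrow(H)
  pool <- function(M) {
    out <- M * 0
    for (t in seq_len(Tt)) {
      nb <- intersect((t - 1):(t + 1), seq_len(Tt))
      out[t, ] <- colMeans(M[nb, , drop = FALSE])
    }
    out
  }
  gelu <- function(v) v * pnorm(v)
  H1 <- H + pool(ln(H, pb$ln1_g, pb$ln1_b))
  Hn <- ln(H1, pb$ln2_g, pb$ln2_b)
  M <- gelu(Hn %*% pb$w1 + rep(pb$b1, each = Tt)) %*% pb$w2 +
    rep(pb$b2, each = Tt)
  H1 + M
}

# CBAM (channel then spatial attention) on [B, C, D, H, W], with the same
# parameter shapes as hbam_params but no clinical term; direct loops
naive_cbam <- function(f, params) {
  d <- dim(f)
  B <- d[1]; C <- d[2]
  sig <- function(v) 1 / (1 + exp(-v))
  mlp <- function(v) {
    h <- pmax(as.vector(v %*% params$mlp_w1) + params$mlp_b1, 0)
    as.vector(h %*% params$mlp_w2)
  }
  out <- f * 0
  gated <- f * 0
  for (b in seq_len(B)) {
    favg <- apply(f[b, , , , , drop = FALSE], 2, mean)
    fmax <- apply(f[b, , , , , drop = FALSE], 2, max)
    gate <- sig(mlp(matrix(favg, 1)) + mlp(matrix(fmax, 1)))
    for (cc in seq_len(C)) gated[b, cc, , , ] <- f[b, cc, , , ] * gate[cc]
  }
  k <- params$kernel; pad <- (k - 1) %/% 2
  for (b in seq_len(B)) {
    avg <- apply(gated[b, , , , , drop = FALSE], c(3, 4, 5), mean)
    mx <- apply(gated[b, , , , , drop = FALSE], c(3, 4, 5), max)
    pooled <- array(0, dim = c(2, d[3], d[4], d[5]))
    pooled[1, , , ] <- avg; pooled[2, , , ] <- mx
    for (od in seq_len(d[3])) for (oh in seq_len(d[4])) for (ow in seq_len(d[5])) {
      acc <- params$spatial_b[1]
      for (kd in seq_len(k)) for (kh in seq_len(k)) for (kw in seq_len(k)) {
        id <- od - pad + kd - 1; ih <- oh - pad + kh - 1; iw <- ow - pad + kw - 1
        if (id >= 1 && id <= d[3] && ih >= 1 && ih <= d[4] && iw >= 1 && iw <= d[5])
          acc <- acc + sum(pooled[, id, ih, iw] * params$spatial_w[kd, kh, kw, , 1])
      }
      out[b, , od, oh, ow] <- gated[b, , od, oh, ow] * sig(acc)
    }
  }
  out
}

# explicit-loop cascaded grouped bidirectional cross-attention
naive_mmca <- function(X, Y, params) {
  dm <- dim(X)
  B <- dm[1]; L <- dm[2]; C <- dm[3]
  N <- params$N; d <- C %/% N
  softmax_row <- function(z) { e <- exp(z - max(z)); e / sum(e) }
  att <- function(q, k, v, bias) {
    S <- t(q) %*% k / sqrt(d) + bias
    W <- t(apply(S, 1, softmax_row))
    W %*% t(v)
  }
  Z <- array(0, dim = c(B, L, 2 * C))
  for (b in seq_len(B)) {
    Xi <- t(matrix(X[b, , ], L, C))   # [C, L]
    Yi <- t(matrix(Y[b, , ], L, C))
    vx <- NULL; vy <- NULL
    catx <- NULL; caty <- NULL
    for (i in seq_len(N)) {
      g <- params$groups[[i]]
      rows <- ((i - 1) * d + 1):(i * d)
      gx <- Xi[rows, , drop = FALSE]
      gy <- Yi[rows, , drop = FALSE]
      if (i > 1) { gx <- gx + t(vx); gy <- gy + t(vy) }
      vx <- att(g$qy %*% gy, g$kx %*% gx, g$vx %*% gx, g$bias)
      vy <- att(g$qx %*% gx, g$ky %*% gy, g$vy %*% gy, g$bias)
      catx <- cbind(catx, vx); caty <- cbind(caty, vy)
    }
    zx <- catx %*% params$proj_x_w + rep(params$proj_x_b, each = L)
    zy <- caty %*% params$proj_y_w + rep(params$proj_y_b, each = L)
    Z[b, , ] <- cbind(zx, zy)
  }
  Z
}

# triple-loop corner-aligned trilinear interpolation
naive_trilinear <- function(vox, target) {
  src <- dim(vox)
  out <- array(0, dim = target)
  for (a in seq_len(target[1])) for (b in seq_len(target[2])) for (cc in seq_len(target[3])) {
    pos <- c(a, b, cc) - 1
    sc <- ifelse(target > 1, (src - 1) / (target - 1), 0)
    p <- pos * sc
    i0 <- pmin(pmax(floor(p), 0), pmax(src - 2, 0))
    fr <- ifelse(src == 1, 0, p - i0)
    acc <- 0
    for (dd in 0:1) for (dh in 0:1) for (dw in 0:1) {
      w <- prod(ifelse(c(dd, dh, dw) == 1, fr, 1 - fr))
      ii <- pmin(i0 + c(dd, dh, dw), src - 1) + 1
      acc <- acc + w * vox[ii[1], ii[2], ii[3]]
    }
    out[a, b, cc] <- acc
  }
  out
}

# brute-force AUROC by concordant-pair counting (ties count 1/2)
naive_auroc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# standardized clinical vector for one subject, using a model's stored stats
std_clinical <- function(model, cohort, id) {
  row <- cohort$clinical[cohort$clinical$subject_id == id, ]
  v <- unlist(row[trifuse:::.clinical_order])
  for (f in trifuse:::.clinical_features)
    v[f] <- (v[f] - model$clinical_stats[[f]]["mean"]) /
      model$clinical_stats[[f]]["sd"]
  unname(v)
}

# lazily trained small model shared across interpretability tests
.fixtures <- new.env()
trained_test_model <- function() {
  if (is.null(.fixtures$model)) {
    coh <- synth_cohort(12, 12, seed = 42)
    sp <- stratified_split(coh$labels, 0.25, seed = 3)
    .fixtures$model <- trifuse(coh, train_ids = sp$train_ids,
                               val_ids = sp$test_ids,
                               control = train_control(epochs = 3,
                                                       patience = 50),
                               seed = 5)
    .fixtures$cohort <- coh
  }
  list(model = .fixtures$model, cohort = .fixtures$cohort)
}
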