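test_that("token flattening is a bijection with row-major (d,h,w) order", {
  set.seed(41)
  f <- array(rnorm(1 * 4 * 2 * 2 * 2), c(1, 4, 2, 2, 2))
  tok <- tokens_from_featuremap(f)
  expect_identical(dim(tok), c(1L, 8L, 4L))
  expect_equal(featuremap_from_tokens(tok, c(2, 2, 2)), f)
  # token at (d, h, w) (0-based) sits at position (d*H + h)*W + w
  D <- 2; H <- 2; W <- 2
  for (d in 0:(D - 1)) for (h in 0:(H - 1)) for (w in 0:(W - 1)) {
    pos <- (d * H + h) * W + w + 1
    expect_equal(tok[1, pos, ], f[1, , d + 1, h + 1, w + 1])
  }
})

test_that("biased attention handles uniform, single-token and closed-form cases", {
  set.seed(42)
  d <- 3; L <- 4
  v <- matrix(rnorm(d * L), d, L)
  # zero queries and zero bias: uniform weights, every output is the mean
  out <- biased_attention(matrix(0, d, L), matrix(rnorm(d * L), d, L), v,
                          matrix(0, L, L))
  expect_equal(out, matrix(rowMeans(v), L, d, byrow = TRUE), tolerance = 1e-12)
  # L = 1: output equals the single value token
  v1 <- matrix(rnorm(d), d, 1)
  out1 <- biased_attention(matrix(rnorm(d), d, 1), matrix(rnorm(d), d, 1), v1,
                           matrix(5, 1, 1))
  expect_equal(out1, t(v1), tolerance = 1e-12)
  # softmax of logits [0, ln 2, ln 3] is [1/6, 1/3, 1/2]
  w <- trifuse:::ad_softmax_rows(matrix(c(0, log(2), log(3)), 1, 3))
  expect_equal(as.vector(w), c(1 / 6, 1 / 3, 1 / 2), tolerance = 1e-12)
})

test_that("attention rows sum to one even for extreme logits", {
  set.seed(43)
  z <- matrix(c(1e4, -1e4, 0, 1e4, 1e4, -1e4, rnorm(10)), 4, 4)
  w <- trifuse:::ad_softmax_rows(z)
  expect_true(all(is.finite(w)))
  expect_lt(max(abs(rowSums(w) - 1)), 1e-6)
})

test_that("mmca_forward matches the explicit-loop reference", {
  for (cse in list(c(B = 1, L = 4, C = 8, N = 1), c(B = 2, L = 8, C = 16, N = 2),
                   c(B = 2, L = 6, C = 16, N = 4))) {
    set.seed(44 + cse["N"])
    p <- mmca_params(cse["C"], cse["L"], cse["N"])
    # nonzero bias so the position term is exercised
    for (i in seq_len(p$N))
      p$groups[[i]]$bias <- matrix(rnorm(cse["L"]^2, sd = 0.3),
                                   cse["L"], cse["L"])
    X <- array(rnorm(prod(cse[1:3])), unname(cse[1:3]))
    Y <- array(rnorm(prod(cse[1:3])), unname(cse[1:3]))
    expect_equal(mmca_forward(X, Y, p), naive_mmca(X, Y, p),
                 tolerance = 1e-6)
  }
})

test_that("N = 1 MMCA equals plain bidirectional cross-attention", {
  set.seed(48)
  B <- 2; L <- 5; C <- 8
  p <- mmca_params(C, L, 1)
  X <- array(rnorm(B * L * C), c(B, L, C))
  Y <- array(rnorm(B * L * C), c(B, L, C))
  out <- mmca_forward(X, Y, p)
  g <- p$groups[[1]]
  for (b in seq_len(B)) {
    Xi <- t(matrix(X[b, , ], L, C)); Yi <- t(matrix(Y[b, , ], L, C))
    vx <- biased_attention(g$qy %*% Yi, g$kx %*% Xi, g$vx %*% Xi, g$bias)
    vy <- biased_attention(g$qx %*% Xi, g$ky %*% Yi, g$vy %*% Yi, g$bias)
    zx <- vx %*% p$proj_x_w + rep(p$proj_x_b, each = L)
    zy <- vy %*% p$proj_y_w + rep(p$proj_y_b, each = L)
    expect_equal(out[b, , ], cbind(zx, zy), tolerance = 1e-10)
  }
})

test_that("tied parameters and X = Y give identical modality outputs", {
  set.seed(49)
  L <- 6; C <- 16
  p <- mmca_params(C, L, 4)
  for (i in seq_len(p$N)) {
    g <- p$groups[[i]]
    g$qy <- g$qx; g$ky <- g$kx; g$vy <- g$vx
    p$groups[[i]] <- g
  }
  p$proj_y_w <- p$proj_x_w; p$proj_y_b <- p$proj_x_b
  X <- array(rnorm(2 * L * C), c(2, L, C))
  out <- mmca_forward(X, X, p)
  expect_equal(out[, , 1:C], out[, , C + 1:C], tolerance = 1e-12)
})

test_that("token permutation with a conjugated bias permutes outputs", {
  set.seed(50)
  L <- 6; C <- 8
  p <- mmca_params(C, L, 2)
  for (i in seq_len(p$N))
    p$groups[[i]]$bias <- matrix(rnorm(L * L, sd = 0.3), L, L)
  X <- array(rnorm(1 * L * C), c(1, L, C))
  Y <- array(rnorm(1 * L * C), c(1, L, C))
  perm <- sample(L)
  p2 <- p
  for (i in seq_len(p$N))
    p2$groups[[i]]$bias <- p$groups[[i]]$bias[perm, perm]
  out1 <- mmca_forward(X, Y, p)
  out2 <- mmca_forward(X[, perm, , drop = FALSE], Y[, perm, , drop = FALSE], p2)
  expect_equal(out2[1, , ], out1[1, perm, ], tolerance = 1e-10)
  expect_error(mmca_forward(X, Y[, 1:4, , drop = FALSE], p), "share")
  expect_error(mmca_params(10, 4, 4), "divisible")
})
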