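test_that("spline basis satisfies partition of unity and hat geometry", {
  grid <- spline_grid(order = 3, grid_size = 5, range = c(-2, 2))
  set.seed(21)
  x <- runif(1000, -2 + 1e-9, 2 - 1e-9)
  B <- bspline_basis(x, grid)
  expect_true(all(B >= -1e-12))
  expect_lt(max(abs(rowSums(B) - 1)), 1e-10)
  # order-1 uniform grid: the two flanking hats are 0.5 at a knot midpoint
  g1 <- spline_grid(order = 1, grid_size = 4, range = c(0, 4))
  b <- bspline_basis(1.5, g1)
  expect_equal(sort(b[b > 0]), c(0.5, 0.5))
  expect_error(spline_grid(range = c(1, 1)), "degenerate")
})

test_that("spline basis matches the brute-force Cox-de Boor recursion", {
  for (k in c(1, 2, 3)) {
    grid <- spline_grid(order = k, grid_size = 5, range = c(-2, 2))
    set.seed(30 + k)
    x <- runif(200, -1.99, 1.99)
    expect_equal(bspline_basis(x, grid), naive_bspline(x, grid),
                 tolerance = 1e-12)
  }
})

test_that("KAN layer reduces correctly and matches a double-loop oracle", {
  grid <- spline_grid()
  set.seed(22)
  p <- kan_params(7, 16, grid)
  # x = 0 with zero spline coefficients: SiLU(0) = 0 and no bias
  p0 <- p; p0$coeffs[] <- 0
  expect_equal(kan_layer_forward(rep(0, 7), p0), rep(0, 16))
  # 1-to-1 with w_b = 1, w_s = 0 is exactly SiLU
  p1 <- kan_params(1, 1, grid)
  p1$w_b[] <- 1; p1$w_s[] <- 0
  for (x in c(-1.3, 0.2, 1.7))
    expect_equal(kan_layer_forward(x, p1), x / (1 + exp(-x)), tolerance = 1e-12)
  # random case equals the literal formula
  set.seed(23)
  x <- runif(7, -1.8, 1.8)
  expect_equal(kan_layer_forward(x, p), naive_kan(x, p), tolerance = 1e-10)
  expect_error(kan_layer_forward(rep(0, 5), p), "dims|non-conformable")
})

test_that("KAN output is linear in the spline coefficients", {
  grid <- spline_grid()
  set.seed(24)
  p <- kan_params(7, 8, grid)
  x <- runif(7, -1.5, 1.5)
  c1 <- array(rnorm(length(p$coeffs)), dim = dim(p$coeffs))
  c2 <- array(rnorm(length(p$coeffs)), dim = dim(p$coeffs))
  f <- function(cc) { q <- p; q$coeffs <- cc; kan_layer_forward(x, q) }
  lhs <- f(2 * c1 + 3 * c2)
  rhs <- 2 * f(c1) + 3 * f(c2) - 4 * f(c1 * 0)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("PoolFormer block obeys its degenerate cases and reference", {
  set.seed(25)
  pf <- poolformer_params(tokens = 6, channels = 8, blocks = 1)
  pb <- pf$blocks[[1]]
  # constant channel vectors: LayerNorm maps to beta = 0, so the token mixer
  # contributes nothing
  Hc <- matrix(rep(rnorm(6), 8), 6, 8)
  Hc[] <- matrix(5, 6, 8)
  out <- poolformer_block_forward(Hc, pb)
  mlp0 <- poolformer_block_forward(Hc * 0, pb)  # pure-MLP response at LN=0
  expect_equal(out - Hc, mlp0, tolerance = 1e-12)
  # single token: pooling is the identity on the normalized sequence
  pf1 <- poolformer_params(tokens = 1, channels = 8, blocks = 1)
  H1 <- matrix(rnorm(8), 1, 8)
  ref <- naive_poolformer_block(H1, pf1$blocks[[1]])
  expect_equal(poolformer_block_forward(H1, pf1$blocks[[1]]), ref,
               tolerance = 1e-12)
  # random input equals the step-by-step reference
  H <- matrix(rnorm(48), 6, 8)
  expect_equal(poolformer_block_forward(H, pb),
               naive_poolformer_block(H, pb), tolerance = 1e-12)
})

test_that("tabular_encode composes the KAN layer and PoolFormer stack", {
  set.seed(26)
  grid <- spline_grid()
  kan <- kan_params(7, 64, grid)
  pf0 <- poolformer_params(8, 8, blocks = 0)
  x <- runif(7, -1.5, 1.5)
  # M = 0 reduces to the KAN output
  expect_equal(tabular_encode(x, kan, pf0), kan_layer_forward(x, kan),
               tolerance = 1e-12)
  pf <- poolformer_params(8, 8, blocks = 2)
  out <- tabular_encode(x, kan, pf)
  expect_length(out, 64)
  # equals manual chaining through the token view
  H <- matrix(kan_layer_forward(x, kan), 8, 8, byrow = TRUE)  # [T, C]
  for (pb in pf$blocks) H <- poolformer_block_forward(H, pb)
  expect_equal(out, as.vector(t(H)), tolerance = 1e-12)
  bad <- poolformer_params(5, 8, blocks = 1)
  expect_error(tabular_encode(x, kan, bad), "tokens")
})
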