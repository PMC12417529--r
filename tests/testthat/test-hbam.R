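rand_fmap <- function(B, C, D, H, W, seed = 1) {
  set.seed(seed)
  array(rnorm(B * C * D * H * W), c(B, C, D, H, W))
}

test_that("embed_clinical is an exact affine map", {
  set.seed(31)
  p <- hbam_params(16, 8)
  p0 <- p; p0$embed_w[] <- 0; p0$embed_b[] <- 0
  expect_equal(embed_clinical(rnorm(8), p0), rep(0, 16))
  # identity-padded weights return the input
  pi_ <- hbam_params(8, 8)
  pi_$embed_w <- diag(8); pi_$embed_b[] <- 0
  x <- rnorm(8)
  expect_equal(embed_clinical(x, pi_), x)
  x <- rnorm(8)
  manual <- as.vector(x %*% p$embed_w) + p$embed_b
  expect_equal(embed_clinical(x, p), manual, tolerance = 1e-12)
})

test_that("hybrid channel attention gates channels as specified", {
  p <- hbam_params(8, 4, reduction = 4)
  f <- rand_fmap(2, 8, 3, 4, 3, seed = 32)
  # zero MLP weights and zero clinical embedding: gate is sigmoid(0) = 0.5
  p0 <- p
  p0$mlp_w1[] <- 0; p0$mlp_b1[] <- 0; p0$mlp_w2[] <- 0
  out <- hybrid_channel_attention(f, matrix(0, 2, 8), p0)
  expect_equal(out, 0.5 * f, tolerance = 1e-12)
  # gates lie in (0,1): magnitude never increases, sign preserved
  e <- matrix(rnorm(16), 2, 8)
  out2 <- hybrid_channel_attention(f, e, p)
  expect_true(all(abs(out2) <= abs(f)))
  expect_true(all(sign(out2) == sign(f) | out2 == 0))
})

test_that("spatial attention halves the input under zero conv weights", {
  p <- hbam_params(8, 4, reduction = 4)
  f <- rand_fmap(2, 8, 3, 4, 3, seed = 33)
  p0 <- p; p0$spatial_w[] <- 0; p0$spatial_b[] <- 0
  expect_equal(spatial_attention(f, p0), 0.5 * f, tolerance = 1e-12)
  out <- spatial_attention(f, p)
  expect_identical(dim(out), dim(f))
  expect_true(all(abs(out) <= abs(f)))
})

test_that("HBAM with a zero clinical embedding reduces to reference CBAM", {
  set.seed(34)
  p <- hbam_params(8, 6, reduction = 4, spatial_kernel = 3)
  f <- rand_fmap(2, 8, 4, 5, 4, seed = 35)
  # zero the embedding so only the image pathway is active
  pz <- p; pz$embed_w[] <- 0; pz$embed_b[] <- 0
  out <- hbam_forward(f, matrix(rnorm(12), 2, 6), pz)
  expect_equal(out, naive_cbam(f, p), tolerance = 1e-12)
  # full composition equals chaining the two exported ops
  e <- embed_clinical(matrix(rnorm(12), 2, 6), p)
  set.seed(36); cli <- matrix(rnorm(12), 2, 6)
  manual <- spatial_attention(
    hybrid_channel_attention(f, embed_clinical(cli, p), p), p)
  expect_equal(hbam_forward(f, cli, p), manual, tolerance = 1e-12)
})

test_that("the clinical pathway of HBAM is live (nonzero input gradient)", {
  set.seed(37)
  p <- hbam_params(8, 6, reduction = 4, spatial_kernel = 3)
  f <- rand_fmap(1, 8, 3, 4, 3, seed = 38)
  cli <- matrix(rnorm(6), 1, 6)
  cn <- trifuse:::ad_leaf(cli)
  out <- hbam_forward(f, cn, p)
  s <- trifuse:::ad_mean_all(out)
  trifuse:::ad_backward(s)
  expect_gt(max(abs(cn$grad)), 0)
  # finite-difference agreement on one coordinate
  fd_i <- which.max(abs(cn$grad))
  eps <- 1e-6
  per <- function(h) { c2 <- cli; c2[fd_i] <- c2[fd_i] + h
    mean(hbam_forward(f, c2, p)) }
  fd <- (per(eps) - per(-eps)) / (2 * eps)
  expect_equal(unname(cn$grad[fd_i]), fd, tolerance = 1e-5)
})
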