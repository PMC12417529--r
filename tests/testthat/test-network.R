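small_inputs <- function(B, shape = c(24, 32, 24), seed = 61) {
  set.seed(seed)
  list(mri = array(rnorm(B * prod(shape)), c(B, 1, shape)),
       pet = array(rnorm(B * prod(shape)), c(B, 1, shape)),
       cli = matrix(rnorm(B * 7, sd = 0.8), B, 7))
}

test_that("the assembled network emits finite, deterministic predictions", {
  cfg <- trifuse_config("test")
  init <- trifuse_init(cfg, seed = 1)
  model <- list(params = init$params, state = init$state, config = cfg)
  inp <- small_inputs(2)
  pred <- trifuse_forward(model, inp$mri, inp$pet, inp$cli)
  expect_equal(nrow(pred), 2L)
  expect_true(all(is.finite(pred$logit)))
  expect_equal(pred$probability, 1 / (1 + exp(-pred$logit)))
  expect_true(all(pred$class %in% 0:1))
  # identical subjects give identical predictions in evaluation mode
  inp$mri[2, , , , ] <- inp$mri[1, , , , ]
  inp$pet[2, , , , ] <- inp$pet[1, , , , ]
  inp$cli[2, ] <- inp$cli[1, ]
  p2 <- trifuse_forward(model, inp$mri, inp$pet, inp$cli)
  expect_equal(p2$logit[1], p2$logit[2], tolerance = 1e-12)
})

test_that("the full forward equals manual chaining of the module ops", {
  cfg <- trifuse_config("test")
  init <- trifuse_init(cfg, seed = 2)
  p <- init$params
  inp <- small_inputs(2, seed = 62)
  model <- list(params = p, state = init$state, config = cfg)
  pred <- trifuse_forward(model, inp$mri, inp$pet, inp$cli)

  f_cli <- tabular_encode(inp$cli, p$tab$kan, p$tab$pf)
  f_mri <- trifuse:::ad_resnet3d(inp$mri, cfg$encoder, p$enc_mri, init$state,
                                 prefix = "mri.")
  f_pet <- trifuse:::ad_resnet3d(inp$pet, cfg$encoder, p$enc_pet, init$state,
                                 prefix = "pet.")
  h_mri <- hbam_forward(f_mri, f_cli, p$hbam_mri)
  h_pet <- hbam_forward(f_pet, f_cli, p$hbam_pet)
  z <- mmca_forward(tokens_from_featuremap(h_mri),
                    tokens_from_featuremap(h_pet), p$mmca)
  pooled <- apply(z, c(1, 3), mean)
  ln <- trifuse:::ad_layernorm(pooled, p$head$ln_g, p$head$ln_b)
  hid <- trifuse:::ad_gelu(ln %*% p$head$w1 + rep(p$head$b1, each = 2))
  logit <- as.vector(hid %*% p$head$w2 + rep(p$head$b2, each = 2))
  expect_equal(pred$logit, logit, tolerance = 1e-10)
})

test_that("focal loss reproduces worked values and reduces to cross-entropy", {
  # gamma = 0, alpha = 1, y = 1, p = 0.5: plain -log p
  expect_equal(focal_loss(0.5, 1, alpha = 1, gamma = 0), log(2),
               tolerance = 1e-6)
  # y = 1, p = 0.9, alpha = 0.25, gamma = 2: 0.25 * 0.01 * 0.105361
  expect_equal(focal_loss(0.9, 1, alpha = 0.25, gamma = 2),
               0.25 * 0.01 * (-log(0.9)), tolerance = 1e-9)
  expect_equal(focal_loss(0.9, 1, alpha = 0.25, gamma = 2), 2.634e-4,
               tolerance = 1e-3)
  # perfectly classified negative: loss tends to 0
  expect_lt(focal_loss(1e-9, 0, alpha = 0.75, gamma = 2), 1e-6)
  expect_error(focal_loss(0.5, 2), "labels")
  # reduction: gamma = 0 with unit class weight equals cross-entropy on 1000
  # random pairs; in the literal form alpha = 1 covers both classes, in the
  # default form alpha_t = 1 means alpha = 1 for positives, 0 for negatives
  set.seed(63)
  p <- runif(1000, 0.001, 0.999)
  y <- rbinom(1000, 1, 0.3)
  ce <- -(y * log(p) + (1 - y) * log(1 - p))
  expect_lt(max(abs(focal_loss(p, y, alpha = 1, gamma = 0,
                               literal_form = TRUE) - ce)), 1e-12)
  expect_lt(max(abs(focal_loss(p, y, alpha = ifelse(y == 1, 1, 0),
                               gamma = 0) - ce)), 1e-12)
  # focal loss never exceeds cross-entropy when alpha_t <= 1
  fl <- focal_loss(p, y, alpha = 0.75, gamma = 2)
  expect_true(all(fl <= ce + 1e-12))
  # literal single-factor variant
  expect_equal(focal_loss(0.9, 0, alpha = 0.5, gamma = 2, literal_form = TRUE),
               -0.5 * 0.01 * log(0.1), tolerance = 1e-12)
})

test_that("focal loss gradients match finite differences", {
  set.seed(64)
  for (literal in c(FALSE, TRUE)) {
    z <- rnorm(8); y <- rbinom(8, 1, 0.5)
    zn <- trifuse:::ad_leaf(matrix(z, ncol = 1))
    loss <- trifuse:::ad_focal_from_logits(zn, y, 0.75, 2, literal)
    trifuse:::ad_backward(loss)
    lf <- function(zz) mean(focal_loss(1 / (1 + exp(-zz)), y, 0.75, 2, literal))
    eps <- 1e-6
    for (i in seq_along(z)) {
      zp <- z; zp[i] <- zp[i] + eps
      zm <- z; zm[i] <- zm[i] - eps
      fd <- (lf(zp) - lf(zm)) / (2 * eps)
      expect_equal(unname(zn$grad[i, 1]), fd, tolerance = 1e-4)
    }
  }
})

test_that("checkpoints round-trip bit-exactly through save and load", {
  cfg <- trifuse_config("test")
  init <- trifuse_init(cfg, seed = 3)
  model <- structure(list(params = init$params, state = init$state,
                          config = cfg, control = train_control(epochs = 1),
                          history = data.frame(),
                          clinical_stats = NULL),
                     class = "trifuse")
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, model$params)
  s1 <- as.list(m2$state); s2 <- as.list(model$state)
  expect_identical(s1[sort(names(s1))], s2[sort(names(s2))])
  inp <- small_inputs(2, seed = 65)
  p1 <- trifuse_forward(model, inp$mri, inp$pet, inp$cli)
  p2 <- trifuse_forward(m2, inp$mri, inp$pet, inp$cli)
  expect_identical(p1$logit, p2$logit)
  expect_true(file.exists(sub("\\.rds$", "_config.json", path)))
})
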