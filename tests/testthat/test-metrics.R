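test_that("cosine schedule hits its closed-form values", {
  expect_equal(cosine_lr(0, 1e-4, 50), 1e-4)
  expect_equal(cosine_lr(25, 1e-4, 50), 5e-5)
  expect_equal(cosine_lr(12.5, 1, 50), (1 + cos(pi / 4)) / 2)
  expect_error(cosine_lr(1, 1e-4, 0), "positive")
})

test_that("confusion counts match brute-force counting", {
  # perfect predictor on 30 positives / 73 negatives
  y <- c(rep(1, 30), rep(0, 73))
  p <- c(rep(0.9, 30), rep(0.1, 73))
  cc <- confusion_from_predictions(p, y)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 30L, TN = 73L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  # all-negative predictor
  cc2 <- confusion_from_predictions(rep(0.1, 103), y)
  expect_equal(cc2$TP, 0L); expect_equal(cc2$FN, 30L)
  # random case vs an explicit loop
  set.seed(71)
  pr <- runif(40); yr <- rbinom(40, 1, 0.4)
  cc3 <- confusion_from_predictions(pr, yr, 0.5)
  tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
  for (i in 1:40) {
    pred <- pr[i] >= 0.5
    if (pred && yr[i] == 1) tp <- tp + 1L
    if (!pred && yr[i] == 0) tn <- tn + 1L
    if (pred && yr[i] == 0) fp <- fp + 1L
    if (!pred && yr[i] == 1) fn <- fn + 1L
  }
  expect_equal(c(cc3$TP, cc3$TN, cc3$FP, cc3$FN), c(tp, tn, fp, fn))
  expect_error(confusion_from_predictions(pr, yr[1:10]), "length")
})

test_that("metrics reproduce hand-evaluated worked examples", {
  perfect <- structure(list(TP = 30, TN = 73, FP = 0, FN = 0),
                       class = "confusion_counts")
  expect_equal(compute_metrics(perfect)$balanced_accuracy, 1.0)
  majority <- structure(list(TP = 0, TN = 73, FP = 0, FN = 30),
                        class = "confusion_counts")
  expect_warning(m <- compute_metrics(majority), "precision")
  expect_equal(m$balanced_accuracy, 0.5)
  mixed <- structure(list(TP = 15, TN = 36, FP = 37, FN = 15),
                     class = "confusion_counts")
  expect_equal(compute_metrics(mixed)$balanced_accuracy,
               0.5 * (0.5 + 36 / 73), tolerance = 1e-12)
  expect_equal(round(compute_metrics(mixed)$balanced_accuracy, 5), 0.49658)
  # AUROC worked example: 3 of 4 pairs concordant
  expect_equal(auroc_mannwhitney(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
})

test_that("balanced accuracy equals (sensitivity + specificity)/2 on random tables", {
  set.seed(72)
  for (i in 1:1000) {
    cc <- structure(list(TP = sample(0:20, 1), TN = sample(0:20, 1),
                         FP = sample(0:20, 1), FN = sample(0:20, 1)),
                    class = "confusion_counts")
    if (cc$TP + cc$FN == 0 || cc$TN + cc$FP == 0) next
    m <- suppressWarnings(compute_metrics(cc))
    expect_equal(m$balanced_accuracy, (m$sensitivity + m$specificity) / 2,
                 tolerance = 1e-12)
  }
})

test_that("midrank AUROC equals brute-force pair counting up to n = 50", {
  set.seed(73)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    p <- round(runif(n), 2)  # rounding forces ties
    expect_equal(auroc_mannwhitney(p, y), naive_auroc(p, y),
                 tolerance = 1e-12)
  }
  expect_warning(expect_true(is.nan(auroc_mannwhitney(runif(5), rep(1, 5)))))
})

test_that("parameter and FLOP counting obey conservation and scaling laws", {
  # a single 7 -> 64 linear map with bias holds 512 parameters
  expect_equal(trifuse:::param_count(list(w = matrix(0, 7, 64),
                                          b = rep(0, 64))), 512L)
  cfg <- trifuse_config("test")
  pf <- count_params_flops(cfg)
  # conservation: the traversal equals an independent flat sum
  init <- trifuse_init(cfg, seed = 1)
  flat_sum <- 0
  add <- function(x) {
    if (inherits(x, "spline_grid")) return(invisible(NULL))
    if (is.list(x)) { for (e in x) add(e); return(invisible(NULL)) }
    if (is.double(x)) flat_sum <<- flat_sum + length(x)
    invisible(NULL)
  }
  add(init$params)
  expect_equal(pf$n_params, flat_sum)
  expect_gt(pf$flops, 0)
  # doubling all encoder widths roughly quadruples encoder-dominated FLOPs
  cfg2 <- trifuse_config("test")
  cfg2$encoder$widths <- cfg$encoder$widths * 2L
  cfg2$c_img <- cfg2$encoder$widths[4]
  pf2 <- count_params_flops(cfg2)
  ratio <- pf2$flops / pf$flops
  expect_gt(ratio, 2.5)
  expect_lt(ratio, 4.5)
})
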