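# Evaluation metrics for the imbalanced pMCI/sMCI task.

#' Cosine-annealed learning rate
#'
#' `lr0 * (1 + cos(pi * (epoch %% T_max) / T_max)) / 2` for a 0-based epoch
#' index.
#'
#' @param epoch Epoch index (0-based).
#' @param lr0 Base learning rate.
#' @param t_max Cosine period.
#' @return The learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, lr0, t_max) {
  if (t_max <= 0) stop("t_max must be positive")
  lr0 * (1 + cos(pi * (epoch %% t_max) / t_max)) / 2
}

#' Confusion counts at a probability threshold
#'
#' @param probabilities Predicted positive-class probabilities.
#' @param labels True 0/1 labels.
#' @param threshold Decision threshold (predict 1 when `p >= threshold`).
#' @return A list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_from_predictions <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels differ in length")
  pred <- as.integer(probabilities >= threshold)
  structure(list(TP = sum(pred == 1 & labels == 1),
                 TN = sum(pred == 0 & labels == 0),
                 FP = sum(pred == 1 & labels == 0),
                 FN = sum(pred == 0 & labels == 1)),
            class = "confusion_counts")
}

#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' Uses midranks, so tied scores contribute 1/2 per tied pair.
#'
#' @param probabilities Scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc_mannwhitney <- function(probabilities, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    warning("AUROC undefined: one class is empty")
    return(NaN)
  }
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from confusion counts and scores
#'
#' Computes accuracy, sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, F1,
#' balanced accuracy `(TP/(TP+FN) + TN/(TN+FP)) / 2` and (when scores are
#' supplied) AUROC. Ratios with an empty denominator are reported as `NaN`
#' with a warning.
#'
#' @param counts A `confusion_counts` object (or `NULL` to derive it from the
#'   scores at threshold 0.5).
#' @param probabilities,labels Optional aligned scores and labels for AUROC.
#' @return A list of class `metrics_report`.
#' @export
compute_metrics <- function(counts = NULL, probabilities = NULL,
                            labels = NULL) {
  if (is.null(counts)) {
    if (is.null(probabilities) || is.null(labels))
      stop("either counts or probabilities+labels must be given")
    counts <- confusion_from_predictions(probabilities, labels)
  }
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  n <- TP + TN + FP + FN
  ratio <- function(num, den, what) {
    if (den == 0) { warning(what, " undefined (empty denominator)"); NaN }
    else num / den
  }
  sens <- ratio(TP, TP + FN, "sensitivity")
  spec <- ratio(TN, TN + FP, "specificity")
  prec <- ratio(TP, TP + FP, "precision")
  f1 <- if (is.nan(sens) || is.nan(prec) || (sens + prec) == 0) NaN
        else 2 * prec * sens / (prec + sens)
  auroc <- if (!is.null(probabilities) && !is.null(labels))
    auroc_mannwhitney(probabilities, labels) else NA_real_
  structure(list(accuracy = (TP + TN) / n, sensitivity = sens,
                 specificity = spec, precision = prec, f1 = f1,
                 balanced_accuracy = (sens + spec) / 2, auroc = auroc,
                 counts = counts, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n=%d  acc=%.4f  sens=%.4f  prec=%.4f  f1=%.4f  bacc=%.4f  auroc=%s\n",
    x$n, x$accuracy, x$sensitivity, x$precision, x$f1, x$balanced_accuracy,
    ifelse(is.na(x$auroc), "NA", sprintf("%.4f", x$auroc))))
  invisible(x)
}

#' Count trainable parameters and forward FLOPs of a configuration
#'
#' Parameters are counted by traversing the initialized arrays. FLOPs follow
#' the multiply-accumulate convention (2 FLOPs per MAC) over all
#' convolutions, linear maps, the KAN layer and the attention matrix
#' products, at the configured input shape and batch size 1; normalizations
#' and activations are not counted.
#'
#' @param config A [trifuse_config()].
#' @return List with `n_params` and `flops`.
#' @export
count_params_flops <- function(config) {
  init <- trifuse_init(config, seed = 1L)
  n_params <- param_count(init$params)
  enc <- config$encoder
  shp <- config$input_shape
  fl <- 0
  conv_fl <- function(k, cin, cout, out_shape) 2 * k^3 * cin * cout * prod(out_shape)
  # encoder (applied to both modalities)
  enc_flops <- function() {
    f <- 0
    s <- shp %/% enc$stem_stride
    f <- f + conv_fl(enc$stem_kernel, 1, enc$widths[1], s)
    s <- s %/% 2L  # stem max-pool
    cin <- enc$widths[1]
    for (st in 1:4) {
      for (b in seq_len(enc$blocks[st])) {
        stride <- if (b == 1L) enc$stage_strides[st] else 1L
        s <- s %/% stride
        cout <- enc$widths[st]
        f <- f + conv_fl(3, cin, cout, s) + conv_fl(3, cout, cout, s)
        if (stride != 1L || cin != cout) f <- f + conv_fl(1, cin, cout, s)
        cin <- cout
      }
    }
    f
  }
  fl <- fl + 2 * enc_flops()
  # tabular branch
  R <- config$grid_size + config$spline_order
  fl <- fl + if (config$use_kan) 2 * 7 * config$d_tab * (1 + R)
             else 2 * 7 * config$d_tab
  Ct <- config$tab_channels; Tt <- config$tab_tokens
  fl <- fl + config$tab_blocks * (2 * Tt * (Ct * 4 * Ct + 4 * Ct * Ct) +
                                    2 * 3 * Tt * Ct)
  C <- config$c_img; L <- config$tokens
  if (config$use_hbam) {
    hid <- C %/% config$hbam_reduction
    per <- 2 * config$d_tab * C + 2 * 2 * (C * hid + hid * C) +
      2 * config$spatial_kernel^3 * 2 * L
    fl <- fl + 2 * per
  }
  if (config$use_mmca) {
    d <- C %/% config$mmca_groups
    per_dir <- 3 * 2 * d * d * L + 2 * L * L * d + 2 * L * L * d
    fl <- fl + config$mmca_groups * 2 * per_dir + 2 * 2 * C * C * L
  }
  fl <- fl + 2 * (2 * C) * config$head_hidden + 2 * config$head_hidden
  list(n_params = n_params, flops = fl)
}
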