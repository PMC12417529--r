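# User-facing modelling interface: fit the triple-modal classifier on a
# cohort and use the standard print / summary / predict / plot verbs.

#' Fit the triple-modal fusion classifier
#'
#' Trains the network on the given cohort subjects with focal loss, Adam and
#' the cosine schedule, using `val_ids` for per-epoch validation and early
#' stopping. If `val_ids` is `NULL`, a stratified fifth of `train_ids` is
#' held out for validation.
#'
#' @param cohort A `trifuse_cohort` from [synth_cohort()] (or any object with
#'   the same structure built from real data).
#' @param train_ids Subject ids to train on (default: all).
#' @param val_ids Validation ids (disjoint from `train_ids`).
#' @param config A [trifuse_config()].
#' @param control A [train_control()].
#' @param seed Master seed: initialization, batch order and the internal
#'   validation split all derive from it.
#' @return An object of class `trifuse` with elements `params`, `state`,
#'   `config`, `control`, `history`, `best_epoch`, `clinical_stats` and
#'   `train_ids`/`val_ids`.
#' @export
trifuse <- function(cohort, train_ids = NULL, val_ids = NULL,
                    config = trifuse_config(), control = train_control(),
                    seed = 1L) {
  if (is.null(train_ids)) train_ids <- names(cohort$labels)
  if (is.null(val_ids)) {
    sp <- stratified_split(cohort$labels[train_ids], 0.2, seed + 17L)
    train_ids <- sp$train_ids
    val_ids <- sp$test_ids
  }
  fit <- train_one_fold(cohort, train_ids, val_ids, config, control, seed)
  structure(list(params = fit$params, state = fit$state, config = config,
                 control = control, history = fit$history,
                 best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss,
                 clinical_stats = fit$stats,
                 train_ids = train_ids, val_ids = val_ids, seed = seed,
                 call = match.call()),
            class = "trifuse")
}

#' @export
print.trifuse <- function(x, ...) {
  pf <- count_params_flops(x$config)
  cat("Triple-modal fusion classifier (pMCI vs sMCI)\n")
  cat("  preset:", x$config$preset, " input:",
      paste(x$config$input_shape, collapse = "x"),
      " tokens:", x$config$tokens, " channels:", x$config$c_img, "\n")
  cat("  parameters:", format(pf$n_params, big.mark = ","),
      " forward FLOPs:", format(pf$flops, big.mark = ","), "\n")
  if (!is.null(x$history) && nrow(x$history))
    cat(sprintf("  trained %d epochs; best validation focal loss %.4f at epoch %d\n",
                nrow(x$history), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.trifuse <- function(object, ...) {
  print(object)
  cat("  modules: tabular =", if (object$config$use_kan) "KAN+PoolFormer" else "MLP+PoolFormer",
      "| HBAM =", object$config$use_hbam, "| MMCA =", object$config$use_mmca, "\n")
  cat("  training subjects:", length(object$train_ids),
      " validation subjects:", length(object$val_ids), "\n")
  invisible(object)
}

#' Predict conversion probabilities for cohort subjects
#'
#' @param object A fitted `trifuse` model.
#' @param cohort A `trifuse_cohort` holding the subjects.
#' @param ids Subject ids to score (default: all in `cohort`).
#' @param type `"prob"`, `"class"` or `"response"` (data frame with both).
#' @param ... Unused.
#' @return Named vector of probabilities / classes, or a data frame.
#' @export
predict.trifuse <- function(object, cohort, ids = NULL,
                            type = c("prob", "class", "response"), ...) {
  type <- match.arg(type)
  if (is.null(ids)) ids <- names(cohort$labels)
  cli <- cohort$clinical
  std <- cli
  for (f in .clinical_features)
    std[[f]] <- (cli[[f]] - object$clinical_stats[[f]]["mean"]) /
      object$clinical_stats[[f]]["sd"]
  probs <- numeric(length(ids))
  bs <- object$control$batch_size
  for (i in seq(1, length(ids), by = bs)) {
    sel <- ids[i:min(i + bs - 1, length(ids))]
    d <- dim(cohort$subjects[[sel[1]]]$mri$voxels)
    mri <- array(0, dim = c(length(sel), 1L, d))
    pet <- array(0, dim = c(length(sel), 1L, d))
    for (j in seq_along(sel)) {
      mri[j, 1, , , ] <- intensity_normalize(cohort$subjects[[sel[j]]]$mri)$voxels
      pet[j, 1, , , ] <- intensity_normalize(cohort$subjects[[sel[j]]]$pet)$voxels
    }
    rows <- match(sel, std$subject_id)
    z <- ad_trifuse(mri, pet, as.matrix(std[rows, .clinical_order]),
                    object$params, object$config, object$state,
                    training = FALSE)
    probs[i:(i + length(sel) - 1)] <- 1 / (1 + exp(-as.vector(nval(z))))
  }
  names(probs) <- ids
  switch(type,
         prob = probs,
         class = stats::setNames(as.integer(probs >= 0.5), ids),
         response = data.frame(subject_id = ids, probability = probs,
                               class = as.integer(probs >= 0.5),
                               row.names = NULL))
}

#' Plot training and validation loss curves
#'
#' @param x A fitted `trifuse` model.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.trifuse <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "focal loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Extract model parameters
#'
#' @param object A fitted `trifuse` model.
#' @param ... Unused.
#' @return The nested list of parameter arrays.
#' @export
coef.trifuse <- function(object, ...) object$params
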