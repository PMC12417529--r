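# Training protocol: Adam with a cosine learning-rate schedule, focal loss,
# per-epoch validation and early stopping; stratified cross-validation with
# per-fold scoring of the held-out test split.

#' Training control parameters
#'
#' Defaults follow the study protocol: 200 epochs, batch size 8, Adam at
#' 1e-4, cosine period 50 and early-stopping patience 50.
#'
#' @param epochs,batch_size,lr,t_max,patience See description.
#' @param alpha,gamma,literal_form Focal-loss settings.
#' @param verbose Print a line per epoch.
#' @return A list of class `train_control`.
#' @export
train_control <- function(epochs = 200L, batch_size = 8L, lr = 1e-4,
                          t_max = 50L, patience = 50L, alpha = 0.75,
                          gamma = 2, literal_form = FALSE, verbose = FALSE) {
  stopifnot(epochs >= 1, batch_size >= 1, lr > 0, t_max >= 1, patience >= 0)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, t_max = as.integer(t_max),
                 patience = as.integer(patience), alpha = alpha, gamma = gamma,
                 literal_form = isTRUE(literal_form), verbose = isTRUE(verbose)),
            class = "train_control")
}

adam_init <- function(params) {
  list(m = param_map(params, function(x) x * 0),
       v = param_map(params, function(x) x * 0),
       t = 0L)
}

.adam_rec <- function(p, g, m, v, lr_t, beta1, beta2, eps) {
  if (inherits(p, "spline_grid")) return(list(p = p, m = m, v = v))
  if (is.list(p)) {
    for (nm in names(p)) {
      r <- .adam_rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr_t, beta1, beta2, eps)
      p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
    }
    return(list(p = p, m = m, v = v))
  }
  if (!is.double(p)) return(list(p = p, m = m, v = v))
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g * g
  list(p = p - lr_t * m / (sqrt(v) + eps), m = m, v = v)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  lr_t <- lr * sqrt(1 - beta2^st$t) / (1 - beta1^st$t)
  r <- .adam_rec(params, grads, st$m, st$v, lr_t, beta1, beta2, eps)
  st$m <- r$m; st$v <- r$v
  list(params = r$p, st = st)
}

# materialize normalized volume batches and standardized clinical rows for a
# set of ids; standardization statistics come from stats_ids only
.prep_data <- function(cohort, stats_ids) {
  cli <- cohort$clinical
  tr <- cli$subject_id %in% stats_ids
  stats <- lapply(.clinical_features, function(f) {
    s <- stats::sd(cli[[f]][tr])
    if (!is.finite(s) || s == 0)
      stop("zero variance in training rows for feature '", f, "'")
    c(mean = mean(cli[[f]][tr]), sd = s)
  })
  names(stats) <- .clinical_features
  std <- cli
  for (f in .clinical_features)
    std[[f]] <- (cli[[f]] - stats[[f]]["mean"]) / stats[[f]]["sd"]
  cache <- new.env(parent = emptyenv())
  get_norm <- function(id, modality) {
    key <- paste0(modality, ".", id)
    if (is.null(cache[[key]]))
      cache[[key]] <- intensity_normalize(cohort$subjects[[id]][[modality]])$voxels
    cache[[key]]
  }
  batch <- function(ids) {
    d <- dim(cohort$subjects[[ids[1]]]$mri$voxels)
    mri <- array(0, dim = c(length(ids), 1L, d))
    pet <- array(0, dim = c(length(ids), 1L, d))
    for (i in seq_along(ids)) {
      mri[i, 1, , , ] <- get_norm(ids[i], "mri")
      pet[i, 1, , , ] <- get_norm(ids[i], "pet")
    }
    rows <- match(ids, std$subject_id)
    list(mri = mri, pet = pet,
         cli = as.matrix(std[rows, .clinical_order]),
         y = cohort$labels[ids])
  }
  list(batch = batch, stats = stats)
}

# evaluation-mode probabilities for ids, in batches
.predict_ids <- function(params, state, config, prep, ids, batch_size = 8L) {
  out <- numeric(length(ids))
  for (i in seq(1, length(ids), by = batch_size)) {
    sel <- ids[i:min(i + batch_size - 1, length(ids))]
    b <- prep$batch(sel)
    z <- ad_trifuse(b$mri, b$pet, b$cli, params, config, state, training = FALSE)
    out[i:(i + length(sel) - 1)] <- 1 / (1 + exp(-as.vector(nval(z))))
  }
  stats::setNames(out, ids)
}

#' Train the network on one training/validation split
#'
#' Runs Adam with the cosine schedule over mini-batches of focal loss; after
#' each epoch the validation focal loss is computed in evaluation mode, and
#' training halts once it has failed to improve for `patience` consecutive
#' epochs. The parameters (and batch-norm state) of the best validation epoch
#' are returned. Fully deterministic for a fixed seed.
#'
#' @param cohort A `trifuse_cohort` (see [synth_cohort()]).
#' @param train_ids,val_ids Disjoint subject id sets.
#' @param config A [trifuse_config()].
#' @param control A [train_control()].
#' @param seed Integer seed controlling initialization and batch order.
#' @return List with `params`, `state`, `history` (one row per epoch),
#'   `best_epoch`, `best_val_loss` and the clinical `stats` used.
#' @export
train_one_fold <- function(cohort, train_ids, val_ids, config,
                           control = train_control(), seed = 1L) {
  if (!length(train_ids) || !length(val_ids)) stop("empty id set")
  if (length(intersect(train_ids, val_ids))) stop("train and val ids overlap")
  prep <- .prep_data(cohort, train_ids)
  init <- trifuse_init(config, seed = seed)
  params <- init$params
  state <- init$state
  opt <- adam_init(params)
  best <- Inf; best_params <- params; best_state <- as.list(state)
  best_epoch <- 0L; wait <- 0L
  hist <- data.frame()
  with_seed(seed + 104729L, {
    for (epoch in seq_len(control$epochs)) {
      lr <- cosine_lr(epoch - 1L, control$lr, control$t_max)
      ord <- sample(train_ids)
      tr_loss <- 0; nb <- 0L
      for (i in seq(1, length(ord), by = control$batch_size)) {
        sel <- ord[i:min(i + control$batch_size - 1, length(ord))]
        b <- prep$batch(sel)
        pn <- param_wrap(params)
        z <- ad_trifuse(b$mri, b$pet, b$cli, pn, config, state, training = TRUE)
        loss <- ad_focal_from_logits(z, b$y, control$alpha, control$gamma,
                                     control$literal_form)
        ad_backward(loss)
        grads <- param_grads(pn)
        res <- adam_step(params, grads, opt, lr)
        params <- res$params; opt <- res$st
        tr_loss <- tr_loss + nval(loss); nb <- nb + 1L
      }
      vb <- prep$batch(val_ids)
      zv <- ad_trifuse(vb$mri, vb$pet, vb$cli, params, config, state,
                       training = FALSE)
      val_loss <- mean(focal_loss(1 / (1 + exp(-as.vector(nval(zv)))), vb$y,
                                  control$alpha, control$gamma,
                                  control$literal_form))
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     train_loss = tr_loss / nb,
                                     val_loss = val_loss))
      if (control$verbose)
        message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f",
                        epoch, lr, tr_loss / nb, val_loss))
      if (val_loss < best) {
        best <- val_loss; best_params <- params
        best_state <- as.list(state); best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait > control$patience) break
      }
    }
  })
  state_best <- new.env(parent = emptyenv())
  for (nm in names(best_state)) state_best[[nm]] <- best_state[[nm]]
  list(params = best_params, state = state_best, history = hist,
       best_epoch = best_epoch, best_val_loss = best, stats = prep$stats)
}

#' Stratified cross-validation with per-fold test-set scoring
#'
#' Carves `k` stratified folds out of the training split, trains on k-1 folds
#' with the remaining fold for validation/early stopping, and scores each
#' trained model both on its validation fold and on the single held-out test
#' split.
#'
#' @param cohort A `trifuse_cohort`.
#' @param split A `split_plan` from [stratified_split()].
#' @param config A [trifuse_config()].
#' @param control A [train_control()].
#' @param k Number of folds.
#' @param seed Master seed; fold assignment and per-fold training seeds are
#'   derived from it by fixed offsets.
#' @return A list of class `trifuse_cv` with `fold_metrics`, `test_metrics`,
#'   `mean`, `sd` and the fold plan.
#' @export
run_cv <- function(cohort, split, config, control = train_control(), k = 5L,
                   seed = 1L) {
  labels <- cohort$labels[split$train_ids]
  folds <- make_cv_folds(labels, k = k, seed = seed + 1L)
  fold_metrics <- list(); test_metrics <- list()
  for (i in seq_len(k)) {
    val_ids <- names(folds$assignments)[folds$assignments == i]
    tr_ids <- setdiff(split$train_ids, val_ids)
    fit <- train_one_fold(cohort, tr_ids, val_ids, config, control,
                          seed = seed + 100L * i)
    prep <- .prep_data(cohort, tr_ids)
    pv <- .predict_ids(fit$params, fit$state, config, prep, val_ids)
    fold_metrics[[i]] <- compute_metrics(NULL, pv, cohort$labels[val_ids])
    pt <- .predict_ids(fit$params, fit$state, config, prep, split$test_ids)
    test_metrics[[i]] <- compute_metrics(NULL, pt, cohort$labels[split$test_ids])
  }
  fields <- c("accuracy", "sensitivity", "precision", "f1",
              "balanced_accuracy", "auroc")
  tab <- sapply(fields, function(f)
    vapply(fold_metrics, function(m) m[[f]], numeric(1)))
  structure(list(fold_metrics = fold_metrics, test_metrics = test_metrics,
                 mean = colMeans(tab), sd = apply(tab, 2, stats::sd),
                 folds = folds),
            class = "trifuse_cv")
}

#' @export
print.trifuse_cv <- function(x, ...) {
  cat("Cross-validation over", length(x$fold_metrics), "folds (validation metrics, mean +/- sd):\n")
  for (f in names(x$mean))
    cat(sprintf("  %-18s %.4f +/- %.4f\n", f, x$mean[f], x$sd[f]))
  invisible(x)
}
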