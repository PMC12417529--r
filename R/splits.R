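# Stratified train/test split and cross-validation folds.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

round_half_up <- function(x) floor(x + 0.5)

#' Stratified train/test split
#'
#' Splits a labelled cohort so that each class contributes
#' `round(test_fraction * n_class)` subjects (rounding half up) to the test
#' set, with membership chosen by a seeded shuffle. With 149 positives, 363
#' negatives and `test_fraction = 0.2` this yields a 30/73 test and 119/290
#' training split.
#'
#' @param labels Named numeric/integer vector of 0/1 class labels; names are
#'   subject ids.
#' @param test_fraction Fraction of each class assigned to the test set,
#'   strictly between 0 and 1.
#' @param seed Integer seed controlling the shuffle.
#' @return An object of class `split_plan` with `train_ids`, `test_ids`,
#'   `seed` and `test_fraction`.
#' @export
stratified_split <- function(labels, test_fraction = 0.2, seed = 1L) {
  if (is.null(names(labels))) stop("labels must be named by subject id")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (!(test_fraction > 0 && test_fraction < 1))
    stop("test_fraction must lie strictly in (0, 1)")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  test_ids <- character(0)
  with_seed(seed, {
    for (cl in c(0, 1)) {
      ids <- names(labels)[labels == cl]
      n_test <- round_half_up(test_fraction * length(ids))
      test_ids <- c(test_ids, sample(ids)[seq_len(n_test)])
    }
  })
  train_ids <- setdiff(names(labels), test_ids)
  structure(list(train_ids = train_ids, test_ids = test_ids,
                 seed = as.integer(seed), test_fraction = test_fraction),
            class = "split_plan")
}

#' Stratified k-fold assignments over the training set
#'
#' Partitions ids into `k` folds so that within each class the fold sizes
#' differ by at most one.
#'
#' @param labels Named 0/1 vector over the training ids.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return An object of class `fold_plan` with `k`, `seed` and `assignments`
#'   (a named integer vector of fold indices in `1..k`).
#' @export
make_cv_folds <- function(labels, k = 5L, seed = 1L) {
  if (is.null(names(labels))) stop("labels must be named by subject id")
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  assignments <- integer(0)
  with_seed(seed, {
    for (cl in c(0, 1)) {
      ids <- names(labels)[labels == cl]
      if (length(ids) < k)
        stop("class ", cl, " has fewer members (", length(ids),
             ") than folds (", k, ")")
      ids <- sample(ids)
      sizes <- rep(length(ids) %/% k, k)
      extra <- length(ids) %% k
      if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
      fold <- rep(seq_len(k), times = sizes)
      a <- stats::setNames(fold, ids)
      assignments <- c(assignments, a)
    }
  })
  structure(list(k = k, seed = as.integer(seed), assignments = assignments),
            class = "fold_plan")
}

#' Serialize a split or fold plan to JSON
#'
#' @param plan A `split_plan` or `fold_plan`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_plan_json <- function(plan, path) {
  if (inherits(plan, "split_plan")) {
    obj <- list(type = "split", seed = plan$seed,
                test_fraction = plan$test_fraction,
                train_ids = plan$train_ids, test_ids = plan$test_ids)
  } else if (inherits(plan, "fold_plan")) {
    obj <- list(type = "folds", seed = plan$seed, k = plan$k,
                ids = names(plan$assignments),
                fold = unname(plan$assignments))
  } else stop("not a split_plan or fold_plan")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a split or fold plan written by [write_plan_json()]
#'
#' @param path JSON path.
#' @return A `split_plan` or `fold_plan`.
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "split")) {
    structure(list(train_ids = obj$train_ids, test_ids = obj$test_ids,
                   seed = as.integer(obj$seed),
                   test_fraction = obj$test_fraction),
              class = "split_plan")
  } else if (identical(obj$type, "folds")) {
    structure(list(k = as.integer(obj$k), seed = as.integer(obj$seed),
                   assignments = stats::setNames(as.integer(obj$fold), obj$ids)),
              class = "fold_plan")
  } else stop("unrecognized plan JSON: ", path)
}
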