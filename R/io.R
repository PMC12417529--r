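#' Construct a volume grid
#'
#' A `volume_grid` holds one 3D image as a numeric array in `[depth, height,
#' width]` order together with its 4x4 voxel-to-world affine. Inputs are
#' assumed already co-registered; no reorientation is attempted.
#'
#' @param voxels Numeric 3D array, all values finite.
#' @param affine 4x4 voxel-to-world matrix (default identity).
#' @param subject_id Subject identifier string.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(voxels, affine = diag(4), subject_id = "") {
  if (length(dim(voxels)) != 3L)
    stop("expected 3D volume for subject '", subject_id, "', got ",
         length(dim(voxels)), "D")
  if (any(dim(voxels) < 1L)) stop("volume shape must be positive")
  if (!all(is.finite(voxels)))
    stop("non-finite voxel values for subject '", subject_id, "'")
  if (!identical(dim(affine), c(4L, 4L))) stop("affine must be 4x4")
  structure(list(voxels = voxels, affine = affine,
                 subject_id = as.character(subject_id)),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> subject:", if (nzchar(x$subject_id)) x$subject_id else "<unnamed>",
      " shape:", paste(dim(x$voxels), collapse = " x "),
      " range: [", signif(min(x$voxels), 4), ",", signif(max(x$voxels), 4), "]\n")
  invisible(x)
}

#' Read a 3D volume from a NIfTI-1 file
#'
#' @param path Path to a `.nii` / `.nii.gz` file containing a 3D image.
#' @param subject_id Optional subject id attached to the result (defaults to
#'   the file name without extension).
#' @return A [volume_grid()].
#' @export
read_volume <- function(path, subject_id = NULL) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 3L)
    stop("expected 3D volume for subject '", subject_id, "', got ",
         length(dm), "D image: ", path)
  vox <- array(as.numeric(img), dim = dm)
  if (any(is.na(vox)))
    stop("NaN voxels in volume for subject '", subject_id, "': ", path)
  aff <- structure(RNifti::xform(img), dimnames = NULL)
  volume_grid(vox, matrix(as.numeric(aff), 4, 4), subject_id)
}

#' Write a volume grid to a NIfTI-1 file
#'
#' @param v A [volume_grid()].
#' @param path Destination path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; `"float"` (32-bit) by default.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path, datatype = "float") {
  stopifnot(inherits(v, "volume_grid"))
  if (!all(is.finite(v$voxels))) stop("refusing to write non-finite voxels")
  img <- RNifti::asNifti(v$voxels)
  img <- RNifti::`pixdim<-`(img, sqrt(colSums(v$affine[1:3, 1:3]^2)))
  img <- RNifti::`qform<-`(img, structure(v$affine, code = 2L))
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Resize a volume by trilinear interpolation
#'
#' Interpolates onto a `target` grid using corner-aligned trilinear
#' interpolation and rescales the affine's voxel axes accordingly, so the
#' world extent spanned by the corner voxels is preserved.
#'
#' @param v A [volume_grid()].
#' @param target Integer vector `(depth, height, width)`.
#' @return A resized [volume_grid()].
#' @export
resize_volume <- function(v, target) {
  stopifnot(inherits(v, "volume_grid"))
  target <- as.integer(target)
  if (length(target) != 3L || any(target < 1L))
    stop("target shape must be three positive integers")
  src <- dim(v$voxels)
  if (identical(src, target)) return(v)
  pos <- lapply(1:3, function(j) {
    if (target[j] == 1L) rep(0, 1)
    else (0:(target[j] - 1)) * (src[j] - 1) / (target[j] - 1)
  })
  i0 <- lapply(1:3, function(j) pmin(pmax(floor(pos[[j]]), 0), max(src[j] - 2, 0)))
  fr <- lapply(1:3, function(j) if (src[j] == 1L) rep(0, target[j]) else pos[[j]] - i0[[j]])
  id <- i0[[1]] + 1L; ih <- i0[[2]] + 1L; iw <- i0[[3]] + 1L
  id1 <- pmin(id + 1L, src[1]); ih1 <- pmin(ih + 1L, src[2]); iw1 <- pmin(iw + 1L, src[3])
  wd <- fr[[1]]; wh <- fr[[2]]; ww <- fr[[3]]
  W <- function(a, b, c) outer(outer(a, b), c)
  vx <- v$voxels
  out <- vx[id,  ih,  iw,  drop = FALSE] * W(1 - wd, 1 - wh, 1 - ww) +
         vx[id1, ih,  iw,  drop = FALSE] * W(wd,     1 - wh, 1 - ww) +
         vx[id,  ih1, iw,  drop = FALSE] * W(1 - wd, wh,     1 - ww) +
         vx[id1, ih1, iw,  drop = FALSE] * W(wd,     wh,     1 - ww) +
         vx[id,  ih,  iw1, drop = FALSE] * W(1 - wd, 1 - wh, ww) +
         vx[id1, ih,  iw1, drop = FALSE] * W(wd,     1 - wh, ww) +
         vx[id,  ih1, iw1, drop = FALSE] * W(1 - wd, wh,     ww) +
         vx[id1, ih1, iw1, drop = FALSE] * W(wd,     wh,     ww)
  dim(out) <- target
  scale <- ifelse(target > 1L, (src - 1) / (target - 1), 1)
  aff <- v$affine
  aff[, 1:3] <- aff[, 1:3] %*% diag(scale)
  volume_grid(out, aff, v$subject_id)
}

#' Z-score a volume's foreground intensities
#'
#' Standardizes voxels with nonzero value (the foreground of a skull-stripped
#' image) to zero mean and unit standard deviation; background voxels that are
#' exactly zero are left at zero.
#'
#' @param v A [volume_grid()].
#' @return A normalized [volume_grid()].
#' @export
intensity_normalize <- function(v) {
  stopifnot(inherits(v, "volume_grid"))
  fg <- abs(v$voxels) > 0
  if (!any(fg))
    stop("all-zero volume for subject '", v$subject_id, "': nothing to normalize")
  vals <- v$voxels[fg]
  s <- stats::sd(vals)
  if (!is.finite(s) || s == 0)
    stop("constant nonzero foreground (zero variance) for subject '",
         v$subject_id, "'")
  out <- v$voxels
  out[fg] <- (vals - mean(vals)) / s
  volume_grid(out, v$affine, v$subject_id)
}

.clinical_features <- c("age", "education", "ptau181", "ttau",
                        "fdg_av45_composite")
.clinical_codes <- c("gender", "apoe4")
.clinical_order <- c("age", "gender", "education", "apoe4", "ptau181",
                     "ttau", "fdg_av45_composite")

#' Load and standardize a clinical table
#'
#' Reads a CSV with columns `subject_id`, the seven clinical features (`age`,
#' `gender`, `education`, `apoe4`, `ptau181`, `ttau`, `fdg_av45_composite`)
#' and a binary `label` (1 = progressive MCI). Continuous features are
#' z-scored using statistics computed from `training_ids` only, so that test
#' subjects never leak into the normalization; `gender` (0/1) and `apoe4`
#' (allele count 0/1/2) pass through as numeric codes. Missing values are
#' errors, not imputed.
#'
#' @param path CSV path (header row, comma separated).
#' @param training_ids Subject ids whose rows define the standardization
#'   statistics.
#' @return An object of class `cohort_table` with elements `records` (a
#'   data.frame with standardized features) and `feature_stats`.
#' @export
load_clinical_table <- function(path, training_ids) {
  if (!file.exists(path)) stop("clinical table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", .clinical_order, "label")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("clinical table missing column(s): ",
                         paste(miss, collapse = ", "))
  df <- df[, required]
  if (anyNA(df)) {
    bad <- required[vapply(df, anyNA, logical(1))]
    stop("missing values in clinical column(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in clinical table")
  if (!all(df$gender %in% c(0, 1)))
    stop("unknown gender code (expected 0/1)")
  if (!all(df$apoe4 %in% c(0, 1, 2)))
    stop("apoe4 must be an allele count in {0, 1, 2}")
  if (!all(df$label %in% c(0, 1)))
    stop("label must be 0 (sMCI) or 1 (pMCI)")
  tr <- df$subject_id %in% training_ids
  if (!any(tr)) stop("no training rows found in clinical table")
  stats <- lapply(.clinical_features, function(f) {
    mu <- mean(df[[f]][tr])
    s <- stats::sd(df[[f]][tr])
    if (!is.finite(s) || s == 0)
      stop("zero variance in training rows for feature '", f,
           "': cannot standardize")
    c(mean = mu, sd = s)
  })
  names(stats) <- .clinical_features
  for (f in .clinical_features)
    df[[f]] <- (df[[f]] - stats[[f]]["mean"]) / stats[[f]]["sd"]
  structure(list(records = df, feature_stats = stats,
                 training_ids = intersect(df$subject_id, training_ids)),
            class = "cohort_table")
}

#' Extract the standardized 7-column feature matrix from a cohort table
#'
#' @param tab A `cohort_table`.
#' @param ids Optional subject ids selecting and ordering rows.
#' @return Numeric matrix `[n, 7]` with rownames set to subject ids.
#' @export
clinical_matrix <- function(tab, ids = NULL) {
  stopifnot(inherits(tab, "cohort_table"))
  df <- tab$records
  if (!is.null(ids)) {
    miss <- setdiff(ids, df$subject_id)
    if (length(miss)) stop("unknown subject id(s): ", paste(miss, collapse = ", "))
    df <- df[match(ids, df$subject_id), ]
  }
  m <- as.matrix(df[, .clinical_order])
  rownames(m) <- df$subject_id
  m
}
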