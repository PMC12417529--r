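# Synthetic paired MRI/PET volumes plus clinical tables with controllable
# class effects. Volumes consist of a bright ellipsoidal "brain" on a zero
# background with smoothed Gaussian noise; the progressive class has its
# intensity reduced inside a fixed ellipsoidal region of each modality
# (mimicking focal atrophy / hypometabolism). Clinical features follow
# class-conditional normals and Bernoullis. Not intended to look like real
# neuroanatomy; it exists so every pipeline stage is testable without
# restricted data.

#' Specify the class effects of the synthetic generator
#'
#' Regions are ellipsoids given as center/radii fractions of the volume.
#' Intensity deltas are subtracted inside the region for class-1 (pMCI-like)
#' subjects; `clinical_shifts` are class-1 mean shifts in units of each
#' feature's standard deviation.
#'
#' @param mri_center,mri_radii,mri_delta MRI effect region and decrement.
#' @param pet_center,pet_radii,pet_delta PET effect region and decrement.
#' @param clinical_shifts Named shifts (sd units) for `age`, `education`,
#'   `ptau181`, `ttau`, `fdg_av45_composite`.
#' @param apoe4_rates Per-class (sMCI, pMCI) Bernoulli rate per allele.
#' @param gender_rate Shared male rate.
#' @param noise_sigma Voxel noise sd before smoothing.
#' @param smoothing Gaussian smoothing sd of the noise field, in voxels.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(mri_center = c(0.42, 0.50, 0.50),
                        mri_radii = c(0.12, 0.10, 0.10),
                        mri_delta = 0.3,
                        pet_center = c(0.60, 0.42, 0.50),
                        pet_radii = c(0.12, 0.10, 0.10),
                        pet_delta = 0.3,
                        clinical_shifts = c(age = 0.3, education = 0,
                                            ptau181 = 1.5, ttau = 1.5,
                                            fdg_av45_composite = -1.5),
                        apoe4_rates = c(0.3, 0.6),
                        gender_rate = 0.5,
                        noise_sigma = 0.1,
                        smoothing = 1) {
  if (mri_delta < 0 || pet_delta < 0) stop("deltas must be nonnegative")
  chk <- function(c0, r0, what) {
    if (any(c0 - r0 < 0) || any(c0 + r0 > 1))
      stop(what, " effect region extends outside the unit cube")
  }
  chk(mri_center, mri_radii, "mri")
  chk(pet_center, pet_radii, "pet")
  structure(list(mri_center = mri_center, mri_radii = mri_radii,
                 mri_delta = mri_delta, pet_center = pet_center,
                 pet_radii = pet_radii, pet_delta = pet_delta,
                 clinical_shifts = clinical_shifts,
                 apoe4_rates = apoe4_rates, gender_rate = gender_rate,
                 noise_sigma = noise_sigma, smoothing = smoothing),
            class = "effect_spec")
}

# boolean ellipsoid mask from center/radii fractions
.ellipsoid_mask <- function(shape, center, radii) {
  cs <- center * shape
  rs <- pmax(radii * shape, 1e-9)
  d <- ((seq_len(shape[1]) - 0.5) - cs[1]) / rs[1]
  h <- ((seq_len(shape[2]) - 0.5) - cs[2]) / rs[2]
  w <- ((seq_len(shape[3]) - 0.5) - cs[3]) / rs[3]
  outer(outer(d^2, h^2, "+"), w^2, "+") <= 1
}

# separable Gaussian smoothing with reflecting edges
.smooth3d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  sm_axis <- function(a, axis) {
    d <- dim(a)
    n <- d[axis]
    idx <- function(i) pmin(pmax(i, 1L), n)  # replicate edges
    out <- array(0, dim = d)
    for (t in -r:r) {
      sl <- idx(seq_len(n) + t)
      out <- out + kern[t + r + 1] * switch(axis,
        a[sl, , , drop = FALSE], a[, sl, , drop = FALSE], a[, , sl, drop = FALSE])
    }
    out
  }
  sm_axis(sm_axis(sm_axis(x, 1L), 2L), 3L)
}

.effect_region <- function(spec, modality, shape) {
  if (modality == "mri") .ellipsoid_mask(shape, spec$mri_center, spec$mri_radii)
  else .ellipsoid_mask(shape, spec$pet_center, spec$pet_radii)
}

.gen_volume <- function(label, spec, shape, modality) {
  brain <- .ellipsoid_mask(shape, c(0.5, 0.5, 0.5), c(0.45, 0.45, 0.45))
  noise <- .smooth3d(array(stats::rnorm(prod(shape), sd = spec$noise_sigma),
                           dim = shape), spec$smoothing)
  v <- array(0, dim = shape)
  v[brain] <- 1 + noise[brain]
  delta <- if (modality == "mri") spec$mri_delta else spec$pet_delta
  if (label == 1 && delta > 0) {
    reg <- .effect_region(spec, modality, shape) & brain
    v[reg] <- v[reg] - delta
  }
  v
}

.clinical_base <- list(age = c(73, 7.3), education = c(16, 2.6),
                       ptau181 = c(25, 10), ttau = c(90, 40),
                       fdg_av45_composite = c(1.2, 0.15))

#' Generate one synthetic subject
#'
#' @param label 0 (stable) or 1 (progressive).
#' @param spec An [effect_spec()].
#' @param shape Volume shape `(D, H, W)`; the default 24x32x24 has the same
#'   3:4:3 aspect as the full-resolution 96x128x96 grid.
#' @param seed Integer seed; identical `(label, seed)` reproduce the subject
#'   bit for bit.
#' @param id Subject id string.
#' @return List with `mri`, `pet` ([volume_grid()]s) and `clinical` (a
#'   one-row data.frame with raw, unstandardized features).
#' @export
synth_subject <- function(label, spec = effect_spec(), shape = c(24L, 32L, 24L),
                          seed = 1L, id = "sub-001") {
  if (any(shape < 4L)) stop("shape too small")
  with_seed(seed, {
    mri <- .gen_volume(label, spec, shape, "mri")
    pet <- .gen_volume(label, spec, shape, "pet")
    sh <- spec$clinical_shifts
    draw <- function(f) {
      b <- .clinical_base[[f]]
      mu <- b[1] + if (label == 1) sh[[f]] * b[2] else 0
      stats::rnorm(1, mu, b[2])
    }
    cli <- data.frame(
      subject_id = id,
      age = draw("age"),
      gender = stats::rbinom(1, 1, spec$gender_rate),
      education = draw("education"),
      apoe4 = stats::rbinom(1, 2, spec$apoe4_rates[label + 1]),
      ptau181 = draw("ptau181"),
      ttau = draw("ttau"),
      fdg_av45_composite = draw("fdg_av45_composite"),
      label = label
    )
    list(mri = volume_grid(mri, diag(4), id),
         pet = volume_grid(pet, diag(4), id),
         clinical = cli)
  })
}

#' Generate a synthetic cohort
#'
#' @param n_pos,n_neg Class counts (progressive / stable).
#' @param spec An [effect_spec()].
#' @param shape Volume shape.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return An object of class `trifuse_cohort`: `subjects` (named list of
#'   `mri`/`pet` volume pairs), `clinical` (raw feature data.frame), `labels`
#'   (named 0/1 vector), plus the generating `spec`, `shape` and `seed`.
#' @export
synth_cohort <- function(n_pos, n_neg, spec = effect_spec(),
                         shape = c(24L, 32L, 24L), seed = 1L) {
  if (n_pos < 1 || n_neg < 1) stop("class counts must be positive")
  ids <- c(sprintf("sub-P%03d", seq_len(n_pos)),
           sprintf("sub-S%03d", seq_len(n_neg)))
  labels <- stats::setNames(c(rep(1L, n_pos), rep(0L, n_neg)), ids)
  subjects <- list()
  clinical <- NULL
  for (i in seq_along(ids)) {
    sub_seed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    s <- synth_subject(labels[[i]], spec, shape, seed = sub_seed, id = ids[i])
    subjects[[ids[i]]] <- list(mri = s$mri, pet = s$pet)
    clinical <- rbind(clinical, s$clinical)
  }
  structure(list(subjects = subjects, clinical = clinical, labels = labels,
                 spec = spec, shape = as.integer(shape),
                 seed = as.integer(seed)),
            class = "trifuse_cohort")
}

#' @export
print.trifuse_cohort <- function(x, ...) {
  cat("<trifuse_cohort>", length(x$subjects), "subjects (",
      sum(x$labels == 1), "pMCI /", sum(x$labels == 0), "sMCI ), volumes",
      paste(x$shape, collapse = "x"), "\n")
  invisible(x)
}

#' Write a cohort to disk as NIfTI pairs + clinical CSV + truth JSON
#'
#' @param cohort A `trifuse_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$subjects)) {
    write_volume(cohort$subjects[[id]]$mri, file.path(dir, paste0(id, "_mri.nii.gz")))
    write_volume(cohort$subjects[[id]]$pet, file.path(dir, paste0(id, "_pet.nii.gz")))
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  truth <- unclass(cohort$spec)
  truth$shape <- cohort$shape
  truth$seed <- cohort$seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
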