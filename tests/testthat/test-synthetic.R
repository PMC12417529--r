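test_that("synthetic subjects are reproducible and class effects are placed", {
  spec <- effect_spec()
  s1 <- synth_subject(1, spec, seed = 101, id = "a")
  s2 <- synth_subject(1, spec, seed = 101, id = "a")
  expect_identical(s1$mri$voxels, s2$mri$voxels)
  expect_identical(s1$clinical, s2$clinical)
  s3 <- synth_subject(1, spec, seed = 102, id = "a")
  expect_false(identical(s1$mri$voxels, s3$mri$voxels))
  expect_error(effect_spec(mri_center = c(0.95, 0.5, 0.5)), "outside")
})

test_that("the class-1 intensity decrement appears inside the MRI region", {
  spec <- effect_spec()
  shape <- c(24L, 32L, 24L)
  reg <- trifuse:::.effect_region(spec, "mri", shape)
  n <- 50
  m0 <- m1 <- numeric(n)
  for (i in 1:n) {
    m0[i] <- mean(synth_subject(0, spec, shape, seed = 200 + i)$mri$voxels[reg])
    m1[i] <- mean(synth_subject(1, spec, shape, seed = 400 + i)$mri$voxels[reg])
  }
  diffhat <- mean(m0) - mean(m1)
  se <- sqrt(var(m0) / n + var(m1) / n)
  expect_lt(abs(diffhat - spec$mri_delta), 2 * se + 0.01)
})

test_that("zero effects make the class-conditional distributions identical", {
  null_spec <- effect_spec(mri_delta = 0, pet_delta = 0,
                           clinical_shifts = c(age = 0, education = 0,
                                               ptau181 = 0, ttau = 0,
                                               fdg_av45_composite = 0),
                           apoe4_rates = c(0.4, 0.4))
  n <- 50
  v0 <- unlist(lapply(1:n, function(i)
    mean(synth_subject(0, null_spec, seed = 600 + i)$mri$voxels)))
  v1 <- unlist(lapply(1:n, function(i)
    mean(synth_subject(1, null_spec, seed = 800 + i)$mri$voxels)))
  expect_gt(stats::ks.test(v0, v1)$p.value, 0.01)
})

test_that("cohorts have the requested composition and round-trip to disk", {
  coh <- synth_cohort(5, 9, seed = 11)
  expect_length(coh$subjects, 14)
  expect_equal(sum(coh$labels == 1), 5)
  expect_equal(sum(coh$labels == 0), 9)
  expect_false(anyDuplicated(names(coh$subjects)) > 0)
  coh2 <- synth_cohort(5, 9, seed = 12)
  expect_false(identical(coh$subjects[[1]]$mri$voxels,
                         coh2$subjects[[1]]$mri$voxels))
  dir <- tempfile()
  write_cohort(coh, dir)
  # reload through the I/O layer: identical features within float32
  tab <- load_clinical_table(file.path(dir, "clinical.csv"),
                             training_ids = names(coh$labels))
  expect_equal(nrow(tab$records), 14)
  id <- names(coh$subjects)[3]
  v <- read_volume(file.path(dir, paste0(id, "_mri.nii.gz")))
  expect_equal(v$voxels, coh$subjects[[id]]$mri$voxels, tolerance = 1e-6)
})

test_that("strong effects make the task linearly separable, null effects do not", {
  spec <- effect_spec()  # defaults: deltas 3x noise sd, shifts 1.5 sd
  coh <- synth_cohort(30, 30, spec, seed = 21)
  shape <- coh$shape
  regm <- trifuse:::.effect_region(spec, "mri", shape)
  regp <- trifuse:::.effect_region(spec, "pet", shape)
  feat <- t(vapply(names(coh$labels), function(id) {
    c(mean(coh$subjects[[id]]$mri$voxels[regm]),
      mean(coh$subjects[[id]]$pet$voxels[regp]))
  }, numeric(2)))
  y <- coh$labels
  fit <- suppressWarnings(glm(y ~ feat, family = binomial))
  expect_gt(auroc_mannwhitney(fitted(fit), y), 0.95)
  # all-zero effects: region means carry no signal beyond sampling noise
  nspec <- effect_spec(mri_delta = 0, pet_delta = 0,
                       clinical_shifts = c(age = 0, education = 0,
                                           ptau181 = 0, ttau = 0,
                                           fdg_av45_composite = 0),
                       apoe4_rates = c(0.4, 0.4))
  coh0 <- synth_cohort(30, 30, nspec, seed = 22)
  feat0 <- vapply(names(coh0$labels), function(id)
    mean(coh0$subjects[[id]]$mri$voxels[regm]), numeric(1))
  expect_lt(abs(auroc_mannwhitney(feat0, coh0$labels) - 0.5), 0.2)
})
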