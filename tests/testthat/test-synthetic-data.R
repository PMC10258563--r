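test_that("class patterns are deterministic and respect blob signs", {
  cfg <- synthetic_config(seed = 11L)
  p1 <- make_class_patterns(cfg)
  p2 <- make_class_patterns(cfg)
  expect_length(p1, cfg$n_classes)
  for (ci in seq_along(p1)) {
    expect_identical(p1[[ci]]$weights, p2[[ci]]$weights)
    expect_true(any(p1[[ci]]$support_mask))
    expect_true(all(p1[[ci]]$weights[!p1[[ci]]$mask] == 0))
  }

  ## a single positive blob: support is the half-maximum footprint
  cfg1 <- synthetic_config(n_blobs_per_class = 1L, negative_blob_fraction = 0,
                           redundant_cluster_count = 0L, seed = 3L)
  p <- make_class_patterns(cfg1)[[1]]
  expect_true(all(p$weights >= 0))
  expect_identical(p$support_mask, abs(p$weights) > 0.5 * max(abs(p$weights)))

  ## all-negative blobs force non-positive weights
  cfgn <- synthetic_config(negative_blob_fraction = 1, seed = 4L)
  for (p in make_class_patterns(cfgn)) expect_true(all(p$weights <= 0))
})

test_that("redundant clusters duplicate the sign of an existing blob", {
  cfg <- synthetic_config(redundant_cluster_count = 2L, seed = 9L)
  for (p in make_class_patterns(cfg)) {
    red <- Filter(function(b) !is.null(b$redundant_of), p$blobs)
    expect_length(red, 2L)
    for (b in red) {
      expect_identical(b$sign, p$blobs[[b$redundant_of]]$sign)
      d <- sqrt(sum((b$center - p$blobs[[b$redundant_of]]$center)^2))
      expect_gt(d, cfg$blob_fwhm)  # spatially disjoint copy
    }
  }
})

test_that("blob placement fails loudly when the mask cannot host the blobs", {
  cfg <- synthetic_config(grid_shape = c(8L, 8L, 8L), n_blobs_per_class = 10L,
                          blob_fwhm = 6, redundant_cluster_count = 0L, seed = 1L)
  expect_error(make_class_patterns(cfg), "failed to place")
})

test_that("noise-free trials equal the planted pattern exactly", {
  cfg <- synthetic_config(grid_shape = c(10L, 10L, 10L), n_subjects = 5L,
                          trials_per_class_per_subject = 2L, noise_sd = 0,
                          subject_sd = 0, n_blobs_per_class = 2L,
                          redundant_cluster_count = 1L, blob_fwhm = 3,
                          seed = 5L)
  out <- generate_dataset(cfg)
  pat <- ground_truth_reference(out$patterns)
  for (split in list(out$train, out$test)) {
    for (i in seq_len(ncol(split$x))) {
      ci <- match(split$meta$label[i], colnames(pat))
      expect_equal(split$x[, i], unname(pat[, ci]))
    }
  }
})

test_that("subject-wise split has the configured size and disjoint subjects", {
  cfg <- synthetic_config(grid_shape = c(10L, 10L, 10L), n_subjects = 10L,
                          trials_per_class_per_subject = 2L, test_fraction = 0.2,
                          n_blobs_per_class = 2L, redundant_cluster_count = 1L,
                          blob_fwhm = 3, seed = 6L)
  out <- generate_dataset(cfg)
  expect_length(unique(out$test$meta$subject_id), 2L)
  expect_length(unique(out$train$meta$subject_id), 8L)
  expect_length(intersect(out$train$meta$subject_id, out$test$meta$subject_id), 0L)
  ## labels balanced within each subject
  tab <- table(out$train$meta$subject_id, out$train$meta$label)
  expect_true(all(tab == cfg$trials_per_class_per_subject))
})

test_that("generation is bit-identical under a fixed config", {
  cfg <- synthetic_config(grid_shape = c(10L, 10L, 10L), n_subjects = 5L,
                          trials_per_class_per_subject = 2L,
                          n_blobs_per_class = 2L, redundant_cluster_count = 1L,
                          blob_fwhm = 3, seed = 12L)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$train$x, b$train$x)
  expect_identical(a$test$meta, b$test$meta)
})

test_that("class means of noisy trials converge to the planted pattern", {
  ## Monte-Carlo check against the generator's own ground truth: 50 trials
  ## at noise_sd equal to the pattern peak still average out to the pattern
  base <- synthetic_config(grid_shape = c(12L, 12L, 12L), n_subjects = 2L,
                           trials_per_class_per_subject = 50L, n_classes = 2L,
                           n_blobs_per_class = 2L, redundant_cluster_count = 1L,
                           blob_fwhm = 3, test_fraction = 0.5, subject_sd = 0,
                           seed = 31L)
  peak <- max(abs(make_class_patterns(base)[[1]]$weights))
  cfg <- base
  cfg$noise_sd <- peak
  out <- generate_dataset(cfg)
  mask <- as.vector(out$train$mask)
  for (ci in seq_along(out$patterns)) {
    cl <- out$patterns[[ci]]$class_id
    mu <- rowMeans(out$train$x[, out$train$meta$label == cl, drop = FALSE])
    expect_gt(cor(mu[mask], as.vector(out$patterns[[ci]]$weights)[mask]), 0.95)
  }
})

test_that("NIfTI round-trip preserves values, mask and metadata", {
  ds <- subset_trials(small_dataset()$test, 1:6)
  path <- file.path(withr::local_tempdir(), "trials.nii.gz")
  write_volume(ds, path)
  back <- read_volume(path)
  expect_equal(back$x, ds$x, tolerance = 1e-6)
  expect_identical(dim(back$mask), dim(ds$mask))
  expect_identical(back$meta$label, ds$meta$label)
  expect_identical(back$meta$trial_id, ds$meta$trial_id)

  ## volumes arrive in order as individual trial volumes
  vols <- as_trial_volumes(back)
  expect_length(vols, 6L)
  expect_identical(vols[[3]]$trial_id, ds$meta$trial_id[3])
  expect_equal(as.vector(vols[[3]]$values), ds$x[, 3], tolerance = 1e-6)

  ## mismatched mask grid is rejected
  bad <- file.path(dirname(path), "bad.nii.gz")
  write_volume(ds, bad)
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4))),
                     sub("\\.nii\\.gz$", "_mask.nii.gz", bad))
  expect_error(read_volume(bad), "mask grid")

  ## malformed file is a parse error
  junk <- file.path(dirname(path), "junk.nii")
  writeLines("not a nifti", junk)
  expect_error(read_volume(junk), "malformed NIfTI")
})
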