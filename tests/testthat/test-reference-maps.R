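test_that("voxelwise OLS matches a direct normal-equations solve", {
  set.seed(6)
  n <- 18; V <- 125   # 5^3 grid worth of voxels
  X <- cbind(a = rep(c(1, 0), each = 9), b = rep(c(0, 1), each = 9),
             n1 = rnorm(n))
  Y <- matrix(rnorm(n * V), n, V)
  fit <- fit_voxelwise_glm(Y, X, contrast = c(1, -1, 0))
  bhat <- solve(crossprod(X), crossprod(X, Y))
  expect_equal(max(abs(fit$coef - bhat)), 0, tolerance = 1e-6)
  ## t statistics against the direct formula
  res <- Y - X %*% bhat
  s2 <- colSums(res^2) / (n - 3)
  cv <- drop(t(c(1, -1, 0)) %*% solve(crossprod(X)) %*% c(1, -1, 0))
  expect_equal(fit$t, drop(crossprod(c(1, -1, 0), bhat)) / sqrt(cv * s2),
               tolerance = 1e-9)
  expect_equal(fit$df, n - 3)
})

test_that("exact fits are flagged degenerate and rank deficiency is named", {
  ## two-condition design, voxel means 3 and 1, zero residual
  X <- cbind(a = rep(c(1, 0), each = 4), b = rep(c(0, 1), each = 4))
  Y <- matrix(rep(c(3, 1), each = 4), 8, 2)
  fit <- fit_voxelwise_glm(Y, X, contrast = c(1, -1))
  expect_equal(unname(fit$effect), c(2, 2))
  expect_true(all(fit$degenerate))
  expect_true(all(!is.finite(fit$t) | fit$degenerate))
  ## collinear column is reported by name
  Xbad <- cbind(X, dup = X[, 1])
  expect_error(fit_voxelwise_glm(Y, Xbad), "dup")
})

test_that("a nuisance regressor orthogonal to the contrast leaves it unchanged", {
  set.seed(7)
  n <- 16
  X <- cbind(a = rep(c(1, 0), each = 8), b = rep(c(0, 1), each = 8))
  nuis <- rep(c(1, -1), 8)                  # orthogonal to a - b
  Y <- matrix(rnorm(n * 40), n, 40)
  f1 <- fit_voxelwise_glm(Y, X, contrast = c(1, -1))
  f2 <- fit_voxelwise_glm(Y, cbind(X, nuis = nuis), contrast = c(1, -1, 0))
  expect_equal(f1$effect, f2$effect, tolerance = 1e-9)
})

test_that("null t statistics are calibrated", {
  set.seed(8)
  n <- 24
  X <- cbind(a = rep(c(1, 0), 12), b = rep(c(0, 1), 12))
  Y <- matrix(rnorm(n * 2000), n, 2000)
  fit <- fit_voxelwise_glm(Y, X, contrast = c(1, -1))
  p <- 2 * pt(-abs(fit$t), fit$df)
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
})

test_that("subject contrasts recover the planted sign pattern and antisymmetry", {
  ## noise-free subject: contrast sign equals the pattern sign on support
  cfg <- synthetic_config(grid_shape = c(10L, 10L, 10L), n_subjects = 5L,
                          trials_per_class_per_subject = 4L, n_classes = 2L,
                          n_blobs_per_class = 2L, redundant_cluster_count = 1L,
                          blob_fwhm = 3, noise_sd = 0.05, subject_sd = 0,
                          seed = 44L)
  out <- generate_dataset(cfg)
  sid <- out$train$meta$subject_id[1]
  ds1 <- subset_trials(out$train, which(out$train$meta$subject_id == sid))
  sc <- subject_contrast(ds1)
  ## two classes: class-A map is the negative of the class-B map
  expect_equal(sc$effect[, 1], -sc$effect[, 2], tolerance = 1e-9)
  p1 <- out$patterns[[1]]
  sup <- as.vector(p1$support_mask)
  ## pattern 2 overlaps pattern 1 only weakly; where pattern 1 dominates,
  ## the contrast sign matches the planted sign
  dom <- sup & abs(as.vector(p1$weights)) >
    2 * abs(as.vector(out$patterns[[2]]$weights))
  expect_gt(mean(sign(sc$effect[dom, 1]) == sign(as.vector(p1$weights)[dom])),
            0.95)
  ## single-class subject errors
  one <- subset_trials(ds1, which(ds1$meta$label == ds1$meta$label[1]))
  expect_error(subject_contrast(one), "single class")
})

test_that("label permutation empties the contrast", {
  ds <- small_dataset()
  sid <- ds$train$meta$subject_id[1]
  ds1 <- subset_trials(ds$train, which(ds$train$meta$subject_id == sid))
  sc <- subject_contrast(ds1)
  set.seed(9)
  perm <- ds1
  perm$meta$label <- sample(perm$meta$label)
  scp <- subject_contrast(perm)
  mask <- as.vector(ds1$mask)
  expect_lt(mean(abs(scp$stat[mask, 1])), mean(abs(sc$stat[mask, 1])))
})

test_that("group stage smooths, aggregates and flags degenerate inputs", {
  ds <- small_dataset()
  subj <- lapply(split(seq_len(ncol(ds$train$x)), ds$train$meta$subject_id),
                 function(ii) subject_contrast(subset_trials(ds$train, ii)))
  expect_error(group_contrast(subj[1:2]), "at least 3")
  ## identical subject maps: effect equals the common (smoothed) map and
  ## the within-subject variance collapses
  same <- subj[c(1, 1, 1)]
  g0 <- group_contrast(same, smoothing_fwhm = 0)
  expect_equal(g0$effect, subj[[1]]$effect, tolerance = 1e-9)
  ## group map recovers the planted pattern
  g <- group_contrast(subj, smoothing_fwhm = 1.5)
  mask <- as.vector(ds$train$mask)
  for (ci in seq_along(ds$patterns)) {
    expect_gt(cor(g$stat[mask, ci], as.vector(ds$patterns[[ci]]$weights)[mask]),
              0.5)
  }
  ## smoothing_fwhm = 0 really is the identity on the first stage inputs
  expect_identical(gaussian_smooth(array(subj[[1]]$effect[, 1], ds$train$grid), 0),
                   array(subj[[1]]$effect[, 1], ds$train$grid))
})

test_that("signal recoverability: support voxels outrank signal-free voxels", {
  ## at default noise levels, the two-stage t-contrast must place >= 80%
  ## of each class's support above the 90th percentile of the voxels that
  ## carry no planted signal from any class (one-vs-rest contrasts put
  ## genuine negative signal on other classes' supports, so those are not
  ## a null reference)
  ds <- cached("default_scale_ds", generate_dataset(synthetic_config(seed = 7L)))
  subj <- lapply(split(seq_len(ncol(ds$train$x)), ds$train$meta$subject_id),
                 function(ii) subject_contrast(subset_trials(ds$train, ii)))
  g <- group_contrast(subj, smoothing_fwhm = 1.5)
  mask <- as.vector(ds$train$mask)
  any_sup <- Reduce(`|`, lapply(ds$patterns, function(p) as.vector(p$support_mask)))
  for (ci in seq_along(ds$patterns)) {
    sup <- as.vector(ds$patterns[[ci]]$support_mask) & mask
    noise_vox <- !any_sup & mask
    thr <- quantile(abs(g$stat[noise_vox, ci]), 0.9)
    signed <- g$stat[sup, ci] * sign(as.vector(ds$patterns[[ci]]$weights)[sup])
    expect_gte(mean(signed > thr), 0.8)
  }
})

test_that("attribution aggregation matches a naive two-loop OLS", {
  toy <- toy_net()
  ds <- subset_trials(toy$data$test, seq_len(ncol(toy$data$test$x)))
  at1 <- attribute_trials(toy$model, ds, "gradient", attribution_params())
  at2 <- at1   # duplicate the maps as a second fictitious model run
  agg1 <- aggregate_attributions(list(at1), smoothing_fwhm = 0)
  agg2 <- aggregate_attributions(list(at1, at2), smoothing_fwhm = 0)
  ## duplicating every map across two runs leaves the group maps unchanged
  expect_equal(agg1$group$effect, agg2$group$effect, tolerance = 1e-8)
  ## naive oracle: per-subject OLS with explicit loops
  sid <- ds$meta$subject_id[1]
  rows <- which(ds$meta$subject_id == sid)
  R <- at1$relevance[, rows]
  labs <- ds$meta$label[rows]
  classes <- sort(unique(ds$meta$label))
  Xd <- sapply(classes, function(cl) as.numeric(labs == cl))
  runs <- sort(unique(ds$meta$run_id[rows]))
  for (rv in runs[-1]) Xd <- cbind(Xd, as.numeric(ds$meta$run_id[rows] == rv))
  rs <- colSums(R)
  Xd <- cbind(Xd, rsum = rs - mean(rs))
  ctr <- c(ifelse(classes == classes[1], 1, -1 / (length(classes) - 1)),
           rep(0, length(runs) - 1), 0)
  beta <- solve(crossprod(Xd), crossprod(Xd, t(R)))
  eff_naive <- drop(crossprod(ctr, beta))
  sm <- agg1$subject_maps[[match(sid, unique(ds$meta$subject_id))]]
  expect_equal(unname(sm$effect[, classes[1]]), unname(eff_naive),
               tolerance = 1e-6)
  ## missing (trial, run) cells are rejected
  short <- at1
  short$relevance <- short$relevance[, -1, drop = FALSE]
  short$meta <- short$meta[-1, , drop = FALSE]
  expect_error(aggregate_attributions(list(at1, short)), "same trials")
})

test_that("ground-truth reference passes patterns through unchanged", {
  ds <- small_dataset()
  ref <- ground_truth_reference(ds$patterns)
  expect_identical(ncol(ref), length(ds$patterns))
  for (ci in seq_along(ds$patterns)) {
    expect_identical(unname(ref[, ci]), as.vector(ds$patterns[[ci]]$weights))
  }
  zp <- ds$patterns[1]
  zp[[1]]$weights[] <- 0
  expect_true(all(ground_truth_reference(zp) == 0))
})
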