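#' Configuration for the synthetic volumetric dataset generator
#'
#' The generator emulates the statistical structure of trial-level
#' activation (beta) maps used in mental-state decoding: per-trial 3D
#' volumes inside a brain-like mask, with C classes each tied to a smooth,
#' signed spatial pattern, spatially redundant duplicate clusters,
#' per-subject random effects, and additive spatially smooth noise.
#'
#' @param grid_shape integer(3), voxels per axis (each >= 8).
#' @param n_subjects number of subjects.
#' @param trials_per_class_per_subject trials per class and subject.
#' @param n_classes number of mental-state classes C (>= 2).
#' @param n_blobs_per_class Gaussian blobs summed per class pattern.
#' @param blob_fwhm blob width (FWHM, voxels).
#' @param negative_blob_fraction fraction of blobs with negative sign.
#' @param redundant_cluster_count extra blobs per class that duplicate the
#'   signal of an existing blob at a disjoint location (planted
#'   predictive redundancy).
#' @param subject_sd scale of the per-subject multiplicative amplitude
#'   perturbation of each blob (0 disables subject effects).
#' @param noise_sd standard deviation of the additive Gaussian noise
#'   before smoothing.
#' @param noise_smoothing_fwhm FWHM (voxels) of the noise smoothing kernel.
#' @param test_fraction fraction of subjects held out as test data.
#' @param n_runs number of acquisition runs the trials are tagged with.
#' @param seed integer seed; the full dataset is deterministic given the
#'   configuration.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(grid_shape = c(16L, 16L, 16L),
                             n_subjects = 12L,
                             trials_per_class_per_subject = 24L,
                             n_classes = 4L,
                             n_blobs_per_class = 3L,
                             blob_fwhm = 4,
                             negative_blob_fraction = 0.25,
                             redundant_cluster_count = 2L,
                             subject_sd = 0.15,
                             noise_sd = 1,
                             noise_smoothing_fwhm = 2,
                             test_fraction = 0.2,
                             n_runs = 2L,
                             seed = 1L) {
  cfg <- list(grid_shape = as.integer(grid_shape),
              n_subjects = as.integer(n_subjects),
              trials_per_class_per_subject = as.integer(trials_per_class_per_subject),
              n_classes = as.integer(n_classes),
              n_blobs_per_class = as.integer(n_blobs_per_class),
              blob_fwhm = blob_fwhm,
              negative_blob_fraction = negative_blob_fraction,
              redundant_cluster_count = as.integer(redundant_cluster_count),
              subject_sd = subject_sd,
              noise_sd = noise_sd,
              noise_smoothing_fwhm = noise_smoothing_fwhm,
              test_fraction = test_fraction,
              n_runs = as.integer(n_runs),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  stop_if_not(length(cfg$grid_shape) == 3L && all(cfg$grid_shape >= 8L),
              "grid_shape must be 3 integers, each >= 8")
  stop_if_not(cfg$n_subjects >= 1L, "n_subjects must be positive")
  stop_if_not(cfg$trials_per_class_per_subject >= 1L,
              "trials_per_class_per_subject must be positive")
  stop_if_not(cfg$n_classes >= 2L, "need at least 2 classes")
  stop_if_not(cfg$n_blobs_per_class >= 1L, "n_blobs_per_class must be positive")
  stop_if_not(cfg$blob_fwhm > 0, "blob_fwhm must be positive")
  stop_if_not(cfg$negative_blob_fraction >= 0 && cfg$negative_blob_fraction <= 1,
              "negative_blob_fraction must lie in [0,1]")
  stop_if_not(cfg$redundant_cluster_count >= 0L, "redundant_cluster_count must be >= 0")
  stop_if_not(cfg$subject_sd >= 0, "subject_sd must be >= 0")
  stop_if_not(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  stop_if_not(cfg$noise_smoothing_fwhm >= 0, "noise_smoothing_fwhm must be >= 0")
  stop_if_not(cfg$test_fraction > 0 && cfg$test_fraction < 1,
              "test_fraction must lie in (0,1)")
  stop_if_not(cfg$test_fraction * cfg$n_subjects >= 1,
              "test_fraction * n_subjects must be >= 1")
  invisible(cfg)
}

#' Brain-like ellipsoid mask for a voxel grid
#'
#' An axis-aligned ellipsoid inscribed in the grid: a cheap stand-in for a
#' brain mask that still produces boundary effects (voxels outside carry
#' no signal and are excluded from all analyses).
#'
#' @param grid_shape integer(3).
#' @return Logical 3D array.
#' @export
ellipsoid_mask <- function(grid_shape) {
  ctr <- (grid_shape + 1) / 2
  rad <- grid_shape / 2
  cx <- ((seq_len(grid_shape[1]) - ctr[1]) / rad[1])^2
  cy <- ((seq_len(grid_shape[2]) - ctr[2]) / rad[2])^2
  cz <- ((seq_len(grid_shape[3]) - ctr[3]) / rad[3])^2
  d <- outer(outer(cx, cy, "+"), cz, "+")
  d <= 1
}

gaussian_blob <- function(grid_shape, center, fwhm) {
  sg <- fwhm_to_sigma(fwhm)
  dx <- (seq_len(grid_shape[1]) - center[1])^2
  dy <- (seq_len(grid_shape[2]) - center[2])^2
  dz <- (seq_len(grid_shape[3]) - center[3])^2
  exp(-outer(outer(dx, dy, "+"), dz, "+") / (2 * sg^2))
}

## draw an in-mask blob center at least min_dist voxels from `avoid` centers
draw_center <- function(mask, grid_shape, avoid = NULL, min_dist = 0,
                        margin = NULL, max_tries = 200L) {
  if (is.null(margin)) margin <- min(2, (min(grid_shape) - 6) / 4)
  for (i in seq_len(max_tries)) {
    ctr <- vapply(seq_len(3), function(a) {
      stats::runif(1, 1 + margin, grid_shape[a] - margin)
    }, numeric(1))
    idx <- pmin(pmax(round(ctr), 1L), grid_shape)
    if (!mask[idx[1], idx[2], idx[3]]) next
    if (!is.null(avoid) && nrow(avoid) > 0) {
      d <- sqrt(rowSums((sweep(avoid, 2, ctr))^2))
      if (any(d < min_dist)) next
    }
    return(ctr)
  }
  stop("failed to place a blob center inside the mask after ", max_tries,
       " tries; enlarge the grid or reduce blob count", call. = FALSE)
}

#' Build the planted ground-truth class patterns
#'
#' Each class pattern is a sum of isotropic Gaussian blobs at seeded
#' random in-mask centres. A configured fraction of blobs is negative
#' (regions of negative association). `redundant_cluster_count` additional
#' blobs per class duplicate the sign and amplitude of an existing blob at
#' a spatially disjoint centre, planting predictive redundancy: a decoder
#' can rely on either copy of the signal.
#'
#' @param config a [synthetic_config()].
#' @return List of `ground_truth_pattern` objects, one per class, each with
#'   fields `class_id`, `weights` (signed volume, zero outside the mask) and
#'   `support_mask` (the half-maximum footprint: |weight| above 50% of the
#'   peak, matching the FWHM parameterisation of the blobs).
#' @export
make_class_patterns <- function(config) {
  validate_synthetic_config(config)
  gs <- config$grid_shape
  mask <- ellipsoid_mask(gs)
  set.seed(derive_seed(config$seed, "patterns"))
  classes <- sprintf("state%02d", seq_len(config$n_classes))
  lapply(seq_len(config$n_classes), function(ci) {
    nb <- config$n_blobs_per_class
    n_neg <- round(config$negative_blob_fraction * nb)
    signs <- c(rep(-1, n_neg), rep(1, nb - n_neg))
    centers <- matrix(0, 0, 3)
    blobs <- vector("list", nb)
    for (b in seq_len(nb)) {
      ctr <- draw_center(mask, gs, avoid = centers,
                         min_dist = config$blob_fwhm)
      centers <- rbind(centers, ctr)
      blobs[[b]] <- list(center = ctr, sign = signs[b], amp = 1)
    }
    ## redundant clusters: copy of an existing blob at a disjoint location
    if (config$redundant_cluster_count > 0) {
      for (rdx in seq_len(config$redundant_cluster_count)) {
        src <- blobs[[1 + (rdx - 1) %% nb]]
        ctr <- draw_center(mask, gs, avoid = centers,
                           min_dist = 1.5 * config$blob_fwhm)
        centers <- rbind(centers, ctr)
        blobs[[length(blobs) + 1]] <- list(center = ctr, sign = src$sign,
                                           amp = src$amp, redundant_of = 1 + (rdx - 1) %% nb)
      }
    }
    w <- array(0, gs)
    for (b in blobs) {
      w <- w + b$sign * b$amp * gaussian_blob(gs, b$center, config$blob_fwhm)
    }
    w[!mask] <- 0
    support <- abs(w) > 0.5 * max(abs(w))
    structure(list(class_id = classes[ci], weights = w,
                   support_mask = support, blobs = blobs, mask = mask),
              class = "ground_truth_pattern")
  })
}

#' Generate a subject-split synthetic dataset
#'
#' Per subject s and class c, each trial is
#' `pattern_c * (1 + subject perturbation) + smooth noise`, masked to the
#' ellipsoid brain mask. The subject perturbation multiplies each blob's
#' amplitude by `1 + N(0, subject_sd^2)` and jitters blob centres by up to
#' one voxel; it is drawn once per subject so the two-stage GLM has a
#' genuine subject-level random effect to absorb. Subjects are split
#' subject-wise into train and test (disjoint subject sets).
#'
#' @param config a [synthetic_config()].
#' @param patterns optionally, precomputed [make_class_patterns()] output.
#' @return List with elements `train` and `test` (each a `trial_dataset`:
#'   a voxel-by-trial matrix plus metadata), and `patterns`.
#' @export
generate_dataset <- function(config, patterns = NULL) {
  validate_synthetic_config(config)
  gs <- config$grid_shape
  if (is.null(patterns)) patterns <- make_class_patterns(config)
  mask <- patterns[[1]]$mask
  n_vox <- prod(gs)
  classes <- vapply(patterns, `[[`, character(1), "class_id")
  C <- length(classes)
  S <- config$n_subjects
  Tn <- config$trials_per_class_per_subject
  n_trials <- S * C * Tn

  set.seed(derive_seed(config$seed, "trials"))
  X <- matrix(0, n_vox, n_trials)
  meta <- data.frame(trial_id = character(n_trials),
                     subject_id = character(n_trials),
                     run_id = character(n_trials),
                     label = character(n_trials),
                     stringsAsFactors = FALSE)
  t_idx <- 0L
  for (s in seq_len(S)) {
    sid <- sprintf("sub%02d", s)
    ## per-subject realisation of every class pattern
    subj_patterns <- lapply(patterns, function(p) {
      if (config$subject_sd == 0) return(p$weights)
      w <- array(0, gs)
      for (b in p$blobs) {
        amp <- b$amp * (1 + stats::rnorm(1, 0, config$subject_sd))
        jit <- stats::runif(3, -1, 1)
        w <- w + b$sign * amp * gaussian_blob(gs, b$center + jit, config$blob_fwhm)
      }
      w[!mask] <- 0
      w
    })
    for (ci in seq_len(C)) {
      base <- as.vector(subj_patterns[[ci]])
      for (tt in seq_len(Tn)) {
        t_idx <- t_idx + 1L
        if (config$noise_sd > 0) {
          eps <- array(stats::rnorm(n_vox, 0, config$noise_sd), gs)
          if (config$noise_smoothing_fwhm > 0) {
            eps <- gaussian_smooth(eps, config$noise_smoothing_fwhm)
          }
          x <- base + as.vector(eps)
        } else {
          x <- base
        }
        x[!mask] <- 0
        X[, t_idx] <- x
        meta$trial_id[t_idx] <- sprintf("%s_%s_t%03d", sid, classes[ci], tt)
        meta$subject_id[t_idx] <- sid
        meta$run_id[t_idx] <- sprintf("run%d", 1 + (tt - 1) %% config$n_runs)
        meta$label[t_idx] <- classes[ci]
      }
    }
  }

  ## subject-wise split
  set.seed(derive_seed(config$seed, "split"))
  n_test <- max(1L, round(config$test_fraction * S))
  test_subjects <- sample(sprintf("sub%02d", seq_len(S)), n_test)
  is_test <- meta$subject_id %in% test_subjects
  out <- list(train = trial_dataset(X[, !is_test, drop = FALSE], meta[!is_test, , drop = FALSE],
                                    mask, gs, classes),
              test = trial_dataset(X[, is_test, drop = FALSE], meta[is_test, , drop = FALSE],
                                   mask, gs, classes),
              patterns = patterns)
  stop_if_not(length(intersect(unique(out$train$meta$subject_id),
                               unique(out$test$meta$subject_id))) == 0L,
              "internal error: train/test subject sets overlap")
  class(out) <- "split_dataset"
  out
}

#' Container for a set of trial volumes
#'
#' Stores trials as a voxel-by-trial matrix (column = one flattened
#' volume) together with the mask, grid and per-trial metadata. This is
#' the in-memory working format of the whole pipeline; [as_trial_volumes()]
#' converts to a list of single-trial objects.
#'
#' @param x numeric matrix, `prod(grid) x n` trial values.
#' @param meta data.frame with columns trial_id, subject_id, run_id, label.
#' @param mask logical 3D array.
#' @param grid integer(3).
#' @param classes character vector of class labels (fixed order).
#' @return A `trial_dataset` object.
#' @export
trial_dataset <- function(x, meta, mask, grid, classes = sort(unique(meta$label))) {
  stop_if_not(nrow(x) == prod(grid), "value matrix does not match grid")
  stop_if_not(ncol(x) == nrow(meta), "metadata rows must match trial count")
  stop_if_not(all(is.finite(x)), "trial values must be finite")
  structure(list(x = x, meta = meta, mask = mask, grid = as.integer(grid),
                 classes = classes),
            class = "trial_dataset")
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("trial_dataset: %d trials on %s grid, %d subjects, classes: %s\n",
              ncol(x$x), paste(x$grid, collapse = "x"),
              length(unique(x$meta$subject_id)),
              paste(x$classes, collapse = ", ")))
  invisible(x)
}

n_trials <- function(ds) ncol(ds$x)

#' Subset a trial dataset
#' @param ds a `trial_dataset`.
#' @param idx trial indices (or logical vector).
#' @return A `trial_dataset` with the selected trials.
#' @export
subset_trials <- function(ds, idx) {
  trial_dataset(ds$x[, idx, drop = FALSE], ds$meta[idx, , drop = FALSE],
                ds$mask, ds$grid, ds$classes)
}

#' Convert a trial dataset to a list of single-trial volumes
#' @param ds a `trial_dataset`.
#' @return List of `trial_volume` objects (values array, mask, label, ids).
#' @export
as_trial_volumes <- function(ds) {
  lapply(seq_len(ncol(ds$x)), function(i) {
    structure(list(values = array(ds$x[, i], ds$grid), mask = ds$mask,
                   label = ds$meta$label[i], subject_id = ds$meta$subject_id[i],
                   run_id = ds$meta$run_id[i], trial_id = ds$meta$trial_id[i]),
              class = "trial_volume")
  })
}

#' Write trial volumes to NIfTI with a CSV sidecar
#'
#' Volumes are stacked into a 4D NIfTI-1 file; trial metadata (trial_id,
#' subject_id, run_id, label) goes to `<path>.csv`, and the mask to
#' `<path>_mask.nii.gz`.
#'
#' @param ds a `trial_dataset` (or a single `trial_volume`).
#' @param path output NIfTI path (e.g. "trials.nii.gz").
#' @return `path`, invisibly.
#' @export
write_volume <- function(ds, path) {
  if (inherits(ds, "trial_volume")) {
    ds <- trial_dataset(matrix(as.vector(ds$values), ncol = 1),
                        data.frame(trial_id = ds$trial_id, subject_id = ds$subject_id,
                                   run_id = ds$run_id, label = ds$label),
                        ds$mask, dim(ds$values))
  }
  arr <- array(ds$x, c(ds$grid, ncol(ds$x)))
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  utils::write.csv(ds$meta, paste0(path, ".csv"), row.names = FALSE)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(ds$mask), ds$grid)),
                     sidecar_mask_path(path))
  invisible(path)
}

sidecar_mask_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
}

#' Read trial volumes from NIfTI (+ CSV sidecar)
#'
#' @param path NIfTI path written by [write_volume()].
#' @return A `trial_dataset`.
#' @export
read_volume <- function(path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop("malformed NIfTI file '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  grid <- dim(arr)[1:3]
  n <- dim(arr)[4]
  meta_path <- paste0(path, ".csv")
  meta <- if (file.exists(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else {
    data.frame(trial_id = sprintf("t%03d", seq_len(n)),
               subject_id = "sub01", run_id = "run1", label = NA_character_)
  }
  stop_if_not(nrow(meta) == n, "sidecar table has %d rows but NIfTI holds %d volumes",
              nrow(meta), n)
  mp <- sidecar_mask_path(path)
  mask <- if (file.exists(mp)) {
    m <- as.array(RNifti::readNifti(mp))
    stop_if_not(all(dim(m)[1:3] == grid), "mask grid does not match volume grid")
    array(m > 0.5, grid)
  } else {
    array(TRUE, grid)
  }
  trial_dataset(matrix(arr, prod(grid), n), meta, mask, grid,
                classes = sort(unique(stats::na.omit(meta$label))))
}
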