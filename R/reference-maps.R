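#' Voxelwise ordinary-least-squares GLM
#'
#' Fits the same design matrix independently to every voxel (column of
#' `Y`) by OLS. Optionally evaluates a t contrast per voxel.
#'
#' @param Y observation-by-voxel matrix (rows = maps/trials).
#' @param X design matrix with named columns.
#' @param contrast optional numeric contrast vector (length = ncol(X)).
#' @return List with `coef` (p x V), `sigma2` (residual variance per
#'   voxel), `df` residual degrees of freedom, and — when a contrast is
#'   given — `effect`, `t` and `se` per voxel. Voxels with (numerically)
#'   zero residual variance are flagged in `degenerate`.
#' @export
fit_voxelwise_glm <- function(Y, X, contrast = NULL) {
  stop_if_not(nrow(Y) == nrow(X), "Y and design row counts differ")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep)]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  stop_if_not(df > 0, "no residual degrees of freedom")
  sigma2 <- colSums(res^2) / df
  out <- list(coef = beta, sigma2 = sigma2, df = df,
              degenerate = sigma2 < 1e-12 * max(mean(colSums(Y^2)), 1e-300))
  if (!is.null(contrast)) {
    stop_if_not(length(contrast) == ncol(X), "contrast length mismatch")
    XtXinv <- chol2inv(qr.R(qrX)[seq_len(ncol(X)), , drop = FALSE])
    cvar <- drop(t(contrast) %*% XtXinv %*% contrast)
    eff <- drop(crossprod(contrast, beta))
    se <- sqrt(cvar * sigma2)
    tval <- eff / se
    tval[out$degenerate & eff == 0] <- 0
    out$effect <- eff
    out$t <- tval
    out$se <- se
    out$contrast <- contrast
  }
  out
}

## class-indicator design (+ optional factor nuisances, reference coded,
## and numeric nuisances, centred)
build_design <- function(labels, classes, nuisance = NULL) {
  X <- sapply(classes, function(cl) as.numeric(labels == cl))
  colnames(X) <- paste0("class_", classes)
  kinds <- rep("interest", length(classes))
  if (!is.null(nuisance)) {
    for (nm in names(nuisance)) {
      v <- nuisance[[nm]]
      if (is.numeric(v)) {
        if (stats::sd(v) < 1e-12) next  # constant regressor: no information
        X <- cbind(X, scale(v, scale = FALSE))
        colnames(X)[ncol(X)] <- nm
        kinds <- c(kinds, "nuisance")
      } else {
        lev <- sort(unique(v))
        if (length(lev) < 2L) next   # constant factor carries no information
        for (lv in lev[-1L]) {       # reference-cell coding keeps full rank
          X <- cbind(X, as.numeric(v == lv))
          colnames(X)[ncol(X)] <- paste0(nm, "_", lv)
          kinds <- c(kinds, "nuisance")
        }
      }
    }
  }
  attr(X, "kinds") <- kinds
  X
}

class_contrast <- function(classes, cl, n_extra) {
  w <- rep(-1 / (length(classes) - 1), length(classes))
  w[classes == cl] <- 1
  c(w, rep(0, n_extra))
}

#' Subject-level one-vs-rest contrast maps
#'
#' Fits the subject's trials with a binary indicator per mental state
#' (plus a run-indicator nuisance when several runs are present) and
#' contrasts each state against the mean of all other states.
#'
#' @param ds `trial_dataset` holding the trials of one subject.
#' @param extra_nuisance optional named list of additional nuisance
#'   regressors (numeric, or factors to be reference-coded).
#' @return A `contrast_maps` object: list with `stat` (voxel x class t
#'   values), `effect`, `df`, `classes`, `grid`, `mask`.
#' @export
subject_contrast <- function(ds, extra_nuisance = NULL) {
  classes <- ds$classes
  present <- unique(ds$meta$label)
  stop_if_not(length(present) >= 2L,
              "subject has a single class; contrasts are undefined")
  nuis <- list()
  if (length(unique(ds$meta$run_id)) > 1L) nuis$run <- ds$meta$run_id
  if (!is.null(extra_nuisance)) nuis <- c(nuis, extra_nuisance)
  X <- build_design(ds$meta$label, classes, if (length(nuis)) nuis else NULL)
  n_extra <- ncol(X) - length(classes)
  Y <- t(ds$x)
  stat <- effect <- matrix(0, nrow(ds$x), length(classes))
  df <- NA_real_
  for (ci in seq_along(classes)) {
    ctr <- class_contrast(classes, classes[ci], n_extra)
    fit <- fit_voxelwise_glm(Y, X, contrast = ctr)
    stat[, ci] <- fit$t
    effect[, ci] <- fit$effect
    df <- fit$df
  }
  colnames(stat) <- colnames(effect) <- classes
  structure(list(stat = stat, effect = effect, df = df, classes = classes,
                 grid = ds$grid, mask = ds$mask, level = "subject"),
            class = "contrast_maps")
}

#' Group-level (random effects) contrast maps
#'
#' Smooths each subject-level map with a Gaussian kernel, then fits a
#' paired design across subjects: one indicator per class (interest) and
#' one indicator per subject (nuisance, reference coded). The per-class
#' statistic is the class indicator tested against zero, i.e. a paired
#' t-test over the subject maps, z-converted via the t distribution.
#'
#' @param subject_maps list of per-subject `contrast_maps` (effect maps
#'   are aggregated, as in a standard two-stage summary-statistics
#'   analysis).
#' @param smoothing_fwhm smoothing kernel FWHM in voxels (0 = identity).
#' @param use_effect aggregate effect maps (default) or t maps.
#' @return A `contrast_maps` object with `stat` holding z values.
#' @export
group_contrast <- function(subject_maps, smoothing_fwhm = 1.5,
                           use_effect = TRUE) {
  stop_if_not(length(subject_maps) >= 3L, "need at least 3 subjects")
  classes <- subject_maps[[1]]$classes
  grid <- subject_maps[[1]]$grid
  S <- length(subject_maps)
  maps <- list()
  lab <- chr <- character(0)
  for (s in seq_len(S)) {
    m <- subject_maps[[s]]
    src <- if (use_effect) m$effect else m$stat
    for (ci in seq_along(classes)) {
      v <- array(src[, ci], grid)
      if (smoothing_fwhm > 0) v <- gaussian_smooth(v, smoothing_fwhm)
      maps[[length(maps) + 1L]] <- as.vector(v)
      lab <- c(lab, classes[ci])
      chr <- c(chr, sprintf("s%03d", s))
    }
  }
  Y <- do.call(rbind, maps)
  X <- build_design(lab, classes, list(subject = chr))
  n_extra <- ncol(X) - length(classes)
  stat <- effect <- matrix(0, ncol(Y), length(classes))
  df <- NA_real_
  for (ci in seq_along(classes)) {
    ctr <- c(as.numeric(classes == classes[ci]), rep(0, n_extra))
    fit <- fit_voxelwise_glm(Y, X, contrast = ctr)
    ## z-conversion through the t CDF at the fitted df (log-scale for
    ## numerical stability in the tails)
    z <- stats::qnorm(stats::pt(fit$t, fit$df, log.p = TRUE), log.p = TRUE)
    z[fit$degenerate] <- 0
    stat[, ci] <- z
    effect[, ci] <- fit$effect
    df <- fit$df
  }
  colnames(stat) <- colnames(effect) <- classes
  structure(list(stat = stat, effect = effect, df = df, classes = classes,
                 grid = grid, mask = subject_maps[[1]]$mask, level = "group"),
            class = "contrast_maps")
}

#' Two-stage aggregation of trial-level attribution maps
#'
#' Stage one fits, per subject, a GLM over all of the subject's
#' attribution maps (trials x model runs) with class indicators of
#' interest and three nuisance terms: the fMRI run indicator (when
#' present), one indicator per model training run, and the per-map total
#' relevance (attribution sums vary with decoding certainty). Stage two
#' equals [group_contrast()].
#'
#' @param attribution_sets list over model runs of `attribution_set`
#'   objects (same trials in each, as produced by [attribute_trials()] on
#'   the same dataset with the ensemble's models).
#' @param smoothing_fwhm group-stage smoothing FWHM (voxels).
#' @return List with `subject_maps` and `group` (a `contrast_maps`).
#' @export
aggregate_attributions <- function(attribution_sets, smoothing_fwhm = 1.5) {
  stop_if_not(length(attribution_sets) >= 1L, "no attribution sets given")
  meta0 <- attribution_sets[[1]]$meta
  for (a in attribution_sets) {
    stop_if_not(nrow(a$meta) == nrow(meta0) &&
                  all(a$meta$trial_id == meta0$trial_id),
                "all model runs must attribute the same trials")
  }
  grid <- attribution_sets[[1]]$grid
  mask <- attribution_sets[[1]]$mask
  classes <- sort(unique(meta0$label))
  subjects <- unique(meta0$subject_id)
  subject_maps <- lapply(subjects, function(sid) {
    rows <- which(meta0$subject_id == sid)
    R <- do.call(cbind, lapply(attribution_sets, function(a) {
      a$relevance[, rows, drop = FALSE]
    }))
    n_runs <- length(attribution_sets)
    meta <- meta0[rep(rows, times = n_runs), , drop = FALSE]
    run_of_model <- rep(sprintf("m%02d", seq_len(n_runs)), each = length(rows))
    rsum <- colSums(R)
    sds <- trial_dataset(R, meta, mask, grid, classes)
    subject_contrast(sds, extra_nuisance = list(model_run = run_of_model,
                                                relevance_sum = rsum))
  })
  group <- if (length(subject_maps) >= 3L) {
    group_contrast(subject_maps, smoothing_fwhm)
  } else {
    ## too few subjects for a paired random-effects stage: the group map
    ## degrades to the smoothed mean of the subject-level effect maps
    eff <- Reduce(`+`, lapply(subject_maps, function(m) {
      apply(m$effect, 2, function(v) {
        as.vector(gaussian_smooth(array(v, grid), smoothing_fwhm))
      })
    })) / length(subject_maps)
    structure(list(stat = eff, effect = eff, df = NA_real_, classes = classes,
                   grid = grid, mask = mask, level = "group-mean"),
              class = "contrast_maps")
  }
  list(subject_maps = subject_maps, group = group)
}

#' Ground-truth reference maps from planted patterns
#'
#' Passes the generator's planted class patterns through as reference
#' volumes: the synthetic stand-in for an external meta-analysis map.
#'
#' @param patterns list of `ground_truth_pattern` ([make_class_patterns()]).
#' @return Voxel-by-class matrix of reference weights.
#' @export
ground_truth_reference <- function(patterns) {
  out <- sapply(patterns, function(p) as.vector(p$weights))
  colnames(out) <- vapply(patterns, `[[`, character(1), "class_id")
  out
}
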