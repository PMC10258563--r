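#' Settings for the k-nearest-neighbour mutual-information estimator
#'
#' @param n_neighbors number of nearest neighbours `k` (default 3).
#' @param tie_noise_scale scale of the deterministic (seeded) jitter added
#'   to break ties in the rank statistics.
#' @param voxel_subsample optional cap on the number of points used (maps
#'   are subsampled deterministically when longer).
#' @param seed seed for jitter and subsampling.
#' @return An `mi_spec` object.
#' @export
mi_spec <- function(n_neighbors = 3L, tie_noise_scale = 1e-10,
                    voxel_subsample = NULL, seed = 1L) {
  stop_if_not(n_neighbors >= 1L, "n_neighbors must be >= 1")
  structure(list(n_neighbors = as.integer(n_neighbors),
                 tie_noise_scale = tie_noise_scale,
                 voxel_subsample = voxel_subsample, seed = as.integer(seed)),
            class = "mi_spec")
}

#' Kraskov-Stoegbauer-Grassberger mutual information estimate
#'
#' Non-parametric MI estimator for continuous variables based on k-nearest
#' neighbour distances (first KSG variant):
#' `I = psi(k) + psi(N) - mean(psi(n_x + 1) + psi(n_y + 1))`,
#' with the neighbourhood defined by the Chebyshev metric in the joint
#' space and `n_x`, `n_y` the marginal neighbour counts within the joint
#' kNN radius. Values are in nats.
#'
#' @param x,y numeric vectors of equal length (>= k+2).
#' @param spec an [mi_spec()].
#' @return The clipped (non-negative) MI estimate, with the raw estimate
#'   in attribute `"raw"`.
#' @export
ksg_mutual_information <- function(x, y, spec = mi_spec()) {
  stop_if_not(length(x) == length(y), "x and y must have equal length")
  k <- spec$n_neighbors
  stop_if_not(length(x) >= k + 2L, "need at least k+2 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input vector: mutual information is degenerate, returning 0")
    out <- 0
    attr(out, "raw") <- 0
    return(out)
  }
  set.seed(derive_seed(spec$seed, "ksg"))
  if (!is.null(spec$voxel_subsample) && length(x) > spec$voxel_subsample) {
    ii <- sample.int(length(x), spec$voxel_subsample)
    x <- x[ii]; y <- y[ii]
  }
  ## tie-breaking jitter, scaled to the data
  x <- x + stats::rnorm(length(x), 0, spec$tie_noise_scale * max(stats::sd(x), 1e-300))
  y <- y + stats::rnorm(length(y), 0, spec$tie_noise_scale * max(stats::sd(y), 1e-300))
  N <- length(x)
  ## kth-NN Chebyshev radius in the joint space (compiled exact scan)
  eps <- ksg_radius_cpp(x, y, k)
  ## strict marginal counts within eps via sorted lookups
  count_within <- function(v, eps) {
    sv <- sort.int(v)
    hi <- findInterval(v + eps, sv, left.open = TRUE)   # first variant: strict
    lo <- findInterval(v - eps, sv)
    hi - lo - 1L                                        # exclude the point itself
  }
  nx <- count_within(x, eps)
  ny <- count_within(y, eps)
  raw <- digamma(k) + digamma(N) -
    mean(digamma(nx + 1) + digamma(ny + 1))
  out <- max(raw, 0)
  attr(out, "raw") <- raw
  out
}

#' Alignment of an attribution map with a reference map
#'
#' Restricts both maps to the mask and reports their KSG mutual
#' information (primary metric) and Pearson correlation (secondary).
#'
#' @param attr_map numeric volume/vector (attribution map).
#' @param ref_map numeric volume/vector (reference map) on the same grid.
#' @param mask logical volume/vector.
#' @param spec an [mi_spec()].
#' @return List with `mi` and `pearson`.
#' @export
alignment_score <- function(attr_map, ref_map, mask, spec = mi_spec()) {
  a <- as.vector(attr_map); r <- as.vector(ref_map); m <- as.vector(mask)
  stop_if_not(length(a) == length(r) && length(a) == length(m),
              "maps and mask must share the grid")
  a <- a[m]; r <- r[m]
  list(mi = ksg_mutual_information(a, r, spec),
       pearson = if (stats::sd(a) > 0 && stats::sd(r) > 0) stats::cor(a, r) else NA_real_)
}

#' Occlude the highest-relevance voxels of a trial
#'
#' Sets to zero the `ceiling(rate * n_mask)` in-mask voxels with the
#' highest relevance (signed descending order; ties broken by voxel
#' index).
#'
#' @param x trial values (vector/volume) or voxel-by-trial matrix.
#' @param relevance matching relevance values.
#' @param rate occlusion rate in [0, 0.5].
#' @param mask logical vector/volume; occlusion counts are relative to
#'   the in-mask voxel count.
#' @param absolute rank by |relevance| instead of signed relevance.
#' @return Occluded copy of `x`.
#' @export
occlude <- function(x, relevance, rate, mask = NULL, absolute = FALSE) {
  stop_if_not(rate >= 0 && rate <= 0.5, "rate must lie in [0, 0.5]")
  xm <- if (is.matrix(x)) x else matrix(as.vector(x), ncol = 1L)
  rm_ <- if (is.matrix(relevance)) relevance else matrix(as.vector(relevance), ncol = 1L)
  stop_if_not(all(dim(xm) == dim(rm_)), "x and relevance dimensions differ")
  mv <- if (is.null(mask)) rep(TRUE, nrow(xm)) else as.vector(mask)
  n_mask <- sum(mv)
  n_occ <- ceiling(rate * n_mask)
  if (n_occ == 0L) return(x)
  widx <- which(mv)
  for (j in seq_len(ncol(xm))) {
    r <- rm_[widx, j]
    if (absolute) r <- abs(r)
    ord <- order(r, -widx, decreasing = TRUE)   # ties: lower voxel index first
    xm[widx[ord[seq_len(n_occ)]], j] <- 0
  }
  if (is.matrix(x)) xm
  else if (is.array(x)) array(xm[, 1L], dim(x))
  else xm[, 1L]
}

#' Occlusion-faithfulness curve of attribution methods
#'
#' For each method, evaluates the model's decoding accuracy after
#' occluding the top `rate` fraction of in-mask voxels per trial (by that
#' method's relevance) over a grid of rates, and records the first rate
#' at which accuracy drops to chance (1/C). Accuracies below chance are
#' retained; a curve that never reaches chance is censored at the largest
#' rate.
#'
#' @param model trained `decoder_model`.
#' @param ds `trial_dataset` of evaluation trials.
#' @param attributions named list of `attribution_set` objects (or one).
#' @param rate_grid occlusion rates (strictly increasing, starting at 0).
#' @return A data.frame (method, rate, accuracy) with per-method
#'   `critical_rate` and `censored` in attribute `"critical"`.
#' @export
faithfulness_curve <- function(model, ds, attributions,
                               rate_grid = seq(0, 0.5, by = 0.025)) {
  stop_if_not(all(diff(rate_grid) > 0), "rate_grid must be strictly increasing")
  if (inherits(attributions, "attribution_set")) {
    attributions <- stats::setNames(list(attributions), attributions$method)
  }
  chance <- 1 / model$n_classes
  rows <- list()
  crit <- data.frame(method = character(0), critical_rate = numeric(0),
                     censored = logical(0))
  for (nm in names(attributions)) {
    at <- attributions[[nm]]
    stop_if_not(ncol(at$relevance) == ncol(ds$x),
                "attribution set does not cover all trials")
    accs <- numeric(length(rate_grid))
    for (ri in seq_along(rate_grid)) {
      Xo <- occlude(ds$x, at$relevance, rate_grid[ri], mask = ds$mask)
      dso <- trial_dataset(Xo, ds$meta, ds$mask, ds$grid, ds$classes)
      accs[ri] <- evaluate(model, dso)$accuracy
    }
    rows[[nm]] <- data.frame(method = nm, rate = rate_grid, accuracy = accs)
    hit <- which(accs <= chance + 1e-12)
    crit <- rbind(crit, data.frame(method = nm,
                                   critical_rate = if (length(hit)) rate_grid[min(hit)] else max(rate_grid),
                                   censored = length(hit) == 0L))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "critical") <- crit
  attr(out, "chance") <- chance
  out
}

## mean per-trial MI between two attribution sets
mean_attribution_mi <- function(set_a, set_b, mask, spec = mi_spec()) {
  n <- ncol(set_a$relevance)
  mv <- as.vector(mask)
  vals <- vapply(seq_len(n), function(i) {
    a <- set_a$relevance[mv, i]
    b <- set_b$relevance[mv, i]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    as.numeric(ksg_mutual_information(a, b, spec))
  }, numeric(1))
  mean(vals)
}

#' Data randomization sanity check
#'
#' Trains a copy of the model configuration on label-shuffled training
#' data for a fixed, long training period (no early stopping) so that the
#' model memorizes the random label assignment, then compares each
#' method's attributions for the original vs. the shuffled-label model by
#' per-trial mutual information (averaged over trials). Lower MI means
#' the method is more sensitive to what was learned from the data. The
#' memorization regime is asserted: training accuracy must exceed
#' `memorize_threshold` while the validation accuracy stays within
#' `chance_band` of chance.
#'
#' @param model the original trained model.
#' @param train_set training `trial_dataset` (labels are shuffled on a
#'   copy).
#' @param test_set trials to attribute.
#' @param methods attribution method names.
#' @param n_epochs_memorize fixed number of training epochs.
#' @param max_memorize_trials trials in the memorization set (random
#'   labels over many trials are not memorizable by the small decoder
#'   family; a class-stratified subset keeps the regime attainable). The
#'   remaining shuffled-label trials form the validation set.
#' @param params an [attribution_params()].
#' @param spec an [mi_spec()].
#' @param seed seed for shuffling and training.
#' @param memorize_threshold,chance_band validity guards.
#' @param shuffled_model optionally, a previously fitted shuffled-label
#'   model (from attribute `"model"` of an earlier call) to compare
#'   against without re-training.
#' @param sets_a,self_mi precomputed attribution sets (named list, one
#'   per method) and self-MI ceiling for the original model, reused
#'   across checks.
#' @param sets_b precomputed attribution sets of the comparison model
#'   (returned in attribute `"sets_b"` of an earlier call).
#' @return data.frame (method, mi, self_mi) plus the shuffled-label model
#'   in attribute `"model"` and its accuracies in attribute `"guards"`.
#' @export
data_randomization_check <- function(model, train_set, test_set, methods,
                                     n_epochs_memorize = 300L,
                                     max_memorize_trials = 32L,
                                     params = attribution_params(),
                                     spec = mi_spec(), seed = 1L,
                                     memorize_threshold = 0.9,
                                     chance_band = 0.1,
                                     shuffled_model = NULL,
                                     sets_a = NULL, self_mi = NULL,
                                     sets_b = NULL) {
  chance <- 1 / model$n_classes
  if (is.null(shuffled_model)) {
    set.seed(derive_seed(seed, "shuffle"))
    shuffled <- train_set
    shuffled$meta$label <- sample(shuffled$meta$label)
    n <- ncol(shuffled$x)
    per <- max(2L, floor(max_memorize_trials / length(unique(shuffled$meta$label))))
    fit_idx <- sort(unlist(lapply(split(seq_len(n), shuffled$meta$label),
                                  function(ii) sample(ii, min(per, length(ii))))))
    fit_set <- subset_trials(shuffled, fit_idx)
    val_set <- subset_trials(shuffled, setdiff(seq_len(n), fit_idx))
    rnd <- build_model(model$config, model$grid, model$n_classes)
    rnd <- train(rnd, fit_set, val_set = val_set, max_epochs = n_epochs_memorize,
                 min_epochs = n_epochs_memorize, seed = derive_seed(seed, "memorize"),
                 early_stopping = FALSE, restore_best = FALSE)
    tr_acc <- evaluate(rnd, fit_set)$accuracy
    va_acc <- evaluate(rnd, val_set)$accuracy
    if (tr_acc < memorize_threshold) {
      stop(sprintf(paste("label-shuffled model failed to memorize (training accuracy %.2f);",
                         "raise n_epochs_memorize or model capacity"), tr_acc),
           call. = FALSE)
    }
    if (abs(va_acc - chance) > chance_band) {
      warning(sprintf(paste("shuffled-label validation accuracy %.2f deviates from",
                            "chance %.2f by more than %.2f"), va_acc, chance, chance_band))
    }
    rnd$memorize_guards <- c(train_acc = tr_acc, val_acc = va_acc, chance = chance)
  } else {
    rnd <- shuffled_model
  }
  res <- randomization_mi(model, rnd, test_set, methods, params, spec,
                          sets_a = sets_a, self_mi = self_mi,
                          sets_b = sets_b)
  attr(res, "model") <- rnd
  attr(res, "guards") <- rnd$memorize_guards
  res
}

#' Model randomization sanity check
#'
#' Compares each method's attributions for the trained model against
#' those for a freshly initialised (untrained) model of the same
#' architecture, by mean per-trial mutual information. The
#' model-independent control method "input" sits at the self-similarity
#' ceiling by construction.
#'
#' @inheritParams data_randomization_check
#' @return data.frame (method, mi, self_mi).
#' @export
model_randomization_check <- function(model, test_set, methods,
                                      params = attribution_params(),
                                      spec = mi_spec(), seed = 1L,
                                      sets_a = NULL, self_mi = NULL) {
  cfg <- model$config
  cfg$seed <- derive_seed(seed, "randweights")
  rnd <- build_model(cfg, model$grid, model$n_classes)
  rnd$classes <- model$classes
  rnd$trained <- TRUE   # architecture-identical, random-weight variant
  randomization_mi(model, rnd, test_set, methods, params, spec,
                   sets_a = sets_a, self_mi = self_mi)
}

randomization_mi <- function(model_a, model_b, test_set, methods, params, spec,
                             sets_a = NULL, self_mi = NULL, sets_b = NULL) {
  if (is.null(sets_a)) {
    sets_a <- lapply(stats::setNames(methods, methods), function(mm) {
      attribute_trials(model_a, test_set, mm, params, reference_data = test_set)
    })
  }
  if (is.null(self_mi)) {
    self_mi <- vapply(methods, function(mm) {
      mean_attribution_mi(sets_a[[mm]], sets_a[[mm]], test_set$mask, spec)
    }, numeric(1))
  }
  if (is.null(sets_b)) {
    sets_b <- lapply(stats::setNames(methods, methods), function(mm) {
      attribute_trials(model_b, test_set, mm, params, reference_data = test_set)
    })
  }
  out <- lapply(methods, function(mm) {
    data.frame(method = mm,
               mi = mean_attribution_mi(sets_a[[mm]], sets_b[[mm]],
                                        test_set$mask, spec),
               self_mi = unname(self_mi[mm]))
  })
  res <- do.call(rbind, out)
  attr(res, "sets_b") <- sets_b
  res
}

#' Compare attribution methods against a baseline method
#'
#' Fits the indicator-coded linear model `score ~ method` with the given
#' baseline as the unmodelled reference level, and reports for every
#' other method the coefficient (mean difference from the baseline) with
#' a 94% bias-corrected stratified-bootstrap percentile interval. A
#' method is flagged `meaningful` when its interval excludes zero.
#'
#' @param scores data.frame with columns `method` and `score` (one row
#'   per observation: subject, model run, ...).
#' @param baseline_method reference method name.
#' @param level interval mass (default 0.94).
#' @param n_boot bootstrap replicates.
#' @param seed bootstrap seed.
#' @return A `comparison_result` data.frame: method, coefficient, lower,
#'   upper, meaningful.
#' @export
compare_methods <- function(scores, baseline_method, level = 0.94,
                            n_boot = 4000L, seed = 1L) {
  stop_if_not(all(c("method", "score") %in% names(scores)),
              "scores needs columns 'method' and 'score'")
  methods <- unique(scores$method)
  stop_if_not(baseline_method %in% methods, "baseline method not in scores")
  stop_if_not(length(methods) >= 2L, "need at least 2 methods")
  counts <- table(scores$method)
  stop_if_not(all(counts >= 3L), "need at least 3 observations per method")
  for (mm in methods) {
    if (stats::sd(scores$score[scores$method == mm]) < 1e-12) {
      warning("method '", mm, "' has (near-)identical scores: degenerate variance")
    }
  }
  set.seed(derive_seed(seed, "boot"))
  base <- scores$score[scores$method == baseline_method]
  alpha <- (1 - level) / 2
  rows <- lapply(setdiff(methods, baseline_method), function(mm) {
    v <- scores$score[scores$method == mm]
    est <- mean(v) - mean(base)
    bs <- vapply(seq_len(n_boot), function(i) {
      mean(v[sample.int(length(v), replace = TRUE)]) -
        mean(base[sample.int(length(base), replace = TRUE)])
    }, numeric(1))
    ## bias-corrected percentile interval
    z0 <- stats::qnorm(pmin(pmax(mean(bs < est), 1 / n_boot), 1 - 1 / n_boot))
    lo_p <- stats::pnorm(2 * z0 + stats::qnorm(alpha))
    hi_p <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha))
    ci <- stats::quantile(bs, c(lo_p, hi_p), names = FALSE, type = 6)
    data.frame(method = mm, coefficient = est, lower = ci[1], upper = ci[2],
               meaningful = ci[1] > 0 | ci[2] < 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline") <- baseline_method
  attr(out, "level") <- level
  class(out) <- c("comparison_result", class(out))
  out
}
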