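#' Parameters shared by the attribution methods
#'
#' Defaults follow the benchmark constants: SmoothGrad draws `K = 50`
#' noise samples with `sigma = 1`; integrated gradients uses an all-zero
#' baseline and the dataset-mean baseline, averaging the two attributions
#' with weights 0.5/0.5; DeepLift SHAP draws `K = 50` random reference
#' samples from the data; the LRP composite applies LRP-0 at the dense
#' output layer and LRP-gamma with `gamma = 0.25` at convolution layers.
#'
#' @param smoothgrad_K number of noise samples.
#' @param smoothgrad_sigma noise standard deviation.
#' @param smoothgrad_absolute average absolute gradients (TRUE, the
#'   default reading) or signed gradients.
#' @param ig_steps midpoint Riemann steps for the path integral.
#' @param ig_baselines baselines to average: subset of
#'   c("zero", "dataset_mean").
#' @param deeplift_reference reference input for DeepLift: "zero",
#'   "dataset_mean", or a numeric volume/vector on the input grid.
#' @param dlshap_K number of random reference samples for DeepLift SHAP.
#' @param lrp_gamma LRP-gamma positive-weight emphasis.
#' @param lrp_eps stabiliser added (sign-matched) to LRP denominators.
#' @param deeplift_tol threshold on |delta pre-activation| below which the
#'   rescale multiplier falls back to the gradient.
#' @param target_output "logit" (default; pre-softmax score of the target
#'   class) or "probability".
#' @param guided_literal if TRUE, guided backpropagation masks only by the
#'   sign of the backpropagated signal (the literal reading); default
#'   FALSE additionally masks by the forward pre-activation sign
#'   (canonical behaviour).
#' @param seed seed for the stochastic methods (SmoothGrad, DeepLift SHAP).
#' @return An `attribution_params` object.
#' @export
attribution_params <- function(smoothgrad_K = 50L, smoothgrad_sigma = 1,
                               smoothgrad_absolute = TRUE,
                               ig_steps = 64L,
                               ig_baselines = c("zero", "dataset_mean"),
                               deeplift_reference = "zero",
                               dlshap_K = 50L, lrp_gamma = 0.25,
                               lrp_eps = 1e-6, deeplift_tol = 1e-7,
                               target_output = c("logit", "probability"),
                               guided_literal = FALSE, seed = 1L) {
  stop_if_not(smoothgrad_K >= 1L, "smoothgrad_K must be >= 1")
  stop_if_not(smoothgrad_sigma > 0, "smoothgrad_sigma must be > 0")
  stop_if_not(ig_steps >= 2L, "ig_steps must be >= 2")
  stop_if_not(dlshap_K >= 1L, "dlshap_K must be >= 1")
  stop_if_not(lrp_gamma >= 0, "lrp_gamma must be >= 0")
  structure(list(smoothgrad_K = as.integer(smoothgrad_K),
                 smoothgrad_sigma = smoothgrad_sigma,
                 smoothgrad_absolute = isTRUE(smoothgrad_absolute),
                 ig_steps = as.integer(ig_steps),
                 ig_baselines = match.arg(ig_baselines, several.ok = TRUE),
                 deeplift_reference = deeplift_reference,
                 dlshap_K = as.integer(dlshap_K),
                 lrp_gamma = lrp_gamma, lrp_eps = lrp_eps,
                 deeplift_tol = deeplift_tol,
                 target_output = match.arg(target_output),
                 guided_literal = isTRUE(guided_literal),
                 seed = as.integer(seed)),
            class = "attribution_params")
}

#' Names of the available attribution methods
#'
#' The registry covers the nine benchmark methods plus the deliberately
#' model-independent control "input" (relevance = the input itself), used
#' by the randomization sanity checks.
#'
#' @return Character vector of method names.
#' @export
attribution_methods <- function() {
  c("gradient", "smoothgrad", "input_x_gradient", "guided_backprop",
    "guided_gradcam", "integrated_gradients", "deeplift", "deeplift_shap",
    "lrp", "input")
}

## method families as used in the benchmark's headline comparison
#' Attribution method families
#' @return Named list with `sensitivity` and `reference` (reference-based
#'   and backward-decomposition) method name vectors.
#' @export
attribution_families <- function() {
  list(sensitivity = c("gradient", "smoothgrad", "guided_backprop", "guided_gradcam"),
       reference = c("input_x_gradient", "integrated_gradients", "deeplift",
                     "deeplift_shap", "lrp"))
}

## resolve a reference spec to an n_vox vector
resolve_reference <- function(ref, n_vox, reference_data = NULL) {
  if (is.character(ref)) {
    switch(ref,
           zero = numeric(n_vox),
           dataset_mean = {
             stop_if_not(!is.null(reference_data),
                         "dataset_mean baseline needs reference_data")
             rowMeans(reference_data)
           },
           stop("unknown reference '", ref, "'"))
  } else {
    v <- as.vector(if (is.array(ref)) ref else ref)
    stop_if_not(length(v) == n_vox, "reference length does not match grid")
    v
  }
}

check_finite_relevance <- function(R, method) {
  if (!all(is.finite(R))) {
    stop("non-finite relevance produced by ", method,
         " (check the model's input-layer scale)", call. = FALSE)
  }
  R
}

#' Compute attribution maps for a batch of trials
#'
#' The workhorse behind [attribute_trials()]: operates on a voxel-by-trial
#' matrix and returns a voxel-by-trial relevance matrix. All methods
#' explain `f(x)` = the model output for the target class of each trial
#' (pre-softmax logit by default), with batch-norm folded into the
#' convolution weights and dropout disabled.
#'
#' Sign conventions: gradient, smoothgrad, guided_backprop and
#' guided_gradcam return non-negative maps; input_x_gradient,
#' integrated_gradients, deeplift, deeplift_shap and lrp return signed
#' maps.
#'
#' @param model a trained `decoder_model`.
#' @param X numeric matrix, `n_vox x B`.
#' @param targets integer vector of target class indices (length B).
#' @param method one of [attribution_methods()].
#' @param params an [attribution_params()].
#' @param reference_data optional voxel-by-trial matrix supplying the
#'   dataset-mean baseline and DeepLift SHAP reference samples (usually
#'   the training data).
#' @return `n_vox x B` relevance matrix.
#' @export
attribute_batch <- function(model, X, targets, method,
                            params = attribution_params(),
                            reference_data = NULL) {
  method <- match.arg(method, attribution_methods())
  fmodel <- if (isTRUE(model$folded)) model else fold_bn(model)
  R <- switch(method,
              gradient = attr_gradient(fmodel, X, targets, params),
              smoothgrad = attr_smoothgrad(fmodel, X, targets, params),
              input_x_gradient = attr_ixg(fmodel, X, targets, params),
              guided_backprop = attr_guided(fmodel, X, targets, params),
              guided_gradcam = attr_guided_gradcam(fmodel, X, targets, params),
              integrated_gradients = attr_ig(fmodel, X, targets, params, reference_data),
              deeplift = attr_deeplift(fmodel, X, targets, params, reference_data),
              deeplift_shap = attr_dlshap(fmodel, X, targets, params, reference_data),
              lrp = attr_lrp(fmodel, X, targets, params),
              input = X)
  check_finite_relevance(R, method)
}

#' Attribute the decoding decisions of a set of trials
#'
#' @param model a trained `decoder_model`.
#' @param ds a `trial_dataset`; each trial is attributed for its actual
#'   class label (the decoded mental state being explained).
#' @param method one of [attribution_methods()], or a character vector of
#'   methods.
#' @param params an [attribution_params()].
#' @param reference_data optional `trial_dataset` for baselines/references
#'   (defaults to `ds`).
#' @param batch trials per internal batch.
#' @return For one method, an `attribution_set`: list with `relevance`
#'   (`n_vox x n_trials` matrix), `method`, `meta`, and `relevance_sum`
#'   per trial. For several methods, a named list of such sets.
#' @export
attribute_trials <- function(model, ds, method = "gradient",
                             params = attribution_params(),
                             reference_data = NULL, batch = 64L) {
  if (length(method) > 1L) {
    out <- lapply(method, function(m) {
      attribute_trials(model, ds, m, params, reference_data, batch)
    })
    names(out) <- method
    return(out)
  }
  refX <- if (!is.null(reference_data)) reference_data$x else ds$x
  targets <- match(ds$meta$label, model$classes)
  stop_if_not(!anyNA(targets), "dataset labels unknown to the model")
  n <- ncol(ds$x)
  R <- matrix(0, nrow(ds$x), n)
  fmodel <- fold_bn(model)
  for (i0 in seq(1L, n, by = batch)) {
    ii <- i0:min(i0 + batch - 1L, n)
    R[, ii] <- attribute_batch(fmodel, ds$x[, ii, drop = FALSE], targets[ii],
                               method, params, reference_data = refX)
  }
  mask_vec <- as.vector(ds$mask)
  R[!mask_vec, ] <- 0
  structure(list(relevance = R, method = method, meta = ds$meta,
                 grid = ds$grid, mask = ds$mask,
                 relevance_sum = colSums(R)),
            class = "attribution_set")
}

#' @export
print.attribution_set <- function(x, ...) {
  cat(sprintf("attribution_set: %s, %d trials on %s grid\n", x$method,
              ncol(x$relevance), paste(x$grid, collapse = "x")))
  invisible(x)
}

## ---- method implementations (all on a folded, inference-mode model) ----

## plain input gradient of the target output
input_gradient <- function(fmodel, X, targets, params, relu_rule = "plain") {
  fw <- nn_forward_eval(fmodel, X)
  dOut <- target_seed(fw$probs, targets, params$target_output)
  nn_backward_input(fmodel, fw, dOut, relu_rule = relu_rule)$dX
}

attr_gradient <- function(fmodel, X, targets, params) {
  abs(input_gradient(fmodel, X, targets, params))
}

attr_ixg <- function(fmodel, X, targets, params) {
  input_gradient(fmodel, X, targets, params) * X
}

attr_smoothgrad <- function(fmodel, X, targets, params) {
  set.seed(derive_seed(params$seed, "smoothgrad"))
  n_vox <- nrow(X); B <- ncol(X)
  acc <- matrix(0, n_vox, B)
  K <- params$smoothgrad_K
  ## batch the K noise draws per trial: one pass per trial over a K-column
  ## noisy batch keeps everything in matrix ops
  for (b in seq_len(B)) {
    Xn <- X[, b] + matrix(stats::rnorm(n_vox * K, 0, params$smoothgrad_sigma),
                          n_vox, K)
    G <- input_gradient(fmodel, Xn, rep(targets[b], K), params)
    acc[, b] <- if (params$smoothgrad_absolute) rowMeans(abs(G)) else rowMeans(G)
  }
  acc
}

attr_guided <- function(fmodel, X, targets, params) {
  rule <- if (params$guided_literal) "literal-guided" else "guided"
  abs(input_gradient(fmodel, X, targets, params, relu_rule = rule))
}

#' GradCam relevance on the final convolution grid
#'
#' Kernel importance weights are the global-average-pooled gradients of
#' the target output with respect to the final convolution layer's
#' activation maps; the weighted activation sum is passed through a ReLU.
#' For a model without convolution layers the input grid itself serves as
#' the (single-channel) feature grid.
#'
#' @inheritParams attribute_batch
#' @return List with `coarse` (array `out_dim x B` relevance on the final
#'   conv grid, flattened to a matrix) and `upsampled` (`n_vox x B`).
#' @export
gradcam <- function(model, X, targets, params = attribution_params()) {
  fmodel <- if (isTRUE(model$folded)) model else fold_bn(model)
  fw <- nn_forward_eval(fmodel, X)
  dOut <- target_seed(fw$probs, targets, params$target_output)
  B <- ncol(X)
  if (length(fmodel$layers) == 0L) {
    ## degenerate conv-free model: input as 1-channel feature grid
    dA <- tcrossprod(dOut, fmodel$dense$W)  # B x n_vox
    alpha <- rowMeans(dA)
    coarse <- pmax(t(X) * alpha, 0)         # B x n_vox
    coarse <- t(coarse)
    return(list(coarse = coarse, upsampled = coarse,
                coarse_dim = fmodel$grid))
  }
  bw <- nn_backward_input(fmodel, fw, dOut)
  dA <- bw$dA_last                      # (B*n_pos) x C gradients wrt last conv A
  lastgeom <- fmodel$layers[[length(fmodel$layers)]]$geom
  n_pos <- lastgeom$n_out_pos
  A <- fw$caches[[length(fmodel$layers)]]$A
  coarse <- matrix(0, n_pos, B)
  for (b in seq_len(B)) {
    rows <- (b - 1L) * n_pos + seq_len(n_pos)
    alpha <- colMeans(dA[rows, , drop = FALSE])
    coarse[, b] <- pmax(A[rows, , drop = FALSE] %*% alpha, 0)
  }
  up <- matrix(0, prod(fmodel$grid), B)
  for (b in seq_len(B)) {
    up[, b] <- as.vector(upsample_trilinear(array(coarse[, b], lastgeom$out_dim),
                                            fmodel$grid))
  }
  list(coarse = coarse, upsampled = up, coarse_dim = lastgeom$out_dim)
}

attr_guided_gradcam <- function(fmodel, X, targets, params) {
  gc <- gradcam(fmodel, X, targets, params)
  gb <- attr_guided(fmodel, X, targets, params)
  gc$upsampled * gb
}

attr_ig <- function(fmodel, X, targets, params, reference_data) {
  n_vox <- nrow(X); B <- ncol(X)
  out <- matrix(0, n_vox, B)
  w <- 1 / length(params$ig_baselines)
  for (ref in params$ig_baselines) {
    bvec <- resolve_reference(ref, n_vox, reference_data)
    out <- out + w * ig_single_baseline(fmodel, X, targets, params, bvec)
  }
  out
}

ig_single_baseline <- function(fmodel, X, targets, params, bvec) {
  n_vox <- nrow(X); B <- ncol(X)
  m <- params$ig_steps
  alphas <- (seq_len(m) - 0.5) / m
  acc <- matrix(0, n_vox, B)
  D <- X - bvec
  ## evaluate all steps of one trial as one batch
  for (b in seq_len(B)) {
    Xa <- bvec + outer(D[, b], alphas)
    G <- input_gradient(fmodel, Xa, rep(targets[b], m), params)
    acc[, b] <- rowMeans(G)
  }
  acc * D
}

## DeepLift rescale/linear composite. Multipliers are propagated through
## the linear layers exactly like gradients; at each ReLU the derivative
## is replaced by the difference ratio (sigma(z) - sigma(z_ref)) /
## (z - z_ref), falling back to the gradient where |z - z_ref| < tol.
## rescale/linear multiplier backward pass for one reference, given the
## cached forward pass of x
deeplift_core <- function(fmodel, fw_x, X, targets, params, bvec) {
  B <- ncol(X)
  fw_b <- nn_forward_eval(fmodel, matrix(bvec, nrow(X), 1L))
  mults <- lapply(seq_along(fmodel$layers), function(l) {
    Zx <- fw_x$caches[[l]]$Zbn
    Zb <- fw_b$caches[[l]]$Zbn           # 1-sample reference, recycle rows
    n_pos <- fmodel$layers[[l]]$geom$n_out_pos
    Zbr <- Zb[rep(seq_len(n_pos), times = B), , drop = FALSE]
    dZ <- Zx - Zbr
    m <- (pmax(Zx, 0) - pmax(Zbr, 0)) / dZ
    small <- abs(dZ) < params$deeplift_tol
    if (any(small)) m[small] <- (Zx > 0)[small]
    m
  })
  dOut <- target_seed(fw_x$probs, targets, params$target_output)
  M <- nn_backward_input(fmodel, fw_x, dOut, relu_rule = "mult", mults = mults)$dX
  (X - bvec) * M
}

attr_deeplift <- function(fmodel, X, targets, params, reference_data,
                          ref = NULL) {
  bvec <- if (is.null(ref)) {
    resolve_reference(params$deeplift_reference, nrow(X), reference_data)
  } else ref
  fw_x <- nn_forward_eval(fmodel, X)
  deeplift_core(fmodel, fw_x, X, targets, params, bvec)
}

attr_dlshap <- function(fmodel, X, targets, params, reference_data) {
  stop_if_not(!is.null(reference_data),
              "deeplift_shap needs reference_data to sample references from")
  set.seed(derive_seed(params$seed, "dlshap"))
  K <- min(params$dlshap_K, ncol(reference_data))
  ridx <- sample.int(ncol(reference_data), K)
  fw_x <- nn_forward_eval(fmodel, X)
  acc <- matrix(0, nrow(X), ncol(X))
  for (k in seq_len(K)) {
    acc <- acc + deeplift_core(fmodel, fw_x, X, targets, params,
                               reference_data[, ridx[k]])
  }
  acc / K
}

## LRP composite: LRP-0 at the dense output layer, LRP-gamma at all
## convolution layers, relevance passed unchanged through ReLUs, seeded
## with f(x) at the target output unit. Batch-norm is handled upstream by
## folding (canonization) into the convolution weights.
attr_lrp <- function(fmodel, X, targets, params) {
  B <- ncol(X)
  fw <- nn_forward_eval(fmodel, X)
  audits <- matrix(NA_real_, length(fmodel$layers) + 2L, B)
  fx <- target_value(fw, targets, "logit")
  if (params$target_output == "probability") {
    ## relevance decomposition is defined on the logit; probabilities
    ## rescale the seed only
    fx <- fx
  }
  audits[1L, ] <- fx
  ## dense layer, LRP-0: r_i = a_i w_ic / z_c * f, with z_c the full
  ## pre-softmax logit (denominator stabilised)
  Wd <- fmodel$dense$W
  Feat <- fw$Feat                         # B x n_feat
  Rfeat <- matrix(0, nrow(Feat), ncol(Feat))
  for (b in seq_len(B)) {
    contrib <- Feat[b, ] * Wd[, targets[b]]
    z <- fw$logits[b, targets[b]]
    Rfeat[b, ] <- contrib / stabilized(z, params$lrp_eps) * fx[b]
  }
  nl <- length(fmodel$layers)
  n_pos_last <- if (nl) fmodel$layers[[nl]]$geom$n_out_pos else prod(fmodel$grid)
  C_last <- if (nl) fmodel$layers[[nl]]$geom$out_channels else 1L
  Rh <- feat_to_h(Rfeat, n_pos_last, B, C_last)
  audits[2L, ] <- colSums(matrix(rowSums(Rh), n_pos_last))  # per-sample sums
  if (nl) {
    for (l in rev(seq_len(nl))) {
      ly <- fmodel$layers[[l]]
      ca <- fw$caches[[l]]
      Wg <- ly$W + params$lrp_gamma * pmax(ly$W, 0)
      bg <- if (!is.null(ly$b)) ly$b + params$lrp_gamma * pmax(ly$b, 0) else NULL
      Zg <- ca$Xcol %*% Wg
      if (!is.null(bg)) Zg <- cadd(Zg, bg)
      Frac <- Rh / stabilized(Zg, params$lrp_eps)
      Rcol <- ca$Xcol * tcrossprod(Frac, Wg)
      Rh <- conv_scatter(Rcol, ly$geom, B)
      n_in <- ly$geom$n_in_pos
      audits[2L + (nl - l + 1L), ] <- colSums(matrix(rowSums(Rh), n_in))
    }
  }
  R <- matrix(Rh, ncol = B)
  attr(R, "layer_sums") <- audits
  R
}

stabilized <- function(z, eps) z + eps * sign(z) + (z == 0) * eps

#' Layerwise relevance sums of an LRP decomposition
#'
#' Returns the relevance total after each redistribution step (row 1 is
#' the seed `f(x)`, subsequent rows the totals entering each earlier
#' layer), used to audit conservation.
#'
#' @inheritParams attribute_batch
#' @return Matrix (layers+2) x B of relevance sums.
#' @export
lrp_layer_sums <- function(model, X, targets, params = attribution_params()) {
  fmodel <- if (isTRUE(model$folded)) model else fold_bn(model)
  R <- attr_lrp(fmodel, X, targets, params)
  attr(R, "layer_sums")
}
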