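#' Decoder hyper-parameter configuration
#'
#' The decoder family is a stack of stride-2 3D-convolution layers
#' (batch-normalisation applied to the linear convolution outputs before
#' the ReLU) followed by a dense softmax output layer. The search grid for
#' each field mirrors the benchmark defaults: layers {3,4}, kernels per
#' layer {4,8,16,32}, kernel size {3,5}, batch size {32,64}, learning rate
#' {3e-4, 1e-3}, dropout {0, 0.25, 0.5}.
#'
#' @param n_conv_layers number of convolution layers.
#' @param n_kernels kernels (output channels) per convolution layer.
#' @param kernel_size cubic kernel edge length.
#' @param batch_size training mini-batch size.
#' @param learning_rate ADAM learning rate.
#' @param dropout_rate dropout rate applied to convolution outputs.
#' @param seed integer seed for parameter initialisation.
#' @param use_bn apply batch-normalisation (TRUE for the benchmark family;
#'   FALSE builds a plain conv net, used e.g. for conservation audits).
#' @param use_bias include additive biases (FALSE gives a bias-free net).
#' @param bn_eps,bn_momentum batch-norm stabiliser and running-stat momentum.
#' @param check_grid if TRUE (default) restrict values to the search grid;
#'   FALSE allows off-grid values (e.g. toy nets in tests).
#' @return A `decoder_config` object.
#' @export
decoder_config <- function(n_conv_layers = 3L, n_kernels = 8L, kernel_size = 3L,
                           batch_size = 32L, learning_rate = 1e-3,
                           dropout_rate = 0, seed = 1L,
                           use_bn = TRUE, use_bias = TRUE,
                           bn_eps = 1e-3, bn_momentum = 0.1,
                           check_grid = TRUE) {
  if (check_grid) {
    stop_if_not(n_conv_layers %in% c(3L, 4L), "n_conv_layers must be 3 or 4")
    stop_if_not(n_kernels %in% c(4L, 8L, 16L, 32L), "n_kernels must be in {4,8,16,32}")
    stop_if_not(kernel_size %in% c(3L, 5L), "kernel_size must be 3 or 5")
    stop_if_not(batch_size %in% c(32L, 64L), "batch_size must be 32 or 64")
    stop_if_not(isTRUE(all.equal(learning_rate, 3e-4)) ||
                  isTRUE(all.equal(learning_rate, 1e-3)),
                "learning_rate must be 3e-4 or 1e-3")
    stop_if_not(dropout_rate %in% c(0, 0.25, 0.5), "dropout_rate must be in {0,0.25,0.5}")
  } else {
    stop_if_not(n_conv_layers >= 0L, "n_conv_layers must be >= 0")
    stop_if_not(kernel_size >= 1L, "kernel_size must be >= 1")
    stop_if_not(dropout_rate >= 0 && dropout_rate < 1, "dropout_rate in [0,1)")
  }
  structure(list(n_conv_layers = as.integer(n_conv_layers),
                 n_kernels = as.integer(n_kernels),
                 kernel_size = as.integer(kernel_size),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 dropout_rate = dropout_rate, seed = as.integer(seed),
                 use_bn = isTRUE(use_bn), use_bias = isTRUE(use_bias),
                 bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "decoder_config")
}

## Geometry of one stride-2 "same"-padded conv layer.
## Padded coordinates are chosen so output cell i covers padded positions
## (i-1)*2+1 ... (i-1)*2+K along each axis.
conv_geometry <- function(in_dim, in_channels, out_channels, K) {
  stop_if_not(all(in_dim >= 2L), "grid too small for this conv depth (dim %s)",
              paste(in_dim, collapse = "x"))
  out_dim <- as.integer(ceiling(in_dim / 2))
  pad_total <- pmax((out_dim - 1L) * 2L + K - in_dim, 0L)
  pad_before <- pad_total %/% 2L
  pd <- in_dim + pad_total
  n_in_pos <- prod(in_dim)
  n_out_pos <- prod(out_dim)
  n_padvox <- prod(pd)

  ## linear indices of original voxels inside the padded volume
  o1 <- seq_len(in_dim[1]) + pad_before[1]
  o2 <- seq_len(in_dim[2]) + pad_before[2]
  o3 <- seq_len(in_dim[3]) + pad_before[3]
  fill_idx <- as.vector(outer(outer(o1, (o2 - 1L) * pd[1], "+"),
                              (o3 - 1L) * pd[1] * pd[2], "+"))

  ## patch index matrix: n_out_pos x K^3, entries in padded linear index
  s1 <- (seq_len(out_dim[1]) - 1L) * 2L + 1L
  s2 <- (seq_len(out_dim[2]) - 1L) * 2L + 1L
  s3 <- (seq_len(out_dim[3]) - 1L) * 2L + 1L
  base <- as.vector(outer(outer(s1, (s2 - 1L) * pd[1], "+"),
                          (s3 - 1L) * pd[1] * pd[2], "+"))
  off <- as.vector(outer(outer(0:(K - 1L), (0:(K - 1L)) * pd[1], "+"),
                         (0:(K - 1L)) * pd[1] * pd[2], "+"))
  idx <- outer(base, off, "+")

  list(in_dim = in_dim, out_dim = out_dim, K = K, K3 = K^3L,
       in_channels = in_channels, out_channels = out_channels,
       pd = pd, fill_idx = fill_idx, idx = idx,
       n_in_pos = n_in_pos, n_out_pos = n_out_pos, n_padvox = n_padvox)
}

## fast column-wise add / multiply (avoid sweep() overhead)
cadd <- function(M, v) M + rep(v, each = nrow(M))
cmul <- function(M, v) M * rep(v, each = nrow(M))
csub <- function(M, v) M - rep(v, each = nrow(M))

## Batched index plans for one conv geometry at a fixed batch size.
## xpad is treated as a flat (n_padvox, B, Cin) buffer; `gather` pulls it
## into im2col layout (rows (p,b), cols (k,c)), `fill`/`scatter` map the
## unpadded voxel block layout (rows (i,b), cols c) in and out. Plans are
## memoised package-wide, keyed by geometry and batch size, so identical
## layer geometries (e.g. across ensemble models) share one plan and
## serialized models stay lean.
.plan_cache <- new.env(parent = emptyenv())

conv_plan <- function(geom, B) {
  key <- paste(c(geom$in_dim, geom$K, geom$in_channels, B), collapse = "_")
  pl <- .plan_cache[[key]]
  if (is.null(pl)) {
    K3 <- geom$K3; Cin <- geom$in_channels
    n_out <- geom$n_out_pos; npad <- geom$n_padvox
    boff <- (seq_len(B) - 1L) * npad
    ## fill: (i, b, c) -> flat xpad index
    fill <- as.vector(outer(outer(geom$fill_idx, boff, "+"),
                            (seq_len(Cin) - 1L) * npad * B, "+"))
    ## batched patch indices, rows ordered (p, b), columns k
    G <- geom$idx[rep(seq_len(n_out), times = B), , drop = FALSE] +
      rep(boff, each = n_out)
    ## gather: (p, b, k, c) -> flat xpad index
    gather <- as.vector(outer(as.vector(G), (seq_len(Cin) - 1L) * npad * B, "+"))
    pl <- list(fill = fill, gather = gather, B = B,
               npad_total = npad * B * Cin)
    .plan_cache[[key]] <- pl
  }
  pl
}

## im2col gather for a sample-major big matrix H ((B*n_in_pos) x Cin)
conv_gather <- function(H, geom, B) {
  pl <- conv_plan(geom, B)
  conv_gather_cpp(H, pl$fill, pl$gather, pl$npad_total,
                  geom$n_out_pos * B, geom$K3 * geom$in_channels)
}

## transpose of conv_gather: scatter-add column gradients back to voxels
conv_scatter <- function(dXcol, geom, B) {
  pl <- conv_plan(geom, B)
  conv_scatter_cpp(dXcol, pl$fill, pl$gather, pl$npad_total,
                   geom$n_in_pos * B, geom$in_channels)
}

#' Build an (untrained) 3D-CNN decoder
#'
#' Layer stack: `n_conv_layers` x (stride-2 same-padded 3D convolution,
#' batch-norm on the linear output, ReLU, dropout) followed by flatten and
#' a dense softmax layer. Initialisation is He-normal for convolutions and
#' scaled-normal for the dense layer, deterministic given `config$seed`.
#'
#' @param config a [decoder_config()].
#' @param grid_shape integer(3) input grid.
#' @param n_classes number of output classes.
#' @param classes optional class label vector (fixed alphabetically
#'   otherwise when training data arrive).
#' @return A `decoder_model` object (untrained).
#' @export
build_model <- function(config, grid_shape, n_classes, classes = NULL) {
  set.seed(derive_seed(config$seed, "init"))
  grid_shape <- as.integer(grid_shape)
  layers <- list()
  in_dim <- grid_shape
  in_ch <- 1L
  n_conv <- config$n_conv_layers
  for (l in seq_len(n_conv)) {
    geom <- conv_geometry(in_dim, in_ch, config$n_kernels, config$kernel_size)
    fan_in <- geom$K3 * in_ch
    W <- matrix(stats::rnorm(fan_in * config$n_kernels, 0, sqrt(2 / fan_in)),
                fan_in, config$n_kernels)
    b <- if (config$use_bias) numeric(config$n_kernels) else NULL
    bn <- if (config$use_bn) {
      list(gamma = rep(1, config$n_kernels), beta = numeric(config$n_kernels),
           rmean = numeric(config$n_kernels), rvar = rep(1, config$n_kernels))
    } else NULL
    layers[[l]] <- list(W = W, b = b, bn = bn, geom = geom)
    in_dim <- geom$out_dim
    in_ch <- config$n_kernels
  }
  n_feat <- prod(in_dim) * in_ch
  Wd <- matrix(stats::rnorm(n_feat * n_classes, 0, sqrt(1 / n_feat)),
               n_feat, n_classes)
  bd <- if (config$use_bias) numeric(n_classes) else NULL
  m <- structure(list(config = config, grid = grid_shape,
                      n_classes = as.integer(n_classes), classes = classes,
                      layers = layers,
                      dense = list(W = Wd, b = bd),
                      feat_dim = c(in_dim, in_ch),
                      history = NULL, trained = FALSE),
                 class = "decoder_model")
  m
}

#' Number of trainable parameters of a decoder
#' @param model a `decoder_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  n <- length(model$dense$W) + length(model$dense$b)
  for (l in model$layers) {
    n <- n + length(l$W) + length(l$b)
    if (!is.null(l$bn)) n <- n + length(l$bn$gamma) + length(l$bn$beta)
  }
  n
}

#' @export
print.decoder_model <- function(x, ...) {
  dims <- vapply(x$layers, function(l) paste(l$geom$out_dim, collapse = "x"),
                 character(1))
  cat(sprintf("decoder_model: %s -> %s -> dense(%d classes); %d parameters%s\n",
              paste(x$grid, collapse = "x"),
              if (length(dims)) paste(dims, collapse = " -> ") else "(no conv)",
              x$n_classes, n_parameters(x),
              if (x$trained) " [trained]" else ""))
  invisible(x)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

## big-matrix <-> feature-matrix reshapes (sample-major blocks)
h_to_feat <- function(H, n_pos, B, C) {
  matrix(aperm(array(H, c(n_pos, B, C)), c(2, 1, 3)), B, n_pos * C)
}
feat_to_h <- function(F_, n_pos, B, C) {
  matrix(aperm(array(F_, c(B, n_pos, C)), c(2, 1, 3)), B * n_pos, C)
}

## Full forward pass.
## X: n_vox x B matrix. train: batch statistics + dropout; eval: running
## stats, no dropout. Returns probs, logits and (optionally) layer caches.
nn_forward <- function(model, X, train = FALSE, keep_cache = FALSE,
                       dropout_masks = NULL) {
  B <- ncol(X)
  cfg <- model$config
  H <- matrix(as.vector(X), ncol = 1L)
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  bn_batch <- vector("list", length(model$layers))
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    geom <- ly$geom
    Xcol <- conv_gather(H, geom, B)
    Zlin <- Xcol %*% ly$W
    if (!is.null(ly$b)) Zlin <- cadd(Zlin, ly$b)
    if (!is.null(ly$bn)) {
      if (train) {
        mu <- colMeans(Zlin)
        va <- colMeans(Zlin^2) - mu^2
        bn_batch[[l]] <- list(mu = mu, va = va)
      } else {
        mu <- ly$bn$rmean
        va <- ly$bn$rvar
      }
      invstd <- 1 / sqrt(va + cfg$bn_eps)
      Zhat <- cmul(csub(Zlin, mu), invstd)
      Zbn <- cadd(cmul(Zhat, ly$bn$gamma), ly$bn$beta)
    } else {
      Zhat <- NULL
      Zbn <- Zlin
    }
    A <- pmax(Zbn, 0)
    M <- NULL
    if (train && cfg$dropout_rate > 0) {
      keep <- 1 - cfg$dropout_rate
      M <- if (!is.null(dropout_masks)) dropout_masks[[l]] else {
        matrix(stats::runif(length(A)) < keep, nrow(A)) / keep
      }
      A <- A * M
    }
    if (keep_cache) {
      caches[[l]] <- list(Xcol = Xcol, Zlin = Zlin, Zhat = Zhat, Zbn = Zbn,
                          A = A, M = M)
    }
    H <- A
  }
  n_pos <- if (length(model$layers)) model$layers[[length(model$layers)]]$geom$n_out_pos else prod(model$grid)
  C_last <- if (length(model$layers)) model$layers[[length(model$layers)]]$geom$out_channels else 1L
  Feat <- h_to_feat(H, n_pos, B, C_last)
  logits <- Feat %*% model$dense$W
  if (!is.null(model$dense$b)) logits <- cadd(logits, model$dense$b)
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, Feat = Feat, caches = caches,
       bn_batch = bn_batch, B = B,
       last_npos = n_pos, last_nch = C_last)
}

## Training backward pass: cross-entropy gradient wrt all parameters.
## fw must come from nn_forward(train=TRUE, keep_cache=TRUE).
nn_backward <- function(model, fw, y_idx) {
  B <- fw$B
  cfg <- model$config
  Y <- matrix(0, B, model$n_classes)
  Y[cbind(seq_len(B), y_idx)] <- 1
  dLogits <- (fw$probs - Y) / B
  grads <- list(dense = list(W = crossprod(fw$Feat, dLogits),
                             b = if (!is.null(model$dense$b)) colSums(dLogits) else NULL),
                layers = vector("list", length(model$layers)))
  dFeat <- tcrossprod(dLogits, model$dense$W)
  dH <- feat_to_h(dFeat, fw$last_npos, B, fw$last_nch)
  for (l in rev(seq_along(model$layers))) {
    ly <- model$layers[[l]]
    ca <- fw$caches[[l]]
    dA <- dH
    if (!is.null(ca$M)) dA <- dA * ca$M
    dZbn <- dA * (ca$Zbn > 0)
    if (!is.null(ly$bn)) {
      st <- fw$bn_batch[[l]]
      invstd <- 1 / sqrt(st$va + cfg$bn_eps)
      dgamma <- colSums(dZbn * ca$Zhat)
      dbeta <- colSums(dZbn)
      dZhat <- cmul(dZbn, ly$bn$gamma)
      m1 <- colMeans(dZhat)
      m2 <- colMeans(dZhat * ca$Zhat)
      dZlin <- cmul(csub(dZhat, m1) - cmul(ca$Zhat, m2), invstd)
    } else {
      dgamma <- dbeta <- NULL
      dZlin <- dZbn
    }
    grads$layers[[l]] <- list(W = crossprod(ca$Xcol, dZlin),
                              b = if (!is.null(ly$b)) colSums(dZlin) else NULL,
                              gamma = dgamma, beta = dbeta)
    if (l > 1L) {
      dXcol <- tcrossprod(dZlin, ly$W)
      dH <- conv_scatter(dXcol, ly$geom, B)
    }
  }
  grads
}

## Fold batch-norm (running statistics) into conv weights/biases.
## Returns a BN-free affine-equivalent model for inference-mode passes;
## the canonical form used by all attribution rules.
fold_bn <- function(model) {
  cfg <- model$config
  for (l in seq_along(model$layers)) {
    ly <- model$layers[[l]]
    if (!is.null(ly$bn)) {
      scale <- ly$bn$gamma / sqrt(ly$bn$rvar + cfg$bn_eps)
      shift <- ly$bn$beta - ly$bn$rmean * scale
      ly$W <- sweep(ly$W, 2, scale, "*")
      b0 <- if (!is.null(ly$b)) ly$b else numeric(ly$geom$out_channels)
      ly$b <- b0 * scale + shift
      ly$bn <- NULL
      model$layers[[l]] <- ly
    }
  }
  model$folded <- TRUE
  model
}

## Inference-mode forward through a folded model with caches for the
## attribution backward rules.
nn_forward_eval <- function(fmodel, X, keep_cache = TRUE) {
  nn_forward(fmodel, X, train = FALSE, keep_cache = keep_cache)
}

## Backward pass to the input in inference mode.
##
## dOut: B x C matrix seeding the dense-layer output gradient.
## relu_rule: "plain"  - gradient masked by forward pre-activation sign
##            "guided" - additionally masked by the sign of the incoming
##                       top-down signal (canonical guided backprop)
##            "literal-guided" - masked by incoming signal sign only
##            "mult"   - elementwise multiplier matrices given in `mults`
##                       replace the ReLU derivative (DeepLift)
## Returns dX (n_vox x B) and the gradient wrt the last conv activation.
nn_backward_input <- function(fmodel, fw, dOut, relu_rule = "plain",
                              mults = NULL) {
  B <- fw$B
  dFeat <- tcrossprod(dOut, fmodel$dense$W)
  dH <- feat_to_h(dFeat, fw$last_npos, B, fw$last_nch)
  dA_last <- dH
  for (l in rev(seq_along(fmodel$layers))) {
    ly <- fmodel$layers[[l]]
    ca <- fw$caches[[l]]
    dZ <- switch(relu_rule,
                 plain = dH * (ca$Zbn > 0),
                 guided = dH * (ca$Zbn > 0) * (dH > 0),
                 `literal-guided` = dH * (dH > 0),
                 mult = dH * mults[[l]],
                 stop("unknown relu_rule"))
    dXcol <- tcrossprod(dZ, ly$W)
    dH <- conv_scatter(dXcol, ly$geom, B)
  }
  dX <- matrix(dH, ncol = B)
  list(dX = dX, dA_last = dA_last)
}

## Seed matrix for the attribution target: derivative of f (logit or
## probability of the target class) wrt the logits.
target_seed <- function(probs, targets, target_output = "logit") {
  B <- nrow(probs)
  C <- ncol(probs)
  dOut <- matrix(0, B, C)
  if (target_output == "logit") {
    dOut[cbind(seq_len(B), targets)] <- 1
  } else {
    pc <- probs[cbind(seq_len(B), targets)]
    dOut <- -probs * pc
    dOut[cbind(seq_len(B), targets)] <- pc * (1 - probs[cbind(seq_len(B), targets)])
  }
  dOut
}

## Scalar model output f for the selected target.
target_value <- function(fw, targets, target_output = "logit") {
  if (target_output == "logit") fw$logits[cbind(seq_len(nrow(fw$logits)), targets)]
  else fw$probs[cbind(seq_len(nrow(fw$probs)), targets)]
}
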