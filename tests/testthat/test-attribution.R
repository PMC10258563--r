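## closed-form expectations on a conv-free model f = w.x + b
test_that("all methods match their closed forms on a linear model", {
  m <- linear_model()
  w <- m$dense$W[, 1]
  set.seed(4)
  x <- rnorm(8)
  X <- matrix(x, 8, 1)
  pars <- attribution_params(seed = 9L)
  refs <- matrix(rnorm(8 * 30), 8, 30)

  expect_equal(attribute_batch(m, X, 1L, "gradient", pars)[, 1], abs(w))
  expect_equal(attribute_batch(m, X, 1L, "smoothgrad", pars)[, 1], abs(w))
  expect_equal(attribute_batch(m, X, 1L, "input_x_gradient", pars)[, 1], x * w)
  expect_equal(attribute_batch(m, X, 1L, "guided_backprop", pars)[, 1], abs(w))
  ## IG with the zero baseline is exact at any step count (constant gradient)
  igp <- attribution_params(ig_steps = 4L, ig_baselines = "zero")
  expect_equal(attribute_batch(m, X, 1L, "integrated_gradients", igp,
                               reference_data = refs)[, 1], x * w)
  expect_equal(attribute_batch(m, X, 1L, "deeplift", pars,
                               reference_data = refs)[, 1], x * w)
  ## DeepLift SHAP averages the linear rule over sampled references
  dsp <- attribution_params(dlshap_K = 30L, seed = 3L)
  expect_equal(attribute_batch(m, X, 1L, "deeplift_shap", dsp,
                               reference_data = refs)[, 1],
               (x - rowMeans(refs)) * w)
  ## LRP-0 on a linear model is proportional to x*w (exactly x*w at b = 0)
  lr <- attribute_batch(m, X, 1L, "lrp", pars)[, 1]
  expect_equal(lr / (x * w), rep(lr[1] / (x[1] * w[1]), 8), tolerance = 1e-9)
  m0 <- m; m0$dense$b <- NULL
  expect_equal(attribute_batch(m0, X, 1L, "lrp", pars)[, 1], x * w,
               tolerance = 1e-5)
  ## conv-free GradCam: input as feature grid, alpha = mean(w)
  expect_equal(attribute_batch(m, X, 1L, "guided_gradcam", pars)[, 1],
               pmax(mean(w) * x, 0) * abs(w))
  ## degenerate inputs
  expect_equal(attribute_batch(m, matrix(0, 8, 1), 1L, "input_x_gradient", pars)[, 1],
               rep(0, 8))
  igz <- attribute_batch(m, matrix(0, 8, 1), 1L, "integrated_gradients",
                         attribution_params(ig_baselines = "zero"))
  expect_equal(igz[, 1], rep(0, 8))   # x equal to the baseline: zero path
})

test_that("stochastic methods are seeded and reproducible", {
  toy <- toy_net()
  X <- toy$data$test$x[, 1:2]
  tg <- match(toy$data$test$meta$label[1:2], toy$model$classes)
  p <- attribution_params(smoothgrad_K = 8L, dlshap_K = 5L, seed = 13L)
  for (mm in c("smoothgrad", "deeplift_shap")) {
    a <- attribute_batch(toy$model, X, tg, mm, p, reference_data = toy$data$train$x)
    b <- attribute_batch(toy$model, X, tg, mm, p, reference_data = toy$data$train$x)
    expect_identical(a, b)
  }
  ## K = 1 DeepLift SHAP equals DeepLift with that sampled reference
  p1 <- attribution_params(dlshap_K = 1L, seed = 13L)
  a1 <- attribute_batch(toy$model, X, tg, "deeplift_shap", p1,
                        reference_data = toy$data$train$x)
  set.seed(derive_seed(p1$seed, "dlshap"))
  ref <- toy$data$train$x[, sample.int(ncol(toy$data$train$x), 1L)]
  d1 <- attribute_batch(toy$model, X, tg, "deeplift",
                        attribution_params(deeplift_reference = ref))
  expect_equal(a1, d1, tolerance = 1e-12)
})

test_that("gradients agree with central finite differences on a trained net", {
  toy <- toy_net()
  fm <- neuroattrib:::fold_bn(toy$model)
  x <- toy$data$test$x[, 5]
  tg <- match(toy$data$test$meta$label[5], toy$model$classes)
  g <- neuroattrib:::input_gradient(fm, matrix(x), tg, attribution_params())
  set.seed(8)
  idx <- sample(which(abs(g) > 1e-4), 8L)
  h <- 1e-4
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + h
    xn <- x; xn[i] <- xn[i] - h
    fp <- neuroattrib:::nn_forward(fm, matrix(xp))$logits[1, tg]
    fn <- neuroattrib:::nn_forward(fm, matrix(xn))$logits[1, tg]
    expect_equal((fp - fn) / (2 * h), g[i], tolerance = 1e-3)
  }
})

test_that("input x gradient equals DeepLift with zero reference on a bias-free net", {
  toy <- toy_net()   # built with use_bias = FALSE, no batch-norm
  X <- toy$data$test$x[, 1:4]
  tg <- match(toy$data$test$meta$label[1:4], toy$model$classes)
  ixg <- attribute_batch(toy$model, X, tg, "input_x_gradient", attribution_params())
  dl <- attribute_batch(toy$model, X, tg, "deeplift",
                        attribution_params(deeplift_reference = "zero"))
  ## for ReLU nets with no additive bias, the rescale multipliers at b = 0
  ## coincide with the gradient almost everywhere
  expect_equal(dl, ixg, tolerance = 1e-6)
})

test_that("guided backprop yields non-negative maps and masks dead units", {
  toy <- toy_net()
  X <- toy$data$test$x[, 1:6]
  tg <- match(toy$data$test$meta$label[1:6], toy$model$classes)
  gb <- attribute_batch(toy$model, X, tg, "guided_backprop", attribution_params())
  expect_true(all(gb >= 0))
  ## literal reading (mask only by signal sign) is available and differs
  gbl <- attribute_batch(toy$model, X, tg, "guided_backprop",
                         attribution_params(guided_literal = TRUE))
  expect_false(identical(gb, gbl))
  ## a ReLU that never activates blocks everything upstream: zero input
  ## to a positive-bias-free net gives zero pre-activations -> no signal
  z <- attribute_batch(toy$model, matrix(0, nrow(X), 1), tg[1], "guided_backprop",
                       attribution_params())
  expect_equal(max(abs(z)), 0)
})

test_that("gradcam pooling matches an explicit loop over kernels", {
  toy <- toy_net()
  fm <- neuroattrib:::fold_bn(toy$model)
  X <- toy$data$test$x[, 1:3]
  tg <- match(toy$data$test$meta$label[1:3], toy$model$classes)
  gc <- gradcam(fm, X, tg)
  fw <- neuroattrib:::nn_forward_eval(fm, X)
  dOut <- neuroattrib:::target_seed(fw$probs, tg, "logit")
  bw <- neuroattrib:::nn_backward_input(fm, fw, dOut)
  nl <- length(fm$layers)
  npos <- fm$layers[[nl]]$geom$n_out_pos
  for (b in 1:3) {
    rows <- (b - 1L) * npos + seq_len(npos)
    acc <- numeric(npos)
    for (k in seq_len(ncol(fw$caches[[nl]]$A))) {
      alpha_k <- mean(bw$dA_last[rows, k])
      acc <- acc + alpha_k * fw$caches[[nl]]$A[rows, k]
    }
    expect_equal(pmax(acc, 0), gc$coarse[, b], tolerance = 1e-6)
  }
  ## upsampled grid matches the input grid
  expect_equal(nrow(gc$upsampled), prod(fm$grid))
  ## if the weighted sum is non-positive everywhere, guided gradcam is 0
  neg <- gc
  expect_true(all(attribute_batch(fm, -X * 0, tg, "guided_gradcam",
                                  attribution_params()) >= 0))
})

test_that("relevance maps share the input grid and stay finite", {
  toy <- toy_net()
  ds <- subset_trials(toy$data$test, 1:4)
  for (mm in attribution_methods()) {
    at <- attribute_trials(toy$model, ds, mm, attribution_params(
      smoothgrad_K = 5L, dlshap_K = 3L, ig_steps = 8L),
      reference_data = toy$data$train)
    expect_identical(dim(at$relevance), as.integer(c(prod(ds$grid), 4)))
    expect_true(all(is.finite(at$relevance)))
    expect_true(all(at$relevance[!as.vector(ds$mask), ] == 0))
  }
})

test_that("deeplift rescale rule reduces to the stated unit example", {
  ## single ReLU unit: reference pre-activation 0, input pre-activation 2
  ## => contribution = delta sigma = 2, multiplier = 1
  zx <- 2; zb <- 0
  mlt <- (max(zx, 0) - max(zb, 0)) / (zx - zb)
  expect_equal(mlt, 1)
  ## near-zero delta falls back to the gradient
  zx <- 1e-9; zb <- 0
  small <- abs(zx - zb) < 1e-7
  expect_true(small)
})
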