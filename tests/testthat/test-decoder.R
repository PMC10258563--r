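test_that("stride-2 stacking halves the grid at every layer", {
  m <- build_model(decoder_config(n_conv_layers = 3L, seed = 1L), c(16L, 16L, 16L), 4L)
  dims <- lapply(m$layers, function(l) l$geom$out_dim)
  expect_equal(dims, list(rep(8L, 3), rep(4L, 3), rep(2L, 3)))
  m4 <- build_model(decoder_config(n_conv_layers = 4L, seed = 1L), c(16L, 16L, 16L), 4L)
  expect_equal(m4$layers[[4]]$geom$out_dim, rep(1L, 3))
  ## too deep for the grid
  cfg5 <- decoder_config(n_conv_layers = 5L, check_grid = FALSE, seed = 1L)
  expect_error(build_model(cfg5, c(16L, 16L, 16L), 4L), "grid too small")
  expect_gt(n_parameters(m), 0L)
})

test_that("forward pass returns normalised probabilities and is seed-deterministic", {
  m1 <- build_model(decoder_config(seed = 3L), c(16L, 16L, 16L), 4L)
  m2 <- build_model(decoder_config(seed = 3L), c(16L, 16L, 16L), 4L)
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)
  expect_identical(m1$dense$W, m2$dense$W)
  set.seed(1)
  X <- matrix(rnorm(4096 * 5), 4096, 5)
  fw <- neuroattrib:::nn_forward(m1, X)
  expect_equal(rowSums(fw$probs), rep(1, 5), tolerance = 1e-6)
  expect_true(all(fw$probs >= 0))
})

test_that("backward pass matches numerical derivatives", {
  set.seed(2)
  cfg <- decoder_config(n_conv_layers = 2L, n_kernels = 3L, kernel_size = 3L,
                        batch_size = 4L, dropout_rate = 0, seed = 3L,
                        check_grid = FALSE)
  m <- build_model(cfg, c(6L, 6L, 6L), 3L)
  X <- matrix(rnorm(216 * 4), 216, 4)
  y <- c(1L, 2L, 3L, 1L)
  fw <- neuroattrib:::nn_forward(m, X, train = TRUE, keep_cache = TRUE)
  gr <- neuroattrib:::nn_backward(m, fw, y)
  lossfun <- function(mm) {
    mean(-log(neuroattrib:::nn_forward(mm, X, train = TRUE)$probs[cbind(1:4, y)]))
  }
  eps <- 1e-5
  probe <- function(get, set, g) {
    for (i in sample(length(get(m)), 3L)) {
      mp <- set(m, i, eps); mn <- set(m, i, -eps)
      num <- (lossfun(mp) - lossfun(mn)) / (2 * eps)
      expect_equal(num, g[i], tolerance = 1e-6)
    }
  }
  probe(function(m) m$layers[[1]]$W,
        function(m, i, e) { m$layers[[1]]$W[i] <- m$layers[[1]]$W[i] + e; m },
        gr$layers[[1]]$W)
  probe(function(m) m$dense$W,
        function(m, i, e) { m$dense$W[i] <- m$dense$W[i] + e; m },
        gr$dense$W)
  probe(function(m) m$layers[[2]]$bn$gamma,
        function(m, i, e) { m$layers[[2]]$bn$gamma[i] <- m$layers[[2]]$bn$gamma[i] + e; m },
        gr$layers[[2]]$gamma)
})

test_that("early stopping rules fire as specified", {
  ## rule (i): three consecutive evaluations worse than the previous best
  losses <- c(1.0, 0.9, 0.95, 0.96, 0.97)
  dec <- early_stop_decision(losses, grace = 5L)
  expect_true(dec$stop)
  expect_identical(dec$rule, "patience")
  ## not before the third consecutive non-improvement
  expect_false(early_stop_decision(losses[1:4], grace = 4L)$stop)
  ## rule (ii): flat losses, sd = 0 <= 0.01
  dec2 <- early_stop_decision(rep(0.7, 10), grace = 10L)
  expect_true(dec2$stop)
  expect_identical(dec2$rule, "plateau")
  ## grace period blocks both rules
  expect_false(early_stop_decision(rep(0.7, 9), grace = 10L)$stop)
  ## an improvement resets the patience counter
  expect_false(early_stop_decision(c(1, .9, .95, .96, .85, .9, .95), grace = 5L,
                                   sd_window = 100L)$stop)
})

test_that("training respects the epoch window and records history", {
  ds <- small_dataset()
  m <- small_model()
  expect_true(m$trained)
  expect_gte(nrow(m$history), 10L)
  expect_lte(nrow(m$history), 20L)
  expect_named(m$history, c("epoch", "train_loss", "train_acc", "val_loss", "val_acc"))
  ## learns the separable synthetic task
  expect_gte(tail(m$history$train_acc, 1), 0.95)
  expect_gte(evaluate(m, ds$test)$accuracy, 0.9)
})

test_that("evaluate reports chance for a constant predictor and identity for a perfect one", {
  ds <- small_dataset()$test
  m <- small_model()
  ## force constant prediction: zero dense weights, bias to class 1
  m0 <- m
  m0$dense$W[] <- 0
  m0$dense$b <- c(10, 0, 0)
  ev <- evaluate(m0, ds)
  expect_equal(ev$accuracy, 1 / 3, tolerance = 1e-9)
  expect_equal(unname(ev$confusion[, 1]), rep(1, 3))
  ## a perfect model has an identity confusion matrix
  evp <- evaluate(m, ds)
  if (evp$accuracy == 1) expect_equal(unname(evp$confusion), diag(3))
  ## accuracy equals the balanced-class mean of the confusion diagonal
  expect_equal(evp$accuracy, mean(diag(evp$counts) / rowSums(evp$counts)),
               tolerance = 1e-9)
})

test_that("hyper-parameter score lambda follows its definition and ordering", {
  expect_equal(hyperparameter_score(0.10, 0.20), 0.30)
  ## of (0,0.1) and (0.1,0.1), the smaller generalisation gap loses:
  ## lambda 0.2 vs 0.1, the second configuration wins
  expect_gt(hyperparameter_score(0.0, 0.1), hyperparameter_score(0.1, 0.1))
  ## monotone in eV at fixed eT, antitone in eT at fixed eV
  expect_gt(hyperparameter_score(0.1, 0.3), hyperparameter_score(0.1, 0.2))
  expect_gt(hyperparameter_score(0.1, 0.2), hyperparameter_score(0.2, 0.2))
  expect_error(hyperparameter_score(1.2, 0.1), "\\[0,1\\]")
})

test_that("grid search selects the argmin-lambda configuration", {
  ds <- small_dataset()
  sub <- subset_trials(ds$train, seq_len(60L))
  grid <- list(decoder_config(n_kernels = 4L, seed = 1L),
               decoder_config(n_kernels = 8L, seed = 1L))
  hs <- hyperparameter_search(grid, sub, n_folds = 3L, seed = 5L,
                              max_epochs = 10L)
  expect_equal(nrow(hs$table), 2L)
  ## oracle: recompute lambda from the table and compare the argmin
  lam <- hs$table$eV + (hs$table$eV - hs$table$eT)
  expect_equal(hs$table$lambda, lam)
  expect_equal(hs$best_index, which.min(lam))
  expect_equal(hs$best_score, min(lam))
})

test_that("stratified folding rejects impossible splits", {
  ds <- small_dataset()
  ## 2 trials of one class cannot stratify into 3 folds with all classes
  idx <- c(which(ds$train$meta$label == ds$train$classes[1])[1:2],
           which(ds$train$meta$label == ds$train$classes[2])[1:6])
  sub <- subset_trials(ds$train, idx)
  expect_error(
    hyperparameter_search(list(decoder_config(seed = 1L)), sub, n_folds = 3L,
                          seed = 1L, max_epochs = 10L),
    "class")
})

test_that("ensembles demand distinct seeds and flag the best run as primary", {
  ds <- small_dataset()
  expect_error(train_ensemble(decoder_config(seed = 1L), ds$train, n_runs = 2L,
                              seeds = c(5L, 5L)), "distinct")
  sub <- subset_trials(ds$train, seq_len(72L))
  ens <- train_ensemble(decoder_config(n_kernels = 4L, seed = 1L), sub,
                        n_runs = 2L, max_epochs = 10L)
  expect_length(ens$models, 2L)
  expect_equal(ens$primary, which.min(ens$val_losses))
  ## n_runs = 1: that run is primary
  e1 <- train_ensemble(decoder_config(n_kernels = 4L, seed = 2L), sub,
                       n_runs = 1L, max_epochs = 10L)
  expect_equal(e1$primary, 1L)
})

test_that("checkpoints round-trip through disk", {
  m <- small_model()
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_decoder(m, path)
  back <- load_decoder(path)
  expect_identical(back$dense$W, m$dense$W)
  expect_true(file.exists(sub("\\.rds$", "_history.csv", path)))
  set.seed(1)
  X <- matrix(rnorm(1000 * 3), 1000, 3)
  expect_identical(neuroattrib:::nn_forward(back, X)$probs,
                   neuroattrib:::nn_forward(m, X)$probs)
})
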