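## ---- ADAM optimiser over the model's parameter list ----

adam_init <- function(model) {
  zero_like <- function(p) if (is.null(p)) NULL else p * 0
  st <- list(t = 0L,
             dense = list(W = zero_like(model$dense$W), b = zero_like(model$dense$b)),
             layers = lapply(model$layers, function(ly) {
               list(W = zero_like(ly$W), b = zero_like(ly$b),
                    gamma = if (!is.null(ly$bn)) zero_like(ly$bn$gamma) else NULL,
                    beta = if (!is.null(ly$bn)) zero_like(ly$bn$beta) else NULL)
             }))
  list(m = st, v = st)
}

adam_update <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mh <- m / (1 - b1^t)
  vh <- v / (1 - b2^t)
  list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

adam_step <- function(model, grads, state, lr) {
  state$m$t <- state$m$t + 1L
  t <- state$m$t
  upd <- function(p, g, mm, vv) {
    if (is.null(p)) return(list(p = NULL, m = NULL, v = NULL))
    adam_update(p, g, mm, vv, lr, t)
  }
  u <- upd(model$dense$W, grads$dense$W, state$m$dense$W, state$v$dense$W)
  model$dense$W <- u$p; state$m$dense$W <- u$m; state$v$dense$W <- u$v
  u <- upd(model$dense$b, grads$dense$b, state$m$dense$b, state$v$dense$b)
  model$dense$b <- u$p; state$m$dense$b <- u$m; state$v$dense$b <- u$v
  for (l in seq_along(model$layers)) {
    u <- upd(model$layers[[l]]$W, grads$layers[[l]]$W,
             state$m$layers[[l]]$W, state$v$layers[[l]]$W)
    model$layers[[l]]$W <- u$p; state$m$layers[[l]]$W <- u$m; state$v$layers[[l]]$W <- u$v
    u <- upd(model$layers[[l]]$b, grads$layers[[l]]$b,
             state$m$layers[[l]]$b, state$v$layers[[l]]$b)
    model$layers[[l]]$b <- u$p; state$m$layers[[l]]$b <- u$m; state$v$layers[[l]]$b <- u$v
    if (!is.null(model$layers[[l]]$bn)) {
      u <- upd(model$layers[[l]]$bn$gamma, grads$layers[[l]]$gamma,
               state$m$layers[[l]]$gamma, state$v$layers[[l]]$gamma)
      model$layers[[l]]$bn$gamma <- u$p
      state$m$layers[[l]]$gamma <- u$m; state$v$layers[[l]]$gamma <- u$v
      u <- upd(model$layers[[l]]$bn$beta, grads$layers[[l]]$beta,
               state$m$layers[[l]]$beta, state$v$layers[[l]]$beta)
      model$layers[[l]]$bn$beta <- u$p
      state$m$layers[[l]]$beta <- u$m; state$v$layers[[l]]$beta <- u$v
    }
  }
  list(model = model, state = state)
}

#' Early-stopping decision from a validation-loss history
#'
#' Training stops (after a grace period of `grace` evaluations, one per
#' epoch) when either (i) the evaluation loss has been worse than its
#' previous best for `patience` consecutive evaluations, or (ii) the
#' standard deviation of the last `sd_window` recorded evaluation losses
#' does not exceed `sd_tol`.
#'
#' @param losses numeric vector of per-epoch validation losses so far.
#' @param grace minimum number of epochs before stopping is considered.
#' @param patience consecutive worse-than-best evaluations triggering stop.
#' @param sd_window,sd_tol window length and threshold for the
#'   loss-plateau rule.
#' @return List with `stop` (logical) and `rule` ("none", "patience" or
#'   "plateau").
#' @export
early_stop_decision <- function(losses, grace = 10L, patience = 3L,
                                sd_window = 10L, sd_tol = 0.01) {
  n <- length(losses)
  if (n < grace) return(list(stop = FALSE, rule = "none"))
  ## consecutive evaluations worse than the running best
  best <- cummin(losses)
  worse_streak <- 0L
  for (i in seq_len(n)) {
    if (i > 1L && losses[i] > best[i - 1L]) worse_streak <- worse_streak + 1L
    else worse_streak <- 0L
  }
  if (worse_streak >= patience) return(list(stop = TRUE, rule = "patience"))
  if (n >= sd_window && stats::sd(losses[(n - sd_window + 1L):n]) <= sd_tol) {
    return(list(stop = TRUE, rule = "plateau"))
  }
  list(stop = FALSE, rule = "none")
}

dataset_targets <- function(ds, classes) {
  match(ds$meta$label, classes)
}

## mean cross-entropy and accuracy on a dataset, inference mode
eval_loss_acc <- function(model, ds, batch = 256L) {
  y <- dataset_targets(ds, model$classes)
  n <- ncol(ds$x)
  loss <- 0
  correct <- 0L
  for (i0 in seq(1L, n, by = batch)) {
    i1 <- min(i0 + batch - 1L, n)
    fw <- nn_forward(model, ds$x[, i0:i1, drop = FALSE], train = FALSE)
    p <- fw$probs[cbind(seq_len(i1 - i0 + 1L), y[i0:i1])]
    loss <- loss + sum(-log(pmax(p, 1e-12)))
    correct <- correct + sum(max.col(fw$probs) == y[i0:i1])
  }
  list(loss = loss / n, acc = correct / n)
}

## stratified random split of trial indices (by label)
stratified_split <- function(labels, fraction) {
  idx_val <- integer(0)
  for (cl in unique(labels)) {
    ii <- which(labels == cl)
    k <- max(1L, round(fraction * length(ii)))
    idx_val <- c(idx_val, sample(ii, k))
  }
  sort(idx_val)
}

#' Train a decoder with ADAM and early stopping
#'
#' Minimises the cross-entropy loss with ADAM. The validation loss is
#' evaluated once per epoch; training stops per [early_stop_decision()]
#' (never before `min_epochs`, never after `max_epochs`). Weights are
#' restored to the epoch with the best validation loss.
#'
#' @param model an untrained `decoder_model` from [build_model()].
#' @param train_set a `trial_dataset`.
#' @param val_split_fraction fraction of `train_set` held out for
#'   validation (ignored when `val_set` is given).
#' @param max_epochs,min_epochs epoch window.
#' @param seed seed controlling the split, shuffling and dropout.
#' @param val_set optional explicit validation `trial_dataset`.
#' @param early_stopping set FALSE to always train `max_epochs` epochs
#'   (used by the label-randomization memorization fits).
#' @param restore_best return the weights of the best-validation epoch
#'   (default); FALSE keeps the final-epoch weights (memorization fits).
#' @return The trained `decoder_model` with a `history` data.frame
#'   (epoch, train_loss, train_acc, val_loss, val_acc) and
#'   `stop_rule`/`best_epoch` fields.
#' @export
train <- function(model, train_set, val_split_fraction = 0.1,
                  max_epochs = 100L, min_epochs = 10L, seed = 1L,
                  val_set = NULL, early_stopping = TRUE, restore_best = TRUE) {
  classes <- sort(unique(train_set$meta$label))
  stop_if_not(length(classes) >= 2L, "need at least 2 classes in training data")
  model$classes <- classes
  stop_if_not(length(classes) == model$n_classes,
              "model built for %d classes but data has %d",
              model$n_classes, length(classes))
  set.seed(derive_seed(seed, "trainsplit"))
  if (is.null(val_set)) {
    vi <- stratified_split(train_set$meta$label, val_split_fraction)
    val_set <- subset_trials(train_set, vi)
    fit_set <- subset_trials(train_set, setdiff(seq_len(ncol(train_set$x)), vi))
  } else {
    fit_set <- train_set
  }
  y <- dataset_targets(fit_set, classes)
  n <- ncol(fit_set$x)
  bs <- model$config$batch_size
  lr <- model$config$learning_rate
  state <- adam_init(model)
  hist <- data.frame()
  best_loss <- Inf
  best_model <- model
  best_epoch <- 0L
  stop_rule <- "max_epochs"
  set.seed(derive_seed(seed, "trainloop"))
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0L
    for (i0 in seq(1L, n, by = bs)) {
      ii <- ord[i0:min(i0 + bs - 1L, n)]
      fw <- nn_forward(model, fit_set$x[, ii, drop = FALSE], train = TRUE,
                       keep_cache = TRUE)
      p <- fw$probs[cbind(seq_along(ii), y[ii])]
      bl <- mean(-log(pmax(p, 1e-12)))
      if (!is.finite(bl)) {
        stop(sprintf("non-finite training loss at epoch %d; reduce the learning rate",
                     epoch), call. = FALSE)
      }
      ep_loss <- ep_loss + bl * length(ii)
      ep_correct <- ep_correct + sum(max.col(fw$probs) == y[ii])
      grads <- nn_backward(model, fw, y[ii])
      ## commit batch-norm running statistics
      mom <- model$config$bn_momentum
      for (l in seq_along(model$layers)) {
        if (!is.null(model$layers[[l]]$bn)) {
          st <- fw$bn_batch[[l]]
          model$layers[[l]]$bn$rmean <- (1 - mom) * model$layers[[l]]$bn$rmean + mom * st$mu
          model$layers[[l]]$bn$rvar <- (1 - mom) * model$layers[[l]]$bn$rvar + mom * st$va
        }
      }
      up <- adam_step(model, grads, state, lr)
      model <- up$model
      state <- up$state
    }
    ev <- eval_loss_acc(model, val_set)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / n,
                                   train_acc = ep_correct / n,
                                   val_loss = ev$loss, val_acc = ev$acc))
    if (ev$loss < best_loss) {
      best_loss <- ev$loss
      best_model <- model
      best_epoch <- epoch
    }
    if (early_stopping && epoch >= min_epochs) {
      dec <- early_stop_decision(hist$val_loss, grace = min_epochs)
      if (dec$stop) { stop_rule <- dec$rule; break }
    }
  }
  out <- if (restore_best) best_model else model
  out$history <- hist
  out$trained <- TRUE
  out$stop_rule <- stop_rule
  out$best_epoch <- best_epoch
  out$best_val_loss <- best_loss
  out
}

#' Decoding accuracy and confusion matrix on a dataset
#'
#' @param model a trained `decoder_model`.
#' @param ds a `trial_dataset`.
#' @return List with `accuracy` and a row-normalised C x C `confusion`
#'   matrix (rows = true class, alphabetical order).
#' @export
evaluate <- function(model, ds) {
  stop_if_not(ncol(ds$x) > 0L, "dataset is empty")
  y <- dataset_targets(ds, model$classes)
  stop_if_not(!anyNA(y), "dataset contains labels unknown to the model")
  pred <- predict_classes(model, ds$x)
  C <- model$n_classes
  cm <- matrix(0, C, C, dimnames = list(model$classes, model$classes))
  for (i in seq_along(y)) cm[y[i], pred[i]] <- cm[y[i], pred[i]] + 1
  rs <- rowSums(cm)
  cmn <- sweep(cm, 1, pmax(rs, 1), "/")
  list(accuracy = mean(pred == y), confusion = cmn, counts = cm)
}

predict_classes <- function(model, X, batch = 256L) {
  n <- ncol(X)
  out <- integer(n)
  for (i0 in seq(1L, n, by = batch)) {
    i1 <- min(i0 + batch - 1L, n)
    fw <- nn_forward(model, X[, i0:i1, drop = FALSE], train = FALSE)
    out[i0:i1] <- max.col(fw$probs)
  }
  out
}

#' Score a hyper-parameter configuration set by cross-validated lambda
#'
#' Each configuration is scored by `lambda = eV + (eV - eT)` where `eT`
#' and `eV` are the mean training and validation decoding errors over
#' `n_folds` stratified folds; the configuration with the lowest lambda
#' wins. The score penalises both poor validation performance and a large
#' generalisation gap.
#'
#' @param grid list of [decoder_config()] objects.
#' @param train_data a `trial_dataset`.
#' @param n_folds number of cross-validation folds.
#' @param seed seed for fold assignment and training.
#' @param max_epochs cap on training epochs per fold fit.
#' @return List with `best` (winning config), `best_score` and a `table`
#'   data.frame of (config index, eT, eV, lambda).
#' @export
hyperparameter_search <- function(grid, train_data, n_folds = 3L, seed = 1L,
                                  max_epochs = 100L) {
  stop_if_not(length(grid) >= 1L, "empty configuration grid")
  labels <- train_data$meta$label
  classes <- sort(unique(labels))
  set.seed(derive_seed(seed, "folds"))
  fold <- integer(length(labels))
  for (cl in classes) {
    ii <- sample(which(labels == cl))
    fold[ii] <- rep_len(seq_len(n_folds), length(ii))
  }
  for (f in seq_len(n_folds)) {
    if (length(unique(labels[fold != f])) < length(classes) ||
        length(unique(labels[fold == f])) < length(classes)) {
      stop("stratified folding failed: fold ", f, " misses a class; ",
           "need at least n_folds trials per class", call. = FALSE)
    }
  }
  rows <- lapply(seq_along(grid), function(gi) {
    cfg <- grid[[gi]]
    eT <- eV <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      tr <- subset_trials(train_data, which(fold != f))
      va <- subset_trials(train_data, which(fold == f))
      mdl <- build_model(cfg, train_data$grid, length(classes))
      mdl <- train(mdl, tr, val_set = va, max_epochs = max_epochs,
                   seed = derive_seed(seed, sprintf("hp%d_f%d", gi, f)))
      eT[f] <- 1 - evaluate(mdl, tr)$accuracy
      eV[f] <- 1 - evaluate(mdl, va)$accuracy
    }
    data.frame(config = gi, eT = mean(eT), eV = mean(eV),
               lambda = hyperparameter_score(mean(eT), mean(eV)))
  })
  tab <- do.call(rbind, rows)
  best <- which.min(tab$lambda)
  list(best = grid[[best]], best_index = best, best_score = tab$lambda[best],
       table = tab)
}

#' Hyper-parameter performance score
#'
#' @param eT mean training decoding error in [0,1].
#' @param eV mean validation decoding error in [0,1].
#' @return `lambda = eV + (eV - eT)`.
#' @export
hyperparameter_score <- function(eT, eV) {
  stop_if_not(all(eT >= 0 & eT <= 1) && all(eV >= 0 & eV <= 1),
              "errors must lie in [0,1]")
  eV + (eV - eT)
}

#' Train a multi-seed decoder ensemble
#'
#' Performs `n_runs` training runs of the same configuration with distinct
#' seeds and fresh 90/10 train/validation splits; the run with the best
#' validation loss is flagged as the primary model.
#'
#' @param config a [decoder_config()].
#' @param data a `trial_dataset`.
#' @param n_runs number of runs.
#' @param seeds optional vector of `n_runs` distinct seeds.
#' @param ... passed to [train()].
#' @return A `decoder_ensemble`: list of models, `primary` index, `seeds`.
#' @export
train_ensemble <- function(config, data, n_runs = 10L, seeds = NULL, ...) {
  stop_if_not(n_runs >= 1L, "n_runs must be >= 1")
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_runs), function(i) derive_seed(config$seed, paste0("run", i)),
                    integer(1))
  }
  stop_if_not(length(seeds) == n_runs, "need one seed per run")
  stop_if_not(!anyDuplicated(seeds), "ensemble seeds must be distinct")
  classes <- sort(unique(data$meta$label))
  models <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- seeds[i]
    mdl <- build_model(cfg, data$grid, length(classes))
    models[[i]] <- train(mdl, data, seed = seeds[i], ...)
  }
  losses <- vapply(models, `[[`, numeric(1), "best_val_loss")
  structure(list(models = models, primary = which.min(losses), seeds = seeds,
                 val_losses = losses),
            class = "decoder_ensemble")
}

#' @export
print.decoder_ensemble <- function(x, ...) {
  cat(sprintf("decoder_ensemble: %d runs, primary = run %d (val loss %.4f)\n",
              length(x$models), x$primary, min(x$val_losses)))
  invisible(x)
}

#' Save / load a trained decoder checkpoint
#'
#' Checkpoints are RDS containers holding parameters, configuration and
#' training history; the training log is additionally written as CSV.
#'
#' @param model a `decoder_model`.
#' @param path output path (".rds").
#' @return `path` invisibly / the restored model.
#' @export
save_decoder <- function(model, path) {
  saveRDS(model, path)
  if (!is.null(model$history)) {
    utils::write.csv(model$history, sub("\\.rds$", "_history.csv", path),
                     row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  m <- readRDS(path)
  stop_if_not(inherits(m, "decoder_model"), "not a decoder checkpoint: %s", path)
  m
}
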