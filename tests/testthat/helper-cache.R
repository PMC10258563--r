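## Shared fixtures, built lazily and memoised for the whole test run.
## The expensive objects (default-scale dataset, 10-run ensemble, full
## benchmark result) are shared across test files so each is built once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- force(expr)
  .fixture_cache[[name]]
}

## small dataset for unit tests: 10^3 grid, 5 subjects, 3 classes
small_dataset <- function() {
  cached("small_ds", generate_dataset(synthetic_config(
    grid_shape = c(10L, 10L, 10L), n_subjects = 5L,
    trials_per_class_per_subject = 8L, n_classes = 3L,
    n_blobs_per_class = 2L, redundant_cluster_count = 1L,
    blob_fwhm = 3, noise_sd = 0.6, seed = 101L)))
}

## quickly trained small model on the small dataset
small_model <- function() {
  cached("small_model", {
    ds <- small_dataset()
    m <- build_model(decoder_config(n_kernels = 4L, seed = 7L),
                     c(10L, 10L, 10L), 3L)
    train(m, ds$train, seed = 7L, max_epochs = 20L)
  })
}

## bias-free, batch-norm-free toy CNN on an 8^3 grid (for sum-rule audits)
toy_net <- function() {
  cached("toy", {
    scfg <- synthetic_config(grid_shape = c(8L, 8L, 8L), n_subjects = 5L,
                             trials_per_class_per_subject = 6L, n_classes = 3L,
                             n_blobs_per_class = 2L, redundant_cluster_count = 0L,
                             blob_fwhm = 2.5, noise_sd = 0.5, seed = 21L)
    ds <- generate_dataset(scfg)
    cfg <- decoder_config(n_conv_layers = 2L, n_kernels = 4L, kernel_size = 3L,
                          batch_size = 16L, dropout_rate = 0, seed = 7L,
                          use_bn = FALSE, use_bias = FALSE, check_grid = FALSE)
    m <- build_model(cfg, scfg$grid_shape, 3L)
    m <- train(m, ds$train, seed = 7L, max_epochs = 15L)
    list(model = m, data = ds)
  })
}

## conv-free model: f(x) = w.x + b per class, exercised by the
## closed-form concordance checks
linear_model <- function(n_vox = 8L, n_classes = 2L, seed = 5L) {
  cfg <- decoder_config(n_conv_layers = 0L, dropout_rate = 0, seed = seed,
                        use_bn = FALSE, check_grid = FALSE)
  m <- build_model(cfg, c(2L, 2L, 2L), n_classes)
  m$classes <- letters[seq_len(n_classes)]
  m
}

## the full default benchmark (study conditions): built once, reused by
## the acceptance-criteria tests
default_benchmark <- function() {
  cached("bench", run_benchmark(benchmark_config(seed = 1L), verbose = FALSE))
}
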