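#' Full-benchmark configuration
#'
#' Bundles all stage configurations of the benchmark pipeline
#' (generate -> [search ->] train ensemble -> attribute -> aggregate ->
#' evaluate -> report) with a single master seed. Per-stage seeds are
#' derived deterministically from the master seed via [derive_seed()], so
#' individual stages can be re-run in isolation.
#'
#' @param synthetic a [synthetic_config()].
#' @param decoder a [decoder_config()] (ignored when `decoder_grid` is
#'   given and the search stage selects a configuration).
#' @param decoder_grid optional list of configs for a hyper-parameter
#'   search stage.
#' @param n_model_runs ensemble size (default 10).
#' @param methods attribution methods to benchmark.
#' @param attribution an [attribution_params()].
#' @param mi an [mi_spec()]; per-trial sanity-check comparisons use
#'   `mi_subsample` voxels.
#' @param occlusion_rates faithfulness occlusion-rate grid.
#' @param smoothing_fwhm group-stage smoothing (voxels).
#' @param attrib_trials_cap cap on test trials attributed per model run
#'   (NULL = all). Trials are subsampled class-stratified, deterministic
#'   under the master seed.
#' @param sanity_checks run the randomization checks.
#' @param sanity_runs number of ensemble runs entering the sanity checks.
#' @param sanity_trials_cap test-trial cap for the sanity checks.
#' @param n_epochs_memorize fixed epochs for the shuffled-label fit.
#' @param mi_subsample voxel subsample for per-trial MI comparisons.
#' @param baseline_method reference method of the statistical comparison.
#' @param seed master seed.
#' @return A `benchmark_config` object.
#' @export
benchmark_config <- function(synthetic = synthetic_config(),
                             decoder = decoder_config(),
                             decoder_grid = NULL,
                             n_model_runs = 10L,
                             methods = setdiff(attribution_methods(), "input"),
                             attribution = attribution_params(),
                             mi = mi_spec(),
                             occlusion_rates = seq(0, 0.5, by = 0.025),
                             smoothing_fwhm = 1.5,
                             attrib_trials_cap = 48L,
                             sanity_checks = TRUE,
                             sanity_runs = 3L,
                             sanity_trials_cap = 12L,
                             n_epochs_memorize = 300L,
                             mi_subsample = 1500L,
                             baseline_method = "deeplift",
                             seed = 1L) {
  stop_if_not(all(methods %in% attribution_methods()),
              "unknown attribution method in config")
  stop_if_not(baseline_method %in% methods, "baseline_method must be benchmarked")
  structure(list(synthetic = synthetic, decoder = decoder,
                 decoder_grid = decoder_grid, n_model_runs = as.integer(n_model_runs),
                 methods = methods, attribution = attribution, mi = mi,
                 occlusion_rates = occlusion_rates,
                 smoothing_fwhm = smoothing_fwhm,
                 attrib_trials_cap = attrib_trials_cap,
                 sanity_checks = isTRUE(sanity_checks),
                 sanity_runs = as.integer(sanity_runs),
                 sanity_trials_cap = sanity_trials_cap,
                 n_epochs_memorize = as.integer(n_epochs_memorize),
                 mi_subsample = mi_subsample,
                 baseline_method = baseline_method,
                 seed = as.integer(seed)),
            class = "benchmark_config")
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 977)) %% .Machine$integer.max)
}

## class-stratified deterministic trial subsample
cap_trials <- function(ds, cap, seed) {
  if (is.null(cap) || ncol(ds$x) <= cap) return(ds)
  set.seed(derive_seed(seed, "trialcap"))
  per <- max(1L, floor(cap / length(unique(ds$meta$label))))
  idx <- unlist(lapply(split(seq_len(ncol(ds$x)), ds$meta$label),
                       function(ii) sample(ii, min(per, length(ii)))))
  subset_trials(ds, sort(idx))
}

#' Run the full attribution benchmark
#'
#' Executes every stage of the benchmark on synthetic data and collects
#' tidy result tables: decoding performance, ground-truth/GLM alignment
#' MI per method, occlusion-faithfulness curves and critical rates,
#' randomization sanity checks, the method comparison statistics, and a
#' four-row summary verdict matrix (aligned / faithful / data-sensitive /
#' model-sensitive). When `out_dir` is given, all tables are written as
#' CSV, stage outputs as RDS checkpoints (reused on re-run when `resume`)
#' and a provenance record (config hash, seeds, package version).
#'
#' @param config a [benchmark_config()].
#' @param out_dir optional output directory.
#' @param resume reuse existing stage checkpoints in `out_dir`.
#' @param until stop after this stage: "generate", "train", "attribute",
#'   or "report" (default, the full pipeline). Earlier stages are loaded
#'   from checkpoints or computed as needed, so each stage consumes the
#'   previous stage's on-disk outputs.
#' @param verbose log stage progress.
#' @return A `benchmark_result` list (partial when `until` stops early);
#'   see Details.
#' @export
run_benchmark <- function(config, out_dir = NULL, resume = FALSE,
                          until = c("report", "generate", "train", "attribute"),
                          verbose = TRUE) {
  until <- match.arg(until)
  t_all <- Sys.time()
  log_stage <- function(...) if (verbose) message(sprintf("[%s] %s",
                                                          format(Sys.time(), "%H:%M:%S"),
                                                          sprintf(...)))
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ckpt <- function(name, expr) {
    path <- if (!is.null(out_dir)) file.path(out_dir, paste0(name, ".rds")) else NULL
    if (resume && !is.null(path) && file.exists(path)) {
      log_stage("stage %s: reusing checkpoint", name)
      return(readRDS(path))
    }
    val <- tryCatch(expr, error = function(e) {
      stop("benchmark stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    if (!is.null(path)) saveRDS(val, path)
    val
  }

  ## -- generate --------------------------------------------------------
  log_stage("stage generate: synthetic dataset")
  scfg <- config$synthetic
  scfg$seed <- derive_seed(config$seed, "generate")
  data <- ckpt("dataset", generate_dataset(scfg))
  if (until == "generate") {
    return(structure(list(config = config, config_hash = config_hash(config),
                          data = data, until = until),
                     class = "benchmark_result"))
  }

  ## -- hyper-parameter search (optional) -------------------------------
  dcfg <- config$decoder
  search_tab <- NULL
  if (!is.null(config$decoder_grid)) {
    log_stage("stage search: %d configurations", length(config$decoder_grid))
    hs <- ckpt("search", hyperparameter_search(config$decoder_grid, data$train,
                                               seed = derive_seed(config$seed, "search")))
    dcfg <- hs$best
    search_tab <- hs$table
  }

  ## -- train ensemble --------------------------------------------------
  log_stage("stage train: ensemble of %d runs", config$n_model_runs)
  dcfg$seed <- derive_seed(config$seed, "train")
  ens <- ckpt("ensemble", train_ensemble(dcfg, data$train,
                                         n_runs = config$n_model_runs))
  perf <- data.frame(run = seq_along(ens$models),
                     test_accuracy = vapply(ens$models, function(m)
                       evaluate(m, data$test)$accuracy, numeric(1)),
                     val_loss = ens$val_losses,
                     primary = seq_along(ens$models) == ens$primary)
  if (until == "train") {
    return(structure(list(config = config, config_hash = config_hash(config),
                          data = data, ensemble = ens, performance = perf,
                          search = search_tab, until = until),
                     class = "benchmark_result"))
  }

  ## -- attribute -------------------------------------------------------
  eval_set <- cap_trials(data$test, config$attrib_trials_cap, config$seed)
  log_stage("stage attribute: %d methods x %d runs x %d trials",
            length(config$methods), length(ens$models), ncol(eval_set$x))
  apars <- config$attribution
  apars$seed <- derive_seed(config$seed, "attrib")
  attribs <- ckpt("attributions", {
    lapply(seq_along(ens$models), function(ri) {
      attribute_trials(ens$models[[ri]], eval_set, config$methods, apars,
                       reference_data = data$train)
    })
  })

  if (until == "attribute") {
    return(structure(list(config = config, config_hash = config_hash(config),
                          data = data, ensemble = ens, performance = perf,
                          search = search_tab, attributions = attribs,
                          until = until),
                     class = "benchmark_result"))
  }

  ## -- aggregate + reference maps --------------------------------------
  log_stage("stage aggregate: two-stage GLM maps")
  refs <- ckpt("references", {
    subj <- lapply(split(seq_len(ncol(data$train$x)), data$train$meta$subject_id),
                   function(ii) subject_contrast(subset_trials(data$train, ii)))
    list(glm_group = group_contrast(subj, config$smoothing_fwhm),
         ground_truth = ground_truth_reference(data$patterns))
  })
  agg <- ckpt("aggregated", {
    lapply(stats::setNames(config$methods, config$methods), function(mm) {
      aggregate_attributions(lapply(attribs, `[[`, mm), config$smoothing_fwhm)$group
    })
  })

  ## -- evaluate: alignment ---------------------------------------------
  log_stage("stage evaluate: alignment MI")
  mask <- data$test$mask
  mi_cfg <- config$mi
  mi_cfg$seed <- derive_seed(config$seed, "mi")
  classes <- data$train$classes
  alignment <- do.call(rbind, lapply(config$methods, function(mm) {
    do.call(rbind, lapply(seq_along(classes), function(ci) {
      gt <- alignment_score(agg[[mm]]$stat[, ci], refs$ground_truth[, ci],
                            mask, mi_cfg)
      gl <- alignment_score(agg[[mm]]$stat[, ci], refs$glm_group$stat[, ci],
                            mask, mi_cfg)
      data.frame(method = mm, class = classes[ci],
                 reference = c("ground_truth", "glm"),
                 mi = c(as.numeric(gt$mi), as.numeric(gl$mi)),
                 pearson = c(gt$pearson, gl$pearson))
    }))
  }))
  ## per-run alignment (run-level observations for the statistics): each
  ## run's attribution maps go through the same two-stage aggregation
  ## before comparison with the planted reference
  run_alignment <- do.call(rbind, lapply(seq_along(attribs), function(ri) {
    do.call(rbind, lapply(config$methods, function(mm) {
      gr <- aggregate_attributions(attribs[[ri]][mm], config$smoothing_fwhm)$group
      mi_vals <- vapply(seq_along(classes), function(ci) {
        as.numeric(alignment_score(gr$stat[, ci], refs$ground_truth[, ci],
                                   mask, mi_cfg)$mi)
      }, numeric(1))
      data.frame(run = ri, method = mm, mi = mean(mi_vals))
    }))
  }))

  ## -- evaluate: faithfulness ------------------------------------------
  log_stage("stage evaluate: occlusion faithfulness")
  faith <- ckpt("faithfulness", {
    lapply(seq_along(ens$models), function(ri) {
      faithfulness_curve(ens$models[[ri]], eval_set, attribs[[ri]],
                         rate_grid = config$occlusion_rates)
    })
  })
  critical <- do.call(rbind, lapply(seq_along(faith), function(ri) {
    cbind(run = ri, attr(faith[[ri]], "critical"))
  }))
  curves <- do.call(rbind, lapply(seq_along(faith), function(ri) {
    cbind(run = ri, faith[[ri]])
  }))

  ## -- evaluate: sanity checks -----------------------------------------
  sanity <- NULL
  if (config$sanity_checks) {
    log_stage("stage evaluate: randomization sanity checks")
    sset <- cap_trials(eval_set, config$sanity_trials_cap, config$seed + 1L)
    mi_fast <- mi_cfg
    mi_fast$voxel_subsample <- config$mi_subsample
    sruns <- seq_len(min(config$sanity_runs, length(ens$models)))
    smethods <- union(config$methods, "input")
    sanity <- ckpt("sanity", {
      shuffled_model <- NULL
      shuffled_sets <- NULL
      sub_idx <- match(sset$meta$trial_id, eval_set$meta$trial_id)
      rows <- list()
      for (ri in sruns) {
        mdl <- ens$models[[ri]]
        ## the original model maps for the sanity trials already exist in
        ## the attribution stage output; reuse them
        sets_a <- lapply(attribs[[ri]][smethods[smethods %in% names(attribs[[ri]])]],
                         function(a) {
                           a$relevance <- a$relevance[, sub_idx, drop = FALSE]
                           a$meta <- sset$meta
                           a$relevance_sum <- colSums(a$relevance)
                           a
                         })
        for (mm in setdiff(smethods, names(sets_a))) {
          sets_a[[mm]] <- attribute_trials(mdl, sset, mm, apars,
                                           reference_data = data$train)
        }
        self_mi <- vapply(smethods, function(mm) {
          mean_attribution_mi(sets_a[[mm]], sets_a[[mm]], sset$mask, mi_fast)
        }, numeric(1))
        dr <- data_randomization_check(mdl, data$train, sset, smethods,
                                       n_epochs_memorize = config$n_epochs_memorize,
                                       params = apars, spec = mi_fast,
                                       seed = derive_seed(config$seed, "drand"),
                                       shuffled_model = shuffled_model,
                                       sets_a = sets_a, self_mi = self_mi,
                                       sets_b = shuffled_sets)
        shuffled_model <- attr(dr, "model")
        shuffled_sets <- attr(dr, "sets_b")
        mr <- model_randomization_check(mdl, sset, smethods, params = apars,
                                        spec = mi_fast,
                                        seed = derive_seed(config$seed, paste0("mrand", ri)),
                                        sets_a = sets_a, self_mi = self_mi)
        rows[[length(rows) + 1L]] <-
          rbind(cbind(run = ri, check = "data", dr,
                      train_acc = unname(attr(dr, "guards")["train_acc"]),
                      val_acc = unname(attr(dr, "guards")["val_acc"])),
                cbind(run = ri, check = "model", mr, train_acc = NA, val_acc = NA))
      }
      do.call(rbind, rows)
    })
  }

  ## -- statistics + summary matrix -------------------------------------
  log_stage("stage report: method comparison and summary")
  cmp_seed <- derive_seed(config$seed, "compare")
  safe_compare <- function(scores) {
    tryCatch(suppressWarnings(compare_methods(scores, config$baseline_method,
                                              seed = cmp_seed)),
             error = function(e) NULL)  # too few runs for the interval criterion
  }
  comparisons <- list(
    alignment = safe_compare(data.frame(method = run_alignment$method,
                                        score = run_alignment$mi)),
    faithfulness = safe_compare(data.frame(method = critical$method,
                                           score = critical$critical_rate)))
  summary_mat <- benchmark_summary_matrix(run_alignment, critical, sanity,
                                          config$methods, cmp_seed)

  res <- structure(list(config = config, config_hash = config_hash(config),
                        data = data, ensemble = ens, performance = perf,
                        search = search_tab,
                        references = refs, aggregated = agg,
                        alignment = alignment, run_alignment = run_alignment,
                        faithfulness = curves, critical = critical,
                        sanity = sanity, comparisons = comparisons,
                        summary = summary_mat,
                        elapsed = as.numeric(difftime(Sys.time(), t_all, units = "secs"))),
                   class = "benchmark_result")
  if (!is.null(out_dir)) write_benchmark_report(res, out_dir)
  res
}

## Table-2-style verdict matrix. A method is checked on an axis when it is
## not meaningfully worse than the best-performing method on that axis
## (94% interval of the difference from the best method includes zero or
## favours the method).
benchmark_summary_matrix <- function(run_alignment, critical, sanity, methods,
                                     seed) {
  verdict <- function(scores, higher_better) {
    means <- tapply(scores$score, scores$method, mean)
    best <- names(means)[if (higher_better) which.max(means) else which.min(means)]
    out <- stats::setNames(rep(TRUE, length(methods)), methods)
    cmp <- tryCatch(suppressWarnings(compare_methods(scores, best, seed = seed)),
                    error = function(e) NULL)
    if (is.null(cmp)) {
      ## too few observations for intervals: median split on the means
      med <- stats::median(means)
      keep <- if (higher_better) means >= med else means <= med
      return(stats::setNames(keep[methods], methods))
    }
    for (i in seq_len(nrow(cmp))) {
      worse <- if (higher_better) cmp$coefficient[i] < 0 else cmp$coefficient[i] > 0
      if (cmp$meaningful[i] && worse && cmp$method[i] %in% methods) {
        out[cmp$method[i]] <- FALSE
      }
    }
    out
  }
  rows <- list(
    aligned = verdict(data.frame(method = run_alignment$method,
                                 score = run_alignment$mi), TRUE),
    faithful = verdict(data.frame(method = critical$method,
                                  score = critical$critical_rate), FALSE))
  if (!is.null(sanity)) {
    for (chk in c("data", "model")) {
      sc <- sanity[sanity$check == chk & sanity$method %in% methods, ]
      nm <- paste0(chk, "_sensitive")
      if (length(unique(sc$run)) >= 3L) {
        rows[[nm]] <- verdict(data.frame(method = sc$method, score = sc$mi), FALSE)
      } else {
        ## too few run-level observations for the interval criterion:
        ## fall back to a median split
        med <- stats::median(tapply(sc$mi, sc$method, mean))
        rows[[nm]] <- tapply(sc$mi, sc$method, mean)[methods] <= med
      }
    }
  }
  mat <- do.call(rbind, lapply(rows, function(r) r[methods]))
  rownames(mat) <- names(rows)
  colnames(mat) <- methods
  mat
}

#' @export
print.benchmark_result <- function(x, ...) {
  if (!is.null(x$until) && x$until != "report") {
    cat(sprintf("benchmark_result (config %s): partial, up to stage %s\n",
                x$config_hash, x$until))
    return(invisible(x))
  }
  cat(sprintf("benchmark_result (config %s, %.0f s)\n", x$config_hash, x$elapsed))
  cat(sprintf("  mean test accuracy: %.3f (chance %.3f)\n",
              mean(x$performance$test_accuracy),
              1 / length(x$data$train$classes)))
  cat("  summary matrix (TRUE = performs comparably well):\n")
  print(ifelse(x$summary, "yes", " no"), quote = FALSE)
  invisible(x)
}

## write tidy CSV tables + provenance
write_benchmark_report <- function(res, out_dir) {
  wr <- function(df, name) utils::write.csv(df, file.path(out_dir, name),
                                            row.names = FALSE)
  wr(res$performance, "performance.csv")
  wr(res$alignment, "alignment.csv")
  wr(res$run_alignment, "alignment_by_run.csv")
  wr(res$faithfulness, "faithfulness_curves.csv")
  wr(res$critical, "critical_rates.csv")
  if (!is.null(res$sanity)) wr(res$sanity, "sanity_checks.csv")
  cmps <- Filter(Negate(is.null), res$comparisons)
  if (length(cmps)) {
    cmp <- do.call(rbind, lapply(names(cmps), function(nm) {
      cbind(metric = nm, as.data.frame(cmps[[nm]]))
    }))
    wr(cmp, "method_comparison.csv")
  }
  sm <- as.data.frame(res$summary)
  sm <- cbind(evaluation = rownames(res$summary), sm)
  wr(sm, "summary_matrix.csv")
  prov <- data.frame(key = c("config_hash", "master_seed", "package_version",
                             "r_version", "timestamp"),
                     value = c(res$config_hash, res$config$seed,
                               as.character(utils::packageVersion("neuroattrib")),
                               paste(R.version$major, R.version$minor, sep = "."),
                               format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  wr(prov, "provenance.csv")
  invisible(out_dir)
}
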