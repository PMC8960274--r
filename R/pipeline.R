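#' Default end-to-end run configuration
#'
#' A nested list mirroring the pipeline stages (phantom cohort, preprocess,
#' model, train, evaluate, explain, assign). One global `seed` fans out to
#' per-stage seeds by stable hashing of (seed, stage name), so individual
#' stages can be re-run in isolation.
#'
#' @param seed global seed.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       phantom = list(n_patients = 60L, class_proportions = rep(1 / 3, 3),
                      repeat_scan_prob = 0.2, n_undifferentiated = 10L,
                      params = list()),
       preprocess = list(target_extent = c(24L, 24L, 16L), margin_fraction = 0.1),
       model = list(n_stages = 3L, channels_per_stage = c(8L, 16L, 32L),
                    dropout_rate = 0.1, leaky_slope = 0.01,
                    lambda_weight = 0.9),
       train = list(k = 5L, epochs = 15L, batch_size = 4L,
                    learning_rate = 1e-3, representation = "mask"),
       evaluate = list(threshold = 0.5),
       explain = list(n_scans = 3L, top_fraction = 0.01, dilation_radius = 3),
       assign = list(threshold = 0.75))
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_run_config(config$seed %||% 1L)
  utils::modifyList(base, config)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(config, f)
  unname(tools::md5sum(f))
}

#' Run the full pipeline: generate, preprocess, train, evaluate, explain, assign
#'
#' Orchestrates every stage on a synthetic cohort and writes all artifacts to
#' `out_dir`: the cohort (`cohort/` + `manifest.csv`), out-of-fold
#' `predictions.csv`, tidy `metrics.csv`, guided-backprop heat maps and
#' hotspot masks (NIfTI) with a localization CSV, `triage.csv` for the
#' undifferentiated scans, and a machine-readable `summary.json` (config
#' hash, package version, per-stage wall times and row counts). Re-running
#' with the same configuration and seed reproduces `predictions.csv`
#' deterministically.
#'
#' @param config nested configuration list (see [default_run_config]) or a
#'   YAML file path; missing entries take defaults.
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return `out_dir`, invisibly; the summary list as attribute `summary`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir, verbose = FALSE) {
  config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  timings <- list(); counts <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    if (verbose) message(sprintf("[%s] %.1fs", name, timings[[name]]))
    out
  }

  manifest <- stage("generate", {
    params <- do.call(phantom_params, config$phantom$params)
    m <- generate_cohort(config$phantom$n_patients,
                         config$phantom$class_proportions,
                         config$phantom$repeat_scan_prob,
                         params, seed = stage_seed(seed, "generate"),
                         n_undifferentiated = config$phantom$n_undifferentiated)
    write_cohort(m, file.path(out_dir, "cohort"))
  })
  counts$scans <- nrow(manifest)

  prep <- stage("preprocess", {
    prepare_cohort(manifest, config$preprocess$target_extent,
                   dir = file.path(out_dir, "cohort"),
                   margin_fraction = config$preprocess$margin_fraction)
  })

  cv <- stage("train", {
    cfg <- csae_config(config$preprocess$target_extent,
                       n_stages = config$model$n_stages,
                       channels_per_stage = config$model$channels_per_stage,
                       dropout_rate = config$model$dropout_rate,
                       leaky_slope = config$model$leaky_slope,
                       lambda_weight = config$model$lambda_weight)
    cv <- cross_validate(prep, k = config$train$k, config = cfg,
                         representation = config$train$representation,
                         epochs = config$train$epochs,
                         batch_size = config$train$batch_size,
                         learning_rate = config$train$learning_rate,
                         seed = stage_seed(seed, "train"), verbose = verbose)
    write.csv(cv$predictions, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    for (i in seq_along(cv$models)) {
      h <- cv$models[[i]]$history
      write.csv(h, file.path(out_dir, sprintf("history%d.csv", i - 1)),
                row.names = FALSE)
      save_csae(cv$models[[i]], file.path(out_dir, sprintf("fold%d.ckpt", i - 1)))
    }
    cv
  })
  counts$predictions <- nrow(cv$predictions)

  metrics <- stage("evaluate", {
    met <- evaluate_predictions(cv$predictions, config$evaluate$threshold)
    write.csv(as.data.frame(met), file.path(out_dir, "metrics.csv"),
              row.names = FALSE)
    met
  })

  localization <- stage("explain", {
    # attribute a few correctly classified lesioned test scans with the model
    # of the fold that held them out
    pred <- cv$predictions
    pcols <- grep("^p_", names(pred), value = TRUE)
    hit <- pred$true_class == sub("^p_", "", pcols)[
      max.col(as.matrix(pred[, pcols]))] & pred$true_class != "control"
    lesioned <- pred$true_class != "control"
    # prefer correctly classified lesioned scans, fall back to any lesioned
    pick <- utils::head(unique(c(which(hit), which(lesioned))),
                        config$explain$n_scans)
    rows <- match(pred$scan_id[pick], prep$manifest$scan_id)
    loc <- data.frame()
    for (j in seq_along(pick)) {
      fidx <- pred$fold[pick[j]] + 1L
      rmat <- representation_matrix(prep, rows[j], cv$representation,
                                    stats = cv$stats[[fidx]])
      hm <- guided_backprop(cv$models[[fidx]], rmat$x, pred$true_class[pick[j]])
      hs <- hotspot_mask(hm, config$explain$top_fraction)
      lesion <- array(prep$lesion[, rows[j]], prep$extent)
      score <- if (any(lesion > 0))
        lesion_localization_score(hs, lesion, config$explain$dilation_radius)
        else NA_real_
      id <- pred$scan_id[pick[j]]
      write_volume(hm, file.path(out_dir, sprintf("heatmap_%s.nii.gz", id)),
                   binary = FALSE)
      write_volume(hs, file.path(out_dir, sprintf("hotspots_%s.nii.gz", id)))
      loc <- rbind(loc, data.frame(scan_id = id, fold = fidx - 1L,
                                   localization = score))
    }
    write.csv(loc, file.path(out_dir, "localization.csv"), row.names = FALSE)
    loc
  })

  triage <- stage("assign", {
    ua <- which(prep$manifest$class_label == "undifferentiated")
    if (length(ua)) {
      scored <- predict_cohort(cv, prep, ua)
      val <- triage_synthetic_validation(scored, config$assign$threshold)
      write.csv(val$triage, file.path(out_dir, "triage.csv"), row.names = FALSE)
      val
    } else NULL
  })

  summary <- list(package_version = as.character(utils::packageVersion("csae")),
                  r_version = R.version.string,
                  seed = seed,
                  config_hash = config_hash(config),
                  stage_seconds = timings,
                  counts = counts,
                  macro_auroc = metrics$macro_auroc,
                  triage_agreement = if (!is.null(triage)) triage$agreement else NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  attr(out_dir, "summary") <- summary
  invisible(out_dir)
}
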