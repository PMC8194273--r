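#' Pipeline configuration
#'
#' Collects every knob of the end-to-end analysis with the study
#' defaults: 0.5/50 Hz Butterworth order-4 pre-filtering, 60 s
#' non-overlapping windows, MVAR order p = 5, the 5 canonical bands on a
#' 1 Hz grid, a 200-tree forest with min 10 samples per leaf and 2.5%
#' features per tree, and 7-fold cross-validation. The config
#' round-trips losslessly through YAML.
#'
#' @param manifest path to a cohort manifest CSV, or NULL when running on
#'   a synthetic cohort.
#' @param synthetic a \code{cohort_spec}, or NULL when reading real data.
#' @param low_cut,high_cut,filter_order Butterworth settings.
#' @param window_seconds,overlap_fraction segmentation.
#' @param p MVAR order.
#' @param bands band definition data.frame.
#' @param grid_step frequency grid step, Hz.
#' @param n_trees,min_leaf,feature_fraction forest hyperparameters.
#' @param cv_mode \code{"subject_unaware"} or
#'   \code{"leave_p_subjects_out"}.
#' @param k folds.
#' @param per_fold subjects per fold per class (lpso mode).
#' @param seed master seed.
#' @param output_dir where \code{\link{run_pipeline}} writes its report.
#' @param fs fallback sampling rate for CSV recordings.
#' @param plots write top-10 importance bar charts (PDF) with the report.
#' @return a list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(manifest = NULL, synthetic = NULL,
                            low_cut = 0.5, high_cut = 50, filter_order = 4,
                            window_seconds = 60, overlap_fraction = 0,
                            p = 5, bands = default_bands(), grid_step = 1,
                            n_trees = 200, min_leaf = 10,
                            feature_fraction = 0.025,
                            cv_mode = c("subject_unaware",
                                        "leave_p_subjects_out"),
                            k = 7, per_fold = c(2, 2), seed = 1,
                            output_dir = "eegforest_report", fs = NULL,
                            plots = TRUE) {
  cv_mode <- match.arg(cv_mode)
  if (is.null(manifest) && is.null(synthetic))
    stop_validation("config needs either a manifest path or a synthetic cohort_spec")
  structure(list(manifest = manifest, synthetic = synthetic,
                 low_cut = low_cut, high_cut = high_cut,
                 filter_order = filter_order,
                 window_seconds = window_seconds,
                 overlap_fraction = overlap_fraction, p = p, bands = bands,
                 grid_step = grid_step, n_trees = n_trees,
                 min_leaf = min_leaf, feature_fraction = feature_fraction,
                 cv_mode = cv_mode, k = k, per_fold = per_fold,
                 seed = seed, output_dir = output_dir, fs = fs,
                 plots = plots),
            class = "pipeline_config")
}

#' Read / write a pipeline config as YAML
#'
#' @param config a \code{pipeline_config}.
#' @param path YAML file.
#' @return \code{path} (write) or a \code{pipeline_config} (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- unclass(config)
  out$bands <- as.list(out$bands)
  out$synthetic <- if (!is.null(out$synthetic)) {
    s <- unclass(out$synthetic)
    s$base_couplings <- as.list(s$base_couplings)
    s$class_couplings <- as.list(s$class_couplings)
    s
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$bands <- as.data.frame(raw$bands, stringsAsFactors = FALSE)
  if (!is.null(raw$synthetic)) {
    s <- raw$synthetic
    raw$synthetic <- cohort_spec(
      m = s$m, fs = s$fs,
      base_couplings = as.data.frame(s$base_couplings),
      class_couplings = as.data.frame(s$class_couplings),
      subject_sigma = s$subject_sigma, noise_sd = s$noise_sd,
      n_per_class = s$n_per_class, minutes = s$minutes, seed = s$seed,
      channel_names = s$channel_names)
  }
  raw$per_fold <- as.numeric(raw$per_fold)
  do.call(pipeline_config, raw[!vapply(raw, is.null, TRUE)])
}

pipeline_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline and write a report bundle
#'
#' Ingests the cohort (manifest or synthetic), band-limits and segments
#' every recording, extracts the GPDC/dDTF band features, cross-validates
#' the forest, and writes to \code{config$output_dir}: the feature matrix
#' (\code{features.csv}), per-fold ROC points (\code{roc_fold_<k>.csv})
#' and AUCs (\code{auc.csv}), the importance summary
#' (\code{importance_summary.csv}), top-10 importance bar charts
#' (\code{importance_min.pdf}, \code{importance_avg.pdf}; optional), and
#' \code{run_metadata.json} echoing the configuration.
#'
#' @param config a \code{pipeline_config}.
#' @return invisibly, a list with \code{features}, \code{cv},
#'   \code{summary}, \code{mean_auc}, \code{output_dir}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    recs <- cohort$recordings
  } else {
    recs <- read_cohort(config$manifest, fs = config$fs)
  }
  pipeline_log("ingest", "%d recordings, %d channels, fs = %g Hz",
               length(recs), nrow(recs[[1]]$data), recs[[1]]$fs)

  recs <- lapply(recs, bandlimit, low_cut = config$low_cut,
                 high_cut = config$high_cut, order = config$filter_order)
  segs <- unlist(lapply(recs, segment_recording,
                        window_seconds = config$window_seconds,
                        overlap_fraction = config$overlap_fraction),
                 recursive = FALSE)
  pipeline_log("segment", "%d segments of %g s", length(segs),
               config$window_seconds)

  fm <- features_from_segments(segs, p = config$p, bands = config$bands,
                               grid_step = config$grid_step)
  pipeline_log("features", "%d segments x %d features", nrow(fm$x), ncol(fm$x))
  write_features_csv(fm, file.path(config$output_dir, "features.csv"))

  folds <- if (config$cv_mode == "subject_unaware")
    subject_unaware_folds(fm, k = config$k)
  else leave_p_subjects_out_folds(fm, k = config$k,
                                  per_fold = config$per_fold,
                                  seed = config$seed)
  cv <- run_cv(fm, folds, n_trees = config$n_trees,
               min_leaf = config$min_leaf,
               feature_fraction = config$feature_fraction,
               seed = config$seed)
  aucs <- vapply(cv, `[[`, 0, "auc")
  pipeline_log("cv", "%s, %d folds, mean AUC %.3f", config$cv_mode,
               config$k, mean(aucs))

  utils::write.csv(data.frame(fold = seq_along(aucs), auc = aucs),
                   file.path(config$output_dir, "auc.csv"),
                   row.names = FALSE)
  for (fr in cv)
    utils::write.csv(fr$roc,
                     file.path(config$output_dir,
                               sprintf("roc_fold_%d.csv", fr$fold_index)),
                     row.names = FALSE)

  summ <- summarize_importance(cv)
  utils::write.csv(data.frame(feature = names(summ$i_min),
                              i_min = unname(summ$i_min),
                              i_avg = unname(summ$i_avg),
                              rank_min = rank(-summ$i_min, ties.method = "first"),
                              rank_avg = rank(-summ$i_avg, ties.method = "first")),
                   file.path(config$output_dir, "importance_summary.csv"),
                   row.names = FALSE)

  if (isTRUE(config$plots)) {
    plot_top_importance(summ, "min",
                        file.path(config$output_dir, "importance_min.pdf"))
    plot_top_importance(summ, "avg",
                        file.path(config$output_dir, "importance_avg.pdf"))
  }

  meta <- list(config = list(cv_mode = config$cv_mode, k = config$k,
                             per_fold = config$per_fold, p = config$p,
                             window_seconds = config$window_seconds,
                             overlap_fraction = config$overlap_fraction,
                             low_cut = config$low_cut,
                             high_cut = config$high_cut,
                             filter_order = config$filter_order,
                             grid_step = config$grid_step,
                             n_trees = config$n_trees,
                             min_leaf = config$min_leaf,
                             feature_fraction = config$feature_fraction,
                             seed = config$seed),
               n_segments = nrow(fm$x), n_features = ncol(fm$x),
               mean_auc = mean(aucs),
               r_version = as.character(getRversion()),
               package_version = as.character(utils::packageVersion("eegforest")))
  jsonlite::write_json(meta, file.path(config$output_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(features = fm, cv = cv, summary = summ,
                 mean_auc = mean(aucs), output_dir = config$output_dir))
}

# horizontal bar chart of the top-10 features of one ranking
plot_top_importance <- function(summ, by = c("min", "avg"), path, k = 10) {
  by <- match.arg(by)
  rk <- if (by == "min") summ$rank_min else summ$rank_avg
  rk <- utils::head(rk, k)
  grDevices::pdf(path, width = 8, height = 5)
  op <- graphics::par(mar = c(4, 12, 2, 1))
  # restore par while the pdf device is still current, then close it
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::barplot(rev(rk$importance), names.arg = rev(rk$feature),
                    horiz = TRUE, las = 1, col = "steelblue",
                    xlab = sprintf("normalized Gini importance (%s over folds)", by),
                    main = sprintf("Top %d features by I_%s", k, by))
  invisible(path)
}
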