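#' Describe one directed coupling of a ground-truth MVAR model
#'
#' A plain row (\code{src != dst}, \code{resonance_hz = NA}) adds the tap
#' \code{A_lag[dst, src] += coef}. A resonator row (\code{src == dst}
#' with \code{resonance_hz} set) installs a damped-oscillator AR(2)
#' block on that channel's diagonal,
#' \code{A_1 += 2 rho cos(2 pi f0 / fs)}, \code{A_2 -= rho^2}, with
#' damping \code{rho = coef}; such a channel's spectrum peaks near
#' \code{f0}, which is what localizes downstream connectivity effects in
#' a frequency band. A cross row with \code{resonance_hz} set is sugar
#' for resonator-on-source plus the tap.
#'
#' @param src,dst channel indices (1-based).
#' @param coef coupling coefficient, or damping rho for a resonator row.
#' @param lag tap lag (ignored for resonator rows).
#' @param resonance_hz oscillator frequency in Hz, or NA.
#' @return a one-row data.frame.
#' @export
coupling <- function(src, dst, coef, lag = 1, resonance_hz = NA) {
  data.frame(src = src, dst = dst, lag = lag, coef = coef,
             resonance_hz = resonance_hz)
}

#' Ground-truth specification for a synthetic two-class cohort
#'
#' Defines the generative study conditions: per-subject MVAR models built
#' from a base coupling list shared by both classes plus class-effect
#' couplings present only in patients (class 1), with per-subject
#' multiplicative coefficient jitter modelling inter-subject
#' heterogeneity. Each subject's recording is a stationary simulation of
#' their model.
#'
#' @param m channel count.
#' @param fs sampling rate in Hz.
#' @param base_couplings data.frame of \code{\link{coupling}} rows shared
#'   by both classes.
#' @param class_couplings couplings added for class-1 subjects only (may
#'   have zero rows for a null cohort).
#' @param subject_sigma standard deviation of the per-subject
#'   multiplicative jitter applied to every coupling coefficient.
#' @param noise_sd per-channel innovation standard deviation (recycled to
#'   length m).
#' @param n_per_class subjects per class.
#' @param minutes recording length per subject.
#' @param seed master seed for the cohort.
#' @param channel_names optional names (length m).
#' @return an object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(m, fs, base_couplings, class_couplings,
                        subject_sigma = 0, noise_sd = 1,
                        n_per_class = 6, minutes = 3, seed = 1,
                        channel_names = NULL) {
  for (df in list(base_couplings, class_couplings)) {
    if (nrow(df) > 0 && !all(c("src", "dst", "lag", "coef") %in% names(df)))
      stop_validation("coupling tables need columns src, dst, lag, coef")
  }
  channel_names <- channel_names %||% sprintf("CH%d", seq_len(m))
  if (length(channel_names) != m)
    stop_validation("need %d channel names", m)
  structure(list(m = m, fs = fs, base_couplings = base_couplings,
                 class_couplings = class_couplings,
                 subject_sigma = subject_sigma,
                 noise_sd = rep_len(noise_sd, m),
                 n_per_class = n_per_class, minutes = minutes,
                 seed = seed, channel_names = channel_names),
            class = "cohort_spec")
}

# expand coupling rows (with jitter multipliers) into coefficient matrices
couplings_to_coeffs <- function(rows, jitter, m, fs, p_min = 1) {
  p <- max(p_min, if (nrow(rows) > 0) max(rows$lag, 2 * any(!is.na(rows$resonance_hz))) else 1)
  if (nrow(rows) > 0 && any(!is.na(rows$resonance_hz))) p <- max(p, 2)
  coeffs <- lapply(seq_len(p), function(k) matrix(0, m, m))
  if (nrow(rows) == 0) return(coeffs)
  for (r in seq_len(nrow(rows))) {
    coef <- rows$coef[r] * jitter[r]
    if (!is.na(rows$resonance_hz[r])) {
      w0 <- 2 * pi * rows$resonance_hz[r] / fs
      s <- rows$src[r]
      rho <- if (rows$src[r] == rows$dst[r]) coef else 0.9
      # pole angle chosen so the AR(2) spectral peak (not the pole angle)
      # sits at the requested frequency: the peak satisfies
      # cos(w_peak) = cos(theta) (1 + rho^2) / (2 rho)
      ctheta <- 2 * rho * cos(w0) / (1 + rho^2)
      coeffs[[1]][s, s] <- coeffs[[1]][s, s] + 2 * rho * ctheta
      coeffs[[2]][s, s] <- coeffs[[2]][s, s] - rho^2
      if (rows$src[r] != rows$dst[r]) {
        k <- rows$lag[r]
        coeffs[[k]][rows$dst[r], rows$src[r]] <-
          coeffs[[k]][rows$dst[r], rows$src[r]] + coef
      }
    } else {
      k <- rows$lag[r]
      coeffs[[k]][rows$dst[r], rows$src[r]] <-
        coeffs[[k]][rows$dst[r], rows$src[r]] + coef
    }
  }
  coeffs
}

#' Build one subject's ground-truth MVAR model
#'
#' Combines base and (for class 1) class-effect couplings, applies the
#' subject's multiplicative coefficient jitter (seeded deterministically
#' from the cohort seed and subject index), and verifies stability,
#' redrawing the jitter up to 100 times if needed.
#'
#' @param spec a \code{cohort_spec}.
#' @param subject_index integer index within the cohort (1-based).
#' @param class_label 0 or 1.
#' @return a stable \code{mvar_model}.
#' @export
build_subject_model <- function(spec, subject_index, class_label) {
  rows <- spec$base_couplings
  if (class_label == 1) rows <- rbind(rows, spec$class_couplings)
  noise_cov <- diag(spec$noise_sd^2, spec$m)
  sseed <- derive_seed(spec$seed, 2L * subject_index + class_label)
  with_seed(sseed, {
    for (attempt in seq_len(100)) {
      jitter <- if (nrow(rows) > 0 && spec$subject_sigma > 0)
        1 + stats::rnorm(nrow(rows), 0, spec$subject_sigma)
      else rep(1, max(1, nrow(rows)))
      coeffs <- couplings_to_coeffs(rows, jitter, spec$m, spec$fs)
      model <- mvar_model(coeffs, noise_cov, spec$fs, spec$channel_names)
      if (spectral_radius(model) < 1) return(model)
      if (spec$subject_sigma == 0) break
    }
    stop_validation("could not build a stable model for subject %d after 100 jitter draws",
                    subject_index)
  })
}

#' Generate a synthetic two-class cohort
#'
#' Simulates every subject's model for \code{minutes * 60 * fs} samples
#' (controls first, then patients) and returns the recordings together
#' with a manifest data.frame and the ground-truth models. Fully
#' reproducible given the spec's seed.
#'
#' @param spec a \code{cohort_spec}.
#' @param dir optional directory; when given, recordings are written as
#'   row-per-channel CSVs and a \code{manifest.csv} alongside them.
#' @return a list with \code{recordings}, \code{manifest},
#'   \code{models}.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_samples <- as.integer(round(spec$minutes * 60 * spec$fs))
  ids <- c(sprintf("C%02d", seq_len(spec$n_per_class)),
           sprintf("P%02d", seq_len(spec$n_per_class)))
  labels <- rep(c(0L, 1L), each = spec$n_per_class)
  models <- vector("list", length(ids))
  recs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    models[[i]] <- build_subject_model(spec, i, labels[i])
    x <- simulate_mvar(models[[i]], n_samples,
                       seed = derive_seed(spec$seed, 1000L + i))
    recs[[i]] <- recording(ids[i], labels[i], spec$channel_names, spec$fs, x)
  }
  manifest <- data.frame(subject_id = ids,
                         path = sprintf("%s.csv", ids),
                         label = labels, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(recs))
      write_recording_csv(recs[[i]], file.path(dir, manifest$path[i]))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(recordings = recs, manifest = manifest, models = models)
}

#' Toy cohort with a planted theta-band directed coupling
#'
#' The default validation scenario: 6 channels (F3, F4, C3, C4, O1, O2)
#' at 110 Hz, 6 + 6 subjects, 9 minutes each. All channels carry mild
#' AR(1) dynamics; O1 additionally carries a sharply damped 6 Hz
#' oscillation (theta; damping 0.95, resonance bandwidth about 1.8 Hz)
#' shared by both classes. Patients (class 1) alone receive a lag-1
#' directed coupling O1 -> O2, whose GPDC signature concentrates at the
#' source resonance, so the discriminative signal lives in the
#' theta-band O1 -> O2 connectivity features -- the planted ground truth
#' the full pipeline should recover. The 110 Hz rate places the 6 Hz
#' pole pair at an angle well separated from DC, keeping the planted
#' effect spectrally distinct from the delta band, and the default
#' coupling of 0.15 keeps GPDC in its informative (non-saturated)
#' regime.
#'
#' @param coupling coupling coefficient of the planted effect
#'   (default 0.15; 0 gives a null cohort).
#' @param subject_sigma per-subject multiplicative jitter SD
#'   (default 0.3).
#' @param rho damping of the source resonator (default 0.95).
#' @param fs sampling rate in Hz (default 110).
#' @param n_per_class,minutes,seed cohort shape and seed.
#' @return a \code{cohort_spec} with attribute \code{planted_features}:
#'   the feature names the effect should surface in.
#' @export
toy_cohort_spec <- function(coupling = 0.15, subject_sigma = 0.3,
                            rho = 0.95, fs = 110,
                            n_per_class = 6, minutes = 9, seed = 1) {
  ch <- c("F3", "F4", "C3", "C4", "O1", "O2")
  base <- do.call(rbind, lapply(c(1, 2, 3, 4, 6), function(i)
    coupling(i, i, coef = 0.4)))
  base <- rbind(base, coupling(5, 5, coef = rho, resonance_hz = 6))
  cls <- if (coupling != 0) coupling(5, 6, coef = coupling) else
    base[0, , drop = FALSE]
  spec <- cohort_spec(m = 6, fs = fs, base_couplings = base,
                      class_couplings = cls,
                      subject_sigma = subject_sigma,
                      n_per_class = n_per_class, minutes = minutes,
                      seed = seed, channel_names = ch)
  attr(spec, "planted_features") <- c("gpdc/theta/O1->O2", "ddtf/theta/O1->O2")
  spec
}

#' Null cohort: same dynamics, no class effect
#'
#' @param ... passed to \code{\link{toy_cohort_spec}}.
#' @return a \code{cohort_spec} whose two classes share the same
#'   generative model (up to subject jitter).
#' @export
null_cohort_spec <- function(...) {
  toy_cohort_spec(coupling = 0, ...)
}

#' Cohort with strong subject heterogeneity on a shared coupling
#'
#' Benchmark for the subject-unaware vs leave-p-subjects-out gap: both
#' classes carry a flat O1 -> O2 coupling (base 0.25), patients get an
#' extra +0.2 on the same entry, and a large multiplicative jitter
#' (SD 0.4) makes subjects overlap across classes. Within-subject
#' segment variation stays small, so a classifier that has seen the test
#' subject during training (subject-unaware CV) scores much better than
#' one evaluated on unseen subjects.
#'
#' @param base_coupling,class_delta,subject_sigma coupling structure.
#' @param n_per_class,minutes,seed cohort shape and seed.
#' @return a \code{cohort_spec}.
#' @export
heterogeneous_cohort_spec <- function(base_coupling = 0.25,
                                      class_delta = 0.2,
                                      subject_sigma = 0.4,
                                      n_per_class = 6, minutes = 9,
                                      seed = 1) {
  ch <- c("F3", "F4", "C3", "C4", "O1", "O2")
  base <- do.call(rbind, lapply(1:6, function(i) coupling(i, i, coef = 0.4)))
  base <- rbind(base, coupling(5, 6, coef = base_coupling))
  cls <- coupling(5, 6, coef = class_delta)
  cohort_spec(m = 6, fs = 110, base_couplings = base,
              class_couplings = cls, subject_sigma = subject_sigma,
              n_per_class = n_per_class, minutes = minutes, seed = seed,
              channel_names = ch)
}

#' End-to-end synthetic benchmark
#'
#' Generates the cohort, extracts band-averaged connectivity features
#' from non-overlapping 60 s windows, runs the requested
#' cross-validation with the forest defaults, and returns the fold
#' results plus the importance summary. This is the workhorse behind
#' the package's ground-truth-recovery validation.
#'
#' @param spec a \code{cohort_spec} (its own seed drives the data).
#' @param mode \code{"lpso"} (leave-p-subjects-out) or \code{"su"}
#'   (subject-unaware).
#' @param k folds; defaults to 3 at toy scale.
#' @param per_fold subjects per fold and class for lpso mode.
#' @param p MVAR order for feature extraction.
#' @param n_trees,min_leaf,feature_fraction forest hyperparameters.
#' @param cv_seed seed for fold assignment and forest training
#'   (defaults to the spec seed).
#' @param window_seconds segmentation window.
#' @return a list with \code{features}, \code{cv}, \code{mean_auc},
#'   \code{summary}.
#' @export
synthetic_benchmark <- function(spec, mode = c("lpso", "su"), k = 3,
                                per_fold = c(2, 2), p = 5,
                                n_trees = 200, min_leaf = 10,
                                feature_fraction = 0.025,
                                cv_seed = NULL, window_seconds = 60) {
  mode <- match.arg(mode)
  cv_seed <- cv_seed %||% spec$seed
  cohort <- generate_cohort(spec)
  segs <- unlist(lapply(cohort$recordings, segment_recording,
                        window_seconds = window_seconds), recursive = FALSE)
  fm <- features_from_segments(segs, p = p)
  folds <- if (mode == "lpso")
    leave_p_subjects_out_folds(fm, k = k, per_fold = per_fold, seed = cv_seed)
  else subject_unaware_folds(fm, k = k)
  cv <- run_cv(fm, folds, n_trees = n_trees, min_leaf = min_leaf,
               feature_fraction = feature_fraction, seed = cv_seed)
  list(features = fm, cv = cv, mean_auc = mean_auc(cv),
       summary = summarize_importance(cv))
}
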