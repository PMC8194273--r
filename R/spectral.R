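#' Canonical EEG frequency bands
#'
#' delta 1-4 Hz, theta 4-8 Hz, alpha 8-12 Hz, beta 12-30 Hz and gamma
#' 30-50 Hz. Band edges are inclusive on both sides when averaged over a
#' 1 Hz grid, so shared edges (4, 8, 12 Hz) contribute to both adjacent
#' bands.
#'
#' @return a data.frame with columns \code{name}, \code{low}, \code{high}.
#' @export
default_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(1, 4, 8, 12, 30),
             high = c(4, 8, 12, 30, 50),
             stringsAsFactors = FALSE)
}

validate_bands <- function(bands, fs) {
  if (!all(c("name", "low", "high") %in% names(bands)))
    stop_validation("bands must have columns name, low, high")
  if (any(bands$low >= bands$high) || any(bands$low <= 0) ||
      any(bands$high >= fs / 2))
    stop_validation("bands must satisfy 0 < low < high < fs/2")
  if (is.unsorted(bands$low)) stop_validation("bands must be sorted by low edge")
  invisible(bands)
}

#' Frequency-domain representation of an MVAR model
#'
#' Evaluates, on a grid of frequencies, the spectral coefficient matrix
#' \deqn{A(f) = \sum_{k=0}^{p} \bar A_k e^{-i 2\pi f k / f_s}, \quad
#'   \bar A_0 = I,\ \bar A_k = -A_k,}
#' the transfer matrix \eqn{H(f) = A(f)^{-1}} and the model spectral
#' matrix \eqn{S(f) = H(f)\, C\, H(f)^H}. These three objects are the
#' basis of all frequency-domain causality measures.
#'
#' @param model an \code{mvar_model}.
#' @param freqs numeric vector of frequencies in Hz, each in (0, fs/2).
#' @return an object of class \code{spectral_stack}: a list with
#'   \code{freqs} and complex arrays \code{A}, \code{H}, \code{S} of
#'   dimension m x m x length(freqs), plus the model's noise covariance.
#' @export
spectral_stack <- function(model, freqs) {
  stopifnot(inherits(model, "mvar_model"))
  freqs <- as.numeric(freqs)
  if (any(freqs <= 0) || any(freqs >= model$fs / 2))
    stop_validation("all frequencies must lie in (0, fs/2) = (0, %g)", model$fs / 2)
  m <- model$m; p <- model$order; nf <- length(freqs)
  A <- array(0i, c(m, m, nf))
  H <- array(0i, c(m, m, nf))
  S <- array(0i, c(m, m, nf))
  eye <- diag(m)
  for (j in seq_len(nf)) {
    w <- -2i * pi * freqs[j] / model$fs
    af <- eye + 0i
    for (k in seq_len(p)) af <- af - model$coeffs[[k]] * exp(w * k)
    hf <- tryCatch(solve(af),
                   error = function(e)
                     stop(sprintf("A(f) is singular at f = %g Hz: %s",
                                  freqs[j], conditionMessage(e)), call. = FALSE))
    A[, , j] <- af
    H[, , j] <- hf
    S[, , j] <- hf %*% model$noise_cov %*% Conj(t(hf))
  }
  structure(list(freqs = freqs, A = A, H = H, S = S,
                 noise_cov = model$noise_cov, m = m, fs = model$fs,
                 channel_names = model$channel_names),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  cat(sprintf("<spectral_stack> m = %d, %d frequencies in [%g, %g] Hz\n",
              x$m, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Generalized partial directed coherence
#'
#' For source channel j and sink channel i,
#' \deqn{GPDC_{ij}(f) = \frac{|A_{ij}(f)| / \sqrt{C_{ii}}}
#'   {\sqrt{\sum_k |A_{kj}(f)|^2 / C_{kk}}},}
#' the noise-variance-weighted, column-normalized outflow measure of
#' Baccala et al. Columns of squared values sum to 1 at every frequency
#' (including the diagonal term); the diagonal is zeroed in the returned
#' array since self-influence carries no pairwise information.
#'
#' @param stack a \code{spectral_stack}.
#' @param noise_cov innovation covariance; defaults to the one stored in
#'   the stack. Must have a strictly positive diagonal.
#' @return an m x m x n_freq non-negative array, zero diagonal; column j
#'   is the source, row i the sink.
#' @export
gpdc <- function(stack, noise_cov = stack$noise_cov) {
  stopifnot(inherits(stack, "spectral_stack"))
  cd <- diag(as.matrix(noise_cov))
  if (any(cd <= 0))
    stop_validation("noise covariance diagonal must be strictly positive")
  m <- stack$m; nf <- length(stack$freqs)
  out <- array(0, c(m, m, nf),
               dimnames = list(stack$channel_names, stack$channel_names, NULL))
  w <- 1 / sqrt(cd)
  for (j in seq_len(nf)) {
    num <- abs(stack$A[, , j]) * w            # rows scaled by 1/sqrt(C_ii)
    den <- sqrt(colSums(num^2))               # per source column
    g <- sweep(num, 2, den, "/")
    diag(g) <- 0
    out[, , j] <- g
  }
  out
}

#' Direct directed transfer function
#'
#' The product of the full-frequency DTF and the partial coherence:
#' \deqn{dDTF_{ij}(f) = \eta_{ij}(f)\,\chi_{ij}(f)}
#' with
#' \deqn{\eta_{ij}(f)^2 = \frac{|H_{ij}(f)|^2}
#'   {\sum_{f'}\sum_k |H_{ik}(f')|^2}, \qquad
#'   \chi_{ij}(f)^2 = \frac{|S^{-1}_{ij}(f)|^2}
#'   {S^{-1}_{ii}(f)\, S^{-1}_{jj}(f)}.}
#' The DTF factor is normalized over the full evaluation grid (per sink
#' row i), so it highlights flows into i relative to everything i
#' receives anywhere in frequency; the partial-coherence factor
#' suppresses mediated (indirect) flows. Diagonal zeroed.
#'
#' @param stack a \code{spectral_stack} evaluated on the full grid over
#'   which the DTF normalization should run.
#' @return an m x m x n_freq non-negative array, zero diagonal.
#' @export
ddtf <- function(stack) {
  stopifnot(inherits(stack, "spectral_stack"))
  m <- stack$m; nf <- length(stack$freqs)
  h2 <- abs(stack$H)^2
  row_tot <- apply(h2, 1, sum)               # per sink, over cols and freqs
  out <- array(0, c(m, m, nf),
               dimnames = list(stack$channel_names, stack$channel_names, NULL))
  for (j in seq_len(nf)) {
    eta <- sqrt(h2[, , j] / row_tot)
    sinv <- tryCatch(solve(stack$S[, , j]),
                     error = function(e)
                       stop(sprintf("S(f) is singular at f = %g Hz: %s",
                                    stack$freqs[j], conditionMessage(e)),
                            call. = FALSE))
    d <- Re(diag(sinv))
    chi <- abs(sinv) / sqrt(outer(d, d))
    dd <- eta * chi
    diag(dd) <- 0
    out[, , j] <- dd
  }
  out
}

#' Average a per-frequency connectivity metric over a band
#'
#' Entrywise arithmetic mean over the grid frequencies
#' \code{low, low + grid_step, ..., high}, endpoints inclusive. Every one
#' of those frequencies must be present in the evaluated grid.
#'
#' @param metric m x m x n_freq array as returned by \code{\link{gpdc}} or
#'   \code{\link{ddtf}}.
#' @param freqs the grid the metric was evaluated on (Hz).
#' @param band numeric \code{c(low, high)} in Hz.
#' @param grid_step grid spacing in Hz (default 1).
#' @return an m x m matrix of band means.
#' @export
band_average <- function(metric, freqs, band, grid_step = 1) {
  wanted <- seq(band[1], band[2], by = grid_step)
  idx <- match(round(wanted / grid_step), round(freqs / grid_step))
  if (anyNA(idx))
    stop_validation("band [%g, %g] is not covered by the evaluated grid",
                    band[1], band[2])
  apply(metric[, , idx, drop = FALSE], c(1, 2), mean)
}

#' Names of the band-averaged connectivity features
#'
#' One feature per metric x band x ordered channel pair, named
#' \code{"metric/band/src->dst"}. Pairs are enumerated source-major in
#' channel order, self-pairs excluded, so m channels give
#' \code{2 * n_bands * m * (m - 1)} features (3420 for the 19-channel
#' 10-20 montage with the 5 default bands).
#'
#' @param channel_names character vector of channel names.
#' @param bands band definition data.frame (default \code{default_bands()}).
#' @param metrics metric labels, in feature-block order.
#' @return character vector of unique feature names.
#' @export
feature_names <- function(channel_names, bands = default_bands(),
                          metrics = c("gpdc", "ddtf")) {
  pairs <- expand.grid(dst = channel_names, src = channel_names,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$src != pairs$dst, ]
  # source-major order: all destinations for src 1, then src 2, ...
  pairs <- pairs[order(match(pairs$src, channel_names),
                       match(pairs$dst, channel_names)), ]
  unlist(lapply(metrics, function(met)
    unlist(lapply(bands$name, function(b)
      sprintf("%s/%s/%s->%s", met, b, pairs$src, pairs$dst)))))
}

#' Band-averaged connectivity feature vector for one segment
#'
#' The per-segment pipeline: fit the MVAR model, evaluate A(f), H(f) and
#' S(f) on the 1 Hz grid spanning all requested bands, compute GPDC and
#' dDTF, average each over every band, and flatten all ordered
#' off-diagonal channel pairs into a named vector. Deterministic given
#' the segment.
#'
#' @param seg an \code{eeg_segment}.
#' @param p MVAR model order (default 5).
#' @param bands band definitions (default \code{default_bands()}).
#' @param grid_step frequency-grid spacing in Hz (default 1).
#' @return a list of class \code{feature_vector} with \code{values},
#'   \code{names}, \code{subject_id}, \code{label}, \code{segment_index}.
#' @export
features_from_segment <- function(seg, p = 5, bands = default_bands(),
                                  grid_step = 1) {
  stopifnot(inherits(seg, "eeg_segment"))
  validate_bands(bands, seg$fs)
  model <- fit_mvar(seg, p = p)
  grid <- seq(min(bands$low), max(bands$high), by = grid_step)
  stack <- spectral_stack(model, grid)
  mats <- list(gpdc = gpdc(stack), ddtf = ddtf(stack))
  ch <- seg$channel_names
  m <- length(ch)
  src_idx <- rep(seq_len(m), each = m)
  dst_idx <- rep(seq_len(m), times = m)
  off <- src_idx != dst_idx
  src_idx <- src_idx[off]; dst_idx <- dst_idx[off]
  values <- unlist(lapply(mats, function(arr)
    unlist(lapply(seq_len(nrow(bands)), function(b) {
      avg <- band_average(arr, grid, c(bands$low[b], bands$high[b]), grid_step)
      avg[cbind(dst_idx, src_idx)]   # row = sink (dst), column = source (src)
    }))), use.names = FALSE)
  nm <- feature_names(ch, bands)
  structure(list(values = as.numeric(values), names = nm,
                 subject_id = seg$subject_id, label = seg$label,
                 segment_index = seg$segment_index),
            class = "feature_vector")
}

#' Assemble a feature matrix from a list of segments
#'
#' @param segments list of \code{eeg_segment} objects (all sharing one
#'   montage).
#' @param p MVAR model order.
#' @param bands band definitions.
#' @param grid_step frequency-grid spacing in Hz.
#' @return an object of class \code{feature_matrix}: a list with
#'   \code{x} (segments x features numeric matrix, feature names as
#'   column names) and \code{meta} (data.frame with \code{subject_id},
#'   \code{label}, \code{segment_index} per row).
#' @export
features_from_segments <- function(segments, p = 5, bands = default_bands(),
                                   grid_step = 1) {
  if (length(segments) == 0) stop_validation("no segments to featurize")
  fvs <- lapply(segments, features_from_segment, p = p, bands = bands,
                grid_step = grid_step)
  x <- do.call(rbind, lapply(fvs, `[[`, "values"))
  colnames(x) <- fvs[[1]]$names
  meta <- data.frame(subject_id = vapply(fvs, `[[`, "", "subject_id"),
                     label = vapply(fvs, `[[`, 0L, "label"),
                     segment_index = vapply(fvs, `[[`, 0L, "segment_index"),
                     stringsAsFactors = FALSE)
  structure(list(x = x, meta = meta), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d segments x %d features, %d subjects (%d patient segments)\n",
              nrow(x$x), ncol(x$x), length(unique(x$meta$subject_id)),
              sum(x$meta$label == 1)))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Index columns \code{subject_id}, \code{segment_index}, \code{label}
#' come first, followed by one column per named feature.
#'
#' @param fm a \code{feature_matrix}.
#' @param path file path.
#' @return \code{path} (write) or a \code{feature_matrix} (read).
#' @export
write_features_csv <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- cbind(fm$meta[, c("subject_id", "segment_index", "label")],
              as.data.frame(fm$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("subject_id", "segment_index", "label")
  if (!all(meta_cols %in% names(df)))
    stop_validation("feature CSV must carry subject_id, segment_index, label columns")
  x <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  structure(list(x = x,
                 meta = data.frame(subject_id = as.character(df$subject_id),
                                   label = as.integer(df$label),
                                   segment_index = as.integer(df$segment_index),
                                   stringsAsFactors = FALSE)),
            class = "feature_matrix")
}
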