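# Independent scalar-loop reference implementations used to cross-check
# the vectorized pipeline. Deliberately naive: explicit loops, no shared
# code with the package internals beyond base matrix inversion.

# A(f) entry by entry
oracle_af <- function(coeffs, fs, f) {
  m <- nrow(coeffs[[1]])
  af <- matrix(0i, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    a <- if (i == j) 1 + 0i else 0 + 0i
    for (k in seq_along(coeffs))
      a <- a - coeffs[[k]][i, j] * exp(-1i * 2 * pi * f * k / fs)
    af[i, j] <- a
  }
  af
}

# GPDC by the literal formula, one entry at a time
oracle_gpdc <- function(coeffs, noise_cov, fs, freqs) {
  m <- nrow(coeffs[[1]])
  out <- array(0, c(m, m, length(freqs)))
  for (q in seq_along(freqs)) {
    af <- oracle_af(coeffs, fs, freqs[q])
    for (j in seq_len(m)) {
      den <- 0
      for (k in seq_len(m))
        den <- den + Mod(af[k, j])^2 / noise_cov[k, k]
      for (i in seq_len(m)) {
        if (i == j) next
        out[i, j, q] <- (Mod(af[i, j]) / sqrt(noise_cov[i, i])) / sqrt(den)
      }
    }
  }
  out
}

# dDTF = full-frequency DTF x partial coherence, literal loops
oracle_ddtf <- function(coeffs, noise_cov, fs, freqs) {
  m <- nrow(coeffs[[1]])
  hs <- lapply(freqs, function(f) solve(oracle_af(coeffs, fs, f)))
  row_tot <- numeric(m)
  for (i in seq_len(m))
    for (q in seq_along(freqs))
      for (k in seq_len(m))
        row_tot[i] <- row_tot[i] + Mod(hs[[q]][i, k])^2
  out <- array(0, c(m, m, length(freqs)))
  for (q in seq_along(freqs)) {
    h <- hs[[q]]
    s <- h %*% noise_cov %*% Conj(t(h))
    sinv <- solve(s)
    for (i in seq_len(m)) for (j in seq_len(m)) {
      if (i == j) next
      eta <- sqrt(Mod(h[i, j])^2 / row_tot[i])
      chi <- Mod(sinv[i, j]) / sqrt(Re(sinv[i, i]) * Re(sinv[j, j]))
      out[i, j, q] <- eta * chi
    }
  }
  out
}

# exhaustive best-split search: every feature, every midpoint, recounting
# class fractions from scratch; same deterministic tie-break contract
oracle_best_split <- function(x, y, min_leaf = 1) {
  n <- length(y)
  if (n < 2 * min_leaf) return(NULL)
  gini_of <- function(labs) {
    p <- mean(labs)
    p * (1 - p) + (1 - p) * p
  }
  parent <- gini_of(y)
  if (parent == 0) return(NULL)
  best <- NULL
  for (f in seq_len(ncol(x))) {
    vals <- sort(unique(x[, f]))
    if (length(vals) < 2) next
    for (v in (vals[-length(vals)] + vals[-1]) / 2) {
      left <- x[, f] <= v
      nl <- sum(left); nr <- n - nl
      if (nl < min_leaf || nr < min_leaf) next
      wg <- (nl * gini_of(y[left]) + nr * gini_of(y[!left])) / n
      dec <- parent - wg
      if (dec > 0 && (is.null(best) || dec > best$decrease))
        best <- list(feature = f, threshold = v, decrease = dec)
    }
  }
  best
}

# AUC by counting concordant / tied pairs
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# random stable MVAR model: scaled down until the companion spectral
# radius is comfortably below 1
random_stable_model <- function(m, p, fs = 100, seed = 1) {
  set.seed(seed)
  coeffs <- lapply(seq_len(p), function(k) matrix(rnorm(m * m, 0, 0.3), m, m))
  model <- mvar_model(coeffs, diag(runif(m, 0.5, 2), m), fs)
  while (spectral_radius(model) >= 0.95) {
    coeffs <- lapply(coeffs, function(a) a * 0.8)
    model <- mvar_model(coeffs, model$noise_cov, fs)
  }
  model
}

# quick segment wrapper around a bare matrix
as_segment <- function(x, fs, subject_id = "S", label = 0L, index = 0L) {
  structure(list(subject_id = subject_id, label = as.integer(label),
                 segment_index = as.integer(index),
                 channel_names = rownames(x) %||% sprintf("ch%d", seq_len(nrow(x))),
                 fs = fs, data = x),
            class = "eeg_segment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
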