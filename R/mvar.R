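#' Construct an MVAR model object
#'
#' An order-p multivariate autoregressive model
#' \deqn{x_t = \sum_{k=1}^p A_k x_{t-k} + u_t,\qquad u_t \sim N(0, C),}
#' where each \eqn{A_k} is an m x m coefficient matrix encoding the lagged
#' directed influence of every channel on every other, and C is the
#' innovation (white-noise) covariance.
#'
#' @param coeffs list of p numeric m x m matrices \eqn{A_1..A_p}.
#' @param noise_cov numeric m x m symmetric covariance matrix with a
#'   strictly positive diagonal.
#' @param fs sampling rate in Hz of the process the model describes.
#' @param channel_names optional channel names (length m).
#' @return an object of class \code{mvar_model}.
#' @export
mvar_model <- function(coeffs, noise_cov, fs, channel_names = NULL) {
  if (!is.list(coeffs) || length(coeffs) < 1)
    stop_validation("coeffs must be a non-empty list of m x m matrices")
  coeffs <- lapply(coeffs, function(a) {
    a <- as.matrix(a); storage.mode(a) <- "double"; a
  })
  m <- nrow(coeffs[[1]])
  ok <- vapply(coeffs, function(a) all(dim(a) == c(m, m)), TRUE)
  if (!all(ok)) stop_validation("all coefficient matrices must be %d x %d", m, m)
  noise_cov <- as.matrix(noise_cov)
  if (!all(dim(noise_cov) == c(m, m)))
    stop_validation("noise_cov must be %d x %d", m, m)
  if (max(abs(noise_cov - t(noise_cov))) > 1e-8 * max(1, max(abs(noise_cov))))
    stop_validation("noise_cov must be symmetric")
  if (any(diag(noise_cov) <= 0))
    stop_validation("noise_cov must have a strictly positive diagonal")
  channel_names <- channel_names %||% sprintf("ch%d", seq_len(m))
  structure(list(order = length(coeffs), coeffs = coeffs,
                 noise_cov = (noise_cov + t(noise_cov)) / 2,
                 m = m, fs = as.numeric(fs),
                 channel_names = as.character(channel_names)),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> m = %d channels, order p = %d, fs = %g Hz, spectral radius %.4f\n",
              x$m, x$order, x$fs, spectral_radius(x)))
  invisible(x)
}

#' Spectral radius of the companion matrix
#'
#' The model is stable (stationary) iff this is < 1.
#'
#' @param model an \code{mvar_model}.
#' @return the largest root modulus of the companion matrix.
#' @export
spectral_radius <- function(model) {
  m <- model$m; p <- model$order
  comp <- matrix(0, m * p, m * p)
  comp[1:m, ] <- do.call(cbind, model$coeffs)
  if (p > 1)
    comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Fit an MVAR model to a segment by multichannel least squares
#'
#' Channel means are subtracted, then the stacked one-step regression over
#' \eqn{t = p+1..n} is solved by ordinary least squares (equivalent to
#' per-equation OLS). The innovation covariance C is the empirical
#' covariance of the residuals with denominator \eqn{n - p}.
#'
#' @param seg an \code{eeg_segment} (or a plain channels x samples matrix,
#'   in which case \code{fs} must be supplied).
#' @param p model order (number of lags), >= 1.
#' @param fs sampling rate; taken from the segment when available.
#' @return an \code{mvar_model}.
#' @export
fit_mvar <- function(seg, p = 5, fs = NULL) {
  x <- as_signal_matrix(seg)
  fs <- fs %||% (if (inherits(seg, "eeg_segment") || inherits(seg, "eeg_recording")) seg$fs else
    stop_validation("fs must be given when fitting a bare matrix"))
  ch <- if (!is.null(rownames(x))) rownames(x) else NULL
  m <- nrow(x); n <- ncol(x)
  if (p < 1) stop_validation("model order p must be >= 1")
  if (n - p < m * p + 1)
    stop_validation("segment too short: %d usable time points < m*p + 1 = %d",
                    n - p, m * p + 1)
  x <- x - rowMeans(x)
  y <- x[, (p + 1):n, drop = FALSE]
  z <- do.call(rbind, lapply(seq_len(p), function(k)
    x[, (p + 1 - k):(n - k), drop = FALSE]))
  g <- tcrossprod(z)                      # (mp) x (mp)
  qg <- qr(g)
  if (qg$rank < m * p)
    stop(sprintf("rank-deficient regressor matrix (rank %d < %d): constant or duplicated channels?",
                 qg$rank, m * p), call. = FALSE)
  a_stack <- t(solve(qg, tcrossprod(z, y)))  # m x (mp)
  resid <- y - a_stack %*% z
  cc <- tcrossprod(resid) / (n - p)
  coeffs <- lapply(seq_len(p), function(k)
    a_stack[, ((k - 1) * m + 1):(k * m), drop = FALSE])
  mvar_model(coeffs, cc, fs, channel_names = ch)
}

#' Residuals of a fitted MVAR model on a segment
#'
#' Recomputes the one-step prediction errors \eqn{u_t} from the segment
#' and the model's coefficients (channel means subtracted first, matching
#' \code{\link{fit_mvar}}).
#'
#' @param model an \code{mvar_model}.
#' @param seg segment or matrix the model was fitted to.
#' @return an m x (n - p) residual matrix.
#' @export
mvar_residuals <- function(model, seg) {
  x <- as_signal_matrix(seg)
  if (nrow(x) != model$m)
    stop_validation("segment has %d channels, model expects %d", nrow(x), model$m)
  p <- model$order; n <- ncol(x)
  x <- x - rowMeans(x)
  y <- x[, (p + 1):n, drop = FALSE]
  pred <- matrix(0, model$m, n - p)
  for (k in seq_len(p))
    pred <- pred + model$coeffs[[k]] %*% x[, (p + 1 - k):(n - k), drop = FALSE]
  y - pred
}

#' Multivariate portmanteau (Ljung-Box) whiteness test on MVAR residuals
#'
#' Computes the Hosking multivariate Ljung-Box statistic on the fitted
#' residual cross-correlations up to \code{max_lag},
#' \deqn{Q = n^2 \sum_{k=1}^{h} \frac{1}{n-k}
#'   \mathrm{tr}(\hat C_k' \hat C_0^{-1} \hat C_k \hat C_0^{-1}),}
#' referred to a chi-square with \eqn{m^2 (h - p)} degrees of freedom.
#' A high p-value (no detectable residual autocorrelation) supports the
#' chosen model order and window length.
#'
#' @param model fitted \code{mvar_model}.
#' @param seg the segment it was fitted to.
#' @param max_lag largest residual lag tested; must exceed the model order.
#' @param alpha significance level for the pass flag (default 0.05).
#' @return a list with \code{statistic}, \code{dof}, \code{p_value} and
#'   \code{pass} (TRUE when p_value > alpha).
#' @export
portmanteau_whiteness <- function(model, seg, max_lag = 20, alpha = 0.05) {
  if (max_lag <= model$order)
    stop_validation("max_lag (%d) must exceed the model order (%d)",
                    max_lag, model$order)
  u <- mvar_residuals(model, seg)
  u <- u - rowMeans(u)
  n <- ncol(u); m <- nrow(u)
  c0 <- tcrossprod(u) / n
  c0i <- solve(c0)
  q <- 0
  for (k in seq_len(max_lag)) {
    ck <- tcrossprod(u[, (k + 1):n, drop = FALSE],
                     u[, 1:(n - k), drop = FALSE]) / n
    q <- q + sum(diag(t(ck) %*% c0i %*% ck %*% c0i)) / (n - k)
  }
  q <- q * n^2
  dof <- m^2 * (max_lag - model$order)
  pval <- stats::pchisq(q, df = dof, lower.tail = FALSE)
  list(statistic = q, dof = dof, p_value = pval, pass = pval > alpha)
}

#' Simulate a stable MVAR process
#'
#' Draws Gaussian innovations with covariance C and iterates the model
#' recursion after a discarded burn-in (default \code{10 * p * m}
#' samples). Reproducible given \code{seed}; the caller's RNG state is
#' left untouched.
#'
#' @param model a stable \code{mvar_model}.
#' @param n_samples number of samples to return.
#' @param seed integer seed (optional but recommended).
#' @param burn_in samples discarded before recording.
#' @return an m x n_samples numeric matrix with channel-name rownames.
#' @export
simulate_mvar <- function(model, n_samples, seed = NULL,
                          burn_in = 10 * model$order * model$m) {
  rho <- spectral_radius(model)
  if (rho >= 1)
    stop_validation("model is unstable: spectral radius %.4f >= 1", rho)
  m <- model$m; p <- model$order
  a_stack <- do.call(cbind, model$coeffs)   # m x (m p)
  lt <- t(chol(model$noise_cov))
  total <- n_samples + burn_in + p
  with_seed(seed, {
    u <- lt %*% matrix(stats::rnorm(m * total), m, total)
    x <- matrix(0, m, total)
    state <- numeric(m * p)                 # [x_{t-1}; ...; x_{t-p}]
    for (t in (p + 1):total) {
      xt <- a_stack %*% state + u[, t]
      x[, t] <- xt
      state <- if (p > 1) c(xt, state[1:(m * (p - 1))]) else as.numeric(xt)
    }
    out <- x[, (burn_in + p + 1):total, drop = FALSE]
    rownames(out) <- model$channel_names
    out
  })
}
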