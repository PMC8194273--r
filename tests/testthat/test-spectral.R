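test_that("spectral stack reduces to identity for a coefficient-free model", {
  z <- mvar_model(list(matrix(0, 2, 2)), diag(2), fs = 100)
  st <- spectral_stack(z, c(1, 10, 40))
  for (q in 1:3) {
    expect_equal(st$A[, , q], diag(2) + 0i, ignore_attr = TRUE)
    expect_equal(st$H[, , q], diag(2) + 0i, ignore_attr = TRUE)
    expect_equal(st$S[, , q], diag(2) + 0i, ignore_attr = TRUE)
  }
})

test_that("univariate AR(1) spectrum matches the closed form", {
  a <- 0.7; fs <- 250
  u <- mvar_model(list(matrix(a, 1, 1)), matrix(1, 1, 1), fs = fs)
  freqs <- c(2, 5, 20, 60)
  st <- spectral_stack(u, freqs)
  for (q in seq_along(freqs)) {
    truth <- 1 / Mod(1 - a * exp(-2i * pi * freqs[q] / fs))^2
    expect_equal(Re(st$S[1, 1, q]), truth, tolerance = 1e-10)
  }
})

test_that("A(f) H(f) = I on every grid frequency of a fitted model", {
  set.seed(21)
  x <- simulate_mvar(random_stable_model(3, 2, seed = 21), 3000, seed = 22)
  st <- spectral_stack(fit_mvar(x, p = 2, fs = 100), 1:49)
  worst <- max(vapply(seq_along(st$freqs), function(q)
    max(Mod(st$A[, , q] %*% st$H[, , q] - diag(3))), 0))
  expect_lt(worst, 1e-8)
  expect_error(spectral_stack(fit_mvar(x, p = 2, fs = 100), c(0, 10)),
               "0, fs/2")
})

test_that("GPDC columns are unit-normalized and vanish without coupling", {
  # diagonal model: no cross-coupling anywhere
  d <- mvar_model(list(diag(c(0.5, -0.3, 0.2))), diag(3), fs = 100)
  g <- gpdc(spectral_stack(d, 1:40))
  expect_true(all(g == 0))

  # column normalization including the diagonal term, over random models
  for (s in 1:20) {
    model <- random_stable_model(3, 2, seed = 100 + s)
    st <- spectral_stack(model, seq(2, 45, by = 4))
    w <- 1 / sqrt(diag(model$noise_cov))
    for (q in seq_along(st$freqs)) {
      num <- Mod(st$A[, , q]) * w
      gg <- sweep(num, 2, sqrt(colSums(num^2)), "/")
      expect_equal(colSums(gg^2), rep(1, 3), tolerance = 1e-10,
                   ignore_attr = TRUE)
      # off-diagonal entries agree with the zero-diagonal output
      g <- gpdc(st)
      expect_equal(g[, , q][upper.tri(gg) | lower.tri(gg)],
                   gg[upper.tri(gg) | lower.tri(gg)], tolerance = 1e-12)
    }
  }
  st <- spectral_stack(random_stable_model(3, 2, seed = 1), c(5, 10))
  expect_error(gpdc(st, noise_cov = diag(c(1, 0, 1))), "positive")
})

test_that("unidirectional coupling yields strictly one-sided GPDC and dDTF", {
  a1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)   # coupling 1 -> 2 only
  model <- mvar_model(list(a1), diag(2), fs = 100)
  st <- spectral_stack(model, 1:49)
  g <- gpdc(st); d <- ddtf(st)
  expect_true(all(g[2, 1, ] > 0.1))          # sink row 2, source col 1
  expect_true(all(g[1, 2, ] <= 1e-10))
  expect_true(all(d[2, 1, ] > 1e-4))
  expect_true(all(d[1, 2, ] <= 1e-10))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("pipeline GPDC/dDTF match the scalar-loop oracle on a 3-channel VAR(2)", {
  coeffs <- list(matrix(c(0.4, 0.35, 0, 0, 0.4, 0.3, 0, 0, 0.4), 3, 3),
                 matrix(c(-0.2, 0.1, 0, 0.15, -0.1, 0, 0, 0.05, -0.15), 3, 3))
  cc <- diag(c(1, 1.5, 0.8))
  model <- mvar_model(coeffs, cc, fs = 120)
  freqs <- 1:50
  st <- spectral_stack(model, freqs)
  g <- gpdc(st); d <- ddtf(st)
  og <- oracle_gpdc(coeffs, cc, 120, freqs)
  od <- oracle_ddtf(coeffs, cc, 120, freqs)
  expect_lt(max(abs(g - og)), 1e-10)
  expect_lt(max(abs(d - od)), 1e-10)
})

test_that("band averaging follows the inclusive 1 Hz grid rule", {
  m <- 2; freqs <- 1:50
  const <- array(3.14, c(m, m, length(freqs)))
  expect_equal(band_average(const, freqs, c(1, 4)),
               matrix(3.14, m, m))
  # identity ramp: metric value = frequency
  ramp <- array(rep(freqs, each = m * m), c(m, m, length(freqs)))
  expect_equal(band_average(ramp, freqs, c(4, 8)), matrix(6, m, m))
  # delta averages exactly the 4 grid points 1..4
  expect_equal(band_average(ramp, freqs, c(1, 4)), matrix(2.5, m, m))
  expect_error(band_average(ramp, freqs, c(40, 60)), "not covered")
})

test_that("feature vectors have the right size, names and determinism", {
  ch19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "C3", "Cz", "C4",
            "P3", "Pz", "P4", "T3", "T4", "T5", "T6", "O1", "O2")
  nm <- feature_names(ch19)
  expect_length(nm, 3420)
  expect_identical(anyDuplicated(nm), 0L)
  expect_false(any(grepl("(\\b\\w+\\b)->\\1", nm)))   # no self-pairs
  expect_length(feature_names(c("a", "b", "c")), 60)

  set.seed(31)
  x <- simulate_mvar(random_stable_model(3, 2, fs = 110, seed = 31),
                     2000, seed = 32)
  seg <- as_segment(x, fs = 110, subject_id = "s9", label = 1L, index = 4L)
  fv1 <- features_from_segment(seg, p = 5)
  fv2 <- features_from_segment(seg, p = 5)
  expect_identical(fv1$values, fv2$values)
  expect_length(fv1$values, 60)
  expect_identical(fv1$names, feature_names(seg$channel_names))
  expect_identical(fv1$subject_id, "s9")
  expect_identical(fv1$label, 1L)
  expect_true(all(is.finite(fv1$values)) && all(fv1$values >= 0))
})

test_that("feature values sit at the named matrix positions", {
  # unidirectional 2-channel model: only src ch1 -> dst ch2 features move
  a1 <- matrix(c(0.5, 0.4, 0, 0.5), 2, 2)
  truth <- mvar_model(list(a1), diag(2), fs = 110,
                      channel_names = c("u", "v"))
  x <- simulate_mvar(truth, 6000, seed = 33)
  fv <- features_from_segment(as_segment(x, 110), p = 2)
  v <- stats::setNames(fv$values, fv$names)
  expect_gt(v[["gpdc/alpha/u->v"]], 0.2)
  expect_lt(v[["gpdc/alpha/v->u"]], 0.1)
})

test_that("feature matrices round-trip through CSV", {
  set.seed(34)
  segs <- lapply(1:3, function(i) {
    x <- simulate_mvar(random_stable_model(3, 1, fs = 110, seed = 40 + i),
                       1500, seed = 50 + i)
    as_segment(x, 110, subject_id = sprintf("S%d", i), label = i %% 2,
               index = 0L)
  })
  fm <- features_from_segments(segs, p = 3)
  expect_identical(dim(fm$x), c(3L, 60L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_features_csv(fm, path)
  back <- read_features_csv(path)
  expect_equal(back$x, fm$x, tolerance = 1e-12)
  expect_identical(back$meta$subject_id, fm$meta$subject_id)
  expect_identical(back$meta$label, as.integer(fm$meta$label))
})
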