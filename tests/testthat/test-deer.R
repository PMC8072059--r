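test_that("elementary kernel matches its definition and the MC powder oracle", {
  t_axis <- c(0, 0.2, 0.5, 1, 2)
  r_axis <- c(20, 30, 45, 60)
  K <- elementary_kernel(t_axis, r_axis)
  expect_equal(K[1, ], rep(1, 4))           # K0(0, r) = 1
  expect_true(all(K >= -0.5 - 1e-9 & K <= 1 + 1e-9))
  # dipolar frequency at 30 A is 52.04/27 MHz
  expect_equal(52.04 / (30 / 10)^3, 1.927, tolerance = 1e-3)
  set.seed(7)
  for (i in seq_along(t_axis)) {
    for (j in seq_along(r_axis)) {
      expect_lt(abs(K[i, j] - mc_kernel(t_axis[i], r_axis[j], n = 4e5)),
                5e-3)
    }
  }
  # high-accuracy quadrature check at a few points
  quad <- function(t, r) {
    z <- seq(0, 1, length.out = 20001)
    w <- 2 * pi * 52.04 / (r / 10)^3
    pracma::trapz(z, cos((1 - 3 * z^2) * w * t))
  }
  for (pt in list(c(0.5, 30), c(1.5, 25), c(2, 50))) {
    expect_equal(elementary_kernel(pt[1], pt[2])[1, 1], quad(pt[1], pt[2]),
                 tolerance = 1e-6)
  }
  expect_error(elementary_kernel(1, -5), "positive")
})

test_that("multipathway signal reduces correctly in limiting cases", {
  ax <- default_r_axis()
  t_axis <- seq(0, 3, by = 0.012)
  dd <- gaussian_pdf(ax, gaussian_params(30, sigma = 0.5))
  # no modulation: constant signal
  v0 <- multipathway_signal(dd, pathway_model(lambda0 = 1, lambda1 = 0), t_axis)
  expect_equal(v0$v, rep(1, length(t_axis)), tolerance = 1e-12)
  # delta-like distribution, no background: L0 + l1 K0(t, r)
  delta <- distance_distribution(ax, as.numeric(ax == 30), normalize = TRUE)
  v1 <- multipathway_signal(delta, pathway_model(0.6, 0.4), t_axis)
  K0 <- elementary_kernel(t_axis, 30)
  expect_equal(v1$v, 0.6 + 0.4 * K0[, 1], tolerance = 1e-12)
  # V(0) = 1 for unit-sum P, L0 + l1 = 1, no background
  expect_equal(v1$v[1], 1)
  # full model equals brute-force term-by-term evaluation
  mod <- pathway_model(0.55, 0.3, 0.1, t02 = 2.5, k_bg = 0.08)
  dd2 <- gaussian_pdf(ax, gaussian_params(42, sigma = 7))
  v2 <- multipathway_signal(dd2, mod, t_axis)
  p <- dd2$p
  brute <- vapply(t_axis, function(t) {
    acc <- 0
    for (k in seq_along(ax)) {
      K0k <- elementary_kernel(t, ax[k])[1, 1]
      K0s <- elementary_kernel(t - mod$t02, ax[k])[1, 1]
      bg <- exp(-mod$k_bg * (mod$lambda1 * abs(t) +
                               mod$lambda2 * abs(t - mod$t02)))
      acc <- acc + p[k] * (mod$lambda0 + mod$lambda1 * K0k +
                             mod$lambda2 * K0s) * bg
    }
    acc
  }, numeric(1))
  expect_equal(v2$v, brute, tolerance = 1e-10)
})

test_that("pathway model enforces amplitude invariants", {
  expect_error(pathway_model(lambda0 = -0.1), "nonnegative")
  expect_error(pathway_model(0.8, 0.3, 0.2), "sum")
  expect_error(pathway_model(k_bg = -1), "nonnegative")
})

test_that("parametric fit recovers a noiseless Gaussian forward model", {
  truth <- gaussian_pdf(default_r_axis(), gaussian_params(35, sigma = 9))
  mod <- pathway_model(lambda0 = 0.7, lambda1 = 0.3, k_bg = 0.05)
  tr <- simulate_trace(truth, mod, t_max = 4, dt = 0.012, noise_sigma = 0)
  fit <- fit_parametric(tr, "gaussian")
  expect_equal(fit$params$mean, 35, tolerance = 0.01)
  expect_equal(fit$params$sigma, 9, tolerance = 0.01)
  expect_equal(fit$pathway$lambda0, 0.7, tolerance = 0.01)
  expect_equal(fit$pathway$lambda1, 0.3, tolerance = 0.01)
  expect_equal(fit$pathway$k_bg, 0.05, tolerance = 0.05)
  expect_true(fit$converged)
})

test_that("Gaussian mean is recovered within 0.5 A under noise", {
  truth <- gaussian_pdf(default_r_axis(), gaussian_params(35, sigma = 9))
  mod <- pathway_model(lambda0 = 0.7, lambda1 = 0.3, k_bg = 0.05)
  means <- vapply(1:6, function(s) {
    tr <- simulate_trace(truth, mod, t_max = 4, dt = 0.012,
                         noise_sigma = 0.002, seed = s)
    fit_parametric(tr, "gaussian", n_starts = 3)$params$mean
  }, numeric(1))
  expect_lt(abs(mean(means) - 35), 0.5)
})

test_that("BIC selects two components for a two-Gaussian ground truth", {
  ax <- default_r_axis()
  truth <- distance_distribution(ax,
    0.55 * gaussian_pdf(ax, gaussian_params(28, sigma = 3))$p +
    0.45 * gaussian_pdf(ax, gaussian_params(47, sigma = 4))$p)
  mod <- pathway_model(0.65, 0.35, k_bg = 0.03)
  hits <- vapply(1:5, function(s) {
    tr <- simulate_trace(truth, mod, t_max = 4, dt = 0.016,
                         noise_sigma = 0.003, seed = s)
    fit_parametric(tr, "multi_gaussian", n_max = 3, criterion = "bic",
                   n_starts = 3)$n_components
  }, numeric(1))
  expect_gte(mean(hits == 2), 0.8)
})

test_that("Tikhonov inversion is consistent with the forward model", {
  ax <- default_r_axis(10, 80, 0.5)
  truth <- gaussian_pdf(ax, gaussian_params(35, sigma = 2))
  mod <- pathway_model(0.7, 0.3, k_bg = 0.05)
  tr <- simulate_trace(truth, mod, t_max = 3.5, dt = 0.012, noise_sigma = 0)
  tk <- tikhonov(tr, alpha = 0.05, model = mod, r_axis = ax)
  expect_equal(tk$dist$r_axis[which.max(tk$dist$p)], 35, tolerance = 0.03)
  expect_gt(overlap(tk$dist, truth), 0.98)
  # very large alpha drives the curvature seminorm toward zero
  tk_big <- tikhonov(tr, alpha = 1e5, model = mod, r_axis = ax)
  L <- ddrensemble:::.second_difference(length(ax))
  expect_lt(sum((L %*% tk_big$dist$p)^2), 1e-10)
})

test_that("criterion-based alpha selection recovers a broad distribution", {
  ax <- default_r_axis(10, 120, 1)
  truth <- gaussian_pdf(ax, gaussian_params(45, sigma = 15))
  mod <- pathway_model(0.7, 0.3, k_bg = 0.03)
  tr <- suppressWarnings(simulate_trace(truth, mod, t_max = 5, dt = 0.016,
                                        noise_sigma = 0.005, seed = 3))
  tk <- tikhonov(tr, alpha = "bic", model = mod, r_axis = ax,
                 alpha_grid = 10^seq(-1, 2, length.out = 10))
  expect_gte(overlap(resample(tk$dist, truth$r_axis), truth), 0.9)
  expect_true(tk$alpha_used %in% 10^seq(-1, 2, length.out = 10))
})

test_that("trace loading normalizes at zero time", {
  tr <- deer_trace(seq(-0.1, 2, by = 0.01),
                   2 * exp(-seq(-0.1, 2, by = 0.01)))
  i0 <- which.min(abs(tr$t_axis))
  expect_equal(tr$v[i0], 1)
  expect_error(deer_trace(c(0, 0.1, 0.05), 1:3), "increasing")
})
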