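test_that("FWHM/sigma conversion is exact and involutive", {
  expect_equal(gaussian_params(30, fwhm = 2.3548)$sigma, 1, tolerance = 1e-4)
  x <- c(0.5, 2.3548, 11.7)
  expect_equal(fwhm_sigma(fwhm_sigma(x, "fwhm"), "sigma"), x)
  expect_error(gaussian_params(30, sigma = -1), "positive")
  expect_error(gaussian_params(30, sigma = 2, fwhm = 3), "inconsistent")
})

test_that("gaussian_pdf is normalized with mode at the mean", {
  ax <- default_r_axis()
  g <- gaussian_pdf(ax, gaussian_params(30, sigma = 4))
  expect_equal(sum(g$p), 1)
  expect_equal(ax[which.max(g$p)], 30)
  # tail mass below 15 A matches the numerical Gaussian CDF
  g2 <- gaussian_pdf(default_r_axis(0.5, 90, 0.5),
                     gaussian_params(27, sigma = 8.2))
  frac <- sum(g2$p[g2$r_axis < 15])
  expect_lt(abs(frac - pnorm(15 - 0.25, 27, 8.2)), 1e-3)
})

test_that("SAW-nu density has the stated moments and skewness ordering", {
  ax <- default_r_axis(0.25, 150, 0.25)
  for (nu in c(0.35, 0.5, 0.6, 0.75)) {
    s <- saw_nu_pdf(ax, saw_nu_params(30, nu))
    m <- distribution_moments(s)
    expect_equal(unname(m["rms"]), 30, tolerance = 0.005)
    expect_equal(sum(s$p), 1)
  }
  sk_good <- distribution_moments(saw_nu_pdf(ax, saw_nu_params(30, 3/5)))
  sk_poor <- distribution_moments(saw_nu_pdf(ax, saw_nu_params(30, 1/3)))
  expect_gt(sk_good["skewness"], 0)
  expect_gt(sk_poor["skewness"], sk_good["skewness"])
  expect_error(saw_nu_params(30, 1.2), "nu")
})

test_that("good-solvent SAW density is close to but distinct from a Gaussian", {
  ax <- default_r_axis(0.5, 120, 0.5)
  s <- saw_nu_pdf(ax, saw_nu_params(30, 3/5))
  fg <- fit_gaussian(s)
  expect_lt(fg$rmsd, 0.05)   # minor deviations on the unit-max scale
  expect_gt(fg$rmsd, 1e-4)   # but not exactly Gaussian
})

test_that("overlap satisfies its axioms and equals 1 - TV distance", {
  ax <- 1:8
  p1 <- distance_distribution(ax, c(0.25, 0.25, 0.25, 0.25, 0, 0, 0, 0),
                              normalize = FALSE)
  p2 <- distance_distribution(ax, c(0, 0, 0.25, 0.25, 0.25, 0.25, 0, 0),
                              normalize = FALSE)
  p3 <- distance_distribution(ax, c(0, 0, 0, 0, 0, 0, 0.5, 0.5),
                              normalize = FALSE)
  expect_equal(overlap(p1, p1), 1)
  expect_equal(overlap(p1, p3), 0)
  expect_equal(overlap(p1, p2), 0.5)
  expect_equal(overlap(p1, p2), overlap(p2, p1))
  set.seed(42)
  for (i in 1:25) {
    a <- distance_distribution(1:40, runif(40))
    b <- distance_distribution(1:40, runif(40))
    o <- overlap(a, b)
    expect_gte(o, 0); expect_lte(o, 1)
    expect_equal(o, 1 - tv_distance(a$p, b$p), tolerance = 1e-12)
  }
})

test_that("geometric mean overlap follows the product rule and AM-GM", {
  expect_equal(geometric_mean_overlap(c(0.9, 0.9)), 0.9)
  expect_equal(geometric_mean_overlap(c(1.0, 0.25)), 0.5)
  expect_equal(geometric_mean_overlap(c(0.8, 0.9, 0.7)),
               prod(c(0.8, 0.9, 0.7))^(1 / 3), tolerance = 1e-12)
  expect_warning(z <- geometric_mean_overlap(c(0.5, 0)), "zero")
  expect_equal(z, 0)
  set.seed(1)
  for (i in 1:20) {
    o <- runif(5, 0.05, 1)
    expect_lte(geometric_mean_overlap(o), mean(o) + 1e-12)
  }
})

test_that("gaussian and SAW-nu fits recover their own parameters", {
  ax <- default_r_axis()
  fg <- fit_gaussian(gaussian_pdf(ax, gaussian_params(30, sigma = 5)))
  expect_equal(fg$params$mean, 30, tolerance = 1e-4)
  expect_equal(fg$params$sigma, 5, tolerance = 1e-4)
  expect_lt(fg$rmsd, 1e-8)
  for (nu in c(0.35, 0.5, 0.6, 0.75)) {
    fs <- fit_saw_nu(saw_nu_pdf(ax, saw_nu_params(30, nu)))
    expect_equal(fs$params$R, 30, tolerance = 0.01)
    expect_equal(fs$params$nu, nu, tolerance = 0.01)
  }
})

test_that("fitted Gaussian mean lies below the RMS of a skewed SAW input", {
  ax <- default_r_axis(0.5, 120, 0.5)
  s <- saw_nu_pdf(ax, saw_nu_params(30, 3/5))
  fg <- fit_gaussian(s)
  expect_lt(fg$params$mean, 30)  # RMS 30; skew pushes the mean below it
})

test_that("fitting a Gaussian with the SAW model pushes nu to the top of its box", {
  ax <- default_r_axis()
  fs <- fit_saw_nu(gaussian_pdf(ax, gaussian_params(30, sigma = 5)))
  expect_gt(fs$rmsd, 0)
  expect_gt(fs$params$nu, 0.8)  # symmetric target forces high nu
})

test_that("resampling preserves mass and moments", {
  ax <- default_r_axis(10, 60, 0.5)
  g <- gaussian_pdf(ax, gaussian_params(27, sigma = 8.2))
  expect_equal(resample(g, ax)$p, g$p, tolerance = 1e-12)
  half <- resample(g, default_r_axis(10, 60, 0.25))
  back <- resample(half, ax)
  expect_lt(1 - overlap(back, g), 1e-6)
  g5 <- gaussian_pdf(ax, gaussian_params(32, sigma = 5))
  coarse <- resample(g5, default_r_axis(10, 60, 1))
  m0 <- distribution_moments(g5); m1 <- distribution_moments(coarse)
  expect_equal(unname(m1["mean"]), unname(m0["mean"]), tolerance = 1e-3)
  expect_equal(unname(m1["sd"]), unname(m0["sd"]), tolerance = 1e-3)
  expect_error(resample(g, default_r_axis(20, 40, 0.5)), "support")
})

test_that("distribution invariants are enforced", {
  expect_error(distance_distribution(c(1, 2, 1.5), c(1, 1, 1)), "increasing")
  expect_error(distance_distribution(c(1, 2, 4), c(1, 1, 1)), "uniform")
  expect_error(distance_distribution(1:3, c(-1, 1, 1)), "nonnegative")
  expect_error(distance_distribution(1:3, c(0, 0, 0)), "all-zero")
})
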