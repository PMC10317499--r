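test_that("efficiency plots recover a planted class exactly when noiseless", {
  pop <- generate_population(class_means = 0.51, class_sds = 0,
                             n_per_class = 6, kdc_range = c(1e-6, 1e-2),
                             L0 = 5.2e-7, seed = 4)
  f <- fit_efficiency_plot(pop$L2, pop$KdC, log10_L0 = log10(5.2e-7))
  expect_equal(f$eta, 0.51, tolerance = 1e-9)
  expect_equal(f$m, slope_from_eta(0.51), tolerance = 1e-9)
  # free intercept recovers log10 L0 on clean data
  ff <- fit_efficiency_plot(pop$L2, pop$KdC)
  expect_equal(ff$intercept, log10(5.2e-7), tolerance = 1e-6)
  # two points with slope 2 through the intercept: eta = 1/2
  x <- c(4, 6)  # log10(1/KdC)
  L2 <- 10^(log10(5.2e-7) + 2 * x)
  expect_equal(fit_efficiency_plot(L2, 10^(-x), log10(5.2e-7))$eta, 0.5)
  expect_error(fit_efficiency_plot(2, 1e-4), "2 points")
  expect_error(fit_efficiency_plot(c(1, 2), c(1e-4, 1e-4)), "degenerate")
})

test_that("efficiency-plot slope is essentially unbiased under noise", {
  set.seed(33)
  eta0 <- 0.51
  etas <- replicate(500, {
    pop <- generate_population(class_means = eta0, class_sds = 0,
                               n_per_class = 8, seed = sample.int(1e6, 1))
    y <- log10(pop$L2) + stats::rnorm(8, 0, 0.1)
    fit_efficiency_plot(10^y, pop$KdC, log10(5.2e-7))$eta
  })
  expect_lt(abs(mean(etas) - eta0), 0.005)
})

test_that("energy correlations give eta = 1 - slope", {
  dG_HA <- seq(-14, -8, length.out = 6)
  f <- fit_energy_correlation(0.5 * dG_HA, dG_HA)
  expect_equal(f$eta, 0.5, tolerance = 1e-12)
  pop <- generate_population(class_means = 0.41, class_sds = 0,
                             n_per_class = 6, seed = 5)
  f2 <- fit_energy_correlation(pop$dG_LA, pop$dG_HA)
  expect_equal(f2$slope, 0.59, tolerance = 1e-9)
  expect_equal(f2$eta, 0.41, tolerance = 1e-9)
  # two classes sharing the same dG_HA design, fitted as one line: the
  # least-squares slope is the average of the class slopes, so the mixed
  # eta lies strictly between the class values
  dG_HA2 <- rep(seq(-15, -9, length.out = 8), 2)
  dG_LA2 <- c((1 - 0.41) * dG_HA2[1:8], (1 - 0.56) * dG_HA2[9:16])
  fmix <- fit_energy_correlation(dG_LA2, dG_HA2)
  expect_gt(fmix$eta, 0.41)
  expect_lt(fmix$eta, 0.56)
})

test_that("x-means solves small cases exactly", {
  cl2 <- xmeans_classify(c(0.30, 0.31, 0.55, 0.56))
  expect_equal(cl2$k, 2)
  expect_equal(cl2$means, c(0.305, 0.555))
  expect_equal(cl2$sizes, c(2L, 2L))
  # exhaustive oracle over contiguous 2-splits with min size 2 confirms SSR
  v <- sort(c(0.30, 0.31, 0.55, 0.56))
  ssr_seg <- function(x) sum((x - mean(x))^2)
  best <- min(vapply(2:2, function(b)
    ssr_seg(v[1:b]) + ssr_seg(v[(b + 1):4]), numeric(1)))
  expect_equal(cl2$SSR, best)
  # identical values: one class, zero SSR
  cl1 <- xmeans_classify(rep(0.44, 6))
  expect_equal(cl1$k, 1)
  expect_equal(cl1$SSR, 0)
  expect_error(xmeans_classify(c(0.3, 0.4, 0.5)), "4 values")
})

test_that("x-means recovers planted reference classes", {
  pop <- generate_population(class_means = c(0.32, 0.41, 0.45, 0.51, 0.55),
                             class_sds = 0.008, n_per_class = 20, seed = 9)
  cl <- xmeans_classify(pop$eta)
  expect_equal(cl$k, 5)
  planted <- as.numeric(tapply(pop$eta, pop$class, mean))
  expect_lt(max(abs(cl$means - planted)), 0.01)
  expect_true(all(cl$sizes >= 2))
  # permutation invariance
  perm <- sample(seq_along(pop$eta))
  cl_p <- xmeans_classify(pop$eta[perm])
  expect_equal(cl_p$k, cl$k)
  expect_equal(cl_p$means, cl$means)
  expect_equal(cl_p$assignments, cl$assignments[perm])
  # SSR equals the sum over classes of within-class squared deviations
  ssr_direct <- sum(vapply(seq_len(cl$k), function(ci) {
    x <- pop$eta[cl$assignments == ci]; sum((x - mean(x))^2)
  }, numeric(1)))
  expect_equal(cl$SSR, ssr_direct, tolerance = 1e-12)
})

test_that("x-means with zero within-class spread is exact", {
  pop <- generate_population(class_means = c(0.32, 0.41, 0.45, 0.51, 0.55),
                             class_sds = 1e-4, n_per_class = 5, seed = 10)
  cl <- xmeans_classify(pop$eta)
  expect_equal(cl$k, 5)
  expect_lt(max(abs(cl$means - c(0.32, 0.41, 0.45, 0.51, 0.55))), 0.001)
})

test_that("x-means never returns an empty or singleton class", {
  set.seed(77)
  for (i in 1:10) {
    v <- stats::runif(12, 0.2, 0.7)
    cl <- xmeans_classify(v)
    expect_true(all(cl$sizes >= 2))
    expect_equal(sum(cl$sizes), length(v))
  }
})

test_that("pearson correlation matches hand computation and calibrates", {
  p <- pearson_correlation(c(1, 2, 3), c(2, 4, 5))
  expect_equal(p$r, 0.9820, tolerance = 1e-4)
  pl <- pearson_correlation(1:10, 2 * (1:10) + 3)
  expect_equal(pl$r, 1)
  expect_lt(pl$p, 1e-12)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  # type-I error calibration at the 5% level
  set.seed(88)
  rej <- replicate(1000, pearson_correlation(stats::rnorm(50),
                                             stats::rnorm(50))$p < 0.05)
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("ANCOVA detects different slopes and only different slopes", {
  set.seed(99)
  x <- rep(seq(0, 2, length.out = 8), 2)
  g <- rep(c("a", "b"), each = 8)
  # identical slopes, different intercepts: no interaction detected
  y0 <- ifelse(g == "a", 1, 2) + 1.7 * x + stats::rnorm(16, 0, 1e-9)
  a0 <- compare_slopes_ancova(x, y0, g)
  expect_gt(a0$p, 0.05)
  # planted slopes 1.4 vs 2.1 at noise sd 0.05
  y1 <- ifelse(g == "a", 1.4, 2.1) * x + stats::rnorm(16, 0, 0.05)
  a1 <- compare_slopes_ancova(x, y1, g)
  expect_lt(a1$p, 0.001)
  expect_error(compare_slopes_ancova(x[g == "a"], y1[g == "a"], g[g == "a"]),
               "2 groups")
})

test_that("plot, correlation and per-member eta views of one class agree", {
  pop <- generate_population(class_means = 0.45, class_sds = 0,
                             n_per_class = 7, seed = 12)
  eta_plot <- fit_efficiency_plot(pop$L2, pop$KdC, log10(5.2e-7))$eta
  eta_corr <- fit_energy_correlation(pop$dG_LA, pop$dG_HA)$eta
  eta_mean <- mean(pop$eta)
  expect_lt(abs(eta_plot - eta_mean), 0.01)
  expect_lt(abs(eta_corr - eta_mean), 0.01)
})
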