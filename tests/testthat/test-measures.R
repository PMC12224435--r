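# Closed-form measures, GFA, and unscented-transform propagation.

test_that("FA closed form matches hand-computed values", {
  # eigenvalues (2, 1, 1): FA = sqrt((2-1)^2 / (4 + 2)) = 1/sqrt(6)
  expect_equal(fa_fast(2, 1), 1 / sqrt(6))
  expect_equal(fa_fast(1, 1), 0)        # isotropic
  expect_equal(fa_fast(3, 1), 2 / sqrt(11))
  # scale invariance (degree-0 homogeneity)
  expect_equal(fa_fast(2.7, 0.9), fa_fast(27, 9))
  # monotone in the ratio lam1/lam2
  expect_true(all(diff(fa_fast(seq(1, 3, 0.1), 1)) > 0))
})

test_that("MD closed form and linearity", {
  expect_equal(mean_diffusivity(2, 1), 4 / 3)
  expect_equal(mean_diffusivity(3, 0.5), 4 / 3)
  expect_equal(mean_diffusivity(4, 2), 2 * mean_diffusivity(2, 1))
})

test_that("MSD closed form, homogeneity and monotonicity", {
  ev <- list(lam = matrix(c(2, 1, 0.5, 0.2), 1), w = 0.7)
  # pi^2 (0.7 * (2 + 2) + 0.3 * (0.5 + 0.4)) = pi^2 * 3.07
  expect_equal(msd(ev), pi^2 * 3.07)
  # degree-1 homogeneous
  ev2 <- list(lam = 2 * ev$lam, w = 0.7)
  expect_equal(msd(ev2), 2 * msd(ev))
  # increasing in each eigenvalue
  ev3 <- ev; ev3$lam[1, 1] <- 2.5
  expect_gt(msd(ev3), msd(ev))
  # two identical fibers average to the single-fiber value
  ev4 <- list(lam = rbind(ev$lam, ev$lam), w = 0.7)
  expect_equal(msd(ev4), msd(ev))
})

test_that("RTOP closed form, homogeneity and monotonicity", {
  ev <- list(lam = matrix(c(2, 1, 0.5, 0.2), 1), w = 0.7)
  ref <- 2 * pi^1.5 * (0.7 / (1 * sqrt(2)) + 0.3 / (0.2 * sqrt(0.5)))
  expect_equal(rtop(ev), ref)
  # degree -3/2 homogeneous
  ev2 <- list(lam = 4 * ev$lam, w = 0.7)
  expect_equal(rtop(ev2), rtop(ev) / 8)
  # decreasing in each eigenvalue
  ev3 <- ev; ev3$lam[1, 2] <- 1.2
  expect_lt(rtop(ev3), rtop(ev))
})

test_that("GFA conventions: bounds, identity and known values", {
  v <- c(1, 0, 0, 0)
  # population: std = sqrt(3)/4 * ... => sqrt(1 - mean^2/rms^2)
  expect_equal(gfa(v), sqrt(1 - mean(v)^2 / mean(v^2)))
  expect_equal(gfa(v), sqrt(3) / 2)
  expect_equal(gfa(c(5, 5, 5, 5)), 0)
  expect_gt(gfa(v, type = "sample"), gfa(v))
  set.seed(1)
  x <- runif(100)
  expect_lte(gfa(x), 1)
  expect_equal(gfa(x)^2, 1 - mean(x)^2 / mean(x^2), tolerance = 1e-12)
})

test_that("an isotropic voxel has near-zero GFA, anisotropic higher", {
  iso <- voxel_params(list(fiber_params(0, 0, 1.5, 1.5, 0.3, 0.3)))
  ani <- voxel_params(list(fiber_params(0, 0, 3, 1, 0.3, 0.3)))
  g_iso <- signal_gfa(simulate_signal(iso, hcp_scheme()))
  g_ani <- signal_gfa(simulate_signal(ani, hcp_scheme()))
  expect_lt(g_iso, 1e-10)
  expect_gt(g_ani, 0.1)
})

test_that("unscented transform is exact for affine maps", {
  set.seed(7)
  d <- 4
  A <- matrix(rnorm(2 * d), 2, d)
  bvec <- rnorm(2)
  mu <- rnorm(d)
  M <- matrix(rnorm(d * d), d)
  Sig <- crossprod(M) + diag(d)
  f <- function(x) drop(A %*% x + bvec)
  r <- unscented_propagate(mu, Sig, f)
  expect_equal(r$mean, drop(A %*% mu + bvec), tolerance = 1e-10)
  expect_equal(r$var, A %*% Sig %*% t(A), tolerance = 1e-8,
               ignore_attr = TRUE)
  # scalar affine
  a <- rnorm(d)
  rs <- unscented_propagate(mu, Sig, function(x) sum(a * x) + 2)
  expect_equal(rs$mean, sum(a * mu) + 2, tolerance = 1e-10)
  expect_equal(rs$var, drop(t(a) %*% Sig %*% a), tolerance = 1e-8)
})

test_that("UT weights sum to one and kappa default is 3 - d", {
  # propagate the identity: mean and covariance must be reproduced
  mu <- c(1, -2)
  Sig <- matrix(c(0.5, 0.1, 0.1, 0.3), 2)
  r <- unscented_propagate(mu, Sig, function(x) x)
  expect_equal(r$mean, mu, tolerance = 1e-10)
  expect_equal(r$var, Sig, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("UT matches Monte Carlo within 5% on each measure", {
  set.seed(12)
  mu <- c(2.2, 1.1, 0.45, 0.2)      # lam1, lam2, lam3, lam4
  sdv <- c(0.08, 0.05, 0.03, 0.02)
  Sig <- diag(sdv^2)
  n_mc <- 1e5
  Z <- matrix(rnorm(n_mc * 4), ncol = 4)
  X <- sweep(Z %*% diag(sdv), 2, mu, "+")
  fns <- list(
    FA = function(x) fa_fast(max(x[1], x[2]), min(x[1], x[2])),
    MD = function(x) mean_diffusivity(x[1], x[2]),
    MSD = function(x) msd(list(lam = matrix(x, 1), w = 0.7)),
    RTOP = function(x) rtop(list(lam = matrix(x, 1), w = 0.7)))
  for (nm in names(fns)) {
    f <- fns[[nm]]
    ut <- unscented_propagate(mu, Sig, f)
    mc <- apply(X, 1, f)
    expect_equal(ut$mean, mean(mc), tolerance = 0.05)
    expect_equal(sqrt(ut$var), sd(mc), tolerance = 0.05)
  }
})

test_that("sigma points below the lower bound are reflected", {
  # large variance forces points below zero; reflection keeps the
  # evaluation inside the domain of sqrt
  r <- unscented_propagate(0.05, matrix(0.01), sqrt,
                           ut_config(lower = 0))
  expect_gte(r$n_reflected, 1)
  expect_true(is.finite(r$mean) && r$mean > 0)
})

test_that("variance-weighted mean matches the closed form", {
  expect_equal(variance_weighted_mean(c(1, 2), c(1, 1)), 1.5)
  expect_equal(variance_weighted_mean(c(1, 2), c(1, 4)),
               (1 / 1 + 2 / 4) / (1 / 1 + 1 / 4))
  # an infinitely noisy point is ignored in the limit
  expect_equal(variance_weighted_mean(c(1, 100), c(1, 1e12)), 1,
               tolerance = 1e-8)
  expect_error(variance_weighted_mean(1:3, c(1, -1, 1)), "positive")
})

test_that("posterior_measure propagates a dominant component", {
  # 6-parameter (single fiber) estimate with small eigenvalue noise
  mu <- c(pi / 4, pi / 3, 2.2, 1.1, 0.45, 0.2)
  Sig <- diag(c(0.02, 0.02, 0.08, 0.05, 0.03, 0.02)^2)
  post <- mixture_posterior(1, matrix(mu, 1), list(Sig))
  est <- select_dominant_component(post)
  for (mm in c("FA", "MD", "MSD", "RTOP")) {
    pm <- posterior_measure(est, mm)
    expect_s3_class(pm, "measure_estimate")
    expect_true(is.finite(pm$mean) && pm$mean > 0)
    expect_true(is.finite(pm$std) && pm$std >= 0)
  }
  pm_md <- posterior_measure(est, "MD")
  expect_equal(pm_md$mean, mean_diffusivity(2.2, 1.1),
               tolerance = 1e-8)
})
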