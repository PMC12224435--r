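# Metrics, matching oracle, baselines and experiment drivers.

test_that("angular error handles antipodal symmetry and identity", {
  m <- sph_to_cart(pi / 3, pi / 4)
  expect_equal(angular_error(rbind(m), rbind(m))$mean_error, 0)
  expect_equal(angular_error(rbind(-m), rbind(m))$mean_error, 0)
  # 90-degree case
  expect_equal(angular_error(rbind(c(1, 0, 0)),
                             rbind(c(0, 0, 1)))$mean_error, 90)
  # known oblique angle
  a <- c(1, 0, 0); b <- c(1, 1, 0) / sqrt(2)
  expect_equal(angular_error(rbind(a), rbind(b))$mean_error, 45)
})

test_that("matching permutation equals exhaustive enumeration", {
  # independent brute-force oracle implemented in the test
  brute <- function(est, true) {
    n <- nrow(true)
    cosm <- abs(true %*% t(est))
    cosm[cosm > 1] <- 1
    ang <- acos(cosm) * 180 / pi
    perms <- if (n == 2) list(1:2, 2:1) else
      list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    tots <- vapply(perms, function(p)
      sum(ang[cbind(seq_len(n), p)]), numeric(1))
    min(tots) / n
  }
  set.seed(17)
  for (rep in 1:5000) {
    n <- sample(2:3, 1)
    est <- matrix(rnorm(3 * n), n)
    est <- est / sqrt(rowSums(est^2))
    true <- matrix(rnorm(3 * n), n)
    true <- true / sqrt(rowSums(true^2))
    ae <- angular_error(est, true)
    expect_equal(ae$mean_error, brute(est, true), tolerance = 1e-10)
  }
})

test_that("eigenvalue error uses the angular matching", {
  f1 <- fiber_params(0, 0, 2, 1, 0.5, 0.2)
  f2 <- fiber_params(pi / 2, 0, 3, 1.2, 0.6, 0.3)
  true <- voxel_params(list(f1, f2))
  # estimate with the fibers swapped and eigenvalues perturbed
  e1 <- fiber_params(pi / 2, 0, 3.1, 1.2, 0.6, 0.3)
  e2 <- fiber_params(0, 0, 2, 1.05, 0.5, 0.2)
  est <- voxel_params(list(e1, e2))
  r <- eigenvalue_error(est, true)
  expect_equal(r$permutation, c(2L, 1L))
  expect_equal(r$total, 0.1 + 0.05, tolerance = 1e-10)
})

test_that("nmse is exactly the normalized residual power", {
  r <- c(1, 2, 3)
  expect_equal(nmse(r, r), 0)
  expect_equal(nmse(r + 1, r), 3 / 14)
  expect_equal(nmse(2 * r, r), 1)
})

test_that("LM baseline recovers a noiseless single fiber", {
  vp <- sample_prior(prior_spec(), 1, 1, seed = 19)[[1]]
  s <- simulate_signal(vp, hcp_scheme())
  fit <- baseline_fit(s, 1, baseline_fit_config(n_restarts = 6,
                                                seed = 2))
  expect_lt(fit$residual, 1e-8)
  est_dir <- sph_to_cart(fit$alpha[1], fit$alpha[2])
  true_dir <- sph_to_cart(vp$fibers[[1]]$theta, vp$fibers[[1]]$phi)
  expect_lt(crossing_angle(est_dir, true_dir), 1)
})

test_that("TRF baseline respects the prior box", {
  vp <- sample_prior(prior_spec(), 1, 1, seed = 23)[[1]]
  s <- add_noise(simulate_signal(vp, hcp_scheme()), 0.04, seed = 3)
  fit <- baseline_fit(s, 1,
                      baseline_fit_config("TRF", n_restarts = 4,
                                          seed = 4))
  std <- dmripost:::.alpha_standardizer(prior_spec(), 1)
  expect_true(all(fit$alpha >= std$lo - 1e-9))
  expect_true(all(fit$alpha <= std$hi + 1e-9))
})

test_that("baseline restarts record residuals and convergence", {
  vp <- sample_prior(prior_spec(), 2, 1, seed = 29)[[1]]
  s <- add_noise(simulate_signal(vp, hcp_scheme()), 0.04, seed = 5)
  fit <- baseline_fit(s, 2, baseline_fit_config(n_restarts = 5,
                                                seed = 6))
  expect_equal(nrow(fit$restarts), 5)
  expect_true(all(c("rss", "converged") %in%
                    colnames(fit$restarts)))
  expect_equal(fit$residual, min(fit$restarts[, "rss"]))
})

test_that("run_sweep returns complete binned statistics", {
  # oracle estimator: returns the truth, so errors must all be 0
  prior <- prior_spec()
  truth_store <- new.env()
  est <- function(signals, scheme) truth_store$alpha
  set.seed(31)
  # reproduce run_sweep's internal sampling to seed the oracle
  vps <- sample_prior(prior, 2, 40)
  truth_store$alpha <- do.call(rbind, lapply(vps, params_to_alpha))
  sw <- run_sweep(est, 2, bin_by = "angle", n_voxels = 40,
                  noise_sigma = 0, n_bins = 4, prior = prior,
                  seed = 31)
  expect_s3_class(sw, "sweep_result")
  expect_equal(nrow(sw), 4)
  expect_equal(sum(sw$n), 40)
  # acos round-trip noise makes "zero" error ~1e-6 degrees
  expect_true(all(sw$median[sw$n > 0] < 1e-5))
  expect_true(all(diff(sw$lo) > 0))
})

test_that("full-scale bounds are exposed machine-readably", {
  fb <- full_scale_bounds()
  expect_equal(unname(fb$misclassification),
               c(0.027, 0.023, 0.047))
  expect_equal(fb$angular_error_deg, 2.93)
  expect_equal(fb$eigenvalue_error, 0.07)
})
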