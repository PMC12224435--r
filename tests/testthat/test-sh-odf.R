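# Spherical harmonics, Funk-Radon transform, ODF maps and peaks.

test_that("sh_basis_size follows (L+1)(L+2)/2 for even L", {
  expect_equal(sh_basis_size(0), 1)
  expect_equal(sh_basis_size(2), 6)
  expect_equal(sh_basis_size(4), 15)
  expect_equal(sh_basis_size(6), 28)
  expect_equal(sh_basis_size(8), 45)
})

test_that("SH basis is orthonormal on a quadrature grid", {
  # product Gauss-Legendre (theta) x uniform (phi) quadrature
  nq <- 48
  gl <- pracma::gaussLegendre(nq, -1, 1)
  phi <- seq(0, 2 * pi, length.out = 2 * nq + 1)[-(2 * nq + 1)]
  th <- acos(gl$x)
  grid <- expand.grid(th = th, ph = phi)
  wts <- rep(gl$w, times = length(phi)) * (2 * pi / (2 * nq))
  B <- sh_basis(4, grid$th, grid$ph)
  G <- t(B) %*% (wts * B)
  expect_equal(G, diag(ncol(B)), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("Funk-Radon eigenvalues are 2 pi P_l(0)", {
  # P_0(0)=1, P_2(0)=-1/2, P_4(0)=3/8, P_6(0)=-5/16, P_8(0)=35/128
  expect_equal(frt_eigenvalue(0), 2 * pi)
  expect_equal(frt_eigenvalue(2), 2 * pi * (-1 / 2))
  expect_equal(frt_eigenvalue(4), 2 * pi * (3 / 8))
  expect_equal(frt_eigenvalue(6), 2 * pi * (-5 / 16))
  expect_equal(frt_eigenvalue(8), 2 * pi * (35 / 128))
})

test_that("fit_sh recovers coefficients of a band-limited function", {
  set.seed(2)
  dirs <- hemisphere_directions(200)
  tp <- t(apply(dirs, 1, cart_to_sph))
  c_true <- rnorm(sh_basis_size(4))
  vals <- drop(sh_basis(4, tp[, 1], tp[, 2]) %*% c_true)
  fit <- fit_sh(vals, dirs, L = 4, lambda = 0)
  expect_equal(fit$coeffs, c_true, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Laplace-Beltrami regularization shrinks high orders only", {
  set.seed(4)
  dirs <- hemisphere_directions(120)
  tp <- t(apply(dirs, 1, cart_to_sph))
  c_true <- rnorm(sh_basis_size(8))
  vals <- drop(sh_basis(8, tp[, 1], tp[, 2]) %*% c_true)
  f0 <- fit_sh(vals, dirs, L = 8, lambda = 0)
  f1 <- fit_sh(vals, dirs, L = 8, lambda = 1e-2)
  # the (l(l+1))^2 penalty is order-selective: the l = 8 block loses
  # most of its energy while the l = 0 coefficient moves only through
  # the off-diagonal coupling of the normal equations
  e0 <- sum(f0$coeffs[29:45]^2); e1 <- sum(f1$coeffs[29:45]^2)
  expect_lt(e1, 0.5 * e0)
  rel_l0 <- abs(f1$coeffs[1] - f0$coeffs[1]) / abs(f0$coeffs[1])
  expect_lt(rel_l0, 1 - e1 / e0)
})

test_that("ODF of a single fiber peaks along the fiber axis", {
  m_true <- sph_to_cart(pi / 4, pi / 3)
  vp <- voxel_params(list(fiber_params(pi / 4, pi / 3, 2.5, 0.8,
                                       0.5, 0.2)))
  s <- simulate_signal(vp, hcp_scheme())
  odf <- compute_odf(fit_sh(s$values[s$scheme$shell_ids == 1],
                            s$scheme$directions[s$scheme$shell_ids == 1, ]))
  pk <- find_peaks(odf)
  expect_gte(nrow(pk$directions), 1)
  expect_lt(crossing_angle(pk$directions[1, ], m_true), 5)
})

test_that("two crossing fibers give two separated ODF peaks", {
  vp <- voxel_params(list(
    fiber_params(pi / 2, 0, 2.8, 0.7, 0.5, 0.2),
    fiber_params(pi / 2, pi / 2, 2.8, 0.7, 0.5, 0.2)))
  s <- simulate_signal(vp, hcp_scheme())
  sel <- s$scheme$shell_ids == 2
  odf <- compute_odf(fit_sh(s$values[sel],
                            s$scheme$directions[sel, ]))
  pk <- find_peaks(odf)
  expect_gte(nrow(pk$directions), 2)
  errs <- angular_error(pk$directions[1:2, ],
                        rbind(c(1, 0, 0), c(0, 1, 0)))
  expect_lt(errs$mean_error, 6)
})

test_that("rendered maps are normalized, finite and shaped", {
  fx <- make_fixture(prior_spec(), hcp_scheme(),
                     counts = c("1" = 2, "2" = 2, "3" = 2),
                     noise_sigma = 0.04, seed = 21)
  expect_equal(dim(fx$maps), c(6, 32 * 32 * 3))
  expect_true(all(is.finite(fx$maps)))
  expect_gte(min(fx$maps), 0)
  expect_lte(max(fx$maps), 1)
  # each channel of each voxel attains both 0 and 1 (min-max)
  for (v in 1:6) for (ch in 1:3) {
    px <- fx$maps[v, (ch - 1) * 1024 + 1:1024]
    expect_equal(min(px), 0)
    expect_equal(max(px), 1)
  }
})

test_that("a constant channel renders as all zeros", {
  sch <- hcp_scheme()
  sig <- matrix(0.5, 1, nrow(sch$directions))
  m <- render_maps_batch(sig, sch)
  expect_true(all(m == 0))
})

test_that("render_map array agrees with the batch layout", {
  vp <- sample_prior(prior_spec(), 2, 1, seed = 33)[[1]]
  s <- simulate_signal(vp, hcp_scheme())
  arr <- render_map(s)
  flat <- render_maps_batch(matrix(s$values, 1), s$scheme)
  expect_equal(as.numeric(arr), as.numeric(flat[1, ]))
  expect_equal(dim(arr), c(32, 32, 3))
})
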