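# Mixture posterior representation, head mapping, SNPE loss,
# dominant-component selection and sampling.

test_that("mixture_posterior validates its invariants", {
  expect_error(mixture_posterior(c(0.5, 0.6), matrix(0, 2, 1),
                                 list(matrix(1), matrix(1))), "sum")
  expect_error(mixture_posterior(1, matrix(0, 1, 2),
                                 list(matrix(c(1, 0, 0, -1), 2))),
               "positive definite")
  p <- mixture_posterior(c(0.3, 0.7), matrix(c(0, 1), 2, 1),
                         list(matrix(1), matrix(2)))
  expect_equal(p$m, 2)
  expect_equal(p$d, 1)
})

test_that("mdn_density matches dnorm mixtures in 1-D", {
  p <- mixture_posterior(c(0.3, 0.7), matrix(c(-1, 2), 2, 1),
                         list(matrix(0.25), matrix(4)))
  xs <- seq(-6, 8, length.out = 11)
  ref <- 0.3 * dnorm(xs, -1, 0.5) + 0.7 * dnorm(xs, 2, 2)
  expect_equal(mdn_density(p, matrix(xs, ncol = 1)), ref,
               tolerance = 1e-12)
  expect_equal(mdn_density(p, matrix(xs, ncol = 1), log = TRUE),
               log(ref), tolerance = 1e-10)
})

test_that("mdn_density integrates to 1 on 1-D toys", {
  set.seed(5)
  for (rep in 1:3) {
    m <- sample(2:4, 1)
    w <- runif(m); w <- w / sum(w)
    mu <- matrix(rnorm(m, sd = 2), m, 1)
    covs <- lapply(runif(m, 0.2, 2), function(s) matrix(s^2))
    p <- mixture_posterior(w, mu, covs)
    xs <- seq(-25, 25, length.out = 20001)
    dens <- mdn_density(p, matrix(xs, ncol = 1))
    integral <- sum(dens) * (xs[2] - xs[1])
    expect_equal(integral, 1, tolerance = 1e-4)
  }
})

test_that("network_head_to_mixture always yields a valid mixture", {
  set.seed(9)
  std <- dmripost:::.alpha_standardizer(prior_spec(), 1)
  for (rep in 1:20) {
    raw <- rnorm(5 * (1 + 6 + 21), sd = 3)
    p <- network_head_to_mixture(raw, 5, 6, std)
    expect_s3_class(p, "mixture_posterior")
    expect_equal(sum(p$weights), 1, tolerance = 1e-9)
    for (S in p$covs) {
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), 0)
    }
  }
})

test_that("head means map back through the prior standardization", {
  std <- dmripost:::.alpha_standardizer(prior_spec(), 1)
  m <- 2; d <- 6; dtri <- 21
  raw <- rep(0, m * (1 + d + dtri))
  # component means at standardized 0 = prior center
  p <- network_head_to_mixture(raw, m, d, std)
  expect_equal(p$means[1, ], std$center, ignore_attr = TRUE)
  expect_equal(p$weights, c(0.5, 0.5))
})

test_that("snpe_loss equals the negative mean log density", {
  set.seed(11)
  prior <- prior_spec()
  std <- dmripost:::.alpha_standardizer(prior, 1)
  posts <- list(); alphas <- matrix(0, 4, 6)
  for (j in 1:4) {
    raw <- rnorm(5 * 28, sd = 0.5)
    posts[[j]] <- network_head_to_mixture(raw, 5, 6, std)
    a <- params_to_alpha(sample_prior(prior, 1, 1)[[1]])
    alphas[j, ] <- a
  }
  manual <- -mean(vapply(1:4, function(j)
    mdn_density(posts[[j]], alphas[j, ], log = TRUE), numeric(1)))
  expect_equal(snpe_loss(posts, alphas, prior), manual,
               tolerance = 1e-10)
  # out-of-support truth is rejected under the prior proposal
  bad <- alphas; bad[1, 3] <- 99
  expect_error(snpe_loss(posts, bad, prior), "support")
})

test_that("dominant-component rules behave as documented", {
  mus <- rbind(rep(0, 2), rep(1, 2))
  covs <- list(diag(2) * 0.01, diag(2) * 1)
  p <- mixture_posterior(c(0.5, 0.5), mus, covs)
  # delta rewards the wide component, inverse rewards the narrow one
  est_d <- select_dominant_component(p, rule = "delta")
  est_i <- select_dominant_component(p, rule = "inverse")
  expect_equal(est_d$component, 2L)
  expect_equal(est_i$component, 1L)
  # delta_i = w_i * trace(Sigma_i^(1/2))
  expect_equal(est_d$delta, c(0.5 * 2 * 0.1, 0.5 * 2 * 1))
  # equal covariances: both rules reduce to argmax w_i
  p2 <- mixture_posterior(c(0.8, 0.2), mus,
                          list(diag(2), diag(2)))
  expect_equal(select_dominant_component(p2, "delta")$component, 1L)
  expect_equal(select_dominant_component(p2, "inverse")$component, 1L)
})

test_that("sample_posterior reproduces mixture moments", {
  p <- mixture_posterior(c(0.25, 0.75), rbind(c(-2, 0), c(2, 1)),
                         list(diag(2) * 0.1, diag(2) * 0.4))
  S <- sample_posterior(p, 2e4, seed = 13)
  mu_true <- 0.25 * c(-2, 0) + 0.75 * c(2, 1)
  expect_equal(colMeans(S), mu_true, tolerance = 0.05)
  comp <- attr(S, "component")
  expect_equal(mean(comp == 2), 0.75, tolerance = 0.02)
})

test_that("posterior_net_config enforces the n! component floor", {
  expect_error(posterior_net_config(3, m = 4), "n!")
  expect_equal(posterior_net_config(1)$m, 5)
  expect_equal(posterior_net_config(2)$m, 5)
  expect_equal(posterior_net_config(3)$m, 10)
  cfg_full <- posterior_net_config(1, scale = "full")
  expect_equal(cfg_full$hidden, 1000)
  expect_equal(cfg_full$lr, 5e-5)
  expect_equal(cfg_full$patience, 30)
  expect_equal(cfg_full$train_size, 2e6)
  expect_equal(cfg_full$batch_size, 100)
  expect_equal(cfg_full$val_fraction, 0.1)
  expect_equal(cfg_full$trunk, "classifier")
})

test_that("posterior head emits the right output dimension", {
  cfg <- posterior_net_config(1, hidden = 16, n_fc = 3)
  model <- build_posterior_net(cfg)
  # m (1 + d + d(d+1)/2) = 5 * (1 + 6 + 21) = 140
  expect_equal(model$net$output_dim, 140)
})
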