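# Shared, lazily trained models and fixtures. Training happens at most
# once per test run; every consumer calls the accessor. Sizes are desk
# scale: large enough to demonstrate the documented behavior, small
# enough that the whole suite runs on one CPU in minutes.

.model_cache <- new.env(parent = emptyenv())

.cached <- function(key, make) {
  if (!exists(key, envir = .model_cache))
    assign(key, make(), envir = .model_cache)
  get(key, envir = .model_cache)
}

# classifier study: well-separated noiseless protocol
ws_prior <- function() well_separated_prior()

ws_train_fixture <- function() .cached("ws_train", function()
  make_fixture(ws_prior(), hcp_scheme(),
               counts = c("1" = 800, "2" = 800, "3" = 800),
               noise_sigma = 0, seed = 11))

ws_holdout_fixture <- function() .cached("ws_holdout", function()
  make_fixture(ws_prior(), hcp_scheme(),
               counts = c("1" = 100, "2" = 100, "3" = 100),
               noise_sigma = 0, seed = 12))

# the same held-out voxels re-rendered from SNR-3 noisy signals
ws_holdout_noisy_maps <- function() .cached("ws_holdout_noisy",
                                            function() {
  ho <- ws_holdout_fixture()
  set.seed(13)
  noisy <- ho$signals + matrix(rnorm(length(ho$signals), 0, 0.04),
                               nrow(ho$signals))
  render_maps_batch(noisy, hcp_scheme())
})

trained_classifier <- function() .cached("classifier", function() {
  fx <- ws_train_fixture()
  cfg <- classifier_config(epochs = 30, lr = 1e-3,
                           optimizer = "adam", seed = 3)
  train_classifier(build_classifier(cfg), fx$maps, fx$labels)
})

# posterior study: default prior, noiseless single-fiber training
posterior1_train_fixture <- function() .cached("p1_train", function()
  make_fixture(prior_spec(), hcp_scheme(), counts = c("1" = 8000),
               noise_sigma = 0, seed = 101))

trained_posterior1 <- function() .cached("posterior1", function() {
  fx <- posterior1_train_fixture()
  cfg <- posterior_net_config(1, scale = "desk", max_epochs = 25,
                              seed = 5)
  train_posterior(cfg, data = list(maps = fx$maps,
                                   alpha = fx$alpha[["1"]]),
                  prior = prior_spec(), scheme = hcp_scheme())
})

posterior1_test_fixture <- function() .cached("p1_test", function()
  make_fixture(prior_spec(), hcp_scheme(), counts = c("1" = 100),
               noise_sigma = 0, seed = 202))

# tiny posterior nets for all three classes: plumbing-scale only
# (exercise the end-to-end pipeline, no accuracy claims)
tiny_posterior <- function(n) .cached(paste0("tiny_post_", n),
                                      function() {
  fx <- make_fixture(prior_spec(), hcp_scheme(),
                     counts = setNames(600, n),
                     noise_sigma = 0.04, seed = 300 + n)
  cfg <- posterior_net_config(n, scale = "desk", hidden = 32,
                              max_epochs = 3, patience = 3,
                              seed = 40 + n)
  train_posterior(cfg, data = list(maps = fx$maps,
                                   alpha = fx$alpha[[as.character(n)]]),
                  prior = prior_spec(), scheme = hcp_scheme())
})
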