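# Noise samplers, analytic densities, the three injection points, and the
# parameter-restoration mechanism.

test_that("noise_spec validates family, scale, and targets", {
  expect_error(noise_spec("triangular", scale = 1), "arg")
  expect_error(noise_spec("cauchy", scale = 0), "scale")
  expect_error(noise_spec("cauchy", scale = -1), "scale")
  expect_error(noise_spec("cauchy", scale = 1, targets = "everything"))
  ns <- noise_spec("laplace", location = 2, scale = 0.5)
  expect_identical(ns$family, "laplace")
})

test_that("the Cauchy density peaks at 1/(pi*sigma) and matches stats::dcauchy", {
  ns1 <- noise_spec("cauchy", location = 0, scale = 1)
  expect_equal(noise_pdf(ns1, 0), 1 / pi, tolerance = 1e-15)
  ns2 <- noise_spec("cauchy", location = 2, scale = 0.5)
  expect_equal(noise_pdf(ns2, 2), 1 / (pi * 0.5), tolerance = 1e-15)
  x <- seq(-5, 5, by = 0.25)
  expect_equal(noise_pdf(ns2, x), stats::dcauchy(x, 2, 0.5),
               tolerance = 1e-12)
  gs <- noise_spec("gaussian", 1, 2)
  expect_equal(noise_pdf(gs, x), stats::dnorm(x, 1, 2), tolerance = 1e-12)
  expect_equal(noise_cdf(gs, x), stats::pnorm(x, 1, 2), tolerance = 1e-12)
})

test_that("samplers honor shape, seed, and the family's support/median", {
  ns <- noise_spec("cauchy", location = 2, scale = 1, seed = 31L)
  draws <- sample_noise(ns, 1e5)
  # sample median of a Cauchy concentrates at the location
  expect_gte(stats::median(draws), 1.98)
  expect_lte(stats::median(draws), 2.02)
  expect_identical(sample_noise(ns, 1e5), draws)  # self-seeding

  arr <- sample_noise(noise_spec("gaussian", 0, 1, seed = 1L), c(3L, 4L))
  expect_identical(dim(arr), c(3L, 4L))

  ex <- sample_noise(noise_spec("exponential", 0, 2, seed = 2L), 1e4)
  expect_true(all(ex >= 0))  # one-sided support above the location
})

test_that("the Laplace sampler agrees with the difference-of-exponentials construction", {
  a <- sample_noise(noise_spec("laplace", 0, 1, seed = 8L), 5e3)
  b <- withr::with_seed(9L, stats::rexp(5e3, 1) - stats::rexp(5e3, 1))
  ks <- suppressWarnings(stats::ks.test(a, b))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cauchy tails dominate Gaussian tails at equal scale", {
  g <- abs(sample_noise(noise_spec("gaussian", 0, 1, seed = 5L), 1e5))
  cc <- abs(sample_noise(noise_spec("cauchy", 0, 1, seed = 6L), 1e5))
  expect_gt(stats::quantile(cc, 0.999), stats::quantile(g, 0.999))
})

test_that("parameter noise is exactly additive and leaves the original untouched", {
  parts <- build_split_model(tiny_spec(), seed = 2L)
  ns <- noise_spec("gaussian", 0, 0.1, targets = "parameters", seed = 3L)
  before <- part_flatten(parts$client)
  noisy <- add_noise_to_params(parts$client, ns)
  expect_identical(part_flatten(parts$client), before)
  noise_flat <- splitfedlab:::flatten_params(attr(noisy, "noise"))
  expect_identical(part_flatten(noisy), before + noise_flat)

  zeros <- splitfedlab:::tree_map(parts$client$params, function(w) w * 0)
  same <- add_noise_to_params(parts$client, ns, noise = zeros)
  expect_identical(part_flatten(same), before)
})

test_that("Gaussian parameter noise concentrates at its location (CLT)", {
  part <- splitfedlab:::new_part(list(dense_layer(1L)),
                                 list(list(W = matrix(0, 1e4, 1),
                                           b = 0)), 1e4L)
  ns <- noise_spec("gaussian", location = 5, scale = 0.01,
                   targets = "parameters", seed = 12L)
  noisy <- add_noise_to_params(part, ns)
  expect_lt(abs(mean(noisy$params[[1]]$W) - 5), 0.001)
})

test_that("transmission noise perturbs payloads only and is exactly additive", {
  parts <- build_split_model(tiny_spec(), seed = 4L)
  batch <- random_batch(n = 3L)
  sm <- client_forward(parts$client, batch$X, indices = 7:9)
  ns <- noise_spec("laplace", 0, 0.5, seed = 21L)
  rec <- add_noise_to_transmission(sm, ns)
  expect_s3_class(rec$noisy, "smashed_batch")
  expect_identical(rec$noisy$activations,
                   rec$original$activations + rec$noise)
  expect_identical(rec$noisy$indices, sm$indices)
  expect_identical(rec$noisy$tag, sm$tag)

  zero <- array(0, dim = dim(sm$activations))
  same <- add_noise_to_transmission(sm, ns, noise = zero)
  expect_identical(same$noisy$activations, sm$activations)

  cfg <- train_config(k = 1L, lr = 0, seed = 1L)
  pkt <- server_step(parts$server, sm, batch$y, cfg)$packet
  rec2 <- add_noise_to_transmission(pkt, ns)
  expect_identical(rec2$noisy$d_smashed, pkt$d_smashed + rec2$noise)
  expect_error(add_noise_to_transmission(list(1), ns), "smashed_batch")
})

test_that("server outputs on noisy activations converge to clean as scale shrinks", {
  parts <- build_split_model(tiny_spec(), seed = 5L)
  batch <- random_batch(n = 2L)
  sm <- client_forward(parts$client, batch$X)
  clean <- server_forward(parts$server, sm)
  diffs <- vapply(c(1, 1e-3, 1e-6), function(sc) {
    ns <- noise_spec("gaussian", 0, sc, seed = 33L)
    max(abs(server_forward(parts$server,
                           add_noise_to_transmission(sm, ns)$noisy) - clean))
  }, numeric(1))
  expect_gt(diffs[1], diffs[2])
  expect_gt(diffs[2], diffs[3])
  expect_lt(diffs[3], 1e-4)
})

test_that("noisy_update reduces to the plain gradient step under zero noise", {
  parts <- build_split_model(tiny_spec(), seed = 6L)
  grads <- splitfedlab:::tree_map(parts$client$params, function(w) w * 0 + 1)
  zeros <- splitfedlab:::tree_map(parts$client$params, function(w) w * 0)
  ns <- noise_spec("cauchy", 0, 1, targets = "update", seed = 2L)
  stepped <- noisy_update(parts$client, grads, lr = 0.1, ns, noise = zeros)
  expect_equal(part_flatten(stepped), part_flatten(parts$client) - 0.1,
               tolerance = 1e-12)
  still <- noisy_update(parts$client, grads, lr = 0, ns, noise = zeros)
  expect_identical(part_flatten(still), part_flatten(parts$client))
  n1 <- noisy_update(parts$client, grads, lr = 0.1, ns)
  n2 <- noisy_update(parts$client, grads, lr = 0.1, ns)
  expect_identical(part_flatten(n1), part_flatten(n2))  # seeded spec
})

test_that("restoration reinstates pristine parameters and guards misuse", {
  fx <- small_trained_state()
  state <- fx$state
  ns <- noise_spec("gaussian", 0, 1, targets = "parameters", seed = 9L)
  state$cfg$dp <- ns
  state$pristine <- state$clients
  state$clients <- lapply(state$clients, add_noise_to_params, spec = ns)
  restored <- restore_parameters(state)
  expect_identical(part_flatten(restored$clients[[1]]),
                   part_flatten(fx$state$clients[[1]]))

  bad <- fx$state
  bad$cfg$dp <- ns
  expect_error(restore_parameters(bad), "pristine")
  # no-op when DP is off
  expect_identical(restore_parameters(fx$state), fx$state)
})

test_that("parameter-only noise leaves the training trajectory unchanged", {
  ds <- small_dataset(6L)
  plan <- partition(ds$train, 2L, seed = 2L)
  cfg_off <- train_config(k = 2L, epochs = 2L, batch_size = 8L, seed = 4L)
  cfg_on <- cfg_off
  cfg_on$dp <- noise_spec("cauchy", 0, 5, targets = "parameters")
  s_off <- train_splitfed(ds$train, plan, cfg_off)
  s_on <- train_splitfed(ds$train, plan, cfg_on)
  expect_identical(part_flatten(s_on$global_client),
                   part_flatten(s_off$global_client))
  expect_identical(part_flatten(s_on$server), part_flatten(s_off$server))
  # but the adversary-visible outbound copies are noisy
  expect_false(identical(part_flatten(s_on$shared_noisy[[1]]),
                         part_flatten(s_on$global_client)))
})

test_that("training with transmission noise stays finite and runs end-to-end", {
  ds <- small_dataset(6L)
  plan <- partition(ds$train, 2L, seed = 3L)
  cfg <- train_config(k = 2L, epochs = 1L, batch_size = 8L, seed = 5L)
  cfg$dp <- noise_spec("gaussian", 0, 0.05,
                       targets = c("activations", "gradients"))
  state <- train_splitfed(ds$train, plan, cfg)
  expect_true(all(is.finite(state$history$loss)))
  cfg$optimizer <- "sgd"
  cfg$dp <- noise_spec("cauchy", 0, 1e-4, targets = "update")
  state2 <- train_splitfed(ds$train, plan, cfg)
  expect_true(all(is.finite(state2$history$loss)))
})
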