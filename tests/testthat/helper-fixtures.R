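# Shared fixtures, built in code. Small enough that every test file stays in
# the seconds range; the expensive full-scale runs live in the acceptance
# tests only.

tiny_spec <- function(n_classes = 3L) {
  split_model_spec(
    image_size = 8L, n_classes = n_classes,
    layers = list(conv_layer(2L, 3L), relu_layer(), pool_layer(2L),
                  flatten_layer(), dense_layer(5L), relu_layer(),
                  dense_layer(n_classes)),
    cut_index = 3L)
}

random_batch <- function(n = 4L, size = 8L, n_classes = 3L, seed = 7L) {
  withr::with_seed(seed, list(
    X = array(stats::runif(size * size * n, -1, 1), dim = c(size, size, n)),
    y = sample(0:(n_classes - 1), n, replace = TRUE)))
}

small_dataset <- function(n_per_class = 15L) {
  raw <- generate_synthetic_images(n_per_class, 4L, 32L, seed = 11L)
  split_train_test(preprocess(raw), 0.2, seed = 3L)
}

# A single linear 2-class head on a scalar activation with all-zero weights
# and bias: the analytic toy for the attack arithmetic.
linear_toy_head <- function() {
  splitfedlab:::new_part(
    layers = list(dense_layer(2L)),
    params = list(list(W = matrix(0, 1, 2), b = c(0, 0))),
    input_shape = 1L, role = "server_part")
}

# Memoised small trained state so attack/protocol tests share one training.
.fixture_env <- new.env(parent = emptyenv())
small_trained_state <- function() {
  if (is.null(.fixture_env$state)) {
    ds <- small_dataset(25L)
    plan <- partition(ds$train, 2L, seed = 5L)
    cfg <- train_config(k = 2L, epochs = 3L, batch_size = 32L, seed = 5L,
                        stop_accuracy = 0.9)
    .fixture_env$state <- train_splitfed(ds$train, plan, cfg, test = ds$test)
    .fixture_env$ds <- ds
  }
  list(state = .fixture_env$state, ds = .fixture_env$ds)
}
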