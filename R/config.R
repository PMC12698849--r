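# Experiment configuration files: a flat YAML document resolved against
# defaults, shared by the command-line interface and scripted runs.

default_experiment_config <- function() {
  list(
    data = list(source = "synthetic", path = NULL, n_per_class = 200L,
                n_classes = 4L, image_size = 32L, seed = 0L,
                test_fraction = 0.2),
    train = list(k = 2L, epochs = 15L, batch_size = 64L, lr = 0.001,
                 optimizer = "adam", amsgrad = TRUE, seed = 1L,
                 aggregate_every = 1L, stop_accuracy = 0.90),
    dp = list(enabled = FALSE, family = "cauchy", location = 0, scale = 1,
              targets = c("activations", "gradients")),
    attack = list(n_samples = 100L, seed = 1L, clone = "exact"),
    sweep = list(families = c("gaussian", "laplace", "cauchy",
                              "exponential"),
                 scales = c(0.01, 0.1, 1, 10), seeds = 1:3,
                 retrain = FALSE))
}

modify_defaults <- function(defaults, override) {
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && is.list(override[[nm]]))
      defaults[[nm]] <- modify_defaults(defaults[[nm]], override[[nm]])
    else defaults[[nm]] <- override[[nm]]
  }
  defaults
}

#' Read and resolve an experiment configuration
#'
#' Reads a YAML file with (any subset of) the sections `data`, `train`,
#' `dp`, `attack`, and `sweep`, filling unspecified keys from the package
#' defaults. `read_experiment_config(NULL)` returns the defaults.
#'
#' @param path YAML file, or `NULL` for defaults
#' @return a nested configuration list
#' @export
read_experiment_config <- function(path = NULL) {
  cfg <- default_experiment_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    cfg <- modify_defaults(cfg, yaml::read_yaml(path))
  }
  cfg
}

#' Materialise the dataset an experiment config describes
#'
#' Synthetic source: generates, preprocesses and splits the image set.
#' Folder source: reads the class-per-subdirectory tree at `cfg$data$path`.
#'
#' @param cfg a resolved experiment config
#' @return list with `train` and `test` preprocessed `labeled_image_set`s
#' @export
config_dataset <- function(cfg) {
  dc <- cfg$data
  data <- if (identical(dc$source, "folder")) {
    load_image_folder(dc$path, dc$image_size)
  } else {
    generate_synthetic_images(dc$n_per_class, dc$n_classes, dc$image_size,
                              seed = dc$seed)
  }
  split_train_test(preprocess(data), dc$test_fraction,
                   seed = dc$seed + 1L)
}

#' Build the [train_config()] an experiment config describes
#'
#' @param cfg a resolved experiment config
#' @return a `train_config` with the DP noise spec attached when enabled
#' @export
config_train_config <- function(cfg) {
  tc <- cfg$train
  dp <- NULL
  if (isTRUE(cfg$dp$enabled))
    dp <- noise_spec(cfg$dp$family, cfg$dp$location, cfg$dp$scale,
                     unlist(cfg$dp$targets))
  train_config(k = tc$k, epochs = tc$epochs, batch_size = tc$batch_size,
               lr = tc$lr, optimizer = tc$optimizer, amsgrad = tc$amsgrad,
               seed = tc$seed, dp = dp,
               aggregate_every = tc$aggregate_every,
               stop_accuracy = tc$stop_accuracy)
}

#' Save and restore a trained SplitFed model
#'
#' Checkpoints are plain JSON: the model spec (layers, cut, shapes) plus the
#' flat parameter vectors of the global client part and the server part in
#' the documented stable order (layers in order, weights before biases).
#' Reloading reproduces forward passes bit-for-bit on the same platform.
#'
#' @param state a `federated_state`
#' @param path output JSON file
#' @return `save_checkpoint`: `path` invisibly; `load_checkpoint`: a
#'   `federated_state` (single aggregated client, no optimizer state)
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "federated_state"))
  spec <- state$spec
  payload <- list(
    image_size = spec$input_shape[1], n_classes = spec$n_classes,
    cut_index = spec$cut_index,
    layers = lapply(spec$layers, function(l) l[!vapply(l, is.null,
                                                       logical(1))]),
    client_flat = part_flatten(state$global_client),
    server_flat = part_flatten(state$server),
    n_i = state$n_i, t = state$t)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname save_checkpoint
#' @param path checkpoint file written by `save_checkpoint`
#' @export
load_checkpoint <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  layers <- lapply(p$layers, function(l) {
    for (nm in c("filters", "ksize", "size", "units"))
      if (!is.null(l[[nm]])) l[[nm]] <- as.integer(l[[nm]])
    l
  })
  p$client_flat <- as.numeric(unlist(p$client_flat))
  p$server_flat <- as.numeric(unlist(p$server_flat))
  p$n_i <- as.numeric(unlist(p$n_i))
  spec <- split_model_spec(image_size = as.integer(p$image_size),
                           n_classes = as.integer(p$n_classes),
                           layers = layers,
                           cut_index = as.integer(p$cut_index))
  parts <- build_split_model(spec, seed = 1L)
  client <- part_unflatten(parts$client, p$client_flat)
  server <- part_unflatten(parts$server, p$server_flat)
  structure(list(spec = spec, clients = list(client),
                 global_client = client, server = server, n_i = p$n_i,
                 t = p$t, cfg = train_config(k = 1L), shared_noisy = NULL,
                 pristine = NULL, history = NULL),
            class = "federated_state")
}
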