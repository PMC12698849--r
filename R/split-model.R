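#' Specify a two-part split convolutional classifier
#'
#' Defines the layer stack of the classifier and the cut position at which it
#' is divided between the client part (input side, up to and including
#' `cut_index`) and the server part (the remainder, ending in a dense layer
#' with one unit per class). The default stack is
#' Conv(8, 3x3) - ReLU - MaxPool(2) - Conv(16, 3x3) - ReLU - MaxPool(2) -
#' [cut] - Flatten - Dense(64) - ReLU - Dense(n_classes), so the "smashed
#' data" crossing the cut is a spatial activation map.
#'
#' @param image_size input image side length in pixels (square, grayscale)
#' @param n_classes number of output classes
#' @param layers optional custom layer list built with [conv_layer()] and
#'   friends; the last layer must be a dense layer with `n_classes` units
#' @param cut_index index of the last client-side layer; must satisfy
#'   `1 <= cut_index < length(layers)`
#' @return an object of class `split_model_spec`
#' @examples
#' spec <- split_model_spec(image_size = 32, n_classes = 4)
#' spec$shapes[[spec$cut_index]]  # shape of the smashed activations
#' @export
split_model_spec <- function(image_size = 32L, n_classes = 4L, layers = NULL,
                             cut_index = NULL) {
  stopifnot(image_size >= 8L, n_classes >= 2L)
  if (is.null(layers)) {
    layers <- list(conv_layer(8L, 3L), relu_layer(), pool_layer(2L),
                   conv_layer(16L, 3L), relu_layer(), pool_layer(2L),
                   flatten_layer(), dense_layer(64L),
                   relu_layer(), dense_layer(n_classes))
    if (is.null(cut_index)) cut_index <- 6L
  }
  if (is.null(cut_index))
    stop("cut_index must be given with a custom layer list")
  cut_index <- as.integer(cut_index)
  if (cut_index < 1L || cut_index >= length(layers))
    stop("cut_index must satisfy 1 <= cut_index < number of layers (",
         length(layers), ")")
  last <- layers[[length(layers)]]
  if (last$type != "dense" || last$units != n_classes)
    stop("final layer must be a dense layer with n_classes = ", n_classes,
         " units")
  input_shape <- c(as.integer(image_size), as.integer(image_size), 1L)
  shapes <- infer_shapes(layers, input_shape)  # validates the stack
  structure(list(layers = layers, cut_index = cut_index,
                 input_shape = input_shape,
                 n_classes = as.integer(n_classes), shapes = shapes),
            class = "split_model_spec")
}

#' @export
print.split_model_spec <- function(x, ...) {
  cat("Split model spec:", length(x$layers), "layers, cut after layer",
      x$cut_index, "\n")
  for (i in seq_along(x$layers)) {
    side <- if (i <= x$cut_index) "client" else "server"
    cat(sprintf("  [%2d] %-8s -> %-12s (%s)\n", i, x$layers[[i]]$type,
                paste(x$shapes[[i]], collapse = "x"), side))
  }
  invisible(x)
}

# Shape of the activations crossing the cut.
cut_shape <- function(spec) spec$shapes[[spec$cut_index]]

#' Initialise the two parts of a split model
#'
#' Draws He-initialised weights for the full layer stack under `seed` and
#' splits them at the cut, so the client and server parts compose to exactly
#' the classifier that monolithic initialisation with the same seed yields.
#'
#' @param spec a [split_model_spec()]
#' @param seed integer seed; identical seeds give bitwise-identical weights
#' @return list with elements `client` and `server`, each a `model_part`
#' @export
build_split_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "split_model_spec"))
  params <- withr::with_seed(as.integer(seed),
                             init_layer_params(spec$layers, spec$input_shape))
  ci <- spec$cut_index
  client <- new_part(spec$layers[seq_len(ci)], params[seq_len(ci)],
                     spec$input_shape, role = "client_part")
  server <- new_part(spec$layers[(ci + 1L):length(spec$layers)],
                     params[(ci + 1L):length(spec$layers)],
                     cut_shape(spec), role = "server_part")
  list(client = client, server = server)
}

#' Compose the two parts back into one monolithic model
#'
#' The result is a single `model_part` whose forward and backward passes run
#' the whole stack at once; it is the reference against which split-model
#' equivalence is asserted.
#'
#' @param client,server the two parts from [build_split_model()]
#' @return a `model_part` covering the full stack
#' @export
combine_parts <- function(client, server) {
  new_part(c(client$layers, server$layers), c(client$params, server$params),
           client$input_shape, role = "monolithic")
}

#' Client-side forward pass
#'
#' Runs the batch through the client part and returns the cut-layer
#' ("smashed") activations that would be transmitted to the main server.
#'
#' @param client the client `model_part`
#' @param X an image batch: `(H, W, N)` or `(H, W, 1, N)` array of pixels,
#'   normally preprocessed to `[-1, 1]`
#' @param client_id integer tag identifying the originating client
#' @param indices optional sample indices carried as batch metadata
#' @param keep_cache retain the layer caches needed for the later backward
#'   pass through the client part
#' @return an object of class `smashed_batch` with fields `activations`,
#'   `client_id`, `indices`, `tag` and (optionally) `cache`
#' @export
client_forward <- function(client, X, client_id = 1L, indices = NULL,
                           keep_cache = FALSE) {
  fw <- part_forward(client, X, keep_cache = keep_cache)
  n <- dim(fw$out)[length(dim(fw$out))]
  structure(list(activations = fw$out, client_id = client_id,
                 indices = indices %||% seq_len(n),
                 tag = sprintf("c%d-%d", client_id, next_tag()),
                 cache = fw$caches),
            class = "smashed_batch")
}

#' Server-side forward pass
#'
#' Maps smashed activations through the server part to raw class scores.
#'
#' @param server the server `model_part`
#' @param smashed a `smashed_batch` (or a bare activation array)
#' @return matrix of raw scores, `n_classes` rows, one column per sample
#' @export
server_forward <- function(server, smashed) {
  act <- if (inherits(smashed, "smashed_batch")) smashed$activations else smashed
  part_forward(server, act, keep_cache = FALSE)$out
}

#' Full forward pass of the composed model
#'
#' @inheritParams client_forward
#' @param part a monolithic `model_part` from [combine_parts()]
#' @return matrix of raw class scores (`n_classes` x n)
#' @export
monolithic_forward <- function(part, X) part_forward(part, X)$out

#' Mean cross-entropy loss of class scores
#'
#' Thin wrapper over [softmax_cross_entropy()] returning just the scalar.
#'
#' @param scores raw class-score matrix (`n_classes` rows)
#' @param labels integer labels in `0:(n_classes-1)`
#' @return non-negative scalar loss
#' @export
cross_entropy_loss <- function(scores, labels) {
  softmax_cross_entropy(scores, labels)$loss
}

#' Flat parameter view of a model part
#'
#' Concatenates all parameters in a stable order: layers in order, each
#' layer's weights before its biases. `part_unflatten` inverts it exactly.
#'
#' @param part a `model_part`
#' @param flat numeric vector from `part_flatten`
#' @return `part_flatten`: numeric vector; `part_unflatten`: a `model_part`
#'   with the same structure as `part` and parameters taken from `flat`
#' @export
part_flatten <- function(part) flatten_params(part$params)

#' @rdname part_flatten
#' @export
part_unflatten <- function(part, flat) {
  part$params <- unflatten_params(flat, part$params)
  part
}

#' @rdname part_flatten
#' @export
part_param_count <- function(part) param_count(part$params)

#' Predict class labels with a composed or partial model
#'
#' @param client,server the two model parts
#' @param X image batch
#' @return integer vector of predicted labels in `0:(n_classes-1)`
#' @export
predict_labels <- function(client, server, X) {
  scores <- server_forward(server, client_forward(client, X))
  max.col(t(scores), ties.method = "first") - 1L
}
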