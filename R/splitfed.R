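# SplitFed orchestration: per-batch client forward -> server loss/backward/
# update -> gradient return -> client backward/update, with federated
# averaging of the client-side parts at the end of each round. A centralized
# trainer over the composed monolithic network is provided as the reference
# trajectory (with one client and no noise the two coincide).

#' Training configuration
#'
#' @param k number of clients
#' @param epochs training rounds (one pass over every client's shard each)
#' @param batch_size minibatch size
#' @param lr learning rate eta
#' @param optimizer `"adam"` (default, with optional AMSGrad) or `"sgd"`
#'   (the plain gradient-descent form in which the update equations are
#'   written)
#' @param amsgrad use the AMSGrad variant of Adam
#' @param beta1,beta2,eps Adam moment decay rates and stabiliser
#' @param seed integer seed controlling initialisation, shuffling, and noise
#' @param dp optional [noise_spec()]; `NULL` disables the defense
#' @param aggregate_every federated-averaging period in epochs
#' @param labels_at `"server"` (labels accompany the smashed data so the main
#'   server computes the loss) or `"client"` (loss computed client-side); the
#'   in-process computation is identical, the flag records the threat-model
#'   wiring
#' @param shuffle reshuffle each client's shard every epoch
#' @param stop_accuracy optional early-stop threshold on held-out accuracy
#'   (only used when `train_splitfed` is given a `test` set)
#' @return a `train_config` list
#' @export
train_config <- function(k = 2L, epochs = 10L, batch_size = 64L, lr = 0.001,
                         optimizer = c("adam", "sgd"), amsgrad = TRUE,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8, seed = 1L,
                         dp = NULL, aggregate_every = 1L,
                         labels_at = c("server", "client"), shuffle = TRUE,
                         stop_accuracy = NULL) {
  optimizer <- match.arg(optimizer)
  labels_at <- match.arg(labels_at)
  stopifnot(k >= 1L, epochs >= 0L, batch_size >= 1L, lr >= 0)
  if (!is.null(dp)) stopifnot(inherits(dp, "noise_spec"))
  structure(list(k = as.integer(k), epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 optimizer = optimizer, amsgrad = amsgrad, beta1 = beta1,
                 beta2 = beta2, eps = eps, seed = as.integer(seed), dp = dp,
                 aggregate_every = as.integer(aggregate_every),
                 labels_at = labels_at, shuffle = shuffle,
                 stop_accuracy = stop_accuracy),
            class = "train_config")
}

# ---- optimizers -------------------------------------------------------------

opt_init <- function(params) {
  zeros <- tree_map(params, function(w) array(0, dim = dim(w) %||% length(w)))
  list(t = 0L, m = zeros, v = zeros, vmax = zeros)
}

# One optimizer step; returns updated params and state. Adam follows the
# standard bias-corrected recursion, with AMSGrad keeping the running max of
# the second moment.
opt_step <- function(params, grads, opt, cfg) {
  if (cfg$lr == 0) return(list(params = params, opt = opt))
  if (cfg$optimizer == "sgd") {
    return(list(params = tree_op(params, grads,
                                 function(w, g) w - cfg$lr * g),
                opt = opt))
  }
  opt$t <- opt$t + 1L
  opt$m <- tree_op(opt$m, grads,
                   function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g)
  opt$v <- tree_op(opt$v, grads,
                   function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g^2)
  bc1 <- 1 - cfg$beta1^opt$t
  bc2 <- 1 - cfg$beta2^opt$t
  if (cfg$amsgrad) {
    opt$vmax <- tree_op(opt$vmax, opt$v, pmax)
    denom <- opt$vmax
  } else denom <- opt$v
  step <- tree_op(opt$m, denom, function(m, v)
    cfg$lr * (m / bc1) / (sqrt(v / bc2) + cfg$eps))
  list(params = tree_op(params, step, `-`), opt = opt)
}

# Apply an optimizer step to a part (opt state rides on the part), then the
# update-rule noise injection when configured.
apply_update <- function(part, grads, cfg) {
  if (is.null(part$opt)) part$opt <- opt_init(part$params)
  st <- opt_step(part$params, grads, part$opt, cfg)
  part$params <- st$params
  part$opt <- st$opt
  if (!is.null(cfg$dp) && "update" %in% cfg$dp$targets) {
    noise <- tree_map(part$params, function(w)
      array(sample_noise(cfg$dp, length(w)), dim = dim(w) %||% length(w)))
    part$params <- tree_op(part$params, noise, `+`)
  }
  part
}

# ---- protocol steps ---------------------------------------------------------

#' Server-side training step
#'
#' The main server runs the smashed activations through its part, computes
#' the cross-entropy loss against the labels transmitted with the batch,
#' backpropagates, updates its own parameters with the configured optimizer,
#' and returns the gradient of the loss w.r.t. the smashed data for the
#' client to continue the backward pass.
#'
#' @param server the server `model_part`
#' @param smashed a `smashed_batch` from [client_forward()]
#' @param labels integer labels for the batch samples
#' @param cfg a [train_config()]
#' @return list with `server` (updated part), `packet` (a `gradient_packet`
#'   carrying `d_smashed`, the batch tag and metadata), `loss`, and `scores`
#' @export
server_step <- function(server, smashed, labels, cfg) {
  n <- dim(smashed$activations)[length(dim(smashed$activations))]
  if (length(labels) != n)
    stop("batch carries ", n, " samples but ", length(labels), " labels")
  fw <- part_forward(server, smashed$activations, keep_cache = TRUE)
  ce <- softmax_cross_entropy(fw$out, labels)
  bw <- part_backward(server, fw$caches, ce$dscores)
  server <- apply_update(server, bw$grads, cfg)
  packet <- structure(list(d_smashed = bw$dinput, tag = smashed$tag,
                           client_id = smashed$client_id,
                           indices = smashed$indices, n = n),
                      class = "gradient_packet")
  list(server = server, packet = packet, loss = ce$loss, scores = fw$out)
}

#' Client-side training step
#'
#' Continues backpropagation from the returned smashed-data gradient through
#' the client part (using the caches of its own clean forward pass) and
#' applies the optimizer update. The resulting client parameter gradients
#' are attached as attribute `"grads"`.
#'
#' @param client the client `model_part`
#' @param smashed the `smashed_batch` this client produced (with
#'   `keep_cache = TRUE`)
#' @param packet the `gradient_packet` returned by [server_step()] for the
#'   same batch
#' @param cfg a [train_config()]
#' @return the updated client `model_part`
#' @export
client_step <- function(client, smashed, packet, cfg) {
  if (!identical(packet$tag, smashed$tag))
    stop("stale gradient packet: tag ", packet$tag,
         " does not match batch tag ", smashed$tag)
  if (is.null(smashed$cache))
    stop("smashed batch was produced without keep_cache = TRUE")
  bw <- part_backward(client, smashed$cache, packet$d_smashed)
  client <- apply_update(client, bw$grads, cfg)
  attr(client, "grads") <- bw$grads
  client
}

#' Federated averaging of client-side parts
#'
#' Elementwise weighted mean of parameter trees with weights
#' `n_i / sum(n_j)` — the aggregation the federated server performs on the
#' client-side parts each round.
#'
#' @param clients list of `model_part`s (or bare parameter trees) of
#'   identical structure
#' @param weights non-negative client weights `n_i`, not all zero
#' @return an object of the same type as `clients[[1]]` holding the average
#' @export
fedavg <- function(clients, weights) {
  stopifnot(length(clients) >= 1L, length(weights) == length(clients))
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  trees <- lapply(clients, function(cl)
    if (inherits(cl, "model_part")) cl$params else cl)
  ref <- lapply(trees, function(tr) vapply(tr, function(p)
    if (is.null(p)) 0L else length(p$W) + length(p$b), integer(1)))
  if (!all(vapply(ref, identical, logical(1), ref[[1]])))
    stop("client parameter structures do not match")
  acc <- tree_map(trees[[1]], function(x) x * w[1])
  for (i in seq_along(trees)[-1])
    acc <- tree_op(acc, tree_map(trees[[i]], function(x) x * w[i]), `+`)
  if (inherits(clients[[1]], "model_part")) {
    out <- clients[[1]]
    out$params <- acc
    attr(out, "grads") <- NULL
    out
  } else acc
}

# Deterministic per-(seed, epoch, client) shard ordering.
epoch_order <- function(seed, epoch, client, idx, shuffle = TRUE) {
  if (!shuffle) return(idx)
  s <- ((seed %% 1000003) * 1009 + epoch * 101 + client) %% 2147483647
  withr::with_seed(as.integer(s), idx[sample.int(length(idx))])
}

chunk_indices <- function(idx, size) {
  split(idx, ceiling(seq_along(idx) / size))
}

#' Train a classifier with split federated learning
#'
#' Runs `cfg$epochs` rounds. Within a round the main server processes the
#' clients sequentially; for each of a client's minibatches the client
#' forward pass produces smashed activations, the server computes the loss
#' and updates its part, the smashed-data gradient is returned, and the
#' client completes the backward pass and updates its part. At the end of
#' each aggregation period the client parts are federated-averaged with
#' weights `n_i` and redistributed, after which all clients hold identical
#' client-side parameters. With DP enabled, noise is injected at every
#' configured target: transmitted activations, returned gradients, outbound
#' parameter copies (with clean-state restoration), and/or the update rule.
#'
#' @param data a preprocessed `labeled_image_set`
#' @param plan a [partition()] plan with `cfg$k` shards
#' @param cfg a [train_config()]
#' @param test optional held-out `labeled_image_set`; evaluated each epoch
#'   and used for `cfg$stop_accuracy` early stopping
#' @param spec optional [split_model_spec()]; defaults to the standard stack
#'   sized from the data
#' @return an object of class `federated_state` with the trained parts,
#'   client weights, round counter, config, and per-epoch `history`
#'   (data.frame of loss/accuracy)
#' @export
train_splitfed <- function(data, plan, cfg, test = NULL, spec = NULL) {
  stopifnot(inherits(plan, "partition_plan"), inherits(cfg, "train_config"))
  if (plan$k != cfg$k)
    stop("partition has ", plan$k, " shards but cfg$k = ", cfg$k)
  if (is.null(spec))
    spec <- split_model_spec(image_size = dim(data$images)[1],
                             n_classes = length(data$class_names))
  parts <- build_split_model(spec, cfg$seed)
  clients <- replicate(cfg$k, parts$client, simplify = FALSE)
  server <- parts$server
  # one ambient stream for all noise draws; everything else is locally seeded
  set.seed(as.integer((cfg$seed * 31 + 17) %% 2147483647))
  hist_rows <- list()
  shared_noisy <- NULL
  dp <- cfg$dp
  for (epoch in seq_len(cfg$epochs)) {
    tot_loss <- 0; tot_correct <- 0L; tot_n <- 0L
    for (i in seq_len(cfg$k)) {
      idx <- epoch_order(cfg$seed, epoch, i, plan$shard_indices[[i]],
                         cfg$shuffle)
      for (b in chunk_indices(idx, cfg$batch_size)) {
        Xb <- data$images[, , b, drop = FALSE]
        yb <- data$labels[b]
        sm <- client_forward(clients[[i]], Xb, client_id = i, indices = b,
                             keep_cache = TRUE)
        sm_tx <- sm
        if (!is.null(dp) && "activations" %in% dp$targets)
          sm_tx <- add_noise_to_transmission(sm, dp)$noisy
        st <- server_step(server, sm_tx, yb, cfg)
        server <- st$server
        packet <- st$packet
        if (!is.null(dp) && "gradients" %in% dp$targets)
          packet <- add_noise_to_transmission(packet, dp)$noisy
        clients[[i]] <- client_step(clients[[i]], sm, packet, cfg)
        if (!is.finite(st$loss))
          stop("non-finite loss at epoch ", epoch, ", client ", i)
        pred <- max.col(t(st$scores), ties.method = "first") - 1L
        tot_loss <- tot_loss + st$loss * length(yb)
        tot_correct <- tot_correct + sum(pred == yb)
        tot_n <- tot_n + length(yb)
      }
    }
    if (epoch %% cfg$aggregate_every == 0L || epoch == cfg$epochs) {
      if (!is.null(dp) && "parameters" %in% dp$targets) {
        # noise perturbs the outbound copies the aggregator/adversary sees;
        # clean local state is restored (restoration mechanism)
        shared_noisy <- lapply(clients, add_noise_to_params, spec = dp)
        global <- fedavg(clients, plan$shard_sizes)
      } else {
        global <- fedavg(clients, plan$shard_sizes)
      }
      for (i in seq_len(cfg$k)) clients[[i]]$params <- global$params
    }
    test_acc <- NA_real_
    if (!is.null(test)) {
      pred <- predict_labels(clients[[1]], server, test$images)
      test_acc <- mean(pred == test$labels)
    }
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, loss = tot_loss / tot_n,
      accuracy = tot_correct / tot_n, test_accuracy = test_acc)
    if (!is.null(cfg$stop_accuracy) && !is.na(test_acc) &&
        test_acc >= cfg$stop_accuracy) break
  }
  structure(list(spec = spec, clients = clients,
                 global_client = clients[[1]], server = server,
                 n_i = plan$shard_sizes, t = length(hist_rows),
                 cfg = cfg, shared_noisy = shared_noisy, pristine = NULL,
                 history = do.call(rbind, hist_rows)),
            class = "federated_state")
}

#' @export
print.federated_state <- function(x, ...) {
  cat("SplitFed state:", length(x$clients), "clients,", x$t,
      "rounds trained\n")
  if (!is.null(x$history)) print(utils::tail(x$history, 3L))
  invisible(x)
}

#' Train the composed monolithic model centrally
#'
#' Reference trajectory: the identical network, initialisation, batch
#' ordering and optimizer, but trained as a single model without the split.
#' With `k = 1` and DP off, [train_splitfed()] reproduces this trajectory.
#'
#' @param data a preprocessed `labeled_image_set`
#' @param cfg a [train_config()] (its `k` is ignored; one worker)
#' @param indices optional training index set (defaults to all samples)
#' @param spec optional [split_model_spec()]
#' @return list with `part` (trained monolithic `model_part`) and `history`
#' @export
train_centralized <- function(data, cfg, indices = NULL, spec = NULL) {
  if (is.null(spec))
    spec <- split_model_spec(image_size = dim(data$images)[1],
                             n_classes = length(data$class_names))
  parts <- build_split_model(spec, cfg$seed)
  part <- combine_parts(parts$client, parts$server)
  indices <- indices %||% seq_len(n_images(data))
  hist_rows <- list()
  for (epoch in seq_len(cfg$epochs)) {
    idx <- epoch_order(cfg$seed, epoch, 1L, indices, cfg$shuffle)
    tot_loss <- 0; tot_n <- 0L
    for (b in chunk_indices(idx, cfg$batch_size)) {
      Xb <- data$images[, , b, drop = FALSE]
      yb <- data$labels[b]
      fw <- part_forward(part, Xb, keep_cache = TRUE)
      ce <- softmax_cross_entropy(fw$out, yb)
      bw <- part_backward(part, fw$caches, ce$dscores)
      part <- apply_update(part, bw$grads, cfg)
      tot_loss <- tot_loss + ce$loss * length(yb)
      tot_n <- tot_n + length(yb)
    }
    hist_rows[[epoch]] <- data.frame(epoch = epoch, loss = tot_loss / tot_n)
  }
  list(part = part, history = do.call(rbind, hist_rows))
}

#' Evaluate a trained SplitFed model on a test set
#'
#' Deterministic forward pass of the global client part and the server part
#' over the test set, followed by the standard classification report.
#'
#' @param state a `federated_state`
#' @param test a preprocessed `labeled_image_set`
#' @return a `metrics_report` (see [compute_metrics()])
#' @export
evaluate_model <- function(state, test) {
  stopifnot(inherits(state, "federated_state"))
  if (n_images(test) == 0L) stop("empty test set")
  pred <- predict_labels(state$global_client, state$server, test$images)
  compute_metrics(test$labels, pred, state$spec$n_classes)
}
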