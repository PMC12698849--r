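# Gradient-matching label inference: an honest-but-curious adversary holding
# a clone of the score-producing part downstream of the cut enumerates the
# candidate labels and, for each observed sample, picks the candidate whose
# clone-model parameter gradients have the lowest mean squared error against
# the observed gradients:
#   z* = argmin_{z in Y} MSE( dL(f2(f1(x)), y)/dPhi2 , dL(clone(f1(x)), z)/dPhi_clone )
# where f1(x) is the cut activation the adversary also observes. With an
# exact clone and no noise the MSE at the true label is exactly zero, so the
# attack recovers every label.

# Gradient of the mean cross-entropy w.r.t. the parameters of `part` for a
# single sample's input activation and a label; returns the flat view.
head_gradient <- function(part, activation, label) {
  fw <- part_forward(part, activation, keep_cache = TRUE)
  ce <- softmax_cross_entropy(fw$out, label)
  bw <- part_backward(part, fw$caches, ce$dscores)
  flatten_params_grads(bw$grads, part$params)
}

# Grad trees may have NULL entries for parameter-free layers; flatten in the
# same stable order as the parameters themselves.
flatten_params_grads <- function(grads, template) {
  out <- lapply(seq_along(template), function(i) {
    if (is.null(template[[i]])) return(numeric(0))
    c(as.vector(grads[[i]]$W), as.vector(grads[[i]]$b))
  })
  unlist(out, use.names = FALSE)
}

#' Record the per-sample gradients an adversary observes
#'
#' For each sample, computes the cut activation and the exact gradient of
#' the loss at the true label w.r.t. the attacked part's parameters (flat
#' view, one sample per record, never batched). When a
#' transmission [noise_spec()] is supplied, the recorded quantities are the
#' noisy ones the adversary would see: activation noise perturbs the
#' transmitted cut activation (and the gradient is the one computed at that
#' noisy activation), gradient noise perturbs the observed parameter
#' gradient.
#'
#' @param state a trained `federated_state`
#' @param samples a `labeled_image_set` subset (one record per image)
#' @param noise optional [noise_spec()] applied to the observations
#' @return list of `observed_gradient` records with fields `grad` (flat
#'   numeric), `activation`, and `true_label`
#' @export
record_observed_gradients <- function(state, samples, noise = NULL) {
  stopifnot(inherits(state, "federated_state"))
  n <- n_images(samples)
  if (n == 0L) stop("empty sample subset")
  attacked <- state$server
  sm <- client_forward(state$global_client, samples$images)
  act <- sm$activations
  d <- dim(act)
  lapply(seq_len(n), function(i) {
    a <- if (length(d) == 4L) act[, , , i, drop = FALSE]
         else act[, i, drop = FALSE]
    if (!is.null(noise) && "activations" %in% noise$targets)
      a <- a + array(sample_noise(noise, length(a)),
                     dim = dim(a) %||% length(a))
    g <- head_gradient(attacked, a, samples$labels[i])
    if (!is.null(noise) && "gradients" %in% noise$targets)
      g <- g + sample_noise(noise, length(g))
    structure(list(grad = g, activation = a,
                   true_label = samples$labels[i]),
              class = "observed_gradient")
  })
}

#' Infer one sample's label by clone-gradient matching
#'
#' For every candidate label `z` in `label_set`, runs the observed cut
#' activation through the clone part, backpropagates the loss at `z`, and
#' computes the mean squared error between the flat clone parameter gradient
#' and the observed gradient. Returns the candidate attaining the minimum
#' (exact ties broken by the lowest label index).
#'
#' @param clone the adversary's clone `model_part` (same architecture as the
#'   attacked part)
#' @param obs an `observed_gradient` record
#' @param label_set integer candidate labels (ascending), default all
#'   classes
#' @return list with `label` (inferred z*) and `mse` (named per-candidate
#'   vector)
#' @export
infer_label <- function(clone, obs, label_set = NULL) {
  if (is.null(label_set)) {
    nc <- clone$layers[[length(clone$layers)]]$units
    label_set <- 0:(nc - 1L)
  }
  if (length(label_set) == 0L) stop("empty candidate label set")
  label_set <- sort(as.integer(label_set))
  mses <- vapply(label_set, function(z) {
    g <- head_gradient(clone, obs$activation, z)
    mean((g - obs$grad)^2)
  }, numeric(1))
  names(mses) <- label_set
  list(label = label_set[which.min(mses)], mse = mses)
}

#' Run the label inference attack over a test subset
#'
#' Iterates [record_observed_gradients()] and [infer_label()] over
#' `n_samples` held-out images and reports the attack accuracy (fraction of
#' samples whose true label is recovered). Deterministic given the state and
#' subset when no noise is configured.
#'
#' @param state a trained `federated_state`
#' @param test a `labeled_image_set` to draw attacked samples from
#' @param n_samples number of samples to attack (capped at the subset size)
#' @param seed integer seed for subset choice and noise draws
#' @param noise optional transmission [noise_spec()] the defense applies to
#'   what the adversary observes
#' @param clone_mode `"exact"` (clone initialised as an exact copy of the
#'   attacked part) or `"reinit"` (freshly initialised clone, the
#'   degraded-knowledge adversary)
#' @return an object of class `attack_result`: data.frame `per_sample`
#'   (true/inferred labels and per-candidate MSEs), `accuracy`, `n`
#' @export
run_attack <- function(state, test, n_samples = 100L, seed = 1L,
                       noise = NULL, clone_mode = c("exact", "reinit")) {
  clone_mode <- match.arg(clone_mode)
  stopifnot(inherits(state, "federated_state"))
  n_samples <- min(as.integer(n_samples), n_images(test))
  if (n_samples < 1L) stop("no samples to attack")
  idx <- withr::with_seed(as.integer(seed),
                          sort(sample.int(n_images(test), n_samples)))
  subset <- test[idx]
  clone <- state$server
  if (clone_mode == "reinit") {
    clone <- build_split_model(state$spec,
                               seed = as.integer(seed) + 1L)$server
  }
  set.seed(as.integer((seed * 131 + 7) %% 2147483647))  # noise stream
  obs <- record_observed_gradients(state, subset, noise = noise)
  label_set <- 0:(state$spec$n_classes - 1L)
  res <- lapply(obs, function(o) infer_label(clone, o, label_set))
  inferred <- vapply(res, `[[`, integer(1), "label")
  mse_mat <- do.call(rbind, lapply(res, `[[`, "mse"))
  colnames(mse_mat) <- paste0("mse_", label_set)
  per_sample <- data.frame(sample = idx, true = subset$labels,
                           inferred = inferred)
  per_sample <- cbind(per_sample, as.data.frame(mse_mat))
  structure(list(per_sample = per_sample,
                 accuracy = mean(inferred == subset$labels),
                 n = n_samples, noise = noise, clone_mode = clone_mode),
            class = "attack_result")
}

#' @export
print.attack_result <- function(x, ...) {
  cat(sprintf("Label inference attack: accuracy %.3f over %d samples (%s clone%s)\n",
              x$accuracy, x$n, x$clone_mode,
              if (is.null(x$noise)) ", no DP noise" else
                sprintf(", %s noise scale %g", x$noise$family,
                        x$noise$scale)))
  invisible(x)
}
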