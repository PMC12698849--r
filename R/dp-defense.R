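# Additive-noise privacy mechanisms: samplers for four distribution
# families, their analytic pdf/cdf, and the three injection points used
# during split federated training — model parameters shared for aggregation,
# transmissions across the cut (activations and gradients), and the
# parameter-update rule itself. No formal (epsilon, delta) accounting is
# performed: the defense is plain additive noise with a location and a scale,
# and its strength is assessed empirically through the attack.

NOISE_FAMILIES <- c("gaussian", "laplace", "cauchy", "exponential")
NOISE_TARGETS <- c("parameters", "activations", "gradients", "update")

#' Describe an additive-noise mechanism
#'
#' @param family one of `"gaussian"`, `"laplace"`, `"cauchy"`,
#'   `"exponential"`
#' @param location location parameter (gamma); for the exponential family the
#'   draws are `location + Exp(mean = scale)`, i.e. one-sided above
#'   `location`
#' @param scale scale parameter (sigma), strictly positive. Gaussian:
#'   standard deviation; Laplace: diversity `b`; Cauchy: half-width at
#'   half-maximum; exponential: the mean of the one-sided part.
#' @param targets where noise is injected, a subset of `"parameters"`
#'   (outbound parameter copies), `"activations"` and `"gradients"` (the two
#'   transmission directions across the cut), and `"update"` (additive noise
#'   in the parameter-update rule)
#' @param seed optional seed making [sample_noise()] self-seeding; when
#'   `NULL` the ambient RNG stream is used
#' @return an object of class `noise_spec`
#' @examples
#' ns <- noise_spec("cauchy", location = 0, scale = 1, targets = "gradients")
#' noise_pdf(ns, 0)  # 1 / pi
#' @export
noise_spec <- function(family, location = 0, scale = 1,
                       targets = c("activations", "gradients"),
                       seed = NULL) {
  family <- match.arg(family, NOISE_FAMILIES)
  if (!is.numeric(scale) || scale <= 0) stop("scale must be > 0")
  targets <- unique(match.arg(targets, NOISE_TARGETS, several.ok = TRUE))
  if (length(targets) == 0L) stop("at least one injection target required")
  structure(list(family = family, location = location, scale = scale,
                 targets = targets, seed = seed),
            class = "noise_spec")
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("Noise spec: %s(location = %g, scale = %g) on {%s}\n",
              x$family, x$location, x$scale,
              paste(x$targets, collapse = ", ")))
  invisible(x)
}

#' Draw i.i.d. noise from a noise specification
#'
#' @param spec a [noise_spec()]
#' @param shape integer vector: dimensions of the returned array (a single
#'   integer gives a plain vector)
#' @return numeric array of i.i.d. draws with the spec's family, location
#'   and scale
#' @export
sample_noise <- function(spec, shape) {
  stopifnot(inherits(spec, "noise_spec"))
  n <- prod(shape)
  draw <- function() {
    switch(spec$family,
      gaussian = stats::rnorm(n, mean = spec$location, sd = spec$scale),
      laplace = {
        u <- stats::runif(n, -0.5, 0.5)
        spec$location - spec$scale * sign(u) * log1p(-2 * abs(u))
      },
      cauchy = stats::rcauchy(n, location = spec$location,
                              scale = spec$scale),
      exponential = spec$location + stats::rexp(n, rate = 1 / spec$scale))
  }
  x <- if (is.null(spec$seed)) draw() else
    withr::with_seed(as.integer(spec$seed), draw())
  if (length(shape) > 1L) array(x, dim = shape) else x
}

#' Analytic density and distribution function of a noise family
#'
#' Closed-form pdf/cdf at `x`, used for goodness-of-fit checks of the
#' samplers. In particular the Cauchy pdf is
#' `1 / (pi * sigma * (1 + ((x - gamma)/sigma)^2))`, so its value at
#' `x = gamma` is `1 / (pi * sigma)`.
#'
#' @param spec a [noise_spec()]
#' @param x numeric vector of evaluation points
#' @return numeric vector of densities (`noise_pdf`) or cumulative
#'   probabilities (`noise_cdf`)
#' @export
noise_pdf <- function(spec, x) {
  g <- spec$location; s <- spec$scale
  switch(spec$family,
    gaussian = exp(-((x - g)^2) / (2 * s^2)) / (s * sqrt(2 * pi)),
    laplace = exp(-abs(x - g) / s) / (2 * s),
    cauchy = 1 / (pi * s * (1 + ((x - g) / s)^2)),
    exponential = ifelse(x < g, 0, exp(-(x - g) / s) / s))
}

#' @rdname noise_pdf
#' @export
noise_cdf <- function(spec, x) {
  g <- spec$location; s <- spec$scale
  switch(spec$family,
    gaussian = stats::pnorm(x, mean = g, sd = s),
    laplace = ifelse(x < g, 0.5 * exp((x - g) / s),
                     1 - 0.5 * exp(-(x - g) / s)),
    cauchy = stats::pcauchy(x, location = g, scale = s),
    exponential = ifelse(x < g, 0, 1 - exp(-(x - g) / s)))
}

#' Add noise to a model part's parameters
#'
#' Produces the noisy outbound copy `param_noisy = param + noise`,
#' elementwise over every weight and bias. The input part is not modified:
#' under the restoration mechanism the clean parameters remain the local
#' working state and only the returned copy is exposed. The sampled noise is
#' attached as attribute `"noise"` (a parameter tree) so the additive
#' contract `noisy - original == noise` is checkable exactly.
#'
#' @param part a `model_part`
#' @param spec a [noise_spec()] (must include target `"parameters"`)
#' @param noise optional pre-sampled noise tree (test hook); when `NULL`,
#'   noise is drawn from `spec`
#' @return a `model_part` with perturbed parameters and a `"noise"` attribute
#' @export
add_noise_to_params <- function(part, spec, noise = NULL) {
  if (is.null(noise))
    noise <- tree_map(part$params, function(w)
      array(sample_noise(spec, length(w)), dim = dim(w) %||% length(w)))
  noisy <- part
  noisy$params <- tree_op(part$params, noise, `+`)
  attr(noisy, "noise") <- noise
  noisy
}

#' Add noise to a transmission across the cut
#'
#' Applies elementwise additive noise to the transmitted arrays of a smashed
#' batch (the cut activations) or a gradient packet (the smashed-data
#' gradient), leaving labels, indices and other metadata untouched.
#'
#' @param transmission a `smashed_batch` or `gradient_packet`
#' @param spec a [noise_spec()]
#' @param noise optional pre-sampled noise array (test hook)
#' @return a `noisy_transmission_record` list with fields `original`,
#'   `noise`, and `noisy`; `noisy` is the same class of object as the input
#'   with its payload perturbed
#' @export
add_noise_to_transmission <- function(transmission, spec, noise = NULL) {
  if (inherits(transmission, "smashed_batch")) {
    payload <- transmission$activations
    set_payload <- function(t, v) { t$activations <- v; t }
  } else if (inherits(transmission, "gradient_packet")) {
    payload <- transmission$d_smashed
    set_payload <- function(t, v) { t$d_smashed <- v; t }
  } else stop("transmission must be a smashed_batch or gradient_packet")
  if (is.null(noise))
    noise <- array(sample_noise(spec, length(payload)),
                   dim = dim(payload) %||% length(payload))
  noisy <- set_payload(transmission, payload + noise)
  structure(list(original = transmission, noise = noise, noisy = noisy),
            class = "noisy_transmission_record")
}

#' Noisy gradient-descent update
#'
#' The plain SGD step with additive noise:
#' `theta' = theta - eta * grad + noise`, the update-rule injection point
#' (Cauchy noise by default in the source mechanism; any family is allowed).
#'
#' @param part a `model_part` holding `theta`
#' @param grads parameter-gradient tree matching `part$params`
#' @param lr learning rate `eta`
#' @param spec a [noise_spec()]
#' @param noise optional pre-sampled noise tree (test hook); all-zero noise
#'   reduces the update to a plain gradient step
#' @return the updated `model_part`
#' @export
noisy_update <- function(part, grads, lr, spec, noise = NULL) {
  if (is.null(noise))
    noise <- tree_map(part$params, function(w)
      array(sample_noise(spec, length(w)), dim = dim(w) %||% length(w)))
  stepped <- tree_op(part$params, grads, function(w, g) w - lr * g)
  part$params <- tree_op(stepped, noise, `+`)
  part
}

#' Restore clean local parameters after a noisy exposure
#'
#' The restoration mechanism keeps training on clean state: noise perturbs
#' only outbound copies (shared parameters, transmissions), and after each
#' iteration the pristine local parameters are reinstated so noise never
#' accumulates in the model that keeps learning. With injection target
#' `"parameters"` only, the training trajectory therefore equals the
#' noise-free trajectory exactly. A no-op when DP is off.
#'
#' @param state a `federated_state`
#' @return the state with every client's working parameters reset to the
#'   pristine (pre-noise) copies
#' @export
restore_parameters <- function(state) {
  stopifnot(inherits(state, "federated_state"))
  if (is.null(state$cfg$dp)) return(state)
  if (is.null(state$pristine))
    stop("no pristine parameter copy to restore from")
  state$clients <- state$pristine
  state$pristine <- NULL
  state
}
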