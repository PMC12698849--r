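# Minimal CNN engine: forward/backward for conv, max-pool, dense, ReLU,
# flatten layers on batches stored as (H, W, C, N) arrays. Convolutions are
# "valid" (no padding), stride 1, implemented by im2col so all heavy work is
# one matrix product. Gradients are exact analytic backprop; they are checked
# against central finite differences in the test suite.

#' Layer constructors
#'
#' Build the layer descriptors from which a split model specification is
#' assembled. `conv_layer` is a stride-1 valid convolution, `pool_layer` a
#' non-overlapping max pool, `dense_layer` a fully connected layer (only
#' valid after `flatten_layer`), `relu_layer` an elementwise rectifier.
#'
#' @param filters number of convolution filters
#' @param ksize square kernel side length in pixels
#' @param size pooling window (and stride) in pixels
#' @param units number of output units
#' @return a layer descriptor list with a `type` field
#' @name layers
NULL

#' @rdname layers
#' @export
conv_layer <- function(filters, ksize = 3L) {
  stopifnot(filters >= 1L, ksize >= 1L)
  list(type = "conv", filters = as.integer(filters), ksize = as.integer(ksize))
}

#' @rdname layers
#' @export
pool_layer <- function(size = 2L) {
  stopifnot(size >= 1L)
  list(type = "pool", size = as.integer(size))
}

#' @rdname layers
#' @export
relu_layer <- function() list(type = "relu")

#' @rdname layers
#' @export
flatten_layer <- function() list(type = "flatten")

#' @rdname layers
#' @export
dense_layer <- function(units) {
  stopifnot(units >= 1L)
  list(type = "dense", units = as.integer(units))
}

# Propagate shapes through the layer list. input_shape = c(H, W, C) before
# flatten; a single integer (feature count) after. Errors on inconsistent
# specs (kernel larger than the map, dense before flatten, ...).
infer_shapes <- function(layers, input_shape) {
  shapes <- vector("list", length(layers))
  s <- input_shape
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      if (length(s) != 3L)
        stop("conv layer ", i, " expects a spatial input, got flat features")
      if (s[1] < ly$ksize || s[2] < ly$ksize)
        stop("conv layer ", i, ": kernel ", ly$ksize, " exceeds input map ",
             s[1], "x", s[2])
      s <- c(s[1] - ly$ksize + 1L, s[2] - ly$ksize + 1L, ly$filters)
    } else if (ly$type == "pool") {
      if (length(s) != 3L) stop("pool layer ", i, " expects a spatial input")
      if (s[1] < ly$size || s[2] < ly$size)
        stop("pool layer ", i, ": window exceeds input map")
      s <- c(s[1] %/% ly$size, s[2] %/% ly$size, s[3])
    } else if (ly$type == "relu") {
      # shape preserved
    } else if (ly$type == "flatten") {
      if (length(s) != 3L) stop("flatten layer ", i, ": input already flat")
      s <- prod(s)
    } else if (ly$type == "dense") {
      if (length(s) != 1L)
        stop("dense layer ", i, " requires flattened input (add flatten_layer)")
      s <- ly$units
    } else stop("unknown layer type: ", ly$type)
    shapes[[i]] <- s
  }
  shapes
}

# He-style initialisation; biases start at zero. Deterministic given the
# ambient RNG state (callers wrap in withr::with_seed).
init_layer_params <- function(layers, input_shape) {
  shapes <- infer_shapes(layers, input_shape)
  params <- vector("list", length(layers))
  s <- input_shape
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      fan_in <- ly$ksize^2 * s[3]
      params[[i]] <- list(
        W = array(stats::rnorm(fan_in * ly$filters, sd = sqrt(2 / fan_in)),
                  dim = c(ly$ksize, ly$ksize, s[3], ly$filters)),
        b = numeric(ly$filters))
    } else if (ly$type == "dense") {
      fan_in <- s
      params[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * ly$units, sd = sqrt(2 / fan_in)),
                   nrow = fan_in, ncol = ly$units),
        b = numeric(ly$units))
    } else {
      params[i] <- list(NULL)
    }
    s <- shapes[[i]]
  }
  params
}

# im2col index matrix: rows enumerate (output row, output col, sample),
# columns enumerate (kernel row, kernel col, input channel). Entry = linear
# index into the (H, W, C, N) input array.
conv_patch_index <- function(H, W, C, N, k) {
  Ho <- H - k + 1L
  Wo <- W - k + 1L
  oh <- rep(seq_len(Ho), times = Wo * N)
  ow <- rep(rep(seq_len(Wo), each = Ho), times = N)
  nn <- rep(seq_len(N), each = Ho * Wo)
  base <- oh + (ow - 1L) * H + (nn - 1L) * (H * W * C)
  dh <- rep(seq_len(k) - 1L, times = k * C)
  dw <- rep(rep(seq_len(k) - 1L, each = k), times = C)
  cc <- rep(seq_len(C) - 1L, each = k * k)
  offs <- dh + dw * H + cc * (H * W)
  list(idx = outer(base, offs, "+"), Ho = Ho, Wo = Wo)
}

conv_forward <- function(X, W, b) {
  d <- dim(X)
  k <- dim(W)[1]
  nf <- dim(W)[4]
  pi <- conv_patch_index(d[1], d[2], d[3], d[4], k)
  Xcol <- matrix(X[pi$idx], nrow = nrow(pi$idx))
  Wmat <- matrix(W, ncol = nf)
  out_mat <- Xcol %*% Wmat
  out_mat <- sweep(out_mat, 2L, b, "+")
  out <- aperm(array(out_mat, c(pi$Ho, pi$Wo, d[4], nf)), c(1L, 2L, 4L, 3L))
  list(out = out, cache = list(Xcol = Xcol, idx = pi$idx, in_dim = d))
}

conv_backward <- function(dout, W, cache) {
  nf <- dim(W)[4]
  dmat <- matrix(aperm(dout, c(1L, 2L, 4L, 3L)), ncol = nf)
  dW <- array(crossprod(cache$Xcol, dmat), dim = dim(W))
  db <- colSums(dmat)
  dXcol <- tcrossprod(dmat, matrix(W, ncol = nf))
  dX <- numeric(prod(cache$in_dim))
  idx <- cache$idx
  for (j in seq_len(ncol(idx))) {
    jj <- idx[, j]
    dX[jj] <- dX[jj] + dXcol[, j]
  }
  list(dW = dW, db = db, dX = array(dX, dim = cache$in_dim))
}

pool_forward <- function(X, s) {
  d <- dim(X)
  Hp <- d[1] %/% s
  Wp <- d[2] %/% s
  M <- Hp * Wp * d[3] * d[4]
  I <- array(seq_len(prod(d)), dim = d)
  nslot <- s * s
  idxmat <- matrix(0L, nrow = M, ncol = nslot)
  slabs <- matrix(0, nrow = M, ncol = nslot)
  Xv <- as.vector(X)
  slot <- 0L
  for (b in seq_len(s)) {
    for (a in seq_len(s)) {
      slot <- slot + 1L
      sub <- as.vector(I[seq(a, by = s, length.out = Hp),
                         seq(b, by = s, length.out = Wp), , , drop = FALSE])
      idxmat[, slot] <- sub
      slabs[, slot] <- Xv[sub]
    }
  }
  amax <- max.col(slabs, ties.method = "first")
  out <- array(slabs[cbind(seq_len(M), amax)], dim = c(Hp, Wp, d[3], d[4]))
  list(out = out,
       cache = list(chosen = idxmat[cbind(seq_len(M), amax)], in_dim = d))
}

pool_backward <- function(dout, cache) {
  dX <- numeric(prod(cache$in_dim))
  dX[cache$chosen] <- as.vector(dout)   # argmax cells are distinct
  array(dX, dim = cache$in_dim)
}

dense_forward <- function(X, W, b) {
  out <- crossprod(W, X) + b
  list(out = out, cache = list(X = X))
}

dense_backward <- function(dout, W, cache) {
  list(dW = cache$X %*% t(dout),
       db = rowSums(dout),
       dX = W %*% dout)
}

# A model "part" bundles layers, their parameters, and the input shape it
# expects. Both halves of a split model, the monolithic composition, and the
# attacker's clone are all parts.
new_part <- function(layers, params, input_shape, role = "model") {
  structure(list(layers = layers, params = params,
                 input_shape = input_shape, role = role),
            class = "model_part")
}

# Coerce user input to the (H, W, C, N) batch layout the engine uses.
as_batch_array <- function(X, input_shape) {
  if (length(input_shape) == 1L) {
    if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
    stopifnot(nrow(X) == input_shape)
    return(X)
  }
  d <- dim(X)
  if (length(d) == 2L) X <- array(X, dim = c(d, 1L, 1L))
  else if (length(d) == 3L) {
    # (H, W, N) grayscale stack -> insert channel axis
    X <- array(X, dim = c(d[1], d[2], 1L, d[3]))
  }
  d <- dim(X)
  if (!identical(as.integer(d[1:3]), as.integer(input_shape)))
    stop("input shape ", paste(d[1:3], collapse = "x"),
         " does not match expected ", paste(input_shape, collapse = "x"))
  X
}

part_forward <- function(part, X, keep_cache = FALSE) {
  X <- as_batch_array(X, part$input_shape)
  caches <- if (keep_cache) vector("list", length(part$layers)) else NULL
  for (i in seq_along(part$layers)) {
    ly <- part$layers[[i]]
    p <- part$params[[i]]
    if (ly$type == "conv") {
      fw <- conv_forward(X, p$W, p$b)
      X <- fw$out
      if (keep_cache) caches[[i]] <- fw$cache
    } else if (ly$type == "pool") {
      fw <- pool_forward(X, ly$size)
      X <- fw$out
      if (keep_cache) caches[[i]] <- fw$cache
    } else if (ly$type == "relu") {
      if (keep_cache) caches[[i]] <- list(mask = X > 0)
      X <- pmax(X, 0)
    } else if (ly$type == "flatten") {
      d <- dim(X)
      if (keep_cache) caches[[i]] <- list(in_dim = d)
      X <- matrix(X, ncol = d[4])
    } else if (ly$type == "dense") {
      fw <- dense_forward(X, p$W, p$b)
      X <- fw$out
      if (keep_cache) caches[[i]] <- fw$cache
    }
  }
  list(out = X, caches = caches)
}

# Backprop dout through the part; returns per-layer parameter gradients
# (same tree shape as part$params) and the gradient w.r.t. the part input.
part_backward <- function(part, caches, dout) {
  grads <- vector("list", length(part$layers))
  for (i in rev(seq_along(part$layers))) {
    ly <- part$layers[[i]]
    p <- part$params[[i]]
    if (ly$type == "conv") {
      bw <- conv_backward(dout, p$W, caches[[i]])
      grads[[i]] <- list(W = bw$dW, b = bw$db)
      dout <- bw$dX
    } else if (ly$type == "pool") {
      dout <- pool_backward(dout, caches[[i]])
    } else if (ly$type == "relu") {
      dout <- dout * caches[[i]]$mask
    } else if (ly$type == "flatten") {
      dout <- array(dout, dim = caches[[i]]$in_dim)
    } else if (ly$type == "dense") {
      bw <- dense_backward(dout, p$W, caches[[i]])
      grads[[i]] <- list(W = bw$dW, b = bw$db)
      dout <- bw$dX
    } else grads[i] <- list(NULL)
  }
  list(grads = grads, dinput = dout)
}

#' Softmax cross-entropy loss
#'
#' Mean cross-entropy between softmax class probabilities and integer labels,
#' with the gradient w.r.t. the raw scores. This is the training loss of the
#' split classifier and the loss whose parameter gradients the label
#' inference attack matches.
#'
#' @param scores matrix of raw class scores, `n_classes` rows, one column per
#'   sample
#' @param labels integer labels in `0:(n_classes - 1)`, one per column
#' @return list with `loss` (scalar), `probs` (softmax matrix), and `dscores`
#'   (gradient of the mean loss w.r.t. `scores`)
#' @export
softmax_cross_entropy <- function(scores, labels) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L)
  n <- ncol(scores)
  if (length(labels) != n)
    stop("got ", length(labels), " labels for ", n, " score columns")
  if (any(labels < 0L | labels >= nrow(scores)))
    stop("labels must lie in 0..", nrow(scores) - 1L)
  z <- sweep(scores, 2L, apply(scores, 2L, max), "-")
  e <- exp(z)
  p <- sweep(e, 2L, colSums(e), "/")
  picked <- p[cbind(labels + 1L, seq_len(n))]
  loss <- -mean(log(picked))
  onehot <- matrix(0, nrow = nrow(scores), ncol = n)
  onehot[cbind(labels + 1L, seq_len(n))] <- 1
  list(loss = loss, probs = p, dscores = (p - onehot) / n)
}

# ---- parameter tree helpers -------------------------------------------------

# Flat view: layer order, weights before biases (a stable, documented order).
flatten_params <- function(params) {
  out <- lapply(params, function(p) {
    if (is.null(p)) return(numeric(0))
    c(as.vector(p$W), as.vector(p$b))
  })
  unlist(out, use.names = FALSE)
}

unflatten_params <- function(flat, template) {
  pos <- 0L
  out <- vector("list", length(template))
  for (i in seq_along(template)) {
    p <- template[[i]]
    if (is.null(p)) { out[i] <- list(NULL); next }
    nw <- length(p$W); nb <- length(p$b)
    W <- array(flat[pos + seq_len(nw)], dim = dim(p$W) %||% nw)
    if (is.matrix(p$W)) W <- matrix(W, nrow = nrow(p$W))
    out[[i]] <- list(W = W, b = flat[pos + nw + seq_len(nb)])
    pos <- pos + nw + nb
  }
  if (pos != length(flat))
    stop("flat vector length ", length(flat), " does not match template (",
         pos, " parameters)")
  out
}

param_count <- function(params) length(flatten_params(params))

# Keep the result in the same shape as the reference value (a plain vector
# stays a plain vector; arrays keep their dim).
shape_like <- function(v, ref) {
  if (is.null(dim(ref))) as.vector(v) else array(v, dim = dim(ref))
}

# Elementwise binary op over two parameter trees; shapes follow `a`.
tree_op <- function(a, b, f) {
  mapply(function(x, y) {
    if (is.null(x)) return(NULL)
    list(W = shape_like(f(x$W, y$W), x$W),
         b = shape_like(f(x$b, y$b), x$b))
  }, a, b, SIMPLIFY = FALSE)
}

tree_map <- function(a, f) {
  lapply(a, function(x) {
    if (is.null(x)) return(NULL)
    list(W = shape_like(f(x$W), x$W), b = shape_like(f(x$b), x$b))
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Monotone counter used to tag smashed batches and gradient packets so a
# stale packet (one produced for a different batch) is detected; never
# touches the RNG stream.
.tag_env <- new.env(parent = emptyenv())
.tag_env$n <- 0L
next_tag <- function() {
  .tag_env$n <- .tag_env$n + 1L
  .tag_env$n
}
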